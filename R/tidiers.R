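# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Hertz-Sneddon fit
#'
#' @param x A `cm_hertz_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @method tidy cm_hertz_fit
#' @export
tidy.cm_hertz_fit <- function(x, ...) {
  tibble::tibble(term = c("E", "fit_range_max"),
                 estimate = c(x$E_Pa, x$fit_range_max_nm),
                 unit = c("Pa", "nm"))
}

#' @rdname tidy.cm_hertz_fit
#' @return For `glance`: one row of fit diagnostics.
#' @method glance cm_hertz_fit
#' @export
glance.cm_hertz_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, rss = x$rss, n = x$n_fit, valid = x$valid)
}

#' Tidy a swelling-kinetics fit
#'
#' @param x A `cm_swell_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `unit`.
#' @method tidy cm_swell_fit
#' @export
tidy.cm_swell_fit <- function(x, ...) {
  tibble::tibble(term = c("R_in", "R_fin", "tau", "ratio"),
                 estimate = c(x$R_in_um, x$R_fin_um, x$tau_s, x$ratio),
                 unit = c("um", "um", "s", ""))
}

#' @rdname tidy.cm_swell_fit
#' @return For `glance`: one row of fit diagnostics.
#' @method glance cm_swell_fit
#' @export
glance.cm_swell_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 identifiable = x$identifiable %||% TRUE)
}

#' Tidy a Mann-Whitney test result
#'
#' @param x A `cm_mwu`.
#' @param ... Unused.
#' @return One-row tibble: `U`, `p.value`, `n1`, `n2`, `method`, `stars`.
#' @method tidy cm_mwu
#' @export
tidy.cm_mwu <- function(x, ...) {
  tibble::tibble(U = x$U, p.value = x$p, n1 = x$n1, n2 = x$n2,
                 method = x$method, stars = x$stars)
}
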