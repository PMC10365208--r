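# Internal helpers shared across modules.

# pN -> nm cantilever deflection for spring constant k in N/m:
# d[nm] = F[pN] * 1e-12 / k * 1e9 = F * 1e-3 / k
deflection_nm <- function(force_pN, k_N_per_m) force_pN * 1e-3 / k_N_per_m

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg, class = "cellmech_error")
}

#' Run code with a fixed RNG seed
#'
#' All generators route their randomness through this helper so that a single
#' integer seed makes a whole simulation reproducible. The caller's RNG state
#' is restored afterwards.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  abort_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed),
           "`seed` must be a single integer")
  withr::with_seed(as.integer(seed), force(code))
}

# Derive a stage-specific child seed from a master seed so stages draw from
# independent streams. Kept below 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(afm = 101L, swelling = 211L, sted = 307L, coloc = 401L,
               rtdc = 503L, stats = 601L)
  as.integer((as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483647L)
}

# ---- image helpers -------------------------------------------------------

# Shift a matrix by (di, dj), padding with `fill`.
shift_mat <- function(m, di, dj, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  si <- max(1, 1 - di):min(n, n - di)
  sj <- max(1, 1 - dj):min(p, p - dj)
  out[si + di, sj + dj] <- m[si, sj, drop = FALSE]
  out
}

# 3x3 grayscale dilation (maximum filter), replicate-free (pads with -Inf).
dilate3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- pmax(out, shift_mat(m, di, dj, -Inf))
  }
  out
}

#' Grayscale morphological reconstruction by dilation
#'
#' Iteratively dilates `seed` under the ceiling `mask` (seed <= mask required)
#' until stability. Used for the h-maxima transform.
#' @noRd
grey_reconstruct <- function(seed, mask, max_iter = 10000L) {
  stopifnot(all(dim(seed) == dim(mask)))
  rec <- pmin(seed, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(dilate3(rec), mask)
    if (identical(nxt, rec)) break
    rec <- nxt
  }
  rec
}

#' H-maxima marker extraction
#'
#' Suppresses maxima of height less than `h` (h-maxima transform
#' HMAX = reconstruct(f - h, f)) and returns the dome regions of the
#' surviving maxima as a binary marker image: pixels where the h-dome
#' image f - HMAX reaches h (within a small tolerance).
#' @noRd
hmaxima_markers <- function(f, h, tol = 1e-6) {
  abort_if(h <= 0, "`h` must be positive")
  rec <- grey_reconstruct(f - h, f)
  (f - rec) >= (h - tol)
}

# Count of 8-neighbors that are TRUE, for a logical matrix.
neighbor_count8 <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    s <- s + shift_mat(m * 1L, di, dj, 0L)
  }
  s
}

# Linear (column-major) indices of TRUE pixels as (row, col) matrix.
which_rc <- function(m) which(m, arr.ind = TRUE)

# Gaussian FWHM (same units as sigma) -> sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
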