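# File interfaces: force-curve TSV dialect, TIFF stacks with YAML sidecars,
# CSV tables for truth/contours/results.

#' Write force curves to a directory of TSV files
#'
#' One file per curve: `#`-prefixed `key=value` header lines
#' (`spring_constant_N_per_m`, `cell_id`, `grid_row`, `grid_col`), then two
#' tab-separated columns `z_nm`, `force_pN`.
#'
#' @param curves Long curve tibble (as from [sim_force_curves()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_force_curves <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- curves |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_map(function(df, key) {
      path <- file.path(dir, paste0(key$curve_id, ".tsv"))
      hdr <- c(
        sprintf("# spring_constant_N_per_m=%.6g", df$k_N_per_m[1]),
        sprintf("# cell_id=%s", df$cell_id[1]),
        sprintf("# grid_row=%d", as.integer(df$grid_row[1])),
        sprintf("# grid_col=%d", as.integer(df$grid_col[1])),
        "z_nm\tforce_pN")
      body <- sprintf("%.6f\t%.6f", df$z_nm, df$force_pN)
      writeLines(c(hdr, body), path)
      path
    })
  invisible(unlist(paths))
}

#' Read force curves from a directory of TSV files
#'
#' @param dir Directory of `.tsv` files written in the format of
#'   [write_force_curves()].
#' @return Long curve tibble: `cell_id`, `curve_id`, `grid_row`, `grid_col`,
#'   `k_N_per_m`, `z_nm`, `force_pN`.
#' @export
read_force_curves <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  abort_if(!length(files), paste("no .tsv curves under", dir))
  purrr::map_dfr(files, function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                              sep = "\t")
    tibble::tibble(
      cell_id = meta[["cell_id"]],
      curve_id = sub("\\.tsv$", "", basename(path)),
      grid_row = as.integer(meta[["grid_row"]]),
      grid_col = as.integer(meta[["grid_col"]]),
      k_N_per_m = as.numeric(meta[["spring_constant_N_per_m"]]),
      z_nm = body$z_nm, force_pN = body$force_pN)
  })
}

#' Write an image stack as multi-page TIFF with a YAML sidecar
#'
#' Intensities are rescaled to the stack maximum and stored as 16-bit; the
#' sidecar (`<stem>.yaml`) records `pixel_size_nm` and any extra metadata
#' (e.g. `frame_rate_hz`, `t0_s`, channel names).
#'
#' @param frames A matrix or list of matrices.
#' @param path Output `.tif` path.
#' @param pixel_size_nm Pixel size, nm/px.
#' @param meta Named list of extra sidecar fields.
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(frames, path, pixel_size_nm, meta = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  mx <- max(vapply(frames, max, numeric(1)), 1e-12)
  pages <- lapply(frames, function(f) pmin(pmax(f / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  side <- c(list(pixel_size_nm = pixel_size_nm, intensity_scale = mx), meta)
  yaml::write_yaml(side, sub("\\.tiff?$", ".yaml", path))
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path `.tif` path (sidecar `<stem>.yaml` must exist).
#' @return List: `frames` (list of matrices, original intensity scale),
#'   `meta` (sidecar contents incl. `pixel_size_nm`).
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- yaml::read_yaml(sub("\\.tiff?$", ".yaml", path))
  sc <- side$intensity_scale %||% 1
  list(frames = lapply(pages, function(p) p * sc), meta = side)
}

#' Write a ground-truth table
#'
#' CSV with columns `id`, `stage`, `parameter`, `value`, `units`.
#'
#' @param truth Truth tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' Write RT-DC event contours
#'
#' Long CSV: `event_id`, `x_px`, `y_px` (vertices in order), plus an
#' optional companion `<stem>_masks.csv` with mask areas.
#'
#' @param contours Contour tibble.
#' @param path Output CSV path.
#' @param mask_areas Optional mask-area tibble.
#' @return Invisibly, `path`.
#' @export
write_contours <- function(contours, path, mask_areas = NULL) {
  readr::write_csv(contours, path)
  if (!is.null(mask_areas))
    readr::write_csv(mask_areas, sub("\\.csv$", "_masks.csv", path))
  invisible(path)
}

#' Read RT-DC event contours
#'
#' @param path CSV path written by [write_contours()].
#' @return List: `contours`, `mask_areas` (NULL if no companion file).
#' @export
read_contours <- function(path) {
  contours <- readr::read_csv(path, show_col_types = FALSE)
  mpath <- sub("\\.csv$", "_masks.csv", path)
  masks <- if (file.exists(mpath))
    readr::read_csv(mpath, show_col_types = FALSE) else NULL
  list(contours = contours, mask_areas = masks)
}
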