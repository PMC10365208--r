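# Super-resolution morphometry: structure masks, meshwork density,
# skeleton-based filament length and branching, Manders colocalization.

#' Segment fluorescent structures
#'
#' Threshold-based structure mask restricted to a region of interest.
#'
#' @param img Numeric matrix (intensity counts).
#' @param roi Logical matrix, same shape (cell footprint); default whole frame.
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"` (intensities strictly above
#'   are kept).
#' @param smooth_sigma_px Optional Gaussian denoising before thresholding
#'   (default 0 = none); useful on shot-noise-limited images.
#' @return Logical structure mask.
#' @export
segment_structures <- function(img, roi = NULL, method = c("otsu", "fixed"),
                               value = NULL, smooth_sigma_px = 0) {
  method <- match.arg(method)
  roi <- roi %||% matrix(TRUE, nrow(img), ncol(img))
  abort_if(!any(roi), "ROI is empty")
  abort_if(any(dim(img) != dim(roi)), "ROI shape mismatch")
  if (smooth_sigma_px > 0) img <- as.matrix(EBImage::gblur(img, smooth_sigma_px))
  if (method == "otsu") {
    v <- img[roi]
    abort_if(diff(range(v)) <= .Machine$double.eps,
             "uniform image: Otsu undefined, use a fixed threshold")
    sc <- max(v)
    thr <- EBImage::otsu(EBImage::Image(pmax(img, 0) / sc), range = c(0, 1)) * sc
  } else {
    abort_if(is.null(value), "fixed thresholding needs `value`")
    thr <- value
  }
  (img > thr) & roi
}

#' Fluorescence density over a region of interest
#'
#' Percentage of the ROI's total fluorescence intensity that falls on
#' structure (above-threshold) pixels:
#' `100 * sum(I[structure]) / sum(I[ROI])`. The area-fraction variant
#' (`100 * #structure / #ROI`) is exposed through `mode`.
#'
#' @param img Intensity matrix.
#' @param roi Logical ROI mask.
#' @param structure Logical structure mask (subset of the ROI).
#' @param mode `"intensity"` (default) or `"area"`.
#' @return Density in percent (0-100).
#' @export
density_percent <- function(img, roi, structure, mode = c("intensity", "area")) {
  mode <- match.arg(mode)
  if (mode == "area") return(100 * sum(structure & roi) / sum(roi))
  tot <- sum(img[roi])
  abort_if(tot <= 0, "zero total ROI intensity")
  100 * sum(img[structure & roi]) / tot
}

# ---- skeletonization ------------------------------------------------------

# Guo-Hall thinning to a 1-px-wide 8-connected skeleton. Chosen over
# Zhang-Suen because it leaves diagonal strokes intact (Zhang-Suen reduces
# oblique bands to a two-pixel staircase whose tip keeps satisfying the
# deletion rule, unzipping the line). Neighbors p2..p9 run clockwise from
# north; rows grow southwards.
thin_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 0:1) {
      p2 <- shift_mat(m,  1,  0, FALSE)   # N
      p3 <- shift_mat(m,  1, -1, FALSE)   # NE
      p4 <- shift_mat(m,  0, -1, FALSE)   # E
      p5 <- shift_mat(m, -1, -1, FALSE)   # SE
      p6 <- shift_mat(m, -1,  0, FALSE)   # S
      p7 <- shift_mat(m, -1,  1, FALSE)   # SW
      p8 <- shift_mat(m,  0,  1, FALSE)   # W
      p9 <- shift_mat(m,  1,  1, FALSE)   # NW
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      mm <- if (pass == 0) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      del <- m & C == 1 & N >= 2 & N <= 3 & !mm
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Skeleton pixel graph: vertices are skeleton pixels; axial neighbors are
# joined with weight 1, diagonal neighbors with weight sqrt(2) but only when
# no axial 2-step path exists (redundant diagonal chords of the thinning
# staircase are dropped, so degrees reflect the true line topology).
skeleton_graph <- function(skel) {
  rc <- which_rc(skel)
  n <- nrow(rc)
  idx <- matrix(0L, nrow(skel), ncol(skel))
  idx[skel] <- seq_len(n)
  edges <- list(); wts <- list()
  add_edges <- function(keep_mat, di, dj, w) {
    ij <- which_rc(keep_mat)
    if (!nrow(ij)) return()
    from <- idx[ij]
    to <- idx[cbind(ij[, 1] + di, ij[, 2] + dj)]
    edges[[length(edges) + 1]] <<- rbind(from, to)
    wts[[length(wts) + 1]] <<- rep(w, length(from))
  }
  has <- function(di, dj) shift_mat(skel, -di, -dj, FALSE)  # neighbor at +step
  add_edges(skel & has(1, 0), 1, 0, 1)
  add_edges(skel & has(0, 1), 0, 1, 1)
  # diagonal (1,1): redundant if (1,0) or (0,1) neighbor present
  add_edges(skel & has(1, 1) & !has(1, 0) & !has(0, 1), 1, 1, sqrt(2))
  # diagonal (1,-1): redundant if (1,0) or (0,-1) neighbor present
  add_edges(skel & has(1, -1) & !has(1, 0) & !has(0, -1), 1, -1, sqrt(2))
  if (!length(edges)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  } else {
    g <- igraph::make_graph(as.vector(do.call(cbind, edges)), n = n,
                            directed = FALSE)
    igraph::E(g)$weight <- unlist(wts)
  }
  list(g = g, rc = rc, idx = idx)
}

# Remove spur branches: leaf-to-junction paths of <= prune_px pixels are
# deleted from the graph (iterated until stable). Returns the pruned graph
# and the surviving vertex ids (into the original rc table).
prune_spurs_graph <- function(g, prune_px) {
  keep <- seq_len(igraph::vcount(g))
  if (prune_px <= 0) return(list(g = g, keep = keep))
  repeat {
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) break
    leaves <- which(deg == 1)
    if (!length(leaves)) break
    adj <- igraph::adjacent_vertices(g, seq_len(igraph::vcount(g)))
    drop <- integer(0)
    for (leaf in leaves) {
      path <- leaf; cur <- leaf; prev <- 0L; hit <- FALSE
      for (s in seq_len(prune_px)) {
        nxts <- setdiff(as.integer(adj[[cur]]), prev)
        if (!length(nxts)) break
        nxt <- nxts[1]
        if (deg[nxt] >= 3) { hit <- TRUE; break }
        path <- c(path, nxt); prev <- cur; cur <- nxt
      }
      if (hit) drop <- c(drop, path)
    }
    drop <- unique(drop)
    if (!length(drop)) break
    keep <- keep[-drop]
    g <- igraph::delete_vertices(g, drop)
  }
  list(g = g, keep = keep)
}

# Decompose a skeleton component into maximal degree-2 chains (segments
# between endpoints/junctions; isolated cycles handled too), then measure
# each chain as a polygonal path resampled every `step` pixels. This removes
# the orientation-dependent overestimate of raw 8-connected step counting.
skeleton_length_px <- function(sub, coords, step = 4L) {
  ne <- igraph::ecount(sub)
  if (ne == 0) return(0)
  deg <- igraph::degree(sub)
  visited <- rep(FALSE, ne)
  adj_e <- igraph::incident_edges(sub, seq_len(igraph::vcount(sub)))
  total <- 0
  walk_from <- function(v0, e0) {
    # returns vertex sequence along the chain starting with edge e0
    seq_v <- v0
    e <- e0
    cur <- v0
    repeat {
      visited[e] <<- TRUE
      ends <- igraph::ends(sub, e, names = FALSE)
      nxt <- if (ends[1] == cur) ends[2] else ends[1]
      seq_v <- c(seq_v, nxt)
      cur <- nxt
      if (deg[cur] != 2) break
      es <- as.integer(adj_e[[cur]])
      es <- es[!visited[es]]
      if (!length(es)) break   # closed loop back at start
      e <- es[1]
    }
    seq_v
  }
  chain_len <- function(seq_v) {
    xy <- coords[seq_v, , drop = FALSE]
    n <- nrow(xy)
    idx <- unique(c(seq(1, n, by = step), n))
    p <- xy[idx, , drop = FALSE]
    sum(sqrt(rowSums(diff(p)^2)))
  }
  terminals <- which(deg != 2)
  for (v in terminals) {
    for (e in as.integer(adj_e[[v]])) {
      if (!visited[e]) total <- total + chain_len(walk_from(v, e))
    }
  }
  # leftover cycles (every vertex degree 2)
  while (any(!visited)) {
    e <- which(!visited)[1]
    v <- igraph::ends(sub, e, names = FALSE)[1]
    total <- total + chain_len(walk_from(v, e))
  }
  total
}

#' Skeletonize a structure mask and measure filaments
#'
#' Thins the mask to a 1-px skeleton (Guo-Hall), prunes spur branches
#' shorter than `prune_spur_px`, labels 8-connected skeleton components as
#' filaments and measures each one's geodesic length (ordered skeleton
#' chains measured as polygonal paths, which avoids the orientation bias of
#' raw pixel-step counting; branched filaments use the total length of the
#' skeleton tree) and branch points (skeleton pixels with 3+ skeleton
#' neighbors on the reduced topology graph, adjacent branch pixels merged
#' into one junction cluster). Filaments not longer than `min_length_nm`
#' are flagged and excluded from downstream summaries.
#'
#' @param mask Logical structure mask.
#' @param pixel_size_nm nm per pixel.
#' @param min_length_nm Retention cutoff; only strictly longer filaments are
#'   retained (default 260 nm, the experimental resolution limit).
#' @param prune_spur_px Spur-pruning cap in px (default 3).
#' @return Object of class `cm_filaments`: list with `filaments` (tibble:
#'   `filament_id`, `length_um`, `n_branch_points`, `n_px`, `retained`),
#'   `skeleton` (logical matrix), `pixel_size_nm`.
#' @export
skeletonize_and_measure <- function(mask, pixel_size_nm, min_length_nm = 260,
                                    prune_spur_px = 3) {
  abort_if(!is.logical(mask) || !is.matrix(mask), "mask must be a logical matrix")
  empty <- structure(list(
    filaments = tibble::tibble(filament_id = integer(), length_um = numeric(),
                               n_branch_points = integer(), n_px = integer(),
                               retained = logical()),
    skeleton = mask & FALSE, pixel_size_nm = pixel_size_nm),
    class = "cm_filaments")
  if (!any(mask)) return(empty)
  skel0 <- thin_mask(mask)
  if (!any(skel0)) return(empty)
  sg0 <- skeleton_graph(skel0)
  pr <- prune_spurs_graph(sg0$g, prune_spur_px)
  g <- pr$g
  rc <- sg0$rc[pr$keep, , drop = FALSE]
  skel <- matrix(FALSE, nrow(mask), ncol(mask))
  skel[rc] <- TRUE
  deg <- igraph::degree(g)
  branch_px <- matrix(FALSE, nrow(mask), ncol(mask))
  branch_px[rc[deg >= 3, , drop = FALSE]] <- TRUE
  bl <- EBImage::bwlabel(EBImage::Image(branch_px * 1))  # 8-connected clusters
  blm <- matrix(as.integer(EBImage::imageData(bl)), nrow(mask), ncol(mask))
  comp <- igraph::components(g)
  # end correction: thinning retracts stroke ends by about the cap radius;
  # extend every terminal by its distance-transform value minus half a pixel
  dt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  rows <- purrr::map_dfr(seq_len(comp$no), function(ci) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    len_px <- skeleton_length_px(sub, rc[vs, , drop = FALSE])
    term <- vs[deg[vs] == 1]
    if (length(vs) == 1) term <- vs    # isolated pixel: one cap each side
    if (length(term))
      len_px <- len_px + sum(pmax(dt[rc[term, , drop = FALSE]] - 0.5, 0))
    pix <- rc[vs, , drop = FALSE]
    clusters <- unique(blm[pix][blm[pix] > 0])
    tibble::tibble(filament_id = ci,
                   length_um = len_px * pixel_size_nm / 1000,
                   n_branch_points = length(clusters),
                   n_px = length(vs))
  })
  rows$retained <- rows$length_um * 1000 > min_length_nm
  structure(list(filaments = rows, skeleton = skel,
                 pixel_size_nm = pixel_size_nm),
            class = "cm_filaments")
}

#' @export
print.cm_filaments <- function(x, ...) {
  cat(sprintf("Filament graph: %d components, %d retained (> cutoff)\n",
              nrow(x$filaments), sum(x$filaments$retained)))
  invisible(x)
}

#' Per-cell filament summaries
#'
#' Median filament length and mean branch points per filament over retained
#' (longer-than-cutoff) filaments.
#'
#' @param graph A `cm_filaments` object (or its `filaments` tibble).
#' @return One-row tibble: `n_filaments`, `median_length_um`,
#'   `mean_branches`, `defined`.
#' @export
branch_stats <- function(graph) {
  fil <- if (inherits(graph, "cm_filaments")) graph$filaments else graph
  kept <- fil[fil$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(tibble::tibble(n_filaments = 0L, median_length_um = NA_real_,
                          mean_branches = NA_real_, defined = FALSE))
  }
  tibble::tibble(n_filaments = nrow(kept),
                 median_length_um = stats::median(kept$length_um),
                 mean_branches = mean(kept$n_branch_points),
                 defined = TRUE)
}

#' Manders colocalization percentage
#'
#' Fraction of the assessed channel's signal lying where the reference
#' channel is above threshold, as a percentage. Default is the
#' intensity-weighted Manders coefficient
#' `100 * sum(Ia[b-mask]) / sum(Ia[ROI])`; `mode = "pixel"` gives the
#' pixel-count variant `100 * |a-mask & b-mask| / |a-mask|`.
#'
#' @param img_a Assessed channel (e.g. actin), matrix.
#' @param img_b Reference channel (e.g. myosin), matrix, same shape.
#' @param roi Logical ROI (default whole frame).
#' @param threshold_a,threshold_b Channel thresholds: `"otsu"` or a number.
#'   `threshold_a` is only used in pixel mode.
#' @param mode `"intensity"` (default) or `"pixel"`.
#' @return Object of class `cm_coloc`: list with `manders_percent`, `mode`,
#'   `threshold_a`, `threshold_b`.
#' @export
manders_percent <- function(img_a, img_b, roi = NULL,
                            threshold_a = "otsu", threshold_b = "otsu",
                            mode = c("intensity", "pixel")) {
  mode <- match.arg(mode)
  abort_if(any(dim(img_a) != dim(img_b)), "channel shapes differ")
  roi <- roi %||% matrix(TRUE, nrow(img_a), ncol(img_a))
  thr <- function(img, t) {
    if (identical(t, "otsu")) {
      segment_structures(img, roi, "otsu")
    } else {
      segment_structures(img, roi, "fixed", value = t)
    }
  }
  mask_b <- thr(img_b, threshold_b)
  if (mode == "intensity") {
    denom <- sum(img_a[roi])
    abort_if(denom <= 0, "assessed channel has zero ROI intensity")
    pct <- 100 * sum(img_a[mask_b & roi]) / denom
    ta <- NA_real_
  } else {
    mask_a <- thr(img_a, threshold_a)
    denom <- sum(mask_a)
    abort_if(denom == 0, "assessed channel mask is empty")
    pct <- 100 * sum(mask_a & mask_b) / denom
    ta <- threshold_a
  }
  structure(list(manders_percent = pct, mode = mode,
                 threshold_a = ta, threshold_b = threshold_b),
            class = "cm_coloc")
}

#' @export
print.cm_coloc <- function(x, ...) {
  cat(sprintf("Manders (%s mode): %.1f%%\n", x$mode, x$manders_percent))
  invisible(x)
}
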