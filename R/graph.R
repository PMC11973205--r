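# Tier 2 substrate: membrane-contact detection, Delaunay spatial graphs,
# radius-limited k-nearest neighbors, and neighbor-distance diagnostics.
# Contacts use border-to-border (membrane) distance under the disc model;
# Delaunay and k-NN use center-to-center distance. Two metrics, deliberately.

as_ppp <- function(cells) {
  pad <- 1
  spatstat.geom::ppp(cells$x_um, cells$y_um,
                     window = spatstat.geom::owin(range(cells$x_um) + c(-pad, pad),
                                                  range(cells$y_um) + c(-pad, pad)),
                     checkdup = FALSE)
}

cell_radii <- function(cells, default_radius_um = 5) {
  if ("radius_um" %in% names(cells)) cells$radius_um
  else rep(default_radius_um, nrow(cells))
}

#' Cell-cell contacts under the membrane distance rule
#'
#' Two cells are in contact when the distance between their outer
#' membranes is at most `threshold_um` (inclusive). Cells are modeled as
#' discs, so the membrane distance is
#' `max(0, centroid distance - r_i - r_j)`; overlapping discs have
#' distance 0 and always touch.
#'
#' @param cells cell table for a single region.
#' @param threshold_um contact range in micrometres (default 6).
#' @param default_radius_um radius for cells lacking `radius_um`.
#' @return Object of class `tme_adjacency`: a data.frame with columns
#'   `a`, `b` (row indices into `cells`, a < b), `cell_a`, `cell_b`
#'   (cell ids) and `border_um`; attribute `n_cells`.
#' @export
contact_pairs <- function(cells, threshold_um = 6, default_radius_um = 5) {
  if (threshold_um < 0) stop("threshold_um must be >= 0", call. = FALSE)
  stopifnot(nrow(cells) >= 1, length(unique(cells$roi_id)) == 1)
  r <- cell_radii(cells, default_radius_um)
  out <- data.frame(a = integer(0), b = integer(0),
                    cell_a = character(0), cell_b = character(0),
                    border_um = numeric(0))
  if (nrow(cells) >= 2) {
    cp <- spatstat.geom::closepairs(as_ppp(cells),
                                    rmax = threshold_um + 2 * max(r),
                                    what = "ijd", twice = FALSE)
    border <- pmax(0, cp$d - r[cp$i] - r[cp$j])
    keep <- border <= threshold_um
    i <- pmin(cp$i[keep], cp$j[keep]); j <- pmax(cp$i[keep], cp$j[keep])
    ord <- order(i, j)
    out <- data.frame(a = i[ord], b = j[ord],
                      cell_a = cells$cell_id[i][ord],
                      cell_b = cells$cell_id[j][ord],
                      border_um = border[keep][ord],
                      stringsAsFactors = FALSE)
  }
  structure(out, n_cells = nrow(cells), roi_id = cells$roi_id[1],
            threshold_um = threshold_um,
            class = c("tme_adjacency", "data.frame"))
}

#' Delaunay spatial graph of cell centroids
#'
#' Edges are the Delaunay triangulation of the centroids. Degenerate
#' inputs fall back to documented conventions: fewer than 3 points give
#' the complete graph; collinear points give the chain graph of the
#' sorted points.
#'
#' @param cells cell table for a single region.
#' @return Object of class `tme_spatial_graph`: data.frame `a`, `b`
#'   (indices, a < b), `dist_um`; attribute `n_cells`.
#' @export
delaunay_graph <- function(cells) {
  n <- nrow(cells)
  stopifnot(n >= 1)
  x <- cells$x_um; y <- cells$y_um
  edge_df <- function(a, b) {
    i <- pmin(a, b); j <- pmax(a, b)
    ord <- order(i, j)
    i <- i[ord]; j <- j[ord]
    dup <- duplicated(paste(i, j))
    i <- i[!dup]; j <- j[!dup]
    data.frame(a = i, b = j,
               dist_um = sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  }
  collinear <- function() {
    if (n <= 2) return(TRUE)
    dx <- x - x[1]; dy <- y - y[1]
    cross <- dx * dy[2] - dy * dx[2]
    scale <- max(abs(c(dx, dy)), 1)
    all(abs(cross) <= 1e-9 * scale^2)
  }
  edges <- if (n == 1) {
    data.frame(a = integer(0), b = integer(0), dist_um = numeric(0))
  } else if (n < 3 || collinear()) {
    if (n < 3) {
      cmb <- utils::combn(n, 2)
      edge_df(cmb[1, ], cmb[2, ])
    } else {
      ord <- order(x, y)  # chain along the line
      edge_df(ord[-n], ord[-1])
    }
  } else {
    dd <- tryCatch(deldir::deldir(x, y), error = function(e) NULL)
    if (is.null(dd)) {
      ord <- order(x, y)
      edge_df(ord[-n], ord[-1])
    } else {
      edge_df(dd$delsgs$ind1, dd$delsgs$ind2)
    }
  }
  structure(edges, n_cells = n, roi_id = cells$roi_id[1],
            class = c("tme_spatial_graph", "data.frame"))
}

#' k nearest neighbors within a radius
#'
#' For each cell, the up-to-`k` nearest other cells by centroid distance,
#' restricted to `radius_um`; ties at the k-th distance are broken by the
#' smaller cell id. Cells with no in-radius neighbor are flagged isolated.
#'
#' @param cells cell table for a single region.
#' @param k neighbor count (default 10).
#' @param radius_um search radius in micrometres (default 40).
#' @return Object of class `tme_neighbors`: list with `cell_id`,
#'   `neighbors` (list of integer index vectors sorted by distance),
#'   `dists` (matching distances), `k`, `radius_um`.
#' @export
knn_within_radius <- function(cells, k = 10, radius_um = 40) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (radius_um <= 0) stop("radius_um must be positive", call. = FALSE)
  n <- nrow(cells)
  stopifnot(n >= 1)
  neighbors <- rep(list(integer(0)), n)
  dists <- rep(list(numeric(0)), n)
  if (n >= 2) {
    cp <- spatstat.geom::closepairs(as_ppp(cells), rmax = radius_um,
                                    what = "ijd", twice = TRUE)
    if (length(cp$i)) {
      ord <- order(cp$i, cp$d, cells$cell_id[cp$j])
      i <- cp$i[ord]; j <- cp$j[ord]; d <- cp$d[ord]
      rank_in_grp <- stats::ave(seq_along(i), i, FUN = seq_along)
      keep <- rank_in_grp <= k
      i <- i[keep]; j <- j[keep]; d <- d[keep]
      f <- factor(i, levels = seq_len(n))
      neighbors <- split(j, f)
      dists <- split(d, f)
    }
  }
  structure(list(cell_id = cells$cell_id, neighbors = neighbors,
                 dists = dists, k = k, radius_um = radius_um,
                 roi_id = cells$roi_id[1]),
            class = "tme_neighbors")
}

#' Neighbor-distance histogram and modal spacing
#'
#' Histogram of Delaunay edge lengths at 1 um bins with the modal bin;
#' used to justify the neighborhood search radius (tissues at typical IMC
#' density have a modal spacing near 10 um, and nearly all neighbors fall
#' within 40 um).
#'
#' @param graph a `tme_spatial_graph` (or any data.frame with `dist_um`).
#' @return list with `histogram` (data.frame `bin_lo`, `bin_hi`, `count`)
#'   and `modal_um` (lower edge of the modal 1 um bin; ties -> smallest).
#' @export
neighbor_distance_stats <- function(graph) {
  d <- graph$dist_um
  if (is.null(d) || length(d) == 0) {
    stop("graph has no edges", call. = FALSE)
  }
  bin <- floor(d)
  tab <- table(bin)
  lo <- as.integer(names(tab))
  hist <- data.frame(bin_lo = lo, bin_hi = lo + 1L,
                     count = as.integer(tab))
  modal <- hist$bin_lo[which.max(hist$count)]
  list(histogram = hist, modal_um = modal)
}
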