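#' Intensity-based segmentation of mRNA particles and granules
#'
#' Particles are segmented purely on fluorescence intensity (no shape
#' filtering): voxels above a threshold are grouped into connected
#' components, 8-connectivity in 2D and 26-connectivity in 3D. Each particle
#' reports its pixel/voxel count, intensity-weighted centroid in nm and, in
#' 2D, its circularity `4*pi*area / perimeter^2`.
#'
#' @name segment
NULL

## global Otsu threshold on raw intensities (histogram-based, any dims)
.otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  mx <- max(v)
  if (mx <= 0) return(Inf)
  ## EBImage's otsu works on [0,1] grayscale; shape of the data is irrelevant
  img <- EBImage::Image(matrix(v / mx, ncol = 1))
  as.numeric(EBImage::otsu(img, range = c(0, 1))) * mx
}

## label 3D foreground (26-connectivity) via graph components
.label3d <- function(fg) {
  d <- dim(fg)
  idx <- which(fg)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(labels)
  rank <- integer(prod(d)); rank[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  edges <- list()
  offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  offs <- offs[offs$ox != 0 | offs$oy != 0 | offs$oz != 0, ]
  offs <- offs[1:(nrow(offs) / 2), ]       # forward half of the 26-neighborhood
  for (k in seq_len(nrow(offs))) {
    nx <- co[, 1] + offs$ox[k]; ny <- co[, 2] + offs$oy[k]
    nz <- co[, 3] + offs$oz[k]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nidx <- (nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]
    hit <- rank[nidx] > 0L
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <-
      cbind(seq_along(idx)[ok][hit], rank[nidx[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Segment an image into particles
#'
#' @param image a 2D matrix, 3D array, or [image_stack()].
#' @param method `"otsu"` for an automatic global threshold, or a numeric
#'   fixed threshold in ADU.
#' @param voxel_nm physical pixel/voxel size; taken from an `image_stack`
#'   automatically.
#' @return A `particle_set`: `labels` (integer array), `table` (data frame
#'   of id, n_px, centroid in nm, and circularity in 2D), `threshold`,
#'   `voxel_nm`.
#' @export
segment <- function(image, method = "otsu", voxel_nm = NULL) {
  if (inherits(image, "image_stack")) {
    if (is.null(voxel_nm)) voxel_nm <- image$voxel_nm
    image <- image$data
    if (dim(image)[3] == 1L) image <- image[, , 1]
  }
  image <- as.array(image)
  nd <- length(dim(image))
  stopifnot(nd %in% c(2L, 3L))
  if (is.null(voxel_nm)) voxel_nm <- c(56, 56, 200)[seq_len(nd)]
  voxel_nm <- voxel_nm[seq_len(nd)]
  thr <- if (identical(method, "otsu")) .otsu_threshold(image) else
    as.numeric(method)
  fg <- image > thr
  if (!any(fg)) {
    tab <- data.frame(id = integer(0), n_px = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0))
    if (nd == 3L) tab$z_nm <- numeric(0) else tab$circularity <- numeric(0)
    return(structure(list(labels = array(0L, dim(image)), table = tab,
                          threshold = thr, voxel_nm = voxel_nm),
                     class = "particle_set"))
  }
  if (nd == 2L) {
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
    storage.mode(labels) <- "integer"
    shp <- EBImage::computeFeatures.shape(labels)
    ids <- seq_len(max(labels))
    circ <- pmin(4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2, 1)
  } else {
    labels <- .label3d(fg)
    ids <- seq_len(max(labels))
    circ <- NULL
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  co <- arrayInd(idx, dim(image))
  w <- image[idx]
  tab <- data.frame(
    id = ids,
    n_px = as.integer(tabulate(lab, length(ids))),
    x_nm = tapply(w * (co[, 1] - 0.5) * voxel_nm[1], lab, sum)[as.character(ids)] /
           tapply(w, lab, sum)[as.character(ids)],
    y_nm = tapply(w * (co[, 2] - 0.5) * voxel_nm[2], lab, sum)[as.character(ids)] /
           tapply(w, lab, sum)[as.character(ids)]
  )
  if (nd == 3L)
    tab$z_nm <- tapply(w * (co[, 3] - 0.5) * voxel_nm[3], lab, sum)[as.character(ids)] /
                tapply(w, lab, sum)[as.character(ids)]
  else
    tab$circularity <- as.numeric(circ)
  rownames(tab) <- NULL
  structure(list(labels = labels, table = tab, threshold = thr,
                 voxel_nm = voxel_nm),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat("particle_set:", nrow(x$table), "particles above threshold",
      signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Object-based overlap statistics between two particle sets
#'
#' A particle of set B overlaps a particle of set A iff they share at least
#' one pixel. Reports the per cent of B particles overlapping any A
#' particle, the particle-count ratio B:A, and for each A particle the per
#' cent of its area covered by overlapping B signal.
#'
#' @param particlesA,particlesB `particle_set`s on the same grid (A is the
#'   reference set, e.g. granules; B the query set, e.g. mRNA particles).
#' @return An `overlap_stats` list: `pct_B_overlapping`, `ratio_B_to_A`,
#'   `area_coverage` (per A particle, %), `pairs` (shared-pixel records).
#' @export
overlap_stats <- function(particlesA, particlesB) {
  stopifnot(inherits(particlesA, "particle_set"),
            inherits(particlesB, "particle_set"),
            all(dim(particlesA$labels) == dim(particlesB$labels)))
  la <- particlesA$labels; lb <- particlesB$labels
  nA <- nrow(particlesA$table); nB <- nrow(particlesB$table)
  shared <- la > 0L & lb > 0L
  pairs <- if (any(shared)) {
    pr <- data.frame(a = la[shared], b = lb[shared])
    agg <- stats::aggregate(rep(1L, nrow(pr)), by = list(a = pr$a, b = pr$b),
                            FUN = sum)
    names(agg)[3] <- "n_shared"
    agg[order(agg$a, agg$b), , drop = FALSE]
  } else {
    data.frame(a = integer(0), b = integer(0), n_shared = integer(0))
  }
  overlapping_b <- unique(pairs$b)
  pct_B <- if (nB > 0) 100 * length(overlapping_b) / nB else NA_real_
  ratio <- if (nA > 0 && nB > 0) nB / nA else NA_real_
  cover <- if (nA > 0) {
    cov_px <- tabulate(la[shared], nA)
    100 * cov_px / particlesA$table$n_px
  } else numeric(0)
  structure(list(pct_B_overlapping = pct_B, ratio_B_to_A = ratio,
                 area_coverage = cover, pairs = pairs,
                 n_A = nA, n_B = nB),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap: %.1f%% of %d B-particles overlap %d A-particles (ratio %.2f)\n",
              x$pct_B_overlapping, x$n_B, x$n_A, x$ratio_B_to_A))
  invisible(x)
}
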