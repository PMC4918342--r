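#' Sub-pixel 3D spot detection and intensity calibration
#'
#' Diffraction-limited spots are modeled as voxel-integrated 3D Gaussians of
#' fixed PSF width sitting on an affine local background
#' `a0 + ax*x + ay*y + az*z`. For a trial center all five linear parameters
#' (four plane coefficients and the Gaussian flux) are profiled out by linear
#' least squares, and only the three center coordinates are optimized, so the
#' fit is exact in the noiseless limit. Integrated intensity is the fitted
#' flux: the amplitude times the Gaussian volume, in ADU.
#'
#' @name spots
NULL

.shifted_max <- function(arr) {
  d <- dim(arr)
  mx <- array(-Inf, d)
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    if (ox == 0 && oy == 0 && oz == 0) next
    xs <- seq_len(d[1]) + ox; ys <- seq_len(d[2]) + oy; zs <- seq_len(d[3]) + oz
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    sub <- arr[xs[okx], ys[oky], zs[okz], drop = FALSE]
    mx[okx, oky, okz] <- pmax(mx[okx, oky, okz, drop = FALSE], sub)
  }
  mx
}

#' Pre-detect candidate spots
#'
#' Finds local maxima (26-neighborhood) above a threshold and suppresses
#' non-maximal candidates within one fit window. Candidates are returned in
#' deterministic order: descending intensity, ties broken by z, y, x.
#'
#' @param stack an [image_stack()].
#' @param threshold intensity cutoff in ADU, or `"auto"` for
#'   `median + k_auto * mad` of the whole stack (robust background
#'   statistics, insensitive to the sparse bright spots).
#' @param window fit window size in voxels (nx, ny, nz), odd integers.
#' @param k_auto multiplier for the `"auto"` threshold.
#' @return Integer matrix of candidate voxel indices (columns x, y, z),
#'   zero rows when nothing exceeds the threshold.
#' @export
predetect <- function(stack, threshold = "auto", window = c(7, 7, 5),
                      k_auto = 5) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- stack$data
  if (identical(threshold, "auto"))
    threshold <- stats::median(arr) + k_auto * stats::mad(arr)
  ## >= all neighbors but > at least one: plateaus of a peak survive (and are
  ## deduplicated by the suppression below), constant regions do not
  isx <- which(arr > threshold & arr >= .shifted_max(arr) &
                 arr > -.shifted_max(-arr), arr.ind = TRUE)
  if (nrow(isx) == 0L)
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  vals <- arr[isx]
  ord <- order(-vals, isx[, 3], isx[, 2], isx[, 1])
  isx <- isx[ord, , drop = FALSE]
  half <- floor(window / 2)
  keep <- logical(nrow(isx))
  for (i in seq_len(nrow(isx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- isx[keep, , drop = FALSE]
    close <- abs(prev[, 1] - isx[i, 1]) <= half[1] &
             abs(prev[, 2] - isx[i, 2]) <= half[2] &
             abs(prev[, 3] - isx[i, 3]) <= half[3]
    keep[i] <- !any(close)
  }
  out <- isx[keep, , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

## unit-flux voxel-integrated Gaussian weights along one axis
.axis_weights <- function(idx, center_nm, sigma, voxel) {
  edges <- c(idx - 1L, idx[length(idx)]) * voxel
  diff(stats::pnorm((edges - center_nm) / sigma))
}

#' Fit one spot
#'
#' @param stack an [image_stack()].
#' @param candidate integer voxel index (x, y, z), e.g. one row of
#'   [predetect()] output.
#' @param window fit window in voxels; clipped at stack borders, in which
#'   case the spot is flagged `"edge"`.
#' @param psf_sigma_nm fixed Gaussian widths used by the kernel.
#' @return One-row data frame: center in nm, integrated intensity (ADU),
#'   affine background coefficients (per nm), fit RSS, status
#'   (`"ok" | "edge" | "failed"`).
#' @export
fit_spot <- function(stack, candidate, window = c(7, 7, 5),
                     psf_sigma_nm = c(80, 80, 250)) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data); v <- stack$voxel_nm
  cand <- as.integer(candidate)
  half <- floor(window / 2)
  lo <- cand - half; hi <- cand + half
  edge <- any(lo < 1L) || any(hi > d)
  lo <- pmax(lo, 1L); hi <- pmin(hi, d)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  sub <- stack$data[ix, iy, iz, drop = FALSE]
  xc <- (ix - 0.5) * v[1]; yc <- (iy - 0.5) * v[2]; zc <- (iz - 0.5) * v[3]
  grid <- expand.grid(x = xc, y = yc, z = zc)
  yv <- as.vector(sub)

  rss_at <- function(p) {
    m <- .axis_weights(ix, p[1], psf_sigma_nm[1], v[1]) %o%
         .axis_weights(iy, p[2], psf_sigma_nm[2], v[2]) %o%
         .axis_weights(iz, p[3], psf_sigma_nm[3], v[3])
    X <- cbind(1, grid$x, grid$y, grid$z, as.vector(m))
    ft <- stats::.lm.fit(X, yv)
    sum(ft$residuals^2)
  }
  coefs_at <- function(p) {
    m <- .axis_weights(ix, p[1], psf_sigma_nm[1], v[1]) %o%
         .axis_weights(iy, p[2], psf_sigma_nm[2], v[2]) %o%
         .axis_weights(iz, p[3], psf_sigma_nm[3], v[3])
    X <- cbind(1, grid$x, grid$y, grid$z, as.vector(m))
    stats::.lm.fit(X, yv)
  }

  start <- (cand - 0.5) * v
  lower <- (lo - 1L) * v; upper <- hi * v
  res <- tryCatch(
    stats::optim(start, rss_at, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(factr = 10)),
    error = function(e) NULL
  )
  fail <- function(status) data.frame(
    x_nm = NA_real_, y_nm = NA_real_, z_nm = NA_real_,
    intensity = NA_real_, bg_a0 = NA_real_, bg_ax = NA_real_,
    bg_ay = NA_real_, bg_az = NA_real_, rss = NA_real_,
    status = status, stringsAsFactors = FALSE)
  if (is.null(res)) return(fail("failed"))
  ft <- coefs_at(res$par)
  flux <- ft$coefficients[5]
  if (!is.finite(flux) || flux <= 0) return(fail("failed"))
  data.frame(
    x_nm = res$par[1], y_nm = res$par[2], z_nm = res$par[3],
    intensity = flux,
    bg_a0 = ft$coefficients[1], bg_ax = ft$coefficients[2],
    bg_ay = ft$coefficients[3], bg_az = ft$coefficients[4],
    rss = sum(ft$residuals^2),
    status = if (edge) "edge" else "ok",
    stringsAsFactors = FALSE
  )
}

#' Detect and fit all spots in a stack
#'
#' Convenience pipeline: [predetect()] then [fit_spot()] per candidate.
#'
#' @inheritParams predetect
#' @inheritParams fit_spot
#' @return Data frame of fitted spots (possibly zero rows).
#' @export
detect_spots <- function(stack, threshold = "auto", window = c(7, 7, 5),
                         psf_sigma_nm = c(80, 80, 250), k_auto = 5) {
  cands <- predetect(stack, threshold, window, k_auto)
  if (nrow(cands) == 0L)
    return(fit_spot(stack, c(1L, 1L, 1L), window, psf_sigma_nm)[0, ])
  do.call(rbind, lapply(seq_len(nrow(cands)), function(i)
    fit_spot(stack, cands[i, ], window, psf_sigma_nm)))
}

#' Calibrate the single-mRNA unit intensity
#'
#' The unit is the integrated fluorescence of one mRNA, estimated from spots
#' fitted in a region of isolated single transcripts. The default estimator
#' is the median, robust against the bright tail of unresolved doublets.
#'
#' @param spots data frame of fitted spots (only `status == "ok"` used).
#' @param min_n minimum number of usable spots.
#' @param estimator `"median"` or `"mean"`.
#' @return An `intensity_unit` list: `unit` (ADU per mRNA), `estimator`, `n`.
#' @export
unit_intensity <- function(spots, min_n = 50, estimator = c("median", "mean")) {
  estimator <- match.arg(estimator)
  ints <- spots$intensity[spots$status == "ok"]
  ints <- ints[is.finite(ints) & ints > 0]
  if (length(ints) < min_n)
    stop("calibration error: ", length(ints), " usable spots, need ", min_n)
  unit <- if (estimator == "median") stats::median(ints) else mean(ints)
  structure(list(unit = unit, estimator = estimator, n = length(ints)),
            class = "intensity_unit")
}

#' Convert a cluster's integrated intensity to an mRNA copy number
#'
#' @param cluster a fitted spot (one-row data frame or list with
#'   `intensity`), or a bare numeric intensity.
#' @param unit an [unit_intensity()] calibration.
#' @return List with `count` (real) and `count_int` (nearest integer).
#' @export
count_mrnas <- function(cluster, unit) {
  stopifnot(inherits(unit, "intensity_unit"), unit$unit > 0)
  intensity <- if (is.numeric(cluster)) cluster else cluster$intensity
  count <- as.numeric(intensity) / unit$unit
  list(count = count, count_int = as.integer(round(count)))
}
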