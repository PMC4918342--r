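#' Inter-channel registration from fiducial beads
#'
#' Multi-color acquisitions carry a small inter-channel pixel shift.
#' Fiducial beads visible in both channels are matched by mutual nearest
#' neighbors, the shift is the mean displacement vector, and the alignment
#' precision is the RMS residual displacement after correction. The shift
#' model is a pure translation; spot coordinates are corrected exactly in
#' coordinate space, while stacks can be resampled (trilinear) for overlays.
#'
#' @name register
NULL

#' Match beads across channels by mutual nearest neighbors
#'
#' @param spotsA,spotsB data frames of fitted spots with `x_nm,y_nm,z_nm`.
#' @param max_radius_nm maximum pairing distance.
#' @return Data frame with indices `a`, `b`, displacement components
#'   (B minus A, nm) and `dist_nm`.
#' @export
match_beads <- function(spotsA, spotsB, max_radius_nm = 300) {
  if (nrow(spotsA) == 0L || nrow(spotsB) == 0L)
    stop("registration error: empty spot list")
  A <- as.matrix(spotsA[, c("x_nm", "y_nm", "z_nm")])
  B <- as.matrix(spotsB[, c("x_nm", "y_nm", "z_nm")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  nnA <- apply(d2, 1, which.min)          # A -> nearest B
  nnB <- apply(d2, 2, which.min)          # B -> nearest A
  mutual <- which(nnB[nnA] == seq_len(nrow(A)))
  pairs <- data.frame(a = mutual, b = nnA[mutual])
  disp <- B[pairs$b, , drop = FALSE] - A[pairs$a, , drop = FALSE]
  pairs$dist_nm <- sqrt(rowSums(disp^2))
  pairs$dx_nm <- disp[, 1]; pairs$dy_nm <- disp[, 2]; pairs$dz_nm <- disp[, 3]
  pairs <- pairs[pairs$dist_nm <= max_radius_nm, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("registration error: no bead pairs within max_radius")
  rownames(pairs) <- NULL
  pairs
}

#' Estimate the channel shift from matched bead pairs
#'
#' @param pairs output of [match_beads()] (>= 3 pairs).
#' @return A `shift_estimate`: `shift_nm` (mean displacement B-A), `n_pairs`,
#'   `precision_nm` (RMS residual 3D displacement after correction), and
#'   per-pair residuals.
#' @export
estimate_shift <- function(pairs) {
  if (nrow(pairs) < 3L)
    stop("registration error: need >= 3 bead pairs, got ", nrow(pairs))
  disp <- as.matrix(pairs[, c("dx_nm", "dy_nm", "dz_nm")])
  shift <- colMeans(disp)
  resid <- sweep(disp, 2, shift)
  rnorm2 <- sqrt(rowSums(resid^2))
  structure(list(shift_nm = shift, n_pairs = nrow(pairs),
                 precision_nm = sqrt(mean(rnorm2^2)),
                 residuals_nm = rnorm2),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("shift (%.1f, %.1f, %.1f) nm from %d beads; precision %.1f nm\n",
              x$shift_nm[1], x$shift_nm[2], x$shift_nm[3],
              x$n_pairs, x$precision_nm))
  invisible(x)
}

#' Apply (or undo) a channel shift
#'
#' Spots are translated exactly in coordinate space. Stacks are resampled by
#' trilinear interpolation (zero padding outside the field); a whole-voxel
#' shift reduces to an integer roll of the grid.
#'
#' @param x a spots data frame (with `x_nm,y_nm,z_nm`) or an [image_stack()].
#' @param shift_nm length-3 translation in nm (or a `shift_estimate`). Spots
#'   in the shifted channel are corrected by subtracting the shift.
#' @return The corrected object.
#' @export
apply_shift <- function(x, shift_nm) {
  if (inherits(shift_nm, "shift_estimate")) shift_nm <- shift_nm$shift_nm
  stopifnot(length(shift_nm) == 3L, all(is.finite(shift_nm)))
  if (is.data.frame(x)) {
    x$x_nm <- x$x_nm - shift_nm[1]
    x$y_nm <- x$y_nm - shift_nm[2]
    x$z_nm <- x$z_nm - shift_nm[3]
    return(x)
  }
  stopifnot(inherits(x, "image_stack"))
  o <- -shift_nm / x$voxel_nm            # content moves by -shift
  f <- floor(o); r <- o - f
  d <- dim(x$data)
  get_shifted <- function(off) {
    out <- array(0, d)
    src <- lapply(1:3, function(ax) {
      idx <- seq_len(d[ax]) - off[ax]
      idx
    })
    okx <- src[[1]] >= 1 & src[[1]] <= d[1]
    oky <- src[[2]] >= 1 & src[[2]] <= d[2]
    okz <- src[[3]] >= 1 & src[[3]] <= d[3]
    if (any(okx) && any(oky) && any(okz))
      out[okx, oky, okz] <- x$data[src[[1]][okx], src[[2]][oky],
                                   src[[3]][okz], drop = FALSE]
    out
  }
  acc <- array(0, d)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    w <- prod(ifelse(c(bx, by, bz) == 1, r, 1 - r))
    if (w == 0) next
    acc <- acc + w * get_shifted(f + c(bx, by, bz))
  }
  image_stack(acc, voxel_nm = x$voxel_nm, channel = x$channel)
}
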