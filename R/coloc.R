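#' Intensity-correlation co-localization: PCC, Costes thresholds, and
#' block-shuffle randomization significance
#'
#' PCC is the Pearson correlation of the two channels' voxel intensities
#' (1 perfect co-localization, 0 chance, -1 exclusion). PCC(Costes)
#' restricts the correlation to voxels above automatically determined
#' per-channel thresholds, chosen on the orthogonal regression line between
#' the channels so that the correlation of sub-threshold voxels is
#' non-positive; it runs from 0 (random) to 1 (high co-localization).
#' Significance is assessed by shuffling pixel blocks of one channel,
#' recomputing PCC(Costes) against the untouched channel n times, and
#' reporting the percentile of the observed value in that null.
#'
#' @name coloc
NULL

.as_array <- function(x) if (inherits(x, "image_stack")) x$data else as.array(x)

.roi_values <- function(img, roi) {
  a <- .as_array(img)
  if (is.null(roi)) as.vector(a) else a[roi]
}

#' Pearson correlation coefficient between two channels
#'
#' @param imgA,imgB arrays or [image_stack()]s on the same grid.
#' @param roi optional logical array selecting the region of interest.
#' @return Pearson r in [-1, 1].
#' @export
pearson <- function(imgA, imgB, roi = NULL) {
  a <- .roi_values(imgA, roi); b <- .roi_values(imgB, roi)
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("ROI must contain at least 2 voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined result: zero variance within ROI")
  stats::cor(a, b)
}

#' Costes automatic thresholds
#'
#' Fits the orthogonal (total least squares) regression `B = a*A + b`, then
#' walks the threshold pair down the regression line from the maximum of A
#' in 1% quantile steps; the first pair for which the PCC of voxels below
#' both thresholds is <= 0 is returned.
#'
#' @inheritParams pearson
#' @return List with `T_A`, `T_B`, `slope`, `intercept`, `flag` (TRUE when
#'   no threshold achieved non-positive sub-threshold PCC and the minimum
#'   intensities were returned instead).
#' @export
costes_threshold <- function(imgA, imgB, roi = NULL) {
  a <- .roi_values(imgA, roi); b <- .roi_values(imgB, roi)
  r_all <- pearson(a, b)
  if (r_all <= 0)
    stop("Costes thresholds undefined: channels are not positively correlated")
  ## orthogonal regression via the principal axis of the covariance
  cv <- stats::cov(cbind(a, b))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  slope <- ev[2] / ev[1]
  intercept <- mean(b) - slope * mean(a)
  qa <- stats::quantile(a, probs = seq(1, 0, by = -0.01), names = FALSE)
  for (TA in qa) {
    TB <- slope * TA + intercept
    below <- a < TA & b < TB
    if (sum(below) < 2L) next
    if (stats::sd(a[below]) == 0 || stats::sd(b[below]) == 0) next
    if (stats::cor(a[below], b[below]) <= 0)
      return(list(T_A = TA, T_B = TB, slope = slope, intercept = intercept,
                  flag = FALSE))
  }
  list(T_A = min(a), T_B = min(b), slope = slope, intercept = intercept,
       flag = TRUE)
}

#' Costes-thresholded Pearson correlation
#'
#' @inheritParams pearson
#' @param thresholds optional precomputed [costes_threshold()] result.
#' @param min_voxels minimum number of supra-threshold voxels.
#' @return PCC over voxels above threshold in both channels.
#' @export
pcc_costes <- function(imgA, imgB, roi = NULL, thresholds = NULL,
                       min_voxels = 10) {
  a <- .roi_values(imgA, roi); b <- .roi_values(imgB, roi)
  if (is.null(thresholds)) thresholds <- costes_threshold(a, b)
  above <- a > thresholds$T_A & b > thresholds$T_B
  if (sum(above) < min_voxels)
    stop("insufficient signal: only ", sum(above), " supra-threshold voxels")
  stats::cor(a[above], b[above])
}

## shuffle equally sized blocks of a 3D array; dims must be multiples of block
.block_shuffle <- function(arr, block) {
  d <- dim(arr)
  nb <- d %/% block
  perm <- sample(prod(nb))
  out <- array(0, d)
  bidx <- arrayInd(seq_len(prod(nb)), nb)
  for (k in seq_len(prod(nb))) {
    src <- bidx[perm[k], ]; dst <- bidx[k, ]
    sx <- ((src[1] - 1) * block[1] + 1):(src[1] * block[1])
    sy <- ((src[2] - 1) * block[2] + 1):(src[2] * block[2])
    sz <- ((src[3] - 1) * block[3] + 1):(src[3] * block[3])
    dx <- ((dst[1] - 1) * block[1] + 1):(dst[1] * block[1])
    dy <- ((dst[2] - 1) * block[2] + 1):(dst[2] * block[2])
    dz <- ((dst[3] - 1) * block[3] + 1):(dst[3] * block[3])
    out[dx, dy, dz] <- arr[sx, sy, sz]
  }
  out
}

#' Costes randomization significance test
#'
#' Shuffles pixel blocks of channel A `n` times; each shuffled copy's
#' PCC(Costes) against the untouched channel B forms the null distribution.
#' Thresholds are estimated once on the observed pair and held fixed for the
#' null. Significance is `100 * fraction of null values below the observed
#' PCC(Costes)`: 100% means the observed co-localization is essentially
#' never reached by chance.
#'
#' @param imgA,imgB [image_stack()]s (or arrays) on the same grid; A is the
#'   channel that gets shuffled.
#' @param n number of randomizations (default 200).
#' @param block_voxels block edge in voxels (length 1 or 3); default the PSF
#'   FWHM in voxels, rounded up.
#' @param seed RNG seed.
#' @param psf_sigma_nm,voxel_nm used only to derive the default block size.
#' @return A `coloc_result`: `pcc`, `thresholds`, `pcc_costes`, `null`
#'   (length n), `significance_pct`, `block_voxels`, `seed`.
#' @export
costes_randomization <- function(imgA, imgB, n = 200, block_voxels = NULL,
                                 seed = 1L, psf_sigma_nm = c(80, 80, 250),
                                 voxel_nm = NULL) {
  if (is.null(voxel_nm))
    voxel_nm <- if (inherits(imgA, "image_stack")) imgA$voxel_nm else
      c(56, 56, 200)
  a <- .as_array(imgA); b <- .as_array(imgB)
  if (length(dim(a)) == 2L) { dim(a) <- c(dim(a), 1L); dim(b) <- c(dim(b), 1L) }
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(block_voxels)) {
    fwhm <- 2 * sqrt(2 * log(2)) * psf_sigma_nm
    block_voxels <- pmax(1L, as.integer(ceiling(fwhm / voxel_nm)))
  }
  block <- as.integer(rep(block_voxels, length.out = 3))
  if (any(block < 1L)) stop("block must be >= 1 voxel")
  block <- pmin(block, dim(a))
  ## crop to whole blocks so every block participates in the shuffle
  keep <- (dim(a) %/% block) * block
  a <- a[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]
  b <- b[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), drop = FALSE]

  ## under a true null the channels may not be positively correlated, in
  ## which case no Costes threshold exists; fall back to minimum-intensity
  ## thresholds (whole ROI) so the randomization test remains defined
  thr <- tryCatch(costes_threshold(a, b),
                  error = function(e) list(T_A = min(a), T_B = min(b),
                                           slope = NA_real_,
                                           intercept = NA_real_, flag = TRUE))
  observed <- pcc_costes(a, b, thresholds = thr)
  set.seed(seed)
  null <- vapply(seq_len(n), function(i) {
    ash <- .block_shuffle(a, block)
    above <- ash > thr$T_A & b > thr$T_B
    if (sum(above) < 3L) return(0)       # no measurable overlap after shuffle
    if (stats::sd(ash[above]) == 0 || stats::sd(b[above]) == 0) return(0)
    stats::cor(ash[above], b[above])
  }, numeric(1))
  structure(list(pcc = pearson(a, b), thresholds = thr,
                 pcc_costes = observed, null = null,
                 significance_pct = 100 * mean(null < observed),
                 block_voxels = block, n = n, seed = seed),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("PCC %.3f; PCC(Costes) %.3f; significance %.1f%% (n=%d shuffles)\n",
              x$pcc, x$pcc_costes, x$significance_pct, x$n))
  invisible(x)
}

#' Center-to-center distances between overlapping particles
#'
#' For every pair of overlapping particles (one from each channel), the
#' Euclidean distance in nm between their fitted sub-pixel spot centers.
#' Each particle is assigned the nearest fitted spot center (within
#' `max_assign_nm` of its intensity-weighted centroid).
#'
#' @param spotsA,spotsB fitted spots of the two (registered) channels.
#' @param particlesA,particlesB `particle_set`s of the two channels.
#' @param max_assign_nm maximum centroid-to-spot assignment distance.
#' @return Data frame of records (a, b, dist_nm) with attributes
#'   `mean_nm` and `sem_nm`.
#' @export
center_distances <- function(spotsA, spotsB, particlesA, particlesB,
                             max_assign_nm = 500) {
  ov <- overlap_stats(particlesA, particlesB)$pairs
  assign_spot <- function(particles, spots) {
    tab <- particles$table
    cols <- intersect(c("x_nm", "y_nm", "z_nm"), names(tab))
    out <- rep(NA_integer_, nrow(tab))
    if (!nrow(spots)) return(out)
    sp <- as.matrix(spots[, cols, drop = FALSE])
    for (i in seq_len(nrow(tab))) {
      p <- as.numeric(tab[i, cols])
      dd <- sqrt(rowSums(sweep(sp, 2, p)^2))
      j <- which.min(dd)
      if (dd[j] <= max_assign_nm) out[i] <- j
    }
    out
  }
  ia <- assign_spot(particlesA, spotsA)
  ib <- assign_spot(particlesB, spotsB)
  rec <- list()
  for (k in seq_len(nrow(ov))) {
    sa <- ia[ov$a[k]]; sb <- ib[ov$b[k]]
    if (is.na(sa) || is.na(sb)) next
    pa <- as.numeric(spotsA[sa, c("x_nm", "y_nm", "z_nm")])
    pb <- as.numeric(spotsB[sb, c("x_nm", "y_nm", "z_nm")])
    rec[[length(rec) + 1L]] <- data.frame(
      a = ov$a[k], b = ov$b[k], dist_nm = sqrt(sum((pa - pb)^2)))
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(a = integer(0), b = integer(0), dist_nm = numeric(0))
  attr(out, "mean_nm") <- if (nrow(out)) mean(out$dist_nm) else NA_real_
  attr(out, "sem_nm") <- if (nrow(out) > 1)
    stats::sd(out$dist_nm) / sqrt(nrow(out)) else NA_real_
  out
}

#' Localization precision from repeated acquisitions of the same field
#'
#' Spots are detected in every repeat and tracked back to the first
#' acquisition by nearest neighbors. A set of neighboring spot pairs is
#' chosen in the first image; each pair's distance is measured in every
#' repeat and the precision is the mean absolute deviation of
#' `(d_i)_k - (d_i)_1` across pairs and repeats (RMS also reported).
#'
#' @param stacks list of [image_stack()]s, >= 2 repeats of the same field.
#' @param n_pairs number of neighboring pairs to track (default 16).
#' @param threshold,psf_sigma_nm passed to [detect_spots()].
#' @param match_radius_nm tracking radius between repeats.
#' @return List: `precision_nm` (mean absolute deviation), `sem_nm`,
#'   `rms_nm`, `diffs_nm` (pairs x repeats-1 matrix), `n_pairs_used`,
#'   `dropped` (pairs lost in any repeat).
#' @export
localization_precision <- function(stacks, n_pairs = 16, threshold = "auto",
                                   psf_sigma_nm = c(80, 80, 250),
                                   match_radius_nm = 150) {
  stopifnot(length(stacks) >= 2L)
  spots <- lapply(stacks, function(s) {
    sp <- detect_spots(s, threshold = threshold, psf_sigma_nm = psf_sigma_nm)
    sp[sp$status == "ok", , drop = FALSE]
  })
  ref <- spots[[1L]]
  if (nrow(ref) < 2L) stop("need at least 2 spots in the first repeat")
  P <- as.matrix(ref[, c("x_nm", "y_nm", "z_nm")])
  ## track each reference spot through every repeat
  tracks <- matrix(NA_real_, nrow(ref), 3 * length(stacks))
  tracks[, 1:3] <- P
  for (k in 2:length(stacks)) {
    Q <- as.matrix(spots[[k]][, c("x_nm", "y_nm", "z_nm")])
    for (i in seq_len(nrow(ref))) {
      if (nrow(Q) == 0L) next
      dd <- sqrt(rowSums(sweep(Q, 2, P[i, ])^2))
      j <- which.min(dd)
      if (dd[j] <= match_radius_nm) tracks[i, (3 * k - 2):(3 * k)] <- Q[j, ]
    }
  }
  ok_spot <- stats::complete.cases(tracks)
  ## nearest-neighbor pairs among tracked reference spots
  cand <- which(ok_spot)
  if (length(cand) < 2L) stop("too few spots tracked through all repeats")
  prs <- t(utils::combn(cand, 2))
  dref <- sqrt(rowSums((P[prs[, 1], , drop = FALSE] -
                        P[prs[, 2], , drop = FALSE])^2))
  ord <- order(dref)
  prs <- prs[ord, , drop = FALSE][seq_len(min(n_pairs, nrow(prs))), ,
                                  drop = FALSE]
  nrep <- length(stacks)
  diffs <- matrix(NA_real_, nrow(prs), nrep - 1L)
  for (p in seq_len(nrow(prs))) {
    i <- prs[p, 1]; j <- prs[p, 2]
    dk <- vapply(seq_len(nrep), function(k) {
      a <- tracks[i, (3 * k - 2):(3 * k)]; b <- tracks[j, (3 * k - 2):(3 * k)]
      sqrt(sum((a - b)^2))
    }, numeric(1))
    diffs[p, ] <- dk[-1L] - dk[1L]
  }
  v <- abs(as.vector(diffs))
  list(precision_nm = mean(v),
       sem_nm = stats::sd(v) / sqrt(length(v)),
       rms_nm = sqrt(mean(as.vector(diffs)^2)),
       diffs_nm = diffs,
       n_pairs_used = nrow(prs),
       dropped = sum(!ok_spot))
}
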