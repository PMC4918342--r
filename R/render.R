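#' Forward model: render a scene channel into a noisy 3D stack
#'
#' Every point source contributes a voxel-integrated 3D Gaussian: its value in
#' voxel `i` along one axis is `F * (pnorm((hi-p)/s) - pnorm((lo-p)/s))` with
#' `lo`, `hi` the voxel's physical bounds, so total rendered flux equals the
#' emitter intensity exactly up to window truncation (windows span 5 sigma,
#' losing well under 1%). Granules render as filled Gaussian blobs whose
#' effective width adds the blob radius (sigma = diameter/4) to the PSF in
#' quadrature. Beads render in every channel.
#'
#' @name render
NULL

#' Camera/photon noise model
#'
#' @param shot logical; apply Poisson photon noise to signal + background.
#' @param read_sd additive Gaussian read noise s.d. (ADU); must be >= 0.
#' @param background flat background level (ADU).
#' @param seed RNG seed recorded in rendered outputs.
#' @return A `noise_model` list.
#' @export
noise_model <- function(shot = FALSE, read_sd = 0, background = 0, seed = 1L) {
  if (read_sd < 0) stop("read_sd must be >= 0")
  structure(list(shot = isTRUE(shot), read_sd = read_sd,
                 background = background, seed = as.integer(seed)),
            class = "noise_model")
}

## accumulate one voxel-integrated Gaussian source into `arr` (in place value)
.render_source <- function(arr, pos, flux, sigma, voxel, nsig = 5) {
  d <- dim(arr)
  w <- list()
  for (ax in 1:3) {
    lo_i <- max(1L, floor((pos[ax] - nsig * sigma[ax]) / voxel[ax]) + 1L)
    hi_i <- min(d[ax], ceiling((pos[ax] + nsig * sigma[ax]) / voxel[ax]))
    if (lo_i > hi_i) return(arr)   # fully outside
    idx <- lo_i:hi_i
    edges <- (c(idx - 1L, idx[length(idx)])) * voxel[ax]
    cdf <- stats::pnorm((edges - pos[ax]) / sigma[ax])
    w[[ax]] <- list(idx = idx, wt = diff(cdf))
  }
  block <- flux * (w[[1]]$wt %o% w[[2]]$wt %o% w[[3]]$wt)
  arr[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] <-
    arr[w[[1]]$idx, w[[2]]$idx, w[[3]]$idx] + block
  arr
}

#' Render one channel of a scene
#'
#' @param scene a `granule_scene`.
#' @param channel `"protein"` for the granule channel, otherwise a species
#'   name present in the scene's emitter table.
#' @param psf_sigma_nm Gaussian PSF widths (sx, sy, sz) in nm; default
#'   c(80, 80, 250).
#' @param noise a [noise_model()].
#' @param shift_nm length-3 translation (nm) applied to every source in this
#'   channel, emulating an inter-channel pixel shift.
#' @param voxel_nm voxel size (dx, dy, dz) nm.
#' @return An [image_stack()] whose attribute `"noise_seed"` records the seed.
#' @export
render_stack <- function(scene, channel, psf_sigma_nm = c(80, 80, 250),
                         noise = noise_model(), shift_nm = c(0, 0, 0),
                         voxel_nm = c(56, 56, 200)) {
  stopifnot(inherits(scene, "granule_scene"))
  psf <- as.numeric(psf_sigma_nm)
  if (length(psf) != 3L || any(psf <= 0)) stop("psf sigmas must be > 0")
  if (length(shift_nm) != 3L || any(!is.finite(shift_nm)))
    stop("shift must be a finite 3-vector")
  dims <- pmax(1L, as.integer(round(scene$field_nm / voxel_nm)))
  arr <- array(0, dims)

  sources <- list()
  if (identical(channel, "protein")) {
    g <- scene$granules
    if (nrow(g)) {
      sg <- sqrt(outer(rep(1, nrow(g)), psf^2) + (g$diameter_nm / 4)^2)
      for (i in seq_len(nrow(g)))
        sources[[length(sources) + 1L]] <-
          list(pos = c(g$x_nm[i], g$y_nm[i], g$z_nm[i]),
               flux = g$intensity[i], sigma = sg[i, ])
    }
  } else {
    e <- scene$emitters[scene$emitters$species == channel, , drop = FALSE]
    for (i in seq_len(nrow(e)))
      sources[[length(sources) + 1L]] <-
        list(pos = c(e$x_nm[i], e$y_nm[i], e$z_nm[i]),
             flux = e$intensity[i], sigma = psf)
  }
  b <- scene$beads
  for (i in seq_len(nrow(b)))
    sources[[length(sources) + 1L]] <-
      list(pos = c(b$x_nm[i], b$y_nm[i], b$z_nm[i]),
           flux = b$intensity[i], sigma = psf)

  for (s in sources)
    arr <- .render_source(arr, s$pos + shift_nm, s$flux, s$sigma, voxel_nm)

  arr <- arr + noise$background
  if (noise$shot || noise$read_sd > 0) set.seed(noise$seed)
  if (noise$shot) arr[] <- stats::rpois(length(arr), pmax(arr, 0))
  if (noise$read_sd > 0)
    arr[] <- arr + stats::rnorm(length(arr), 0, noise$read_sd)
  arr[arr < 0] <- 0

  out <- image_stack(arr, voxel_nm = voxel_nm, channel = channel)
  attr(out, "noise_seed") <- noise$seed
  out
}

#' Simulate noisy pairwise-distance measurements of a labeled geometry
#'
#' Draws `n_draws` full pairwise-distance matrices around the exact distances
#' of a labeled point set, adding i.i.d. normal noise of the given s.d. to
#' each unique pair. Negative perturbed distances are redrawn (keeping the
#' noise symmetric rather than truncating it).
#'
#' @param geometry numeric matrix, one labeled point per row (nm), with
#'   rownames as labels.
#' @param sd_nm measurement noise s.d. per distance (nm), >= 0.
#' @param n_draws number of matrices to draw (>= 1).
#' @param seed RNG seed.
#' @return A list of symmetric distance matrices; attribute `"degenerate"` is
#'   TRUE when all points coincide.
#' @export
make_distance_dataset <- function(geometry, sd_nm, n_draws, seed = 1L) {
  geometry <- as.matrix(geometry)
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (sd_nm < 0) stop("sd_nm must be >= 0")
  d0 <- as.matrix(stats::dist(geometry))
  degenerate <- all(d0 < 1e-12)
  if (degenerate) warning("degenerate geometry: all points coincident")
  set.seed(seed)
  up <- upper.tri(d0)
  out <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    dk <- d0
    vals <- d0[up] + stats::rnorm(sum(up), 0, sd_nm)
    while (any(vals < 0)) {
      neg <- vals < 0
      vals[neg] <- d0[up][neg] + stats::rnorm(sum(neg), 0, sd_nm)
    }
    dk[up] <- vals
    dk[lower.tri(dk)] <- t(dk)[lower.tri(dk)]
    out[[k]] <- dk
  }
  attr(out, "degenerate") <- degenerate
  attr(out, "seed") <- seed
  out
}
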