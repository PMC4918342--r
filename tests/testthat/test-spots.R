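# brute-force oracle: every voxel that is a strict 26-neighborhood maximum
brute_local_maxima <- function(arr, threshold) {
  d <- dim(arr)
  out <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    v <- arr[x, y, z]
    if (v <= threshold) next
    best <- TRUE
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      if (ox == 0 && oy == 0 && oz == 0) next
      nx <- x + ox; ny <- y + oy; nz <- z + oz
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3])
        next
      if (arr[nx, ny, nz] > v) best <- FALSE
    }
    if (best) out <- rbind(out, c(x, y, z))
  }
  out
}

test_that("predetection finds isolated maxima and matches the exhaustive oracle", {
  flat <- image_stack(array(5, c(10, 10, 5)))
  expect_equal(nrow(predetect(flat, threshold = 1)), 0L)

  one <- single_spot_stack(offset_vox = c(0, 0, 0))
  cand <- predetect(one$stack, threshold = 1)
  expect_equal(nrow(cand), 1L)
  peak <- which(one$stack$data == max(one$stack$data), arr.ind = TRUE)
  expect_equal(unname(cand[1, ]), unname(peak[1, ]))

  ## two spots far apart: candidates equal the brute-force local-max scan
  sc <- make_granule_scene(scene_config(n_granules = 0, n_single = 0))
  sc$emitters <- data.frame(id = 1:2, species = "mrna1",
                            x_nm = c(600, 2400), y_nm = c(700, 2200),
                            z_nm = c(1100, 2900),
                            intensity = 1000, cluster_id = NA_integer_,
                            granule_id = NA_integer_)
  st <- render_stack(sc, "mrna1")
  cand2 <- predetect(st, threshold = 0.5)
  oracle <- brute_local_maxima(st$data, 0.5)
  expect_equal(nrow(cand2), 2L)
  expect_equal(cand2[order(cand2[, 1]), ],
               oracle[order(oracle[, 1]), ], ignore_attr = TRUE)
})

test_that("noiseless sub-voxel spots are recovered to nanometre accuracy", {
  for (off in list(c(0.3, 0.6, 0.4), c(-0.45, 0.1, -0.2))) {
    fx <- single_spot_stack(offset_vox = off)
    sp <- detect_spots(fx$stack, threshold = 0.5)
    expect_equal(nrow(sp), 1L)
    expect_equal(sp$status, "ok")
    err <- sqrt((sp$x_nm - fx$truth[1])^2 + (sp$y_nm - fx$truth[2])^2 +
                (sp$z_nm - fx$truth[3])^2)
    expect_lt(err, 1)
    expect_equal(sp$intensity, fx$flux, tolerance = 1e-3)
    expect_lt(sp$rss, 1e-6 * max(fx$stack$data)^2)  # residual tiny vs peak
  }
})

test_that("an affine ramp background does not bias the fitted intensity", {
  fx <- single_spot_stack(offset_vox = c(0.2, -0.3, 0.1), flux = 2000)
  st <- fx$stack
  d <- dim(st$data)
  ramp <- outer(outer(50 + 0.5 * seq_len(d[1]), rep(1, d[2])), rep(1, d[3]))
  st$data <- st$data + ramp
  sp <- detect_spots(st, threshold = max(ramp) + 10)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$intensity, 2000, tolerance = 0.01)
  err <- sqrt((sp$x_nm - fx$truth[1])^2 + (sp$y_nm - fx$truth[2])^2 +
              (sp$z_nm - fx$truth[3])^2)
  expect_lt(err, 1)
  ## recovered plane slope matches the staged ramp (0.5 ADU/voxel = 0.5/56 per nm)
  expect_equal(sp$bg_ax, 0.5 / 56, tolerance = 0.05)
})

test_that("localization error at SNR ~20 stays below 20 nm laterally", {
  errs <- matrix(NA_real_, 100, 2)
  for (i in 1:100) {
    off <- c(stats::runif(2, -0.5, 0.5), stats::runif(1, -0.5, 0.5))
    fx <- single_spot_stack(
      offset_vox = off, flux = 20000,
      noise = noise_model(shot = TRUE, read_sd = 3, background = 100,
                          seed = i))
    sp <- detect_spots(fx$stack, threshold = "auto")
    expect_gte(nrow(sp), 1L)
    errs[i, ] <- c(sp$x_nm[1] - fx$truth[1], sp$y_nm[1] - fx$truth[2])
  }
  rmse_lat <- sqrt(mean(errs^2))
  expect_lt(rmse_lat, 20)
})

test_that("localization is equivariant under whole-voxel translation", {
  fx <- single_spot_stack(offset_vox = c(0.25, -0.15, 0.3))
  sp0 <- detect_spots(fx$stack, threshold = 0.5)
  shifted <- fx$stack
  d <- dim(shifted$data)
  arr <- array(0, d)
  arr[3:d[1], 2:d[2], 1:(d[3] - 1)] <-
    fx$stack$data[1:(d[1] - 2), 1:(d[2] - 1), 2:d[3]]
  shifted$data <- arr
  sp1 <- detect_spots(shifted, threshold = 0.5)
  expect_equal(sp1$x_nm - sp0$x_nm, 2 * 56, tolerance = 1e-6)
  expect_equal(sp1$y_nm - sp0$y_nm, 1 * 56, tolerance = 1e-6)
  expect_equal(sp1$z_nm - sp0$z_nm, -1 * 200, tolerance = 1e-6)
})

test_that("unit intensity calibration is robust and errors on scant data", {
  spots <- data.frame(intensity = rep(1000, 60), status = "ok")
  u <- unit_intensity(spots)
  expect_equal(u$unit, 1000)
  expect_equal(u$n, 60L)
  expect_error(unit_intensity(spots[0, ]), "calibration")
  expect_error(unit_intensity(spots[1:10, ]), "calibration")

  ## rendered spots with lognormal brightness: median recovers the scale
  set.seed(42)
  n <- 60
  ints <- 1000 * stats::rlnorm(n, 0, 0.15)
  sc <- make_granule_scene(scene_config(n_granules = 0, n_single = n,
                                        seed = 8, field_nm = c(4500, 4500, 4000),
                                        edge_margin_nm = 500))
  sc$emitters$intensity <- ints
  st <- render_stack(sc, "mrna1", noise = noise_model(shot = TRUE,
                                                      background = 5, seed = 9))
  sp <- detect_spots(st, threshold = "auto")
  u2 <- unit_intensity(sp, min_n = 40)
  expect_equal(u2$unit, stats::median(ints), tolerance = 0.05)
})

test_that("cluster counting is exact arithmetic and linear in intensity", {
  u <- structure(list(unit = 1000, estimator = "median", n = 60L),
                 class = "intensity_unit")
  expect_equal(count_mrnas(5000, u)$count, 5)
  expect_equal(count_mrnas(1000, u)$count, 1)
  expect_equal(count_mrnas(data.frame(intensity = 7250), u)$count_int, 7L)
  ## linearity
  expect_equal(count_mrnas(2 * 3300, u)$count, 2 * count_mrnas(3300, u)$count)

  ## staged 7-mRNA cluster rendered noiselessly recovers 7 +- 0.1
  fx <- single_spot_stack(offset_vox = c(0.1, 0.2, -0.3), flux = 7000)
  sp <- detect_spots(fx$stack, threshold = 0.5)
  expect_equal(count_mrnas(sp, u)$count, 7, tolerance = 0.1 / 7)
})
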