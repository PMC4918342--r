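disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
}

test_that("segmentation recovers simple shapes with their circularity", {
  img <- disk_mask(40, 20, 20, 10) * 100
  seg <- segment(img, method = 50, voxel_nm = c(56, 56))
  expect_equal(nrow(seg$table), 1L)
  expect_gte(seg$table$circularity, 0.9)
  expect_lte(seg$table$circularity, 1)

  two <- (disk_mask(60, 15, 15, 8) | disk_mask(60, 45, 45, 8)) * 100
  seg2 <- segment(two, method = 50, voxel_nm = c(56, 56))
  expect_equal(nrow(seg2$table), 2L)

  none <- segment(matrix(0, 20, 20), method = 10, voxel_nm = c(56, 56))
  expect_equal(nrow(none$table), 0L)
})

test_that("3D segmentation of a staged scene matches the truth table", {
  sc <- make_granule_scene(scene_config(
    n_granules = 20, n_single = 0, seed = 17,
    field_nm = c(7000, 7000, 7000), min_separation_nm = 1300,
    edge_margin_nm = 900))
  st <- render_stack(sc, "protein")
  seg <- segment(st)
  expect_equal(nrow(seg$table), 20L)
  ## match each truth granule to its nearest segmented centroid
  for (g in seq_len(20)) {
    dd <- sqrt((seg$table$x_nm - sc$granules$x_nm[g])^2 +
               (seg$table$y_nm - sc$granules$y_nm[g])^2 +
               (seg$table$z_nm - sc$granules$z_nm[g])^2)
    expect_lt(min(dd), 200)  # within one z-voxel
  }
})

test_that("overlap statistics follow pixel-count arithmetic", {
  base <- array(0L, c(30, 30, 1))
  la <- base; la[1:10, 1:10, 1] <- 1L; la[1:10, 21:30, 1] <- 2L  # two 100-px granules
  lb <- base; lb[3:7, 3:10, 1] <- 1L                             # 40 px inside granule 1
  mk <- function(lab) {
    img <- (lab > 0) * 100
    ps <- segment(img[, , 1], method = 50, voxel_nm = c(56, 56))
    ps
  }
  A <- mk(la); B <- mk(lb)
  ov <- overlap_stats(A, B)
  expect_equal(ov$pct_B_overlapping, 100)      # the one B particle overlaps
  expect_equal(nrow(ov$pairs), 1L)             # half the A particles covered
  expect_equal(ov$ratio_B_to_A, 1 / 2)
  covered <- ov$area_coverage[ov$pairs$a[1]]
  expect_equal(covered, 100 * 40 / 100)
  expect_true(all(ov$area_coverage <= 100))

  same <- overlap_stats(A, A)
  expect_equal(same$pct_B_overlapping, 100)
  expect_equal(same$ratio_B_to_A, 1)
  expect_true(all(same$area_coverage == 100))

  ## disjoint masks
  lc <- base; lc[21:30, 1:5, 1] <- 1L
  C <- mk(lc)
  expect_equal(overlap_stats(A, C)$pct_B_overlapping, 0)
})

test_that("Pearson correlation behaves at its defining limits", {
  set.seed(51)
  a <- array(stats::rpois(10000, 20), c(100, 100, 1))
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, max(a) - a), -1)
  b <- array(stats::rpois(10000, 20), c(100, 100, 1))
  expect_lt(abs(pearson(a, b)), 0.05)
  expect_error(pearson(array(1, c(10, 10, 1)), a[1:10, 1:10, 1, drop = FALSE]),
               "zero variance")
})

test_that("Costes thresholds make sub-threshold voxels uncorrelated", {
  cp <- colocalized_pair(n_spots = 40, seed = 61)
  thr <- costes_threshold(cp$A, cp$B)
  expect_false(thr$flag)
  a <- cp$A$data; b <- cp$B$data
  below <- a < thr$T_A & b < thr$T_B
  expect_lte(stats::cor(a[below], b[below]), 0)

  ## identical images: no decorrelated sub-threshold set exists
  thr_same <- costes_threshold(cp$A, cp$A)
  expect_true(thr_same$flag)
  expect_equal(thr_same$T_A, min(a))
  expect_equal(pcc_costes(cp$A, cp$A, thresholds = thr_same), 1)

  ## thresholds separate true signal voxels from the noise floor
  truth <- render_stack(cp$scene, "mrna1")$data   # noiseless, no background
  spot_vox <- truth > 0.05 * max(truth)
  expect_gte(mean(a[spot_vox] > thr$T_A), 0.95)
})

test_that("PCC(Costes) is high for colocalized spots and near 0 when shuffled", {
  cp <- colocalized_pair(n_spots = 40, seed = 71, flux = 20000, background = 5)
  expect_gte(pcc_costes(cp$A, cp$B), 0.95)
  set.seed(72)
  ash <- cp$A
  ash$data[] <- sample(ash$data)
  thr <- costes_threshold(cp$A, cp$B)
  above <- ash$data > thr$T_A & cp$B$data > thr$T_B
  expect_lt(abs(stats::cor(ash$data[above], cp$B$data[above])), 0.1)
})

test_that("central clusters score a higher PCC(Costes) than peripheral ones", {
  pcc_for_offset <- function(offset, seed) {
    sc <- make_granule_scene(scene_config(
      n_granules = 10, n_single = 0, radial_offset_nm = offset, seed = seed,
      field_nm = c(5000, 5000, 5000), min_separation_nm = 1100,
      edge_margin_nm = 800, cluster_copies = 8))
    P <- render_stack(sc, "protein",
                      noise = noise_model(shot = TRUE, background = 10,
                                          seed = seed + 1))
    M <- render_stack(sc, "mrna1",
                      noise = noise_model(shot = TRUE, background = 10,
                                          seed = seed + 2))
    pcc_costes(M, P)
  }
  central <- pcc_for_offset(54, 81)
  peripheral <- pcc_for_offset(198, 91)
  expect_gt(central, peripheral)
})

test_that("block-shuffle randomization flags genuine colocalization as significant", {
  cp <- colocalized_pair(n_spots = 50, seed = 101)
  res <- costes_randomization(cp$A, cp$B, n = 200, seed = 5)
  expect_length(res$null, 200)
  expect_equal(res$significance_pct, 100)
  expect_gte(res$pcc_costes, 0.9)

  ## null calibration: a channel against its own shuffled copy is not
  ## systematically significant; significance spreads over the repeats
  blk <- res$block_voxels
  d <- dim(cp$A$data)
  keep <- (d %/% blk) * blk
  ac <- cp$A$data[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                  drop = FALSE]
  sigs <- vapply(1:12, function(k) {
    set.seed(1000 + k)
    ash <- granulescope:::.block_shuffle(ac, blk)
    r <- costes_randomization(image_stack(ash, channel = "shuf"),
                              image_stack(ac, channel = "a"),
                              n = 40, seed = 2000 + k)
    r$significance_pct
  }, numeric(1))
  expect_lt(mean(sigs), 95)      # not pinned at "always significant"
  expect_gt(stats::sd(sigs), 1)  # spread across repeats
})

test_that("center distances recover staged offsets", {
  ## coincident and exactly offset constructions
  mkset <- function(xs) {
    img <- array(0, c(60, 60, 20))
    for (x in xs) img[(x - 1):(x + 1), 30:32, 10] <- 100
    segment(image_stack(img), method = 50)
  }
  A <- mkset(c(20, 40))
  ovA <- overlap_stats(A, A)
  spots <- data.frame(x_nm = A$table$x_nm, y_nm = A$table$y_nm,
                      z_nm = A$table$z_nm, intensity = 100, status = "ok")
  rec0 <- center_distances(spots, spots, A, A)
  expect_true(all(rec0$dist_nm == 0))

  spots2 <- spots
  spots2$x_nm <- spots2$x_nm + 100
  rec1 <- center_distances(spots, spots2, A, A)
  expect_equal(rec1$dist_nm, rep(100, nrow(rec1)))
})

test_that("staged 54 nm granule-cluster offsets are recovered within 2 s.e.m.", {
  sc <- make_granule_scene(scene_config(
    n_granules = 50, n_single = 0, radial_offset_nm = 54, seed = 111,
    field_nm = c(11000, 11000, 6000), min_separation_nm = 1300,
    edge_margin_nm = 800, cluster_copies = 8, granule_intensity = 40000))
  P <- render_stack(sc, "protein",
                    noise = noise_model(shot = TRUE, background = 10, seed = 112))
  M <- render_stack(sc, "mrna1",
                    noise = noise_model(shot = TRUE, background = 10, seed = 113))
  segP <- segment(P); segM <- segment(M)
  spP <- detect_spots(P, threshold = "auto")
  spM <- detect_spots(M, threshold = "auto")
  rec <- center_distances(spP[spP$status == "ok", ], spM[spM$status == "ok", ],
                          segP, segM)
  expect_gte(nrow(rec), 40)
  expect_lt(abs(attr(rec, "mean_nm") - 54), 2 * attr(rec, "sem_nm") + 3)
})

test_that("center distances are invariant under a global translation", {
  img <- array(0, c(40, 40, 10))
  img[10:12, 10:12, 5] <- 100; img[30:32, 30:32, 5] <- 100
  A <- segment(image_stack(img), method = 50)
  sp <- data.frame(x_nm = A$table$x_nm, y_nm = A$table$y_nm,
                   z_nm = A$table$z_nm, intensity = 1, status = "ok")
  base <- center_distances(sp, sp, A, A)
  ## same translation applied to both channels (spots and particle centroids)
  v <- c(-500, 250, -100)
  mv <- apply_shift(sp, v)
  A2 <- A
  A2$table$x_nm <- A2$table$x_nm - v[1]
  A2$table$y_nm <- A2$table$y_nm - v[2]
  A2$table$z_nm <- A2$table$z_nm - v[3]
  moved <- center_distances(mv, mv, A2, A2)
  expect_equal(moved$dist_nm, base$dist_nm)
})

test_that("localization precision is zero for identical repeats and tracks noise", {
  sc <- make_granule_scene(scene_config(
    n_granules = 0, n_single = 10, seed = 121, unit_intensity = 20000,
    field_nm = c(4000, 4000, 4000), edge_margin_nm = 600))
  clean <- render_stack(sc, "mrna1", noise = noise_model(background = 5))
  res0 <- localization_precision(list(clean, clean, clean), n_pairs = 6,
                                 threshold = 20)
  expect_equal(res0$precision_nm, 0, tolerance = 1e-6)

  ## 12 noisy repeats, 16 pairs requested -> 16 x 11 difference values,
  ## and the precision matches a Monte-Carlo prediction from the per-spot
  ## localization errors measured against the truth table
  stacks <- lapply(1:12, function(k)
    render_stack(sc, "mrna1",
                 noise = noise_model(shot = TRUE, read_sd = 3,
                                     background = 50, seed = 300 + k)))
  res <- localization_precision(stacks, n_pairs = 16, threshold = "auto")
  expect_equal(dim(res$diffs_nm), c(16L, 11L))
  expect_gt(res$precision_nm, 0)

  ## per-axis spot localization error from truth
  tt <- scene_truth_table(sc)
  errs <- do.call(rbind, lapply(stacks, function(s) {
    sp <- detect_spots(s, threshold = "auto")
    sp <- sp[sp$status == "ok", ]
    t(vapply(seq_len(nrow(sp)), function(i) {
      dd <- sqrt((tt$x_nm - sp$x_nm[i])^2 + (tt$y_nm - sp$y_nm[i])^2 +
                 (tt$z_nm - sp$z_nm[i])^2)
      j <- which.min(dd)
      c(sp$x_nm[i] - tt$x_nm[j], sp$y_nm[i] - tt$y_nm[j],
        sp$z_nm[i] - tt$z_nm[j])
    }, numeric(3)))
  }))
  sig <- apply(errs, 2, stats::sd)
  ## Monte-Carlo oracle: pair distances under those per-axis errors
  set.seed(99)
  pts <- as.matrix(tt[, c("x_nm", "y_nm", "z_nm")])
  sim <- replicate(2000, {
    i <- sample(nrow(pts), 2)
    p1 <- pts[i[1], ]; p2 <- pts[i[2], ]
    d1 <- sqrt(sum((p1 + stats::rnorm(3, 0, sig) -
                    p2 - stats::rnorm(3, 0, sig))^2))
    d2 <- sqrt(sum((p1 + stats::rnorm(3, 0, sig) -
                    p2 - stats::rnorm(3, 0, sig))^2))
    abs(d1 - d2)
  })
  expect_gt(res$precision_nm / mean(sim), 0.5)
  expect_lt(res$precision_nm / mean(sim), 2)
})
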