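# Shared staged fixtures, all generated in code under fixed seeds.

# a single emitter at a known sub-voxel position, rendered noiselessly
single_spot_stack <- function(offset_vox = c(0.3, 0.6, 0.4), flux = 1000,
                              center_vox = c(20L, 20L, 10L),
                              noise = noise_model()) {
  sc <- make_granule_scene(scene_config(n_granules = 0, n_single = 0))
  pos <- (center_vox - 0.5 + offset_vox) * c(56, 56, 200)
  sc$emitters <- data.frame(id = 1L, species = "mrna1",
                            x_nm = pos[1], y_nm = pos[2], z_nm = pos[3],
                            intensity = flux, cluster_id = NA_integer_,
                            granule_id = NA_integer_)
  list(stack = render_stack(sc, "mrna1", noise = noise), truth = pos,
       flux = flux)
}

# non-planar 5-point reference geometry on the granule scale (nm);
# point 1 is the protein center, 2..5 the four mRNA cluster centers
reference_geometry <- function() {
  g <- rbind(granule = c(0, 0, 0),
             sp1 = c(54, 0, 0),
             sp2 = c(10, 110, 0),
             sp3 = c(-30, 20, 160),
             sp4 = c(100, 100, 80))
  colnames(g) <- c("x", "y", "z")
  g
}

reference_distances <- function() as.matrix(stats::dist(reference_geometry()))

# best rigid alignment allowing reflection: helper oracle for comparisons
# that are only defined up to rigid motion + mirror
align_up_to_reflection <- function(X, ref) {
  r1 <- register_structure(X, ref)
  Xm <- X
  Xm[, 1] <- -Xm[, 1]
  r2 <- register_structure(Xm, ref)
  if (r1$rmsd_nm <= r2$rmsd_nm) r1 else r2
}

# two-channel perfectly colocalized stacks (identical emitter positions)
# over a Poisson noise floor
colocalized_pair <- function(n_spots = 50, seed = 21, flux = 5000,
                             background = 10) {
  sc <- make_granule_scene(scene_config(
    n_granules = 0, n_single = n_spots, seed = seed,
    unit_intensity = flux, field_nm = c(3500, 3500, 4000)))
  A <- render_stack(sc, "mrna1",
                    noise = noise_model(shot = TRUE, background = background,
                                        seed = seed + 1))
  B <- render_stack(sc, "mrna1",
                    noise = noise_model(shot = TRUE, background = background,
                                        seed = seed + 2))
  list(A = A, B = B, scene = sc)
}
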