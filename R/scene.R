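#' Ground-truth scene generation for granule imaging simulations
#'
#' A scene is the physical ground truth behind a simulated acquisition:
#' granules (protein blobs), homotypic mRNA clusters placed at configurable
#' radial offsets inside or at the edge of granules, single mRNAs scattered
#' outside granules, and fiducial beads visible in every channel. All
#' coordinates are in nanometres within a rectangular field.
#'
#' @name scene
NULL

#' Default scene configuration
#'
#' Returns the default parameter list for [make_granule_scene()]. Fields can
#' be overridden by passing a named list; unknown names are an error.
#'
#' Radial offsets default to the three regimes used throughout the package:
#' central clusters at 54 nm, peripheral clusters at 198 nm (edge of a
#' typical granule), and unassociated species at 408 nm.
#'
#' @param ... named overrides of the default fields.
#' @return A named list of scene parameters.
#' @export
scene_config <- function(...) {
  cfg <- list(
    field_nm        = c(3000, 3000, 4000),  # X, Y, Z extent
    n_granules      = 12,
    granule_diameter_nm = list(mean = 350, sd = 75, max = 500, min = 150),
    granule_intensity   = 20000,            # integrated photons per granule blob
    species         = "mrna1",
    radial_offset_nm = 54,                  # per-species radial cluster offset
    cluster_copies  = 5,                    # mRNA copies per homotypic cluster
    unit_intensity  = 1000,                 # photons per single mRNA
    n_single        = 40,                   # single mRNAs outside granules
    n_beads         = 0,
    bead_intensity  = 30000,
    min_separation_nm = 700,                # center-to-center granule spacing
    edge_margin_nm  = 400,                  # keep objects away from field edges
    seed            = 1L
  )
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1L]])) ov <- ov[[1L]]
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown scene_config fields: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Generate a ground-truth granule scene
#'
#' Places `n_granules` round granules (diameter drawn from a truncated normal,
#' capped at `granule_diameter_nm$max`) at mutually separated random positions,
#' one homotypic cluster per granule and species at the species' radial offset
#' in a uniformly random direction, `n_single` single mRNAs of unit intensity
#' outside all granules, and `n_beads` fiducial beads. The returned object
#' carries a full truth table: every emitter's position, intensity, cluster
#' and granule membership.
#'
#' @param config a list from [scene_config()] (or overrides passed to it).
#' @return An object of class `granule_scene` with elements `emitters`,
#'   `granules`, `beads` (data frames in nm), `field_nm`, and `config`.
#' @export
make_granule_scene <- function(config = scene_config()) {
  cfg <- do.call(scene_config, config)
  stopifnot(length(cfg$field_nm) == 3L)
  if (cfg$n_granules < 0 || cfg$n_single < 0 || cfg$n_beads < 0)
    stop("counts must be nonnegative")
  if (any(cfg$radial_offset_nm < 0)) stop("radial offsets must be >= 0")
  set.seed(cfg$seed)

  field <- as.numeric(cfg$field_nm)
  margin <- cfg$edge_margin_nm
  if (cfg$n_granules > 0 && any(field <= 2 * margin))
    stop("field too small for the requested edge margin")

  ## quick capacity check before rejection sampling
  if (cfg$n_granules > 0) {
    usable <- prod(pmax(field - 2 * margin, 0))
    packed <- cfg$n_granules * (4 / 3) * pi * (cfg$min_separation_nm / 2)^3
    if (packed > 2 * usable)
      stop("field too small to place ", cfg$n_granules,
           " granules at the requested separation")
  }

  dia_par <- cfg$granule_diameter_nm
  rdiam <- function(n) {
    d <- stats::rnorm(n, dia_par$mean, dia_par$sd)
    bad <- d < dia_par$min | d > dia_par$max
    while (any(bad)) {
      d[bad] <- stats::rnorm(sum(bad), dia_par$mean, dia_par$sd)
      bad <- d < dia_par$min | d > dia_par$max
    }
    d
  }

  ## granule centers by rejection sampling with a minimum separation
  centers <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  while (nrow(centers) < cfg$n_granules) {
    p <- margin + stats::runif(3) * (field - 2 * margin)
    ok <- nrow(centers) == 0L ||
      min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= cfg$min_separation_nm
    if (ok) centers <- rbind(centers, p)
    attempts <- attempts + 1L
    if (attempts > 2000L * max(cfg$n_granules, 1L))
      stop("field too small: could not place granules at the requested separation")
  }

  granules <- if (cfg$n_granules > 0) {
    data.frame(
      id = seq_len(cfg$n_granules),
      x_nm = centers[, 1], y_nm = centers[, 2], z_nm = centers[, 3],
      diameter_nm = rdiam(cfg$n_granules),
      intensity = cfg$granule_intensity,
      channel = "protein", stringsAsFactors = FALSE
    )
  } else {
    data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               z_nm = numeric(0), diameter_nm = numeric(0),
               intensity = numeric(0), channel = character(0),
               stringsAsFactors = FALSE)
  }

  species <- as.character(cfg$species)
  offsets <- rep(as.numeric(cfg$radial_offset_nm), length.out = length(species))
  copies  <- rep(as.numeric(cfg$cluster_copies), length.out = length(species))
  n_single <- rep(as.integer(cfg$n_single), length.out = length(species))

  em <- list()
  cluster_id <- 0L
  for (s in seq_along(species)) {
    ## one homotypic cluster per granule, at the species' radial offset
    ## in a uniformly random direction
    if (cfg$n_granules > 0) {
      u <- matrix(stats::rnorm(3 * cfg$n_granules), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pos <- centers + u * offsets[s]
      for (g in seq_len(cfg$n_granules)) {
        cluster_id <- cluster_id + 1L
        em[[length(em) + 1L]] <- data.frame(
          species = species[s],
          x_nm = pos[g, 1], y_nm = pos[g, 2], z_nm = pos[g, 3],
          intensity = copies[s] * cfg$unit_intensity,
          cluster_id = cluster_id, granule_id = g,
          stringsAsFactors = FALSE
        )
      }
    }
    ## single mRNAs away from every granule
    ns <- n_single[s]
    if (ns > 0) {
      singles <- matrix(NA_real_, ns, 3)
      got <- 0L; tries <- 0L
      clearance <- if (cfg$n_granules > 0) max(granules$diameter_nm) else 0
      while (got < ns) {
        p <- margin + stats::runif(3) * (field - 2 * margin)
        far <- cfg$n_granules == 0L ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) > clearance
        if (far) { got <- got + 1L; singles[got, ] <- p }
        tries <- tries + 1L
        if (tries > 10000L * ns) stop("field too small to place single mRNAs")
      }
      em[[length(em) + 1L]] <- data.frame(
        species = species[s],
        x_nm = singles[, 1], y_nm = singles[, 2], z_nm = singles[, 3],
        intensity = cfg$unit_intensity,
        cluster_id = NA_integer_, granule_id = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  emitters <- if (length(em)) do.call(rbind, em) else
    data.frame(species = character(0), x_nm = numeric(0), y_nm = numeric(0),
               z_nm = numeric(0), intensity = numeric(0),
               cluster_id = integer(0), granule_id = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(emitters)) emitters <- cbind(id = seq_len(nrow(emitters)), emitters)
  else emitters <- cbind(data.frame(id = integer(0)), emitters)

  beads <- if (cfg$n_beads > 0) {
    data.frame(
      id = seq_len(cfg$n_beads),
      x_nm = margin + stats::runif(cfg$n_beads) * (field[1] - 2 * margin),
      y_nm = margin + stats::runif(cfg$n_beads) * (field[2] - 2 * margin),
      z_nm = margin + stats::runif(cfg$n_beads) * (field[3] - 2 * margin),
      intensity = cfg$bead_intensity, stringsAsFactors = FALSE
    )
  } else {
    data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               z_nm = numeric(0), intensity = numeric(0),
               stringsAsFactors = FALSE)
  }

  structure(
    list(emitters = emitters, granules = granules, beads = beads,
         field_nm = field, config = cfg),
    class = "granule_scene"
  )
}

#' @export
print.granule_scene <- function(x, ...) {
  cat("granule_scene:", nrow(x$granules), "granules,",
      nrow(x$emitters), "emitters,", nrow(x$beads), "beads;",
      "field", paste(round(x$field_nm), collapse = " x "), "nm\n")
  invisible(x)
}

#' Scene truth table
#'
#' The auditable per-emitter ground truth: position (nm), intensity, cluster
#' and granule membership, ready to be written as CSV next to rendered stacks.
#'
#' @param scene a `granule_scene`.
#' @return A data frame with one row per emitter.
#' @export
scene_truth_table <- function(scene) {
  stopifnot(inherits(scene, "granule_scene"))
  scene$emitters
}
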