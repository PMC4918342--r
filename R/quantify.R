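#' Absolute transcript quantification and localization efficiency
#'
#' Transcript numbers come from integrated fluorescence calibrated by the
#' single-mRNA unit intensity. Counts in a reference ROI extrapolate to the
#' whole embryo by volume; molar concentration follows from Avogadro's
#' number. Localization efficiency applies the 3D granule-protein mask to
#' the mRNA channel: the per cent of the embryo's transcripts whose
#' fluorescence falls inside the mask, corrected by the mask's capture
#' fraction (peripheral clusters are segmented less efficiently, so the raw
#' figure underestimates true localization).
#'
#' @name quantify
NULL

.N_AVOGADRO <- 6.02214076e23

#' Molar concentration of counted molecules in a volume
#'
#' @param count number of molecules (>= 0).
#' @param volume_um3 volume in cubic micrometres (> 0).
#' @return List: `count`, `volume_um3`, `volume_L`, `concentration_nM`
#'   (`count / (N_A * volume_L) * 1e9`).
#' @export
concentration <- function(count, volume_um3) {
  if (volume_um3 <= 0) stop("volume must be > 0")
  if (count < 0) stop("count must be >= 0")
  vol_L <- volume_um3 * 1e-15
  list(count = count, volume_um3 = volume_um3, volume_L = vol_L,
       concentration_nM = count / (.N_AVOGADRO * vol_L) * 1e9)
}

#' Extrapolate an ROI count to the whole embryo
#'
#' @param count_roi molecules counted in the ROI.
#' @param v_roi_um3,v_embryo_um3 ROI and embryo volumes (um^3), with
#'   `v_roi_um3 <= v_embryo_um3`.
#' @return Extrapolated total count.
#' @export
extrapolate_total <- function(count_roi, v_roi_um3, v_embryo_um3) {
  if (v_roi_um3 <= 0 || v_embryo_um3 <= 0) stop("volumes must be > 0")
  if (v_roi_um3 > v_embryo_um3) stop("ROI volume exceeds embryo volume")
  count_roi * v_embryo_um3 / v_roi_um3
}

## modal intensity of a vector (histogram mode of rounded values)
.modal_intensity <- function(v) {
  if (!length(v)) return(0)
  tb <- table(round(v))
  as.numeric(names(tb)[which.max(tb)])
}

#' Build the 3D granule mask from the protein channel
#'
#' 3D connected components above a threshold (26-connectivity), dropping
#' components smaller than `min_voxels`.
#'
#' @param granule_stack [image_stack()] of the granule-protein channel.
#' @param method `"otsu"` or a numeric threshold.
#' @param min_voxels minimum component size kept.
#' @return Logical 3D mask.
#' @export
granule_mask <- function(granule_stack, method = "otsu", min_voxels = 2) {
  seg <- segment(granule_stack, method = method)
  keep <- seg$table$id[seg$table$n_px >= min_voxels]
  array(seg$labels %in% keep, dim(seg$labels))
}

#' Localization efficiency of an mRNA species
#'
#' @param granule_stack protein channel used to build the 3D mask (or a
#'   logical mask array directly).
#' @param mrna_stack registered mRNA channel.
#' @param unit an [unit_intensity()] calibration.
#' @param embryo_total total transcripts in the embryo (e.g. from
#'   [extrapolate_total()]).
#' @param capture capture fraction of the mask in (0, 1]; see
#'   [capture_fraction()].
#' @param method threshold method for the mask when a stack is given.
#' @return An `efficiency_result`: `localized`, `unlocalized` (mRNA
#'   equivalents), `embryo_total`, `raw_pct`, `capture`, `corrected_pct`.
#' @export
localization_efficiency <- function(granule_stack, mrna_stack, unit,
                                    embryo_total, capture = 1,
                                    method = "otsu") {
  stopifnot(inherits(unit, "intensity_unit"), unit$unit > 0)
  if (capture <= 0 || capture > 1) stop("capture fraction must be in (0, 1]")
  mask <- if (is.logical(granule_stack) || is.array(granule_stack) &&
              is.logical(granule_stack[1]))
    granule_stack else granule_mask(granule_stack, method = method)
  m <- .as_array(mrna_stack)
  stopifnot(all(dim(mask) == dim(m)))
  if (!any(mask)) {
    warning("empty granule mask: efficiency 0")
    return(structure(list(localized = 0, unlocalized = NA_real_,
                          embryo_total = embryo_total, raw_pct = 0,
                          capture = capture, corrected_pct = 0),
                     class = "efficiency_result"))
  }
  bg <- .modal_intensity(m[!mask])
  localized <- sum(m[mask] - bg) / unit$unit
  unlocalized <- sum(m[!mask] - bg) / unit$unit
  raw <- 100 * localized / embryo_total
  structure(list(localized = localized, unlocalized = unlocalized,
                 embryo_total = embryo_total, raw_pct = raw,
                 capture = capture, corrected_pct = raw / capture),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf(
    "localization efficiency: raw %.2f%%, capture %.3f, corrected %.2f%%\n",
    x$raw_pct, x$capture, x$corrected_pct))
  invisible(x)
}

#' Capture fraction of the granule mask
#'
#' Fraction of the true cluster (posterior mRNA) signal that falls inside
#' the mask. The reference for "true signal" is either a noiseless truth
#' render of the clusters, or the mRNA channel itself segmented above a
#' threshold.
#'
#' @param mrna_stack mRNA channel, or a truth render of cluster signal only.
#' @param mask logical 3D granule mask.
#' @param reference `"truth"` to treat `mrna_stack` as the true cluster
#'   signal (background-free), or `"self"` to first self-segment the mRNA
#'   channel (Otsu) and use its supra-threshold signal as reference.
#' @return Capture fraction in (0, 1].
#' @export
capture_fraction <- function(mrna_stack, mask, reference = c("truth", "self")) {
  reference <- match.arg(reference)
  m <- .as_array(mrna_stack)
  stopifnot(all(dim(mask) == dim(m)))
  if (reference == "self") {
    thr <- .otsu_threshold(m)
    keep <- m > thr
    m <- m * keep
  }
  total <- sum(m)
  if (total <= 0) stop("zero true signal: capture fraction undefined")
  max(min(sum(m[mask]) / total, 1), .Machine$double.eps)
}
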