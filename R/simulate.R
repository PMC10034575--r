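#' Simulation configuration for a synthetic treatment series
#'
#' The simulator emulates the dosimetric situation of pelvic adaptive
#' radiotherapy at desk scale: a reference dose conformal to a CTV-plus-
#' margin PTV with a finite-gradient penumbra, per-fraction rigid plus
#' smooth elastic deformations of the target and neighbouring organs at
#' risk, a scheduled dose fixed in the reference frame, and an adapted
#' dose re-conformed to the deformed target.
#'
#' Defaults: 64^3 grid at 2 mm; CTV ellipsoid semi-axes (25, 20, 20) mm at
#' the grid center; 2 Gy x 6 fractions; 4 mm penumbra scale (~5%/mm
#' falloff); 5 mm interfraction translation SD and 3 mm elastic amplitude
#' (pelvic-target motion scale); 5 mm PTV margin; contour edit-class mix
#' 25/22/11/2 of 61 and adaptive-delivery probability 45/61.
#'
#' @param grid_shape voxel counts per axis.
#' @param spacing_mm per-axis voxel size (mm).
#' @param ctv_semiaxes_mm CTV ellipsoid semi-axes (mm).
#' @param ctv_center_mm CTV center (mm); default grid center.
#' @param dose_per_fraction_gy prescribed dose per fraction (Gy).
#' @param n_fractions fractions per series (>= 1).
#' @param penumbra_mm dose falloff scale (mm) outside the PTV.
#' @param drift_sd_mm per-axis SD (mm) of the rigid interfraction
#'   translation.
#' @param deform_amp_mm amplitude (mm) of the smooth elastic deformation.
#' @param margin_mm CTV-to-PTV margin (mm).
#' @param edit_class_probs length-4 sampling weights for edit classes 0-3.
#' @param p_adapted probability a fraction is delivered with the adaptive
#'   plan.
#' @param oars list of organ-at-risk specs (`label`, `semiaxes_mm`,
#'   `offset_mm` from the CTV center); default bladder-like and
#'   rectum-like ellipsoids.
#' @param seed integer seed recorded in the series manifest.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(64, 64, 64),
                       spacing_mm = c(2, 2, 2),
                       ctv_semiaxes_mm = c(25, 20, 20),
                       ctv_center_mm = NULL,
                       dose_per_fraction_gy = 2,
                       n_fractions = 6,
                       penumbra_mm = 4,
                       drift_sd_mm = 5,
                       deform_amp_mm = 3,
                       margin_mm = 5,
                       edit_class_probs = c(25, 22, 11, 2) / 61,
                       p_adapted = 45 / 61,
                       oars = NULL,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 2)) stop("grid_shape must be >= 2 per axis")
  if (any(spacing_mm <= 0) || any(ctv_semiaxes_mm <= 0) || penumbra_mm <= 0)
    stop("all lengths must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (drift_sd_mm < 0 || deform_amp_mm < 0 || margin_mm < 0)
    stop("drift, deformation amplitude and margin must be >= 0")
  if (is.null(ctv_center_mm))
    ctv_center_mm <- (grid_shape - 1) * spacing_mm / 2
  if (is.null(oars)) {
    oars <- list(
      list(label = "bladder", semiaxes_mm = c(20, 15, 15),
           offset_mm = c(0, 40, 5)),
      list(label = "rectum", semiaxes_mm = c(12, 12, 30),
           offset_mm = c(0, -35, 0))
    )
  }
  structure(list(
    grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
    ctv_semiaxes_mm = as.numeric(ctv_semiaxes_mm),
    ctv_center_mm = as.numeric(ctv_center_mm),
    dose_per_fraction_gy = dose_per_fraction_gy,
    n_fractions = as.integer(n_fractions),
    penumbra_mm = penumbra_mm, drift_sd_mm = drift_sd_mm,
    deform_amp_mm = deform_amp_mm, margin_mm = margin_mm,
    edit_class_probs = edit_class_probs / sum(edit_class_probs),
    p_adapted = p_adapted, oars = oars, seed = as.integer(seed)
  ), class = "sim_config")
}

# Physical voxel-center coordinate arrays for a config grid.
sim_coords <- function(config) {
  sh <- config$grid_shape; sp <- config$spacing_mm
  ax <- lapply(1:3, function(a) (seq_len(sh[a]) - 1) * sp[a])
  list(
    x = array(rep(ax[[1]], times = sh[2] * sh[3]), dim = sh),
    y = array(rep(rep(ax[[2]], each = sh[1]), times = sh[3]), dim = sh),
    z = array(rep(ax[[3]], each = sh[1] * sh[2]), dim = sh)
  )
}

ellipsoid_mask <- function(coords, center, semiaxes) {
  ((coords$x - center[1]) / semiaxes[1])^2 +
  ((coords$y - center[2]) / semiaxes[2])^2 +
  ((coords$z - center[3]) / semiaxes[3])^2 <= 1
}

# Conformal dose surrogate: prescription inside the PTV, sigmoidal falloff
# with Euclidean distance d outside: Rx / (1 + exp(d/penumbra - 3)).
conformal_dose <- function(ptv_voxels, config) {
  rx <- config$dose_per_fraction_gy
  cap <- 15 * config$penumbra_mm          # dose < 1e-5 Rx beyond the cap
  d <- distance_transform(ptv_voxels, config$spacing_mm, cap = cap)
  vals <- rx / (1 + exp(d / config$penumbra_mm - 3))
  vals[d >= cap] <- 0                     # truncate the far tail to zero
  vals[ptv_voxels] <- rx
  vals
}

#' Build the reference plan of a synthetic series
#'
#' Reference CTV (ellipsoid), PTV (margin expansion) and a conformal
#' reference dose with sigmoidal penumbra. Coverage goals hold on the CTV
#' by construction (uniform prescription inside the PTV).
#'
#' @param config a [sim_config()].
#' @return an object of class `reference_plan`: list with `config`, `ctv`,
#'   `ptv`, `dose` and per-OAR reference masks.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  coords <- sim_coords(config)
  sp <- config$spacing_mm
  ctv <- structure_mask(
    ellipsoid_mask(coords, config$ctv_center_mm, config$ctv_semiaxes_mm),
    "CTV", sp)
  ptv <- expand_margin(ctv, config$margin_mm)
  dose <- dose_grid(conformal_dose(ptv$voxels, config), sp)
  oars <- lapply(config$oars, function(o)
    structure_mask(
      ellipsoid_mask(coords, config$ctv_center_mm + o$offset_mm,
                     o$semiaxes_mm),
      o$label, sp))
  structure(list(config = config, ctv = ctv, ptv = ptv, dose = dose,
                 oars = oars, coords = coords),
            class = "reference_plan")
}

# Smooth elastic displacement sampled on the grid: one low-frequency
# sinusoidal mode per component, scaled so the peak magnitude equals the
# configured amplitude.
sample_elastic <- function(ref) {
  config <- ref$config
  if (config$deform_amp_mm == 0) {
    z <- array(0, dim = config$grid_shape)
    return(list(z, z, z))
  }
  extent <- (config$grid_shape - 1) * config$spacing_mm
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  phase <- stats::runif(3, 0, 2 * pi)
  amp <- stats::runif(3, -1, 1)
  amp <- amp / max(abs(amp)) * config$deform_amp_mm
  arg <- 2 * pi * (dir[1] * ref$coords$x + dir[2] * ref$coords$y +
                   dir[3] * ref$coords$z) / max(extent)
  lapply(1:3, function(c3) amp[c3] * sin(arg + phase[c3]))
}

# Warp a reference-frame logical mask to the fraction frame using the
# approximate inverse of the forward map x -> x + t + e(x).
warp_mask <- function(mask, elastic, translation, coords) {
  pts <- cbind(as.numeric(coords$x) - translation[1] - as.numeric(elastic[[1]]),
               as.numeric(coords$y) - translation[2] - as.numeric(elastic[[2]]),
               as.numeric(coords$z) - translation[3] - as.numeric(elastic[[3]]))
  v <- interp_trilinear(mask$voxels * 1.0, mask$spacing, mask$origin, pts,
                        fill = 0)
  structure_mask(array(v >= 0.5, dim = dim(mask$voxels)),
                 switch(mask$label, CTV = "iCTV", mask$label),
                 mask$spacing, mask$origin)
}

#' Sample one synthetic fraction
#'
#' Draws a rigid translation (per-axis normal with SD `drift_sd_mm`) plus a
#' smooth elastic component, deforms the CTV and OARs accordingly, keeps
#' the scheduled dose fixed in the reference frame, and recomputes the
#' adapted dose conformally to the deformed target (iCTV expanded by the
#' PTV margin). The stored displacement field maps reference points to
#' fraction points (pull-back convention).
#'
#' @param ref a `reference_plan` from [make_reference()].
#' @param index 1-based fraction number.
#' @param translation optional fixed translation (mm) overriding the random
#'   draw (used for controlled experiments).
#' @param elastic optional list of three displacement-component arrays
#'   overriding the random elastic draw.
#' @return a `fraction_record`.
#' @export
sample_fraction <- function(ref, index, translation = NULL, elastic = NULL) {
  stopifnot(inherits(ref, "reference_plan"))
  config <- ref$config
  if (is.null(translation))
    translation <- stats::rnorm(3, 0, config$drift_sd_mm)
  if (is.null(elastic)) elastic <- sample_elastic(ref)
  sh <- config$grid_shape
  vectors <- array(0, dim = c(sh, 3))
  for (c3 in 1:3)
    vectors[, , , c3] <- translation[c3] + elastic[[c3]]
  dvf <- displacement_field(vectors, config$spacing_mm)
  ictv <- warp_mask(ref$ctv, elastic, translation, ref$coords)
  oars <- lapply(ref$oars, function(o)
    warp_mask(o, elastic, translation, ref$coords))
  iptv <- expand_margin(ictv, config$margin_mm)
  adapted <- dose_grid(conformal_dose(iptv$voxels, config),
                       config$spacing_mm)
  edit_class <- sample(0:3, 1, prob = config$edit_class_probs)
  delivered <- if (stats::runif(1) < config$p_adapted) "adapted" else "scheduled"
  fraction_record(index, ictv, scheduled_dose = ref$dose,
                  adapted_dose = adapted, dvf = dvf, oars = oars,
                  delivered_plan = delivered, edit_class = edit_class)
}

#' Simulate a complete synthetic treatment series
#'
#' Deterministic given `config$seed`. The same seed with a different PTV
#' margin reproduces the identical deformation draws (the anatomy of the
#' day does not depend on the plan), so margin policies can be compared on
#' matched fractions.
#'
#' @param config a [sim_config()].
#' @return a `series_record`.
#' @export
simulate_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- make_reference(config)
  set.seed(config$seed)
  fractions <- lapply(seq_len(config$n_fractions), function(i)
    sample_fraction(ref, i))
  series_record(ref$ctv, ref$dose,
                prescription_gy = config$dose_per_fraction_gy * config$n_fractions,
                dose_per_fraction_gy = config$dose_per_fraction_gy,
                ptv_margin_mm = config$margin_mm,
                fractions = fractions)
}

#' Generate a cohort of synthetic treatment series
#'
#' Per-series seeds are derived from the master seed; per-series fraction
#' counts and drift settings can vary. Optionally writes every series to
#' disk via [write_series()].
#'
#' @param n_series number of series.
#' @param base_config a [sim_config()] supplying shared settings.
#' @param seed master seed.
#' @param n_fractions integer vector (recycled) of per-series fraction
#'   counts; default `base_config$n_fractions`.
#' @param drift_sd_mm numeric vector (recycled) of per-series drift SDs;
#'   default `base_config$drift_sd_mm`.
#' @param out_dir if non-`NULL`, write each series under
#'   `out_dir/series_XX/`.
#' @return list with `series` (list of `series_record`) and `manifest`
#'   (a [tibble::tibble] of per-series settings and seeds).
#' @export
generate_cohort <- function(n_series, base_config = sim_config(), seed = 1L,
                            n_fractions = NULL, drift_sd_mm = NULL,
                            out_dir = NULL) {
  if (is.null(n_fractions)) n_fractions <- base_config$n_fractions
  if (is.null(drift_sd_mm)) drift_sd_mm <- base_config$drift_sd_mm
  n_fractions <- rep_len(n_fractions, n_series)
  drift_sd_mm <- rep_len(drift_sd_mm, n_series)
  series_seeds <- (as.integer(seed) * 1000L + seq_len(n_series)) %% .Machine$integer.max
  series <- vector("list", n_series)
  for (s in seq_len(n_series)) {
    cfg <- base_config
    cfg$n_fractions <- as.integer(n_fractions[s])
    cfg$drift_sd_mm <- drift_sd_mm[s]
    cfg$seed <- series_seeds[s]
    series[[s]] <- simulate_series(cfg)
    if (!is.null(out_dir))
      write_series(series[[s]], file.path(out_dir, sprintf("series_%02d", s)))
  }
  manifest <- tibble::tibble(
    series = seq_len(n_series), seed = series_seeds,
    n_fractions = as.integer(n_fractions), drift_sd_mm = drift_sd_mm,
    margin_mm = base_config$margin_mm,
    dose_per_fraction_gy = base_config$dose_per_fraction_gy)
  list(series = series, manifest = manifest)
}
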