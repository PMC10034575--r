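#' Expand a structure by an isotropic margin
#'
#' CTV-to-PTV expansion on the voxel lattice: a voxel belongs to the
#' expanded structure iff its center lies within Euclidean distance
#' `margin_mm` of any source-voxel center. Anisotropic spacing is honored
#' through the distance transform. `margin_mm = 0` returns the mask
#' unchanged.
#'
#' @param mask a non-empty `structure_mask`.
#' @param margin_mm margin in mm (>= 0).
#' @param label label for the expanded mask (default: `PTV` for `CTV`,
#'   `iPTV` for `iCTV`, otherwise the source label).
#' @return a `structure_mask`.
#' @export
expand_margin <- function(mask, margin_mm, label = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  if (margin_mm < 0) stop("margin must be >= 0")
  if (is.null(label))
    label <- switch(mask$label, CTV = "PTV", iCTV = "iPTV", mask$label)
  if (margin_mm == 0)
    return(structure_mask(mask$voxels, label, mask$spacing, mask$origin))
  dist <- distance_transform(mask$voxels, mask$spacing,
                             cap = margin_mm + max(mask$spacing))
  structure_mask(dist <= margin_mm + 1e-9, label, mask$spacing, mask$origin)
}

#' Map a fraction dose into the reference frame (pull-back)
#'
#' `dose_ref(x) = dose_fraction(x + v(x))` by trilinear interpolation, where
#' `v` is the displacement field on the reference grid. Mapped points
#' falling outside the fraction dose grid contribute 0 Gy; their count is
#' attached as attribute `n_oob` and raises a warning when positive.
#'
#' @param dose_fraction `dose_grid` in the fraction frame.
#' @param dvf `displacement_field` on the reference grid (reference ->
#'   fraction).
#' @param points optional n x 3 matrix of reference-frame physical points
#'   at which to evaluate (default: all voxel centers of the dvf grid, in
#'   which case a `dose_grid` on that grid is returned).
#' @param warn warn when mapped points fall out of bounds (default `TRUE`).
#' @return a `dose_grid` (or a numeric vector when `points` is supplied),
#'   with attribute `n_oob`.
#' @export
pull_back <- function(dose_fraction, dvf, points = NULL, warn = TRUE) {
  stopifnot(inherits(dose_fraction, "dose_grid"),
            inherits(dvf, "displacement_field"))
  as_grid <- is.null(points)
  if (as_grid) {
    sh <- grid_shape(dvf)
    idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                                 k = seq_len(sh[3])))
    points <- voxel_coords(dvf, idx)
    disp <- matrix(dvf$vectors, ncol = 3)
  } else {
    disp <- vapply(1:3, function(c3)
      interp_trilinear(dvf$vectors[, , , c3], dvf$spacing, dvf$origin,
                       points),
      numeric(nrow(points)))
  }
  mapped <- points + disp
  v <- interp_trilinear(dose_fraction$values, dose_fraction$spacing,
                        dose_fraction$origin, mapped, fill = 0)
  n_oob <- attr(v, "n_oob")
  if (warn && n_oob > 0)
    warning(sprintf("%d mapped points fell outside the dose grid (0 Gy)",
                    n_oob))
  if (!as_grid) return(v)
  sh <- grid_shape(dvf)
  out <- dose_grid(array(pmax(as.numeric(v), 0), dim = sh),
                   dvf$spacing, dvf$origin)
  attr(out, "n_oob") <- n_oob
  out
}

# Regular grid covering the same physical extent as `g` at `res` mm.
resample_geometry <- function(g, res) {
  sh <- grid_shape(g)
  extent <- (sh - 1) * g$spacing
  new_sh <- pmax(2L, as.integer(floor(extent / res)) + 1L)
  list(shape = new_sh, spacing = rep(res, 3), origin = g$origin)
}

#' Accumulate per-fraction doses in the reference frame
#'
#' Each fraction's dose (scheduled, adapted, or whichever plan was actually
#' delivered) is pulled back to the reference frame through that fraction's
#' displacement field and summed voxel-wise on a grid resampled to
#' `resolution_mm`.
#'
#' @param series a `series_record` whose fractions carry displacement
#'   fields.
#' @param plan_choice `"adapted"`, `"scheduled"` or `"as_delivered"`.
#' @param resolution_mm accumulation grid resolution in mm (default 1).
#' @return an object of class `accumulated_dose`: list with `grid` (a
#'   `dose_grid` in reference geometry), `n_fractions`, `provenance`
#'   (plan used per fraction) and `n_oob` (total out-of-bounds pull-back
#'   points).
#' @export
accumulate <- function(series,
                       plan_choice = c("adapted", "scheduled", "as_delivered"),
                       resolution_mm = 1) {
  stopifnot(inherits(series, "series_record"))
  plan_choice <- match.arg(plan_choice)
  geo <- resample_geometry(series$reference_dose, resolution_mm)
  idx <- as.matrix(expand.grid(i = seq_len(geo$shape[1]),
                               j = seq_len(geo$shape[2]),
                               k = seq_len(geo$shape[3])))
  pts <- sweep(sweep(idx - 1, 2, geo$spacing, `*`), 2, geo$origin, `+`)
  total <- numeric(nrow(pts))
  prov <- character(length(series$fractions))
  n_oob <- 0L
  for (s in seq_along(series$fractions)) {
    f <- series$fractions[[s]]
    plan <- switch(plan_choice,
                   adapted = "adapted", scheduled = "scheduled",
                   as_delivered = f$delivered_plan)
    dgrid <- if (plan == "adapted") f$adapted_dose else f$scheduled_dose
    if (is.null(dgrid))
      stop(sprintf("fraction %d has no %s dose", f$index, plan))
    if (is.null(f$dvf))
      stop(sprintf("fraction %d has no displacement field", f$index))
    v <- pull_back(dgrid, f$dvf, points = pts, warn = FALSE)
    n_oob <- n_oob + attr(v, "n_oob")
    total <- total + v
    prov[s] <- plan
  }
  grid <- dose_grid(array(pmax(total, 0), dim = geo$shape),
                    geo$spacing, geo$origin)
  structure(list(grid = grid, n_fractions = length(series$fractions),
                 provenance = prov, n_oob = n_oob),
            class = "accumulated_dose")
}

#' Resample a structure mask onto an accumulation grid
#'
#' Nearest-neighbour style resampling via trilinear interpolation of the
#' 0/1 field thresholded at 0.5.
#'
#' @param mask a `structure_mask`.
#' @param grid a `dose_grid` defining the target geometry.
#' @return a `structure_mask` on `grid`'s geometry.
#' @export
resample_mask <- function(mask, grid) {
  sh <- grid_shape(grid)
  idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  pts <- voxel_coords(grid, idx)
  v <- interp_trilinear(mask$voxels * 1.0, mask$spacing, mask$origin, pts,
                        fill = 0)
  structure_mask(array(v >= 0.5, dim = sh), mask$label,
                 grid$spacing, grid$origin)
}
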