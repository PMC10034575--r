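#' Compute a dose-volume histogram
#'
#' Differential and cumulative DVH of the dose inside a structure, on
#' uniform bins covering `[0, max in-structure dose]`. The cumulative curve
#' gives, at each bin's lower edge, the fraction of the structure receiving
#' at least that dose (so `cumulative[1] == 1`).
#'
#' @param dose a `dose_grid`.
#' @param mask a `structure_mask` on the same grid.
#' @param bin_width bin width in Gy (> 0).
#' @return an object of class `dvh` with fields `bin_edges` (length
#'   nbins + 1), `differential` (sums to 1), `cumulative` (at lower edges),
#'   `structure_volume_ml`, `min_dose`, `max_dose`, `mean_dose`.
#' @export
compute_dvh <- function(dose, mask, bin_width) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  check_same_grid(dose, mask, "dose", sprintf("mask '%s'", mask$label))
  if (!any(mask$voxels)) stop("empty structure")
  if (bin_width <= 0) stop("bin_width must be > 0")
  d <- dose$values[mask$voxels]
  dmax <- max(d)
  nbins <- max(1L, ceiling(dmax / bin_width + 1e-12))
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  # findInterval puts a value equal to an edge into the bin above; clamp the
  # maximum into the top bin
  bin <- pmin(findInterval(d, edges, left.open = FALSE), nbins)
  bin[d <= 0] <- 1L
  counts <- tabulate(bin, nbins)
  differential <- counts / length(d)
  # cumulative curve evaluated exactly from voxel doses at every bin edge:
  # fraction of voxels with dose >= edge (so the curve is authoritative for
  # Dx/Vx and free of in-bin placement error at the edges)
  sd <- sort(d)
  n_lt <- findInterval(edges, sd, left.open = TRUE)  # voxels strictly below
  cum_all <- (length(d) - n_lt) / length(d)
  structure(list(
    bin_edges = edges,
    differential = differential,
    cumulative = cum_all[seq_len(nbins)],
    cum_top = cum_all[nbins + 1L],
    structure_volume_ml = length(d) * prod(dose$spacing) / 1000,
    min_dose = min(d),
    max_dose = dmax,
    mean_dose = mean(d)
  ), class = "dvh")
}

# Cumulative volume fraction (>= dose) as a piecewise-linear function of
# dose, defined at all bin edges. Returns the two vectors for interpolation.
dvh_cum_curve <- function(dvh) {
  list(dose = dvh$bin_edges,
       cum = c(dvh$cumulative, dvh$cum_top))
}

#' Dose covering x% of the structure (Dx%)
#'
#' Largest dose `D` such that the cumulative DVH at `D` is at least
#' `x/100`, with linear interpolation between bin edges. `x = 100` returns
#' the lower edge of the coldest occupied bin.
#'
#' @param dvh a `dvh`.
#' @param x volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  q <- x / 100
  cc <- dvh_cum_curve(dvh)
  # walk from the hot end: the largest edge with cum >= q
  j <- max(which(cc$cum >= q - 1e-15))
  if (j == length(cc$dose)) return(min(cc$dose[j], dvh$max_dose))
  c0 <- cc$cum[j]; c1 <- cc$cum[j + 1]
  d <- cc$dose[j] + (c0 - q) / (c0 - c1) * (cc$dose[j + 1] - cc$dose[j])
  # the true cumulative drops to 0 just above the hottest voxel; keep the
  # interpolated answer inside the realized dose range
  min(d, dvh$max_dose)
}

#' Volume (% of structure) receiving at least a threshold dose (Vx)
#'
#' Linear interpolation of the cumulative DVH at the threshold.
#'
#' @param dvh a `dvh`.
#' @param threshold dose threshold in Gy (>= 0).
#' @return percentage of the structure volume in \[0, 100\].
#' @export
volume_at_dose <- function(dvh, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  cc <- dvh_cum_curve(dvh)
  if (threshold > max(cc$dose)) return(0)
  100 * stats::approx(cc$dose, cc$cum, xout = threshold, rule = 2)$y
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' `gEUD(a) = (sum_i v_i d_i^a)^(1/a)` over the differential DVH with bin
#' midpoint doses `d_i` and volume fractions `v_i`. Large negative `a`
#' emphasizes cold spots (targets; `a = -20` is the conventional target
#' exponent here); positive `a` emphasizes hot spots (serial organs at
#' risk). The dominant dose is factored out before exponentiation so the
#' evaluation is stable for |a| of several hundred.
#'
#' @param dvh a `dvh`, or a list with fields `d` (doses) and `v` (volume
#'   fractions summing to 1) for voxel-exact evaluation.
#' @param a gEUD exponent (non-zero).
#' @return gEUD in Gy. If any occupied bin has zero dose and `a < 0`, the
#'   mathematical limit 0 is returned with a warning.
#' @export
geud <- function(dvh, a) {
  if (a == 0) stop("a = 0 is not supported (geometric-mean limit not used)")
  if (inherits(dvh, "dvh")) {
    occ <- dvh$differential > 0
    mid <- (dvh$bin_edges[-length(dvh$bin_edges)] +
            dvh$bin_edges[-1]) / 2
    # midpoints of the extreme occupied bins can overshoot the realized
    # dose range by half a bin; clamp so gEUD stays within [min, max] dose
    d <- pmin(pmax(mid[occ], dvh$min_dose), dvh$max_dose)
    v <- dvh$differential[occ]
  } else {
    keep <- dvh$v > 0
    d <- dvh$d[keep]
    v <- dvh$v[keep]
  }
  v <- v / sum(v)
  if (a < 0 && any(d <= 0)) {
    warning("zero dose inside structure with a < 0: gEUD -> 0 (limit)")
    return(0)
  }
  dref <- if (a > 0) max(d) else min(d)  # dominant term for stability
  dref * sum(v * (d / dref)^a)^(1 / a)
}

#' Minimum dose inside a structure
#'
#' @param dose a `dose_grid`.
#' @param mask a non-empty `structure_mask` on the same grid.
#' @return minimum voxel dose in Gy.
#' @export
min_dose <- function(dose, mask) {
  check_same_grid(dose, mask, "dose", sprintf("mask '%s'", mask$label))
  if (!any(mask$voxels)) stop("empty structure")
  min(dose$values[mask$voxels])
}

#' Default DVH bin width: 0.1% of the prescription
#' @param prescription_gy prescription dose in Gy.
#' @export
default_bin_width <- function(prescription_gy) prescription_gy / 1000

#' Coverage and cold-spot endpoints for one structure under one plan
#'
#' Computes D95/D98/D99, minimum dose, V95/V100 (thresholds at 95% and 100%
#' of the prescription) and gEUD from one DVH. Dx values are clamped from
#' below at the exact voxel minimum, which the linear in-bin interpolation
#' can undercut by at most one bin width.
#'
#' @param dose a `dose_grid`.
#' @param mask a `structure_mask`.
#' @param prescription_gy prescription dose (Gy) defining V95/V100
#'   thresholds and the default bin width.
#' @param a gEUD exponent (default -20, the target convention).
#' @param bin_width DVH bin width in Gy; default 0.1% of prescription.
#' @return a one-row [tibble::tibble] with columns `structure`, `min_dose`,
#'   `d95`, `d98`, `d99`, `v95`, `v100`, `geud`, `mean_dose`,
#'   `volume_ml`.
#' @export
endpoints <- function(dose, mask, prescription_gy, a = -20,
                      bin_width = default_bin_width(prescription_gy)) {
  dvh <- compute_dvh(dose, mask, bin_width)
  dmin <- dvh$min_dose
  dx <- function(x) max(dose_at_volume(dvh, x), dmin)
  tibble::tibble(
    structure = mask$label,
    min_dose = dmin,
    d95 = dx(95), d98 = dx(98), d99 = dx(99),
    v95 = volume_at_dose(dvh, 0.95 * prescription_gy),
    v100 = volume_at_dose(dvh, 1.00 * prescription_gy),
    geud = geud(dvh, a),
    mean_dose = dvh$mean_dose,
    volume_ml = dvh$structure_volume_ml
  )
}
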