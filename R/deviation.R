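#' Percentage deviation of a per-fraction metric from its planning reference
#'
#' `100 * (value - reference) / reference`. Deviations of coverage metrics
#' on the deformed target are normalized by the same metric evaluated for
#' the undeformed CTV under the reference plan.
#'
#' @param value_fraction metric value at the fraction.
#' @param value_reference metric value for the planning reference (> 0).
#' @return deviation in percent.
#' @export
percent_deviation <- function(value_fraction, value_reference) {
  if (any(value_reference <= 0)) stop("degenerate reference")
  100 * (value_fraction - value_reference) / value_reference
}

#' Adaptation gain
#'
#' Difference of the adapted-plan and scheduled-plan percentage deviations
#' for the same fraction and characteristic (positive favors adaptation).
#'
#' @param dev_adapted,dev_scheduled deviations in percent.
#' @return gain in percent.
#' @export
adaptation_gain <- function(dev_adapted, dev_scheduled) {
  dev_adapted - dev_scheduled
}

dev_characteristics <- c("min_dose", "d95", "d98", "d99", "v95", "geud")

#' Per-fraction deviation table for a treatment series
#'
#' For every fraction, evaluates coverage endpoints of the deformed target
#' (iCTV, or the iCTV expanded by `eval_margin_mm`) against that fraction's
#' scheduled and adapted dose grids, normalizes each by the reference value
#' (undeformed CTV, reference plan — same expansion applied), and tabulates
#' the adaptation gain. Fractions without an adapted dose get `NA` adapted
#' deviations.
#'
#' @param series a `series_record`.
#' @param a_target gEUD exponent for the target (default -20).
#' @param eval_margin_mm optional margin (mm) by which both the per-fraction
#'   target and the reference CTV are expanded before evaluation (0 =
#'   evaluate the CTV/iCTV itself). Evaluating the iPTV probes what a plan
#'   with that PTV margin would deliver.
#' @param characteristics subset of
#'   `c("min_dose", "d95", "d98", "d99", "v95", "geud")`.
#' @return a [tibble::tibble] with columns `fraction`, `structure`,
#'   `characteristic`, `reference_value`, `value_scheduled`,
#'   `value_adapted`, `pct_dev_scheduled`, `pct_dev_adapted`, `gain`.
#' @export
series_deviations <- function(series, a_target = -20, eval_margin_mm = 0,
                              characteristics = dev_characteristics) {
  stopifnot(inherits(series, "series_record"))
  characteristics <- match.arg(characteristics, dev_characteristics,
                               several.ok = TRUE)
  rx_fx <- series$dose_per_fraction_gy
  expand <- function(mask) {
    if (eval_margin_mm > 0) expand_margin(mask, eval_margin_mm) else mask
  }
  struct_label <- if (eval_margin_mm > 0) "iPTV" else "iCTV"
  ref_mask <- expand(series$reference_ctv)
  ref <- endpoints(series$reference_dose, ref_mask, rx_fx, a = a_target)
  rows <- lapply(series$fractions, function(f) {
    m <- expand(f$ictv)
    sch <- endpoints(f$scheduled_dose, m, rx_fx, a = a_target)
    ada <- if (!is.null(f$adapted_dose))
      endpoints(f$adapted_dose, m, rx_fx, a = a_target) else NULL
    per_char <- lapply(characteristics, function(ch) {
      rv <- ref[[ch]]
      vs <- sch[[ch]]
      va <- if (is.null(ada)) NA_real_ else ada[[ch]]
      ps <- percent_deviation(vs, rv)
      pa <- if (is.na(va)) NA_real_ else percent_deviation(va, rv)
      tibble::tibble(
        fraction = f$index, structure = struct_label, characteristic = ch,
        reference_value = rv, value_scheduled = vs, value_adapted = va,
        pct_dev_scheduled = ps, pct_dev_adapted = pa,
        gain = if (is.na(pa)) NA_real_ else adaptation_gain(pa, ps))
    })
    do.call(rbind, per_char)
  })
  do.call(rbind, rows)
}

#' Summarize a deviation distribution
#'
#' Median with an empirical 5th--95th percentile interval (the "90%
#' interval" used for reporting deviation spreads), or optionally a
#' bootstrap confidence interval of the median.
#'
#' @param values numeric vector of deviations (%).
#' @param interval `"percentile"` (default; empirical 5th/95th percentiles,
#'   linear interpolation between order statistics) or `"bootstrap"`
#'   (percentile bootstrap CI of the median).
#' @param n_boot bootstrap replicates (bootstrap mode only).
#' @return a one-row [tibble::tibble] with `median`, `lo90`, `hi90`, `n`.
#' @export
summarize_deviations <- function(values, interval = c("percentile", "bootstrap"),
                                 n_boot = 2000) {
  interval <- match.arg(interval)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  med <- stats::median(values)
  if (interval == "percentile") {
    qq <- stats::quantile(values, c(0.05, 0.95), names = FALSE, type = 7)
  } else {
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(values, replace = TRUE)), numeric(1))
    qq <- stats::quantile(meds, c(0.025, 0.975), names = FALSE, type = 7)
  }
  tibble::tibble(median = med, lo90 = qq[1], hi90 = qq[2],
                 n = length(values))
}

#' Empirical cumulative distribution function of deviations
#'
#' Right-continuous step function: 0 below the sample minimum, `rank/n` at
#' each sample point, 1 at and above the maximum.
#'
#' @param values numeric vector.
#' @return a function mapping dose deviation (%) to cumulative probability.
#' @export
deviation_ecdf <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values")
  stats::ecdf(values)
}
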