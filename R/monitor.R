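#' Configuration of the IGRT-to-ART switching rule
#'
#' A series being delivered with the scheduled plan is monitored offline
#' through its per-fraction target gEUD deviations. A fraction is a
#' violation when its deviation falls strictly below `cutpoint_pct`. The
#' series is flagged for a switch to adaptive delivery when the second
#' violation occurs within the first `early_window` fractions, or when,
#' beyond that window, violations exceed a proportion `late_proportion` of
#' fractions.
#'
#' @param cutpoint_pct violation cutpoint in percent (< 0; default -7).
#' @param early_window number of initial fractions for the
#'   second-violation trigger (default 9).
#' @param late_proportion violation proportion threshold after the early
#'   window (default 0.20).
#' @param late_scope `"all"` (default): the running proportion is taken
#'   over all fractions observed so far; `"post_window"`: over fractions
#'   after the early window only.
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(cutpoint_pct = -7, early_window = 9,
                        late_proportion = 0.20,
                        late_scope = c("all", "post_window")) {
  late_scope <- match.arg(late_scope)
  if (cutpoint_pct >= 0) stop("cutpoint must be negative")
  if (early_window < 1) stop("early_window must be >= 1")
  if (late_proportion <= 0 || late_proportion >= 1)
    stop("late_proportion must be in (0, 1)")
  structure(list(cutpoint_pct = cutpoint_pct,
                 early_window = as.integer(early_window),
                 late_proportion = late_proportion,
                 late_scope = late_scope),
            class = "rule_config")
}

#' Evaluate the IGRT-to-ART switching rule on a deviation sequence
#'
#' Sequential, fraction-by-fraction evaluation of scheduled-plan target
#' gEUD deviations (%). After each fraction `i`:
#' * if fraction `i` is within the early window and it completes the
#'   second violation, switch (trigger `second_violation_early`);
#' * if `i` is beyond the early window and the running violation
#'   proportion exceeds `late_proportion`, switch (trigger
#'   `proportion_late`).
#'
#' Once a switch fires, later fractions are not evaluated. If both
#' triggers would fire at the same fraction, `second_violation_early` is
#' reported.
#'
#' @param deviations numeric vector of per-fraction deviations (%),
#'   ordered by fraction.
#' @param config a [rule_config()].
#' @return an object of class `switch_decision`: list with `switched`,
#'   `switch_after_fraction` (or `NA`), `trigger` (`second_violation_early`,
#'   `proportion_late` or `none`) and `violation_indices` (indices observed
#'   up to the decision point).
#' @export
evaluate_switch <- function(deviations, config = rule_config()) {
  if (length(deviations) == 0L) stop("empty deviation sequence")
  stopifnot(inherits(config, "rule_config"))
  violations <- integer(0)
  for (i in seq_along(deviations)) {
    if (deviations[i] < config$cutpoint_pct)  # strictly below the cutpoint
      violations <- c(violations, i)
    early <- i <= config$early_window
    if (early && length(violations) == 2L && violations[2] == i) {
      return(structure(list(switched = TRUE, switch_after_fraction = i,
                            trigger = "second_violation_early",
                            violation_indices = violations),
                       class = "switch_decision"))
    }
    if (!early) {
      n_viol <- if (config$late_scope == "all") length(violations)
                else sum(violations > config$early_window)
      n_seen <- if (config$late_scope == "all") i
                else i - config$early_window
      if (n_seen > 0 && n_viol / n_seen > config$late_proportion) {
        return(structure(list(switched = TRUE, switch_after_fraction = i,
                              trigger = "proportion_late",
                              violation_indices = violations),
                         class = "switch_decision"))
      }
    }
  }
  structure(list(switched = FALSE, switch_after_fraction = NA_integer_,
                 trigger = "none", violation_indices = violations),
            class = "switch_decision")
}

#' Tally contour edit classes
#'
#' Edits of daily propagated target contours are graded 0 (none), 1
#' (minor), 2 (intermediate), 3 (major). Returns counts and percentages
#' (reported to 1 decimal).
#'
#' @param edit_classes integer vector with values in 0..3.
#' @param total denominator for the percentages; defaults to
#'   `length(edit_classes)`. Supply it explicitly when some fractions of
#'   the series carry no grading but still count toward the total.
#' @return a [tibble::tibble] with columns `edit_class`, `count`, `pct`
#'   (1-decimal percentage), `pct_raw`.
#' @export
tally_edits <- function(edit_classes, total = length(edit_classes)) {
  if (length(edit_classes) == 0L) stop("empty series")
  if (!all(edit_classes %in% 0:3)) stop("edit classes must be in 0..3")
  if (total < length(edit_classes)) stop("total below the number of gradings")
  counts <- vapply(0:3, function(k) sum(edit_classes == k), integer(1))
  pct_raw <- 100 * counts / total
  tibble::tibble(edit_class = 0:3, count = counts,
                 pct = round(pct_raw, 1), pct_raw = pct_raw)
}

#' Share of fractions delivered with the adaptive plan
#'
#' @param delivered_plans character vector of `"adapted"` / `"scheduled"`.
#' @return percentage of fractions delivered adaptively, rounded to 1
#'   decimal.
#' @export
delivered_fraction_share <- function(delivered_plans) {
  if (length(delivered_plans) == 0L) stop("empty series")
  if (!all(delivered_plans %in% c("adapted", "scheduled")))
    stop("delivered plans must be 'adapted' or 'scheduled'")
  round(100 * sum(delivered_plans == "adapted") / length(delivered_plans), 1)
}

#' Check target coverage goals
#'
#' Coverage goals for the prescribed dose: V100% strictly above 95% of the
#' structure volume and D98% strictly above 98% of the prescription.
#'
#' @param endpoint_row a one-row endpoint table from [endpoints()].
#' @param prescription_gy prescription dose in Gy.
#' @return list with logical `v100_pass`, `d98_pass`, `all_pass`.
#' @export
coverage_check <- function(endpoint_row, prescription_gy) {
  v100_pass <- endpoint_row$v100 > 95
  d98_pass <- endpoint_row$d98 > 0.98 * prescription_gy
  list(v100_pass = v100_pass, d98_pass = d98_pass,
       all_pass = v100_pass && d98_pass)
}
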