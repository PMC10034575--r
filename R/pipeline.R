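#' Per-fraction deviation table for a cohort of series
#'
#' Runs [series_deviations()] over a list of series and stacks the results
#' with a `series` column.
#'
#' @param series_list list of `series_record`s.
#' @param a_target target gEUD exponent (default -20).
#' @param eval_margin_mm evaluation margin passed to [series_deviations()].
#' @return a [tibble::tibble].
#' @export
evaluate_cohort <- function(series_list, a_target = -20, eval_margin_mm = 0) {
  rows <- lapply(seq_along(series_list), function(s) {
    tbl <- series_deviations(series_list[[s]], a_target = a_target,
                             eval_margin_mm = eval_margin_mm)
    tbl$series <- s
    tbl[, c("series", setdiff(names(tbl), "series"))]
  })
  do.call(rbind, rows)
}

#' Apply the switching rule to every series of a deviation table
#'
#' Uses the scheduled-plan gEUD deviations, ordered by fraction, of each
#' series.
#'
#' @param deviations a cohort deviation table from [evaluate_cohort()].
#' @param config a [rule_config()].
#' @return a [tibble::tibble] with one row per series: `series`,
#'   `switched`, `switch_after_fraction`, `trigger`, `n_violations`.
#' @export
monitor_cohort <- function(deviations, config = rule_config()) {
  ge <- deviations[deviations$characteristic == "geud", ]
  rows <- lapply(split(ge, ge$series), function(tbl) {
    tbl <- tbl[order(tbl$fraction), ]
    dec <- evaluate_switch(tbl$pct_dev_scheduled, config)
    tibble::tibble(series = tbl$series[1], switched = dec$switched,
                   switch_after_fraction = dec$switch_after_fraction,
                   trigger = dec$trigger,
                   n_violations = length(dec$violation_indices))
  })
  do.call(rbind, rows)
}

#' Accumulated-dose gEUD deviations and adaptation gains for a cohort
#'
#' For each series, accumulates the adapted and the scheduled plans over
#' all fractions, evaluates the target gEUD of each accumulated dose on the
#' reference CTV (resampled to the accumulation grid), and normalizes by
#' the series-total reference gEUD (`n_fractions` times the per-fraction
#' reference, since gEUD is homogeneous of degree one in dose).
#'
#' @param series_list list of `series_record`s.
#' @param a_target target gEUD exponent (default -20).
#' @param resolution_mm accumulation resolution (default 1 mm).
#' @return a [tibble::tibble] with per-series columns `pct_geud_adapted`,
#'   `pct_geud_scheduled`, `gain`.
#' @export
accumulate_gains <- function(series_list, a_target = -20, resolution_mm = 1) {
  rows <- lapply(seq_along(series_list), function(s) {
    ser <- series_list[[s]]
    n <- length(ser$fractions)
    rx_fx <- ser$dose_per_fraction_gy
    ref_geud <- geud(compute_dvh(ser$reference_dose, ser$reference_ctv,
                                 default_bin_width(rx_fx)), a_target)
    pct <- vapply(c("adapted", "scheduled"), function(plan) {
      acc <- accumulate(ser, plan, resolution_mm = resolution_mm)
      mask <- resample_mask(ser$reference_ctv, acc$grid)
      g <- geud(compute_dvh(acc$grid, mask,
                            default_bin_width(n * rx_fx)), a_target)
      percent_deviation(g, n * ref_geud)
    }, numeric(1))
    tibble::tibble(series = s, pct_geud_adapted = pct[["adapted"]],
                   pct_geud_scheduled = pct[["scheduled"]],
                   gain = adaptation_gain(pct[["adapted"]],
                                          pct[["scheduled"]]))
  })
  do.call(rbind, rows)
}

#' Summary table of a cohort deviation table
#'
#' Median and empirical 5th--95th percentile interval per characteristic
#' and plan.
#'
#' @param deviations a cohort deviation table.
#' @return a [tibble::tibble] keyed by `characteristic` and `plan`.
#' @export
summarize_cohort <- function(deviations) {
  chars <- unique(deviations$characteristic)
  rows <- lapply(chars, function(ch) {
    sub <- deviations[deviations$characteristic == ch, ]
    do.call(rbind, lapply(c("scheduled", "adapted"), function(plan) {
      col <- if (plan == "scheduled") sub$pct_dev_scheduled
             else sub$pct_dev_adapted
      s <- summarize_deviations(col)
      tibble::tibble(characteristic = ch, plan = plan, median = s$median,
                     lo90 = s$lo90, hi90 = s$hi90, n = s$n)
    }))
  })
  do.call(rbind, rows)
}

#' Run the full synthetic evaluation pipeline
#'
#' simulate -> evaluate -> monitor -> accumulate -> report, for each PTV
#' margin under study, on matched deformation draws. Writes
#' `deviations.csv`, `summaries.csv`, `decisions.json`,
#' `accumulated_gains.csv`, `stats.csv`, per-margin accumulated scheduled
#' dose NRRDs, `report.md` and `run.json` (settings + seed) under
#' `out_dir`.
#'
#' @param base_config a [sim_config()]; its margin field is overridden by
#'   `margins_mm`.
#' @param n_series number of series per cohort (default 10).
#' @param margins_mm PTV margins to evaluate (default `c(5, 0)`).
#' @param a_target target gEUD exponent (default -20).
#' @param rule a [rule_config()].
#' @param seed master seed.
#' @param resolution_mm accumulation resolution (default: native grid
#'   spacing).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `deviations`, `summaries`, `decisions`, `gains`,
#'   `stats`, `report` (all tibbles or character), invisibly when writing.
#' @export
run_pipeline <- function(base_config = sim_config(), n_series = 10,
                         margins_mm = c(5, 0), a_target = -20,
                         rule = rule_config(), seed = 1L,
                         resolution_mm = NULL, out_dir = NULL) {
  if (length(margins_mm) < 1) stop("at least one margin is required")
  if (a_target == 0) stop("target exponent must be non-zero")
  if (is.null(resolution_mm)) resolution_mm <- min(base_config$spacing_mm)
  all_dev <- list(); all_dec <- list(); all_gain <- list()
  cohorts <- list()
  for (m in margins_mm) {
    cfg <- base_config
    cfg$margin_mm <- m
    cohort <- generate_cohort(n_series, cfg, seed = seed)
    cohorts[[as.character(m)]] <- cohort
    dev <- evaluate_cohort(cohort$series, a_target = a_target)
    dev$margin_mm <- m
    dec <- monitor_cohort(dev, rule)
    dec$margin_mm <- m
    gains <- accumulate_gains(cohort$series, a_target = a_target,
                              resolution_mm = resolution_mm)
    gains$margin_mm <- m
    all_dev[[as.character(m)]] <- dev
    all_dec[[as.character(m)]] <- dec
    all_gain[[as.character(m)]] <- gains
  }
  deviations <- do.call(rbind, all_dev)
  decisions <- do.call(rbind, all_dec)
  gains <- do.call(rbind, all_gain)
  summaries <- do.call(rbind, lapply(margins_mm, function(m) {
    s <- summarize_cohort(deviations[deviations$margin_mm == m, ])
    s$margin_mm <- m
    s
  }))
  # paired comparison of adapted vs scheduled gEUD deviations per margin
  stats_tbl <- do.call(rbind, lapply(margins_mm, function(m) {
    ge <- deviations[deviations$margin_mm == m &
                     deviations$characteristic == "geud", ]
    ok <- !is.na(ge$gain)
    wt <- wilcoxon_signed_rank(ge$gain[ok])
    wt$comparison <- sprintf("geud_adapted_vs_scheduled_margin%gmm", m)
    wt
  }))
  report <- cohort_report(cohorts[[1]]$series, margins_mm[1])
  out <- list(deviations = deviations, summaries = summaries,
              decisions = decisions, gains = gains, stats = stats_tbl,
              report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(deviations, file.path(out_dir, "deviations.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(gains, file.path(out_dir, "accumulated_gains.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_tbl, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(decisions, file.path(out_dir, "decisions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (m in margins_mm) {
      ser1 <- cohorts[[as.character(m)]]$series[[1]]
      acc <- accumulate(ser1, "scheduled", resolution_mm = resolution_mm)
      write_nrrd(acc$grid$values,
                 file.path(out_dir,
                           sprintf("accumulated_scheduled_margin%gmm_series01.nrrd", m)),
                 spacing = acc$grid$spacing, origin = acc$grid$origin,
                 type = "double")
    }
    writeLines(report, file.path(out_dir, "report.md"))
    jsonlite::write_json(
      list(seed = seed, n_series = n_series, margins_mm = margins_mm,
           a_target = a_target,
           rule = unclass(rule),
           config = unclass(base_config)[setdiff(names(base_config), "oars")],
           resolution_mm = resolution_mm),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Per-series cohort report
#'
#' Markdown table of per-series settings: fractions, dose per fraction,
#' PTV volume (mL) and the share of adaptively delivered fractions.
#'
#' @param series_list list of `series_record`s.
#' @param margin_mm margin used for the PTV volume column.
#' @return character vector of markdown lines.
#' @export
cohort_report <- function(series_list, margin_mm = 5) {
  if (!length(series_list)) stop("empty cohort")
  lines <- c(
    sprintf("# Synthetic cohort report (PTV margin %g mm)", margin_mm),
    "",
    "| Series | Fractions | Dose/fraction (Gy) | PTV volume (mL) | Adaptive fractions (%) |",
    "|---|---|---|---|---|")
  for (s in seq_along(series_list)) {
    ser <- series_list[[s]]
    ptv <- expand_margin(ser$reference_ctv, margin_mm)
    vol <- sum(ptv$voxels) * voxel_volume(ptv) / 1000
    share <- delivered_fraction_share(
      vapply(ser$fractions, function(f) f$delivered_plan, character(1)))
    lines <- c(lines, sprintf("| %d | %d | %.1f | %.1f | %.1f |",
                              s, length(ser$fractions),
                              ser$dose_per_fraction_gy, vol, share))
  }
  lines
}
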