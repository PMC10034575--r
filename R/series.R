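#' Construct a per-fraction treatment record
#'
#' One delivered fraction: the deformed target of the day (iCTV), organ-at-
#' risk masks, the scheduled dose (reference plan recomputed on the anatomy
#' of the day), optionally the adapted (re-optimized) dose, the displacement
#' field linking reference to fraction geometry, which plan was delivered,
#' and the contour edit class (0 none, 1 minor, 2 intermediate, 3 major).
#'
#' @param index 1-based fraction number.
#' @param ictv `structure_mask` of the deformed CTV.
#' @param scheduled_dose `dose_grid` of the scheduled plan.
#' @param adapted_dose `dose_grid` of the adapted plan, or `NULL` when the
#'   fraction was delivered as IGRT only (absence is explicit: zero dose is
#'   a legal value).
#' @param dvf `displacement_field` (reference -> fraction).
#' @param oars list of `structure_mask` organ-at-risk masks.
#' @param delivered_plan `"adapted"` or `"scheduled"`.
#' @param edit_class integer 0--3.
#' @return an object of class `fraction_record`.
#' @export
fraction_record <- function(index, ictv, scheduled_dose, adapted_dose = NULL,
                            dvf = NULL, oars = list(),
                            delivered_plan = c("adapted", "scheduled"),
                            edit_class = 0L) {
  delivered_plan <- match.arg(delivered_plan)
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stop("fraction index must be >= 1")
  edit_class <- as.integer(edit_class)
  if (is.na(edit_class) || !edit_class %in% 0:3)
    stop(sprintf("edit_class must be in 0..3, got %s", edit_class))
  stopifnot(inherits(ictv, "structure_mask"),
            inherits(scheduled_dose, "dose_grid"))
  if (!is.null(adapted_dose)) stopifnot(inherits(adapted_dose, "dose_grid"))
  if (!is.null(dvf)) stopifnot(inherits(dvf, "displacement_field"))
  check_same_grid(ictv, scheduled_dose,
                  sprintf("fraction %d iCTV", index),
                  sprintf("fraction %d scheduled dose", index))
  if (!is.null(adapted_dose))
    check_same_grid(adapted_dose, scheduled_dose,
                    sprintf("fraction %d adapted dose", index),
                    sprintf("fraction %d scheduled dose", index))
  for (o in oars) stopifnot(inherits(o, "structure_mask"))
  structure(list(index = index, ictv = ictv, oars = oars,
                 scheduled_dose = scheduled_dose, adapted_dose = adapted_dose,
                 dvf = dvf, delivered_plan = delivered_plan,
                 edit_class = edit_class),
            class = "fraction_record")
}

#' Construct a treatment series
#'
#' @param reference_ctv `structure_mask` of the planning-CT CTV.
#' @param reference_dose `dose_grid` of the reference plan.
#' @param prescription_gy total prescribed dose (Gy).
#' @param dose_per_fraction_gy prescribed dose per fraction (Gy); must
#'   satisfy `dose_per_fraction_gy * n_fractions == prescription_gy`.
#' @param ptv_margin_mm CTV-to-PTV margin (mm).
#' @param fractions ordered list of `fraction_record`s (>= 1, unique
#'   indices).
#' @return an object of class `series_record`.
#' @export
series_record <- function(reference_ctv, reference_dose, prescription_gy,
                          dose_per_fraction_gy, ptv_margin_mm, fractions) {
  stopifnot(inherits(reference_ctv, "structure_mask"),
            inherits(reference_dose, "dose_grid"))
  check_same_grid(reference_ctv, reference_dose,
                  "reference CTV", "reference dose")
  if (length(fractions) < 1L) stop("a series needs at least one fraction")
  idx <- vapply(fractions, function(f) f$index, integer(1))
  if (anyDuplicated(idx)) stop("fraction indices must be unique")
  n <- length(fractions)
  if (abs(dose_per_fraction_gy * n - prescription_gy) > 1e-9)
    stop(sprintf(
      "prescription inconsistent: %g Gy/fraction x %d fractions != %g Gy total",
      dose_per_fraction_gy, n, prescription_gy))
  for (f in fractions)
    check_same_grid(f$ictv, reference_dose,
                    sprintf("fraction %d iCTV", f$index), "reference dose")
  structure(list(reference_ctv = reference_ctv,
                 reference_dose = reference_dose,
                 prescription_gy = prescription_gy,
                 dose_per_fraction_gy = dose_per_fraction_gy,
                 ptv_margin_mm = ptv_margin_mm,
                 fractions = fractions[order(idx)]),
            class = "series_record")
}

#' @export
print.series_record <- function(x, ...) {
  cat(sprintf(
    "<series_record> %d fractions, %.3g Gy total (%.3g Gy/fraction), PTV margin %g mm\n",
    length(x$fractions), x$prescription_gy, x$dose_per_fraction_gy,
    x$ptv_margin_mm))
  cat(sprintf("  grid %s, spacing %s mm\n",
              paste(grid_shape(x$reference_dose), collapse = "x"),
              paste(format(x$reference_dose$spacing), collapse = " ")))
  invisible(x)
}

#' Write a treatment series to disk
#'
#' Volumes go to NRRD files (masks as 8-bit 0/1, doses and displacement
#' fields as double) and a JSON manifest ties them together. The written
#' series round-trips through [read_series()] bit-exactly for masks and
#' within 1e-6 Gy for doses.
#'
#' @param series a `series_record`.
#' @param out_dir output directory (created if missing).
#' @param encoding NRRD payload encoding, `"gzip"` or `"raw"`.
#' @return path to the JSON manifest, invisibly.
#' @export
write_series <- function(series, out_dir, encoding = "gzip") {
  stopifnot(inherits(series, "series_record"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))
  g <- series$reference_dose
  wv <- function(x, name, type) {
    write_nrrd(x, file.path(out_dir, name), spacing = g$spacing,
               origin = g$origin, type = type, encoding = encoding)
    name
  }
  manifest <- list(
    prescription_Gy = series$prescription_gy,
    dose_per_fraction_Gy = series$dose_per_fraction_gy,
    ptv_margin_mm = series$ptv_margin_mm,
    reference = list(
      ctv = wv(series$reference_ctv$voxels, "reference_ctv.nrrd", "uint8"),
      dose = wv(series$reference_dose$values, "reference_dose.nrrd", "double")
    ),
    fractions = lapply(series$fractions, function(f) {
      pre <- sprintf("fx%02d", f$index)
      rec <- list(
        index = f$index,
        delivered_plan = f$delivered_plan,
        edit_class = f$edit_class,
        ictv = wv(f$ictv$voxels, paste0(pre, "_ictv.nrrd"), "uint8"),
        scheduled_dose = wv(f$scheduled_dose$values,
                            paste0(pre, "_scheduled.nrrd"), "double")
      )
      if (!is.null(f$adapted_dose))
        rec$adapted_dose <- wv(f$adapted_dose$values,
                               paste0(pre, "_adapted.nrrd"), "double")
      if (!is.null(f$dvf))
        rec$dvf <- wv(f$dvf$vectors, paste0(pre, "_dvf.nrrd"), "double")
      if (length(f$oars)) {
        rec$oars <- lapply(f$oars, function(o) {
          list(label = o$label,
               file = wv(o$voxels,
                         sprintf("%s_oar_%s.nrrd", pre, o$label), "uint8"))
        })
      }
      rec
    })
  )
  manifest_path <- file.path(out_dir, "series.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a treatment series from a JSON manifest
#'
#' Inverse of [write_series()]. All type and grid invariants are validated;
#' a missing volume file raises an error naming the file, and a fraction
#' whose grid disagrees with the reference raises an error naming the
#' fraction.
#'
#' @param manifest_path path to `series.json`.
#' @return a `series_record`.
#' @export
read_series <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path))
  root <- dirname(manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  rv <- function(name) {
    p <- file.path(root, name)
    if (!file.exists(p)) stop(sprintf("volume file missing: %s", p))
    read_nrrd(p)
  }
  ref_dose_raw <- rv(m$reference$dose)
  ref_dose <- dose_grid(ref_dose_raw$values, ref_dose_raw$spacing,
                        ref_dose_raw$origin)
  ref_ctv_raw <- rv(m$reference$ctv)
  ref_ctv <- structure_mask(ref_ctv_raw$values, "CTV",
                            ref_ctv_raw$spacing, ref_ctv_raw$origin)
  fracs <- lapply(m$fractions, function(fr) {
    ictv_raw <- rv(fr$ictv)
    ictv <- structure_mask(ictv_raw$values, "iCTV",
                           ictv_raw$spacing, ictv_raw$origin)
    sched_raw <- rv(fr$scheduled_dose)
    sched <- dose_grid(sched_raw$values, sched_raw$spacing, sched_raw$origin)
    adapted <- NULL
    if (!is.null(fr$adapted_dose)) {
      a <- rv(fr$adapted_dose)
      adapted <- dose_grid(a$values, a$spacing, a$origin)
    }
    dvf <- NULL
    if (!is.null(fr$dvf)) {
      v <- rv(fr$dvf)
      dvf <- displacement_field(v$values, v$spacing, v$origin)
    }
    oars <- lapply(fr$oars %||% list(), function(o) {
      raw <- rv(o$file)
      structure_mask(raw$values, o$label, raw$spacing, raw$origin)
    })
    fraction_record(fr$index, ictv, sched, adapted, dvf, oars,
                    fr$delivered_plan, fr$edit_class)
  })
  series_record(ref_ctv, ref_dose, m$prescription_Gy,
                m$dose_per_fraction_Gy, m$ptv_margin_mm, fracs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
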