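#' Construct a 3D dose grid
#'
#' A `dose_grid` holds a scalar dose field (Gy) on a regular, axis-aligned
#' voxel lattice. Arrays are stored `[x, y, z]` (x fastest, matching the
#' fastest-axis-first convention of the on-disk NRRD volumes) and voxel
#' centers sit at `origin + (index - 1) * spacing` in physical mm.
#'
#' @param values numeric 3D array of per-voxel dose in Gy; all finite and
#'   non-negative.
#' @param spacing numeric length-3, per-axis voxel size in mm (> 0).
#' @param origin numeric length-3, physical position (mm) of the center of
#'   voxel (1, 1, 1).
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("dose values must be a 3D array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be non-negative")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (length(origin) != 3L) stop("origin must have 3 components")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Construct a binary structure mask
#'
#' Masks share the grid geometry of the dose they are evaluated against.
#' Target labels (`CTV`, `iCTV`, `PTV`, `iPTV`) must be non-empty.
#'
#' @param voxels logical 3D array; `TRUE` marks voxels inside the structure.
#' @param label structure label, one of `CTV`, `iCTV`, `PTV`, `iPTV`,
#'   `bladder`, `rectum`, `other`.
#' @inheritParams dose_grid
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, label = "other", spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("mask voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  labels <- c("CTV", "iCTV", "PTV", "iPTV", "bladder", "rectum", "other")
  label <- match.arg(label, labels)
  if (label %in% c("CTV", "iCTV", "PTV", "iPTV") && !any(voxels))
    stop(sprintf("target structure '%s' must be non-empty", label))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (length(origin) != 3L) stop("origin must have 3 components")
  structure(list(voxels = voxels, label = label, spacing = spacing,
                 origin = origin),
            class = "structure_mask")
}

#' Construct a displacement field
#'
#' Per-voxel 3-vectors (mm) defined on the reference grid. The convention is
#' pull-back: the vector at reference point `x` points to the corresponding
#' fraction-frame point `x + v(x)`.
#'
#' @param vectors numeric 4D array of shape `c(nx, ny, nz, 3)`; component
#'   order (x, y, z) in mm; finite everywhere.
#' @inheritParams dose_grid
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing, origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement vectors must be an (nx, ny, nz, 3) array")
  if (anyNA(vectors) || any(!is.finite(vectors)))
    stop("displacement vectors must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "displacement_field")
}

grid_shape <- function(g) {
  if (inherits(g, "structure_mask")) dim(g$voxels)
  else if (inherits(g, "displacement_field")) dim(g$vectors)[1:3]
  else dim(g$values)
}

#' Physical coordinates of voxel centers
#'
#' @param g a `dose_grid`, `structure_mask` or `displacement_field`.
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of physical coordinates in mm.
#' @export
voxel_coords <- function(g, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

#' Voxel volume in mm^3
#' @param g a grid-bearing object.
#' @export
voxel_volume <- function(g) prod(g$spacing)

# Grid geometry equality within 1e-6 mm on spacing/origin plus exact shape.
grids_compatible <- function(a, b, tol = 1e-6) {
  identical(grid_shape(a), grid_shape(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what_a = "grid A", what_b = "grid B") {
  if (!grids_compatible(a, b))
    stop(sprintf(
      "grid mismatch between %s [%s] and %s [%s]",
      what_a, paste(grid_shape(a), collapse = "x"),
      what_b, paste(grid_shape(b), collapse = "x")))
  invisible(TRUE)
}

#' Trilinear interpolation of a 3D field at arbitrary physical points
#'
#' Points outside the grid's voxel-center bounding box return `fill` and are
#' counted in the `n_oob` attribute of the result.
#'
#' @param values 3D numeric array.
#' @param spacing,origin grid geometry (mm).
#' @param pts n x 3 matrix of physical query points (mm).
#' @param fill value for out-of-bounds points (default 0).
#' @return numeric vector of length n with attribute `n_oob`.
#' @keywords internal
interp_trilinear <- function(values, spacing, origin, pts, fill = 0) {
  d <- dim(values)
  # continuous 1-based index coordinates
  u <- sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`) + 1
  oob <- u[, 1] < 1 | u[, 1] > d[1] |
         u[, 2] < 1 | u[, 2] > d[2] |
         u[, 3] < 1 | u[, 3] > d[3]
  u[oob, ] <- 1  # placeholder; overwritten with fill below
  i0 <- pmin(pmax(floor(u[, 1]), 1), d[1] - 1L)
  j0 <- pmin(pmax(floor(u[, 2]), 1), d[2] - 1L)
  k0 <- pmin(pmax(floor(u[, 3]), 1), d[3] - 1L)
  if (d[1] == 1L) i0 <- rep(1, nrow(u))
  if (d[2] == 1L) j0 <- rep(1, nrow(u))
  if (d[3] == 1L) k0 <- rep(1, nrow(u))
  fx <- u[, 1] - i0; fy <- u[, 2] - j0; fz <- u[, 3] - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  lin <- function(i, j, k) values[cbind(i, j, k)]
  v <-
    lin(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
    lin(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
    lin(i1, j1, k0) * fx       * fy       * (1 - fz) +
    lin(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    lin(i1, j0, k1) * fx       * (1 - fy) * fz +
    lin(i0, j1, k1) * (1 - fx) * fy       * fz +
    lin(i1, j1, k1) * fx       * fy       * fz
  v[oob] <- fill
  attr(v, "n_oob") <- sum(oob)
  v
}

#' Euclidean distance transform of a binary mask
#'
#' Distance (mm) from each voxel center to the nearest `TRUE` voxel center,
#' honoring anisotropic spacing; 0 inside the mask. Computed as a separable
#' squared-distance transform (exact per-axis minimisation, vectorised
#' across lines). `cap` bounds the search radius: distances beyond it are
#' returned as `cap` (useful when only a finite shell matters).
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param spacing per-axis voxel size, mm.
#' @param cap maximum distance of interest, mm (default `Inf`).
#' @return numeric 3D array of distances in mm.
#' @export
distance_transform <- function(mask, spacing, cap = Inf) {
  if (!any(mask)) stop("distance transform of an empty mask")
  d <- dim(mask)
  big <- if (is.finite(cap)) cap^2 else
    sum((d * spacing)^2) + 1
  f <- array(ifelse(mask, 0, big), dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    s <- spacing[ax]
    if (n == 1L) next
    kmax <- n - 1L
    if (is.finite(cap)) kmax <- min(kmax, ceiling(cap / s))
    g <- f
    perm_in <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    gm <- aperm(g, perm_in)            # axis of interest first
    dm <- dim(gm)
    gm <- matrix(gm, nrow = dm[1])     # rows: positions along axis
    res <- gm
    for (k in seq_len(kmax)) {
      cost <- (k * s)^2
      # shift down: candidate from position i - k
      res[(k + 1):dm[1], ] <- pmin(res[(k + 1):dm[1], , drop = FALSE],
                                   gm[1:(dm[1] - k), , drop = FALSE] + cost)
      # shift up: candidate from position i + k
      res[1:(dm[1] - k), ] <- pmin(res[1:(dm[1] - k), , drop = FALSE],
                                   gm[(k + 1):dm[1], , drop = FALSE] + cost)
    }
    res <- array(res, dim = dm)
    f <- aperm(res, order(perm_in))
  }
  out <- sqrt(f)
  if (is.finite(cap)) out[out > cap] <- cap
  out
}
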