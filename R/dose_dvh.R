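# Dose grids, structure masks, cumulative DVHs and the standard
# plan-quality metrics (Dx, Vx, Dmean, homogeneity and conformity indices,
# D95-based renormalization).

#' A 3D dose grid
#'
#' @param values 3D array of doses, Gy; dimensions index `(x, y, z)`.
#' @param voxel_size Voxel edge lengths `(dx, dy, dz)`, mm (default 4 mm
#'   isotropic, the usual clinical dose-grid resolution).
#' @param origin Coordinates of the first voxel center, mm.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(values, voxel_size = c(4, 4, 4), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' A binary structure mask on a dose-grid lattice
#'
#' @param name Structure name (e.g. `"PTV"`, `"bladder"`, `"rectum"`,
#'   `"body"`).
#' @param mask Logical 3D array, same shape as the dose grid it refers to.
#' @return Object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  structure(list(name = name, mask = mask), class = "structure_mask")
}

mask_values <- function(grid, mask) {
  m <- if (inherits(mask, "structure_mask")) mask$mask else mask
  if (!identical(dim(m), dim(grid$values)))
    stop("mask shape differs from dose grid")
  v <- grid$values[m]
  if (!length(v)) stop("structure mask is empty")
  v
}

#' Cumulative dose-volume histogram
#'
#' Cumulative relative-volume curve on uniform dose bins: `volume[k]` is
#' the fraction of the structure receiving at least `dose[k]`. The curve
#' starts at 1 at 0 Gy, is non-increasing, and reaches 0 above the maximum
#' dose.
#'
#' @param grid A [dose_grid()].
#' @param mask A [structure_mask()] or logical array.
#' @param bin_width Bin width in Gy (default 0.1).
#' @return Object of class `dvh_curve` with `dose` (bin edges, Gy) and
#'   `volume` (fractions).
#' @export
compute_dvh <- function(grid, mask, bin_width = 0.1) {
  v <- mask_values(grid, mask)
  edges <- seq(0, max(v) + 2 * bin_width, by = bin_width)
  vol <- vapply(edges, function(d) mean(v >= d), numeric(1))
  structure(list(dose = edges, volume = vol, bin_width = bin_width,
                 n_voxels = length(v)),
            class = "dvh_curve")
}

#' Dose-at-volume and volume-at-dose
#'
#' `dvh_D(curve, x)` is the minimum dose received by the hottest `x%` of
#' the structure volume, read off the cumulative curve with linear
#' interpolation. `dvh_V(curve, d)` is the percent volume receiving at
#' least `d` Gy. For prescription-relative `V_p` metrics (e.g. V95 meaning
#' 95% of the prescription), convert with `d = p/100 * rx` first.
#'
#' @param curve A `dvh_curve`.
#' @param x Volume level, percent.
#' @param d Dose level, Gy.
#' @return Gy (`dvh_D`) or percent volume (`dvh_V`).
#' @export
dvh_D <- function(curve, x) {
  v <- x / 100
  if (v < 0 || v > 1) stop("volume level must be in [0, 100]")
  vol <- curve$volume; dose <- curve$dose
  if (v <= min(vol)) return(dose[max(which(vol == min(vol) | vol >= v))])
  # largest dose at which the cumulative volume still reaches v
  k <- max(which(vol >= v))
  if (k == length(vol) || vol[k] == v) return(dose[k])
  # interpolate on the falling segment between edges k and k+1
  d0 <- dose[k]; d1 <- dose[k + 1]; v0 <- vol[k]; v1 <- vol[k + 1]
  if (v1 == v0) return(d0)
  d0 + (v - v0) / (v1 - v0) * (d1 - d0)
}

#' @rdname dvh_D
#' @export
dvh_V <- function(curve, d) {
  if (d < 0) stop("dose level must be non-negative")
  if (d >= max(curve$dose)) return(0)
  100 * stats::approx(curve$dose, curve$volume, xout = d, rule = 2)$y
}

#' Homogeneity index
#'
#' `HI = (D2 - D98) / D50` (ICRU 83); 0 for a perfectly uniform dose.
#' An ICRU 62 style alternative `D2 / D98` is available via `formula`.
#'
#' @param curve A `dvh_curve`.
#' @param formula `"icru83"` (default) or `"ratio"` (`D2/D98`).
#' @return Dimensionless index.
#' @export
homogeneity_index <- function(curve, formula = c("icru83", "ratio")) {
  formula <- match.arg(formula)
  d2 <- dvh_D(curve, 2); d98 <- dvh_D(curve, 98); d50 <- dvh_D(curve, 50)
  switch(formula, icru83 = (d2 - d98) / d50, ratio = d2 / d98)
}

#' Conformity index
#'
#' `CI = (body volume receiving >= rx) / (PTV volume)` (ICRU 62 style
#' prescription-isodose ratio). Values above 1 indicate the prescription
#' isodose spills outside the target.
#'
#' @param grid A [dose_grid()].
#' @param ptv_mask,body_mask [structure_mask()] or logical arrays.
#' @param rx Prescription dose, Gy.
#' @return Dimensionless index.
#' @export
conformity_index <- function(grid, ptv_mask, body_mask, rx) {
  pm <- if (inherits(ptv_mask, "structure_mask")) ptv_mask$mask else ptv_mask
  bm <- if (inherits(body_mask, "structure_mask")) body_mask$mask else body_mask
  n_ptv <- sum(pm)
  if (n_ptv == 0) stop("PTV mask is empty")
  sum(grid$values >= rx & bm) / n_ptv
}

#' Renormalize a dose grid so that D95 of the PTV equals a target dose
#'
#' Applies the uniform scaling `target / D95(PTV)`, the normalization
#' convention "95% of the PTV receives the prescription dose".
#'
#' @param grid A [dose_grid()].
#' @param ptv_mask [structure_mask()] or logical array.
#' @param target Target D95 in Gy (e.g. 76).
#' @param bin_width DVH bin width used to locate D95 (default 0.01 Gy so
#'   the post-condition holds to 0.01 Gy).
#' @return A rescaled [dose_grid()].
#' @export
renormalize_to_d95 <- function(grid, ptv_mask, target, bin_width = 0.01) {
  v <- mask_values(grid, ptv_mask)
  if (max(v) <= 0) stop("PTV receives no dose; cannot renormalize")
  d95 <- dvh_D(compute_dvh(grid, ptv_mask, bin_width), 95)
  if (d95 <= 0) stop("PTV D95 is zero; cannot renormalize")
  grid$values <- grid$values * (target / d95)
  grid
}

#' Mean, minimum and maximum structure dose
#'
#' Computed on the voxel values directly (not DVH-interpolated).
#'
#' @param grid A [dose_grid()].
#' @param mask [structure_mask()] or logical array.
#' @return Named numeric vector `c(mean, min, max)`, Gy.
#' @export
mean_min_max <- function(grid, mask) {
  v <- mask_values(grid, mask)
  c(mean = mean(v), min = min(v), max = max(v))
}

#' Table-style DVH metric panel for one plan
#'
#' Convenience wrapper computing the standard prostate plan-quality panel
#' for a structure: requested `D_x` points, prescription-relative `V_p`
#' points, mean/min/max, and (for the target) HI and CI.
#'
#' @param grid A [dose_grid()].
#' @param mask Structure mask.
#' @param rx Prescription dose, Gy.
#' @param d_levels Volume levels for `D_x`, percent.
#' @param v_levels Prescription-percent levels for `V_p`.
#' @param bin_width DVH bin width, Gy.
#' @return Named numeric vector of metrics.
#' @export
dvh_metrics <- function(grid, mask, rx, d_levels = c(2, 50, 98),
                        v_levels = c(95, 98, 100, 107), bin_width = 0.01) {
  curve <- compute_dvh(grid, mask, bin_width)
  mmm <- mean_min_max(grid, mask)
  out <- c(
    stats::setNames(vapply(d_levels, dvh_D, numeric(1), curve = curve),
                    paste0("D", d_levels)),
    stats::setNames(vapply(v_levels * rx / 100, dvh_V, numeric(1),
                           curve = curve), paste0("V", v_levels)),
    Dmean = unname(mmm["mean"]), Dmin = unname(mmm["min"]),
    Dmax = unname(mmm["max"]), HI = homogeneity_index(curve))
  out
}

#' Write / read the portable JSON dose-grid format
#'
#' Stores the array (column-major flattened), dimensions, voxel size and
#' origin under a version tag. Masks are stored the same way with 0/1
#' values via [write_mask_json()].
#'
#' @param grid A [dose_grid()].
#' @param path File path.
#' @return `read_dose_grid_json` returns a [dose_grid()].
#' @export
write_dose_grid_json <- function(grid, path) {
  obj <- list(schema = "vmatqa-dose-grid/1", dim = dim(grid$values),
              voxel_size = grid$voxel_size, origin = grid$origin,
              values = as.numeric(grid$values))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid_json
#' @export
read_dose_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "vmatqa-dose-grid/1"))
    stop("unknown dose-grid schema")
  dose_grid(array(obj$values, dim = obj$dim), obj$voxel_size, obj$origin)
}

#' @rdname write_dose_grid_json
#' @param mask A [structure_mask()].
#' @export
write_mask_json <- function(mask, path) {
  obj <- list(schema = "vmatqa-mask/1", name = mask$name,
              dim = dim(mask$mask), values = as.integer(mask$mask))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "vmatqa-mask/1")) stop("unknown mask schema")
  structure_mask(obj$name, array(as.logical(obj$values), dim = obj$dim))
}
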