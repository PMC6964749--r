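# In-field overlap volume histograms (OVH) and the library-lookup
# knowledge-based dose-volume prediction built on them.

#' Signed Euclidean distance field of a target structure
#'
#' Distance from each voxel center to the target surface: negative inside
#' the target, approximately zero on boundary voxels, positive outside
#' (exact Euclidean metric on voxel centers, anisotropic spacing
#' supported). Outside voxels carry the distance to the nearest target
#' voxel center; inside voxels carry minus (distance to the nearest
#' non-target voxel center less one voxel), so a voxel on the target
#' surface sits at 0.
#'
#' @param target_mask [structure_mask()] or logical 3D array.
#' @param grid A [dose_grid()] supplying the lattice spacing.
#' @return 3D numeric array of signed distances, mm.
#' @export
signed_distance_field <- function(target_mask, grid) {
  m <- if (inherits(target_mask, "structure_mask")) target_mask$mask else target_mask
  if (!identical(dim(m), dim(grid$values)))
    stop("target mask shape differs from grid")
  if (!any(m)) stop("target mask is empty")
  dm <- dim(m)
  d_out <- cpp_edt3d(as.logical(m), dm, grid$voxel_size)
  d_in <- cpp_edt3d(!m, dm, grid$voxel_size)
  h <- min(grid$voxel_size)
  sdf <- array(d_out, dim = dm)
  sdf[m] <- -(array(d_in, dim = dm)[m] - h)
  sdf
}

#' Restrict an OAR mask to the treatment-field extent
#'
#' Keeps the voxels whose superior-inferior (z) coordinate lies within the
#' jaw-projected field extent at isocenter. For coplanar full arcs the
#' lateral extent is rotationally swept, so the field restriction reduces
#' to a z slab.
#'
#' @param oar_mask [structure_mask()] or logical 3D array.
#' @param grid A [dose_grid()].
#' @param field_extent Length-2 `(z_low, z_high)` in mm, e.g. from
#'   [field_extent()].
#' @return Logical 3D array.
#' @export
infield_mask <- function(oar_mask, grid, field_extent) {
  m <- if (inherits(oar_mask, "structure_mask")) oar_mask$mask else oar_mask
  z <- grid$origin[3] + (seq_len(dim(m)[3]) - 1L) * grid$voxel_size[3]
  keep_z <- z >= field_extent[1] & z <= field_extent[2]
  out <- m
  out[, , !keep_z] <- FALSE
  if (!any(out))
    warning("no OAR voxels inside the field extent", call. = FALSE)
  out
}

#' Jaw-projected field extent of a plan along the leaf-side axis
#'
#' Union of the Y-jaw intervals over all control points of all arcs. The
#' beam-limiting-device Y axis maps to the patient superior-inferior axis
#' for coplanar arcs.
#'
#' @param plan A [vmat_plan()].
#' @return `c(low, high)` in mm at isocenter.
#' @export
field_extent <- function(plan) {
  lo <- Inf; hi <- -Inf
  for (arc in plan$arcs)
    for (cp in arc$control_points) {
      lo <- min(lo, cp$jaw_y[1]); hi <- max(hi, cp$jaw_y[2])
    }
  c(lo, hi)
}

#' In-field overlap volume histogram
#'
#' `OVH(r)` is the fraction of the in-field OAR volume lying within signed
#' distance `r` of the target surface (negative `r` = inside the target).
#' Both numerator and denominator are restricted to in-field voxels. The
#' curve is tabulated on a distance lattice spanning the observed signed
#' distances at `distance_step` (default 1 mm).
#'
#' @param target_mask,oar_mask [structure_mask()] or logical arrays.
#' @param grid A [dose_grid()].
#' @param field_extent Optional `(z_low, z_high)` mm; `NULL` uses the whole
#'   grid.
#' @param distance_step Lattice step, mm.
#' @return Object of class `ovh_curve` with `distances` (mm) and
#'   `fractions` (non-decreasing, reaching 1).
#' @export
compute_ovh <- function(target_mask, oar_mask, grid, field_extent = NULL,
                        distance_step = 1) {
  om <- if (inherits(oar_mask, "structure_mask")) oar_mask$mask else oar_mask
  if (!is.null(field_extent)) om <- infield_mask(om, grid, field_extent)
  if (!any(om)) stop("no in-field OAR voxels; OVH undefined")
  sdf <- signed_distance_field(target_mask, grid)
  d <- sdf[om]
  lat <- seq(floor(min(d)), ceiling(max(d)) + distance_step, by = distance_step)
  fr <- vapply(lat, function(r) mean(d <= r), numeric(1))
  structure(list(distances = lat, fractions = fr, step = distance_step,
                 n_voxels = length(d)),
            class = "ovh_curve")
}

#' Inverse OVH lookup: distance at a volume level
#'
#' The smallest distance at which the OVH reaches `v` percent, linearly
#' interpolated between lattice points.
#'
#' @param curve An `ovh_curve`.
#' @param v Volume level, percent.
#' @return Distance in mm.
#' @export
ovh_distance_at <- function(curve, v) {
  f <- v / 100
  if (f < 0 || f > 1) stop("volume level must be in [0, 100]")
  d <- curve$distances; fr <- curve$fractions
  if (f <= fr[1]) return(d[1])
  k <- which(fr >= f)[1]
  if (fr[k] == fr[k - 1]) return(d[k])
  d[k - 1] + (f - fr[k - 1]) / (fr[k] - fr[k - 1]) * (d[k] - d[k - 1])
}

#' Knowledge-base entry
#'
#' One prior patient (or a standardized Pareto-optimal re-plan of one) in
#' the dose database: per-OAR OVH geometry and the doses achieved at the
#' standard relative-volume levels.
#'
#' @param patient_id Identifier string.
#' @param source `"clinical"` or `"pareto"`.
#' @param ovh Named list (per OAR) of [compute_ovh()] curves.
#' @param achieved Named list (per OAR) of named numeric vectors: achieved
#'   dose (Gy) at each volume level, names are the levels in percent.
#' @return Object of class `kbp_entry`.
#' @export
kbp_entry <- function(patient_id, source = c("clinical", "pareto"), ovh, achieved) {
  source <- match.arg(source)
  for (oar in names(achieved)) {
    if (any(achieved[[oar]] < 0)) stop("achieved doses must be non-negative")
    if (is.null(names(achieved[[oar]])))
      stop("achieved dose vectors must be named by volume level")
  }
  structure(list(patient_id = patient_id, source = source,
                 ovh = ovh, achieved = achieved),
            class = "kbp_entry")
}

#' Build a knowledge base from a cohort
#'
#' @param cohort List; each element needs `patient_id`, `source`, `ovh`
#'   (named list of `ovh_curve` per OAR) and `dvh` (named list of
#'   `dvh_curve` per OAR).
#' @param levels Relative-volume levels in percent (default
#'   `c(10, 30, 50, 65, 80)`).
#' @return List of [kbp_entry()] objects.
#' @export
build_database <- function(cohort, levels = c(10, 30, 50, 65, 80)) {
  lapply(cohort, function(p) {
    achieved <- lapply(p$dvh, function(curve)
      stats::setNames(vapply(levels, dvh_D, numeric(1), curve = curve),
                      as.character(levels)))
    kbp_entry(p$patient_id, p$source, p$ovh, achieved)
  })
}

#' OVH-guided dose-volume prediction
#'
#' For each OAR and volume level `v`, an entry is eligible when its OVH
#' distance at `v` is no larger than the query's (its geometry is at least
#' as unfavorable); the prediction is the lowest achieved dose at `v` over
#' all eligible clinical and Pareto entries. When no entry is eligible the
#' entry with the nearest OVH distance is used and flagged as a fallback.
#'
#' @param query Named list (per OAR) of `ovh_curve` objects for the new
#'   patient.
#' @param db List of [kbp_entry()] objects.
#' @param levels Volume levels in percent.
#' @return Object of class `dose_prediction`: per OAR, a data frame with
#'   `level`, `dose` (Gy), `matched` (entry ids), `fallback` (logical).
#' @export
predict_dose_volumes <- function(query, db, levels = c(10, 30, 50, 65, 80)) {
  if (!length(db)) stop("knowledge base is empty")
  out <- lapply(names(query), function(oar) {
    rows <- lapply(levels, function(v) {
      dq <- ovh_distance_at(query[[oar]], v)
      have <- vapply(db, function(e)
        !is.null(e$ovh[[oar]]) && !is.null(e$achieved[[oar]][[as.character(v)]]),
        logical(1))
      if (!any(have)) stop("no database entry covers OAR '", oar, "'")
      de <- vapply(db[have], function(e) ovh_distance_at(e$ovh[[oar]], v),
                   numeric(1))
      dose <- vapply(db[have], function(e) e$achieved[[oar]][[as.character(v)]],
                     numeric(1))
      ids <- vapply(db[have], function(e) e$patient_id, character(1))
      elig <- de <= dq + 1e-9
      if (any(elig)) {
        k <- which(elig)[which.min(dose[elig])]
        data.frame(level = v, dose = min(dose[elig]),
                   matched = paste(ids[elig], collapse = ";"),
                   fallback = FALSE, stringsAsFactors = FALSE)
      } else {
        k <- which.min(abs(de - dq))
        data.frame(level = v, dose = dose[k], matched = ids[k],
                   fallback = TRUE, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })
  names(out) <- names(query)
  structure(out, class = "dose_prediction")
}

## ---- JSON-lines persistence ----

ovh_to_list <- function(c) list(distances = c$distances, fractions = c$fractions,
                                step = c$step, n_voxels = c$n_voxels)
ovh_from_list <- function(l) structure(
  list(distances = as.numeric(unlist(l$distances)),
       fractions = as.numeric(unlist(l$fractions)),
       step = as.numeric(l$step), n_voxels = as.integer(l$n_voxels)),
  class = "ovh_curve")

#' Write / read a knowledge base as JSON lines
#'
#' One entry per line, schema-tagged, preserving the clinical/pareto
#' source, per-OAR OVH curves and achieved dose levels.
#'
#' @param db List of [kbp_entry()] objects.
#' @param path File path.
#' @return `read_kbp_database` returns a list of [kbp_entry()].
#' @export
write_kbp_database <- function(db, path) {
  lines <- vapply(db, function(e) {
    jsonlite::toJSON(list(schema = "vmatqa-kbp/1", patient_id = e$patient_id,
                          source = e$source,
                          ovh = lapply(e$ovh, ovh_to_list),
                          achieved = lapply(e$achieved, as.list)),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kbp_database
#' @export
read_kbp_database <- function(path) {
  lapply(readLines(path), function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (!identical(o$schema, "vmatqa-kbp/1")) stop("unknown KBP schema")
    kbp_entry(o$patient_id, o$source,
              lapply(o$ovh, ovh_from_list),
              lapply(o$achieved, function(a)
                stats::setNames(as.numeric(unlist(a)), names(a))))
  })
}
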