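#' Multileaf collimator geometry
#'
#' Describes the leaf-pair layout of an MLC projected to the isocenter
#' plane. Leaves travel along the IEC 61217 X axis; pairs are stacked along
#' Y (inferior to superior). Bank A is the negative-X bank, bank B the
#' positive-X bank.
#'
#' @param n_pairs Number of opposed leaf pairs (default 80, a 160-leaf head).
#' @param leaf_widths Per-pair physical widths at isocenter, mm. A scalar is
#'   recycled to all pairs (default 5 mm).
#' @param center Y coordinate of the middle of the leaf bank, mm.
#' @return An object of class `mlc_geometry` with fields `n_pairs`,
#'   `leaf_widths` and `leaf_bounds` (the `n_pairs + 1` pair boundaries, mm).
#' @export
mlc_geometry <- function(n_pairs = 80, leaf_widths = 5, center = 0) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (length(leaf_widths) == 1L) leaf_widths <- rep(leaf_widths, n_pairs)
  if (length(leaf_widths) != n_pairs) stop("leaf_widths must have length n_pairs")
  if (any(leaf_widths <= 0)) stop("leaf widths must be positive")
  bounds <- center - sum(leaf_widths) / 2 + c(0, cumsum(leaf_widths))
  structure(
    list(n_pairs = n_pairs, leaf_widths = as.numeric(leaf_widths),
         leaf_bounds = as.numeric(bounds)),
    class = "mlc_geometry"
  )
}

#' A single VMAT control point
#'
#' @param gantry_angle Gantry angle in degrees, `[0, 360)`.
#' @param cumulative_weight Cumulative meterset weight in `[0, 1]`.
#' @param bank_a,bank_b Per-pair leaf-tip positions along the travel axis,
#'   mm at isocenter. Bank A is the negative-X bank so `bank_b >= bank_a`;
#'   a closed pair has `bank_a == bank_b`.
#' @param jaw_x,jaw_y Length-2 jaw intervals `(low, high)`, mm.
#' @return Object of class `control_point`.
#' @export
control_point <- function(gantry_angle, cumulative_weight, bank_a, bank_b,
                          jaw_x = c(-200, 200), jaw_y = c(-200, 200)) {
  if (length(bank_a) != length(bank_b)) stop("bank lengths differ")
  structure(
    list(gantry_angle = as.numeric(gantry_angle) %% 360,
         cumulative_weight = as.numeric(cumulative_weight),
         bank_a = as.numeric(bank_a), bank_b = as.numeric(bank_b),
         jaw_x = as.numeric(jaw_x), jaw_y = as.numeric(jaw_y)),
    class = "control_point"
  )
}

#' A VMAT arc (one dynamic beam)
#'
#' @param control_points List of [control_point()] objects in delivery order.
#' @param beam_mu Total monitor units delivered by the arc.
#' @param gantry_direction `"CW"` or `"CCW"`.
#' @param nominal_cp_spacing Nominal gantry spacing between control points,
#'   degrees (default 4).
#' @return Object of class `vmat_arc`.
#' @export
vmat_arc <- function(control_points, beam_mu, gantry_direction = "CW",
                     nominal_cp_spacing = 4) {
  gantry_direction <- match.arg(gantry_direction, c("CW", "CCW"))
  structure(
    list(control_points = control_points, beam_mu = as.numeric(beam_mu),
         gantry_direction = gantry_direction,
         nominal_cp_spacing = as.numeric(nominal_cp_spacing)),
    class = "vmat_arc"
  )
}

#' A VMAT treatment plan
#'
#' @param plan_id Plan identifier string.
#' @param arcs List of [vmat_arc()] objects.
#' @param rx_dose_per_fraction Prescription dose per fraction, Gy.
#' @param n_fractions Number of fractions.
#' @param mlc Shared [mlc_geometry()].
#' @return Object of class `vmat_plan`; `total_mu` is the sum of arc MUs.
#' @export
vmat_plan <- function(plan_id, arcs, rx_dose_per_fraction, n_fractions = 38,
                      mlc = mlc_geometry()) {
  structure(
    list(plan_id = as.character(plan_id), arcs = arcs,
         rx_dose_per_fraction = as.numeric(rx_dose_per_fraction),
         n_fractions = as.integer(n_fractions),
         total_mu = sum(vapply(arcs, function(a) a$beam_mu, numeric(1))),
         mlc = mlc),
    class = "vmat_plan"
  )
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("<vmat_plan> %s: %d arc(s), %.1f MU total, %g Gy x %d fx, %d leaf pairs\n",
              x$plan_id, length(x$arcs), x$total_mu,
              x$rx_dose_per_fraction, x$n_fractions, x$mlc$n_pairs))
  invisible(x)
}

# Shortest signed gantry difference in degrees, in (-180, 180].
gantry_delta <- function(from, to) {
  d <- (to - from) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Validate a VMAT plan against structural and mechanical constraints
#'
#' Checks the structural invariants of the plan (meterset weight
#' monotonicity and range, bank ordering, array lengths, jaw sanity, MU
#' positivity) and the mechanical leaf-speed constraint
#' `|delta position| / |delta gantry| <= max_leaf_speed` for every leaf of
#' both banks across every control-point transition. Gantry differences are
#' taken as the shortest signed arc modulo 360.
#'
#' Violations are data, not errors: the return value is a data frame with
#' one row per violation (columns `type`, `arc`, `cp`, `leaf`, `detail`),
#' empty when the plan is valid. The row order is deterministic
#' (arc-major, then control point, then leaf).
#'
#' @param plan A [vmat_plan()].
#' @param max_leaf_speed Maximum permitted leaf speed, mm per degree of
#'   gantry rotation (default 7).
#' @return Data frame of violations (zero rows when valid).
#' @export
validate_plan <- function(plan, max_leaf_speed = 7) {
  v <- list()
  add <- function(type, arc = NA_integer_, cp = NA_integer_,
                  leaf = NA_integer_, detail = "") {
    v[[length(v) + 1L]] <<- data.frame(
      type = type, arc = arc, cp = cp, leaf = leaf, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (!length(plan$arcs)) add("no_arcs", detail = "plan has no arcs")
  if (!is.na(plan$total_mu) && plan$total_mu <= 0)
    add("total_mu", detail = sprintf("total_mu = %g", plan$total_mu))
  if (plan$rx_dose_per_fraction <= 0)
    add("rx_dose", detail = sprintf("rx_dose_per_fraction = %g",
                                    plan$rx_dose_per_fraction))
  np <- plan$mlc$n_pairs
  for (ai in seq_along(plan$arcs)) {
    arc <- plan$arcs[[ai]]
    cps <- arc$control_points
    if (length(cps) < 2L) {
      add("n_control_points", ai, detail = "arc has < 2 control points")
      next
    }
    w <- vapply(cps, function(cp) cp$cumulative_weight, numeric(1))
    if (abs(w[1]) > 1e-9)
      add("weight_start", ai, 1L, detail = sprintf("first weight %g != 0", w[1]))
    if (abs(w[length(w)] - 1) > 1e-9)
      add("weight_end", ai, length(w),
          detail = sprintf("last weight %g != 1", w[length(w)]))
    for (i in seq_len(length(cps))) {
      cp <- cps[[i]]
      if (i > 1L && w[i] < w[i - 1L] - 1e-12)
        add("weight_monotonicity", ai, i,
            detail = sprintf("cumulative weight decreases: %g -> %g", w[i - 1L], w[i]))
      if (length(cp$bank_a) != np || length(cp$bank_b) != np)
        add("bank_length", ai, i,
            detail = sprintf("bank lengths %d/%d != n_pairs %d",
                             length(cp$bank_a), length(cp$bank_b), np))
      bad <- which(cp$bank_b < cp$bank_a - 1e-9)
      for (lf in bad)
        add("bank_order", ai, i, lf,
            sprintf("bank_b %g < bank_a %g", cp$bank_b[lf], cp$bank_a[lf]))
      if (diff(cp$jaw_x) <= 0 || diff(cp$jaw_y) <= 0)
        add("jaw_degenerate", ai, i, detail = "jaw interval non-positive")
    }
    for (i in seq_len(length(cps) - 1L)) {
      a <- cps[[i]]; b <- cps[[i + 1L]]
      dg <- abs(gantry_delta(a$gantry_angle, b$gantry_angle))
      if (dg < 1e-9) next  # no rotation: speed constraint not applicable
      for (bank in c("bank_a", "bank_b")) {
        sp <- abs(b[[bank]] - a[[bank]]) / dg
        bad <- which(sp > max_leaf_speed + 1e-9)
        for (lf in bad)
          add("leaf_speed", ai, i + 1L, lf,
              sprintf("%s leaf %d: %.3f mm/deg > %g", bank, lf, sp[lf], max_leaf_speed))
      }
    }
  }
  if (!length(v))
    return(data.frame(type = character(), arc = integer(), cp = integer(),
                      leaf = integer(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

PLAN_SCHEMA <- "vmatqa-plan/1"

#' Write / read the portable JSON plan format
#'
#' The JSON schema stores all plan fields losslessly (units: mm, deg, MU;
#' meterset weights dimensionless) under a version tag, so that
#' `read_plan_json(write_plan_json(p))` reproduces `p` exactly.
#'
#' @param plan A [vmat_plan()].
#' @param path File path.
#' @return `write_plan_json` returns `path` invisibly; `read_plan_json`
#'   returns a [vmat_plan()].
#' @export
write_plan_json <- function(plan, path) {
  arcs <- lapply(plan$arcs, function(a) {
    list(
      beam_mu = a$beam_mu,
      gantry_direction = a$gantry_direction,
      nominal_cp_spacing = a$nominal_cp_spacing,
      control_points = lapply(a$control_points, function(cp) {
        list(gantry_angle = cp$gantry_angle,
             cumulative_weight = cp$cumulative_weight,
             bank_a = cp$bank_a, bank_b = cp$bank_b,
             jaw_x = cp$jaw_x, jaw_y = cp$jaw_y)
      }))
  })
  obj <- list(
    schema = PLAN_SCHEMA,
    plan_id = plan$plan_id,
    rx_dose_per_fraction = plan$rx_dose_per_fraction,
    n_fractions = plan$n_fractions,
    mlc = list(n_pairs = plan$mlc$n_pairs, leaf_widths = plan$mlc$leaf_widths,
               leaf_bounds = plan$mlc$leaf_bounds),
    arcs = arcs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse plan JSON: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, PLAN_SCHEMA))
    stop("unknown plan schema version: ", if (is.null(obj$schema)) "<missing>"
         else obj$schema)
  if (!length(obj$arcs)) stop("plan has no arcs")
  num <- function(x) as.numeric(unlist(x))
  mlc <- structure(
    list(n_pairs = as.integer(obj$mlc$n_pairs),
         leaf_widths = num(obj$mlc$leaf_widths),
         leaf_bounds = num(obj$mlc$leaf_bounds)),
    class = "mlc_geometry")
  arcs <- lapply(obj$arcs, function(a) {
    cps <- lapply(a$control_points, function(cp) {
      control_point(cp$gantry_angle, cp$cumulative_weight,
                    num(cp$bank_a), num(cp$bank_b),
                    num(cp$jaw_x), num(cp$jaw_y))
    })
    vmat_arc(cps, a$beam_mu, a$gantry_direction, a$nominal_cp_spacing)
  })
  vmat_plan(obj$plan_id, arcs, obj$rx_dose_per_fraction, obj$n_fractions, mlc)
}
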