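# Plan complexity metrics: MU/Gy, modulation complexity score (MCS),
# edge metric (EM), and mean leaf motion per degree of gantry rotation (LM).

#' Monitor units per Gy of fractional prescription dose
#'
#' Total planned MU normalized by the prescription dose per fraction, so
#' plans with different prescriptions can be compared on one scale.
#'
#' @param plan A [vmat_plan()].
#' @return MU per Gy (numeric scalar).
#' @export
mu_per_gy <- function(plan) {
  if (plan$rx_dose_per_fraction <= 0)
    stop("rx_dose_per_fraction must be positive")
  plan$total_mu / plan$rx_dose_per_fraction
}

#' Aperture of one control point
#'
#' Clips each leaf pair's open interval to the X jaws and flags the pairs
#' whose leaf band overlaps the Y jaws. A pair counts as "within the jaws"
#' when its Y-interval overlaps `jaw_y` by more than `min_overlap` mm
#' (default 0.5), avoiding knife-edge ambiguity.
#'
#' @param cp A [control_point()].
#' @param mlc An [mlc_geometry()].
#' @param min_overlap Minimum Y-overlap in mm for a pair to count as in-jaw.
#' @return A list of class `aperture` with per-pair vectors: `lo`, `hi`
#'   (clipped interval, mm), `gap` (`max(0, hi - lo)`), `width` (Y overlap
#'   with the jaws, mm), `full_width` (physical leaf width), `in_jaw`
#'   (logical), plus the raw `bank_a`, `bank_b` positions.
#' @export
segment_aperture <- function(cp, mlc, min_overlap = 0.5) {
  lo_y <- mlc$leaf_bounds[-(mlc$n_pairs + 1L)]
  hi_y <- mlc$leaf_bounds[-1L]
  y_ov <- pmax(0, pmin(hi_y, cp$jaw_y[2]) - pmax(lo_y, cp$jaw_y[1]))
  in_jaw <- y_ov > min_overlap
  lo <- pmax(cp$bank_a, cp$jaw_x[1])
  hi <- pmin(cp$bank_b, cp$jaw_x[2])
  gap <- pmax(0, hi - lo)
  structure(list(lo = lo, hi = hi, gap = gap, width = y_ov,
                 full_width = mlc$leaf_widths, in_jaw = in_jaw,
                 bank_a = cp$bank_a, bank_b = cp$bank_b),
            class = "aperture")
}

#' Leaf sequence variability of one aperture
#'
#' Product over the two banks of
#' `sum_{n=1}^{N-1} (pos_max - |p_n - p_{n+1}|) / ((N-1) * pos_max)`,
#' where `p` are the bank's leaf positions over the `N` in-jaw pairs and
#' `pos_max = max(p) - min(p)`. A bank with `pos_max = 0` (all leaves
#' aligned, zero variability) contributes a factor of 1 by convention.
#'
#' @param aperture Result of [segment_aperture()].
#' @return LSV in `[0, 1]`.
#' @export
compute_lsv <- function(aperture) {
  idx <- which(aperture$in_jaw)
  if (length(idx) < 2L) stop("LSV needs at least 2 in-jaw leaf pairs")
  bank_lsv <- function(p) {
    pos_max <- max(p) - min(p)
    if (pos_max <= 0) return(1)
    sum(pos_max - abs(diff(p))) / ((length(p) - 1L) * pos_max)
  }
  bank_lsv(aperture$bank_a[idx]) * bank_lsv(aperture$bank_b[idx])
}

# Per-pair maximum gaps over an arc: each leaf's extreme position over all
# control points, so AAV is normalized by the arc's maximal aperture.
arc_max_gaps <- function(arc, mlc) {
  amin <- Reduce(pmin, lapply(arc$control_points, function(cp) cp$bank_a))
  bmax <- Reduce(pmax, lapply(arc$control_points, function(cp) cp$bank_b))
  list(amin = amin, bmax = bmax)
}

#' Aperture area variability of one aperture
#'
#' Ratio of the aperture's summed in-jaw leaf gaps to the gaps of the arc's
#' maximal aperture (per-leaf extreme positions over all control points of
#' the arc). Equals 1 when every leaf sits at its arc-wide extreme.
#'
#' @param aperture Result of [segment_aperture()].
#' @param max_gaps Result of [arc_max_gaps()] for the enclosing arc
#'   (list with `amin`, `bmax`).
#' @return AAV in `[0, 1]`.
#' @export
compute_aav <- function(aperture, max_gaps) {
  idx <- which(aperture$in_jaw)
  if (length(idx) < 1L) stop("AAV needs at least 1 in-jaw leaf pair")
  denom <- sum(pmax(0, max_gaps$bmax[idx] - max_gaps$amin[idx]))
  if (denom <= 0) return(1)
  min(1, sum(aperture$gap[idx]) / denom)
}

#' Modulation complexity score of a plan
#'
#' Per arc,
#' `MCS = sum_i ((AAV_i + AAV_{i+1})/2) * ((LSV_i + LSV_{i+1})/2) * W_i`
#' with `W_i` the meterset fraction delivered between control points `i`
#' and `i+1`; the plan value is the MU-weighted mean over arcs. MCS runs
#' from 1 (an unmodulated, static conformal arc) down toward 0 as
#' modulation increases.
#'
#' @param plan A [vmat_plan()].
#' @return List with `mcs` (plan value) and `per_arc` (numeric vector).
#' @export
compute_mcs <- function(plan) {
  per_arc <- vapply(plan$arcs, function(arc) {
    cps <- arc$control_points
    if (length(cps) < 2L) stop("MCS needs >= 2 control points per arc")
    mg <- arc_max_gaps(arc, plan$mlc)
    ap <- lapply(cps, segment_aperture, mlc = plan$mlc)
    lsv <- vapply(ap, compute_lsv, numeric(1))
    aav <- vapply(ap, compute_aav, numeric(1), max_gaps = mg)
    w <- diff(vapply(cps, function(cp) cp$cumulative_weight, numeric(1)))
    i <- seq_len(length(cps) - 1L)
    sum(((aav[i] + aav[i + 1L]) / 2) * ((lsv[i] + lsv[i + 1L]) / 2) * w)
  }, numeric(1))
  mu <- vapply(plan$arcs, function(a) a$beam_mu, numeric(1))
  list(mcs = sum(per_arc * mu) / sum(mu), per_arc = per_arc)
}

# Length of the symmetric difference of two intervals given as c(lo, hi);
# NULL represents an empty interval.
interval_symdiff <- function(i1, i2) {
  len <- function(i) if (is.null(i)) 0 else max(0, i[2] - i[1])
  if (is.null(i1) || is.null(i2)) return(len(i1) + len(i2))
  if (min(i1[2], i2[2]) <= max(i1[1], i2[1])) return(len(i1) + len(i2))
  abs(i1[1] - i2[1]) + abs(i1[2] - i2[2])
}

# Edge metric of a single aperture: (C1 * L_end + C2 * L_side) / area.
# L_side sums the exposed leaf-side edge: the symmetric difference of
# adjacent in-jaw open intervals, plus the full gap lengths bordering the
# closed pairs / jaw edges above and below the aperture. Returns NA for a
# zero-area aperture.
aperture_edge_metric <- function(aperture, c1 = 0, c2 = 1) {
  idx <- which(aperture$in_jaw)
  open <- idx[aperture$gap[idx] > 0]
  area <- sum(aperture$gap[idx] * aperture$width[idx])
  if (area <= 0) return(NA_real_)
  ivals <- c(list(NULL),
             lapply(idx, function(n) if (aperture$gap[n] > 0)
               c(aperture$lo[n], aperture$hi[n]) else NULL),
             list(NULL))
  l_side <- sum(vapply(seq_len(length(ivals) - 1L), function(j)
    interval_symdiff(ivals[[j]], ivals[[j + 1L]]), numeric(1)))
  l_end <- 2 * sum(aperture$full_width[open])
  (c1 * l_end + c2 * l_side) / area
}

#' Edge metric of a plan
#'
#' The meterset-weighted ratio of exposed in-field MLC edge length to
#' aperture area, `EM_cp = (C1 * L_end + C2 * L_side) / A_cp`, where
#' `L_end` is the leaf-end (tip) edge length, `L_side` the leaf-side edge
#' length and `A_cp` the aperture area. Control-point weights are
#' `w_cp = (dW_left + dW_right) / 2` (endpoints take their single adjacent
#' meterset interval). Zero-area control points with nonzero weight are
#' degenerate: they are dropped from the weighted mean with a warning. The
#' plan value is the MU-weighted mean over arcs. Default scaling factors
#' `C1 = 0`, `C2 = 1`.
#'
#' @param plan A [vmat_plan()].
#' @param c1,c2 Scaling factors for leaf-end and leaf-side edge length.
#' @return List with `em` (plan value, 1/mm), `per_arc`, and
#'   `n_degenerate` (count of excluded zero-area control points).
#' @export
compute_edge_metric <- function(plan, c1 = 0, c2 = 1) {
  n_degenerate <- 0L
  per_arc <- vapply(plan$arcs, function(arc) {
    cps <- arc$control_points
    w <- vapply(cps, function(cp) cp$cumulative_weight, numeric(1))
    dw <- diff(w)
    w_cp <- (c(0, dw) + c(dw, 0)) / 2
    em_cp <- vapply(cps, function(cp)
      aperture_edge_metric(segment_aperture(cp, plan$mlc), c1, c2), numeric(1))
    bad <- is.na(em_cp) & w_cp > 0
    if (any(bad)) {
      n_degenerate <<- n_degenerate + sum(bad)
      warning(sum(bad), " zero-area control point(s) with nonzero weight ",
              "excluded from edge metric", call. = FALSE)
    }
    keep <- !is.na(em_cp)
    if (!any(keep) || sum(w_cp[keep]) <= 0) return(0)
    sum(w_cp[keep] * em_cp[keep]) / sum(w_cp[keep])
  }, numeric(1))
  mu <- vapply(plan$arcs, function(a) a$beam_mu, numeric(1))
  list(em = sum(per_arc * mu) / sum(mu), per_arc = per_arc,
       n_degenerate = n_degenerate)
}

#' Mean leaf motion per degree of gantry rotation
#'
#' For every control-point transition, the mean over the in-jaw leaves of
#' both banks of `|delta position| / |delta gantry|`; the plan value is the
#' unweighted mean of the per-transition means, pooled over arcs. Gantry
#' differences use the shortest signed arc modulo 360.
#'
#' @param plan A [vmat_plan()].
#' @return List with `lm` (mm/deg), `per_arc` (per-arc means).
#' @export
compute_leaf_motion <- function(plan) {
  arc_vals <- lapply(plan$arcs, function(arc) {
    cps <- arc$control_points
    if (length(cps) < 2L) stop("LM needs >= 2 control points per arc")
    out <- numeric(0)
    for (i in seq_len(length(cps) - 1L)) {
      a <- cps[[i]]; b <- cps[[i + 1L]]
      dg <- abs(gantry_delta(a$gantry_angle, b$gantry_angle))
      dpos <- c(abs(b$bank_a - a$bank_a), abs(b$bank_b - a$bank_b))
      if (dg < 1e-9) {
        if (any(dpos > 1e-9))
          stop("leaf motion across a zero gantry increment is undefined")
        next
      }
      in_jaw <- segment_aperture(a, plan$mlc)$in_jaw
      sel <- rep(in_jaw, 2L)
      if (!any(sel)) next
      out <- c(out, mean(dpos[sel] / dg))
    }
    out
  })
  all_t <- unlist(arc_vals)
  list(lm = if (length(all_t)) mean(all_t) else 0,
       per_arc = vapply(arc_vals, function(v) if (length(v)) mean(v) else 0,
                        numeric(1)))
}

#' Full complexity report for a plan
#'
#' Computes MU/Gy, MCS, EM and LM with their per-arc breakdowns.
#'
#' @param plan A [vmat_plan()].
#' @param c1,c2 Edge-metric scaling factors (defaults 0 and 1).
#' @return Object of class `complexity_report`: a list with `plan_id`,
#'   `mu`, `mu_per_gy`, `mcs`, `em`, `lm`, and a `per_arc` data frame.
#' @export
complexity_report <- function(plan, c1 = 0, c2 = 1) {
  mcs <- compute_mcs(plan)
  em <- compute_edge_metric(plan, c1, c2)
  lm <- compute_leaf_motion(plan)
  structure(list(
    plan_id = plan$plan_id,
    mu = plan$total_mu,
    mu_per_gy = mu_per_gy(plan),
    mcs = mcs$mcs, em = em$em, lm = lm$lm,
    per_arc = data.frame(arc = seq_along(plan$arcs),
                         beam_mu = vapply(plan$arcs, function(a) a$beam_mu,
                                          numeric(1)),
                         mcs = mcs$per_arc, em = em$per_arc, lm = lm$per_arc)
  ), class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s: MU %.1f (%.1f MU/Gy), MCS %.3f, EM %.4f /mm, LM %.3f mm/deg\n",
              x$plan_id, x$mu, x$mu_per_gy, x$mcs, x$em, x$lm))
  invisible(x)
}

#' Serialize / deserialize a complexity report as JSON
#' @param report A `complexity_report`.
#' @param path File path.
#' @return `read_complexity_json` returns a `complexity_report`.
#' @export
write_complexity_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_complexity_json
#' @export
read_complexity_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_arc <- as.data.frame(obj$per_arc)
  structure(obj, class = "complexity_report")
}

#' Complexity table for a list of plans
#'
#' @param plans List of [vmat_plan()] objects.
#' @param c1,c2 Edge-metric scaling factors.
#' @return Data frame with one row per plan: `plan_id`, `mu`, `mu_per_gy`,
#'   `mcs`, `em`, `lm`.
#' @export
complexity_table <- function(plans, c1 = 0, c2 = 1) {
  rows <- lapply(plans, function(p) {
    r <- complexity_report(p, c1, c2)
    data.frame(plan_id = r$plan_id, mu = r$mu, mu_per_gy = r$mu_per_gy,
               mcs = r$mcs, em = r$em, lm = r$lm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
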