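# Synthetic cohort generator: prostate-like anatomies, two-arc VMAT plans
# at controlled modulation, a fluence-convolution dose surrogate, and
# perturbed diode-array style measurements. The dose engine is a surrogate
# for exercising the analysis machinery, not a physics engine.
#
# Geometry: patient x lateral, y anterior-posterior, z superior-inferior.
# The gantry rotates in the x-y plane; at angle theta the leaf-travel axis
# u = x cos(theta) + y sin(theta) and the leaf-side axis is z.

#' Specification of a synthetic QA cohort
#'
#' Defaults state the emulated study conditions: 31 patients, two coplanar
#' 360-degree arcs at 4-degree control-point spacing, a 7 mm/deg leaf-speed
#' limit, 38 x 2 Gy fractionation (so D95-to-76-Gy normalization is
#' meaningful), a uniform 7 mm detector grid over 26 x 26 cm, and a
#' measurement perturbation model of 0.5 mm SD static per-leaf calibration
#' offsets, a 0.4 degree MLC servo lag, a continuous-delivery (control
#' point subdivision) surrogate for TPS discretization error, and 1.5%
#' proportional noise.
#' Reference plans draw a lower modulation level than the KBP-style
#' re-plans.
#'
#' @param n_patients Number of patients (default 31).
#' @param seed Master seed; all randomness derives from it.
#' @param ptv_semiaxes_mm Range of PTV semi-axes, mm.
#' @param oar_separation_mm Range of OAR-to-PTV surface separation, mm
#'   (negative values overlap).
#' @param ref_modulation,kbp_modulation Modulation-level ranges for the two
#'   arms (each in `[0, 1]`).
#' @param max_leaf_speed Leaf-speed limit, mm per degree of gantry rotation.
#' @param cp_spacing Control-point spacing, degrees.
#' @param rx_per_fraction,n_fractions Prescription (2 Gy x 38).
#' @param voxel_mm Anatomy/dose lattice resolution, mm.
#' @param plane_spacing_mm Rendered coronal plane resolution, mm.
#' @param penumbra_sigma_mm Gaussian penumbra kernel sigma, mm.
#' @param detector_spacing_mm,detector_extent_mm Detector grid spec.
#' @param n_replicates Measured deliveries per plan (default 3).
#' @param perturbation List with `leaf_offset_mm`, `lag_deg`,
#'   `cp_subdivision`, `noise_sd_frac`, `shift_mm` (length 2).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 31, seed = 20190101,
                        ptv_semiaxes_mm = c(22, 34),
                        oar_separation_mm = c(-12, 4),
                        ref_modulation = c(0.15, 0.40),
                        kbp_modulation = c(0.55, 0.85),
                        max_leaf_speed = 7, cp_spacing = 4,
                        rx_per_fraction = 2, n_fractions = 38,
                        voxel_mm = 4, plane_spacing_mm = 2,
                        penumbra_sigma_mm = 3,
                        detector_spacing_mm = 7, detector_extent_mm = 260,
                        n_replicates = 3,
                        perturbation = list(leaf_offset_mm = 0.5,
                                            lag_deg = 0.4,
                                            cp_subdivision = 2,
                                            noise_sd_frac = 0.015,
                                            shift_mm = c(0, 0))) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  stopifnot(all(ptv_semiaxes_mm > 0), voxel_mm > 0, detector_spacing_mm > 0)
  if (any(c(ref_modulation, kbp_modulation) < 0) ||
      any(c(ref_modulation, kbp_modulation) > 1))
    stop("modulation ranges must lie in [0, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

# deterministic per-patient / per-use sub-seeds, kept well below 2^31
derive_seed <- function(seed, i, k = 0L) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + k * 1299709) %% 2147483629)
}

## ---- anatomy ----

ellipsoid_mask <- function(xs, ys, zs, center, semi) {
  dx2 <- ((xs - center[1]) / semi[1])^2
  dy2 <- ((ys - center[2]) / semi[2])^2
  dz2 <- ((zs - center[3]) / semi[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  r2 <= 1
}

#' Generate a prostate-like synthetic anatomy
#'
#' Ellipsoidal PTV at the isocenter with an adjacent bladder
#' (anterior-superior) and rectum (posterior, elongated along z), inside a
#' cylindrical body, on a uniform lattice (default 4 mm). The OAR-to-PTV
#' surface separation is drawn from `spec$oar_separation_mm`; negative
#' separations give overlap.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (fully determines the anatomy).
#' @return List with `grid` (a zero [dose_grid()] supplying the lattice),
#'   `masks` (named list of [structure_mask()]: ptv, bladder, rectum,
#'   body), and `params` (the drawn geometry parameters).
#' @export
generate_anatomy <- function(spec, seed) {
  set.seed(seed)
  h <- spec$voxel_mm
  nx <- ny <- as.integer(round(280 / h)) + 1L
  nz <- as.integer(round(176 / h)) + 1L
  origin <- c(-(nx - 1) / 2 * h, -(ny - 1) / 2 * h, -(nz - 1) / 2 * h)
  xs <- origin[1] + (seq_len(nx) - 1) * h
  ys <- origin[2] + (seq_len(ny) - 1) * h
  zs <- origin[3] + (seq_len(nz) - 1) * h
  ptv_semi <- stats::runif(3, spec$ptv_semiaxes_mm[1], spec$ptv_semiaxes_mm[2])
  sep_bl <- stats::runif(1, spec$oar_separation_mm[1], spec$oar_separation_mm[2])
  sep_re <- stats::runif(1, spec$oar_separation_mm[1], spec$oar_separation_mm[2])
  bl_semi <- stats::runif(3, 28, 42)
  re_semi <- c(stats::runif(2, 12, 18), stats::runif(1, 45, 60))
  # anterior = -y, posterior = +y, superior = +z
  bl_center <- c(0, -(ptv_semi[2] + bl_semi[2] + sep_bl) * 0.82,
                 stats::runif(1, 10, 25))
  re_center <- c(0, (ptv_semi[2] + re_semi[2] + sep_re) * 0.82,
                 stats::runif(1, -10, 5))
  ptv <- ellipsoid_mask(xs, ys, zs, c(0, 0, 0), ptv_semi)
  bladder <- ellipsoid_mask(xs, ys, zs, bl_center, bl_semi)
  rectum <- ellipsoid_mask(xs, ys, zs, re_center, re_semi)
  body <- outer(outer(xs^2, ys^2, "+"), rep(0, nz), "+") <= 132^2
  grid <- dose_grid(array(0, dim = c(nx, ny, nz)), rep(h, 3), origin)
  list(grid = grid,
       masks = list(ptv = structure_mask("PTV", ptv),
                    bladder = structure_mask("bladder", bladder),
                    rectum = structure_mask("rectum", rectum),
                    body = structure_mask("body", body)),
       params = list(ptv_semi = ptv_semi, bl_center = bl_center,
                     bl_semi = bl_semi, re_center = re_center,
                     re_semi = re_semi, sep_bl = sep_bl, sep_re = sep_re))
}

## ---- plan generation ----

# Conformal BEV apertures of the PTV for a set of gantry angles.
# Returns, per angle, per-pair open intervals [lo, hi] with closed pairs at 0.
bev_apertures <- function(anatomy, angles_deg, mlc, margin = 7) {
  m <- anatomy$masks$ptv$mask
  g <- anatomy$grid
  idx <- which(m, arr.ind = TRUE)
  px <- g$origin[1] + (idx[, 1] - 1) * g$voxel_size[1]
  py <- g$origin[2] + (idx[, 2] - 1) * g$voxel_size[2]
  pz <- g$origin[3] + (idx[, 3] - 1) * g$voxel_size[3]
  pair <- findInterval(pz, mlc$leaf_bounds, rightmost.closed = TRUE)
  pair[pair < 1 | pair > mlc$n_pairs] <- NA
  ok <- !is.na(pair)
  px <- px[ok]; py <- py[ok]; pair <- pair[ok]
  lapply(angles_deg, function(th) {
    u <- px * cospi(th / 180) + py * sinpi(th / 180)
    lo <- rep(0, mlc$n_pairs); hi <- rep(0, mlc$n_pairs)
    mn <- tapply(u, pair, min); mx <- tapply(u, pair, max)
    p <- as.integer(names(mn))
    lo[p] <- mn - margin; hi[p] <- mx + margin
    list(lo = lo, hi = hi, open = seq_len(mlc$n_pairs) %in% p)
  })
}

# Band-limited perturbation field over (control point, leaf pair). The
# frequency bands are chosen so a fully modulated plan shows the leaf
# dynamics of clinical VMAT: gantry-frequency content up to ~22 cycles per
# arc drives leaf speeds of order 1 mm/deg (well under the 7 mm/deg limit)
# and leaf-frequency content up to ~12 cycles per bank produces the
# leaf-to-leaf aperture irregularity the edge metric responds to.
smooth_field <- function(n_cp, n_pairs, n_modes = 4) {
  f <- matrix(0, n_cp, n_pairs)
  for (k in seq_len(n_modes)) {
    fc <- stats::runif(1, 4, 22)   # cycles over the arc
    fl <- stats::runif(1, 1, 12)   # cycles over the bank
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    f <- f + outer(sin(2 * pi * fc * seq_len(n_cp) / n_cp + ph1),
                   sin(2 * pi * fl * seq_len(n_pairs) / n_pairs + ph2))
  }
  f / sqrt(n_modes)
}

#' Generate a two-arc VMAT plan at a controlled modulation level
#'
#' Builds two full 360-degree arcs at the spec's control-point spacing with
#' apertures conformal to the PTV beam's-eye-view outline, then adds
#' band-limited per-leaf perturbations and meterset-weight variation scaled
#' by `modulation_level`. Leaf trajectories are clamped sequentially so no
#' leaf ever exceeds the spec's leaf-speed limit, and total MU grows with
#' the modulation level.
#'
#' @param anatomy Result of [generate_anatomy()].
#' @param modulation_level Modulation dial in `[0, 1]` (0 = conformal arc).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A [vmat_plan()] that passes [validate_plan()] at the spec's
#'   leaf-speed limit.
#' @export
generate_plan <- function(anatomy, modulation_level, spec, seed) {
  stopifnot(modulation_level >= 0, modulation_level <= 1)
  set.seed(seed)
  mlc <- mlc_geometry()
  n_cp <- as.integer(360 / spec$cp_spacing) + 1L
  max_step <- spec$max_leaf_speed * spec$cp_spacing  # mm per CP transition
  # MU grows with the modulation dial and with target size (larger targets
  # need more output), plus a small replan-to-replan noise; the size and
  # modulation spreads dominate the cohort MU variance, as in clinical arms
  size_factor <- sqrt(prod(anatomy$params$ptv_semi[c(1, 3)])) / 28
  total_mu <- (380 + 310 * modulation_level) * size_factor *
    exp(stats::rnorm(1, 0, 0.05))
  mu_split <- stats::runif(1, 0.47, 0.53)
  arc_mu <- c(mu_split, 1 - mu_split) * total_mu
  # field extent from the PTV z-range (+ margin), fixed per arc
  zext <- range(anatomy$grid$origin[3] +
                  (which(apply(anatomy$masks$ptv$mask, 3, any)) - 1) *
                  anatomy$grid$voxel_size[3])
  jaw_y <- c(zext[1] - 10, zext[2] + 10)
  arcs <- lapply(1:2, function(ai) {
    dir <- if (ai == 1L) "CW" else "CCW"
    steps <- if (ai == 1L) seq(0, 360, by = spec$cp_spacing)
             else seq(360, 0, by = -spec$cp_spacing)
    angles <- steps %% 360
    bev <- bev_apertures(anatomy, angles, mlc)
    lo <- t(vapply(bev, `[[`, numeric(mlc$n_pairs), "lo"))
    hi <- t(vapply(bev, `[[`, numeric(mlc$n_pairs), "hi"))
    open <- t(vapply(bev, `[[`, logical(mlc$n_pairs), "open"))
    # Modulation narrows the conformal opening into a sweeping leaf window:
    # the half-width shrinks with the modulation level while the window
    # center sweeps back and forth across the BEV outline (triangle wave,
    # a few crossings per arc, leaf- and arc-specific phase), so target
    # coverage stays near-uniform and extra MU compensates the reduced duty
    # cycle -- the way modulated VMAT trades aperture size for monitor
    # units without blowing up target hot spots. A small wander field on
    # top supplies leaf-to-leaf irregularity.
    half0 <- (hi - lo) / 2
    fs <- smooth_field(n_cp, mlc$n_pairs)   # window-center irregularity
    fn <- smooth_field(n_cp, mlc$n_pairs)   # window narrowing
    half_w <- pmax(half0 * (1 - modulation_level * (0.5 + 0.3 * fn)), 1)
    n_sweeps <- 2 + round(3 * modulation_level)
    phase <- outer((n_sweeps * seq_len(n_cp)) / n_cp,
                   stats::runif(mlc$n_pairs), "+") + stats::runif(1)
    tri <- abs(2 * (phase - floor(phase)) - 1)   # triangle wave in [0, 1]
    # The sweep overshoots the outline by up to one half-width so the
    # window crosses fully over every point (uniform duty ~ half_w/half0,
    # every point built from moving window edges); the overshoot ramps in
    # with modulation so level 0 stays a static conformal arc.
    ov <- half_w * min(1, modulation_level / 0.3)
    lo_c <- lo + half_w - ov
    hi_c <- hi - half_w + ov
    ctr <- lo_c + pmax(hi_c - lo_c, 0) * tri +
      0.2 * half0 * modulation_level * fs
    bank_a <- ifelse(open, ctr - half_w, lo)
    bank_b <- ifelse(open, ctr + half_w, hi)
    # clamp trajectories to the leaf-speed limit
    for (i in 2:n_cp) {
      bank_a[i, ] <- bank_a[i - 1, ] +
        pmax(pmin(bank_a[i, ] - bank_a[i - 1, ], max_step), -max_step)
      bank_b[i, ] <- bank_b[i - 1, ] +
        pmax(pmin(bank_b[i, ] - bank_b[i - 1, ], max_step), -max_step)
      over <- bank_a[i, ] > bank_b[i, ]
      mid <- (bank_a[i, over] + bank_b[i, over]) / 2
      bank_a[i, over] <- mid; bank_b[i, over] <- mid
    }
    jaw_x <- c(min(bank_a) - 5, max(bank_b) + 5)
    dw <- rep(1, n_cp - 1L) *
      (1 + 0.4 * modulation_level * abs(stats::filter(
        stats::rnorm(n_cp + 9L), rep(1 / sqrt(10), 10L), sides = 1L)[-seq_len(10L)]))
    w <- c(0, cumsum(dw) / sum(dw))
    w[n_cp] <- 1
    cps <- lapply(seq_len(n_cp), function(i)
      control_point(angles[i], w[i], bank_a[i, ], bank_b[i, ], jaw_x, jaw_y))
    vmat_arc(cps, arc_mu[ai], dir, spec$cp_spacing)
  })
  vmat_plan(sprintf("synth-%08d-m%03d", seed, round(100 * modulation_level)),
            arcs, spec$rx_per_fraction, spec$n_fractions)
}

## ---- dose rendering ----

gauss_band_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  M <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- M[cbind(i[ok], j[ok])] + k[o + r + 1]
  }
  M / rowSums(M)  # edge-renormalized: flat fields stay flat
}

# per-CP meterset weights (endpoints take their single adjacent interval)
cp_weights <- function(arc) {
  w <- vapply(arc$control_points, function(cp) cp$cumulative_weight, numeric(1))
  dw <- diff(w)
  (c(0, dw) + c(dw, 0)) / 2
}

#' Render the surrogate dose of a plan
#'
#' Fluence accumulation over control points (aperture indicator times
#' meterset weight times beam MU, back-projected at each gantry angle)
#' convolved with a Gaussian penumbra kernel and converted to Gy with a
#' fixed output calibration. Deterministic given the plan. Renders the
#' coronal plane through the isocenter (y = 0) and/or the full 3D grid on
#' the anatomy lattice.
#'
#' @param plan A [vmat_plan()].
#' @param anatomy Result of [generate_anatomy()] (required for
#'   `what != "plane"`; supplies the 3D lattice).
#' @param what `"plane"`, `"grid"` or `"both"`.
#' @param spec A [cohort_spec()] (plane resolution, penumbra sigma).
#' @param bank_offset_a,bank_offset_b Static positional offsets added to
#'   every control point's bank A / bank B leaf positions (mm; scalar or
#'   per-pair vector). Used by the measurement perturbation model to
#'   emulate MLC calibration error. Default 0.
#' @param calibration Gy per MU of open-field fluence (default 0.004).
#' @return List with `plane` (a [dose_plane()], per-fraction Gy) and/or
#'   `grid` (a [dose_grid()], total dose in Gy over all fractions).
#' @export
render_dose <- function(plan, anatomy = NULL, what = c("plane", "grid", "both"),
                        spec = cohort_spec(), bank_offset_a = 0,
                        bank_offset_b = 0, calibration = 0.004) {
  what <- match.arg(what)
  mlc <- plan$mlc
  out <- list()
  if (what %in% c("plane", "both")) {
    half <- spec$detector_extent_mm / 2
    xs <- seq(-half, half, by = spec$plane_spacing_mm)
    zs <- xs
    pair_of_row <- findInterval(zs, mlc$leaf_bounds, rightmost.closed = TRUE)
    pair_of_row[pair_of_row < 1 | pair_of_row > mlc$n_pairs] <- NA
    F <- matrix(0, length(zs), length(xs))
    for (arc in plan$arcs) {
      w_cp <- cp_weights(arc) * arc$beam_mu
      for (i in seq_along(arc$control_points)) {
        cp <- arc$control_points[[i]]
        lo <- pmax(cp$bank_a + bank_offset_a, cp$jaw_x[1])
        hi <- pmin(cp$bank_b + bank_offset_b, cp$jaw_x[2])
        # z rows outside the Y jaws or the leaf bank are blocked
        lo_r <- rep(Inf, length(zs)); hi_r <- rep(-Inf, length(zs))
        okz <- !is.na(pair_of_row) & zs >= cp$jaw_y[1] & zs <= cp$jaw_y[2]
        lo_r[okz] <- lo[pair_of_row[okz]]
        hi_r[okz] <- hi[pair_of_row[okz]]
        u <- xs * cospi(cp$gantry_angle / 180)
        F <- F + w_cp[i] * (outer(lo_r, u, "<=") & outer(hi_r, u, ">="))
      }
    }
    sig <- spec$penumbra_sigma_mm / spec$plane_spacing_mm
    B <- gauss_band_matrix(length(zs), sig)
    F <- B %*% F %*% t(B)
    out$plane <- dose_plane(calibration * F, spacing = spec$plane_spacing_mm,
                            origin = c(-half, -half))
  }
  if (what %in% c("grid", "both")) {
    if (is.null(anatomy)) stop("anatomy required to render the 3D grid")
    g <- anatomy$grid
    dm <- dim(g$values)
    xs <- g$origin[1] + (seq_len(dm[1]) - 1) * g$voxel_size[1]
    ys <- g$origin[2] + (seq_len(dm[2]) - 1) * g$voxel_size[2]
    zs <- g$origin[3] + (seq_len(dm[3]) - 1) * g$voxel_size[3]
    Xv <- rep(xs, times = dm[2] * dm[3])
    Yv <- rep(rep(ys, each = dm[1]), times = dm[3])
    pair_of_z <- findInterval(zs, mlc$leaf_bounds, rightmost.closed = TRUE)
    pair_of_z[pair_of_z < 1 | pair_of_z > mlc$n_pairs] <- mlc$n_pairs + 1L
    pv <- rep(pair_of_z, each = dm[1] * dm[2])
    Zv <- rep(zs, each = dm[1] * dm[2])
    F <- numeric(prod(dm))
    for (arc in plan$arcs) {
      w_cp <- cp_weights(arc) * arc$beam_mu
      for (i in seq_along(arc$control_points)) {
        cp <- arc$control_points[[i]]
        lo <- c(pmax(cp$bank_a + bank_offset_a, cp$jaw_x[1]), Inf)
        hi <- c(pmin(cp$bank_b + bank_offset_b, cp$jaw_x[2]), -Inf)
        # rows outside the Y jaws are blocked via the sentinel pair
        lo[seq_len(mlc$n_pairs)][
          mlc$leaf_bounds[-1] < cp$jaw_y[1] |
          mlc$leaf_bounds[-(mlc$n_pairs + 1L)] > cp$jaw_y[2]] <- Inf
        u <- Xv * cospi(cp$gantry_angle / 180) + Yv * sinpi(cp$gantry_angle / 180)
        inb <- u >= lo[pv] & u <= hi[pv]
        F <- F + w_cp[i] * inb
      }
    }
    A <- array(F, dim = dm)
    sig <- spec$penumbra_sigma_mm / g$voxel_size
    B1 <- gauss_band_matrix(dm[1], sig[1])
    B2 <- gauss_band_matrix(dm[2], sig[2])
    B3 <- gauss_band_matrix(dm[3], sig[3])
    for (k in seq_len(dm[3])) A[, , k] <- B1 %*% A[, , k] %*% t(B2)
    A <- array(matrix(A, dm[1] * dm[2], dm[3]) %*% t(B3), dim = dm)
    out$grid <- dose_grid(calibration * A * plan$n_fractions,
                          g$voxel_size, g$origin)
  }
  out
}

# Continuous-delivery surrogate: subdivide every control-point interval,
# interpolating gantry angle, leaf banks and cumulative weight linearly.
# A plan rendered after subdivision approximates the continuously delivered
# fluence; the difference from the 4-degree rendering is the control-point
# discretization error of the "TPS", which grows with leaf speed.
subdivide_plan <- function(plan, factor = 2L) {
  if (factor <= 1L) return(plan)
  for (ai in seq_along(plan$arcs)) {
    cps <- plan$arcs[[ai]]$control_points
    n <- length(cps)
    out <- vector("list", (n - 1L) * factor + 1L)
    k <- 1L
    for (i in seq_len(n - 1L)) {
      a <- cps[[i]]; b <- cps[[i + 1L]]
      dg <- gantry_delta(a$gantry_angle, b$gantry_angle)
      for (s in seq_len(factor) - 1L) {
        t <- s / factor
        out[[k]] <- control_point(
          a$gantry_angle + t * dg,
          (1 - t) * a$cumulative_weight + t * b$cumulative_weight,
          (1 - t) * a$bank_a + t * b$bank_a,
          (1 - t) * a$bank_b + t * b$bank_b,
          a$jaw_x, a$jaw_y)
        k <- k + 1L
      }
    }
    out[[k]] <- cps[[n]]
    plan$arcs[[ai]]$control_points <- out
  }
  plan
}

# Delivered-plan surrogate for MLC servo lag: every leaf trails its planned
# trajectory by lag_deg degrees of gantry rotation, i.e. its position error
# is proportional to its local speed. Central differences along each arc.
apply_mlc_lag <- function(plan, lag_deg) {
  if (lag_deg == 0) return(plan)
  for (ai in seq_along(plan$arcs)) {
    cps <- plan$arcs[[ai]]$control_points
    n <- length(cps)
    ang <- vapply(cps, function(cp) cp$gantry_angle, numeric(1))
    A <- t(vapply(cps, function(cp) cp$bank_a, numeric(length(cps[[1]]$bank_a))))
    B <- t(vapply(cps, function(cp) cp$bank_b, numeric(length(cps[[1]]$bank_b))))
    lagged <- function(M) {
      i0 <- c(1L, seq_len(n - 2L), n - 1L)   # one-sided at the arc ends
      i1 <- c(2L, seq(3L, n), n)
      dg <- abs(gantry_delta(ang[i0], ang[i1]))
      dg[dg < 1e-9] <- Inf
      M - lag_deg * (M[i1, , drop = FALSE] - M[i0, , drop = FALSE]) / dg
    }
    A2 <- lagged(A); B2 <- lagged(B)
    swap <- A2 > B2
    mid <- (A2 + B2) / 2
    A2[swap] <- mid[swap]; B2[swap] <- mid[swap]
    for (i in seq_len(n)) {
      cps[[i]]$bank_a <- A2[i, ]
      cps[[i]]$bank_b <- B2[i, ]
    }
    plan$arcs[[ai]]$control_points <- cps
  }
  plan
}

#' Deterministic delivered-dose plane under a measurement error model
#'
#' Re-renders a plan as the machine would deliver it: control points
#' subdivided (continuous-delivery surrogate for the TPS's discrete
#' calculation), every leaf lagging its trajectory by `lag_deg` degrees,
#' and static per-leaf calibration offsets drawn `N(0, leaf_offset_mm)`
#' from `calibration_seed`. Returns the input plane unchanged when no MLC
#' error term is active.
#'
#' @inheritParams perturb_measurement
#' @return A [dose_plane()] on the rendering lattice.
#' @export
delivered_dose_plane <- function(plane, model, plan = NULL,
                                 spec = cohort_spec()) {
  off <- if (is.null(model$leaf_offset_mm)) 0 else model$leaf_offset_mm
  lag <- if (is.null(model$lag_deg)) 0 else model$lag_deg
  subdiv <- if (is.null(model$cp_subdivision)) 2L else model$cp_subdivision
  cal_seed <- if (is.null(model$calibration_seed)) 77L else model$calibration_seed
  if (off == 0 && lag == 0 && subdiv <= 1L) return(plane)
  if (is.null(plan)) stop("plan required to apply MLC errors")
  set.seed(cal_seed)
  np <- plan$mlc$n_pairs
  oa <- if (off != 0) stats::rnorm(np, 0, off) else rep(0, np)
  ob <- if (off != 0) stats::rnorm(np, 0, off) else rep(0, np)
  delivered <- subdivide_plan(apply_mlc_lag(plan, lag), subdiv)
  render_dose(delivered, what = "plane", spec = spec,
              bank_offset_a = oa, bank_offset_b = ob)$plane
}

#' Perturb a computed plane into a synthetic "measured" plane
#'
#' Emulates delivery and measurement error: re-renders the plan with
#' static per-leaf MLC calibration offsets (each leaf of each bank drawn
#' `N(0, leaf_offset_mm)` from the machine's `calibration_seed`, so the
#' error pattern is a fixed machine state shared by all plans and
#' replicates), adds proportional Gaussian noise, applies a rigid setup
#' shift, then samples the result onto the diode-array grid (uniform
#' spacing over the detector extent). With a zero-magnitude model the
#' output is the input plane resampled onto the detector grid. Replicates
#' of the same plan differ only in the noise realization through `seed`.
#'
#' The two MLC error terms make the delivered fluence error spatially
#' structured and complexity-coupled: per-leaf offsets perturb each leaf
#' window edge with relative dose impact roughly `offset / gap width`
#' (narrow modulated apertures suffer more), and the servo lag scales every
#' leaf's positional error with its speed (high-leaf-motion plans suffer
#' more).
#'
#' @param plane The computed [dose_plane()] (used directly when no MLC
#'   error is requested).
#' @param model List with `leaf_offset_mm` (SD of the per-leaf offsets,
#'   mm), `lag_deg` (MLC servo lag in degrees of gantry rotation),
#'   `cp_subdivision` (control-point subdivision factor of the
#'   continuous-delivery surrogate, default 2), `noise_sd_frac`,
#'   `shift_mm`, and optionally `calibration_seed` (default 77).
#' @param seed Integer seed for the noise realization.
#' @param plan The [vmat_plan()]; required when any MLC error term is
#'   active.
#' @param spec A [cohort_spec()] (detector grid and render settings).
#' @param delivered_plane Optional precomputed delivered plane (the
#'   deterministic re-render under the model's MLC error terms), e.g. from
#'   [delivered_dose_plane()]; avoids re-rendering per replicate.
#' @return A [dose_plane()] on the detector lattice.
#' @export
perturb_measurement <- function(plane, model, seed, plan = NULL,
                                spec = cohort_spec(),
                                delivered_plane = NULL) {
  noise <- if (is.null(model$noise_sd_frac)) 0 else model$noise_sd_frac
  shift <- if (is.null(model$shift_mm)) c(0, 0) else model$shift_mm
  p <- if (!is.null(delivered_plane)) delivered_plane
       else delivered_dose_plane(plane, model, plan, spec)
  set.seed(seed)
  if (noise > 0)
    p$values <- pmax(p$values * (1 + stats::rnorm(length(p$values), 0, noise)), 0)
  p$origin <- p$origin + shift
  half <- floor((spec$detector_extent_mm / 2) / spec$detector_spacing_mm) *
    spec$detector_spacing_mm
  dx <- seq(-half, half, by = spec$detector_spacing_mm)
  pts <- expand.grid(x = dx, y = dx)
  v <- interp_plane(p, pts$x, pts$y)
  v[is.na(v)] <- 0
  dose_plane(matrix(v, nrow = length(dx), byrow = TRUE),
             spacing = spec$detector_spacing_mm, origin = c(-half, -half))
}

#' Generate one synthetic patient
#'
#' Anatomy, a reference plan (lower modulation) and a KBP-style re-plan
#' (higher modulation), their computed coronal planes, optional 3D dose
#' grids renormalized to PTV D95 = 76 Gy, and the replicate "measured"
#' detector planes for each plan.
#'
#' @param spec A [cohort_spec()].
#' @param i Patient index (drives the derived seeds).
#' @param render `"plane"` (default) or `"both"` (adds the 3D grids).
#' @return List of class `synthetic_patient`.
#' @export
generate_patient <- function(spec, i, render = c("plane", "both")) {
  render <- match.arg(render)
  anat <- generate_anatomy(spec, derive_seed(spec$seed, i, 1L))
  set.seed(derive_seed(spec$seed, i, 2L))
  mod_ref <- stats::runif(1, spec$ref_modulation[1], spec$ref_modulation[2])
  mod_kbp <- stats::runif(1, spec$kbp_modulation[1], spec$kbp_modulation[2])
  arms <- list(reference = mod_ref, kbp = mod_kbp)
  plans <- list(); planes <- list(); grids <- list(); measured <- list()
  for (k in seq_along(arms)) {
    arm <- names(arms)[k]
    plan <- generate_plan(anat, arms[[k]], spec, derive_seed(spec$seed, i, 10L + k))
    rd <- render_dose(plan, anat, what = if (render == "both") "both" else "plane",
                      spec = spec)
    plans[[arm]] <- plan
    planes[[arm]] <- rd$plane
    if (render == "both")
      grids[[arm]] <- renormalize_to_d95(rd$grid, anat$masks$ptv,
                                         spec$rx_per_fraction * spec$n_fractions)
    delivered <- delivered_dose_plane(planes[[arm]], spec$perturbation,
                                      plan = plan, spec = spec)
    measured[[arm]] <- lapply(seq_len(spec$n_replicates), function(r)
      perturb_measurement(planes[[arm]], spec$perturbation,
                          derive_seed(spec$seed, i, 100L * k + r),
                          plan = plan, spec = spec,
                          delivered_plane = delivered))
  }
  structure(list(patient_id = sprintf("P%03d", i), anatomy = anat,
                 modulation = unlist(arms), plans = plans, planes = planes,
                 grids = grids, measured = measured),
            class = "synthetic_patient")
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param render `"plane"` (default; complexity + gamma pipeline) or
#'   `"both"` (adds renormalized 3D dose grids for DVH/OVH work).
#' @param out_dir Optional directory; when given, plans (JSON), planes
#'   (CSV) and a seed manifest (JSON) are written under it.
#' @return List of class `synthetic_cohort`: `spec`, `patients`, `manifest`.
#' @export
generate_cohort <- function(spec, render = c("plane", "both"), out_dir = NULL) {
  render <- match.arg(render)
  patients <- lapply(seq_len(spec$n_patients), function(i)
    generate_patient(spec, i, render))
  manifest <- data.frame(
    patient_id = vapply(patients, `[[`, character(1), "patient_id"),
    seed_anatomy = vapply(seq_len(spec$n_patients), function(i)
      derive_seed(spec$seed, i, 1L), integer(1)),
    mod_reference = vapply(patients, function(p) p$modulation[["reference"]],
                           numeric(1)),
    mod_kbp = vapply(patients, function(p) p$modulation[["kbp"]], numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in patients) {
      base <- file.path(out_dir, p$patient_id)
      dir.create(base, showWarnings = FALSE)
      for (arm in names(p$plans)) {
        write_plan_json(p$plans[[arm]], file.path(base, paste0(arm, "_plan.json")))
        write_dose_plane_csv(p$planes[[arm]],
                             file.path(base, paste0(arm, "_computed.csv")))
        for (r in seq_along(p$measured[[arm]]))
          write_dose_plane_csv(p$measured[[arm]][[r]],
                               file.path(base, sprintf("%s_measured_%d.csv", arm, r)))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  structure(list(spec = spec, patients = patients, manifest = manifest),
            class = "synthetic_cohort")
}
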