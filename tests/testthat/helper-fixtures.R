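# Fixtures are built in code: small MLC heads, hand-sized plans, and smooth
# random dose planes with correlation length above the gamma search scale.

small_mlc <- function(n_pairs = 10, width = 10) mlc_geometry(n_pairs, width)

# A static "rectangle" arc: every control point has the same fully open
# aperture over the given pairs, jaws wide open.
make_rect_plan <- function(n_cp = 5, n_pairs = 10, width = 10,
                           open_pairs = seq_len(n_pairs),
                           gap = c(-50, 50), beam_mu = 200, rx = 2) {
  mlc <- small_mlc(n_pairs, width)
  bank_a <- rep(0, n_pairs); bank_b <- rep(0, n_pairs)
  bank_a[open_pairs] <- gap[1]; bank_b[open_pairs] <- gap[2]
  cps <- lapply(seq_len(n_cp), function(i)
    control_point(gantry_angle = (i - 1) * 4,
                  cumulative_weight = (i - 1) / (n_cp - 1),
                  bank_a, bank_b,
                  jaw_x = c(-100, 100), jaw_y = c(-100, 100)))
  vmat_plan("rect", list(vmat_arc(cps, beam_mu, "CW", 4)), rx, 38, mlc)
}

# Arbitrary hand-specified arc from matrices of bank positions (rows = CPs).
make_plan_from_banks <- function(bank_a, bank_b, weights = NULL,
                                 angles = NULL, mlc = NULL,
                                 jaw_x = c(-100, 100), jaw_y = c(-100, 100),
                                 beam_mu = 100, rx = 2) {
  n_cp <- nrow(bank_a); n_pairs <- ncol(bank_a)
  if (is.null(mlc)) mlc <- small_mlc(n_pairs)
  if (is.null(weights)) weights <- seq(0, 1, length.out = n_cp)
  if (is.null(angles)) angles <- (seq_len(n_cp) - 1) * 4
  cps <- lapply(seq_len(n_cp), function(i)
    control_point(angles[i], weights[i], bank_a[i, ], bank_b[i, ], jaw_x, jaw_y))
  vmat_plan("banks", list(vmat_arc(cps, beam_mu, "CW", 4)), rx, 38, mlc)
}

# Smooth random plane: plateau with band-limited bumps (correlation length
# ~ wavelength of the low-order modes), positive everywhere.
smooth_random_plane <- function(n = 15, spacing = 3, seed = 1, base = 2) {
  set.seed(seed)
  xs <- seq_len(n) * spacing
  f <- matrix(0, n, n)
  for (k in 1:3) {
    fx <- runif(1, 0.3, 1.2) / (n * spacing)
    fy <- runif(1, 0.3, 1.2) / (n * spacing)
    f <- f + runif(1, 0.1, 0.3) *
      outer(sin(2 * pi * fy * xs + runif(1, 0, 6)),
            sin(2 * pi * fx * xs + runif(1, 0, 6)))
  }
  dose_plane(base * (1 + f), spacing = spacing, origin = c(0, 0))
}

# Linear dose ramp along x on a fine lattice.
ramp_plane <- function(n = 41, spacing = 2, slope = 0.02, base = 1) {
  xs <- (seq_len(n) - 1) * spacing
  vals <- matrix(rep(base + slope * xs, each = n), n, n, byrow = TRUE)
  dose_plane(vals, spacing = spacing, origin = c(0, 0))
}

tiny_cohort_spec <- function(...) cohort_spec(n_patients = 2, seed = 424242, ...)

expect_plan_equal <- function(p1, p2, tol = 1e-6) {
  expect_equal(p1$plan_id, p2$plan_id)
  expect_equal(p1$rx_dose_per_fraction, p2$rx_dose_per_fraction, tolerance = tol)
  expect_equal(p1$n_fractions, p2$n_fractions)
  expect_equal(p1$mlc$leaf_bounds, p2$mlc$leaf_bounds, tolerance = tol)
  expect_equal(length(p1$arcs), length(p2$arcs))
  for (i in seq_along(p1$arcs)) {
    a1 <- p1$arcs[[i]]; a2 <- p2$arcs[[i]]
    expect_equal(a1$beam_mu, a2$beam_mu, tolerance = tol)
    expect_equal(a1$gantry_direction, a2$gantry_direction)
    expect_equal(length(a1$control_points), length(a2$control_points))
    for (j in seq_along(a1$control_points)) {
      c1 <- a1$control_points[[j]]; c2 <- a2$control_points[[j]]
      expect_equal(c1$gantry_angle, c2$gantry_angle, tolerance = tol)
      expect_equal(c1$cumulative_weight, c2$cumulative_weight, tolerance = tol)
      expect_equal(c1$bank_a, c2$bank_a, tolerance = tol)
      expect_equal(c1$bank_b, c2$bank_b, tolerance = tol)
      expect_equal(c1$jaw_x, c2$jaw_x, tolerance = tol)
      expect_equal(c1$jaw_y, c2$jaw_y, tolerance = tol)
    }
  }
  invisible(TRUE)
}
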