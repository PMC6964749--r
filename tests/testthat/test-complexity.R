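test_that("MU per Gy is the normalized monitor-unit count", {
  p <- make_rect_plan(beam_mu = 600, rx = 2)
  expect_equal(mu_per_gy(p), 300)
  p$arcs[[1]]$beam_mu <- 450; p$total_mu <- 450
  expect_equal(mu_per_gy(p), 225)
  # scaling MU and fractional dose together leaves the metric unchanged
  k <- 3.7
  p2 <- p; p2$total_mu <- p$total_mu * k
  p2$rx_dose_per_fraction <- p$rx_dose_per_fraction * k
  expect_equal(mu_per_gy(p2), mu_per_gy(p))
  p$rx_dose_per_fraction <- 0
  expect_error(mu_per_gy(p), "positive")
})

test_that("segment_aperture clips to jaws and excludes out-of-jaw pairs", {
  mlc <- small_mlc(4, 10)   # pairs span y in [-20, 20]
  cp <- control_point(0, 0, bank_a = rep(-30, 4), bank_b = rep(30, 4),
                      jaw_x = c(-100, 100), jaw_y = c(-20, 9))
  ap <- segment_aperture(cp, mlc)
  # pair 4 spans y [10, 20]: fully behind the Y jaw
  expect_identical(ap$in_jaw, c(TRUE, TRUE, TRUE, FALSE))
  # pair 3 spans [0, 10]: clipped to 9 mm of width
  expect_equal(ap$width[3], 9)
  # unclipped pair passes through
  expect_equal(ap$gap[1], 60)
  # jaw bisecting a gap halves its length
  cp2 <- control_point(0, 0, rep(-30, 4), rep(30, 4),
                       jaw_x = c(-30, 0), jaw_y = c(-20, 20))
  expect_equal(segment_aperture(cp2, mlc)$gap[1], 30)
})

test_that("LSV matches the hand-evaluated formula and its conventions", {
  mlc <- small_mlc(3, 10)
  # one bank {0, 5, 10}, other bank constant: LSV = 0.5 * 1
  cp <- control_point(0, 0, bank_a = c(0, 5, 10), bank_b = rep(30, 3),
                      jaw_x = c(-100, 100), jaw_y = c(-100, 100))
  expect_equal(compute_lsv(segment_aperture(cp, mlc)), 0.5)
  # all pairs identical: zero-variability convention gives 1
  cp2 <- control_point(0, 0, rep(-10, 3), rep(10, 3))
  expect_equal(compute_lsv(segment_aperture(cp2, mlc)), 1)
  # a single in-jaw pair is a domain error
  cp3 <- control_point(0, 0, rep(-10, 3), rep(10, 3),
                       jaw_y = c(-15, -11))
  expect_error(compute_lsv(segment_aperture(cp3, mlc)), "2 in-jaw")
})

test_that("AAV is 1 for a static arc at every control point", {
  p <- make_rect_plan(n_cp = 6)
  arc <- p$arcs[[1]]
  mg <- vmatqa:::arc_max_gaps(arc, p$mlc)
  for (cp in arc$control_points)
    expect_equal(compute_aav(segment_aperture(cp, p$mlc), mg), 1)
})

test_that("MCS is 1 for a static open rectangle and bounded in [0,1]", {
  expect_equal(compute_mcs(make_rect_plan())$mcs, 1, tolerance = 1e-12)
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 3)
  for (m in c(0.1, 0.6, 1)) {
    mcs <- compute_mcs(generate_plan(anat, m, spec, 50 + round(10 * m)))$mcs
    expect_gte(mcs, 0); expect_lte(mcs, 1)
  }
})

test_that("MCS matches an independent spreadsheet-style evaluation", {
  # 3 CPs x 3 pairs, hand-specified banks and weights
  bank_a <- rbind(c(-20, -30, -10), c(-15, -25, -12), c(-10, -18, -8))
  bank_b <- rbind(c(10, 25, 15), c(12, 30, 18), c(20, 28, 22))
  w <- c(0, 0.4, 1)
  p <- make_plan_from_banks(bank_a, bank_b, weights = w)

  # independent oracle: direct loop evaluation of the published formulas
  pos_max <- function(v) max(v) - min(v)
  lsv_bank <- function(v) {
    pm <- pos_max(v)
    if (pm <= 0) return(1)
    sum(pm - abs(diff(v))) / ((length(v) - 1) * pm)
  }
  amin <- apply(bank_a, 2, min); bmax <- apply(bank_b, 2, max)
  lsv <- aav <- numeric(3)
  for (i in 1:3) {
    lsv[i] <- lsv_bank(bank_a[i, ]) * lsv_bank(bank_b[i, ])
    aav[i] <- sum(bank_b[i, ] - bank_a[i, ]) / sum(bmax - amin)
  }
  expected <- sum(sapply(1:2, function(i)
    ((aav[i] + aav[i + 1]) / 2) * ((lsv[i] + lsv[i + 1]) / 2) * (w[i + 1] - w[i])))
  expect_equal(compute_mcs(p)$mcs, expected, tolerance = 1e-9)
})

test_that("edge metric reproduces analytic aperture values", {
  # single open pair, width 10, gap 20: EM = 2g / (w g) = 0.2 /mm
  p1 <- make_rect_plan(n_pairs = 5, width = 10, open_pairs = 3, gap = c(-10, 10))
  expect_equal(compute_edge_metric(p1)$em, 0.2)
  # two identical adjacent pairs: no inter-pair side edge, EM halves
  p2 <- make_rect_plan(n_pairs = 5, width = 10, open_pairs = c(3, 4),
                       gap = c(-10, 10))
  expect_equal(compute_edge_metric(p2)$em, 0.1)
  # zero scaling factors zero the metric
  expect_equal(compute_edge_metric(p2, c1 = 0, c2 = 0)$em, 0)
})

test_that("edge metric is translation invariant and scales as 1/s", {
  bank_a <- rbind(c(-20, -30, -10), c(-15, -25, -12))
  bank_b <- rbind(c(10, 25, 15), c(12, 30, 18))
  p <- make_plan_from_banks(bank_a, bank_b)
  em0 <- compute_edge_metric(p)$em
  # uniform translation of all leaves
  pt <- make_plan_from_banks(bank_a + 13, bank_b + 13)
  expect_equal(compute_edge_metric(pt)$em, em0, tolerance = 1e-12)
  # isotropic magnification by s (positions and leaf widths)
  s <- 2.5
  ps <- make_plan_from_banks(bank_a * s, bank_b * s,
                             mlc = mlc_geometry(3, 10 * s),
                             jaw_x = c(-250, 250), jaw_y = c(-250, 250))
  expect_equal(compute_edge_metric(ps)$em, em0 / s, tolerance = 1e-12)
})

test_that("degenerate zero-area control points are excluded with a warning", {
  bank_a <- rbind(c(-10, -10, -10), c(0, 0, 0), c(-10, -10, -10))
  bank_b <- rbind(c(10, 10, 10), c(0, 0, 0), c(10, 10, 10))
  p <- make_plan_from_banks(bank_a, bank_b)
  expect_warning(em <- compute_edge_metric(p), "zero-area")
  expect_identical(em$n_degenerate, 1L)
  expect_true(em$em > 0)
})

test_that("leaf motion matches hand arithmetic and is direction invariant", {
  p <- make_rect_plan()
  expect_equal(compute_leaf_motion(p)$lm, 0)
  # 10 in-jaw pairs = 20 leaf ends; one moves 8 mm over 4 degrees
  p2 <- make_rect_plan(n_cp = 2)
  p2$arcs[[1]]$control_points[[2]]$bank_b[5] <-
    p2$arcs[[1]]$control_points[[2]]$bank_b[5] + 8
  expect_equal(compute_leaf_motion(p2)$lm, (8 / 4) / 20)
  # reversing the arc leaves LM unchanged
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 5)
  pg <- generate_plan(anat, 0.7, spec, 61)
  rev_plan <- pg
  for (ai in seq_along(rev_plan$arcs)) {
    cps <- rev(rev_plan$arcs[[ai]]$control_points)
    w <- vapply(rev_plan$arcs[[ai]]$control_points,
                function(cp) cp$cumulative_weight, numeric(1))
    wr <- rev(1 - w)
    for (i in seq_along(cps)) cps[[i]]$cumulative_weight <- wr[i]
    rev_plan$arcs[[ai]]$control_points <- cps
  }
  expect_equal(compute_leaf_motion(rev_plan)$lm, compute_leaf_motion(pg)$lm,
               tolerance = 1e-12)
  # distinct positions across a zero gantry increment are a domain error
  p3 <- make_plan_from_banks(rbind(c(-10, -10), c(-5, -10)),
                             rbind(c(10, 10), c(10, 10)),
                             angles = c(0, 0))
  expect_error(compute_leaf_motion(p3), "zero gantry")
  # generator plans respect the 7 mm/deg bound
  expect_lte(compute_leaf_motion(pg)$lm, 7)
})

test_that("per-leaf jitter strictly degrades MCS, monotone in amplitude", {
  set.seed(42)
  amps <- seq(0, 9, length.out = 10)
  base <- make_rect_plan(n_cp = 10, n_pairs = 12, gap = c(-40, 40))
  jitter_mcs <- vapply(amps, function(a) {
    p <- base
    for (i in seq_along(p$arcs[[1]]$control_points)) {
      p$arcs[[1]]$control_points[[i]]$bank_a <-
        p$arcs[[1]]$control_points[[i]]$bank_a + rnorm(12, 0, max(a, 1e-9))
      p$arcs[[1]]$control_points[[i]]$bank_b <-
        p$arcs[[1]]$control_points[[i]]$bank_b + rnorm(12, 0, max(a, 1e-9))
    }
    compute_mcs(p)$mcs
  }, numeric(1))
  expect_lt(cor(amps, jitter_mcs, method = "spearman"), 0)
  expect_lt(jitter_mcs[10], jitter_mcs[1])
})

test_that("complexity report aggregates the individual metrics and round-trips", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 5)
  p <- generate_plan(anat, 0.5, spec, 62)
  r <- complexity_report(p)
  expect_equal(r$mu_per_gy, mu_per_gy(p))
  expect_equal(r$mcs, compute_mcs(p)$mcs)
  expect_equal(r$em, compute_edge_metric(p)$em)
  expect_equal(r$lm, compute_leaf_motion(p)$lm)
  f <- tempfile(fileext = ".json")
  write_complexity_json(r, f)
  r2 <- read_complexity_json(f)
  expect_equal(r2$mcs, r$mcs)
  expect_equal(r2$per_arc$em, r$per_arc$em)
  # batch table covers each plan with one row
  plans <- list(p, generate_plan(anat, 0.2, spec, 63),
                generate_plan(anat, 0.8, spec, 64))
  tab <- complexity_table(plans)
  expect_identical(nrow(tab), 3L)
  expect_named(tab, c("plan_id", "mu", "mu_per_gy", "mcs", "em", "lm"))
})
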