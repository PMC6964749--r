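test_that("anatomy generation is reproducible and seed-sensitive", {
  spec <- tiny_cohort_spec()
  a1 <- generate_anatomy(spec, 123)
  a2 <- generate_anatomy(spec, 123)
  a3 <- generate_anatomy(spec, 124)
  expect_identical(a1$masks$ptv$mask, a2$masks$ptv$mask)
  expect_identical(a1$params, a2$params)
  expect_false(identical(a1$masks$ptv$mask, a3$masks$ptv$mask))
  expect_true(all(vapply(a1$masks, function(m) sum(m$mask) > 0, logical(1))))
})

test_that("generated plans satisfy their mechanical contract", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 21)
  for (m in c(0, 0.5, 1)) {
    p <- generate_plan(anat, m, spec, 400 + round(10 * m))
    expect_identical(nrow(validate_plan(p, spec$max_leaf_speed)), 0L)
    expect_length(p$arcs, 2)
    for (arc in p$arcs) {
      expect_length(arc$control_points, 91)
      w <- vapply(arc$control_points, function(cp) cp$cumulative_weight,
                  numeric(1))
      expect_equal(w[1], 0); expect_equal(w[91], 1)
      expect_true(all(diff(w) >= 0))
    }
  }
  expect_error(generate_plan(anat, 1.2, spec, 1), "modulation")
})

test_that("an unmodulated plan is a near-static conformal arc", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 22)
  p0 <- generate_plan(anat, 0, spec, 410)
  r0 <- complexity_report(p0)
  expect_gt(r0$mcs, 0.65)    # dynamic conformal arc: BEV tracking only
  expect_lt(r0$lm, 0.1)
  p1 <- generate_plan(anat, 1, spec, 410)
  r1 <- complexity_report(p1)
  expect_gt(r1$em, r0$em)
  expect_gt(r1$lm, r0$lm)
  expect_lt(r1$mcs, r0$mcs)
  expect_gt(r1$mu, r0$mu)
})

test_that("high modulation beats low modulation pairwise across seeds", {
  spec <- tiny_cohort_spec()
  for (s in 1:6) {
    anat <- generate_anatomy(spec, 500 + s)
    r_lo <- complexity_report(generate_plan(anat, 0.15, spec, 600 + s))
    r_hi <- complexity_report(generate_plan(anat, 0.85, spec, 700 + s))
    expect_gt(r_hi$em, r_lo$em)
    expect_gt(r_hi$lm, r_lo$lm)
    expect_lt(r_hi$mcs, r_lo$mcs)
  }
})

test_that("dose rendering is deterministic and linear in MU", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 23)
  p <- generate_plan(anat, 0.4, spec, 420)
  r1 <- render_dose(p, what = "plane", spec = spec)$plane
  r2 <- render_dose(p, what = "plane", spec = spec)$plane
  expect_identical(r1$values, r2$values)
  p2 <- p
  for (i in seq_along(p2$arcs)) p2$arcs[[i]]$beam_mu <- 2 * p2$arcs[[i]]$beam_mu
  r2x <- render_dose(p2, what = "plane", spec = spec)$plane
  expect_equal(r2x$values, 2 * r1$values, tolerance = 1e-12)
})

test_that("an open static beam renders a flat plateau with penumbra", {
  spec <- tiny_cohort_spec()
  p <- make_rect_plan(n_cp = 3, n_pairs = 20, width = 10, gap = c(-60, 60),
                      open_pairs = 5:16)
  pl <- render_dose(p, what = "plane", spec = spec)$plane
  mid <- which(abs(plane_x_coords <- (seq_len(ncol(pl$values)) - 1) *
                     pl$spacing[1] + pl$origin[1]) < 30)
  core <- pl$values[mid, mid]
  expect_lt((max(core) - min(core)) / max(core), 1e-6)  # flat plateau
  # penumbra: dose falls off smoothly outside the field edge
  edge_prof <- pl$values[66, ]
  expect_lt(max(abs(diff(edge_prof))) / max(edge_prof), 0.35)
  expect_lt(min(edge_prof), 0.05 * max(edge_prof))
})

test_that("zero-magnitude perturbation is pure detector resampling", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 24)
  p <- generate_plan(anat, 0.4, spec, 430)
  pl <- render_dose(p, what = "plane", spec = spec)$plane
  none <- list(leaf_offset_mm = 0, lag_deg = 0, cp_subdivision = 1,
               noise_sd_frac = 0, shift_mm = c(0, 0))
  meas <- perturb_measurement(pl, none, 1, plan = p, spec = spec)
  expect_equal(meas$spacing, c(7, 7))
  direct <- interp_plane <- vmatqa:::interp_plane
  half <- floor((spec$detector_extent_mm / 2) / 7) * 7
  dx <- seq(-half, half, by = 7)
  pts <- expand.grid(x = dx, y = dx)
  v <- direct(pl, pts$x, pts$y)
  expect_equal(as.numeric(t(meas$values)), as.numeric(matrix(v, length(dx))),
               tolerance = 1e-12)
})

test_that("replicates share the delivered plane and differ only by noise", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 25)
  p <- generate_plan(anat, 0.6, spec, 440)
  pl <- render_dose(p, what = "plane", spec = spec)$plane
  m1 <- perturb_measurement(pl, spec$perturbation, 1, plan = p, spec = spec)
  m1b <- perturb_measurement(pl, spec$perturbation, 1, plan = p, spec = spec)
  m2 <- perturb_measurement(pl, spec$perturbation, 2, plan = p, spec = spec)
  expect_identical(m1$values, m1b$values)       # same seed, same replicate
  expect_false(identical(m1$values, m2$values)) # new noise draw
  noiseless <- spec$perturbation; noiseless$noise_sd_frac <- 0
  n1 <- perturb_measurement(pl, noiseless, 1, plan = p, spec = spec)
  n2 <- perturb_measurement(pl, noiseless, 2, plan = p, spec = spec)
  expect_identical(n1$values, n2$values)        # only noise separates replicates
})

test_that("setup shift moves the sampled plane", {
  spec <- tiny_cohort_spec()
  p <- make_rect_plan(n_cp = 3, n_pairs = 20, width = 10, gap = c(-60, 60),
                      open_pairs = 5:16)
  pl <- render_dose(p, what = "plane", spec = spec)$plane
  shifted <- list(leaf_offset_mm = 0, lag_deg = 0, cp_subdivision = 1,
                  noise_sd_frac = 0, shift_mm = c(14, 0))
  m <- perturb_measurement(pl, shifted, 1, plan = p, spec = spec)
  m0 <- perturb_measurement(pl, within(shifted, shift_mm <- c(0, 0)), 1,
                            plan = p, spec = spec)
  # a 14 mm shift equals two detector pixels along x
  expect_equal(m$values[, 3:37], m0$values[, 1:35], tolerance = 1e-9)
})

test_that("the 3D dose grid renormalizes to D95 = 76 Gy", {
  spec <- tiny_cohort_spec()
  pat <- generate_patient(spec, 1, render = "both")
  for (arm in c("reference", "kbp")) {
    g <- pat$grids[[arm]]
    curve <- compute_dvh(g, pat$anatomy$masks$ptv, 0.01)
    expect_equal(dvh_D(curve, 95), 76, tolerance = 0.01)
  }
})

test_that("cohort generation yields the stated layout, reproducibly", {
  spec <- tiny_cohort_spec()
  out <- tempfile()
  co <- generate_cohort(spec, render = "plane", out_dir = out)
  expect_length(co$patients, 2)
  for (pat in co$patients) {
    expect_named(pat$plans, c("reference", "kbp"))
    expect_length(pat$measured$reference, 3)
    expect_length(pat$measured$kbp, 3)
    expect_lt(pat$modulation[["reference"]], pat$modulation[["kbp"]])
  }
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "P001", "kbp_measured_3.csv")))
  co2 <- generate_cohort(spec, render = "plane")
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$patients[[2]]$measured$kbp[[2]]$values,
                   co2$patients[[2]]$measured$kbp[[2]]$values)
})
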