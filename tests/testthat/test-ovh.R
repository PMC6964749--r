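cube_grid <- function(n = 13, h = 4) {
  dose_grid(array(0, dim = c(n, n, n)), c(h, h, h),
            origin = -c(1, 1, 1) * (n - 1) / 2 * h)
}
cube_mask <- function(n, idx) {
  m <- array(FALSE, dim = c(n, n, n))
  m[idx, idx, idx] <- TRUE
  m
}

test_that("signed distance field has the stated sign and boundary behavior", {
  n <- 13; g <- cube_grid(n)
  target <- cube_mask(n, 5:9)
  sdf <- signed_distance_field(target, g)
  # voxel adjacent to a target face sits one voxel size outside
  expect_equal(sdf[4, 7, 7], 4)
  expect_equal(sdf[10, 7, 7], 4)
  # face voxel of the target is on the boundary (zero by convention)
  expect_equal(sdf[5, 7, 7], 0)
  # deep interior is negative
  expect_lt(sdf[7, 7, 7], 0)
  expect_equal(sdf[7, 7, 7], -(3 * 4 - 4))
  expect_error(signed_distance_field(array(FALSE, dim = dim(g$values)), g),
               "empty")
})

test_that("in-field restriction keeps the jaw-projected z slab", {
  n <- 13; g <- cube_grid(n)
  oar <- cube_mask(n, 3:11)        # 9 slabs in z: centers -20..20 mm
  full <- infield_mask(oar, g, c(-100, 100))
  expect_identical(full, oar)
  # a field excluding the superior third (z > 6 mm) keeps 6/9 of voxels
  part <- infield_mask(oar, g, c(-100, 6))
  expect_equal(sum(part) / sum(oar), 6 / 9)
  expect_warning(empty <- infield_mask(oar, g, c(300, 400)), "no OAR voxels")
  expect_false(any(empty))
})

test_that("field_extent unions the Y jaws over all control points", {
  p <- make_rect_plan()
  expect_equal(field_extent(p), c(-100, 100))
  p$arcs[[1]]$control_points[[2]]$jaw_y <- c(-120, 50)
  expect_equal(field_extent(p), c(-120, 100))
})

test_that("OVH limits: containment and separation", {
  n <- 13; g <- cube_grid(n)
  target <- cube_mask(n, 4:10)
  inside <- cube_mask(n, 6:8)      # OAR entirely inside the target
  ovh_in <- compute_ovh(target, inside, g)
  # every OAR voxel is at negative signed distance, so OVH(0) = 1
  expect_true(all(ovh_in$distances[ovh_in$fractions < 1] < 0))
  expect_equal(ovh_in$fractions[length(ovh_in$fractions)], 1)
  # disjoint OAR: a slab whose nearest face is 2 voxels (8 mm) away;
  # the curve is zero below that surface distance
  apart <- array(FALSE, dim = c(n, n, n))
  apart[12, 4:10, 4:10] <- TRUE
  ovh_out <- compute_ovh(target, apart, g)
  expect_gte(min(ovh_out$distances[ovh_out$fractions > 0]), 8)
  expect_gt(ovh_out$fractions[ovh_out$distances == 8], 0)
})

test_that("OVH matches a brute-force per-voxel oracle on concentric cubes", {
  n <- 11; g <- cube_grid(n); h <- 4
  target <- cube_mask(n, 4:8)
  oar <- cube_mask(n, 2:10) & !target    # cubic shell
  ovh <- compute_ovh(target, oar, g, distance_step = 1)
  # oracle: direct distance minimization over voxel centers
  coords <- function(m) {
    ix <- which(m, arr.ind = TRUE)
    (ix - (n + 1) / 2) * h
  }
  tc <- coords(target); oc <- coords(oar); nc <- coords(!target)
  d_oracle <- vapply(seq_len(nrow(oc)), function(i) {
    dd <- sqrt(colSums((t(tc) - oc[i, ])^2))
    min(dd)
  }, numeric(1))
  # all shell voxels are outside the target, so signed = unsigned here
  fr_oracle <- vapply(ovh$distances, function(r) mean(d_oracle <= r), numeric(1))
  expect_equal(ovh$fractions, fr_oracle, tolerance = 1e-12)
})

test_that("OVH curves are monotone and reach 1", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 15)
  ovh <- compute_ovh(anat$masks$ptv, anat$masks$rectum, anat$grid,
                     field_extent = c(-40, 40))
  expect_true(all(diff(ovh$fractions) >= 0))
  expect_equal(ovh$fractions[length(ovh$fractions)], 1)
  expect_true(all(ovh$fractions >= 0 & ovh$fractions <= 1))
})

test_that("inverse OVH lookup interpolates as specified", {
  curve <- structure(list(distances = c(0, 1, 2, 3),
                          fractions = c(0, 0.25, 0.25, 1)),
                     class = "ovh_curve")
  expect_equal(ovh_distance_at(curve, 100), 3)
  expect_equal(ovh_distance_at(curve, 0), 0)
  # interpolated midpoints on the rising segments
  expect_equal(ovh_distance_at(curve, 12.5), 0.5)
  expect_equal(ovh_distance_at(curve, 62.5), 2.5)
})

make_entry <- function(id, d30, dose30, source = "clinical") {
  # step OVH curve reaching 30% exactly at distance d30
  curve <- structure(list(distances = c(d30 - 1, d30, d30 + 30),
                          fractions = c(0, 0.30, 1)), class = "ovh_curve")
  kbp_entry(id, source, list(rectum = curve),
            list(rectum = c("30" = dose30)))
}

test_that("the prediction rule takes the minimum over eligible entries", {
  db <- list(make_entry("a", 10, 40), make_entry("b", 15, 35))
  query <- list(rectum = structure(list(distances = c(11, 12, 40),
                                        fractions = c(0, 0.3, 1)),
                                   class = "ovh_curve"))
  pred <- predict_dose_volumes(query, db, levels = 30)
  expect_equal(pred$rectum$dose, 40)   # only the d=10 entry is eligible
  expect_false(pred$rectum$fallback)
  # Pareto knowledge lowers the objective
  db2 <- c(db, list(make_entry("p", 8, 30, source = "pareto")))
  expect_equal(predict_dose_volumes(query, db2, levels = 30)$rectum$dose, 30)
  # a query identical to a database patient is bounded by its own dose
  query_self <- list(rectum = db[[2]]$ovh$rectum)
  expect_lte(predict_dose_volumes(query_self, db, levels = 30)$rectum$dose, 35)
  expect_error(predict_dose_volumes(query, list(), levels = 30), "empty")
})

test_that("predictions fall back to the nearest entry when none is eligible", {
  db <- list(make_entry("a", 10, 40), make_entry("b", 15, 35))
  query <- list(rectum = structure(list(distances = c(1, 2, 30),
                                        fractions = c(0, 0.3, 1)),
                                   class = "ovh_curve"))
  pred <- predict_dose_volumes(query, db, levels = 30)
  expect_true(pred$rectum$fallback)
  expect_identical(pred$rectum$matched, "a")
})

test_that("growing the database never increases a prediction", {
  set.seed(31)
  base <- lapply(1:5, function(i)
    make_entry(paste0("e", i), runif(1, 5, 20), runif(1, 25, 45)))
  query <- list(rectum = structure(list(distances = c(13, 14, 40),
                                        fractions = c(0, 0.3, 1)),
                                   class = "ovh_curve"))
  p1 <- predict_dose_volumes(query, base, levels = 30)$rectum$dose
  for (k in 1:5) {
    base <- c(base, list(make_entry(paste0("x", k), runif(1, 5, 20),
                                    runif(1, 20, 45))))
    p2 <- predict_dose_volumes(query, base, levels = 30)$rectum$dose
    expect_lte(p2, p1)
    p1 <- p2
  }
})

test_that("predictions are monotone in query geometry", {
  db <- lapply(1:6, function(i) make_entry(paste0("e", i), 4 + 2 * i, 50 - 3 * i))
  dist_q <- function(d) list(rectum = structure(
    list(distances = c(d - 1, d, d + 30), fractions = c(0, 0.3, 1)),
    class = "ovh_curve"))
  doses <- vapply(seq(5, 18, by = 1), function(d)
    predict_dose_volumes(dist_q(d), db, levels = 30)$rectum$dose, numeric(1))
  expect_true(all(diff(doses) <= 0))   # more favorable geometry, lower dose
})

test_that("database build and JSONL round-trip preserve entries", {
  spec <- tiny_cohort_spec()
  anat <- generate_anatomy(spec, 16)
  ovh <- list(rectum = compute_ovh(anat$masks$ptv, anat$masks$rectum, anat$grid),
              bladder = compute_ovh(anat$masks$ptv, anat$masks$bladder, anat$grid))
  set.seed(2)
  doses <- sort(runif(2500, 5, 70), decreasing = TRUE)
  g <- dose_grid(array(doses, dim = c(50, 50, 1)), c(4, 4, 4))
  dvh <- compute_dvh(g, array(TRUE, dim = c(50, 50, 1)), 0.1)
  cohort <- lapply(1:3, function(i)
    list(patient_id = paste0("P", i), source = if (i == 3) "pareto" else "clinical",
         ovh = ovh, dvh = list(rectum = dvh, bladder = dvh)))
  db <- build_database(cohort)
  expect_length(db, 3)
  expect_identical(db[[3]]$source, "pareto")
  for (e in db) {
    expect_setequal(names(e$achieved$rectum), c("10", "30", "50", "65", "80"))
    expect_true(all(e$achieved$rectum > 0))
  }
  f <- tempfile(fileext = ".jsonl")
  write_kbp_database(db, f)
  db2 <- read_kbp_database(f)
  expect_length(db2, 3)
  expect_identical(db2[[3]]$source, "pareto")
  expect_equal(db2[[1]]$achieved$rectum, db[[1]]$achieved$rectum)
  expect_equal(db2[[2]]$ovh$rectum$fractions, db[[2]]$ovh$rectum$fractions)
})
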