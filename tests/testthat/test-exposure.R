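# Projected TI exposure metrics and steering.

test_that("envelope-amplitude identity holds to machine precision", {
  set.seed(42)
  a <- runif(1e5, -10, 10)
  b <- runif(1e5, -10, 10)
  lhs <- abs(abs(a + b) - abs(a - b))
  rhs <- 2 * pmin(abs(a), abs(b))
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("projected amplitudes match worked examples and the time-domain oracle", {
  ex <- c(1, 0, 0)
  expect_equal(projected_envelope_amplitude(c(1, 0, 0), c(1, 0, 0), ex), 2)
  expect_equal(projected_envelope_amplitude(c(1, 0, 0), c(0, 1, 0), ex), 0)
  expect_equal(projected_envelope_amplitude(c(3, 0, 0), c(1, 0, 0), ex), 2)
  expect_equal(projected_absolute_amplitude(c(1, 0, 0), c(1, 0, 0), ex), 2)
  expect_equal(projected_absolute_amplitude(c(1, 0, 0), c(0, 1, 0), ex), 1)
  expect_equal(projected_absolute_amplitude(c(3, 0, 0), c(1, 0, 0), ex), 4)
  expect_error(projected_envelope_amplitude(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "unit")

  set.seed(7)
  for (i in 1:100) {
    E1 <- rnorm(3); E2 <- rnorm(3)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    p1 <- sum(E1 * n); p2 <- sum(E2 * n)
    eam <- projected_envelope_amplitude(E1, E2, n)
    eabs <- projected_absolute_amplitude(E1, E2, n)
    expect_equal(eam, envelope_oracle_eam(p1, p2), tolerance = 1e-3)
    expect_equal(eabs, envelope_oracle_eabs(p1, p2), tolerance = 1e-3)
  }
})

test_that("exposure maps obey zero-current, linearity, bounds and pair-swap symmetry", {
  fx <- sphere_fixture("symmetric")
  ex0 <- exposure_maps(fx$s1, fx$s2, 0, 1, fx$ph)
  expect_true(all(ex0$eam[!is.na(ex0$eam)] == 0))
  ex1 <- exposure_maps(fx$s1, fx$s2, 1, 1.5, fx$ph)
  ex2 <- exposure_maps(fx$s1, fx$s2, 2, 3, fx$ph)
  expect_equal(ex2$eam, 2 * ex1$eam, tolerance = 1e-12)
  expect_equal(ex2$eabs, 2 * ex1$eabs, tolerance = 1e-12)
  ok <- !is.na(ex1$eam)
  expect_true(all(ex1$eam[ok] >= 0))
  expect_true(all(ex1$eam[ok] <= ex1$eabs[ok] + 1e-12))
  sw <- exposure_maps(fx$s2, fx$s1, 1.5, 1, fx$ph)
  expect_equal(sw$eam, ex1$eam, tolerance = 1e-12)
})

test_that("ROI summaries report medians and normalizations", {
  map <- array(NA_real_, c(3, 3, 1))
  map[, 1, 1] <- c(1, 2, 3)
  map[, 2, 1] <- c(2, 2, 2)
  map[, 3, 1] <- c(4, 4, 4)
  masks <- list(a = array(FALSE, dim(map)), b = array(FALSE, dim(map)),
                c = array(FALSE, dim(map)))
  masks$a[, 1, 1] <- TRUE; masks$b[, 2, 1] <- TRUE; masks$c[, 3, 1] <- TRUE
  rs <- roi_summary(map, masks)
  expect_equal(rs$median, c(2, 2, 4))
  rs_t <- roi_summary(map, masks, "to_target_median", target = "a")
  expect_identical(rs_t$normalized[1], 1)
  rs_f <- roi_summary(map, masks, "fraction_of_subregion_sum")
  expect_equal(rs_f$normalized, c(0.25, 0.25, 0.5))
  expect_lt(abs(sum(rs_f$normalized) - 1), 1e-9)
  empty <- list(z = array(FALSE, dim(map)))
  expect_error(roi_summary(map, empty), "empty")
})

test_that("steering moves the envelope centroid toward the weaker pair", {
  fx <- sphere_fixture("symmetric")
  rois <- target_parcel_masks(fx$ph)
  ratios <- list(c(3, 1), c(8 / 3, 4 / 3), c(2, 2), c(4 / 3, 8 / 3), c(1, 3))
  st <- steering_sweep(fx$s1, fx$s2, ratios, rois, fx$ph)
  fr <- as.matrix(st[, grep("^frac_", names(st))])
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  # pair 1 (e1-e2) sits anterior (+y): lowering I1 steers the centroid +y
  expect_true(all(diff(st$centroid_mm) > 0))
  # equal currents on the symmetric montage: centroid at the midpoint
  expect_lt(abs(st$centroid_mm[3]), max(fx$ph$spacing))
  expect_error(steering_sweep(fx$s1, fx$s2, list(c(-1, 2)), rois, fx$ph),
               "negative")
})

test_that("equal currents put the brain envelope peak on the symmetry plane", {
  fx <- sphere_fixture("symmetric")
  ex <- exposure_maps(fx$s1, fx$s2, 1, 1, fx$ph)
  brain <- fx$ph$labels %in% c(4L, 5L, fx$ph$target_label)
  pk <- eam_peak(ex, mask = brain)
  y <- tistim:::axis_coords(fx$ph)[[2]][pk[2]]
  # nearest voxel centers to the y = 0 plane sit half a voxel away
  expect_lte(abs(y), 1.5 * fx$ph$spacing[2])
})

test_that("deep target sees more envelope modulation, cortex more absolute amplitude", {
  fx <- sphere_fixture("default")
  ex <- exposure_maps(fx$s1, fx$s2, 1, 1, fx$ph)
  target <- fx$ph$labels == fx$ph$target_label
  cortex <- superficial_cortex_roi(fx$ph, fx$mt)
  expect_gt(median(ex$eam[target]), median(ex$eam[cortex], na.rm = TRUE))
  expect_gt(median(ex$eabs[cortex], na.rm = TRUE), median(ex$eabs[target]))
})
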