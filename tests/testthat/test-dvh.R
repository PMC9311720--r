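test_that("uniform dose gives a step-function DVH", {
  cv <- uniform_dvh(50)
  expect_equal(dvh_metric(cv, "V30Gy"), 100)
  expect_equal(dvh_metric(cv, "V50Gy"), 100)
  expect_equal(dvh_metric(cv, "V51Gy"), 0)
  expect_equal(cv$volume_pct[1], 100)
  expect_equal(tail(cv$volume_pct, 1), 0)
  expect_equal(dvh_metric(cv, "Dmean"), 50)
  expect_equal(dvh_metric(cv, "Dmax"), 50)
})

test_that("two-level dose: V40 = 50%, Dmean = 40, D50% = 60", {
  tl <- two_level_dose(20, 60)
  cv <- compute_dvh(tl$dose, tl$mask)
  expect_equal(dvh_metric(cv, "V40Gy"), 50)
  expect_equal(dvh_metric(cv, "Dmean"), 40)
  expect_equal(dvh_metric(cv, "D50%"), 60)
})

test_that("DVH matches a brute-force per-threshold count on random volumes", {
  set.seed(77)
  for (rep in 1:3) {
    dims <- c(9L, 8L, 5L)
    dose <- array(runif(prod(dims), 0, 75), dims)
    mask <- array(runif(prod(dims)) > 0.4, dims)
    cv <- compute_dvh(dose, mask, bin_width_gy = 0.05)
    vox <- dose[mask]
    probes <- seq(0, max(vox), length.out = 25)
    for (d in probes) {
      oracle <- 100 * sum(vox >= d) / length(vox)
      # evaluate at the nearest bin edge to avoid interpolation smoothing
      edge <- cv$dose_gy[which.min(abs(cv$dose_gy - d))]
      oracle_edge <- 100 * sum(vox >= edge - 1e-9) / length(vox)
      expect_equal(stats::approx(cv$dose_gy, cv$volume_pct, edge)$y, oracle_edge,
                   tolerance = 1e-9)
    }
    expect_equal(dvh_metric(cv, "Dmean"), mean(vox), tolerance = 1e-12)
    expect_equal(dvh_metric(cv, "Dmax"), max(vox), tolerance = 1e-12)
  }
})

test_that("cumulative curve is monotone and refinement-stable", {
  pl <- fixture_plan(11)
  cv1 <- compute_dvh(pl$dose, pl$anatomy$masks$rectum, bin_width_gy = 0.1)
  cv2 <- compute_dvh(pl$dose, pl$anatomy$masks$rectum, bin_width_gy = 0.05)
  expect_true(all(diff(cv1$volume_pct) <= 1e-12))
  one_voxel_pct <- 100 / attr(cv1, "voxel_count")
  for (m in c("V20Gy", "V40Gy", "V55Gy")) {
    expect_lt(abs(dvh_metric(cv1, m) - dvh_metric(cv2, m)), one_voxel_pct)
  }
  # Dmin <= Dmean <= Dmax
  st <- attr(cv1, "dose_stats")
  expect_lte(st["min"], st["mean"])
  expect_lte(st["mean"], st["max"])
})

test_that("DVH metric parsing and domain handling", {
  cv <- uniform_dvh(50)
  expect_error(dvh_metric(cv, "Q50"), "Unrecognised")
  expect_warning(dvh_metric(cv, "D120%"), "clamped")
  expect_equal(dvh_metric(cv, "V200Gy"), 0)  # above max: zero volume
})

test_that("empty or misaligned inputs are rejected", {
  dims <- c(4L, 4L, 2L)
  dose <- array(1, dims)
  expect_error(compute_dvh(dose, array(FALSE, dims)), "Empty")
  expect_error(compute_dvh(dose, array(TRUE, c(4L, 4L, 3L))), "Misaligned")
  expect_error(compute_dvh(dose, array(TRUE, dims), bin_width_gy = 0), "positive")
})

test_that("DVH text export round-trips", {
  pl <- fixture_plan(11)
  cv <- compute_dvh(pl$dose, pl$anatomy$masks$rectum)
  path <- tempfile(fileext = ".tsv")
  write_dvh(cv, path)
  cv2 <- read_dvh(path)
  expect_equal(cv2$dose_gy, cv$dose_gy)
  expect_equal(cv2$volume_pct, cv$volume_pct)
  expect_equal(attr(cv2, "voxel_count"), attr(cv, "voxel_count"))
  expect_equal(dvh_metric(cv2, "Dmean"), dvh_metric(cv, "Dmean"), tolerance = 1e-9)
})
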