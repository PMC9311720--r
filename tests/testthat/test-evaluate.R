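cube_dose <- function(dims, value, xs, ys, zs) {
  arr <- array(0, dims)
  arr[xs, ys, zs] <- value
  dose_grid(arr, c(1, 1, 1))
}

test_that("Dice similarity matches direct set counting on constructed cubes", {
  dims <- c(20L, 20L, 10L)
  a <- cube_dose(dims, 50, 1:10, 1:10, 1:10)   # 1000 voxels
  b <- cube_dose(dims, 50, 6:15, 1:10, 1:10)   # 1000 voxels, 500 shared
  expect_equal(isodose_dsc(a, a, 40), 1)
  expect_equal(isodose_dsc(a, b, 40), 2 * 500 / 2000)
  disjoint <- cube_dose(dims, 50, 11:20, 11:20, 1:10)
  expect_equal(isodose_dsc(a, disjoint, 40), 0)
  # symmetry
  expect_equal(isodose_dsc(a, b, 40), isodose_dsc(b, a, 40))
  # both-empty convention
  expect_message(v <- isodose_dsc(a, a, 99), "DSC = 1 by convention")
  expect_equal(v, 1)
  expect_error(isodose_dsc(a, b, 0), "positive")
  expect_error(
    isodose_dsc(a, dose_grid(array(0, c(4, 4, 4)), c(1, 1, 1)), 40),
    "Misaligned"
  )
})

test_that("DSC profile excludes isodoses touching the volume boundary", {
  dims <- c(12L, 12L, 6L)
  inner <- cube_dose(dims, 50, 4:8, 4:8, 3:4)
  touching <- cube_dose(dims, 50, 1:8, 4:8, 3:4)  # reaches x = 1 face
  prof <- suppressMessages(dsc_profile(inner, touching, levels_gy = c(40)))
  expect_false(prof$included[1])
  expect_true(is.na(prof$dsc[1]))
  prof2 <- dsc_profile(touching, inner, levels_gy = c(40))
  expect_true(prof2$included[1])
})

test_that("DVH error profiles summarise predicted-minus-planned errors", {
  mk_curve <- function(v_at) {
    df <- tibble::tibble(dose_gy = c(0, 10, 20, 30), volume_pct = c(100, v_at, 10, 0))
    structure(df, class = c("dvh_curve", class(tibble::tibble())),
              structure = "rectum", voxel_count = 100L, source = "planned",
              dose_stats = NULL)
  }
  truth <- lapply(c(50, 60, 70, 55, 65), mk_curve)
  expect_equal(dvh_error_profile(truth, truth, "V10Gy")$mean, 0)
  expect_equal(dvh_error_profile(truth, truth, "V10Gy")$sd, 0)

  pred <- lapply(c(52, 62, 72, 57, 67), mk_curve)  # constant +2 offset
  prof <- dvh_error_profile(pred, truth, "V10Gy")
  expect_equal(prof$mean, 2)
  expect_equal(prof$sd, 0)

  # order-statistics oracle for the IQR on scattered errors
  offs <- c(-3, 0, 1, 4, 9)
  pred2 <- lapply(c(50, 60, 70, 55, 65) + offs, mk_curve)
  prof2 <- dvh_error_profile(pred2, truth, "V10Gy")
  q <- unname(quantile(offs, c(0.25, 0.75)))
  expect_equal(prof2$q1, q[1])
  expect_equal(prof2$q3, q[2])
  expect_equal(prof2$iqr, diff(q))
  expect_gte(prof2$whisker_low, min(offs))
  expect_lte(prof2$whisker_high, max(offs))

  # permutation invariance over the cohort
  perm <- c(3, 1, 5, 2, 4)
  prof3 <- dvh_error_profile(pred2[perm], truth[perm], "V10Gy")
  expect_equal(prof3$mean, prof2$mean)
  expect_equal(prof3$iqr, prof2$iqr)
  expect_error(dvh_error_profile(pred2[1:3], truth), "differ in length")
  expect_error(dvh_error_profile(pred2[1], truth[1]), "at least 2")
})

test_that("Bland-Altman bias and limits follow the closed formulas", {
  x <- c(3.1, 4.2, 5.0, 6.3)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba1 <- bland_altman(x + 1, x)
  expect_equal(ba1$mean_bias, 1)
  expect_equal(ba1$loa_low, 1)
  expect_equal(ba1$loa_high, 1)

  d <- c(-1, 0, 1)
  ba2 <- bland_altman(c(5, 6, 7) + d, c(5, 6, 7))
  expect_equal(ba2$mean_bias, 0)
  expect_equal(ba2$loa_high, 1.96 * sd(d))   # sample (n-1) SD
  expect_equal(ba2$loa_low, -1.96 * sd(d))
  expect_true(ba2$loa_low <= ba2$mean_bias && ba2$mean_bias <= ba2$loa_high)
  expect_error(bland_altman(1, 1), "length >= 2")

  td <- tidy(ba2)
  expect_equal(td$difference, d)
  gl <- glance(ba2)
  expect_named(gl, c("n", "mean_bias", "sd", "loa_low", "loa_high"))
})
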