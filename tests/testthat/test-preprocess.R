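test_that("spline resampling reproduces constants, identity and ramps", {
  dims <- c(12L, 10L, 8L)
  sp <- c(4, 4, 5)
  const <- dose_grid(array(10, dims), sp)
  rs <- resample_dose(const, c(2, 2, 2.5), c(24L, 20L, 16L))
  expect_equal(max(abs(rs$dose_gy - 10)), 0, tolerance = 1e-9)

  rnd <- dose_grid(array(runif(prod(dims), 0, 70), dims), sp)
  same <- resample_dose(rnd, sp, dims)
  expect_equal(same$dose_gy, rnd$dose_gy, tolerance = 1e-12)

  # linear ramp along x is preserved by cubic interpolation
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  ramp <- dose_grid(array(rep(xs, times = prod(dims[2:3])), dims), sp)
  tgt_sp <- c(1.6, 4, 5); tgt_dim <- c(30L, 10L, 8L)
  rr <- resample_dose(ramp, tgt_sp, tgt_dim)
  xt <- (seq_len(tgt_dim[1]) - 0.5) * tgt_sp[1]
  interior <- xt > sp[1] & xt < max(xs) - sp[1]
  analytic <- array(rep(xt, times = prod(tgt_dim[2:3])), tgt_dim)
  expect_lt(max(abs(rr$dose_gy - analytic)[interior, , ]), 1e-6)

  expect_error(resample_dose(const, c(0, 1, 1), dims), "positive")
})

test_that("crop centres follow the anatomical centring rules", {
  ss <- block_anatomy()
  mi <- crop_to_input(ss, shape = c(16L, 16L, 8L))
  # left-right centre: floor of the PTV53 centre of mass (x = 8:15 -> 11.5)
  com53_x <- mean(8:15)
  expect_equal(mi$crop_offset[1], floor(com53_x) - 8L + 1L)
  # cranio-caudal centre: floor of the rectal centre of mass (z = 3:10 -> 6.5)
  expect_equal(mi$crop_offset[3], floor(mean(3:10)) - 4L + 1L)
  # the whole rectum is inside the crop
  expect_equal(sum(mi$channels$rectum), sum(ss$masks$rectum))
  expect_named(mi$channels, c("ptv68", "ptv60", "ptv53", "rectum", "bladder"))
})

test_that("a rectum touching the window edge is still fully sampled", {
  ss <- block_anatomy(rect_y = 16:22)  # posterior rectum
  mi <- crop_to_input(ss, shape = c(16L, 16L, 8L))
  expect_equal(sum(mi$channels$rectum), sum(ss$masks$rectum))
  # an impossible window errors explicitly
  wide <- block_anatomy(rect_y = 2:22)
  expect_error(crop_to_input(wide, shape = c(16L, 16L, 8L)), "cannot fit")
})

test_that("crop/uncrop round-trips dose values at the recorded offset", {
  pl <- fixture_plan(11)
  mi <- crop_to_input(pl$anatomy, pl$dose, shape = c(32L, 32L, 16L))
  back <- uncrop(mi$dose, mi$crop_offset, mi$source_dim)
  ends <- pmin(mi$crop_offset + dim(mi$dose) - 1L, mi$source_dim)
  lo <- pmax(mi$crop_offset, 1L)
  expect_equal(back[lo[1]:ends[1], lo[2]:ends[2], lo[3]:ends[3]],
               pl$dose$dose_gy[lo[1]:ends[1], lo[2]:ends[2], lo[3]:ends[3]])
})

test_that("windows that overrun the grid are zero-padded with a warning", {
  ss <- block_anatomy(dims = c(20L, 20L, 10L))
  expect_warning(mi <- crop_to_input(ss, shape = c(32L, 32L, 16L)), "zero-padding")
  expect_equal(dim(mi$channels$rectum), c(32L, 32L, 16L))
  expect_equal(sum(mi$channels$rectum), sum(ss$masks$rectum))
})

test_that("normalization is a strict inverse pair with a brute-force cohort max", {
  doses <- lapply(c(3, 5), function(s) fixture_plan(s)$dose)
  const <- norm_constant_from_cohort(doses)
  expect_equal(const$max_dose_gy, max(vapply(doses, function(d) max(d$dose_gy),
                                             numeric(1))))
  x <- doses[[1]]$dose_gy
  expect_equal(denormalize_dose(normalize_dose(x, const), const), x,
               tolerance = 1e-12)
  expect_equal(max(normalize_dose(x, normalization_constant(max(x)))), 1,
               tolerance = 1e-12)
  expect_error(normalization_constant(0), "positive")
})
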