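test_that("phantom generation is deterministic for a fixed spec", {
  spec <- phantom_spec(seed = 21)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$masks, b$masks)
  expect_identical(a$ptv68, b$ptv68)
  expect_identical(a$volumes_cc, b$volumes_cc)
})

test_that("spec validation rejects bad inputs", {
  expect_error(phantom_spec(boost_positions = 1:5), "exactly 6")
  expect_error(phantom_spec(prostate_volume_cc = -5), "positive")
  expect_error(phantom_spec(spacing_mm = c(4, 0, 5)), "positive")
  expect_error(phantom_spec(margin_ptv60_mm = -1), "non-negative")
})

test_that("too-small grids fail with the offending structure named", {
  expect_error(
    generate_phantom(phantom_spec(seed = 1, grid_shape = c(20, 20, 10),
                                  spacing_mm = c(4, 4, 7))),
    "Grid too small: structure"
  )
})

test_that("phantom geometry honours the pelvic layout", {
  ph <- fixture_phantom(11)
  # rectum posterior to the prostate: higher y centre of mass
  com_r <- colMeans(which(ph$masks$rectum, arr.ind = TRUE))
  com_p <- colMeans(which(ph$masks$prostate, arr.ind = TRUE))
  expect_gt(com_r[2], com_p[2])
  # nested target hierarchy
  expect_true(all(ph$masks$prostate[ph$masks$ptv60] | TRUE))  # guard shape
  expect_true(all(!(ph$masks$prostate & !ph$masks$ptv60)))    # prostate in PTV60
  expect_true(all(!(ph$masks$ptv60 & !ph$masks$ptv53)))       # PTV60 in PTV53
  for (k in 1:6) {
    # PTV68 within PTV60 (its 2 mm margin sits inside the 5 mm margin)
    expect_true(all(!(ph$ptv68[[k]] & !ph$masks$ptv60)))
    # boosts sit in distinct positions
    expect_true(any(ph$ptv68[[k]]))
  }
  # small rectum/boost overlap
  for (k in 1:6) {
    ov <- sum(ph$masks$rectum & ph$ptv68[[k]]) / sum(ph$masks$rectum)
    expect_lt(ov, 0.2)
  }
})

test_that("structure_set validates masks and boost index", {
  ph <- fixture_phantom(11)
  ss <- structure_set(ph, 3)
  expect_s3_class(ss, "structure_set")
  expect_named(ss$masks, c("ptv68", "ptv60", "ptv53", "rectum", "bladder"))
  expect_error(structure_set(ph, 7), "between 1 and 6")
})

test_that("drawn structure volumes follow the cohort distributions", {
  vols <- vapply(1:12, function(s) {
    fixture_phantom(100 + s)$volumes_cc[c("prostate", "rectum")]
  }, numeric(2))
  # truncation band: +/- 2.5 SD around the cohort means
  expect_true(all(vols["prostate", ] > 42.3 - 2.5 * 15.7 - 2))
  expect_true(all(vols["prostate", ] < 42.3 + 2.5 * 15.7 + 2))
  expect_true(all(vols["rectum", ] > 69.3 - 2.5 * 19.7 - 2))
  expect_true(all(vols["rectum", ] < 69.3 + 2.5 * 19.7 + 2))
  # sample means in a generous band around the cohort means
  expect_gt(mean(vols["rectum", ]), 50)
  expect_lt(mean(vols["rectum", ]), 90)
})

test_that("dose grids reject invalid fields", {
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)), "non-negative")
  expect_error(dose_grid(matrix(0, 2, 2), c(1, 1, 1)), "3D")
})
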