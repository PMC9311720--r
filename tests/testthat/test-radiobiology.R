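# Voxel-based power-mean oracle, independent of the curve-based implementation.
# Scaling by the maximum keeps d^(1/n) finite for strongly serial exponents.
geud_oracle <- function(doses, n) {
  dmax <- max(doses)
  if (dmax == 0) return(0)
  dmax * mean((doses / dmax)^(1 / n))^n
}

test_that("EQD2 closed forms hold", {
  fx20 <- fractionation_scheme(20, 3)
  # dose delivered at exactly 2 Gy per fraction is its own EQD2
  expect_equal(eqd2_transform(40, fx20), 40, tolerance = 1e-12)
  expect_equal(eqd2_transform(0, fx20), 0)
  # 60 Gy in 20 fractions, alpha/beta 3: 60 * (3 + 3) / (2 + 3) = 72
  expect_equal(eqd2_transform(60, fx20), 72, tolerance = 1e-12)
  expect_error(fractionation_scheme(0), "positive")
})

test_that("EQD2 increases hypofractionated and decreases hyperfractionated doses", {
  fx <- fractionation_scheme(20, 3)
  above <- seq(42, 70, by = 2)   # > 2 Gy/fraction
  below <- seq(2, 38, by = 2)    # < 2 Gy/fraction
  expect_true(all(eqd2_transform(above, fx) > above))
  expect_true(all(eqd2_transform(below, fx) < below))
  # monotone in dose
  d <- seq(0, 80, by = 0.5)
  expect_true(all(diff(eqd2_transform(d, fx)) > 0))
})

test_that("gEUD limits: mean at n = 1, uniform invariance, max as n -> 0", {
  pl <- fixture_plan(11)
  cv <- compute_dvh(pl$dose, pl$anatomy$masks$rectum, bin_width_gy = 0.02)
  vox <- pl$dose$dose_gy[pl$anatomy$masks$rectum]
  expect_equal(geud(cv, 1), mean(vox), tolerance = 1e-3)
  u <- uniform_dvh(70)
  for (n in c(1, 0.5, 0.085, 1e-3)) expect_equal(geud(u, n), 70, tolerance = 1e-6)
  # n -> 0+ approaches the maximum dose
  expect_equal(geud(cv, 1e-3), max(vox), tolerance = 1e-2)
  expect_error(geud(cv, 0), "positive")
})

test_that("gEUD matches high-precision direct summation across exponents", {
  tl <- two_level_dose(30, 70)
  cv <- compute_dvh(tl$dose, tl$mask, bin_width_gy = 0.01)
  vox <- tl$dose[tl$mask]
  for (n in c(1, 0.5, 0.085, 1e-3)) {
    expect_equal(geud(cv, n), geud_oracle(vox, n), tolerance = 1e-3)
  }
  # the serial exponent is dominated by the hot half
  expect_gt(geud(cv, 0.085), 65)
  # bounded by [Dmean, Dmax] for n <= 1
  for (n in c(1, 0.5, 0.085, 1e-3)) {
    g <- geud(cv, n)
    expect_gte(g + 1e-6, mean(vox))
    expect_lte(g, max(vox) + 1e-6)
  }
})

test_that("LKB probit behaves as a probit", {
  for (ep in c("LRB", "LFI")) {
    p <- lkb_preset(ep)
    expect_equal(lkb_ntcp(p$td50_gy, p), 0.5, tolerance = 1e-12)
    expect_equal(lkb_ntcp(p$td50_gy * (1 + p$m), p), pnorm(1), tolerance = 1e-12)
    # zero-dose limit: exactly the probit tail at -1/m (about 1.1e-4 for the
    # bleeding preset, about 1% for the incontinence preset)
    expect_equal(lkb_ntcp(0, p), pnorm(-1 / p$m), tolerance = 1e-12)
    expect_lt(lkb_ntcp(0, p), 0.011)
    # probit symmetry around TD50
    for (dg in c(5, 15, 30)) {
      expect_equal(lkb_ntcp(p$td50_gy + dg, p) + lkb_ntcp(max(p$td50_gy - dg, 0), p),
                   1, tolerance = 1e-9)
    }
  }
  # strictly increasing in gEUD
  p <- lkb_preset("LRB")
  g <- seq(0, 150, by = 5)
  expect_true(all(diff(lkb_ntcp(g, p)) > 0))
  expect_error(lkb_parameters(97.7, 0.27, 1.5), "Invalid LKB")
  expect_error(lkb_preset("XYZ"), "Unknown endpoint")
})

test_that("risk pipeline is monotone and vanishes at zero dose", {
  zero <- uniform_dvh(0)
  # the zero-dose floor of each preset is its probit tail at -1/m
  expect_equal(risk(zero, "LRB"), pnorm(-1 / 0.27), tolerance = 1e-9)
  expect_equal(risk(zero, "LFI"), pnorm(-1 / 0.43), tolerance = 1e-9)
  expect_lt(risk(zero, "LRB"), 2e-4)

  pl <- fixture_plan(11)
  cv <- compute_dvh(pl$dose, pl$anatomy$masks$rectum)
  scale_curve <- function(curve, f) {
    df <- tibble::tibble(dose_gy = curve$dose_gy * f, volume_pct = curve$volume_pct)
    structure(df, class = class(curve), structure = attr(curve, "structure"),
              voxel_count = attr(curve, "voxel_count"),
              source = attr(curve, "source"), dose_stats = NULL)
  }
  for (ep in c("LRB", "LFI")) {
    r <- vapply(c(0.8, 0.9, 1, 1.1, 1.2),
                function(f) risk(scale_curve(cv, f), ep), numeric(1))
    expect_true(all(diff(r) > 0))
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("simulated cohort toxicity risks fall in the clinically observed band", {
  risks <- vapply(1:8, function(s) {
    pl <- fixture_plan(50 + s, boost = ((s - 1) %% 6) + 1)
    cv <- compute_dvh(pl$dose, pl$anatomy$masks$rectum)
    risk(cv, "LRB")
  }, numeric(1)) * 100
  # band check: overlap the observed 3.3-10.4% grade-2 late rectal bleeding range
  expect_gt(max(risks), 3.3)
  expect_lt(max(risks), 15)
  expect_gt(median(risks), 1)
  expect_lt(median(risks), 11)
})
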