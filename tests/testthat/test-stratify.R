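test_that("constraint tables validate structure and nested leniency", {
  tab <- default_constraint_table()
  expect_s3_class(tab, "constraint_table")
  expect_equal(sort(unique(tab$dose_gy)), c(24.6, 32.4, 40.8, 48.6, 60, 68))
  # the top optimal entry carries the 0.2% (not 0%) tolerance
  expect_equal(tab$max_volume_pct[tab$level == "optimal" & tab$dose_gy == 68], 0.2)

  expect_error(
    constraint_table(tibble::tibble(dose_gy = c(50, 50), max_volume_pct = c(30, 20),
                                    level = c("optimal", "mandatory"))),
    "Nested leniency"
  )
  expect_error(
    constraint_table(tibble::tibble(dose_gy = -1, max_volume_pct = 10,
                                    level = "optimal")),
    "positive"
  )
  expect_error(
    constraint_table(tibble::tibble(dose_gy = 50, max_volume_pct = 120,
                                    level = "optimal")),
    "\\[0, 100\\]"
  )
})

test_that("constraint tables round-trip through YAML", {
  tab <- default_constraint_table()
  path <- tempfile(fileext = ".yaml")
  write_constraint_table(tab, path)
  tab2 <- read_constraint_table(path)
  expect_equal(tab2$dose_gy, tab$dose_gy)
  expect_equal(tab2$max_volume_pct, tab$max_volume_pct)
  expect_equal(tab2$level, tab$level)
})

test_that("constraint checking labels plans with the equality tie-break", {
  zero <- uniform_dvh(0)
  out <- check_constraints(zero, level = "optimal")
  expect_equal(out$label, "low")
  expect_lt(out$margin, 0)

  hot <- uniform_dvh(80)
  expect_equal(check_constraints(hot, level = "optimal")$label, "high")
  expect_equal(check_constraints(hot, level = "mandatory")$label, "high")

  # a DVH exactly at every threshold passes (equality is within tolerance)
  tab <- constraint_table(tibble::tibble(dose_gy = c(30, 50),
                                         max_volume_pct = c(60, 20),
                                         level = "optimal"))
  exact <- structure(
    tibble::tibble(dose_gy = c(0, 30, 50, 70), volume_pct = c(100, 60, 20, 0)),
    class = c("dvh_curve", class(tibble::tibble())),
    structure = "rectum", voxel_count = 100L, source = "planned", dose_stats = NULL
  )
  out_eq <- check_constraints(exact, tab, "optimal")
  expect_equal(out_eq$label, "low")
  expect_equal(out_eq$margin, 0)
  expect_error(check_constraints(exact, tab, "mandatory"), "no entries")
})

test_that("risk stratification includes the threshold itself as high risk", {
  expect_equal(stratify_by_risk(0.064, 0.064)$label, "high")
  expect_equal(stratify_by_risk(0, 0.05)$label, "low")
  expect_equal(stratify_by_risk(0.2, 0.05)$margin, 0.15)
  expect_error(stratify_by_risk(1.2, 0.5), "probabilities")
  # label flips at most once as the threshold rises
  risk_val <- 0.07
  ths <- seq(0, 0.2, by = 0.01)
  labels <- vapply(ths, function(t) stratify_by_risk(risk_val, t)$label, character(1))
  expect_lte(sum(diff(labels == "high") != 0), 1)
})

test_that("confusion metrics reproduce the published worked examples", {
  # all 5 within-tolerance and all 9 exceeding plans correctly identified
  opt <- confusion_metrics(confusion_counts(tp = 9, fp = 0, tn = 5, fn = 0))
  expect_equal(opt$accuracy, 1)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)

  # 9 of 10 within and 2 of 4 exceeding correct
  man <- confusion_metrics(confusion_counts(tp = 2, fp = 1, tn = 9, fn = 2))
  expect_equal(man$accuracy, 11 / 14, tolerance = 1e-9)
  expect_equal(round(100 * man$accuracy, 1), 78.6)
  expect_equal(man$sensitivity, 0.5)
  expect_equal(man$specificity, 0.9)

  all1 <- confusion_metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(unlist(all1[c("sensitivity", "specificity", "accuracy")]),
               c(sensitivity = 0.5, specificity = 0.5, accuracy = 0.5))
})

test_that("undefined metrics are flagged, not silently zeroed", {
  m <- confusion_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(m$sensitivity))
  expect_match(m$undefined, "sensitivity")
  expect_error(confusion_counts(0, 0, 0, 0), "positive total")
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("confusion counts equal brute-force recomputation from labels", {
  set.seed(42)
  for (rep in 1:5) {
    pred <- sample(c("high", "low"), 40, replace = TRUE)
    truth <- sample(c("high", "low"), 40, replace = TRUE)
    cc <- confusion_from_labels(pred, truth)
    # independent enumeration
    expect_equal(cc$tp, sum(pred == "high" & truth == "high"))
    expect_equal(cc$fp, sum(pred == "high" & truth == "low"))
    expect_equal(cc$tn, sum(pred == "low" & truth == "low"))
    expect_equal(cc$fn, sum(pred == "low" & truth == "high"))
    m <- confusion_metrics(cc)
    expect_equal(m$accuracy, mean(pred == truth))
  }
})

test_that("threshold sweeps count agreement correctly", {
  r <- c(0.02, 0.05, 0.08, 0.11)
  sw <- threshold_sweep(r, r, thresholds = c(0.01, 0.06, 0.2))
  expect_equal(sw$agreement, c(1, 1, 1))

  pred <- c(0.03, 0.07, 0.04, 0.10)
  truth <- c(0.05, 0.06, 0.02, 0.12)
  # hand count at threshold 0.05: pred labels L,H,L,H; truth H,H,L,H -> 3/4
  sw2 <- threshold_sweep(pred, truth, thresholds = 0.05)
  expect_equal(sw2$agreement, 0.75)
  # below all risks or above all risks -> full agreement
  expect_equal(threshold_sweep(pred, truth, 0.001)$agreement, 1)
  expect_equal(threshold_sweep(pred, truth, 0.99)$agreement, 1)
  expect_error(threshold_sweep(numeric(0), numeric(0)), "non-empty")
})
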