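test_that("network configuration enforces shape divisibility and names the axis", {
  expect_error(network_config(c(100, 128, 64), levels = 5),
               "dimension X = 100.*not divisible.*16")
  expect_error(network_config(c(128, 128, 60), levels = 5), "dimension Z")
  expect_error(network_config(c(32, 32, 16), levels = 1), "at least 2")
  cfg <- network_config(c(32, 32, 16), levels = 3, growth = 4)
  expect_s3_class(cfg, "network_config")
})

test_that("full-scale configuration bottlenecks at 8 x 8 x 4", {
  cfg <- network_config(c(128L, 128L, 64L), levels = 5L)
  shapes <- network_shapes(cfg)
  expect_length(shapes, 5)
  expect_equal(shapes[[1]], c(128L, 128L, 64L))
  expect_equal(shapes[[5]], c(8L, 8L, 4L))
})

test_that("forward pass honours the shape contract on zero input", {
  cfg <- network_config(c(16, 16, 8), levels = 3, growth = 3)
  model <- build_network(cfg, seed = 4)
  y <- spacerstrat:::hdunet_forward(model, matrix(0, prod(cfg$input_shape), 5))
  expect_length(y, prod(cfg$input_shape))
  expect_true(all(is.finite(y)))
  expect_error(
    spacerstrat:::hdunet_forward(model, matrix(0, 64, 5)),
    "shape mismatch"
  )
})

test_that("parameter count grows with the growth rate", {
  shapes <- c(16, 16, 8)
  counts <- vapply(c(2, 4, 8), function(g) {
    n_params(build_network(network_config(shapes, levels = 3, growth = g), 1))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("analytic gradients match finite differences", {
  cfg <- network_config(c(8, 8, 4), levels = 2, growth = 2, in_channels = 2)
  model <- build_network(cfg, seed = 11)
  set.seed(5)
  X <- matrix(rnorm(prod(cfg$input_shape) * 2), ncol = 2)
  y_t <- rnorm(prod(cfg$input_shape))
  fwd <- spacerstrat:::hdunet_forward(model, X, keep_cache = TRUE)
  gr <- spacerstrat:::hdunet_backward(model, fwd$cache,
                                      2 * (fwd$y - y_t) / length(y_t))
  loss_at <- function(m) mean((spacerstrat:::hdunet_forward(m, X) - y_t)^2)
  eps <- 1e-6
  paths <- list(
    list(\(p) p$down[[1]]$W,     \(p, v) { p$down[[1]]$W <- v; p }),
    list(\(p) p$up[[1]]$W,       \(p, v) { p$up[[1]]$W <- v; p }),
    list(\(p) p$dense_up[[1]]$W, \(p, v) { p$dense_up[[1]]$W <- v; p }),
    list(\(p) p$final$W,         \(p, v) { p$final$W <- v; p }),
    list(\(p) p$down[[2]]$b,     \(p, v) { p$down[[2]]$b <- v; p })
  )
  for (pth in paths) {
    par <- pth[[1]](model$params)
    for (i in sample(length(par), min(4, length(par)))) {
      bump <- function(h) {
        m2 <- model
        p <- pth[[1]](m2$params); p[i] <- p[i] + h
        m2$params <- pth[[2]](m2$params, p)
        loss_at(m2)
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      ana <- pth[[1]](gr)[i]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("training is seeded-deterministic and can overfit two plans", {
  tr <- lapply(c(3, 5), function(s) {
    pl <- fixture_plan(s)
    mi <- crop_to_input(pl$anatomy, pl$dose, c(32L, 32L, 16L))
    list(mi = mi, x = as_input_matrix(mi), dose_crop = mi$dose, plan_id = paste0("p", s))
  })
  nc <- norm_constant_from_cohort(lapply(tr, `[[`, "dose_crop"))
  tr <- lapply(tr, function(s) { s$y <- as.numeric(normalize_dose(s$dose_crop, nc)); s })
  cfg <- network_config(c(32, 32, 16), levels = 2, growth = 4)
  tc <- training_config(learning_rate = 2e-3, epochs = 120, batch_size = 2, seed = 9)

  tm1 <- train_network(build_network(cfg, 9), tr, tc, nc)
  tm2 <- train_network(build_network(cfg, 9), tr, tc, nc)
  expect_identical(tm1$manifest$loss_history, tm2$manifest$loss_history)

  hist <- tm1$manifest$loss_history
  expect_lt(hist[length(hist)], 0.1 * hist[1])

  # self-consistency on an overfitted training plan: rectal Dmean within 2 Gy
  pred <- predict_dose(tm1, tr[[1]]$mi)
  rect <- tr[[1]]$mi$channels$rectum
  expect_lt(abs(mean(pred$dose_gy[rect]) - mean(tr[[1]]$dose_crop[rect])), 2)
})

test_that("prediction output is denormalized, clamped and traceable", {
  cfg <- network_config(c(16, 16, 8), levels = 2, growth = 2)
  model <- build_network(cfg, 3)
  tm <- structure(
    c(model, list(norm_const = normalization_constant(68),
                  manifest = list(epochs = 0, n_plans = 0, final_loss = NA))),
    class = c("trained_model", "hdunet")
  )
  X <- matrix(0, prod(cfg$input_shape), 5)
  dg <- predict_dose(tm, X)
  expect_true(all(dg$dose_gy >= 0))
  expect_equal(dim(dg$dose_gy), cfg$input_shape)
  tm_noconst <- tm; tm_noconst$norm_const <- NULL
  expect_error(predict_dose(tm_noconst, X), "normalization constant")
})

test_that("leave-one-out folds respect patient grouping", {
  expect_equal(loocv_plan(20, 6)$n_train[1], 114)
  expect_equal(nrow(loocv_plan(20, 6)), 20)
  expect_equal(loocv_plan(3, 6)$n_train[1], 12)

  mk_sample <- function(p, b) {
    list(x = matrix(0, 1024, 5), y = numeric(1024),
         plan_id = sprintf("p%03d_%s", p, LETTERS[b]), patient = p, boost = b)
  }
  # missing boost plan -> error listing the plan id
  ds_bad <- list(mk_sample(1, 1), mk_sample(1, 2), mk_sample(2, 1))
  expect_error(
    loocv(ds_bad, network_config(c(16, 16, 4), 2, 2), training_config(epochs = 1)),
    "missing boost plans: p002_B"
  )

  ds <- c(lapply(1:2, function(b) mk_sample(1, b)),
          lapply(1:2, function(b) mk_sample(2, b)),
          lapply(1:2, function(b) mk_sample(3, b)))
  cfg <- network_config(c(16, 16, 4), levels = 2, growth = 2)
  res <- loocv(ds, cfg, training_config(epochs = 1, batch_size = 4, seed = 1),
               normalization_constant(68))
  # union of fold predictions covers every plan exactly once
  expect_setequal(res$predictions$plan_id,
                  vapply(ds, `[[`, character(1), "plan_id"))
  expect_equal(anyDuplicated(res$predictions$plan_id), 0L)
  for (f in res$manifest) {
    held <- f$held_out_patient
    expect_false(any(grepl(sprintf("p%03d", held), f$train_plan_ids)))
    expect_equal(f$n_train, 4)
    expect_equal(f$n_test, 2)
  }
})
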