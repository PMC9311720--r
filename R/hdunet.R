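#' Configuration of the hierarchically dense 3D U-Net
#'
#' A five-level (by default) 3D U-Net with dense concatenative connections:
#' within each resolution level every 3x3x3 convolution's output is
#' concatenated onto the running feature stack, and across levels the
#' expansive path concatenates all same-resolution feature maps from the
#' contracting path. Downsampling is 2x max-pooling, upsampling trilinear
#' interpolation followed by convolution, every convolution is followed by a
#' rectified linear unit, and a final 1x1x1 linear convolution produces the
#' single dose channel. At full scale (128 x 128 x 64 input, 5 levels) the
#' bottleneck feature maps are 8 x 8 x 4.
#'
#' @param input_shape Spatial input shape `(X, Y, Z)`; every dimension must
#'   be divisible by `2^(levels - 1)`.
#' @param levels Number of resolution levels (default 5).
#' @param growth Number of feature maps added by each dense convolution.
#' @param in_channels Number of input channels (5 structure masks).
#' @param kernel Convolution kernel edge length (3).
#' @return A `network_config`.
#' @export
network_config <- function(input_shape = c(128L, 128L, 64L), levels = 5L,
                           growth = 8L, in_channels = 5L, kernel = 3L) {
  input_shape <- as.integer(input_shape)
  levels <- as.integer(levels)
  if (levels < 2) abort("`levels` must be at least 2.")
  div <- 2L^(levels - 1L)
  ax <- c("X", "Y", "Z")
  bad <- which(input_shape %% div != 0L)
  if (length(bad)) {
    abort(sprintf(
      "Input dimension %s = %d is not divisible by 2^(levels-1) = %d.",
      ax[bad[1]], input_shape[bad[1]], div))
  }
  if (growth < 1) abort("`growth` must be a positive integer.")
  structure(
    list(input_shape = input_shape, levels = levels, growth = as.integer(growth),
         in_channels = as.integer(in_channels), kernel = as.integer(kernel)),
    class = "network_config"
  )
}

#' Spatial shapes at every network level
#'
#' @param cfg A [network_config()].
#' @return A list of integer shape vectors, one per level; the last entry is
#'   the bottleneck shape.
#' @export
network_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  lapply(seq_len(cfg$levels), function(l) cfg$input_shape %/% (2L^(l - 1L)))
}

# Feature-stack channel bookkeeping for the dense topology.
channel_plan <- function(cfg) {
  L <- cfg$levels; g <- cfg$growth
  stack_ch <- integer(L); keep_ch <- integer(L)
  stack_ch[1] <- cfg$in_channels
  for (l in seq_len(L)) {
    keep_ch[l] <- stack_ch[l] + g
    if (l < L) stack_ch[l + 1] <- keep_ch[l]
  }
  up_in <- integer(L - 1); merged <- integer(L - 1); out_ch <- integer(L - 1)
  u <- keep_ch[L]
  for (l in rev(seq_len(L - 1))) {
    up_in[l] <- u
    merged[l] <- keep_ch[l] + g
    out_ch[l] <- merged[l] + g
    u <- out_ch[l]
  }
  list(stack = stack_ch, keep = keep_ch, up_in = up_in, merged = merged,
       final_in = if (L > 1) out_ch[1] else keep_ch[1])
}

he_init <- function(n_out, n_in_cols) {
  matrix(rnorm(n_out * n_in_cols, sd = sqrt(2 / n_in_cols)), nrow = n_out)
}

#' Build an untrained network
#'
#' Allocates and He-initialises all convolution weights for the dense
#' topology described by the configuration.
#'
#' @param cfg A [network_config()].
#' @param seed Seed for the weight initialisation.
#' @return An `hdunet` object holding the configuration and parameter list.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- channel_plan(cfg)
  k3 <- cfg$kernel^3
  g <- cfg$growth
  L <- cfg$levels
  with_seed(seed, {
    params <- list(
      down = lapply(seq_len(L), function(l) {
        list(W = he_init(g, k3 * ch$stack[l]), b = numeric(g))
      }),
      up = lapply(seq_len(L - 1), function(l) {
        list(W = he_init(g, k3 * ch$up_in[l]), b = numeric(g))
      }),
      dense_up = lapply(seq_len(L - 1), function(l) {
        list(W = he_init(g, k3 * ch$merged[l]), b = numeric(g))
      }),
      final = list(W = he_init(1, ch$final_in), b = numeric(1))
    )
    structure(list(cfg = cfg, params = params, channels = ch), class = "hdunet")
  })
}

#' Number of trainable parameters
#' @param model An `hdunet` or `trained_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  p <- unlist(model$params, recursive = TRUE, use.names = FALSE)
  length(p)
}

relu <- function(z) (z > 0) * z

# Forward pass. X: (Nvox x in_channels) matrix at the configured input shape.
# Returns list(y = Nvox vector, cache) for training, or just y.
hdunet_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  L <- cfg$levels
  shapes <- network_shapes(cfg)
  if (nrow(X) != prod(cfg$input_shape) || ncol(X) != cfg$in_channels) {
    abort(sprintf("Input shape mismatch: expected %d voxels x %d channels, got %d x %d.",
                  prod(cfg$input_shape), cfg$in_channels, nrow(X), ncol(X)))
  }
  keep <- vector("list", L)
  cache <- if (keep_cache) {
    list(A = vector("list", L), zmask_down = vector("list", L),
         pool_idx = vector("list", L - 1),
         Uu = vector("list", L - 1), zmask_up = vector("list", L - 1),
         M = vector("list", L - 1), zmask_dense = vector("list", L - 1),
         U_final = NULL)
  } else NULL
  A <- X
  for (l in seq_len(L)) {
    Z <- .conv3d_fwd(A, shapes[[l]], p$down[[l]]$W, p$down[[l]]$b, cfg$kernel)
    Fz <- relu(Z)
    if (keep_cache) { cache$A[[l]] <- A; cache$zmask_down[[l]] <- Z > 0 }
    keep[[l]] <- cbind(A, Fz)
    if (l < L) {
      pl <- .maxpool3d_fwd(keep[[l]], shapes[[l]])
      A <- pl$Y
      if (keep_cache) cache$pool_idx[[l]] <- pl$idx
    }
  }
  U <- keep[[L]]
  for (l in rev(seq_len(L - 1))) {
    Uu <- .upsample3d_fwd(U, shapes[[l + 1]])
    Z2 <- .conv3d_fwd(Uu, shapes[[l]], p$up[[l]]$W, p$up[[l]]$b, cfg$kernel)
    G <- relu(Z2)
    M <- cbind(keep[[l]], G)
    Z3 <- .conv3d_fwd(M, shapes[[l]], p$dense_up[[l]]$W, p$dense_up[[l]]$b, cfg$kernel)
    H <- relu(Z3)
    if (keep_cache) {
      cache$Uu[[l]] <- Uu; cache$zmask_up[[l]] <- Z2 > 0
      cache$M[[l]] <- M; cache$zmask_dense[[l]] <- Z3 > 0
    }
    U <- cbind(M, H)
  }
  Y <- .conv3d_fwd(U, shapes[[1]], p$final$W, p$final$b, 1L)
  if (keep_cache) {
    cache$U_final <- U
    list(y = as.numeric(Y), cache = cache)
  } else {
    as.numeric(Y)
  }
}

# Backward pass: gradients of a scalar loss with dL/dy = dy (Nvox vector).
# Returns a gradient list shaped like model$params.
hdunet_backward <- function(model, cache, dy) {
  cfg <- model$cfg; p <- model$params
  L <- cfg$levels; g <- cfg$growth
  shapes <- network_shapes(cfg)
  ch <- model$channels
  grads <- list(down = vector("list", L), up = vector("list", L - 1),
                dense_up = vector("list", L - 1), final = NULL)

  bw <- .conv3d_bwd(cache$U_final, shapes[[1]], p$final$W, matrix(dy, ncol = 1), 1L)
  grads$final <- list(W = bw$dW, b = as.numeric(bw$db))
  dU <- bw$dX
  dkeep <- vector("list", L)
  for (l in seq_len(L - 1)) {
    nm <- ch$merged[l]
    dM <- dU[, seq_len(nm), drop = FALSE]
    dH <- dU[, nm + seq_len(g), drop = FALSE]
    dZ3 <- dH * cache$zmask_dense[[l]]
    bw3 <- .conv3d_bwd(cache$M[[l]], shapes[[l]], p$dense_up[[l]]$W, dZ3, cfg$kernel)
    grads$dense_up[[l]] <- list(W = bw3$dW, b = as.numeric(bw3$db))
    dM <- dM + bw3$dX
    nk <- ch$keep[l]
    dkeep[[l]] <- dM[, seq_len(nk), drop = FALSE]
    dG <- dM[, nk + seq_len(g), drop = FALSE]
    dZ2 <- dG * cache$zmask_up[[l]]
    bw2 <- .conv3d_bwd(cache$Uu[[l]], shapes[[l]], p$up[[l]]$W, dZ2, cfg$kernel)
    grads$up[[l]] <- list(W = bw2$dW, b = as.numeric(bw2$db))
    dU <- .upsample3d_bwd(bw2$dX, shapes[[l + 1]])
  }
  dkeep[[L]] <- dU
  for (l in rev(seq_len(L))) {
    dK <- dkeep[[l]]
    ns <- ch$stack[l]
    dA <- dK[, seq_len(ns), drop = FALSE]
    dF <- dK[, ns + seq_len(g), drop = FALSE]
    dZ <- dF * cache$zmask_down[[l]]
    bw1 <- .conv3d_bwd(cache$A[[l]], shapes[[l]], p$down[[l]]$W, dZ, cfg$kernel)
    grads$down[[l]] <- list(W = bw1$dW, b = as.numeric(bw1$db))
    dA <- dA + bw1$dX
    if (l > 1) {
      dkeep[[l - 1]] <- dkeep[[l - 1]] +
        .maxpool3d_bwd(dA, cache$pool_idx[[l - 1]], prod(shapes[[l - 1]]))
    }
  }
  grads
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Number of full passes over the training set.
#' @param batch_size Mini-batch size.
#' @param seed Seed for weight initialisation and shuffling.
#' @return A `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 200L,
                            batch_size = 2L, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (epochs < 1) abort("`epochs` must be at least 1.")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_config")
}

# elementwise param-tree arithmetic
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}
tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else f(a)
}

#' Train the dose-prediction network
#'
#' Minimises voxelwise mean squared error between the network output and the
#' normalized planned dose with the Adam optimizer. Deterministic for a
#' fixed `training_config` seed (single-threaded).
#'
#' @param model An [build_network()] result.
#' @param dataset A list of training samples, each
#'   `list(x = <Nvox x 5 matrix>, y = <Nvox normalized dose vector>,
#'   plan_id = <string>)` (see [as_input_matrix()]).
#' @param tc A [training_config()].
#' @param norm_const The [normalization_constant()] used to normalize `y`;
#'   stored with the model for prediction-time rescaling.
#' @param verbose Print the loss every few epochs.
#' @return A `trained_model`: parameters, config, normalization constant and
#'   a training manifest (plan ids, seed, epochs, loss history).
#' @export
train_network <- function(model, dataset, tc = training_config(),
                          norm_const = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hdunet"), inherits(tc, "training_config"))
  if (!length(dataset)) abort("Training dataset is empty.")
  nvox <- prod(model$cfg$input_shape)
  for (s in dataset) {
    if (nrow(s$x) != nvox || length(s$y) != nvox) {
      abort("All training tensors must share the configured input shape.")
    }
  }
  params <- model$params
  m_state <- tree_map(params, function(x) x * 0)
  v_state <- tree_map(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n <- length(dataset)
  loss_history <- numeric(tc$epochs)
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1, n, by = tc$batch_size)) {
        idx <- ord[b0:min(n, b0 + tc$batch_size - 1L)]
        gsum <- NULL
        bloss <- 0
        for (i in idx) {
          model$params <- params
          fw <- hdunet_forward(model, dataset[[i]]$x, keep_cache = TRUE)
          resid <- fw$y - dataset[[i]]$y
          bloss <- bloss + mean(resid^2)
          gr <- hdunet_backward(model, fw$cache, 2 * resid / length(resid))
          gsum <- if (is.null(gsum)) gr else tree_map2(gsum, gr, `+`)
        }
        bloss <- bloss / length(idx)
        if (!is.finite(bloss)) {
          abort(sprintf("Non-finite loss at epoch %d, batch starting %d; aborting.",
                        epoch, b0))
        }
        ep_loss <- ep_loss + bloss * length(idx)
        g <- tree_map(gsum, function(x) x / length(idx))
        t_step <- t_step + 1L
        m_state <- tree_map2(m_state, g, function(m, gg) beta1 * m + (1 - beta1) * gg)
        v_state <- tree_map2(v_state, g, function(v, gg) beta2 * v + (1 - beta2) * gg^2)
        corr <- tc$learning_rate * sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
        upd <- tree_map2(m_state, v_state, function(m, v) corr * m / (sqrt(v) + eps))
        params <- tree_map2(params, upd, `-`)
      }
      loss_history[epoch] <- ep_loss / n
      if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
        message(sprintf("epoch %3d  mse %.6f", epoch, loss_history[epoch]))
      }
    }
  })
  model$params <- params
  structure(
    list(
      cfg = model$cfg, params = params, channels = model$channels,
      norm_const = norm_const,
      manifest = list(
        plan_ids = vapply(dataset, function(s) s$plan_id %||% "", character(1)),
        n_plans = n, seed = tc$seed, epochs = tc$epochs,
        learning_rate = tc$learning_rate, batch_size = tc$batch_size,
        final_loss = loss_history[tc$epochs], loss_history = loss_history
      )
    ),
    class = c("trained_model", "hdunet")
  )
}

#' Flatten a model input to the network's matrix form
#'
#' @param input A `model_input` from [crop_to_input()].
#' @return A `(Nvox x 5)` numeric matrix of the binary structure channels in
#'   the fixed order ptv68, ptv60, ptv53, rectum, bladder.
#' @export
as_input_matrix <- function(input) {
  stopifnot(inherits(input, "model_input"))
  do.call(cbind, lapply(input$channels, function(m) as.numeric(m)))
}

#' Predict a dose distribution
#'
#' Runs the network forward, rescales the output by the stored training-set
#' normalization constant and clamps negative values to zero.
#'
#' @param model A `trained_model` (must carry a normalization constant).
#' @param input A `model_input` from [crop_to_input()] (or a raw
#'   `(Nvox x 5)` matrix).
#' @return A [dose_grid()] on the crop grid, with attributes `crop_offset`,
#'   `source_dim` and `runtime_s`.
#' @export
predict_dose <- function(model, input) {
  stopifnot(inherits(model, "hdunet"))
  if (inherits(model, "trained_model") && is.null(model$norm_const)) {
    abort("Model has no stored normalization constant; cannot rescale predictions.")
  }
  X <- if (inherits(input, "model_input")) as_input_matrix(input) else input
  t0 <- proc.time()[["elapsed"]]
  y <- hdunet_forward(model, X)
  dt <- proc.time()[["elapsed"]] - t0
  const <- if (inherits(model, "trained_model")) model$norm_const else NULL
  if (!is.null(const)) y <- denormalize_dose(y, const)
  y <- pmax(y, 0)
  arr <- array(y, dim = model$cfg$input_shape)
  sp <- if (inherits(input, "model_input")) input$spacing_mm else c(1, 1, 1)
  dg <- dose_grid(arr, sp)
  attr(dg, "runtime_s") <- dt
  if (inherits(input, "model_input")) {
    attr(dg, "crop_offset") <- input$crop_offset
    attr(dg, "source_dim") <- input$source_dim
  }
  dg
}

#' Leave-one-patient-out cross-validation
#'
#' Splits the plan dataset by patient (all boost plans of the held-out
#' patient are excluded from that fold's training set), trains one model per
#' fold and predicts the held-out plans. Patient-level fold integrity is
#' asserted on every split.
#'
#' @param dataset A list of samples `list(x, y, plan_id, patient, boost)`.
#' @param cfg A [network_config()].
#' @param tc A [training_config()].
#' @param norm_const A [normalization_constant()].
#' @param verbose Print per-fold progress.
#' @return A list with `predictions` (tibble: `patient`, `boost`, `plan_id`,
#'   `y_pred` list-column of normalized dose vectors rescaled to Gy) and
#'   `manifest` (per-fold plan ids).
#' @export
loocv <- function(dataset, cfg, tc = training_config(), norm_const = NULL,
                  verbose = FALSE) {
  patients <- vapply(dataset, function(s) s$patient, numeric(1))
  boosts <- vapply(dataset, function(s) s$boost, numeric(1))
  ids <- vapply(dataset, function(s) s$plan_id %||% "", character(1))
  up <- sort(unique(patients))
  if (length(up) < 2) abort("Cross-validation needs at least 2 patients.")
  expected <- sort(unique(boosts))
  for (p in up) {
    have <- sort(boosts[patients == p])
    if (!identical(have, expected)) {
      missing <- setdiff(expected, have)
      abort(sprintf("Patient %g is missing boost plans: %s.",
                    p, paste(sprintf("p%03d_%s", p, LETTERS[missing]), collapse = ", ")))
    }
  }
  preds <- list()
  manifest <- list()
  for (f in seq_along(up)) {
    hold <- up[f]
    tr_idx <- which(patients != hold)
    te_idx <- which(patients == hold)
    stopifnot(length(intersect(tr_idx, te_idx)) == 0)
    if (any(patients[tr_idx] == hold)) abort("Fold leakage detected.")  # nocov
    model <- build_network(cfg, seed = tc$seed + f)
    tm <- train_network(model, dataset[tr_idx], tc, norm_const)
    fold_pred <- lapply(te_idx, function(i) {
      y <- hdunet_forward(tm, dataset[[i]]$x)
      if (!is.null(norm_const)) y <- pmax(denormalize_dose(y, norm_const), 0)
      tibble(patient = patients[i], boost = boosts[i], plan_id = ids[i],
             y_pred = list(y))
    })
    preds <- c(preds, fold_pred)
    manifest[[f]] <- list(fold = f, held_out_patient = hold,
                          n_train = length(tr_idx), n_test = length(te_idx),
                          train_plan_ids = ids[tr_idx], test_plan_ids = ids[te_idx])
    if (verbose) message(sprintf("fold %d/%d done (patient %g held out)", f, length(up), hold))
  }
  list(predictions = bind_rows(preds), manifest = manifest)
}

#' Fold arithmetic for the leave-one-out harness
#'
#' The training/held-out split sizes without running any training: with `p`
#' patients and `b` plans each, every fold trains on `(p - 1) * b` plans.
#'
#' @param n_patients,n_boosts Cohort shape.
#' @return A tibble `fold`, `n_train`, `n_test`.
#' @export
loocv_plan <- function(n_patients, n_boosts = 6L) {
  tibble(fold = seq_len(n_patients),
         n_train = (n_patients - 1L) * n_boosts,
         n_test = n_boosts)
}

#' @export
print.hdunet <- function(x, ...) {
  cat(sprintf("<%s> %d-level HD U-Net, growth %d, input %s, %d parameters\n",
              if (inherits(x, "trained_model")) "trained_model" else "hdunet",
              x$cfg$levels, x$cfg$growth,
              paste(x$cfg$input_shape, collapse = "x"), n_params(x)))
  if (inherits(x, "trained_model")) {
    cat(sprintf("  trained %d epochs on %d plans, final mse %.6f\n",
                x$manifest$epochs, x$manifest$n_plans, x$manifest$final_loss))
  }
  invisible(x)
}

#' Broom-style summaries of a trained model
#'
#' `tidy()` returns the per-epoch loss history; `glance()` a one-row summary.
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trained_model <- function(x, ...) {
  tibble(epoch = seq_along(x$manifest$loss_history),
         mse = x$manifest$loss_history)
}

#' @rdname tidy.trained_model
#' @export
glance.trained_model <- function(x, ...) {
  tibble(levels = x$cfg$levels, growth = x$cfg$growth,
         n_parameters = n_params(x), n_plans = x$manifest$n_plans,
         epochs = x$manifest$epochs, final_mse = x$manifest$final_loss,
         max_dose_gy = x$norm_const$max_dose_gy %||% NA_real_)
}
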