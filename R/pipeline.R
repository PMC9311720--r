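#' Configuration for an end-to-end pipeline run
#'
#' Bundles every knob of the simulate -> preprocess -> train -> predict ->
#' evaluate -> stratify workflow, with a single base seed from which every
#' stochastic stage derives its own. The defaults are the desk-scale
#' replication experiment: 20 training phantoms with six boost plans each, a
#' 14-phantom held-out test cohort with one plan each, a 32 x 32 x 16 crop
#' and a three-level network.
#'
#' @param seed Base seed; all stage seeds derive from it.
#' @param n_train,n_test Number of training / held-out phantoms.
#' @param shape Network crop shape.
#' @param levels,growth Network topology (see [network_config()]).
#' @param epochs,learning_rate,batch_size Training schedule (see
#'   [training_config()]).
#' @param spec_args Extra arguments for [phantom_spec()].
#' @param fx A [fractionation_scheme()].
#' @param constraints A [constraint_table()].
#' @param dsc_levels Isodose levels (Gy) for the Dice profile.
#' @param risk_thresholds Thresholds for the risk-agreement sweep.
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L, n_train = 20L, n_test = 14L,
                       shape = c(32L, 32L, 16L), levels = 3L, growth = 4L,
                       epochs = 25L, learning_rate = 1e-3, batch_size = 6L,
                       spec_args = list(), fx = fractionation_scheme(),
                       constraints = default_constraint_table(),
                       dsc_levels = default_dsc_levels(),
                       risk_thresholds = seq(0.01, 0.08, by = 0.005)) {
  structure(
    list(seed = as.integer(seed), n_train = as.integer(n_train),
         n_test = as.integer(n_test), shape = as.integer(shape),
         levels = as.integer(levels), growth = as.integer(growth),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), spec_args = spec_args,
         fx = fx, constraints = constraints, dsc_levels = dsc_levels,
         risk_thresholds = risk_thresholds),
    class = "run_config"
  )
}

pipeline_stages <- function() {
  c("simulate", "preprocess", "train", "predict", "evaluate", "stratify")
}

#' Prepare network training/prediction samples from a simulated cohort
#'
#' Crops each plan to the network volume, flattens the mask channels, and
#' (for training) normalizes the planned dose by the cohort maximum.
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param shape Crop shape.
#' @param norm_const A [normalization_constant()], or `NULL` to compute it
#'   from this cohort's planned doses.
#' @return A list `samples` (each with `x`, `y`, `mi`, `dose_crop`,
#'   `patient`, `boost`, `plan_id`) and `norm_const`.
#' @export
prepare_dataset <- function(cohort, shape = c(32L, 32L, 16L), norm_const = NULL) {
  samples <- lapply(seq_len(nrow(cohort)), function(i) {
    mi <- crop_to_input(cohort$anatomy[[i]], cohort$dose[[i]], shape)
    list(mi = mi, x = as_input_matrix(mi), dose_crop = mi$dose,
         patient = cohort$patient[i], boost = cohort$boost[i],
         plan_id = cohort$plan_id[i])
  })
  if (is.null(norm_const)) {
    norm_const <- norm_constant_from_cohort(lapply(samples, `[[`, "dose_crop"))
  }
  samples <- lapply(samples, function(s) {
    s$y <- as.numeric(normalize_dose(s$dose_crop, norm_const))
    s
  })
  list(samples = samples, norm_const = norm_const)
}

require_stage <- function(state, key, stage_needed) {
  if (is.null(state[[key]])) {
    abort(paste0("Missing artifact '", key, "': run stage '", stage_needed,
                 "' first."))
  }
  invisible(TRUE)
}

#' Run the stratification pipeline
#'
#' Orchestrates the full workflow on synthetic cohorts. Each stage reads its
#' inputs from the run state (persisted under `out`), writes text reports,
#' and records itself in `manifest.json`. Re-running with the same
#' configuration and seed reproduces every artifact byte for byte.
#'
#' Stages: `simulate` (phantoms + planned dose + ground-truth labels),
#' `preprocess` (crop, normalize), `train`, `predict`, `evaluate`
#' (DVH error profile, Dice profile, Bland-Altman risk agreement),
#' `stratify` (four stratification methods, confusion metrics, threshold
#' sweep).
#'
#' @param cfg A [run_config()].
#' @param out Output directory for state, reports and the manifest.
#' @param stages Subset of stages to run (in pipeline order).
#' @param verbose Print progress.
#' @return The run state (invisibly), a list with all intermediate objects
#'   and report tibbles.
#' @export
run_pipeline <- function(cfg = run_config(), out = tempfile("spacerstrat_run_"),
                         stages = pipeline_stages(), verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(package_version = as.character(utils::packageVersion("spacerstrat")),
         seed = cfg$seed, config = config_echo(cfg), stages_run = list())
  }
  say <- function(...) if (verbose) message(sprintf(...))

  for (stage in pipeline_stages()[pipeline_stages() %in% stages]) {
    t0 <- proc.time()[["elapsed"]]
    state <- switch(stage,
      simulate = stage_simulate(state, cfg, out, say),
      preprocess = stage_preprocess(state, cfg, say),
      train = stage_train(state, cfg, say),
      predict = stage_predict(state, cfg, say),
      evaluate = stage_evaluate(state, cfg, out, say),
      stratify = stage_stratify(state, cfg, out, say)
    )
    manifest$stages_run[[stage]] <- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }
  saveRDS(state, state_path)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(state)
}

config_echo <- function(cfg) {
  list(n_train = cfg$n_train, n_test = cfg$n_test, shape = cfg$shape,
       levels = cfg$levels, growth = cfg$growth, epochs = cfg$epochs,
       learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
       n_fractions = cfg$fx$n_fractions, alpha_beta_gy = cfg$fx$alpha_beta_gy,
       constraint_source = attr(cfg$constraints, "source"))
}

stage_simulate <- function(state, cfg, out, say) {
  say("simulate: %d training phantoms x 6 boosts + %d test phantoms",
      cfg$n_train, cfg$n_test)
  base <- (cfg$seed * 1000L) %% 2147483647L
  state$train_cohort <- simulate_cohort(cfg$n_train, seed = base,
                                        spec_args = cfg$spec_args, labels = FALSE)
  state$test_cohort <- simulate_cohort(cfg$n_test, seed = base + 500L,
                                       spec_args = cfg$spec_args,
                                       boosts = "rotate", labels = TRUE)
  state
}

stage_preprocess <- function(state, cfg, say) {
  require_stage(state, "train_cohort", "simulate")
  say("preprocess: cropping to %s and normalizing", paste(cfg$shape, collapse = "x"))
  tr <- prepare_dataset(state$train_cohort, cfg$shape)
  te <- prepare_dataset(state$test_cohort, cfg$shape, norm_const = tr$norm_const)
  state$train_samples <- tr$samples
  state$test_samples <- te$samples
  state$norm_const <- tr$norm_const
  state
}

stage_train <- function(state, cfg, say) {
  require_stage(state, "train_samples", "preprocess")
  say("train: %d plans, %d epochs", length(state$train_samples), cfg$epochs)
  net_cfg <- network_config(cfg$shape, levels = cfg$levels, growth = cfg$growth)
  model <- build_network(net_cfg, seed = cfg$seed)
  tc <- training_config(learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                        batch_size = cfg$batch_size, seed = cfg$seed)
  state$model <- train_network(model, state$train_samples, tc, state$norm_const)
  state
}

stage_predict <- function(state, cfg, say) {
  require_stage(state, "model", "train")
  require_stage(state, "test_samples", "preprocess")
  say("predict: %d held-out plans", length(state$test_samples))
  state$predictions <- lapply(state$test_samples, function(s) {
    pred <- predict_dose(state$model, s$mi)
    truth <- dose_grid(s$dose_crop, s$mi$spacing_mm)
    rect <- s$mi$channels$rectum
    list(plan_id = s$plan_id, patient = s$patient, boost = s$boost,
         pred = pred, truth = truth,
         dvh_pred = compute_dvh(pred, rect, source = "predicted"),
         dvh_truth = compute_dvh(truth, rect, source = "planned"))
  })
  state
}

stage_evaluate <- function(state, cfg, out, say) {
  require_stage(state, "predictions", "predict")
  say("evaluate: DVH errors, Dice profile, Bland-Altman risk agreement")
  preds <- state$predictions
  dvh_p <- lapply(preds, `[[`, "dvh_pred")
  dvh_t <- lapply(preds, `[[`, "dvh_truth")
  err <- dvh_error_profile(dvh_p, dvh_t)

  dsc <- bind_rows(lapply(preds, function(p) {
    mutate(dsc_profile(p$pred, p$truth, cfg$dsc_levels), plan_id = p$plan_id)
  }))

  risks <- bind_rows(lapply(preds, function(p) {
    tibble(plan_id = p$plan_id,
           lrb_pred = risk(p$dvh_pred, "LRB", cfg$fx),
           lrb_truth = risk(p$dvh_truth, "LRB", cfg$fx),
           lfi_pred = risk(p$dvh_pred, "LFI", cfg$fx),
           lfi_truth = risk(p$dvh_truth, "LFI", cfg$fx))
  }))
  ba_lrb <- bland_altman(100 * risks$lrb_pred, 100 * risks$lrb_truth)
  ba_lfi <- bland_altman(100 * risks$lfi_pred, 100 * risks$lfi_truth)

  # rectal Dmean accuracy vs a predict-the-cohort-mean-dose baseline
  base <- Reduce(`+`, lapply(state$train_samples, `[[`, "dose_crop")) /
    length(state$train_samples)
  dmean <- bind_rows(lapply(seq_along(preds), function(i) {
    rect <- state$test_samples[[i]]$mi$channels$rectum
    tibble(plan_id = preds[[i]]$plan_id,
           dmean_truth = mean(preds[[i]]$truth$dose_gy[rect]),
           dmean_pred = mean(preds[[i]]$pred$dose_gy[rect]),
           dmean_baseline = mean(base[rect]))
  }))

  state$evaluation <- list(dvh_errors = err, dsc = dsc, risks = risks,
                           bland_altman = list(lrb = ba_lrb, lfi = ba_lfi),
                           dmean = dmean)
  utils::write.csv(as.data.frame(err), file.path(out, "dvh_errors.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dsc), file.path(out, "dsc_profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(dsc_mean = mean(dsc$dsc[dsc$included], na.rm = TRUE),
         lrb = as.list(glance(ba_lrb)), lfi = as.list(glance(ba_lfi)),
         dmean_mae_gy = mean(abs(dmean$dmean_pred - dmean$dmean_truth)),
         dmean_baseline_mae_gy = mean(abs(dmean$dmean_baseline - dmean$dmean_truth))),
    file.path(out, "evaluation_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  state
}

stage_stratify <- function(state, cfg, out, say) {
  require_stage(state, "predictions", "predict")
  require_stage(state, "evaluation", "evaluate")
  say("stratify: four methods, confusion metrics, threshold sweep")
  preds <- state$predictions
  risks <- state$evaluation$risks
  med_lrb <- median(risks$lrb_truth)
  med_lfi <- median(risks$lfi_truth)

  rows <- bind_rows(lapply(seq_along(preds), function(i) {
    p <- preds[[i]]
    r <- risks[risks$plan_id == p$plan_id, ]
    per_method <- function(method, pred_out, truth_out) {
      tibble(plan_id = p$plan_id, method = method,
             label_pred = pred_out$label, label_truth = truth_out$label,
             margin_pred = pred_out$margin, margin_truth = truth_out$margin,
             binding = pred_out$binding)
    }
    bind_rows(
      per_method("optimal_dvh",
                 check_constraints(p$dvh_pred, cfg$constraints, "optimal"),
                 check_constraints(p$dvh_truth, cfg$constraints, "optimal")),
      per_method("mandatory_dvh",
                 check_constraints(p$dvh_pred, cfg$constraints, "mandatory"),
                 check_constraints(p$dvh_truth, cfg$constraints, "mandatory")),
      per_method("lrb_risk",
                 stratify_by_risk(r$lrb_pred, med_lrb, "lrb_risk"),
                 stratify_by_risk(r$lrb_truth, med_lrb, "lrb_risk")),
      per_method("lfi_risk",
                 stratify_by_risk(r$lfi_pred, med_lfi, "lfi_risk"),
                 stratify_by_risk(r$lfi_truth, med_lfi, "lfi_risk"))
    )
  }))

  conf <- rows |>
    group_by(.data$method) |>
    summarise(confusion_metrics(confusion_from_labels(.data$label_pred,
                                                      .data$label_truth)),
              .groups = "drop")

  sweep_lrb <- threshold_sweep(risks$lrb_pred, risks$lrb_truth, cfg$risk_thresholds)
  sweep_lfi <- threshold_sweep(risks$lfi_pred, risks$lfi_truth, cfg$risk_thresholds)

  state$stratification <- list(report = rows, confusion = conf,
                               sweep = list(lrb = sweep_lrb, lfi = sweep_lfi),
                               median_risk = c(lrb = med_lrb, lfi = med_lfi))
  fmt <- rows |>
    mutate(across(c("margin_pred", "margin_truth"), ~ sprintf("%.6f", .x)))
  utils::write.csv(as.data.frame(fmt), file.path(out, "stratification.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(confusion = conf,
         median_truth_risk = as.list(state$stratification$median_risk),
         agreement_at_median_lrb = sweep_agreement_at(sweep_lrb, med_lrb),
         agreement_at_median_lfi = sweep_agreement_at(sweep_lfi, med_lfi)),
    file.path(out, "stratification_summary.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  state
}

sweep_agreement_at <- function(sweep, threshold) {
  i <- which.min(abs(sweep$threshold - threshold))
  sweep$agreement[i]
}

#' Desk-scale replication experiment
#'
#' One call that runs the whole pipeline at desk scale with the default
#' [run_config()] and returns the state: the trained model, evaluation
#' summaries and stratification report.
#'
#' @param seed Base seed.
#' @param out Output directory.
#' @param ... Overrides passed to [run_config()].
#' @return The pipeline state (invisibly returned by [run_pipeline()]).
#' @export
replicate_small <- function(seed = 1L, out = tempfile("spacerstrat_run_"), ...) {
  run_pipeline(run_config(seed = seed, ...), out = out)
}
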