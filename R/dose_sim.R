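#' Analytic dose fall-off configuration
#'
#' Parameters of the analytic plan-dose surrogate: each prescription target
#' contributes its plateau inside the target and a sigmoidal fall-off with
#' distance outside it; a rectum-proximity attenuation term reproduces the
#' concave, rectum-sparing isodoses of optimised plans.
#'
#' @param falloff_half_mm Distance (mm) at which the fall-off reaches half of
#'   the plateau.
#' @param steepness_mm Sigmoid steepness scale (mm); must be strictly positive.
#' @param sparing_weight Maximum fractional dose reduction near the rectum,
#'   in `[0, 1)`. `NULL` uses the phantom's own planning-style value.
#' @param sparing_range_mm Exponential range (mm) of the rectal sparing term.
#' @param noise_sd_gy Standard deviation (Gy) of the smooth plan-variability
#'   noise field added to the dose.
#' @param z_compression Anisotropy of the fall-off metric: distances along
#'   the cranio-caudal axis count this many times more than in-plane
#'   distances, reproducing the sharper beam-edge fall-off of arc plans
#'   compared with in-plane scatter.
#' @return A `falloff_config` list.
#' @export
falloff_config <- function(falloff_half_mm = 11,
                           steepness_mm = 4,
                           sparing_weight = NULL,
                           sparing_range_mm = 8,
                           noise_sd_gy = 0.1,
                           z_compression = 1.6) {
  if (!is.numeric(steepness_mm) || steepness_mm <= 0) {
    abort("`steepness_mm` must be strictly positive: a zero-steepness fall-off is degenerate.")
  }
  if (falloff_half_mm <= 0) abort("`falloff_half_mm` must be positive.")
  if (!is.null(sparing_weight) &&
      (sparing_weight < 0 || sparing_weight >= 1)) {
    abort("`sparing_weight` must lie in [0, 1).")
  }
  if (sparing_range_mm <= 0) abort("`sparing_range_mm` must be positive.")
  if (noise_sd_gy < 0) abort("`noise_sd_gy` must be non-negative.")
  if (z_compression <= 0) abort("`z_compression` must be positive.")
  structure(
    list(falloff_half_mm = falloff_half_mm, steepness_mm = steepness_mm,
         sparing_weight = sparing_weight, sparing_range_mm = sparing_range_mm,
         noise_sd_gy = noise_sd_gy, z_compression = z_compression),
    class = "falloff_config"
  )
}

# Prescription plateaus. The 60/53 Gy plateaus sit 1 Gy above prescription so
# that the coverage objectives (>= 95% of PTV60 at 60 Gy, >= 95% of PTV53 at
# 53 Gy) hold with margin under the plan-variability noise; the boost plateau
# is exactly 68 Gy so the PTV68 median lands at 68 +/- noise.
plan_prescriptions <- function() {
  list(ptv68 = 68, ptv60 = 61, ptv53 = 54)
}

#' Simulate the planned dose for one boost variant
#'
#' Analytic surrogate for an optimised three-dose-level plan: prescription
#' plateaus of 68/60/53 Gy over PTV68/PTV60/PTV53 with sigmoidal
#' distance-driven fall-off, attenuated near the rectum so isodoses bow
#' concavely around it, plus a smooth seeded noise field emulating
#' plan-to-plan variability. Every emitted plan is checked against the
#' coverage objectives (>= 95% of PTV60 at 60 Gy, >= 95% of PTV53 at 53 Gy,
#' PTV68 median within 68 +/- 0.3 Gy) by direct voxel count.
#'
#' @param phantom A [generate_phantom()] result (or a `structure_set`).
#' @param boost_index Boost variant 1-6; ignored when `phantom` is already a
#'   `structure_set`.
#' @param falloff_cfg A [falloff_config()].
#' @param seed Noise seed; defaults to a value derived from the phantom spec
#'   seed and the boost index so plans are reproducible.
#' @return A [dose_grid()] on the phantom grid.
#' @export
simulate_plan_dose <- function(phantom, boost_index = 1L,
                               falloff_cfg = falloff_config(),
                               seed = NULL) {
  if (inherits(phantom, "structure_set")) {
    ss <- phantom
    sparing_default <- 0.32
    if (is.null(seed)) seed <- 7L
  } else {
    stopifnot(inherits(phantom, "phantom"))
    ss <- structure_set(phantom, boost_index)
    sparing_default <- phantom$planning$sparing_weight
    if (is.null(seed)) seed <- (phantom$spec$seed * 101L + as.integer(boost_index)) %% 2147483647L
  }
  stopifnot(inherits(falloff_cfg, "falloff_config"))
  w <- falloff_cfg$sparing_weight %||% sparing_default

  sp <- ss$spacing_mm
  dims <- dim(ss$masks$rectum)
  rx <- plan_prescriptions()

  d_rect <- distance_to_mask(ss$masks$rectum, sp)
  g <- 1 - w * exp(-d_rect / falloff_cfg$sparing_range_mm)

  f0 <- plogis(falloff_cfg$falloff_half_mm / falloff_cfg$steepness_mm)
  falloff <- function(d) {
    pmin(1, plogis((falloff_cfg$falloff_half_mm - d) / falloff_cfg$steepness_mm) / f0)
  }

  sp_fall <- sp * c(1, 1, falloff_cfg$z_compression)
  dose <- array(0, dims)
  for (nm in names(rx)) {
    mask <- ss$masks[[nm]]
    d <- distance_to_mask(mask, sp_fall)
    comp <- rx[[nm]] * pmax(mask, falloff(d) * g)
    dose <- pmax(dose, comp)
  }
  if (falloff_cfg$noise_sd_gy > 0) {
    noise <- with_seed(seed, smooth_noise(dims, falloff_cfg$noise_sd_gy))
    dose <- pmax(dose + noise, 0)
  }

  check_coverage(dose, ss)
  dose_grid(dose, sp, ss$origin_mm)
}

check_coverage <- function(dose, ss) {
  v60 <- 100 * sum(dose[ss$masks$ptv60] >= 60) / sum(ss$masks$ptv60)
  v53 <- 100 * sum(dose[ss$masks$ptv53] >= 53) / sum(ss$masks$ptv53)
  med68 <- median(dose[ss$masks$ptv68])
  fails <- character()
  if (v60 < 95) fails <- c(fails, sprintf("V60Gy(PTV60) = %.1f%% < 95%%", v60))
  if (v53 < 95) fails <- c(fails, sprintf("V53Gy(PTV53) = %.1f%% < 95%%", v53))
  if (abs(med68 - 68) > 0.3) {
    fails <- c(fails, sprintf("median PTV68 dose = %.2f Gy outside 68 +/- 0.3 Gy", med68))
  }
  if (length(fails)) {
    abort(paste0("Plan fails coverage objectives: ", paste(fails, collapse = "; ")))
  }
  invisible(TRUE)
}

#' Ground-truth label for a simulated plan
#'
#' Labels a (anatomy, dose) pair with the same DVH, radiobiology and
#' stratification operations used on predicted dose: whether the rectal DVH
#' exceeds the optimal and mandatory constraint levels, and the LKB risks of
#' grade-2 late rectal bleeding and late fecal incontinence.
#'
#' @param anatomy A `structure_set`.
#' @param dose A `dose_grid` on the same grid.
#' @param constraints A [constraint_table()].
#' @param fx A [fractionation_scheme()].
#' @return A one-row tibble: `exceeds_optimal`, `exceeds_mandatory`,
#'   `risk_lrb`, `risk_lfi`.
#' @export
label_plan <- function(anatomy, dose,
                       constraints = default_constraint_table(),
                       fx = fractionation_scheme()) {
  stopifnot(inherits(anatomy, "structure_set"), inherits(dose, "dose_grid"))
  if (!any(anatomy$masks$rectum)) abort("Empty rectum mask.")
  assert_same_grid(dim(dose$dose_gy), dose$spacing_mm,
                   dim(anatomy$masks$rectum), anatomy$spacing_mm,
                   "dose and anatomy")
  curve <- compute_dvh(dose, anatomy$masks$rectum)
  opt <- check_constraints(curve, constraints, "optimal")
  man <- check_constraints(curve, constraints, "mandatory")
  tibble(
    exceeds_optimal = opt$label == "high",
    exceeds_mandatory = man$label == "high",
    risk_lrb = risk(curve, "LRB", fx),
    risk_lfi = risk(curve, "LFI", fx)
  )
}

#' Simulate a cohort of phantoms and plans
#'
#' Generates `n` seeded phantoms and, for each, the six boost-variant plans
#' with their ground-truth labels. This is the training/test material for the
#' dose-prediction network and the stratification experiments.
#'
#' @param n Number of phantoms (patients).
#' @param seed Base seed; phantom `i` uses `seed + i`.
#' @param spec_args Extra arguments passed to [phantom_spec()].
#' @param falloff_cfg A [falloff_config()] shared by all plans (its
#'   `sparing_weight = NULL` default lets each phantom keep its own
#'   planning-style weight).
#' @param boosts Which boost variants to simulate per phantom, or
#'   `"rotate"` for one plan per phantom cycling through the six variants
#'   (the shape of a test cohort with one clinical lesion each).
#' @param labels Compute ground-truth labels per plan (slower).
#' @return A tibble with one row per plan: `patient`, `boost`, `phantom`
#'   (list), `anatomy` (list of `structure_set`), `dose` (list of
#'   `dose_grid`), and label columns when requested.
#' @export
simulate_cohort <- function(n, seed = 1L, spec_args = list(),
                            falloff_cfg = falloff_config(),
                            boosts = 1:6, labels = TRUE) {
  rotate <- identical(boosts, "rotate")
  rows <- list()
  i <- 0L
  for (p in seq_len(n)) {
    spec <- do.call(phantom_spec, c(list(seed = seed + p), spec_args))
    ph <- generate_phantom(spec)
    pb <- if (rotate) ((p - 1L) %% 6L) + 1L else boosts
    for (b in pb) {
      ss <- structure_set(ph, b)
      dg <- simulate_plan_dose(ph, b, falloff_cfg)
      i <- i + 1L
      row <- tibble(
        patient = p, boost = b,
        plan_id = sprintf("p%03d_%s", p, LETTERS[b]),
        phantom = list(ph), anatomy = list(ss), dose = list(dg)
      )
      if (labels) row <- dplyr::bind_cols(row, label_plan(ss, dg))
      rows[[i]] <- row
    }
  }
  bind_rows(rows)
}
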