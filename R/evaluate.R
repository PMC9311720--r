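#' Dice similarity of isodose volumes
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)` where `A` and `B` are the voxel
#' sets at or above `level_gy` in the predicted and ground-truth dose. When
#' both sets are empty the level is trivially in agreement and 1 is returned
#' (with a message).
#'
#' @param pred,truth [dose_grid()] objects on the same grid.
#' @param level_gy Isodose level in Gy (> 0).
#' @return DSC in `[0, 1]`.
#' @export
isodose_dsc <- function(pred, truth, level_gy) {
  stopifnot(inherits(pred, "dose_grid"), inherits(truth, "dose_grid"))
  if (level_gy <= 0) abort("`level_gy` must be positive.")
  assert_same_grid(dim(pred$dose_gy), pred$spacing_mm,
                   dim(truth$dose_gy), truth$spacing_mm, "dose grids")
  a <- pred$dose_gy >= level_gy
  b <- truth$dose_gy >= level_gy
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    rlang::inform(sprintf("Both isodose volumes empty at %.1f Gy; DSC = 1 by convention.",
                          level_gy))
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

# Default reporting isodose levels for the 68/60/53 Gy schedule.
default_dsc_levels <- function() c(24.6, 32.4, 40.8, 48.6, 60, 68)

#' DSC profile over reporting isodose levels
#'
#' Evaluates [isodose_dsc()] at each level, excluding (and flagging) levels
#' whose ground-truth isodose volume touches the volume boundary — those
#' isodoses are not fully encompassed by the sampled array and their Dice
#' value would be truncated.
#'
#' @param pred,truth [dose_grid()] objects on the same grid.
#' @param levels_gy Isodose levels (Gy).
#' @return A tibble `level_gy`, `dsc`, `included`.
#' @export
dsc_profile <- function(pred, truth, levels_gy = default_dsc_levels()) {
  touches_boundary <- function(mask) {
    d <- dim(mask)
    any(mask[1, , ]) || any(mask[d[1], , ]) || any(mask[, 1, ]) ||
      any(mask[, d[2], ]) || any(mask[, , 1]) || any(mask[, , d[3]])
  }
  rows <- lapply(levels_gy, function(lv) {
    tb <- truth$dose_gy >= lv
    inc <- !touches_boundary(tb)
    if (!inc) {
      rlang::inform(sprintf(
        "Isodose %.1f Gy touches the volume boundary; excluded from the DSC profile.", lv))
    }
    tibble(level_gy = lv,
           dsc = if (inc) isodose_dsc(pred, truth, lv) else NA_real_,
           included = inc)
  })
  bind_rows(rows)
}

#' Prediction-error profile over DVH parameters
#'
#' For each DVH parameter, computes the signed error `predicted - planned`
#' (positive = over-prediction) across a cohort of paired curves and
#' summarises it: mean, median, SD, quartiles, IQR and Tukey whiskers
#' (most extreme values within 1.5 IQR of the box).
#'
#' @param pred,truth Equal-length lists of `dvh_curve` objects, paired by
#'   position.
#' @param parameters DVH metrics to profile, e.g. `c("V30Gy", "Dmean")`.
#' @return A tibble with one row per parameter: `parameter`, `n`, `mean`,
#'   `median`, `sd`, `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`.
#' @export
dvh_error_profile <- function(pred, truth,
                              parameters = sprintf("V%gGy", seq(10, 65, by = 5))) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` pair lists differ in length.")
  if (length(pred) < 2) abort("Need at least 2 DVH pairs to profile errors.")
  rows <- lapply(parameters, function(p) {
    err <- vapply(seq_along(pred), function(i) {
      dvh_metric(pred[[i]], p) - dvh_metric(truth[[i]], p)
    }, numeric(1))
    q <- unname(quantile(err, c(0.25, 0.75), type = 7))
    iqr <- q[2] - q[1]
    in_lo <- err[err >= q[1] - 1.5 * iqr]
    in_hi <- err[err <= q[2] + 1.5 * iqr]
    tibble(parameter = p, n = length(err), mean = mean(err),
           median = median(err), sd = sd(err),
           q1 = q[1], q3 = q[2], iqr = iqr,
           whisker_low = min(in_lo), whisker_high = max(in_hi))
  })
  out <- bind_rows(rows)
  structure(out, class = c("dvh_error_profile", class(out)))
}

#' Bland-Altman agreement between predicted and planned risks
#'
#' Paired differences `pred - truth`, their mean bias, and 95% limits of
#' agreement `mean +/- 1.96 * SD` using the sample (n-1) standard deviation.
#'
#' @param pred,truth Paired numeric vectors (n >= 2), e.g. toxicity risks.
#' @return A `bland_altman` object; see [tidy()] / [glance()] methods.
#' @export
bland_altman <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2) {
    abort("Bland-Altman needs paired vectors of length >= 2.")
  }
  d <- pred - truth
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(differences = d, means = (pred + truth) / 2,
         mean_bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd = s, n = length(d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$mean_bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Tidy methods for evaluation objects
#'
#' `tidy.bland_altman()` returns the per-pair differences; `glance()` the
#' bias and limits of agreement.
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(pair = seq_len(x$n), mean = x$means, difference = x$differences)
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, mean_bias = x$mean_bias, sd = x$sd,
         loa_low = x$loa_low, loa_high = x$loa_high)
}
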