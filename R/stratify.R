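#' Rectal DVH constraint table
#'
#' A table of `VdGy <= max_volume_pct` tolerance entries at two levels:
#' `optimal` (planning goals) and `mandatory` (hard limits). Mandatory
#' thresholds must be at least as lenient as optimal thresholds at the same
#' dose (nested leniency), so a plan exceeding mandatory constraints also
#' exceeds optimal ones.
#'
#' @param entries A data frame with columns `dose_gy`, `max_volume_pct`,
#'   `level` (`"optimal"`/`"mandatory"`).
#' @param source Provenance tag stored with the table.
#' @return A `constraint_table` tibble with a derived `metric` column.
#' @export
constraint_table <- function(entries, source = "user") {
  entries <- as_tibble(entries)
  need <- c("dose_gy", "max_volume_pct", "level")
  if (!all(need %in% names(entries))) {
    abort(paste0("Constraint entries need columns: ", paste(need, collapse = ", ")))
  }
  if (any(entries$dose_gy <= 0)) abort("Constraint doses must be positive.")
  if (any(entries$max_volume_pct < 0 | entries$max_volume_pct > 100)) {
    abort("Constraint volume tolerances must lie in [0, 100]%.")
  }
  if (!all(entries$level %in% c("optimal", "mandatory"))) {
    abort("Constraint `level` must be \"optimal\" or \"mandatory\".")
  }
  wide <- tidyr::pivot_wider(entries, id_cols = "dose_gy",
                             names_from = "level",
                             values_from = "max_volume_pct")
  if (all(c("optimal", "mandatory") %in% names(wide))) {
    both <- !is.na(wide$optimal) & !is.na(wide$mandatory)
    if (any(wide$mandatory[both] < wide$optimal[both])) {
      abort("Nested leniency violated: mandatory tolerance below optimal at the same dose.")
    }
  }
  out <- entries |>
    mutate(metric = sprintf("V%.4gGy", .data$dose_gy)) |>
    arrange(.data$level, .data$dose_gy)
  structure(out, class = c("constraint_table", class(out)), source = source)
}

#' Default rectal tolerance table
#'
#' Onjukka-style rectal tolerances for the 68/60/53 Gy three-dose-level
#' schedule, expressed as maximum percent rectal volume at the six reporting
#' doses 24.6, 32.4, 40.8, 48.6, 60 and 68 Gy. The top-dose optimal entry
#' carries a 0.2% (not 0%) tolerance for practical planning reasons. These
#' defaults are user-overridable via [constraint_table()] or
#' [read_constraint_table()]; the threshold values are calibrated to the
#' packaged plan simulator so that failures concentrate at the two highest
#' doses, as in clinical dose-escalated planning.
#'
#' @return A `constraint_table`.
#' @export
default_constraint_table <- function() {
  constraint_table(
    tibble(
      dose_gy        = c(24.6, 32.4, 40.8, 48.6, 60, 68,
                         24.6, 32.4, 40.8, 48.6, 60, 68),
      max_volume_pct = c(45,   30,   12,   5.5,  0.4, 0.2,
                         55,   40,   16,   7.2,  1.0, 0.6),
      level = rep(c("optimal", "mandatory"), each = 6)
    ),
    source = "Onjukka-derived defaults (simulator-calibrated, user-overridable)"
  )
}

#' Read / write a constraint table as YAML
#'
#' @param path YAML file with fields `source` and `entries`
#'   (list of `{dose_gy, max_volume_pct, level}`).
#' @param table A `constraint_table` to write.
#' @return A `constraint_table` (read); `path` invisibly (write).
#' @export
read_constraint_table <- function(path) {
  y <- yaml::read_yaml(path)
  constraint_table(bind_rows(lapply(y$entries, as_tibble)),
                   source = y$source %||% path)
}

#' @rdname read_constraint_table
#' @export
write_constraint_table <- function(table, path) {
  stopifnot(inherits(table, "constraint_table"))
  yaml::write_yaml(
    list(source = attr(table, "source"),
         entries = lapply(seq_len(nrow(table)), function(i) {
           list(dose_gy = table$dose_gy[i],
                max_volume_pct = table$max_volume_pct[i],
                level = table$level[i])
         })),
    path
  )
  invisible(path)
}

new_stratification_outcome <- function(method, label, margin, binding) {
  tibble(method = method, label = label, margin = margin, binding = binding)
}

#' Constraint-based stratification of one rectal DVH
#'
#' Labels a plan `"high"` (candidate for rectal spacer insertion) if any
#' `VdGy` value of its rectal DVH strictly exceeds the tolerance at the
#' requested level; a plan exactly at every threshold is within tolerance
#' (`"low"`). The margin is the largest signed excess over a threshold, in
#' percentage points; `binding` names the constraint attaining it.
#'
#' @param rect_dvh A physical-dose rectal `dvh_curve`.
#' @param table A [constraint_table()].
#' @param level `"optimal"` or `"mandatory"`.
#' @return A one-row stratification outcome tibble: `method`, `label`
#'   (`"high"`/`"low"`), `margin`, `binding`.
#' @export
check_constraints <- function(rect_dvh, table = default_constraint_table(),
                              level = "optimal") {
  stopifnot(inherits(rect_dvh, "dvh_curve"), inherits(table, "constraint_table"))
  rows <- table[table$level == level, ]
  if (!nrow(rows)) abort(paste0("Constraint table has no entries at level '", level, "'."))
  measured <- vapply(rows$metric, function(m) dvh_metric(rect_dvh, m), numeric(1))
  margins <- measured - rows$max_volume_pct
  i <- which.max(margins)
  new_stratification_outcome(
    method = paste0(level, "_dvh"),
    label = if (margins[i] > 0) "high" else "low",
    margin = unname(margins[i]),
    binding = sprintf("%s<=%.4g%%", rows$metric[i], rows$max_volume_pct[i])
  )
}

#' Risk-threshold stratification
#'
#' Labels a patient `"high"` when the toxicity risk is at or above the
#' threshold (the threshold itself counts as high risk, matching "offer the
#' spacer to patients with risk >= threshold").
#'
#' @param risk Probability in `[0, 1]`.
#' @param threshold Probability in `[0, 1]`.
#' @param method Outcome tag, e.g. `"lrb_risk"` or `"lfi_risk"`.
#' @return A one-row stratification outcome tibble.
#' @export
stratify_by_risk <- function(risk, threshold, method = "lrb_risk") {
  if (risk < 0 || risk > 1 || threshold < 0 || threshold > 1) {
    abort("`risk` and `threshold` must be probabilities in [0, 1].")
  }
  new_stratification_outcome(
    method = method,
    label = if (risk >= threshold) "high" else "low",
    margin = risk - threshold,
    binding = sprintf("risk>=%.4g", threshold)
  )
}

#' Confusion counts and metrics for stratification
#'
#' The positive class is "exceeds tolerance / high risk". Sensitivity is the
#' fraction of truly-exceeding plans identified, specificity the fraction of
#' truly-within plans identified, accuracy the overall fraction correct.
#' Metrics whose denominator is empty are returned as `NA` with a flag
#' rather than silently as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts, or pass a single
#'   `confusion_counts` object to `confusion_metrics()`.
#' @return `confusion_counts()`: a classed one-row tibble.
#'   `confusion_metrics()`: a one-row tibble `sensitivity`, `specificity`,
#'   `accuracy`, `undefined` (comma-separated names of undefined metrics).
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("Confusion counts must sum to a positive total.")
  out <- tibble(tp = as.integer(tp), fp = as.integer(fp),
                tn = as.integer(tn), fn = as.integer(fn))
  structure(out, class = c("confusion_counts", class(out)))
}

#' @rdname confusion_counts
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(tp, "confusion_counts")) {
    c0 <- tp
  } else {
    c0 <- confusion_counts(tp, fp, tn, fn)
  }
  undef <- character()
  sens <- if (c0$tp + c0$fn > 0) c0$tp / (c0$tp + c0$fn) else {
    undef <- c(undef, "sensitivity"); NA_real_
  }
  spec <- if (c0$tn + c0$fp > 0) c0$tn / (c0$tn + c0$fp) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  total <- c0$tp + c0$fp + c0$tn + c0$fn
  tibble(sensitivity = sens, specificity = spec,
         accuracy = (c0$tp + c0$tn) / total,
         undefined = paste(undef, collapse = ","))
}

#' Confusion counts from paired labels
#'
#' @param pred,truth Logical vectors (or `"high"`/`"low"` characters), TRUE /
#'   `"high"` = exceeds tolerance.
#' @return A `confusion_counts` object.
#' @export
confusion_from_labels <- function(pred, truth) {
  as_pos <- function(x) if (is.character(x)) x == "high" else as.logical(x)
  p <- as_pos(pred); t <- as_pos(truth)
  if (length(p) != length(t)) abort("`pred` and `truth` must have equal length.")
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   tn = sum(!p & !t), fn = sum(!p & t))
}

#' Agreement between predicted and planned risk stratification across thresholds
#'
#' For each risk threshold, both risk series are dichotomised at that
#' threshold (risk >= threshold = high) and the fraction of patients whose
#' labels agree is reported.
#'
#' @param pred_risks,truth_risks Paired probability vectors.
#' @param thresholds Vector of thresholds to sweep.
#' @return A tibble `threshold`, `agreement` (fraction in `[0, 1]`).
#' @export
threshold_sweep <- function(pred_risks, truth_risks,
                            thresholds = seq(0.02, 0.12, by = 0.005)) {
  if (!length(pred_risks) || length(pred_risks) != length(truth_risks)) {
    abort("`pred_risks` and `truth_risks` must be non-empty and paired.")
  }
  tibble(threshold = thresholds) |>
    mutate(agreement = vapply(thresholds, function(th) {
      mean((pred_risks >= th) == (truth_risks >= th))
    }, numeric(1)))
}
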