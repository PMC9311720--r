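#' Plot a cumulative DVH
#'
#' @param object A `dvh_curve`.
#' @param ... Further curves to overlay (named arguments become legend
#'   labels).
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "dvh_curve")]
  curves <- c(list(object), extra)
  labels <- c(attr(object, "source") %||% "curve 1",
              names(extra) %||% paste("curve", seq_along(extra) + 1))
  df <- bind_rows(lapply(seq_along(curves), function(i) {
    tibble(dose_gy = curves[[i]]$dose_gy, volume_pct = curves[[i]]$volume_pct,
           curve = labels[i])
  }))
  ggplot(df, aes(x = .data$dose_gy, y = .data$volume_pct, colour = .data$curve)) +
    geom_step(direction = "hv") +
    labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL,
         title = paste0("Cumulative DVH: ", attr(object, "structure") %||% "")) +
    theme_minimal()
}

#' Bland-Altman plot of risk agreement
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot: per-pair differences against means, with the mean bias
#'   (solid) and 95% limits of agreement (dotted).
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$mean, y = .data$difference)) +
    geom_point() +
    geom_hline(yintercept = object$mean_bias, linewidth = 0.8) +
    geom_hline(yintercept = c(object$loa_low, object$loa_high), linetype = "dotted") +
    labs(x = "Mean of predicted and planned", y = "Predicted - planned") +
    theme_minimal()
}

#' Box-style plot of the DVH prediction-error profile
#'
#' @param object A [dvh_error_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot with IQR boxes, medians, means and Tukey whiskers.
#' @export
autoplot.dvh_error_profile <- function(object, ...) {
  df <- mutate(object, parameter = factor(.data$parameter,
                                          levels = unique(.data$parameter)))
  ggplot(df, aes(x = .data$parameter)) +
    geom_errorbar(aes(ymin = .data$whisker_low, ymax = .data$whisker_high),
                  width = 0.25) +
    geom_crossbar(aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
                  fill = "grey85", width = 0.6) +
    geom_point(aes(y = .data$mean), shape = 4, size = 2) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = NULL, y = "Prediction error (percentage points)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Agreement-versus-threshold curve for risk stratification
#'
#' @param sweep A [threshold_sweep()] tibble (optionally several, named, for
#'   overlaying endpoints).
#' @param ... Further sweep tibbles to overlay.
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(sweep, ...) {
  extra <- list(...)
  sweeps <- c(list(sweep), extra)
  labels <- c(names(extra), "")
  labels <- if (length(extra)) c("sweep 1", names(extra)) else "agreement"
  df <- bind_rows(lapply(seq_along(sweeps), function(i) {
    mutate(sweeps[[i]], endpoint = labels[i])
  }))
  ggplot(df, aes(x = 100 * .data$threshold, y = 100 * .data$agreement,
                 colour = .data$endpoint)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "Risk threshold (%)", y = "Correctly stratified (%)",
         colour = NULL) +
    ylim(0, 100) +
    theme_minimal()
}

#' Axial slice through a dose grid
#'
#' @param dose A [dose_grid()].
#' @param z Slice index (default: the slice with the highest dose).
#' @param mask Optional structure mask whose outline is overlaid.
#' @return A ggplot raster of the slice.
#' @export
plot_dose_slice <- function(dose, z = NULL, mask = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  arr <- dose$dose_gy
  if (is.null(z)) {
    z <- which.max(apply(arr, 3, max))
  }
  sl <- arr[, , z]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl))) |>
    mutate(dose = as.numeric(sl[cbind(.data$x, .data$y)]))
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$dose)) +
    geom_raster() +
    scale_fill_viridis_c(name = "Gy") +
    coord_equal() +
    labs(x = "x (left-right)", y = "y (anterior-posterior)",
         title = sprintf("Axial slice z = %d", z)) +
    theme_minimal()
  if (!is.null(mask)) {
    ms <- mask[, , z]
    dfm <- tidyr::expand_grid(x = seq_len(nrow(ms)), y = seq_len(ncol(ms))) |>
      mutate(inside = as.numeric(ms[cbind(.data$x, .data$y)]))
    p <- p + geom_contour(data = dfm,
                          mapping = aes(x = .data$x, y = .data$y, z = .data$inside),
                          breaks = 0.5, colour = "red", inherit.aes = FALSE)
  }
  p
}
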