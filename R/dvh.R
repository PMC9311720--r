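#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of a structure by direct voxel counting:
#' `volume_pct[j]` is the percentage of the structure's voxels receiving at
#' least `dose_gy[j]`. The curve starts at 100% at 0 Gy, is non-increasing,
#' and its final bin (just above the maximum voxel dose) is 0%.
#'
#' @param dose A [dose_grid()] or numeric 3D array of dose in Gy.
#' @param mask Logical array selecting the structure's voxels.
#' @param bin_width_gy Histogram bin width in Gy (default 0.1).
#' @param structure Optional structure name stored with the curve.
#' @param source `"planned"` or `"predicted"`, stored with the curve.
#' @return A `dvh_curve`: a tibble with columns `dose_gy`, `volume_pct` and
#'   attributes `structure`, `voxel_count`, `source`, `dose_stats`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.1,
                        structure = "rectum", source = "planned") {
  if (inherits(dose, "dose_grid")) {
    assert_same_grid(dim(dose$dose_gy), dose$spacing_mm, dim(mask), dose$spacing_mm)
    if (!identical(dim(dose$dose_gy), dim(mask))) {
      abort("Misaligned grids: dose and mask shapes differ.")
    }
    dose <- dose$dose_gy
  }
  if (!identical(dim(dose), dim(mask))) {
    abort("Misaligned grids: dose and mask shapes differ.")
  }
  if (!any(mask)) abort("Empty structure mask: DVH undefined.")
  if (bin_width_gy <= 0) abort("`bin_width_gy` must be positive.")
  vox <- sort(as.numeric(dose[mask]))
  n <- length(vox)
  dmax <- vox[n]
  edges <- seq(0, dmax + bin_width_gy, by = bin_width_gy)
  # voxels with dose >= edge (equality counts as receiving the dose)
  below <- findInterval(edges - 1e-9, vox)
  vol <- 100 * (n - below) / n
  out <- tibble(dose_gy = edges, volume_pct = vol)
  structure(out,
            class = c("dvh_curve", class(out)),
            structure = structure, voxel_count = n, source = source,
            dose_stats = c(mean = mean(vox), max = dmax, min = vox[1]))
}

new_dvh_curve <- function(df, template) {
  structure(df,
            class = c("dvh_curve", class(tibble())),
            structure = attr(template, "structure"),
            voxel_count = attr(template, "voxel_count"),
            source = attr(template, "source"),
            dose_stats = attr(template, "dose_stats"))
}

#' Scalar DVH metrics
#'
#' Evaluates `VdGy` (percent volume receiving at least `d` Gy, linear
#' interpolation between bins), `Dv%` (dose to the hottest `v`% of the
#' volume, inverse interpolation), `Dmax` and `Dmean`. When called on a
#' `dose`+`mask` pair, `Dmax`/`Dmean` are direct voxel statistics; on a
#' curve they are read from the stored voxel statistics when available,
#' otherwise from the curve itself. Volume queries above the recorded
#' maximum dose return 0 (no voxel receives more than the maximum);
#' negative doses and volume queries outside `[0, 100]`% are clamped with a
#' warning.
#'
#' @param x A `dvh_curve`, or a [dose_grid()]/array (then supply `mask`).
#' @param metric Character like `"V60Gy"`, `"D2%"`, `"Dmax"`, `"Dmean"`.
#' @param mask Structure mask when `x` is a dose volume.
#' @return The metric value (percent for `V`, Gy for `D`).
#' @export
dvh_metric <- function(x, metric, mask = NULL) {
  if (!inherits(x, "dvh_curve")) {
    if (inherits(x, "dose_grid")) x_arr <- x$dose_gy else x_arr <- x
    if (is.null(mask)) abort("Supply `mask` when `x` is a dose volume.")
    vox <- as.numeric(x_arr[mask])
    if (metric == "Dmax") return(max(vox))
    if (metric == "Dmean") return(mean(vox))
    x <- compute_dvh(x_arr, mask)
  }
  if (length(metric) != 1L) abort("`metric` must be a single string.")
  if (metric == "Dmax") {
    st <- attr(x, "dose_stats")
    if (!is.null(st)) return(unname(st["max"]))
    return(max(x$dose_gy[x$volume_pct > 0]))
  }
  if (metric == "Dmean") {
    st <- attr(x, "dose_stats")
    if (!is.null(st)) return(unname(st["mean"]))
    return(dvh_mean_from_curve(x))
  }
  mv <- regmatches(metric, regexec("^V([0-9]*\\.?[0-9]+)(Gy)?$", metric))[[1]]
  if (length(mv)) {
    d <- as.numeric(mv[2])
    if (d < 0) {
      warn("Negative query dose; clamped to 0 Gy.")
      d <- 0
    }
    # doses above the recorded maximum trivially enclose zero volume
    if (d > max(x$dose_gy)) return(0)
    return(stats::approx(x$dose_gy, x$volume_pct, xout = d, rule = 2)$y)
  }
  md <- regmatches(metric, regexec("^D([0-9]*\\.?[0-9]+)%?$", metric))[[1]]
  if (length(md)) {
    v <- as.numeric(md[2])
    if (v < 0 || v > 100) {
      warn("Volume query outside [0, 100]%; clamped.")
      v <- min(max(v, 0), 100)
    }
    # invert the non-increasing curve: dose at which volume_pct == v
    ok <- rev(!duplicated(rev(x$volume_pct)))  # keep last bin of each plateau
    return(stats::approx(x$volume_pct[ok], x$dose_gy[ok], xout = v, rule = 2)$y)
  }
  abort(paste0("Unrecognised DVH metric '", metric,
               "'; use e.g. \"V60Gy\", \"D2%\", \"Dmax\", \"Dmean\"."))
}

# Differential form of a cumulative curve: fractional volumes (summing to 1).
# The mass between edges d_j and d_(j+1) holds the voxels with dose in
# [d_j, d_(j+1)), so it is attributed the lower edge d_j: exact whenever
# doses align with bin edges (uniform and stepwise fields), biased low by
# less than one bin width otherwise. Works for non-uniform edges (EQD2).
dvh_differential <- function(curve) {
  v <- curve$volume_pct / 100
  d <- curve$dose_gy
  n <- length(d)
  frac <- v[-n] - v[-1]
  keep <- frac > 0
  list(frac = frac[keep], dose = d[-n][keep])
}

dvh_mean_from_curve <- function(curve) {
  df <- dvh_differential(curve)
  sum(df$frac * df$dose)
}

#' Write / read a DVH as two-column tab-separated text
#'
#' The de-facto planning-system export dialect: a header line, then
#' `dose_gy<TAB>volume_pct` rows. Metadata (structure, voxel count, source)
#' travels in a JSON sidecar next to the table.
#'
#' @param curve A `dvh_curve`.
#' @param path Output path for the `.tsv` file.
#' @return `path`, invisibly (`write_dvh`); a `dvh_curve` (`read_dvh`).
#' @export
write_dvh <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  utils::write.table(as.data.frame(curve)[, c("dose_gy", "volume_pct")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(structure = attr(curve, "structure"),
               voxel_count = attr(curve, "voxel_count"),
               source = attr(curve, "source"),
               dose_stats = as.list(attr(curve, "dose_stats")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dvh
#' @export
read_dvh <- function(path) {
  df <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(df,
            class = c("dvh_curve", class(tibble())),
            structure = meta$structure %||% "unknown",
            voxel_count = meta$voxel_count %||% NA_integer_,
            source = meta$source %||% "unknown",
            dose_stats = if (!is.null(meta$dose_stats)) unlist(meta$dose_stats))
}
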