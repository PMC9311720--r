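#' Resample a dose grid with cubic splines
#'
#' Separable third-order (natural cubic) spline interpolation of the dose
#' onto a new grid sharing the source origin. Voxel centres sit at
#' `(i - 0.5) * spacing`; interpolation overshoot below zero is clamped to 0.
#'
#' @param dose A [dose_grid()].
#' @param target_spacing_mm New voxel spacing (3 positive numbers).
#' @param target_shape New grid shape (3 positive integers).
#' @return A [dose_grid()] on the target grid.
#' @export
resample_dose <- function(dose, target_spacing_mm, target_shape) {
  stopifnot(inherits(dose, "dose_grid"))
  target_spacing_mm <- check_spacing(target_spacing_mm)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1)) {
    abort("`target_shape` must be 3 positive integers.")
  }
  if (identical(dim(dose$dose_gy), target_shape) &&
      max(abs(dose$spacing_mm - target_spacing_mm)) < 1e-12) {
    return(dose)
  }
  arr <- dose$dose_gy
  for (ax in 1:3) {
    src <- (seq_len(dim(arr)[ax]) - 0.5) * dose$spacing_mm[ax]
    tgt <- (seq_len(target_shape[ax]) - 0.5) * target_spacing_mm[ax]
    arr <- axis_spline_interp(arr, ax, src, tgt)
  }
  arr[arr < 0] <- 0
  dose_grid(arr, target_spacing_mm, dose$origin_mm)
}

# Cubic-spline interpolation of a 3D array along one axis.
axis_spline_interp <- function(arr, axis, src, tgt) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  out <- matrix(0, nrow = length(tgt), ncol = ncol(m))
  if (length(src) < 4) {
    for (j in seq_len(ncol(m))) {
      out[, j] <- stats::approx(src, m[, j], xout = tgt, rule = 2)$y
    }
  } else {
    for (j in seq_len(ncol(m))) {
      out[, j] <- stats::splinefun(src, m[, j], method = "natural")(tgt)
    }
  }
  res <- array(out, dim = c(length(tgt), d[2], d[3]))
  aperm(res, order(perm))
}

#' Crop anatomy (and dose) to the network input volume
#'
#' Fixed-size crop of the five structure masks (channel order `ptv68`,
#' `ptv60`, `ptv53`, `rectum`, `bladder`) and, optionally, the dose:
#' centred left-right on the PTV53 centre of mass, cranio-caudally on the
#' rectal centre of mass (non-integer centres floored), and placed
#' anterior-posteriorly so the entire rectum lies inside the window. The
#' window may extend past the source grid, in which case it is zero-padded
#' (with a warning); the crop offset is recorded for inverse mapping.
#'
#' @param anatomy A `structure_set`.
#' @param dose Optional [dose_grid()] on the same grid.
#' @param shape Crop shape, `(X, Y, Z)`; `c(128, 128, 64)` at full scale,
#'   `c(32, 32, 16)` for desk-scale runs.
#' @return A `model_input` object: `channels` (named list of 5 cropped
#'   masks), `dose` (cropped dose array or `NULL`), `crop_offset` (1-based
#'   start indices in the source grid, may be non-positive when padded),
#'   `source_dim`, `spacing_mm`.
#' @export
crop_to_input <- function(anatomy, dose = NULL, shape = c(32L, 32L, 16L)) {
  stopifnot(inherits(anatomy, "structure_set"))
  shape <- as.integer(shape)
  src_dim <- dim(anatomy$masks$rectum)
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "dose_grid"))
    assert_same_grid(dim(dose$dose_gy), dose$spacing_mm, src_dim,
                     anatomy$spacing_mm, "dose and anatomy")
  }

  com53 <- mask_com(anatomy$masks$ptv53)
  com_rect <- mask_com(anatomy$masks$rectum)
  start <- integer(3)
  start[1] <- floor(com53[1]) - shape[1] %/% 2 + 1L   # left-right on PTV53
  start[3] <- floor(com_rect[3]) - shape[3] %/% 2 + 1L  # cranio-caudal on rectum

  # anterior-posterior: any placement containing the whole rectum
  ry <- range(which(apply(anatomy$masks$rectum, 2, any)))
  if (ry[2] - ry[1] + 1L > shape[2]) {
    abort(sprintf(
      "Rectum spans %d voxels anterior-posteriorly; cannot fit the %d-voxel crop window in any placement.",
      ry[2] - ry[1] + 1L, shape[2]))
  }
  # keep the window as anterior as the rectum allows (a small posterior
  # inset), so the targets and the dose bath anterior to the rectum stay in
  # view while the whole rectum is sampled
  start[2] <- ry[2] + 2L - shape[2] + 1L
  start[2] <- min(start[2], ry[1])

  # hard assert: no rectal voxel may be discarded
  rz <- range(which(apply(anatomy$masks$rectum, 3, any)))
  rx <- range(which(apply(anatomy$masks$rectum, 1, any)))
  ends <- start + shape - 1L
  if (rx[1] < start[1] || rx[2] > ends[1] || rz[1] < start[3] || rz[2] > ends[3]) {
    abort("Crop window would discard rectal voxels; enlarge the crop shape.")
  }
  if (any(start < 1L) || any(ends > src_dim)) {
    warn("Crop window extends past the source grid; zero-padding.")
  }

  crop1 <- function(arr, fill) {
    out <- array(fill, dim = shape)
    s_lo <- pmax(start, 1L); s_hi <- pmin(ends, src_dim)
    if (all(s_lo <= s_hi)) {
      t_lo <- s_lo - start + 1L; t_hi <- s_hi - start + 1L
      out[t_lo[1]:t_hi[1], t_lo[2]:t_hi[2], t_lo[3]:t_hi[3]] <-
        arr[s_lo[1]:s_hi[1], s_lo[2]:s_hi[2], s_lo[3]:s_hi[3]]
    }
    out
  }

  channels <- list(
    ptv68 = crop1(anatomy$masks$ptv68, FALSE),
    ptv60 = crop1(anatomy$masks$ptv60, FALSE),
    ptv53 = crop1(anatomy$masks$ptv53, FALSE),
    rectum = crop1(anatomy$masks$rectum, FALSE),
    bladder = crop1(anatomy$masks$bladder, FALSE)
  )
  if (sum(channels$rectum) != sum(anatomy$masks$rectum)) {
    abort("Internal error: rectum voxels lost in cropping.")  # nocov
  }
  structure(
    list(
      channels = channels,
      dose = if (!is.null(dose)) crop1(dose$dose_gy, 0) else NULL,
      crop_offset = start,
      source_dim = src_dim,
      spacing_mm = anatomy$spacing_mm
    ),
    class = "model_input"
  )
}

#' Paste a cropped volume back into its source grid
#'
#' Inverse of the [crop_to_input()] bookkeeping: places `values` (an array of
#' the crop shape) at `crop_offset` in a zero-filled grid of the source
#' shape, discarding any padded region.
#'
#' @param values Array of the crop shape.
#' @param crop_offset 1-based start indices from [crop_to_input()].
#' @param source_dim Source grid shape.
#' @return An array of shape `source_dim`.
#' @export
uncrop <- function(values, crop_offset, source_dim) {
  out <- array(0, dim = source_dim)
  ends <- crop_offset + dim(values) - 1L
  s_lo <- pmax(crop_offset, 1L); s_hi <- pmin(ends, source_dim)
  if (all(s_lo <= s_hi)) {
    t_lo <- s_lo - crop_offset + 1L; t_hi <- s_hi - crop_offset + 1L
    out[s_lo[1]:s_hi[1], s_lo[2]:s_hi[2], s_lo[3]:s_hi[3]] <-
      values[t_lo[1]:t_hi[1], t_lo[2]:t_hi[2], t_lo[3]:t_hi[3]]
  }
  out
}

#' Dose normalization constant
#'
#' The network trains on dose divided by the maximum voxel dose across the
#' training cohort; predictions are rescaled by the same stored constant.
#'
#' @param max_dose_gy Strictly positive maximum dose (Gy).
#' @param cohort_id Identifier of the cohort the constant was computed from.
#' @param doses For `norm_constant_from_cohort()`: a list of [dose_grid()]s
#'   or arrays.
#' @return A `normalization_constant`.
#' @export
normalization_constant <- function(max_dose_gy, cohort_id = "training") {
  if (!is.numeric(max_dose_gy) || max_dose_gy <= 0) {
    abort("`max_dose_gy` must be strictly positive.")
  }
  structure(list(max_dose_gy = max_dose_gy, cohort_id = cohort_id),
            class = "normalization_constant")
}

#' @rdname normalization_constant
#' @export
norm_constant_from_cohort <- function(doses, cohort_id = "training") {
  mx <- max(vapply(doses, function(d) {
    if (inherits(d, "dose_grid")) max(d$dose_gy) else max(d)
  }, numeric(1)))
  normalization_constant(mx, cohort_id)
}

#' Normalize / denormalize dose by the cohort constant
#'
#' @param x Numeric array or [dose_grid()] array values.
#' @param const A [normalization_constant()].
#' @return `normalize_dose()`: unitless values in roughly `[0, 1]`;
#'   `denormalize_dose()`: Gy.
#' @export
normalize_dose <- function(x, const) {
  stopifnot(inherits(const, "normalization_constant"))
  if (inherits(x, "dose_grid")) x$dose_gy / const$max_dose_gy
  else x / const$max_dose_gy
}

#' @rdname normalize_dose
#' @export
denormalize_dose <- function(x, const) {
  stopifnot(inherits(const, "normalization_constant"))
  x * const$max_dose_gy
}
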