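# Internal voxel-grid helpers shared by the phantom simulator, preprocessing
# and evaluation code. Volumes are logical/numeric 3D arrays with dim
# (x, y, z): x = patient left-right, y = anterior -> posterior (increasing
# towards the rectum), z = cranio-caudal. Physical voxel-centre coordinates
# are (i - 0.5) * spacing_mm, i.e. the grid origin sits at a corner.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_spacing <- function(spacing_mm) {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L ||
      any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 strictly positive finite numbers.")
  }
  as.numeric(spacing_mm)
}

voxel_cc <- function(spacing_mm) prod(spacing_mm) / 1000

mask_volume_cc <- function(mask, spacing_mm) sum(mask) * voxel_cc(spacing_mm)

coords_mm <- function(dims, spacing_mm) {
  list(
    x = (seq_len(dims[1]) - 0.5) * spacing_mm[1],
    y = (seq_len(dims[2]) - 0.5) * spacing_mm[2],
    z = (seq_len(dims[3]) - 0.5) * spacing_mm[3]
  )
}

# Euclidean distance (mm) from each voxel to the nearest TRUE voxel.
distance_to_mask <- function(mask, spacing_mm) {
  d <- .edt_mm(as.logical(mask), dim(mask), as.numeric(spacing_mm))
  array(d, dim = dim(mask))
}

# Morphological dilation by a Euclidean ball of radius `r_mm`.
dilate_mm <- function(mask, spacing_mm, r_mm) {
  if (r_mm <= 0) return(mask)
  distance_to_mask(mask, spacing_mm) <= r_mm + 1e-9
}

ellipsoid_mask <- function(dims, spacing_mm, center_mm, semi_mm) {
  cc <- coords_mm(dims, spacing_mm)
  ex <- ((cc$x - center_mm[1]) / semi_mm[1])^2
  ey <- ((cc$y - center_mm[2]) / semi_mm[2])^2
  ez <- ((cc$z - center_mm[3]) / semi_mm[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

# Approximate signed distance (mm) to an ellipsoid surface, measured along
# the ray from the centre (exact for spheres): negative inside. Continuous
# fields keep sub-voxel expansion margins meaningful on coarse grids, where
# a voxel-EDT dilation could not grow by less than one voxel.
radial_dist_field <- function(dims, spacing_mm, center_mm, semi_mm) {
  cc <- coords_mm(dims, spacing_mm)
  r2 <- outer(outer((cc$x - center_mm[1])^2, (cc$y - center_mm[2])^2, "+"),
              (cc$z - center_mm[3])^2, "+")
  e2 <- outer(outer(((cc$x - center_mm[1]) / semi_mm[1])^2,
                    ((cc$y - center_mm[2]) / semi_mm[2])^2, "+"),
              ((cc$z - center_mm[3]) / semi_mm[3])^2, "+")
  r <- sqrt(r2)
  e <- sqrt(e2)
  d <- r - r / pmax(e, 1e-12)
  d[e < 1e-12] <- -min(semi_mm)
  d
}

# Center of mass of a mask, in voxel index units (1-based, can be fractional).
mask_com <- function(mask) {
  stopifnot(any(mask))
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

# Draw from N(mean, sd) truncated at +/- 2.5 sd (and at `lower`).
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  lo <- max(mean - 2.5 * sd, lower)
  hi <- mean + 2.5 * sd
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

# Smooth white noise: (1,2,1)/4 kernel applied `passes` times along each axis,
# rescaled to the requested standard deviation.
smooth_noise <- function(dims, sd, passes = 2) {
  x <- array(rnorm(prod(dims)), dim = dims)
  sm1 <- function(a, axis) {
    n <- dim(a)[axis]
    lo <- c(1, seq_len(n - 1))
    hi <- c(seq_len(n - 1) + 1, n)
    if (axis == 1) (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4
    else if (axis == 2) (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4
    else (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4
  }
  for (p in seq_len(passes)) for (ax in 1:3) x <- sm1(x, ax)
  s <- sd(as.vector(x))
  if (s > 0) x <- x * (sd / s)
  x
}

assert_same_grid <- function(a_dim, a_spacing, b_dim, b_spacing, what = "grids") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)) ||
      max(abs(a_spacing - b_spacing)) > 1e-6) {
    abort(paste0("Misaligned ", what,
                 ": shapes/spacings must match voxel for voxel."))
  }
  invisible(TRUE)
}
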