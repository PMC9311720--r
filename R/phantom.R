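#' Specification for a synthetic pelvic phantom
#'
#' Defines the geometry and sampling rules for one synthetic pelvic anatomy:
#' a prostate (CTV60) with seminal-vesicle lobes (together CTV53), a rectum
#' running cranio-caudally posterior to the prostate, a bladder, and six
#' peripheral-zone boost lesions (DILs) from which the boosted target volumes
#' PTV68-A..F are grown. Margins follow the dose-escalation planning
#' convention: PTV60 = prostate + 5 mm, PTV53 = prostate+vesicles + 9 mm,
#' CTV68 = DIL + 3 mm cropped to the prostate, PTV68 = CTV68 + 2 mm.
#'
#' Structure volumes left as `NA` are drawn per phantom (seeded) from normal
#' distributions truncated at 2.5 SD: prostate 42.3 (15.7) cc and rectum
#' 69.3 (19.7) cc, matching a dose-escalated prostate radiotherapy cohort;
#' bladder 180 (40) cc. Boost lesion volumes are log-normal with median
#' 3.1 cc, truncated to 1-9 cc, and placed in posterior-weighted
#' peripheral-zone sectors.
#'
#' Array axes are (x, y, z): x = left-right, y = anterior to posterior
#' (the rectum lies at high y), z = cranio-caudal.
#'
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec (including this seed).
#' @param grid_shape Integer vector (nx, ny, nz) of grid voxels.
#' @param spacing_mm Numeric vector of voxel spacings in mm.
#' @param prostate_volume_cc,rectum_volume_cc,bladder_volume_cc Structure
#'   volumes in cc, or `NA` to draw them from the cohort distributions.
#' @param boost_positions Six angular placements (degrees) of the boost
#'   lesions in the axial plane, 0 = directly posterior (towards the rectum).
#' @param margin_ptv60_mm,margin_ptv53_mm,margin_ctv68_mm,margin_ptv68_mm
#'   Geometric expansion margins in mm.
#' @return A `phantom_spec` object (a validated list).
#' @export
phantom_spec <- function(seed = 1L,
                         grid_shape = c(48L, 48L, 28L),
                         spacing_mm = c(4, 4, 7),
                         prostate_volume_cc = NA_real_,
                         rectum_volume_cc = NA_real_,
                         bladder_volume_cc = NA_real_,
                         boost_positions = c(-100, -60, -20, 20, 60, 100),
                         margin_ptv60_mm = 5,
                         margin_ptv53_mm = 9,
                         margin_ctv68_mm = 3,
                         margin_ptv68_mm = 2) {
  if (length(boost_positions) != 6L) {
    abort("`boost_positions` must contain exactly 6 angular placements.")
  }
  if (!is.numeric(grid_shape) || length(grid_shape) != 3L || any(grid_shape < 8)) {
    abort("`grid_shape` must be 3 positive integers (>= 8 voxels per axis).")
  }
  spacing_mm <- check_spacing(spacing_mm)
  vols <- c(prostate = prostate_volume_cc, rectum = rectum_volume_cc,
            bladder = bladder_volume_cc)
  bad <- !is.na(vols) & vols <= 0
  if (any(bad)) {
    abort(paste0("Structure volumes must be positive; offending: ",
                 paste(names(vols)[bad], collapse = ", "), "."))
  }
  margins <- c(margin_ptv60_mm, margin_ptv53_mm, margin_ctv68_mm, margin_ptv68_mm)
  if (any(margins < 0)) abort("Expansion margins must be non-negative.")
  structure(
    list(
      seed = as.integer(seed),
      grid_shape = as.integer(grid_shape),
      spacing_mm = spacing_mm,
      prostate_volume_cc = prostate_volume_cc,
      rectum_volume_cc = rectum_volume_cc,
      bladder_volume_cc = bladder_volume_cc,
      boost_positions = as.numeric(boost_positions),
      margin_ptv60_mm = margin_ptv60_mm,
      margin_ptv53_mm = margin_ptv53_mm,
      margin_ctv68_mm = margin_ctv68_mm,
      margin_ptv68_mm = margin_ptv68_mm
    ),
    class = "phantom_spec"
  )
}

boundary_check <- function(mask, name) {
  d <- dim(mask)
  touches <- any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
  if (touches) {
    abort(paste0("Grid too small: structure '", name,
                 "' reaches the grid boundary; enlarge `grid_shape` or reduce volumes."))
  }
  invisible(TRUE)
}

#' Generate a synthetic pelvic phantom
#'
#' Builds the voxelised anatomy described by a [phantom_spec()]: binary masks
#' for the prostate proxy, PTV60, PTV53 (seminal-vesicle proxy included),
#' rectum, bladder, and the six boosted targets PTV68-A..F. Deterministic for
#' a fixed spec; two calls with the same spec give voxel-identical masks.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` object: masks, the six PTV68 variants, realised
#'   volumes, grid metadata and per-phantom planning style parameters.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$spacing_mm
  ext <- dims * sp
  with_seed(spec$seed, {
    v_pro <- if (is.na(spec$prostate_volume_cc)) {
      rnorm_trunc(1, 42.3, 15.7, lower = 15)
    } else spec$prostate_volume_cc
    v_rec <- if (is.na(spec$rectum_volume_cc)) {
      rnorm_trunc(1, 69.3, 19.7, lower = 25)
    } else spec$rectum_volume_cc
    v_bla <- if (is.na(spec$bladder_volume_cc)) {
      rnorm_trunc(1, 150, 35, lower = 70)
    } else spec$bladder_volume_cc
    gap_mm <- runif(1, 0.5, 4.5)          # prostate-to-rectum separation
    rect_len <- runif(1, 56, 70)          # cranio-caudal rectal extent (mm)
    rect_wiggle <- runif(1, 0, 4)         # lateral meander amplitude (mm)
    jitter <- runif(6, -8, 8)             # per-boost angular jitter (deg)
    dil_vol <- pmin(pmax(exp(rnorm(6, log(3.1), 0.5)), 1.0), 9.0)
    dil_zoff <- runif(6, -0.25, 0.25)
    sparing_weight <- runif(1, 0.25, 0.40)

    # prostate ellipsoid, slightly anterior of grid centre; continuous
    # distance fields keep the millimetre expansion margins exact on the
    # coarse voxel grid
    ratios <- c(1, 0.85, 0.95) * exp(rnorm(3, 0, 0.04))
    r0 <- (3 * v_pro * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
    semi_p <- r0 * ratios
    ctr_p <- c(ext[1] / 2, ext[2] / 2 - 0.12 * ext[2], ext[3] / 2)
    phi_p <- radial_dist_field(dims, sp, ctr_p, semi_p)
    prostate <- phi_p <= 0

    # seminal-vesicle proxy: two superior-posterior lobes
    ves_ctr1 <- ctr_p + c(-0.55 * semi_p[1], 0.45 * semi_p[2], semi_p[3] + 2)
    ves_ctr2 <- ctr_p + c(0.55 * semi_p[1], 0.45 * semi_p[2], semi_p[3] + 2)
    ves_semi <- c(9, 7, 10)
    phi_53 <- pmin(phi_p,
                   radial_dist_field(dims, sp, ves_ctr1, ves_semi),
                   radial_dist_field(dims, sp, ves_ctr2, ves_semi))
    vesicles <- (phi_53 <= 0) & !prostate

    # rectum: meandering, gently tapered tube posterior to the prostate
    rect_r0 <- sqrt(v_rec * 1000 / (pi * rect_len))
    cc <- coords_mm(dims, sp)
    rectum <- array(FALSE, dims)
    z_lo <- ctr_p[3] - rect_len / 2
    z_hi <- ctr_p[3] + rect_len / 2
    y_front <- ctr_p[2] + semi_p[2] + gap_mm
    for (iz in seq_len(dims[3])) {
      zc <- cc$z[iz]
      if (zc < z_lo || zc > z_hi) next
      u <- (zc - ctr_p[3]) / (rect_len / 2)   # -1..1 along the tube
      rr <- rect_r0 * (1 - 0.18 * u^2)        # taper towards both ends
      cx <- ctr_p[1] + rect_wiggle * sin(pi * u)
      cyl <- y_front + rr
      slab <- outer((cc$x - cx)^2, (cc$y - cyl)^2, "+") <= rr^2
      rectum[, , iz] <- slab
    }
    # one-shot radius correction for taper + voxelisation
    v_real <- mask_volume_cc(rectum, sp)
    if (v_real > 0 && abs(v_real - v_rec) / v_rec > 0.02) {
      scale <- sqrt(v_rec / v_real)
      for (iz in seq_len(dims[3])) {
        zc <- cc$z[iz]
        if (zc < z_lo || zc > z_hi) next
        u <- (zc - ctr_p[3]) / (rect_len / 2)
        rr <- scale * rect_r0 * (1 - 0.18 * u^2)
        cx <- ctr_p[1] + rect_wiggle * sin(pi * u)
        cyl <- y_front + rr
        rectum[, , iz] <- outer((cc$x - cx)^2, (cc$y - cyl)^2, "+") <= rr^2
      }
    }

    # bladder: anterior-superior ellipsoid, carved away from prostate/rectum
    br <- (3 * v_bla * 1000 / (4 * pi * 0.9 * 0.75))^(1 / 3)
    semi_b <- br * c(1, 0.9, 0.75)
    ctr_b <- c(ctr_p[1], ctr_p[2] - 0.35 * semi_p[2] - 0.35 * semi_b[2],
               ctr_p[3] + semi_p[3] + 0.6 * semi_b[3])
    bladder <- ellipsoid_mask(dims, sp, ctr_b, semi_b) & !prostate & !rectum

    ctv53 <- prostate | vesicles
    ptv60 <- phi_p <= spec$margin_ptv60_mm
    ptv53 <- phi_53 <= spec$margin_ptv53_mm

    # six boost lesions in the peripheral zone -> CTV68 -> PTV68-A..F.
    # CTV68 = DIL + 3 mm cropped to the gland; PTV68 adds 2 mm (the margins
    # are composed on the continuous fields: the outer margin applies to
    # both the lesion and the gland-crop boundary).
    angles <- (spec$boost_positions + jitter) * pi / 180
    ptv68 <- vector("list", 6)
    for (k in 1:6) {
      dv <- min(dil_vol[k], 0.25 * v_pro)
      rd <- (3 * dv * 1000 / (4 * pi))^(1 / 3)
      # peripheral placement, pulled inward enough that the lesion stays
      # mostly inside the gland (larger lesions sit more centrally)
      f_in <- min(0.7, max(0.3, 1 - (rd + 2) / mean(semi_p[1:2])))
      ctr_d <- c(
        ctr_p[1] + f_in * semi_p[1] * sin(angles[k]),
        ctr_p[2] + f_in * semi_p[2] * cos(angles[k]),
        ctr_p[3] + dil_zoff[k] * semi_p[3]
      )
      phi_d <- sqrt(outer(outer((cc$x - ctr_d[1])^2, (cc$y - ctr_d[2])^2, "+"),
                          (cc$z - ctr_d[3])^2, "+")) - rd
      ctv68 <- (phi_d <= spec$margin_ctv68_mm) & prostate
      if (!any(ctv68)) abort("Degenerate boost lesion: CTV68 empty after cropping.")
      ptv68[[k]] <- (phi_d <= spec$margin_ctv68_mm + spec$margin_ptv68_mm) &
        (phi_p <= spec$margin_ptv68_mm)
    }
    names(ptv68) <- paste0("ptv68_", LETTERS[1:6])

    for (nm in c("ptv53", "ptv60", "rectum", "bladder")) {
      boundary_check(get(nm), nm)
    }
    for (k in 1:6) boundary_check(ptv68[[k]], names(ptv68)[k])

    structure(
      list(
        spec = spec,
        dims = dims,
        spacing_mm = sp,
        origin_mm = c(0, 0, 0),
        masks = list(
          prostate = prostate, ctv53 = ctv53,
          ptv60 = ptv60, ptv53 = ptv53,
          rectum = rectum, bladder = bladder
        ),
        ptv68 = ptv68,
        volumes_cc = c(
          prostate = mask_volume_cc(prostate, sp),
          rectum = mask_volume_cc(rectum, sp),
          bladder = mask_volume_cc(bladder, sp),
          setNames(vapply(ptv68, mask_volume_cc, numeric(1), spacing_mm = sp),
                   names(ptv68))
        ),
        planning = list(gap_mm = gap_mm, sparing_weight = sparing_weight)
      ),
      class = "phantom"
    )
  })
}

#' Extract the five-structure set for one boost variant
#'
#' @param phantom A [generate_phantom()] result.
#' @param boost_index Which PTV68 variant to use, 1-6 (A-F).
#' @return A `structure_set`: named masks `ptv68`, `ptv60`, `ptv53`,
#'   `rectum`, `bladder` on the phantom grid.
#' @export
structure_set <- function(phantom, boost_index = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  boost_index <- as.integer(boost_index)
  if (boost_index < 1L || boost_index > 6L) {
    abort("`boost_index` must be between 1 and 6 (PTV68-A..F).")
  }
  ss <- structure(
    list(
      masks = list(
        ptv68 = phantom$ptv68[[boost_index]],
        ptv60 = phantom$masks$ptv60,
        ptv53 = phantom$masks$ptv53,
        rectum = phantom$masks$rectum,
        bladder = phantom$masks$bladder
      ),
      spacing_mm = phantom$spacing_mm,
      origin_mm = phantom$origin_mm,
      boost_index = boost_index
    ),
    class = "structure_set"
  )
  validate_structure_set(ss)
  ss
}

validate_structure_set <- function(ss) {
  stopifnot(inherits(ss, "structure_set"))
  need <- c("ptv68", "ptv60", "ptv53", "rectum", "bladder")
  if (!all(need %in% names(ss$masks))) {
    abort(paste0("structure_set must contain masks: ", paste(need, collapse = ", ")))
  }
  dims <- dim(ss$masks[[1]])
  for (nm in need) {
    m <- ss$masks[[nm]]
    if (!identical(dim(m), dims)) abort(paste0("Mask '", nm, "' is on a different grid."))
    if (!any(m)) abort(paste0("Mask '", nm, "' is empty."))
  }
  ov <- sum(ss$masks$rectum & ss$masks$ptv68) / sum(ss$masks$rectum)
  if (ov >= 0.2) {
    abort("Implausible anatomy: rectum/PTV68 overlap exceeds 20% of the rectum.")
  }
  invisible(ss)
}

#' A scalar dose field on a voxel grid
#'
#' @param dose_gy Non-negative numeric 3D array of dose in Gy.
#' @param spacing_mm Voxel spacing in mm.
#' @param origin_mm Grid origin in mm.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(dose_gy, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(dose_gy) || length(dim(dose_gy)) != 3L) {
    abort("`dose_gy` must be a 3D array.")
  }
  if (any(!is.finite(dose_gy)) || any(dose_gy < 0)) {
    abort("Dose must be finite and non-negative everywhere.")
  }
  structure(
    list(dose_gy = dose_gy, spacing_mm = check_spacing(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "dose_grid"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> grid", paste(x$dims, collapse = "x"),
      "@", paste(x$spacing_mm, collapse = "x"), "mm\n")
  v <- x$volumes_cc
  cat(sprintf("  prostate %.1f cc | rectum %.1f cc | bladder %.1f cc\n",
              v["prostate"], v["rectum"], v["bladder"]))
  cat(sprintf("  PTV68 A-F: %s cc\n",
              paste(sprintf("%.1f", v[grep("ptv68", names(v))]), collapse = ", ")))
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid>", paste(dim(x$dose_gy), collapse = "x"),
      sprintf("max %.1f Gy, mean %.1f Gy\n", max(x$dose_gy), mean(x$dose_gy)))
  invisible(x)
}
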