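# Session-cached small fixtures: phantoms and plans are deterministic given
# their seed, so they are built once and reused across tests.
.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function(seed = 11) {
  key <- paste0("ph", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_phantom(phantom_spec(seed = seed))
  }
  .fixtures[[key]]
}

fixture_plan <- function(seed = 11, boost = 1) {
  key <- paste0("plan", seed, "_", boost)
  if (is.null(.fixtures[[key]])) {
    ph <- fixture_phantom(seed)
    .fixtures[[key]] <- list(
      phantom = ph,
      anatomy = structure_set(ph, boost),
      dose = simulate_plan_dose(ph, boost)
    )
  }
  .fixtures[[key]]
}

# Hand-built anatomy with rectangular structures and known centres of mass,
# for crop bookkeeping tests.
block_anatomy <- function(dims = c(24L, 24L, 12L), spacing = c(4, 4, 5),
                          rect_y = 14:18) {
  blank <- array(FALSE, dims)
  mk <- function(xs, ys, zs) {
    m <- blank
    m[xs, ys, zs] <- TRUE
    m
  }
  structure(
    list(
      masks = list(
        ptv68 = mk(11:12, 10:11, 6:7),
        ptv60 = mk(9:14, 8:12, 5:8),
        ptv53 = mk(8:15, 7:13, 4:9),
        rectum = mk(10:13, rect_y, 3:10),
        bladder = mk(9:14, 4:6, 7:10)
      ),
      spacing_mm = spacing, origin_mm = c(0, 0, 0), boost_index = 1L
    ),
    class = "structure_set"
  )
}

# Two-level dose: half the mask voxels at `lo`, half at `hi`.
two_level_dose <- function(lo = 20, hi = 60, n_half = 100) {
  dims <- c(10L, 10L, 4L)
  mask <- array(FALSE, dims)
  mask[seq_len(2 * n_half)] <- TRUE
  dose <- array(0, dims)
  dose[seq_len(n_half)] <- lo
  dose[n_half + seq_len(n_half)] <- hi
  list(dose = dose, mask = mask)
}

# Uniform-dose DVH at a single dose level.
uniform_dvh <- function(dose_gy = 70, bin = 0.1) {
  dims <- c(6L, 6L, 3L)
  mask <- array(TRUE, dims)
  compute_dvh(array(dose_gy, dims), mask, bin_width_gy = bin)
}
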