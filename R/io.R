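#' Export a plan (masks + dose) as NIfTI with a YAML sidecar
#'
#' Writes one NIfTI volume per structure mask, one for the dose, and a
#' `plan.yaml` sidecar carrying the phantom spec, seed, boost index and
#' (optionally) the ground-truth plan label.
#'
#' @param anatomy A `structure_set`.
#' @param dose A [dose_grid()] on the same grid (or `NULL`).
#' @param dir Output directory (created if missing).
#' @param label Optional one-row label tibble from [label_plan()].
#' @param spec Optional [phantom_spec()] echoed into the sidecar.
#' @return `dir`, invisibly.
#' @export
export_plan_nifti <- function(anatomy, dose = NULL, dir, label = NULL, spec = NULL) {
  stopifnot(inherits(anatomy, "structure_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write1 <- function(arr, name) {
    img <- RNifti::asNifti(arr * 1.0)
    RNifti::pixdim(img) <- anatomy$spacing_mm
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  for (nm in names(anatomy$masks)) write1(anatomy$masks[[nm]], nm)
  if (!is.null(dose)) {
    assert_same_grid(dim(dose$dose_gy), dose$spacing_mm,
                     dim(anatomy$masks$rectum), anatomy$spacing_mm)
    write1(dose$dose_gy, "dose")
  }
  side <- list(
    spacing_mm = as.numeric(anatomy$spacing_mm),
    origin_mm = as.numeric(anatomy$origin_mm),
    boost_index = anatomy$boost_index
  )
  if (!is.null(spec)) side$spec <- unclass(spec)
  if (!is.null(label)) side$label <- as.list(label)
  yaml::write_yaml(side, file.path(dir, "plan.yaml"))
  invisible(dir)
}

#' Read a plan exported by [export_plan_nifti()]
#'
#' @param dir Directory holding the NIfTI files and `plan.yaml`.
#' @return A list `anatomy` (`structure_set`), `dose` ([dose_grid()] or
#'   `NULL`) and `meta` (the sidecar contents).
#' @export
read_plan_nifti <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "plan.yaml"))
  sp <- as.numeric(meta$spacing_mm)
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) return(NULL)
    arr <- as.array(RNifti::readNifti(f))
    array(arr, dim = dim(arr))
  }
  masks <- lapply(c(ptv68 = "ptv68", ptv60 = "ptv60", ptv53 = "ptv53",
                    rectum = "rectum", bladder = "bladder"), function(n) rd(n) > 0.5)
  ss <- structure(
    list(masks = masks, spacing_mm = sp,
         origin_mm = as.numeric(meta$origin_mm %||% c(0, 0, 0)),
         boost_index = meta$boost_index %||% NA_integer_),
    class = "structure_set"
  )
  validate_structure_set(ss)
  darr <- rd("dose")
  list(anatomy = ss,
       dose = if (!is.null(darr)) dose_grid(darr, sp, ss$origin_mm),
       meta = meta)
}

#' Export a cropped model input as a multi-channel NIfTI
#'
#' Writes the five structure channels (and the cropped dose, when present)
#' as 4D NIfTI volumes, plus a JSON sidecar recording the channel order,
#' crop offset, source grid and (optionally) the normalization constant.
#'
#' @param input A `model_input` from [crop_to_input()].
#' @param dir Output directory (created if missing).
#' @param norm_const Optional [normalization_constant()] echoed into the
#'   metadata.
#' @return `dir`, invisibly.
#' @export
export_model_input <- function(input, dir, norm_const = NULL) {
  stopifnot(inherits(input, "model_input"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- simplify2array(lapply(input$channels, function(m) m * 1.0))
  img <- RNifti::asNifti(ch)
  RNifti::pixdim(img) <- c(input$spacing_mm, 1)
  RNifti::writeNifti(img, file.path(dir, "channels.nii.gz"))
  if (!is.null(input$dose)) {
    dimg <- RNifti::asNifti(input$dose)
    RNifti::pixdim(dimg) <- input$spacing_mm
    RNifti::writeNifti(dimg, file.path(dir, "dose.nii.gz"))
  }
  meta <- list(channel_order = names(input$channels),
               crop_offset = as.integer(input$crop_offset),
               source_dim = as.integer(input$source_dim),
               spacing_mm = as.numeric(input$spacing_mm))
  if (!is.null(norm_const)) meta$normalization <- unclass(norm_const)
  jsonlite::write_json(meta, file.path(dir, "input_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint bundles weights, network configuration, the normalization
#' constant and the training manifest, so a loaded model can predict
#' immediately on compatible inputs.
#'
#' @param model A `trained_model`.
#' @param path File path (`.rds`).
#' @return `path` invisibly (save); a `trained_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model")) abort("File does not contain a trained model.")
  m
}
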