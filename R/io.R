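#' Write / read a voxel phantom as NIfTI with a JSON sidecar
#'
#' The label volume is written as an integer-coded NIfTI image (spacing in
#' the header, mm) plus a JSON sidecar mapping codes to tissue ids and
#' carrying the generator parameters; the HTV mask is stored as a second
#' NIfTI volume (`*_htv.nii.gz`). The GTV mask is recoverable from the label
#' volume itself.
#'
#' @param phantom a `voxel_phantom` (3D).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (isTRUE(phantom$is_2d)) stop("only 3D phantoms are persisted as NIfTI")
  codes <- stats::setNames(seq_along(phantom_label_set()), phantom_label_set())
  lab <- phantom$labels
  img <- array(0L, dim = dim(lab))
  keep <- !is.na(lab)
  img[keep] <- codes[lab[keep]]
  sp <- phantom$spacing_mm
  attr(img, "pixdim") <- c(sp, sp, sp)
  attr(img, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "int16"), path)
  htv <- array(as.integer(phantom$htv_mask), dim = dim(phantom$htv_mask))
  attr(htv, "pixdim") <- c(sp, sp, sp)
  attr(htv, "pixunits") <- "mm"
  base <- sub("\\.nii(\\.gz)?$", "", path)
  RNifti::writeNifti(RNifti::asNifti(htv, datatype = "int16"),
                     paste0(base, "_htv.nii.gz"))
  sidecar <- list(
    codes = as.list(codes),
    spacing_mm = sp,
    origin_mm = phantom$origin_mm,
    gtv_center_mm = phantom$gtv_center_mm,
    seed = phantom$seed,
    params = unclass(phantom$params)
  )
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  sidecar <- jsonlite::fromJSON(paste0(base, ".json"))
  img <- as.array(RNifti::readNifti(path))
  codes <- unlist(sidecar$codes)
  lab <- array(NA_character_, dim = dim(img))
  keep <- img > 0
  lab[keep] <- names(codes)[match(img[keep], codes)]
  htv <- as.array(RNifti::readNifti(paste0(base, "_htv.nii.gz"))) > 0
  params <- do.call(phantom_params, sidecar$params[
    intersect(names(sidecar$params), names(formals(phantom_params)))])
  structure(list(
    labels = lab,
    gtv_mask = !is.na(lab) & lab == "gtv",
    htv_mask = htv,
    spacing_mm = sidecar$spacing_mm,
    origin_mm = sidecar$origin_mm,
    gtv_center_mm = sidecar$gtv_center_mm,
    params = params, seed = sidecar$seed
  ), class = "voxel_phantom")
}

#' Load an experiment configuration from YAML
#'
#' Recognized blocks: `phantom:` ([phantom_params()] fields), `solver:`
#' ([solver_settings()] fields plus optional applicator fields `n_channels`,
#' `bolus_radius_mm`, `source_radius_mm`), `swarm:` ([swarm_config()] fields),
#' and `study:` (`sites`, `sizes`, `schemes`, `seed`, `drive`, `output_dir`).
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, fn) {
    args <- y[[block]]
    if (is.null(args)) return(fn())
    do.call(fn, args[intersect(names(args), names(formals(fn)))])
  }
  phantom <- take("phantom", phantom_params)
  solver <- take("solver", solver_settings)
  swarm <- take("swarm", swarm_config)
  app_args <- y$solver[intersect(names(y$solver),
                                 names(formals(applicator_model)))]
  applicator <- do.call(applicator_model, if (is.null(app_args)) list() else app_args)
  st <- y$study
  experiment_config(
    phantom = phantom,
    sites = st$sites %||% "cervix",
    sizes = st$sizes %||% c("small", "medium", "large"),
    schemes = st$schemes %||% .scheme_names,
    solver = solver, applicator = applicator, swarm = swarm,
    seed = st$seed %||% 1L,
    drive = st$drive %||% "pso",
    output_dir = st$output_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
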