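#' @useDynLib sarsense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef quantile runif sd median
#' @importFrom utils write.csv head
"_PACKAGE"

# Tissue ids whose dielectric/density values are looked up under another id.
# Subcutaneous (SAT) and visceral fat are distinct anatomical labels but share
# the fat properties in every segmentation scheme.
.property_aliases <- c(
  sat          = "fat",
  visceral_fat = "fat"
)

.scheme_names <- c(
  "detailed", "clinical", "bone_type", "bladder",
  "intestine", "bladder_and_intestine", "combined"
)

# Water-content classification used by the reduction rules: low-water tissues
# take fat properties, bone compartments collapse to cortical bone, everything
# else (organs, lumina, urine) is muscle-equivalent. GTV is always preserved.
.low_water_labels  <- c("fat", "sat", "visceral_fat")
.bone_labels       <- c("bone_cortical", "bone_marrow", "bone_cancellous")
.high_water_labels <- c(
  "muscle", "small_intestine_wall", "small_intestine_lumen",
  "large_intestine_wall", "large_intestine_lumen", "bladder_wall", "urine"
)

#' Load a tissue dielectric property table
#'
#' Reads a JSON list of records with fields `tissue_id`, `eps_r` (relative
#' permittivity), `sigma_eff` (effective conductivity, S/m) and `rho` (mass
#' density, kg/m3), all given at the 100 MHz operating frequency.
#'
#' @param path Path to a JSON property table. Defaults to the table shipped
#'   with the package (14 tissues including water bolus and applicator shell).
#' @return A `data.frame` of class `tissue_table` with one row per tissue.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_properties.json", package = "sarsense")
  }
  if (!file.exists(path)) stop("property table not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  required <- c("tissue_id", "eps_r", "sigma_eff", "rho")
  missing <- setdiff(required, names(recs))
  if (length(missing) > 0) {
    stop("property table is missing field(s): ", paste(missing, collapse = ", "))
  }
  tab <- as.data.frame(recs)[required]
  validate_tissue_table(tab)
}

#' @rdname load_property_table
#' @export
default_tissue_table <- function() load_property_table(NULL)

validate_tissue_table <- function(tab) {
  for (i in seq_len(nrow(tab))) {
    id <- tab$tissue_id[i]
    vals <- c(tab$eps_r[i], tab$sigma_eff[i], tab$rho[i])
    if (any(!is.finite(vals))) {
      stop("non-finite property for tissue '", id, "'")
    }
    if (tab$rho[i] <= 0) stop("non-positive density for tissue '", id, "'")
    if (tab$sigma_eff[i] < 0) stop("negative conductivity for tissue '", id, "'")
    # eps_r >= 1 for biological tissue and water; the applicator shell (a
    # thin casing material) is exempted by convention but still must be > 0
    if (tab$eps_r[i] <= 0) stop("non-positive permittivity for tissue '", id, "'")
    if (tab$eps_r[i] < 1 && id != "applicator_shell") {
      stop("relative permittivity < 1 for tissue '", id, "'")
    }
  }
  if (anyDuplicated(tab$tissue_id)) stop("duplicate tissue_id in property table")
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Resolve tissue properties for a set of labels
#'
#' Maps each label to its property row, applying the SAT/visceral-fat alias
#' (both carry fat dielectric properties).
#'
#' @param tissue_ids character vector of labels.
#' @param table a `tissue_table`.
#' @return data.frame with columns tissue_id, eps_r, sigma_eff, rho (one row
#'   per input label, in input order).
#' @export
resolve_properties <- function(tissue_ids, table = default_tissue_table()) {
  keys <- ifelse(tissue_ids %in% names(.property_aliases),
                 .property_aliases[tissue_ids], tissue_ids)
  idx <- match(keys, table$tissue_id)
  if (anyNA(idx)) {
    bad <- unique(tissue_ids[is.na(idx)])
    stop("no properties for tissue(s): ", paste(bad, collapse = ", "))
  }
  out <- table[idx, ]
  out$tissue_id <- tissue_ids
  rownames(out) <- NULL
  out
}

#' Build a segmentation-reduction scheme
#'
#' Constructs the total mapping from every detailed tissue label to the label
#' retained under a named segmentation scheme. The reduction rule assigns all
#' high-water tissues (organs, bladder wall, urine, intestine walls and
#' lumina) to muscle, low-water tissues (SAT, visceral fat) to fat, and all
#' bone compartments to cortical bone; each scheme then re-instates the labels
#' it delineates. The GTV maps to itself in every scheme.
#'
#' @param name one of `"detailed"`, `"clinical"`, `"bone_type"`, `"bladder"`,
#'   `"intestine"`, `"bladder_and_intestine"`, `"combined"`.
#' @param detailed_labels character vector: the phantom's detailed label set.
#' @param extra_classes optional named character vector classifying labels the
#'   built-in rule does not know, values in `c("high_water","low_water","bone")`.
#' @return An object of class `segmentation_scheme`: list with `name` and
#'   `mapping` (named character vector, detailed label -> retained label).
#' @export
build_scheme <- function(name, detailed_labels, extra_classes = NULL) {
  name <- match.arg(name, .scheme_names)
  detailed_labels <- unique(as.character(detailed_labels))

  if (name == "detailed") {
    mapping <- stats::setNames(detailed_labels, detailed_labels)
    return(new_scheme(name, mapping))
  }

  preserve <- switch(name,
    clinical  = character(0),
    bone_type = c("bone_marrow", "bone_cancellous"),
    bladder   = c("urine", "bladder_wall"),
    intestine = c("small_intestine_wall", "small_intestine_lumen",
                  "large_intestine_wall", "large_intestine_lumen"),
    bladder_and_intestine = c("urine", "bladder_wall",
                  "small_intestine_wall", "small_intestine_lumen",
                  "large_intestine_wall", "large_intestine_lumen"),
    combined  = c("bone_marrow", "bone_cancellous", "urine", "bladder_wall",
                  "small_intestine_wall", "small_intestine_lumen",
                  "large_intestine_wall", "large_intestine_lumen")
  )

  map_one <- function(lab) {
    if (lab == "gtv") return("gtv")
    if (lab %in% preserve) return(lab)
    if (lab %in% .low_water_labels) return("fat")
    if (lab %in% .bone_labels) return("bone_cortical")
    if (lab %in% .high_water_labels) return("muscle")
    if (!is.null(extra_classes) && lab %in% names(extra_classes)) {
      return(switch(extra_classes[[lab]],
        high_water = "muscle", low_water = "fat", bone = "bone_cortical",
        stop("unknown water class '", extra_classes[[lab]], "' for label '", lab, "'")))
    }
    stop("no reduction rule for detailed label '", lab,
         "'; supply its water class via extra_classes")
  }
  mapping <- vapply(detailed_labels, map_one, character(1))
  # close the mapping over its own image so scheme application is idempotent
  extra <- setdiff(unique(unname(mapping)), names(mapping))
  if (length(extra) > 0) {
    mapping <- c(mapping, stats::setNames(extra, extra))
  }
  new_scheme(name, mapping)
}

new_scheme <- function(name, mapping) {
  structure(list(name = name, mapping = mapping),
            class = "segmentation_scheme")
}

#' Apply a segmentation scheme to a label vector or array
#'
#' @param labels character vector/array of detailed tissue labels (NA allowed
#'   for unlabeled voxels).
#' @param scheme a `segmentation_scheme`.
#' @return labels after reduction, same shape.
#' @export
apply_scheme <- function(labels, scheme) {
  stopifnot(inherits(scheme, "segmentation_scheme"))
  dims <- dim(labels)
  lab <- as.character(labels)
  keep <- !is.na(lab)
  unmapped <- setdiff(unique(lab[keep]), names(scheme$mapping))
  if (length(unmapped) > 0) {
    stop("scheme '", scheme$name, "' has no mapping for label(s): ",
         paste(unmapped, collapse = ", "))
  }
  out <- lab
  out[keep] <- unname(scheme$mapping[lab[keep]])
  dim(out) <- dims
  out
}

#' Retained label set of a scheme
#' @param scheme a `segmentation_scheme`.
#' @return sorted character vector of retained tissue ids.
#' @export
retained_labels <- function(scheme) sort(unique(unname(scheme$mapping)))

#' Load a segmentation scheme from JSON
#'
#' JSON format: `{"name": ..., "mapping": {"detailed_id": "retained_id", ...}}`.
#' Seven defaults are shipped under `extdata/schemes/`.
#'
#' @param name_or_path a scheme name (loads the shipped default) or a path to
#'   a scheme JSON file.
#' @export
load_scheme <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    path <- system.file("extdata", "schemes", paste0(name_or_path, ".json"),
                        package = "sarsense")
    if (!nzchar(path)) stop("unknown scheme or missing file: ", name_or_path)
  }
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$name) || is.null(obj$mapping)) {
    stop("scheme JSON must have fields 'name' and 'mapping'")
  }
  new_scheme(obj$name, unlist(obj$mapping))
}

#' Validate a scheme against a label set and property table
#'
#' Checks the mapping is total over the label set, retained ids resolve in the
#' property table, and GTV maps to itself.
#' @param scheme a `segmentation_scheme`.
#' @param detailed_labels labels the mapping must cover.
#' @param table a `tissue_table`.
#' @export
validate_scheme <- function(scheme, detailed_labels,
                            table = default_tissue_table()) {
  missing <- setdiff(detailed_labels, names(scheme$mapping))
  if (length(missing) > 0) {
    stop("scheme '", scheme$name, "' not total; unmapped: ",
         paste(missing, collapse = ", "))
  }
  resolve_properties(retained_labels(scheme), table)  # errors if unresolvable
  if ("gtv" %in% names(scheme$mapping) && scheme$mapping[["gtv"]] != "gtv") {
    stop("scheme '", scheme$name, "' must preserve the GTV")
  }
  invisible(scheme)
}

#' Default detailed label set of the synthetic phantom
#' @return character vector of the 13 anatomical labels the generator emits.
#' @export
phantom_label_set <- function() {
  c("sat", "visceral_fat", "muscle",
    "bone_cortical", "bone_marrow", "bone_cancellous",
    "small_intestine_wall", "small_intestine_lumen",
    "large_intestine_wall", "large_intestine_lumen",
    "bladder_wall", "urine", "gtv")
}
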