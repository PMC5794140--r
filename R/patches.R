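#' Social-ecological patch classes and livelihood benefits
#'
#' The landscape is described through eight categories: six social-ecological
#' patches (bare soil, depression, field, forest, homestead, shrubland) plus
#' two plain land covers (water, urban land) that carry no benefit scores.
#' Fallow is deliberately absent: its land cover is too variable to separate
#' spectrally, so it is not a mappable category here. Integer codes are fixed
#' (1 = bare_soil ... 8 = urban, 0/NA = nodata) so serialized maps are stable.
#'
#' @return `patch_classes()` returns the eight class labels in code order;
#'   `social_patches()` the six patch labels (excluding water/urban);
#'   `benefit_labels()` the five livelihood benefits.
#' @examples
#' patch_classes()
#' patch_code("field")
#' patch_label(3L)
#' @export
patch_classes <- function() {
  c("bare_soil", "depression", "field", "forest",
    "homestead", "shrubland", "water", "urban")
}

#' @rdname patch_classes
#' @export
social_patches <- function() {
  setdiff(patch_classes(), c("water", "urban"))
}

#' @rdname patch_classes
#' @export
benefit_labels <- function() {
  c("annual_crops", "nutritional_diversity_medicinal",
    "material_assets_energy", "saving_insurance", "income")
}

#' Convert between patch labels and integer codes
#'
#' @param label character vector of patch class labels.
#' @param code integer vector of class codes (1-8); 0 and NA map to NA.
#' @return `patch_code()` returns integer codes; `patch_label()` labels.
#' @export
patch_code <- function(label) {
  i <- match(label, patch_classes())
  if (anyNA(i) && !anyNA(label)) {
    bad <- unique(label[is.na(i)])
    stop("unknown patch class label(s): ", paste(bad, collapse = ", "))
  }
  as.integer(i)
}

#' @rdname patch_code
#' @export
patch_label <- function(code) {
  code <- as.integer(code)
  code[code == 0L] <- NA_integer_
  if (any(!is.na(code) & (code < 1L | code > 8L))) {
    stop("patch codes must be in 0..8 (0/NA = nodata)")
  }
  patch_classes()[code]
}

# internal fast lookups
.CODE <- stats::setNames(seq_along(
  c("bare_soil", "depression", "field", "forest",
    "homestead", "shrubland", "water", "urban")),
  c("bare_soil", "depression", "field", "forest",
    "homestead", "shrubland", "water", "urban"))
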