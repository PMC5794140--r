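#' Published study-area landcover and accuracy table
#'
#' The landcover composition and 15 m relative accuracies reported for the
#' two provincial study areas the hybrid method was developed on, shipped
#' as a reference dataset. Overall relative accuracies were 74.4%
#' (area 1) and 77.8% (area 2); urban land carries no accuracy entry.
#'
#' @return data frame with per-class landcover percentages and relative
#'   accuracies for both study areas.
#' @export
study_landcover_table <- function() {
  utils::read.delim(system.file("extdata", "study_area_landcover.tsv",
                                package = "sepatch"))
}

#' Cover sum of the four reliably mapped patch types
#'
#' Depression, homestead, field and bare soil are the patches mapped with
#' 81-96% relative accuracy; their combined landcover share (about 70% of
#' study area 1 and 92% of study area 2) bounds how much of the landscape
#' the maps capture with high confidence.
#'
#' @param area study area, 1 or 2.
#' @param table landcover table (defaults to [study_landcover_table()]).
#' @return combined landcover percentage of the four core patches.
#' @export
core_patch_cover_sum <- function(area = 1, table = study_landcover_table()) {
  stopifnot(area %in% c(1, 2))
  col <- paste0("area", area, "_landcover_pct")
  core <- c("bare_soil", "depression", "field", "homestead")
  sum(table[[col]][table$class %in% core])
}
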