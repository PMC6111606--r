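# The five building classes of the national-survey taxonomy. Order matters:
# it is the column order of the district design matrix.
.categories <- c(
  "multi_floor", "multi_floor_independent",
  "low_floor", "low_floor_independent", "abandoned"
)

# Residential classes (abandoned stock never houses population).
.residential <- .categories[1:4]

# Merged two-class scheme used when the four-class fit is degenerate.
.merge_map <- c(
  multi_floor = "multi", multi_floor_independent = "multi",
  low_floor = "low", low_floor_independent = "low"
)

#' Building categories
#'
#' The five footprint classes used throughout the package: multi-floor and
#' low-floor buildings (large, >= 1600 m2 footprints), their "independent"
#' (small, >= 200 m2) counterparts, and abandoned buildings, which are never
#' counted as residential.
#'
#' @param residential_only If `TRUE`, drop `"abandoned"`.
#' @return Character vector of category names.
#' @export
building_categories <- function(residential_only = FALSE) {
  if (residential_only) .residential else .categories
}
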