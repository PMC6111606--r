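#' The 14-street Wuchang reference table
#'
#' The published per-street statistics for the Wuchang district worked
#' example: census population, merged-class residential areas (multi-floor
#' plus multi-floor-independent; low-floor plus low-floor-independent), and
#' the published estimated populations, fitting errors and corrected
#' coefficients. The area columns feed [fit_density_model()] directly as a
#' merged two-class aggregate; the remaining columns are reference values
#' for regression tests.
#'
#' @param reference If `FALSE`, return only the model inputs
#'   (`street_id`, `population`, `area_multi`, `area_low`).
#' @return A 14-row tibble.
#' @export
table3_fixture <- function(reference = TRUE) {
  path <- system.file("extdata", "wuchang_streets.csv", package = "popgrid")
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  d <- as_tibble(d)
  if (!reference) d <- d[, c("street_id", "population", "area_multi", "area_low")]
  d
}
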