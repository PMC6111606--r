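# Street-level method: per-community aggregates C1/C2, the community
# extraction-completeness rule (ratios R4 = C1/C2 and R5 = P/C1), the
# average community density P/C1, and 50-m disaggregation. Least squares is
# deliberately not used at this granularity: community samples are few and
# their area ranges narrow, so a per-community mean density is estimated
# instead.

# Membership rule for C1: residential, community-attributed,
# residential-quarter-attributed -- plus community-attributed buildings
# without an rq id in augmented communities.
community_member <- function(buildings, augmented_communities = character(0)) {
  res <- buildings$category %in% .residential & !is.na(buildings$community_id)
  base <- res & !is.na(buildings$rq_id)
  extra <- res & is.na(buildings$rq_id) &
    buildings$community_id %in% augmented_communities
  base | extra
}

#' Per-community area aggregates
#'
#' `C1` is the residential house area carrying residential-quarter
#' attribution (summed over the community's residential quarters); `C2` is
#' the total building area attributed to the community, abandoned stock
#' included.
#'
#' @param buildings Preprocessed building tibble.
#' @param census Community census tibble `(unit_id, population)`.
#' @return Tibble with one row per community: `community_id`, `street_id`,
#'   `P` (census persons), `C1`, `C2`, `augmented = FALSE`. Communities with
#'   census population but no buildings are flagged with a warning.
#' @export
aggregate_communities <- function(buildings, census) {
  b <- buildings[!is.na(buildings$community_id), , drop = FALSE]
  ids <- sort(unique(c(b$community_id, census$unit_id)))
  in_c1 <- community_member(b)
  agg <- purrr::map_dfr(ids, function(cid) {
    sel <- b$community_id == cid
    st <- unique(b$street_id[sel])
    st <- st[!is.na(st)]
    tibble(
      community_id = cid,
      street_id = if (length(st)) st[1] else NA_character_,
      C1 = sum(b$area[sel & in_c1]),
      C2 = sum(b$area[sel])
    )
  })
  agg <- left_join(agg, rename(census, community_id = "unit_id"), by = "community_id")
  agg <- rename(agg, P = "population")
  empty <- !is.na(agg$P) & agg$P > 0 & agg$C2 == 0
  if (any(empty)) {
    warn(paste0(
      "community(ies) with census population but no attributed buildings: ",
      paste(agg$community_id[empty], collapse = ", ")
    ))
  }
  agg$augmented <- FALSE
  agg[, c("community_id", "street_id", "P", "C1", "C2", "augmented")]
}

#' Extraction-completeness test for communities
#'
#' Extraction is incomplete exactly when `C1/C2 < t` **and** the implied
#' residential density `P/C1` exceeds `dmax` (one person per square metre by
#' default). `C1 = 0` counts as incomplete whenever the community has
#' population.
#'
#' @param agg Community aggregates from [aggregate_communities()].
#' @param t Area-ratio threshold (default 0.20).
#' @param dmax Density ceiling in persons/m2 (default 1).
#' @return `agg` with a logical `complete` column.
#' @export
extraction_complete_community <- function(agg, t = 0.20, dmax = 1.0) {
  if (any(agg$C2 == 0 & agg$C1 > 0)) abort("C2 = 0 with C1 > 0 is inconsistent")
  dens <- ifelse(agg$C1 > 0, agg$P / agg$C1, Inf)
  agg$complete <- !(agg$C1 / pmax(agg$C2, .Machine$double.xmin) < t & dens > dmax)
  agg$complete[agg$C1 == 0 & agg$P > 0] <- FALSE
  agg$complete[agg$C2 == 0] <- TRUE
  agg
}

#' Augment incomplete communities
#'
#' In communities failing the completeness test, buildings with community
#' attribution but no residential-quarter attribution are regarded as
#' residential and their areas added to `C1`.
#'
#' @param agg Community aggregates; `complete` computed if absent.
#' @param buildings The building tibble the aggregates came from.
#' @param t,dmax Thresholds forwarded to [extraction_complete_community()].
#' @return Updated aggregate tibble with `augmented` flags.
#' @export
augment_residential_community <- function(agg, buildings, t = 0.20, dmax = 1.0) {
  if (!"complete" %in% names(agg)) agg <- extraction_complete_community(agg, t, dmax)
  todo <- agg$community_id[!agg$complete]
  if (length(todo) == 0) return(agg)
  b <- buildings
  extra <- b$category %in% .residential & !is.na(b$community_id) &
    is.na(b$rq_id) & b$community_id %in% todo
  add <- vapply(todo, function(cid) sum(b$area[extra & b$community_id == cid]), numeric(1))
  k <- match(todo, agg$community_id)
  agg$C1[k] <- agg$C1[k] + add
  agg$augmented[k] <- TRUE
  agg
}

#' Community population densities
#'
#' The street-level model: `density = P / C1` persons per square metre of
#' residential house area.
#'
#' @param agg Community aggregates, augmented where required.
#' @return `agg` with a `density` column. Communities with population but no
#'   residential area after augmentation abort with an actionable error
#'   (spreading their population over `C2` would silently bias the grid).
#' @export
community_density <- function(agg) {
  bad <- agg$C1 == 0 & agg$P > 0
  if (any(bad)) {
    abort(paste0(
      "community(ies) with census population but zero residential area ",
      "after augmentation: ", paste(agg$community_id[bad], collapse = ", "),
      " -- check residential-quarter/community attribution"
    ))
  }
  agg$density <- ifelse(agg$C1 > 0, agg$P / agg$C1, 0)
  agg
}

#' Disaggregate community populations to a grid
#'
#' Each residential building contributes `density(community) * area`,
#' apportioned to cells by exact polygon-cell intersection-area fractions.
#' The buildings included are exactly those summed into `C1`, so per-community
#' grid sums equal the community censuses to float tolerance.
#'
#' @param buildings Preprocessed building tibble.
#' @param densities Community density tibble from [community_density()].
#' @param spec A [grid_spec()] (50 m cells by default in the pipeline);
#'   derived from the building extent when `NULL`.
#' @param cell_size Used only when `spec` is `NULL`.
#' @return A [pop_grid()].
#' @export
disaggregate_street <- function(buildings, densities, spec = NULL, cell_size = 50) {
  if (is.null(spec)) spec <- grid_from_extent(buildings$geometry, cell_size)
  if (!"density" %in% names(densities)) abort("run community_density() first")
  aug <- densities$community_id[densities$augmented]
  sel <- community_member(buildings, augmented_communities = aug)
  b <- buildings[sel, , drop = FALSE]
  missing <- setdiff(unique(b$community_id), densities$community_id)
  if (length(missing)) {
    abort(paste0(
      "building(s) in community(ies) without a census/density: ",
      paste(missing, collapse = ", ")
    ))
  }
  b <- left_join(b, densities[, c("community_id", "density")], by = "community_id")
  pop_grid(spec, apportion_to_grid(b$geometry, b$density * b$area, spec))
}

#' Grid occupancy histogram
#'
#' Bins the per-cell populations of a grid into the standard report bins
#' (0, (0,25], (25,50], (50,100], ..., >1200 by default) and reports counts
#' and proportions summing to the number of cells and 100%.
#'
#' @param grid A [pop_grid()].
#' @param breaks Increasing positive break points; bins are `0`,
#'   `(0, b1]`, `(b1, b2]`, ..., `> b_last`.
#' @return Tibble `(bin, count, proportion_pct)`.
#' @export
grid_occupancy <- function(grid, breaks = c(25, 50, 100, 150, 200, 300, 450, 700, 1200)) {
  v <- as.numeric(grid$values)
  labs <- c(
    "0",
    paste0("(", c(0, head(breaks, -1)), ",", breaks, "]"),
    paste0(">", tail(breaks, 1))
  )
  idx <- findInterval(v, c(0, breaks), left.open = TRUE) + 1L
  idx[v == 0] <- 1L
  counts <- tabulate(idx, nbins = length(labs))
  tibble(
    bin = factor(labs, levels = labs),
    count = counts,
    proportion_pct = counts / length(v) * 100
  )
}
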