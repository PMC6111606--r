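# Attribute assignment: delete buildings in non-residential quarters, then
# attach residential-quarter, community and street attributions by spatial
# relation. "Belonging to" a unit polygon is decided by majority intersection
# area (>= 50% of the building's footprint area); when every intersection is
# exactly zero the building's representative point decides; otherwise the
# building stays unassigned at that level. Ties are broken by largest
# intersection area, then lowest unit id.

# For each building, the id of the owning unit under the majority-area rule,
# or NA. Units carry columns id, geometry.
assign_by_majority <- function(buildings, units) {
  if (nrow(units) == 0) return(rep(NA_character_, nrow(buildings)))
  ubb <- vapply(units$geometry, poly_bbox, numeric(4))
  ord <- order(units$id)
  vapply(seq_len(nrow(buildings)), function(b) {
    g <- buildings$geometry[[b]]
    bb <- poly_bbox(g)
    cand <- which(
      ubb[1, ] < bb["xmax"] & ubb[3, ] > bb["xmin"] &
        ubb[2, ] < bb["ymax"] & ubb[4, ] > bb["ymin"]
    )
    if (length(cand) == 0) return(NA_character_)
    inter <- vapply(cand, function(u) intersection_area(g, units$geometry[[u]]), numeric(1))
    ga <- poly_area(g)
    if (max(inter) == 0) {
      # degenerate overlap: fall back to the representative point
      pt <- poly_centroid(g)
      hit <- cand[vapply(cand, function(u) point_in_poly(pt, units$geometry[[u]]), logical(1))]
      if (length(hit) == 0) return(NA_character_)
      return(sort(units$id[hit])[1])
    }
    frac <- inter / ga
    best <- max(frac)
    if (best < 0.5 - 1e-9) return(NA_character_)
    winners <- cand[abs(frac - best) <= 1e-9]
    sort(units$id[winners])[1]
  }, character(1))
}

#' Delete buildings belonging to non-residential quarters
#'
#' A building is deleted when the majority of its footprint area lies inside
#' a non-residential-quarter unit (factories, institutions, companies).
#'
#' @param buildings Building tibble.
#' @param nrq_units Admin tibble of level `non_residential_quarter` (may be
#'   empty, in which case all buildings are retained).
#' @return List with `buildings` (retained rows) and `report`
#'   (`tibble(input, deleted, retained)`).
#' @export
drop_nonresidential <- function(buildings, nrq_units) {
  validate_buildings(buildings)
  owner <- if (is.null(nrq_units) || nrow(nrq_units) == 0) {
    rep(NA_character_, nrow(buildings))
  } else {
    assign_by_majority(buildings, nrq_units)
  }
  keep <- is.na(owner)
  list(
    buildings = buildings[keep, , drop = FALSE],
    report = tibble(
      input = nrow(buildings), deleted = sum(!keep), retained = sum(keep)
    )
  )
}

#' Attach residential-quarter attribution
#'
#' @param buildings Building tibble (after [drop_nonresidential()]).
#' @param rq_units Admin tibble of level `residential_quarter`.
#' @return List with `buildings` (with `rq_id` filled where assigned) and
#'   `report` (`tibble(assigned, unassigned)`).
#' @export
assign_residential_quarter <- function(buildings, rq_units) {
  owner <- assign_by_majority(buildings, rq_units)
  buildings$rq_id <- owner
  list(
    buildings = buildings,
    report = tibble(assigned = sum(!is.na(owner)), unassigned = sum(is.na(owner)))
  )
}

#' Attach community attribution
#'
#' Applied to all retained buildings, including those already carrying a
#' residential-quarter id.
#'
#' @param buildings Building tibble.
#' @param communities Admin tibble of level `community`.
#' @return List with `buildings` and `report`.
#' @export
assign_community <- function(buildings, communities) {
  owner <- assign_by_majority(buildings, communities)
  buildings$community_id <- owner
  list(
    buildings = buildings,
    report = tibble(assigned = sum(!is.na(owner)), unassigned = sum(is.na(owner)))
  )
}

#' Resolve each community to its street
#'
#' A community belongs to the street containing its representative point.
#'
#' @param communities Admin tibble of level `community`.
#' @param streets Admin tibble of level `street`.
#' @return `communities` with a `street_id` column.
#' @export
resolve_community_streets <- function(communities, streets) {
  communities$street_id <- vapply(communities$geometry, function(g) {
    pt <- poly_centroid(g)
    hit <- which(vapply(streets$geometry, function(sg) point_in_poly(pt, sg), logical(1)))
    if (length(hit) == 0) NA_character_ else sort(streets$id[hit])[1]
  }, character(1))
  communities
}

#' Attach street attribution
#'
#' Buildings with a community inherit that community's street (resolved via
#' the community's representative point); buildings without a community are
#' assigned directly by the majority-area rule against street polygons.
#' Buildings ending with no street are listed as unattributed and excluded
#' downstream.
#'
#' @param buildings Building tibble with community attribution done.
#' @param communities Admin tibble of level `community`.
#' @param streets Admin tibble of level `street`.
#' @return List with `buildings` and `report` (counts plus `unattributed`
#'   building ids).
#' @export
assign_street <- function(buildings, communities, streets) {
  communities <- resolve_community_streets(communities, streets)
  lut <- setNames(communities$street_id, communities$id)
  street <- rep(NA_character_, nrow(buildings))
  has_com <- !is.na(buildings$community_id)
  street[has_com] <- unname(lut[buildings$community_id[has_com]])
  direct <- which(is.na(street))
  if (length(direct)) {
    street[direct] <- assign_by_majority(buildings[direct, , drop = FALSE], streets)
  }
  buildings$street_id <- street
  list(
    buildings = buildings,
    report = tibble(
      via_community = sum(has_com & !is.na(street)),
      direct = sum(!has_com & !is.na(street)),
      unattributed = list(buildings$id[is.na(street)])
    )
  )
}

#' Full preprocessing chain
#'
#' Runs the four assignment steps in their fixed order: delete buildings in
#' non-residential quarters, attach residential-quarter ids, attach community
#' ids, attach street ids. Idempotent: re-running on its own output changes
#' nothing.
#'
#' @param buildings Raw building tibble.
#' @param nrq_units,rq_units,communities,streets Admin unit tibbles (the
#'   non-residential-quarter layer may be `NULL` or empty).
#' @return List with `buildings` (attributed, retained rows) and `report`, a
#'   one-row tibble combining the per-step counts with the list-column
#'   `unattributed`.
#' @export
preprocess_buildings <- function(buildings, nrq_units, rq_units, communities, streets) {
  s1 <- drop_nonresidential(buildings, nrq_units)
  s2 <- assign_residential_quarter(s1$buildings, rq_units)
  s3 <- assign_community(s2$buildings, communities)
  s4 <- assign_street(s3$buildings, communities, streets)
  report <- tibble(
    input = s1$report$input,
    deleted = s1$report$deleted,
    retained = s1$report$retained,
    rq_assigned = s2$report$assigned,
    community_assigned = s3$report$assigned,
    street_via_community = s4$report$via_community,
    street_direct = s4$report$direct,
    unattributed = s4$report$unattributed
  )
  stopifnot(report$deleted + report$retained == report$input)
  list(buildings = s4$buildings, report = report)
}
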