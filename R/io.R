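# Readers and writers for the vector and census formats the pipeline touches.
# Vector layers are GeoJSON FeatureCollections of simple polygons; all
# coordinates must be in one projected CRS in metres. Geographic (lon/lat)
# coordinates are rejected rather than silently reprojected, because the
# density models are driven by areas in m2.

check_projected <- function(geoms, what) {
  bb <- vapply(geoms, poly_bbox, numeric(4))
  if (max(abs(bb[c(1, 3), ])) <= 180 && max(abs(bb[c(2, 4), ])) <= 90) {
    abort(paste0(
      what, " coordinates look geographic (lon/lat); supply data in a ",
      "projected CRS in metres"
    ))
  }
  invisible(TRUE)
}

geojson_ring <- function(geom) {
  type <- geom$type %||% abort("feature has no geometry type")
  if (identical(type, "Polygon")) {
    rings <- geom$coordinates
  } else if (identical(type, "MultiPolygon")) {
    if (length(geom$coordinates) != 1) {
      abort("MultiPolygon features with more than one part are not supported")
    }
    rings <- geom$coordinates[[1]]
  } else {
    abort(paste0("unsupported geometry type: ", type))
  }
  if (length(rings) > 1) warn("polygon holes are ignored")
  ring <- rings[[1]]
  m <- do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2])))
  poly_matrix(m[, 1], m[, 2])
}

read_geojson_features <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("expected a GeoJSON FeatureCollection")
  }
  gj$features
}

write_geojson_features <- function(geoms, props, path) {
  features <- lapply(seq_along(geoms), function(k) {
    ring <- geoms[[k]]
    ring <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1], ring[r, 2]))
    pr <- lapply(props[k, , drop = FALSE], function(v) {
      v <- v[[1]]
      if (length(v) == 1 && is.na(v)) NULL else v
    })
    pr <- pr[!vapply(pr, is.null, logical(1))]
    list(
      type = "Feature",
      properties = pr,
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}

feature_prop <- function(f, name) {
  if (is.null(name)) return(NA)
  v <- f$properties[[name]]
  if (is.null(v)) NA else v
}

#' Read building footprints from GeoJSON
#'
#' Each feature becomes one footprint row. The survey's native attribute
#' names are mapped onto the package vocabulary through `field_map`; category
#' values may additionally be recoded with `category_codes`.
#'
#' @param path GeoJSON file of polygon features in a projected CRS (metres).
#' @param field_map Named list mapping roles to attribute names:
#'   `category` (required), and optionally `id`, `area`, `rq_id`,
#'   `community_id`, `street_id`. When no `area` field is mapped, the area is
#'   computed from the geometry.
#' @param category_codes Optional named character vector translating native
#'   category codes to the five values of [building_categories()].
#' @return A tibble with columns `id`, `geometry` (list of polygon matrices),
#'   `area`, `category`, `rq_id`, `community_id`, `street_id`.
#' @export
read_buildings <- function(path,
                           field_map = list(category = "category"),
                           category_codes = NULL) {
  feats <- read_geojson_features(path)
  if (length(feats) == 0) abort("no features in file")
  geoms <- lapply(feats, function(f) geojson_ring(f$geometry))
  check_projected(geoms, "building")
  get <- function(role) {
    vapply(feats, function(f) {
      v <- feature_prop(f, field_map[[role]])
      if (is.na(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  category <- get("category")
  if (!is.null(category_codes)) {
    known <- category %in% names(category_codes)
    category[known] <- unname(category_codes[category[known]])
  }
  bad <- !category %in% .categories
  if (any(bad)) {
    abort(paste0(
      "unmappable building category value(s): ",
      paste(unique(category[bad]), collapse = ", ")
    ))
  }
  id <- get("id")
  if (all(is.na(id))) id <- paste0("b", seq_along(feats))
  area <- if (!is.null(field_map$area)) {
    as.numeric(vapply(feats, function(f) as.numeric(feature_prop(f, field_map$area)), numeric(1)))
  } else {
    vapply(geoms, poly_area, numeric(1))
  }
  out <- tibble(
    id = id, geometry = geoms, area = area, category = category,
    rq_id = get("rq_id"), community_id = get("community_id"),
    street_id = get("street_id")
  )
  validate_buildings(out)
}

#' Validate a building footprint table
#'
#' Checks the container invariants: positive areas, known categories, unique
#' ids, polygon geometries.
#'
#' @param buildings Tibble as returned by [read_buildings()].
#' @return The input, invisibly usable in a pipe.
#' @export
validate_buildings <- function(buildings) {
  need <- c("id", "geometry", "area", "category", "rq_id", "community_id", "street_id")
  miss <- setdiff(need, names(buildings))
  if (length(miss)) abort(paste0("buildings table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(buildings$id)) abort("duplicate building ids")
  if (any(buildings$area <= 0)) abort("building areas must be positive")
  bad <- !buildings$category %in% .categories
  if (any(bad)) {
    abort(paste0("unknown building category: ", paste(unique(buildings$category[bad]), collapse = ", ")))
  }
  buildings
}

#' Write building footprints to GeoJSON
#'
#' Inverse of [read_buildings()] with the package's own field names; a
#' written city re-reads to the identical footprint set.
#'
#' @param buildings Building tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_buildings <- function(buildings, path) {
  validate_buildings(buildings)
  props <- buildings[, c("id", "area", "category", "rq_id", "community_id", "street_id")]
  write_geojson_features(buildings$geometry, props, path)
}

#' Read administrative / functional units from GeoJSON
#'
#' @param path GeoJSON file of polygon features in a projected CRS.
#' @param level One of `"street"`, `"community"`, `"residential_quarter"`,
#'   `"non_residential_quarter"`. Street and community units must carry a
#'   population attribute; the quarter levels must not.
#' @param field_map Named list with `id` (required), `population` (required
#'   for street/community), and for communities optionally `street_id`.
#' @return Tibble with columns `id`, `level`, `geometry`, `population` (and
#'   `street_id` for communities when mapped).
#' @export
read_admin_units <- function(path, level, field_map = list(id = "id", population = "population")) {
  level <- match.arg(level, c("street", "community", "residential_quarter", "non_residential_quarter"))
  feats <- read_geojson_features(path)
  if (length(feats) == 0) abort("no features in file")
  geoms <- lapply(feats, function(f) geojson_ring(f$geometry))
  check_projected(geoms, paste0(level, " unit"))
  id <- vapply(feats, function(f) as.character(feature_prop(f, field_map$id)), character(1))
  if (any(is.na(id))) abort("every unit needs an id")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate unit id: ", paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  out <- tibble(id = id, level = level, geometry = geoms)
  if (level %in% c("street", "community")) {
    if (is.null(field_map$population)) abort(paste0(level, " units need a population field"))
    pop <- vapply(feats, function(f) {
      v <- feature_prop(f, field_map$population)
      if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
    }, numeric(1))
    if (any(is.na(pop))) abort(paste0("missing population for ", level, " unit(s)"))
    if (any(pop < 0)) abort("populations must be non-negative")
    out$population <- pop
  }
  if (level == "community" && !is.null(field_map$street_id)) {
    out$street_id <- vapply(feats, function(f) {
      v <- feature_prop(f, field_map$street_id)
      if (is.na(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  out
}

#' Write administrative units to GeoJSON
#' @param units Tibble from [read_admin_units()] (or the synthetic generator).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_admin_units <- function(units, path) {
  keep <- intersect(c("id", "population", "street_id"), names(units))
  write_geojson_features(units$geometry, units[, keep, drop = FALSE], path)
}

#' Read a census table
#'
#' A CSV with header `unit_id,population`: one row per street or community.
#'
#' @param path CSV file.
#' @return Tibble `(unit_id, population)`.
#' @export
read_census <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(d) == 0) abort("census file is empty")
  if (!all(c("unit_id", "population") %in% names(d))) {
    abort("census CSV must have columns unit_id, population")
  }
  pop <- suppressWarnings(as.numeric(d$population))
  if (any(is.na(pop))) abort("non-numeric census population")
  if (any(pop < 0)) abort("negative census population")
  if (anyDuplicated(d$unit_id)) abort("duplicate unit_id in census")
  tibble(unit_id = as.character(d$unit_id), population = pop)
}

#' Write a census table
#' @param census Tibble `(unit_id, population)`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  readr::write_csv(census[, c("unit_id", "population")], path)
  invisible(path)
}
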