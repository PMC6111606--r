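# Synthetic-city generator. Lays streets, communities and building lots out
# as a rectangular partition (axis-aligned rectangles keep every
# intersection-area oracle exact), plants per-category population densities,
# and produces censuses from the noiseless totals under multiplicative
# lognormal noise. Abandoned buildings never receive residential-quarter or
# community attribution, so they populate the street-only area R2 and the
# all-buildings totals R3/C2 but never the residential vectors R1/C1.

# Footprint size ranges honouring the survey taxonomy floors:
# large classes >= 1600 m2, independent/abandoned classes >= 200 m2.
.size_ranges <- list(
  multi_floor = c(40, 60),
  multi_floor_independent = c(15, 30),
  low_floor = c(40, 60),
  low_floor_independent = c(15, 30),
  abandoned = c(40, 60)
)
.lot_size <- 70

#' Parameters of a synthetic city
#'
#' @param n_streets Number of street units (default 14, a typical district).
#' @param communities_per_street Communities per street (default 6).
#' @param buildings_per_community Building lots per community (default 10).
#' @param rq_coverage Fraction of residential buildings given
#'   residential-quarter attribution (default 0.9).
#' @param category_mix Named probabilities over the five categories
#'   (must sum to 1).
#' @param true_densities Named planted densities in persons/m2 for the four
#'   residential categories.
#' @param census_noise_sd Multiplicative lognormal sd on censuses (0 = exact).
#' @param mix_tilt Lognormal sd of a per-street tilt on the category mix
#'   (streets differ in building stock; 0 = identical mixes everywhere).
#' @param occupancy_range Range of the per-street lot occupancy probability
#'   (streets differ in built density).
#' @param density_heterogeneity Lognormal sd of a per-community density
#'   multiplier (0 = the district-level uniform-density assumption holds
#'   exactly).
#' @param collinear If `TRUE`, multi-floor-independent areas are rescaled so
#'   each street's class-2 total is exactly 0.4 x its class-1 total, making
#'   the four-class design rank-deficient.
#' @param origin City origin coordinates in metres (projected CRS).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `city_params` list.
#' @export
city_params <- function(n_streets = 14,
                        communities_per_street = 6,
                        buildings_per_community = 10,
                        rq_coverage = 0.9,
                        category_mix = c(
                          multi_floor = 0.45, multi_floor_independent = 0.20,
                          low_floor = 0.15, low_floor_independent = 0.15,
                          abandoned = 0.05
                        ),
                        true_densities = c(
                          multi_floor = 0.11, multi_floor_independent = 0.09,
                          low_floor = 0.05, low_floor_independent = 0.04
                        ),
                        census_noise_sd = 0.05,
                        mix_tilt = 0.5,
                        occupancy_range = c(0.6, 0.95),
                        density_heterogeneity = 0,
                        collinear = FALSE,
                        origin = c(20000, 20000),
                        seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8) abort("category_mix must sum to 1")
  if (!setequal(names(category_mix), .categories)) {
    abort("category_mix must name the five building categories")
  }
  if (!setequal(names(true_densities), .residential)) {
    abort("true_densities must name the four residential categories")
  }
  if (any(true_densities < 0)) abort("densities must be non-negative")
  if (rq_coverage < 0 || rq_coverage > 1) abort("rq_coverage must lie in [0, 1]")
  if (census_noise_sd < 0) abort("census_noise_sd must be non-negative")
  structure(
    list(
      n_streets = n_streets,
      communities_per_street = communities_per_street,
      buildings_per_community = buildings_per_community,
      rq_coverage = rq_coverage,
      category_mix = category_mix[.categories],
      true_densities = true_densities[.residential],
      census_noise_sd = census_noise_sd,
      mix_tilt = mix_tilt,
      occupancy_range = occupancy_range,
      density_heterogeneity = density_heterogeneity,
      collinear = collinear,
      origin = origin,
      seed = as.integer(seed)
    ),
    class = "city_params"
  )
}

#' Named scenario presets
#'
#' * `"clean"` -- full attribution, no noise, one uniform density
#'   (0.08 persons/m2) so both levels' grids equal the truth grid.
#' * `"partial-rq"` -- sparse residential-quarter attribution and a large
#'   abandoned share, firing both extraction-completeness rules so the
#'   augmentation paths are exercised.
#' * `"negative-coef"` -- exactly collinear class areas forcing the
#'   two-class merge.
#' * `"street-vs-district"` -- per-community density heterogeneity so the
#'   two levels disagree and the cross-validation has spread.
#'
#' @param name Scenario name (dashes or underscores).
#' @param seed Integer seed.
#' @return A [city_params()] object.
#' @export
scenario <- function(name, seed = 1L) {
  uniform <- setNames(rep(0.08, 4), .residential)
  switch(gsub("_", "-", name),
    "clean" = city_params(
      rq_coverage = 1, census_noise_sd = 0, true_densities = uniform, seed = seed
    ),
    "partial-rq" = city_params(
      rq_coverage = 0.07, census_noise_sd = 0, mix_tilt = 0,
      category_mix = c(
        multi_floor = 0.30, multi_floor_independent = 0.13,
        low_floor = 0.09, low_floor_independent = 0.08, abandoned = 0.40
      ),
      seed = seed
    ),
    "negative-coef" = city_params(
      collinear = TRUE, census_noise_sd = 0, rq_coverage = 1,
      true_densities = c(
        multi_floor = 0.11, multi_floor_independent = 0.09,
        low_floor = 0.05, low_floor_independent = 0.05
      ),
      seed = seed
    ),
    "street-vs-district" = city_params(
      density_heterogeneity = 0.2, census_noise_sd = 0.05, seed = seed
    ),
    abort(paste0("unknown scenario: ", name))
  )
}

#' Generate a synthetic city
#'
#' Builds a deterministic city for the given parameters: rectangular,
#' non-overlapping building footprints on a street/community/lot partition
#' of a rectangle; category- and size-consistent areas; planted per-building
#' true populations `density(category) x area` (times a per-community
#' multiplier when heterogeneity is on); censuses equal to noiseless totals
#' times lognormal noise. Residential-quarter units cover runs of adjacent
#' attributed lots; abandoned buildings carry street attribution only.
#'
#' @param params A [city_params()] object.
#' @return List with `buildings`, `rq_units`, `communities`, `streets`,
#'   `street_census`, `community_census`, and `truth` (per-building true
#'   populations, noiseless unit totals, planted densities).
#' @export
generate_city <- function(params) {
  stopifnot(inherits(params, "city_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)

  ns <- params$n_streets
  cps <- params$communities_per_street
  bpc <- params$buildings_per_community
  # lot grid inside a community, community grid inside a street, street grid
  nbx <- ceiling(sqrt(bpc)); nby <- ceiling(bpc / nbx)
  ncx <- ceiling(sqrt(cps)); ncy <- ceiling(cps / ncx)
  nsx <- ceiling(sqrt(ns)); nsy <- ceiling(ns / nsx)
  com_w <- nbx * .lot_size; com_h <- nby * .lot_size
  st_w <- ncx * com_w; st_h <- ncy * com_h
  ox <- params$origin[1]; oy <- params$origin[2]

  streets <- purrr::map_dfr(seq_len(ns), function(s) {
    sx <- (s - 1) %% nsx; sy <- (s - 1) %/% nsx
    tibble(
      id = sprintf("S%02d", s), level = "street",
      geometry = list(rect_poly(
        ox + sx * st_w, oy + sy * st_h, ox + (sx + 1) * st_w, oy + (sy + 1) * st_h
      ))
    )
  })

  rows <- list(); rq_ids <- character(0); rq_geoms <- list()
  com_ids <- character(0); com_street <- character(0); com_geoms <- list()
  bid <- 0L; rqid <- 0L
  for (s in seq_len(ns)) {
    sbb <- poly_bbox(streets$geometry[[s]])
    # streets differ in building stock: tilted category mix, variable
    # lot occupancy
    mix_s <- params$category_mix * if (params$mix_tilt > 0) {
      rlnorm(length(.categories), 0, params$mix_tilt)
    } else {
      rep(1, length(.categories))
    }
    mix_s <- mix_s / sum(mix_s)
    p_occ <- runif(1, params$occupancy_range[1], params$occupancy_range[2])
    mult <- if (params$density_heterogeneity > 0) {
      rlnorm(cps, meanlog = -params$density_heterogeneity^2 / 2, sdlog = params$density_heterogeneity)
    } else {
      rep(1, cps)
    }
    for (cc in seq_len(cps)) {
      cx <- (cc - 1) %% ncx; cy <- (cc - 1) %/% ncx
      cxmin <- sbb["xmin"] + cx * com_w; cymin <- sbb["ymin"] + cy * com_h
      cid <- sprintf("%s-C%02d", streets$id[s], cc)
      com_ids <- c(com_ids, cid)
      com_street <- c(com_street, streets$id[s])
      com_geoms[[length(com_geoms) + 1]] <-
        rect_poly(cxmin, cymin, cxmin + com_w, cymin + com_h)
      occ <- which(runif(bpc) < p_occ)
      if (length(occ) == 0) occ <- 1L
      nb_c <- length(occ)
      cats <- sample(.categories, nb_c, replace = TRUE, prob = mix_s)
      in_rq <- runif(nb_c) < params$rq_coverage & cats != "abandoned"
      dims <- t(vapply(cats, function(cat) {
        r <- .size_ranges[[cat]]
        runif(2, r[1], r[2])
      }, numeric(2)))
      lot <- list(
        lot = occ - 1L,
        lx = unname(cxmin + ((occ - 1L) %% nbx) * .lot_size),
        ly = unname(cymin + ((occ - 1L) %/% nbx) * .lot_size),
        category = cats, in_rq = in_rq,
        com_mult = rep(mult[cc], nb_c),
        w = unname(dims[, 1]), h = unname(dims[, 2]),
        id = sprintf("B%05d", bid + seq_len(nb_c)),
        community_id = rep(cid, nb_c),
        street_id = rep(streets$id[s], nb_c),
        rq_id = rep(NA_character_, nb_c)
      )
      bid <- bid + nb_c

      # residential quarters: horizontal runs of adjacent attributed lots
      for (ry in 0:(nby - 1)) {
        in_row <- which((lot$lot %/% nbx) == ry & lot$in_rq)
        if (length(in_row) == 0) next
        runs <- split(in_row, cumsum(c(1, diff(lot$lot[in_row]) != 1)))
        for (run in runs) {
          rqid <- rqid + 1L
          rid <- sprintf("RQ%04d", rqid)
          rq_ids <- c(rq_ids, rid)
          rq_geoms[[length(rq_geoms) + 1]] <- rect_poly(
            min(lot$lx[run]), min(lot$ly[run]),
            max(lot$lx[run]) + .lot_size, max(lot$ly[run]) + .lot_size
          )
          lot$rq_id[run] <- rid
        }
      }
      rows[[length(rows) + 1]] <- lot
    }
  }
  lotq <- tibble(
    lot = unlist(lapply(rows, `[[`, "lot")),
    lx = unlist(lapply(rows, `[[`, "lx")),
    ly = unlist(lapply(rows, `[[`, "ly")),
    category = unlist(lapply(rows, `[[`, "category")),
    in_rq = unlist(lapply(rows, `[[`, "in_rq")),
    com_mult = unlist(lapply(rows, `[[`, "com_mult")),
    w = unlist(lapply(rows, `[[`, "w")),
    h = unlist(lapply(rows, `[[`, "h")),
    id = unlist(lapply(rows, `[[`, "id")),
    community_id = unlist(lapply(rows, `[[`, "community_id")),
    street_id = unlist(lapply(rows, `[[`, "street_id")),
    rq_id = unlist(lapply(rows, `[[`, "rq_id"))
  )

  # centre each footprint in its lot
  xmin <- lotq$lx + (.lot_size - lotq$w) / 2
  ymin <- lotq$ly + (.lot_size - lotq$h) / 2
  buildings <- tibble(
    id = lotq$id,
    geometry = lapply(seq_len(nrow(lotq)), function(k) {
      rect_poly(xmin[k], ymin[k], xmin[k] + lotq$w[k], ymin[k] + lotq$h[k])
    }),
    area = lotq$w * lotq$h,
    category = lotq$category,
    rq_id = lotq$rq_id,
    community_id = if_else(lotq$category == "abandoned", NA_character_, lotq$community_id),
    street_id = lotq$street_id
  )

  if (params$collinear) {
    # rescale multi_floor_independent footprints so each street's class-2
    # area is exactly 0.4 x its class-1 area (rank-deficient design)
    for (sid in unique(buildings$street_id)) {
      i1 <- buildings$street_id == sid & buildings$category == "multi_floor"
      i2 <- buildings$street_id == sid & buildings$category == "multi_floor_independent"
      if (!any(i2) || !any(i1)) next
      target <- 0.4 * sum(buildings$area[i1])
      f <- sqrt(target / sum(buildings$area[i2]))
      f <- min(f, (.lot_size - 2) / max(pmax(lotq$w[i2], lotq$h[i2])))
      for (k in which(i2)) {
        g <- buildings$geometry[[k]]
        ctr <- poly_centroid(g)
        g <- cbind(ctr[1] + (g[, 1] - ctr[1]) * f, ctr[2] + (g[, 2] - ctr[2]) * f)
        colnames(g) <- c("x", "y")
        buildings$geometry[[k]] <- g
        buildings$area[k] <- poly_area(g)
      }
      # exactness: adjust areas attribute to hit the target exactly
      buildings$area[i2] <- buildings$area[i2] * target / sum(buildings$area[i2])
    }
  }

  dens <- c(params$true_densities, abandoned = 0)
  com_mult <- setNames(lotq$com_mult, lotq$id)
  true_pop <- unname(dens[buildings$category]) * buildings$area *
    unname(com_mult[buildings$id])

  truth_building <- tibble(
    id = buildings$id, street_id = buildings$street_id,
    community_id = lotq$community_id, true_population = true_pop
  )
  street_truth <- truth_building %>%
    group_by(unit_id = .data$street_id) %>%
    summarise(population = sum(.data$true_population), .groups = "drop")
  community_truth <- truth_building %>%
    group_by(unit_id = .data$community_id) %>%
    summarise(population = sum(.data$true_population), .groups = "drop")

  noise <- function(n) {
    if (params$census_noise_sd == 0) {
      rep(1, n)
    } else {
      rlnorm(n, meanlog = -params$census_noise_sd^2 / 2, sdlog = params$census_noise_sd)
    }
  }
  street_census <- mutate(street_truth, population = .data$population * noise(n()))
  community_census <- mutate(community_truth, population = .data$population * noise(n()))

  communities <- tibble(
    id = com_ids, level = "community", street_id = com_street,
    geometry = com_geoms
  )
  communities$population <- community_census$population[match(communities$id, community_census$unit_id)]
  streets$population <- street_census$population[match(streets$id, street_census$unit_id)]

  list(
    buildings = validate_buildings(buildings),
    rq_units = tibble(
      id = rq_ids, level = rep("residential_quarter", length(rq_ids)),
      geometry = rq_geoms
    ),
    communities = communities,
    streets = streets,
    street_census = street_census,
    community_census = community_census,
    truth = list(
      buildings = truth_building,
      street_totals = street_truth,
      community_totals = community_truth,
      densities = params$true_densities,
      params = params
    )
  )
}
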