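# Street-level model: community aggregates, completeness, density,
# 50-m disaggregation, occupancy histogram.

test_that("community aggregates separate residential and total areas", {
  b <- tibble::tibble(
    id = c("a", "b"),
    geometry = list(popgrid:::rect_poly(0, 0, 20, 20), popgrid:::rect_poly(30, 0, 40, 10)),
    area = c(400, 100),
    category = c("multi_floor", "low_floor"),
    rq_id = c("r1", NA),
    community_id = "C1",
    street_id = "S1"
  )
  cen <- tibble::tibble(unit_id = "C1", population = 50)
  agg <- aggregate_communities(b, cen)
  expect_equal(agg$C1, 400)
  expect_equal(agg$C2, 500)
  expect_equal(agg$P, 50)

  # abandoned stock counts in C2, never in C1
  b$category[2] <- "abandoned"
  agg2 <- aggregate_communities(b, cen)
  expect_equal(agg2$C2, 500)
  expect_equal(agg2$C1, 400)
})

test_that("community completeness uses both the area ratio and density cap", {
  mk <- function(C1, C2, P) tibble::tibble(
    community_id = "C", street_id = "S", P = P, C1 = C1, C2 = C2, augmented = FALSE
  )
  expect_false(extraction_complete_community(mk(100, 1000, 150))$complete) # 0.1 & 1.5
  expect_true(extraction_complete_community(mk(800, 1000, 400))$complete)
  expect_false(extraction_complete_community(mk(0, 1000, 10))$complete)   # C1 = 0
  # low density saves a low area ratio
  expect_true(extraction_complete_community(mk(100, 1000, 50))$complete)  # 0.1 & 0.5
})

test_that("community augmentation and densities recover planted values", {
  city <- generate_city(scenario("clean", seed = 31))
  dens <- city_densities(city)
  # uniform-density city: every community density equals 0.08 exactly
  expect_equal(
    dens$density[dens$P > 0],
    rep(0.08, sum(dens$P > 0)),
    tolerance = 1e-10
  )

  # partial attribution: augmentation restores the full residential area
  city2 <- generate_city(scenario("partial-rq", seed = 32))
  cagg <- extraction_complete_community(
    aggregate_communities(city2$buildings, city2$community_census)
  )
  expect_true(any(!cagg$complete))
  dens2 <- community_density(augment_residential_community(cagg, city2$buildings))
  b <- city2$buildings
  for (cid in dens2$community_id[!cagg$complete]) {
    full <- sum(b$area[!is.na(b$community_id) & b$community_id == cid &
      b$category != "abandoned"])
    expect_equal(dens2$C1[dens2$community_id == cid], full)
  }
})

test_that("zero population gives zero density; missing area errors", {
  agg0 <- tibble::tibble(
    community_id = "C", street_id = "S", P = 0, C1 = 0, C2 = 100, augmented = FALSE
  )
  expect_equal(community_density(agg0)$density, 0)
  aggbad <- tibble::tibble(
    community_id = "C", street_id = "S", P = 10, C1 = 0, C2 = 100, augmented = FALSE
  )
  expect_error(community_density(aggbad), "zero residential area")
})

test_that("street disaggregation is exact per cell and conserves censuses", {
  b <- tibble::tibble(
    id = "a", geometry = list(popgrid:::rect_poly(10, 10, 20, 15)),
    area = 50, category = "multi_floor", rq_id = "r", community_id = "C1",
    street_id = "S1"
  )
  dens <- tibble::tibble(
    community_id = "C1", street_id = "S1", P = 5, C1 = 50, C2 = 50,
    augmented = FALSE, density = 0.1
  )
  g <- disaggregate_street(b, dens, grid_spec(0, 0, 50, 2, 2))
  expect_equal(g$values[1, 1], 5)

  # 50/50 split across two cells
  b$geometry <- list(popgrid:::rect_poly(40, 10, 60, 15))
  b$area <- 100
  dens$C1 <- 100; dens$P <- 10
  g2 <- disaggregate_street(b, dens, grid_spec(0, 0, 50, 2, 2))
  expect_equal(g2$values[1, 1], 5)
  expect_equal(g2$values[1, 2], 5)

  # per-community conservation on a synthetic city with noisy censuses
  city <- small_city(seed = 33, census_noise_sd = 0.1)
  dcity <- city_densities(city)
  spec <- grid_from_extent(city$buildings$geometry, 50)
  gs <- disaggregate_street(city$buildings, dcity, spec)
  expect_equal(grid_total(gs), sum(dcity$P), tolerance = 1e-6)
  # spot-check one community by restricting the buildings
  cid <- dcity$community_id[which(dcity$P > 0)[1]]
  bsub <- city$buildings[!is.na(city$buildings$community_id) &
    city$buildings$community_id == cid, ]
  gsub <- disaggregate_street(bsub, dcity, spec)
  expect_equal(grid_total(gsub), dcity$P[dcity$community_id == cid], tolerance = 1e-9)
})

test_that("the occupancy histogram covers all cells and sums to 100%", {
  spec <- grid_spec(0, 0, 50, 4, 3)
  vals <- matrix(c(0, 0, 10, 25, 26, 80, 140, 190, 250, 400, 800, 1300), 3, 4)
  occ <- grid_occupancy(pop_grid(spec, vals))
  expect_equal(sum(occ$count), 12)
  expect_equal(sum(occ$proportion_pct), 100)
  expect_equal(occ$count[occ$bin == "0"], 2)
  expect_equal(occ$count[occ$bin == "(0,25]"], 2)   # 10 and 25
  expect_equal(occ$count[occ$bin == ">1200"], 1)
})
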