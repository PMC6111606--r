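# District-level model: aggregates, completeness rule, augmentation,
# no-intercept fit with dynamic merging, correction, disaggregation.

test_that("street aggregates compute R1/R2/R3 and per-category areas", {
  b <- tibble::tibble(
    id = c("a", "b", "c"),
    geometry = list(
      popgrid:::rect_poly(0, 0, 10, 10),
      popgrid:::rect_poly(20, 0, 30, 20),
      popgrid:::rect_poly(40, 0, 50, 5)
    ),
    area = c(100, 200, 50),
    category = c("multi_floor", "low_floor", "multi_floor"),
    rq_id = c("r1", "r2", NA),
    community_id = c("c1", "c1", NA),
    street_id = "S1"
  )
  cen <- tibble::tibble(unit_id = "S1", population = 40)
  agg <- aggregate_streets(b, cen)
  expect_equal(agg$R1, 300)
  expect_equal(agg$R2, 50)
  expect_equal(agg$R3, 350)
  expect_equal(agg$area_multi_floor, 100)
  expect_equal(agg$area_low_floor, 200)

  # no rq buildings: R1 = 0 and the completeness rule fires (R2/R3 = 1)
  b2 <- b; b2$rq_id <- NA_character_; b2$community_id <- NA_character_
  agg2 <- extraction_complete(aggregate_streets(b2, cen))
  expect_equal(agg2$R1, 0)
  expect_false(agg2$complete)
})

test_that("aggregates equal brute-force sums on a synthetic city", {
  city <- small_city(seed = 21)
  agg <- aggregate_streets(city$buildings, city$street_census)
  b <- city$buildings
  for (sid in agg$street_id) {
    sel <- !is.na(b$street_id) & b$street_id == sid
    expect_equal(agg$R3[agg$street_id == sid], sum(b$area[sel]))
    expect_equal(
      agg$R1[agg$street_id == sid],
      sum(b$area[sel & !is.na(b$rq_id) & b$category != "abandoned"])
    )
    expect_equal(
      agg$R2[agg$street_id == sid],
      sum(b$area[sel & is.na(b$community_id)])
    )
  }
})

test_that("the completeness rule uses strict thresholds on both ratios", {
  mk <- function(R1, R2, R3 = 100) tibble::tibble(
    street_id = "S", population = 1, R1 = R1, R2 = R2, R3 = R3,
    area_multi_floor = R1, area_multi_floor_independent = 0,
    area_low_floor = 0, area_low_floor_independent = 0, augmented = FALSE
  )
  expect_false(extraction_complete(mk(15, 30))$complete) # 0.15 & 0.30
  expect_true(extraction_complete(mk(50, 10))$complete)
  expect_true(extraction_complete(mk(20, 30))$complete)  # R1/R3 = 0.20 exactly
  expect_true(extraction_complete(mk(15, 20))$complete)  # R2/R3 = 0.20 exactly
})

test_that("augmentation moves community-only residential area into R1", {
  b <- tibble::tibble(
    id = c("a", "b", "c"),
    geometry = list(
      popgrid:::rect_poly(0, 0, 10, 10),
      popgrid:::rect_poly(20, 0, 28, 10),
      popgrid:::rect_poly(40, 0, 50, 60)
    ),
    area = c(100, 80, 600),
    category = c("multi_floor", "multi_floor", "abandoned"),
    rq_id = c("r1", NA, NA),
    community_id = c("c1", "c1", NA),
    street_id = "S1"
  )
  cen <- tibble::tibble(unit_id = "S1", population = 30)
  agg <- extraction_complete(aggregate_streets(b, cen)) # R1/R3=0.128, R2/R3=0.77
  expect_false(agg$complete)
  agg2 <- augment_residential(agg, b)
  expect_equal(agg2$R1, 180)
  expect_equal(agg2$area_multi_floor, 180)
  expect_true(agg2$augmented)

  # nothing to add leaves the aggregate unchanged
  agg3 <- augment_residential(agg, b[c(1, 3), ])
  expect_equal(agg3$R1, agg$R1)
})

test_that("the fit matches the explicit normal-equations solution", {
  city <- small_city(seed = 22, census_noise_sd = 0.05)
  agg <- aggregate_streets(city$buildings, city$street_census)
  m <- fit_density_model(agg)
  X <- as.matrix(agg[, paste0("area_", building_categories(TRUE))])
  keep <- colSums(X) > 0
  beta <- solve(t(X[, keep]) %*% X[, keep], t(X[, keep]) %*% agg$population)
  if (!m$merged) {
    expect_equal(unname(m$coefficients[keep]), as.numeric(beta), tolerance = 1e-8)
  } else {
    Xm <- cbind(X[, 1] + X[, 2], X[, 3] + X[, 4])
    betam <- solve(t(Xm) %*% Xm, t(Xm) %*% agg$population)
    expect_equal(unname(m$coefficients), as.numeric(betam), tolerance = 1e-8)
  }
})

test_that("noiseless synthetic data recovers planted densities to 1e-8", {
  city <- generate_city(city_params(
    n_streets = 8, communities_per_street = 3, buildings_per_community = 8,
    rq_coverage = 1, census_noise_sd = 0, seed = 23
  ))
  m <- fit_density_model(aggregate_streets(city$buildings, city$street_census))
  expect_false(m$merged)
  expect_equal(
    unname(m$coefficients[building_categories(TRUE)]),
    unname(city$truth$densities[building_categories(TRUE)]),
    tolerance = 1e-8
  )
})

test_that("a single street with one category gives the exact ratio", {
  agg <- tibble::tibble(
    street_id = "S", population = 100,
    area_multi_floor = 1000, area_multi_floor_independent = 0,
    area_low_floor = 0, area_low_floor_independent = 0
  )
  m <- suppressWarnings(fit_density_model(agg))
  expect_equal(unname(m$coefficients["multi_floor"]), 0.1)
  expect_equal(m$r_squared, 1)
})

test_that("merge machinery leaves a healthy four-class fit untouched", {
  city <- generate_city(city_params(
    n_streets = 10, communities_per_street = 4, buildings_per_community = 8,
    rq_coverage = 1, census_noise_sd = 0.02, seed = 24
  ))
  agg <- aggregate_streets(city$buildings, city$street_census)
  m <- fit_density_model(agg)
  expect_false(m$merged)
  expect_true(all(m$coefficients >= 0))
  expect_gte(m$r_squared, 0.5)
  expect_null(m$initial_fit)
})

test_that("correction makes per-street predicted populations exact", {
  city <- small_city(seed = 25, census_noise_sd = 0.1)
  agg <- aggregate_streets(city$buildings, city$street_census)
  m <- fit_density_model(agg)
  cc <- correct_coefficients(m)
  # sum over categories of a'_k * S_k equals the census for every street
  for (sid in agg$street_id) {
    a <- cc[cc$street_id == sid, ]
    S <- unlist(agg[agg$street_id == sid, paste0("area_", a$category)])
    expect_equal(
      sum(a$corrected * S),
      agg$population[agg$street_id == sid],
      tolerance = 1e-9
    )
  }
  # ratio 1 keeps the coefficients
  expect_equal(
    cc$corrected[abs(cc$ratio - 1) < 1e-12],
    cc$coefficient[abs(cc$ratio - 1) < 1e-12]
  )
})

test_that("fitting errors follow the (y - yhat)/y convention", {
  m <- fit_density_model(table3_fixture(reference = FALSE))
  fe <- fitting_errors(m)
  # an underestimated street has a positive error
  expect_gt(fe$error_pct[fe$street_id == "Huanghelou"], 0)
  direct <- (fe$population - fe$fitted) / fe$population * 100
  expect_equal(fe$error_pct, direct)
})

test_that("district disaggregation apportions by intersection area and conserves", {
  # one building fully in one cell
  b <- tibble::tibble(
    id = "a", geometry = list(popgrid:::rect_poly(10, 10, 20, 20)),
    area = 100, category = "multi_floor", rq_id = "r", community_id = "c",
    street_id = "S1"
  )
  cc <- tibble::tibble(
    street_id = "S1", category = building_categories(TRUE),
    ratio = 1, coefficient = 0.1, corrected = 0.1, augmented = FALSE
  )
  g <- disaggregate_district(b, cc, grid_spec(0, 0, 50, 2, 2))
  expect_equal(g$values[1, 1], 10)
  expect_equal(grid_total(g), 10)

  # spanning two cells 60/40
  b2 <- b
  b2$geometry <- list(popgrid:::rect_poly(44, 10, 54, 20))
  g2 <- disaggregate_district(b2, cc, grid_spec(0, 0, 50, 2, 2))
  expect_equal(g2$values[1, 1], 6)
  expect_equal(g2$values[1, 2], 4)

  # synthetic city: grid total equals the street census total
  city <- small_city(seed = 26, census_noise_sd = 0.05)
  m <- fit_city_district(city)
  gd <- disaggregate_district(city$buildings, correct_coefficients(m))
  expect_equal(
    grid_total(gd), sum(city$street_census$population),
    tolerance = 1e-6
  )
})

test_that("tidy and glance expose the model in broom shape", {
  m <- fit_density_model(table3_fixture(reference = FALSE))
  td <- tidy(m)
  expect_equal(td$term, c("multi", "low"))
  gl <- glance(m)
  expect_true(all(c("r.squared", "merged", "nobs", "origin.slope") %in% names(gl)))
  expect_equal(gl$nobs, 14)
})
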