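# Independent oracles used across the suite. Deliberately naive and
# self-contained: none of them calls into the package's geometry or
# statistics code paths.

# Overlap area of two axis-aligned rectangles given as c(xmin, ymin, xmax, ymax).
oracle_rect_overlap <- function(a, b) {
  max(0, min(a[3], b[3]) - max(a[1], b[1])) * max(0, min(a[4], b[4]) - max(a[2], b[2]))
}

rect_bounds <- function(p) c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))

# Monte-Carlo intersection area of two polygons by point sampling (for
# non-rectangular cases); tol governs the sample size.
oracle_mc_area <- function(subject, clip, n = 2e5, seed = 42) {
  set.seed(seed)
  bb <- rect_bounds(subject)
  xs <- runif(n, bb[1], bb[3]); ys <- runif(n, bb[2], bb[4])
  inside <- function(px, py, poly) {
    np <- nrow(poly)
    jj <- c(2:np, 1)
    res <- logical(length(px))
    for (k in seq_along(px)) {
      crosses <- ((poly[, 2] > py[k]) != (poly[jj, 2] > py[k])) &
        (px[k] < (poly[jj, 1] - poly[, 1]) * (py[k] - poly[, 2]) /
          (poly[jj, 2] - poly[, 2]) + poly[, 1])
      res[k] <- sum(crosses) %% 2 == 1
    }
    res
  }
  hit <- inside(xs, ys, subject) & inside(xs, ys, clip)
  mean(hit) * (bb[3] - bb[1]) * (bb[4] - bb[2])
}

# Direct-formula local Moran evaluation with explicit neighbour scans over a
# values matrix (rows = j, cols = i), queen contiguity, row-standardised.
oracle_local_moran <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  x <- as.numeric(values)
  z <- x - mean(x)
  m2 <- sum(z^2) / length(x)
  out <- matrix(NA_real_, nr, nc)
  for (j in 1:nr) {
    for (i in 1:nc) {
      nbv <- c()
      for (dj in -1:1) {
        for (di in -1:1) {
          if (dj == 0 && di == 0) next
          jj <- j + dj; ii <- i + di
          if (jj >= 1 && jj <= nr && ii >= 1 && ii <= nc) {
            nbv <- c(nbv, values[jj, ii] - mean(x))
          }
        }
      }
      out[j, i] <- if (m2 == 0) 0 else (values[j, i] - mean(x)) * mean(nbv) / m2
    }
  }
  out
}

# Brute-force block sums for grid aggregation.
oracle_block_sums <- function(values, factor) {
  nr <- ceiling(nrow(values) / factor); nc <- ceiling(ncol(values) / factor)
  pad <- matrix(0, nr * factor, nc * factor)
  pad[seq_len(nrow(values)), seq_len(ncol(values))] <- values
  out <- matrix(0, nr, nc)
  for (j in 1:nr) {
    for (i in 1:nc) {
      out[j, i] <- sum(pad[((j - 1) * factor + 1):(j * factor), ((i - 1) * factor + 1):(i * factor)])
    }
  }
  out
}

# A small fully-attributed city for fast end-to-end tests.
small_city <- function(seed = 1, census_noise_sd = 0, ...) {
  generate_city(city_params(
    n_streets = 6, communities_per_street = 4, buildings_per_community = 8,
    rq_coverage = 1, census_noise_sd = census_noise_sd, seed = seed, ...
  ))
}

# Full district chain: aggregates -> completeness -> augmentation -> fit.
fit_city_district <- function(city, ...) {
  agg <- aggregate_streets(city$buildings, city$street_census)
  agg <- extraction_complete(agg)
  agg <- augment_residential(agg, city$buildings)
  fit_density_model(agg, ...)
}

# Full street chain: aggregates -> completeness -> augmentation -> densities.
city_densities <- function(city) {
  cagg <- aggregate_communities(city$buildings, city$community_census)
  cagg <- extraction_complete_community(cagg)
  cagg <- augment_residential_community(cagg, city$buildings)
  community_density(cagg)
}
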