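# Verification suite: local Moran's I, nearest distances, buffer coverage,
# grid aggregation, cross-level relative error.

test_that("a constant field yields all-zero local Moran and no clusters", {
  g <- pop_grid(grid_spec(0, 0, 50, 4, 4), 7)
  r <- local_morans_i(g, n_perm = 99, seed = 1)
  expect_equal(r$local_i, rep(0, 16))
  expect_true(all(r$cluster == "not-significant"))
})

test_that("local Moran matches the direct-formula oracle", {
  # checkerboard: negative autocorrelation on corners/edges; interior queen
  # neighbourhoods balance to exactly zero (4 like diagonals vs 4 unlike
  # edge neighbours)
  vals <- outer(1:4, 1:4, function(j, i) (i + j) %% 2)
  g <- pop_grid(grid_spec(0, 0, 50, 4, 4), vals)
  r <- local_morans_i(g, n_perm = 99, seed = 2)
  expect_true(all(r$local_i <= 0))
  corners <- r[(r$i %in% c(0, 3)) & (r$j %in% c(0, 3)), ]
  expect_true(all(corners$local_i < 0))
  expected <- oracle_local_moran(vals)
  got <- matrix(0, 4, 4)
  got[cbind(r$j + 1, r$i + 1)] <- r$local_i
  expect_equal(got, expected, tolerance = 1e-12)

  # and on a random 7 x 9 grid
  set.seed(3)
  vals2 <- matrix(rpois(63, 20), 7, 9)
  g2 <- pop_grid(grid_spec(0, 0, 50, 9, 7), vals2)
  r2 <- local_morans_i(g2, n_perm = 99, seed = 3)
  got2 <- matrix(0, 7, 9)
  got2[cbind(r2$j + 1, r2$i + 1)] <- r2$local_i
  expect_equal(got2, oracle_local_moran(vals2), tolerance = 1e-12)
})

test_that("a hot corner block is labelled High-High under permutation", {
  vals <- matrix(1, 5, 5)
  vals[1:2, 1:2] <- 100
  g <- pop_grid(grid_spec(0, 0, 50, 5, 5), vals)
  r <- local_morans_i(g, n_perm = 999, alpha = 0.05, seed = 4)
  hot <- r[r$i < 2 & r$j < 2, ]
  expect_true(all(hot$cluster == "High-High"))
  # reproducible under the same seed
  r2 <- local_morans_i(g, n_perm = 999, alpha = 0.05, seed = 4)
  expect_equal(r$p_value, r2$p_value)
})

test_that("nearest-feature distances are Euclidean and class means match brute force", {
  g <- pop_grid(grid_spec(0, 0, 100, 10, 10), matrix(runif(100, 1, 50), 10, 10))
  # feature at a cell centre: that cell's distance is 0
  pts <- tibble::tibble(x = 250, y = 350)
  d <- popgrid:::nearest_feature_distance(250, 350, pts)
  expect_equal(d, 0)
  expect_equal(popgrid:::nearest_feature_distance(250, 650, pts), 300)

  set.seed(5)
  pts3 <- tibble::tibble(x = runif(3, 0, 1000), y = runif(3, 0, 1000))
  res <- average_nearest_distance(g, pts3, class_breaks = c(10, 25, 40))
  tb <- tibble::as_tibble(g)
  tb <- tb[tb$population > 0, ]
  bru <- vapply(seq_len(nrow(tb)), function(k) {
    min(sqrt((pts3$x - tb$x_center[k])^2 + (pts3$y - tb$y_center[k])^2))
  }, numeric(1))
  cls <- findInterval(tb$population, c(10, 25, 40), left.open = TRUE) + 1
  for (k in sort(unique(cls))) {
    expect_equal(res$mean_distance[k], mean(bru[cls == k]))
  }
  expect_equal(sum(res$n_cells), nrow(tb))
})

test_that("point-ring buffer coverage grows monotonically to 100%", {
  # 3 x 3 uniform grid, single centre point: seed 1/9, first ring 9/9
  g <- pop_grid(grid_spec(0, 0, 50, 3, 3), 1)
  cov <- buffer_coverage(g, tibble::tibble(x = 75, y = 75), ring_count = 2)
  expect_equal(cov$coverage_pct, c(100 / 9, 100, 100), tolerance = 1e-9)
  expect_true(all(diff(cov$coverage_pct) >= 0))
  expect_true(all(cov$coverage_pct <= 100 + 1e-9))

  # features covering every cell: 100% at seed
  allpts <- tibble::as_tibble(g)[, c("x_center", "y_center")]
  names(allpts) <- c("x", "y")
  cov2 <- buffer_coverage(g, allpts, ring_count = 1)
  expect_equal(cov2$coverage_pct[1], 100)

  # oracle: exhaustive Chebyshev enumeration on a random grid
  set.seed(6)
  vals <- matrix(rpois(25, 10), 5, 5)
  g3 <- pop_grid(grid_spec(0, 0, 50, 5, 5), vals)
  pt <- tibble::tibble(x = 30, y = 30) # cell (0, 0)
  cov3 <- buffer_coverage(g3, pt, ring_count = 4)
  for (r in 0:4) {
    cells <- expand.grid(i = 0:4, j = 0:4)
    keep <- pmax(abs(cells$i - 0), abs(cells$j - 0)) <= r
    expect_equal(
      cov3$covered_population[cov3$ring == r],
      sum(vals[cbind(cells$j[keep] + 1, cells$i[keep] + 1)])
    )
  }
})

test_that("line-buffer coverage counts cells whose centre is within distance", {
  vals <- matrix(1, 4, 4)
  g <- pop_grid(grid_spec(0, 0, 50, 4, 4), vals)
  line <- list(cbind(x = c(0, 0), y = c(0, 200))) # the left edge
  cov <- buffer_coverage(g, line, mode = "line-buffers", distances = c(30, 80, 130, 200))
  # centre columns at x = 25, 75, 125, 175
  expect_equal(cov$covered_population, c(4, 8, 12, 16))
  expect_true(all(diff(cov$coverage_pct) >= 0))
})

test_that("grid aggregation equals brute-force block sums and conserves totals", {
  set.seed(7)
  vals <- matrix(runif(100, 0, 30), 10, 10)
  fine <- pop_grid(grid_spec(0, 0, 50, 10, 10), vals)
  coarse <- aggregate_grid(fine, 5)
  expect_equal(coarse$values, oracle_block_sums(vals, 5))
  expect_equal(grid_total(coarse), grid_total(fine))
  expect_equal(coarse$spec$cell_size, 250)

  # 5 x 5 block of ones collapses to a single cell of 25
  ones <- pop_grid(grid_spec(0, 0, 50, 5, 5), 1)
  expect_equal(aggregate_grid(ones, 5)$values, matrix(25, 1, 1))

  # non-multiple dimensions are zero-padded, conserving the total
  odd <- pop_grid(grid_spec(0, 0, 50, 7, 7), matrix(1, 7, 7))
  agg <- aggregate_grid(odd, 5)
  expect_equal(grid_total(agg), 49)
})

test_that("cross-level relative error is bounded, antisymmetric and well-binned", {
  spec <- grid_spec(0, 0, 250, 3, 2)
  cs <- pop_grid(spec, matrix(c(3, 0, 2, 2, 0, 5), 2, 3))
  ss <- pop_grid(spec, matrix(c(1, 0, 2, 6, 0, 0), 2, 3))
  cv <- cross_validate(cs, ss)
  expect_equal(cv$n_undefined, 2)
  expect_true(all(cv$cells$relative_error >= -2 & cv$cells$relative_error <= 2))
  # CS=3, SS=1 -> 1.0; equal cells -> 0; SS=0, CS>0 -> 2
  expect_equal(cv$cells$relative_error[cv$cells$CS == 3], 1)
  expect_equal(cv$cells$relative_error[cv$cells$CS == 2 & cv$cells$SS == 2], 0)
  expect_equal(cv$cells$relative_error[cv$cells$CS == 5], 2)
  expect_equal(as.character(cv$cells$bin[cv$cells$CS == 5]), ">1.0")
  expect_equal(as.character(cv$cells$bin[cv$cells$CS == 3]), "(0.8,1.0]")

  # antisymmetry under swapping the two levels
  cv2 <- cross_validate(ss, cs)
  expect_equal(cv2$cells$relative_error, -cv$cells$relative_error)

  # identical grids: everything lands in the "0" bin
  cv3 <- cross_validate(cs, cs)
  expect_equal(
    cv3$histogram$proportion_pct[cv3$histogram$bin == "0"], 100
  )

  # mismatched specs are rejected
  other <- pop_grid(grid_spec(0, 0, 250, 2, 3), 1)
  expect_error(cross_validate(cs, other), "grid_spec")
})

test_that("proportion_within sums the bins inside a band", {
  hist <- tibble::tibble(
    bin = factor(c("<-1.0", "[-1.0,-0.8)", "[-0.8,-0.4)", "[-0.4,0)", "0",
      "(0,0.4]", "(0.4,0.8]", "(0.8,1.0]", ">1.0")),
    proportion_pct = c(4.77, 2.54, 5.61, 10.23, 32.15, 19.46, 16.08, 5.23, 3.93)
  )
  expect_equal(proportion_within(hist, -0.4, 0.4), 61.84)
  expect_equal(proportion_within(hist, -1, 1), 91.3, tolerance = 1e-9)
})
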