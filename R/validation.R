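# Verification suite: local Moran's I with conditional permutation
# inference, nearest-feature distance statistics by population class,
# multi-ring buffer population coverage, and cross-level relative error.

grid_neighbors <- function(n_rows, n_cols, contiguity = c("queen", "rook")) {
  contiguity <- match.arg(contiguity)
  offs <- if (contiguity == "queen") {
    cbind(
      dj = c(-1, -1, -1, 0, 0, 1, 1, 1),
      di = c(-1, 0, 1, -1, 1, -1, 0, 1)
    )
  } else {
    cbind(dj = c(-1, 0, 0, 1), di = c(0, -1, 1, 0))
  }
  lapply(seq_len(n_rows * n_cols), function(k) {
    j <- (k - 1) %% n_rows + 1
    i <- (k - 1) %/% n_rows + 1
    jj <- j + offs[, "dj"]; ii <- i + offs[, "di"]
    ok <- jj >= 1 & jj <= n_rows & ii >= 1 & ii <= n_cols
    (ii[ok] - 1) * n_rows + jj[ok]
  })
}

#' Local Moran's I over a population grid
#'
#' Per cell, `I_i = z_i * sum_j w_ij z_j / (sum z^2 / n)` with deviations
#' `z = x - mean(x)` and row-standardised contiguity weights. Significance is
#' assessed by conditional permutation: each cell's neighbours are redrawn
#' from the remaining cells `n_perm` times, and the pseudo p-value is the
#' one-sided proportion of permuted statistics at least as extreme as the
#' observed one. Significant cells are labelled by the quadrant of
#' `(z_i, lag_i)`: High-High, Low-Low, High-Low, Low-High.
#'
#' @param grid A [pop_grid()] with at least 9 cells.
#' @param contiguity `"queen"` (default) or `"rook"`.
#' @param n_perm Number of conditional permutations (>= 99; default 999).
#' @param alpha Significance level for cluster labels (default 0.05).
#' @param seed Optional integer seed for reproducible p-values.
#' @return Tibble with one row per cell: `i`, `j`, `population`, `local_i`,
#'   `p_value`, `cluster`. A constant grid yields all-zero `local_i` and
#'   `"not-significant"` labels.
#' @export
local_morans_i <- function(grid, contiguity = c("queen", "rook"),
                           n_perm = 999, alpha = 0.05, seed = NULL) {
  contiguity <- match.arg(contiguity)
  s <- grid$spec
  n <- s$n_rows * s$n_cols
  if (n < 9) abort("local Moran's I needs at least 9 cells")
  if (n_perm < 99) abort("use at least 99 permutations")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  x <- as.numeric(grid$values) # column-major: k = (i-1)*n_rows + j
  nb <- grid_neighbors(s$n_rows, s$n_cols, contiguity)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(k) mean(z[nb[[k]]]), numeric(1))
  constant <- m2 == 0
  ii <- if (constant) rep(0, n) else z * lag / m2

  p <- rep(1, n)
  cluster <- rep("not-significant", n)
  if (!constant) {
    for (k in seq_len(n)) {
      kn <- length(nb[[k]])
      zk <- z[-k]
      # conditional permutation: redraw the neighbourhood from the other cells
      perm_lag <- vapply(seq_len(n_perm), function(r) {
        mean(zk[sample.int(length(zk), kn)])
      }, numeric(1))
      perm_i <- z[k] * perm_lag / m2
      ge <- sum(perm_i >= ii[k])
      ge <- min(ge, n_perm - ge)
      p[k] <- (ge + 1) / (n_perm + 1)
    }
    sig <- p <= alpha
    cluster[sig & z > 0 & lag > 0] <- "High-High"
    cluster[sig & z < 0 & lag < 0] <- "Low-Low"
    cluster[sig & z > 0 & lag <= 0] <- "High-Low"
    cluster[sig & z < 0 & lag >= 0] <- "Low-High"
  }
  ij <- expand.grid(j = 0:(s$n_rows - 1), i = 0:(s$n_cols - 1))
  tibble(
    i = ij$i, j = ij$j, population = x,
    local_i = ii, p_value = p,
    cluster = factor(cluster, levels = c("High-High", "Low-Low", "High-Low", "Low-High", "not-significant"))
  )
}

#' Plot local Moran cluster labels
#' @param object Result of [local_morans_i()] (class carried via attribute is
#'   not required; any tibble with `i`, `j`, `cluster` works).
#' @param cell_size Cell size used for plotting coordinates.
#' @return A ggplot object.
#' @export
plot_lisa_clusters <- function(object, cell_size = 1) {
  ggplot2::ggplot(object, ggplot2::aes(.data$i * cell_size, .data$j * cell_size, fill = .data$cluster)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      "High-High" = "#d7191c", "Low-Low" = "#2c7bb6",
      "High-Low" = "#fdae61", "Low-High" = "#abd9e9",
      "not-significant" = "grey90"
    ), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

as_point_matrix <- function(features) {
  if (is.data.frame(features)) {
    cbind(x = features$x, y = features$y)
  } else {
    features
  }
}

#' Mean distance to the nearest feature by population class
#'
#' Cells with population are classed by `class_breaks` (deciles of the
#' nonzero cells by default); within each class the mean Euclidean distance
#' from cell centre to the nearest feature is reported.
#'
#' @param grid A [pop_grid()].
#' @param features Point features as a tibble/matrix with columns `x`, `y`,
#'   or a list of polyline matrices.
#' @param class_breaks Optional increasing break points on population (the
#'   classes partition the nonzero cells).
#' @param n_classes Number of quantile classes when `class_breaks` is `NULL`.
#' @return Tibble `(class, n_cells, mean_distance)`.
#' @export
average_nearest_distance <- function(grid, features, class_breaks = NULL, n_classes = 10) {
  d <- as_tibble(grid)
  d <- d[d$population > 0, , drop = FALSE]
  if (nrow(d) == 0) abort("grid has no populated cells")
  dist <- nearest_feature_distance(d$x_center, d$y_center, features)
  if (is.null(class_breaks)) {
    class_breaks <- unique(quantile(d$population, probs = seq_len(n_classes - 1) / n_classes))
  }
  cls <- findInterval(d$population, class_breaks, left.open = TRUE) + 1L
  edges <- c(0, class_breaks, Inf)
  labs <- paste0("(", format(edges[-length(edges)], digits = 4, trim = TRUE), ",",
    format(edges[-1], digits = 4, trim = TRUE), "]")
  d %>%
    mutate(class = factor(labs[cls], levels = labs), distance = dist) %>%
    group_by(.data$class) %>%
    summarise(n_cells = n(), mean_distance = mean(.data$distance), .groups = "drop")
}

nearest_feature_distance <- function(x, y, features) {
  if (is.list(features) && !is.data.frame(features)) {
    if (length(features) == 0) abort("empty feature set")
    vapply(seq_along(x), function(k) {
      min(vapply(features, function(l) point_segline_dist(x[k], y[k], l), numeric(1)))
    }, numeric(1))
  } else {
    pts <- as_point_matrix(features)
    if (is.null(pts) || nrow(pts) == 0) abort("empty feature set")
    vapply(seq_along(x), function(k) {
      min(sqrt((pts[, 1] - x[k])^2 + (pts[, 2] - y[k])^2))
    }, numeric(1))
  }
}

#' Multi-ring buffer population coverage
#'
#' Point mode: the seed set is the cells containing features; ring `k`
#' contains the cells at Chebyshev (8-neighbour, default) cell distance `k`
#' from any seed, and coverage is the cumulative percentage of total grid
#' population within distance `k`. Line mode: Euclidean buffers at the given
#' distances around the polylines; a cell counts when its centre lies within
#' the buffer distance.
#'
#' @param grid A [pop_grid()] with positive total population.
#' @param features Points (tibble/matrix `x`,`y`) or list of polyline
#'   matrices.
#' @param mode `"point-rings"` or `"line-buffers"`.
#' @param ring_count Number of rings beyond the seed (point mode).
#' @param distances Buffer distances in metres (line mode; default
#'   `c(50, 100, 150, 200)`).
#' @param growth `"chebyshev"` (8-neighbour, default) or `"rook"`
#'   (4-neighbour Manhattan) ring growth for point mode.
#' @return Tibble `(ring, label, covered_population, coverage_pct)` with
#'   cumulative, non-decreasing coverage bounded by 100.
#' @export
buffer_coverage <- function(grid, features,
                            mode = c("point-rings", "line-buffers"),
                            ring_count = 4, distances = c(50, 100, 150, 200),
                            growth = c("chebyshev", "rook")) {
  mode <- match.arg(mode)
  growth <- match.arg(growth)
  s <- grid$spec
  total <- grid_total(grid)
  if (total <= 0) abort("grid has zero total population")
  d <- as_tibble(grid)
  if (mode == "point-rings") {
    pts <- as_point_matrix(features)
    idx <- cell_index(s, pts[, 1], pts[, 2])
    ok <- !is.na(idx$i)
    if (!any(ok)) abort("no feature falls inside the grid")
    seeds <- unique(cbind(idx$i[ok], idx$j[ok]))
    cheb <- vapply(seq_len(nrow(d)), function(k) {
      di <- abs(seeds[, 1] - d$i[k]); dj <- abs(seeds[, 2] - d$j[k])
      min(if (growth == "chebyshev") pmax(di, dj) else di + dj)
    }, numeric(1))
    rings <- 0:ring_count
    purrr::map_dfr(rings, function(r) {
      cov <- sum(d$population[cheb <= r])
      tibble(
        ring = r,
        label = if (r == 0) "seed" else paste0("ring ", r),
        covered_population = cov,
        coverage_pct = cov / total * 100
      )
    })
  } else {
    if (!is.list(features) || is.data.frame(features)) {
      features <- list(as_point_matrix(features))
    }
    dist <- nearest_feature_distance(d$x_center, d$y_center, features)
    purrr::map_dfr(seq_along(distances), function(k) {
      cov <- sum(d$population[dist <= distances[k]])
      tibble(
        ring = k,
        label = paste0(distances[k], " m buffer"),
        covered_population = cov,
        coverage_pct = cov / total * 100
      )
    })
  }
}

crossval_bins <- function() {
  tibble(
    bin = factor(
      c("<-1.0", "[-1.0,-0.8)", "[-0.8,-0.4)", "[-0.4,0)", "0",
        "(0,0.4]", "(0.4,0.8]", "(0.8,1.0]", ">1.0"),
      levels = c("<-1.0", "[-1.0,-0.8)", "[-0.8,-0.4)", "[-0.4,0)", "0",
        "(0,0.4]", "(0.4,0.8]", "(0.8,1.0]", ">1.0")
    )
  )
}

bin_relative_errors <- function(rel) {
  cut_one <- function(v) {
    if (v == 0) return("0")
    if (v < 0) {
      if (v < -1) "<-1.0" else if (v < -0.8) "[-1.0,-0.8)" else if (v < -0.4) "[-0.8,-0.4)" else "[-0.4,0)"
    } else {
      if (v <= 0.4) "(0,0.4]" else if (v <= 0.8) "(0.4,0.8]" else if (v <= 1) "(0.8,1.0]" else ">1.0"
    }
  }
  vapply(rel, cut_one, character(1))
}

#' Cross-level relative error
#'
#' Compares the district-level grid with the aggregated street-level grid
#' cell by cell via the symmetric relative error
#' `2 * (CS - SS) / (CS + SS)`, bounded in `[-2, 2]` and zero iff the two
#' agree. Cells empty on both levels are excluded and counted separately.
#'
#' @param coarse District-level [pop_grid()].
#' @param fine_aggregated Street-level grid aggregated to the same
#'   [grid_spec()] (see [aggregate_grid()]).
#' @return List of class `cross_validation`: `cells` (per-cell tibble with
#'   `relative_error` and `bin`), `histogram` (counts/proportions over the
#'   standard report bins), `n_undefined` (both-zero cells).
#' @export
cross_validate <- function(coarse, fine_aggregated) {
  sa <- coarse$spec; sb <- fine_aggregated$spec
  same <- isTRUE(all.equal(unclass(sa), unclass(sb), tolerance = 1e-9))
  if (!same) abort("grids must share the same grid_spec (aggregate the fine grid first)")
  cs <- as.numeric(coarse$values)
  ss <- as.numeric(fine_aggregated$values)
  defined <- !(cs == 0 & ss == 0)
  rel <- 2 * (cs[defined] - ss[defined]) / (cs[defined] + ss[defined])
  # agreement to float tolerance counts as exact agreement
  rel[abs(rel) < 1e-9] <- 0
  d <- as_tibble(coarse)[defined, c("i", "j")]
  d$CS <- cs[defined]; d$SS <- ss[defined]
  d$relative_error <- rel
  d$bin <- factor(bin_relative_errors(rel), levels = levels(crossval_bins()$bin))
  hist <- d %>%
    group_by(.data$bin, .drop = FALSE) %>%
    summarise(count = n(), .groups = "drop") %>%
    mutate(proportion_pct = .data$count / sum(.data$count) * 100)
  structure(
    list(cells = d, histogram = hist, n_undefined = sum(!defined)),
    class = "cross_validation"
  )
}

#' @export
print.cross_validation <- function(x, ...) {
  cat(sprintf(
    "<cross_validation> %d cells compared (%d empty on both levels)\n",
    nrow(x$cells), x$n_undefined
  ))
  print(x$histogram)
  invisible(x)
}

#' Share of cross-level differences within a symmetric band
#'
#' Sums the binned proportions over the bins fully contained in
#' `[lo, hi]` -- e.g. the default band `[-0.4, 0.4]` covers the bins
#' `[-0.4,0)`, `0` and `(0,0.4]`.
#'
#' @param x A [cross_validate()] result, or its histogram tibble
#'   (`bin`, `proportion_pct`).
#' @param lo,hi Band limits (must be bin edges).
#' @return Percentage of compared cells within the band.
#' @export
proportion_within <- function(x, lo = -0.4, hi = 0.4) {
  hist <- if (inherits(x, "cross_validation")) x$histogram else x
  edges <- list(
    "<-1.0" = c(-2, -1), "[-1.0,-0.8)" = c(-1, -0.8), "[-0.8,-0.4)" = c(-0.8, -0.4),
    "[-0.4,0)" = c(-0.4, 0), "0" = c(0, 0), "(0,0.4]" = c(0, 0.4),
    "(0.4,0.8]" = c(0.4, 0.8), "(0.8,1.0]" = c(0.8, 1), ">1.0" = c(1, 2)
  )
  keep <- vapply(as.character(hist$bin), function(b) {
    e <- edges[[b]]
    e[1] >= lo - 1e-12 && e[2] <= hi + 1e-12
  }, logical(1))
  sum(hist$proportion_pct[keep])
}
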