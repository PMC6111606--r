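# District-level method: per-street area aggregates R1/R2/R3, the
# extraction-completeness rule, the no-intercept category density regression
# with dynamic merging, per-street coefficient correction, and 250-m
# disaggregation.
#
# Model: y_i = a1*S1i + a2*S2i + a3*S3i + a4*S4i + e_i over streets i, with
# no intercept (every person lives in some residential floor area). If any
# coefficient is negative (or not estimable) or the centred R^2 is below
# 0.5, the four classes collapse pairwise (multi + multi-independent,
# low + low-independent) and the two-class model is refit.

area_cols4 <- paste0("area_", .residential)
area_cols2 <- c("area_multi", "area_low")

# Membership rule for the district design matrix: a building contributes to
# its street's S when it is residential (non-abandoned), street-attributed
# and residential-quarter-attributed -- plus, on streets where extraction was
# incomplete and augmentation applied, community-attributed buildings
# without a residential-quarter id.
district_member <- function(buildings, augmented_streets = character(0)) {
  res <- buildings$category %in% .residential & !is.na(buildings$street_id)
  base <- res & !is.na(buildings$rq_id)
  extra <- res & is.na(buildings$rq_id) & !is.na(buildings$community_id) &
    buildings$street_id %in% augmented_streets
  base | extra
}

#' Per-street area aggregates
#'
#' Computes, for every street with attributed buildings:
#' * `R1` -- total area of residential (non-abandoned) buildings with a
#'   residential-quarter attribution,
#' * `R2` -- total area of buildings with a street but no community
#'   attribution,
#' * `R3` -- total area of all street-attributed buildings,
#' plus the per-category areas `area_<category>` of the `R1` buildings, which
#' form the regression design matrix.
#'
#' @param buildings Preprocessed building tibble.
#' @param census Street census tibble `(unit_id, population)`.
#' @return Tibble with one row per street: `street_id`, `population`, `R1`,
#'   `R2`, `R3`, the four `area_*` columns, and `augmented = FALSE`. Streets
#'   present in the census but with no buildings get zero areas and a
#'   warning.
#' @export
aggregate_streets <- function(buildings, census) {
  b <- buildings[!is.na(buildings$street_id), , drop = FALSE]
  ids <- sort(unique(c(b$street_id, census$unit_id)))
  in_r1 <- district_member(b)
  agg <- purrr::map_dfr(ids, function(sid) {
    sel <- b$street_id == sid
    s <- vapply(.residential, function(cat) {
      sum(b$area[sel & in_r1 & b$category == cat])
    }, numeric(1))
    tibble(
      street_id = sid,
      R1 = sum(b$area[sel & in_r1]),
      R2 = sum(b$area[sel & is.na(b$community_id)]),
      R3 = sum(b$area[sel]),
      !!!setNames(as.list(s), area_cols4)
    )
  })
  agg <- left_join(agg, rename(census, street_id = "unit_id"), by = "street_id")
  if (any(is.na(agg$population))) {
    warn(paste0(
      "street(s) without census population: ",
      paste(agg$street_id[is.na(agg$population)], collapse = ", ")
    ))
  }
  if (any(agg$R3 == 0)) {
    warn(paste0(
      "street(s) with no attributed building area (excluded from the fit): ",
      paste(agg$street_id[agg$R3 == 0], collapse = ", ")
    ))
  }
  agg$augmented <- FALSE
  agg[, c("street_id", "population", "R1", "R2", "R3", area_cols4, "augmented")]
}

#' Extraction-completeness test for streets
#'
#' Residential extraction on a street counts as incomplete exactly when
#' `R1/R3 < t1` **and** `R2/R3 > t2` (both comparisons strict; equality at a
#' threshold counts as complete). Incomplete streets should be passed through
#' [augment_residential()].
#'
#' @param agg Street aggregate tibble from [aggregate_streets()].
#' @param t1,t2 Thresholds, both defaulting to 0.20.
#' @return `agg` with a logical `complete` column.
#' @export
extraction_complete <- function(agg, t1 = 0.20, t2 = 0.20) {
  if (any(agg$R3 == 0)) {
    warn("streets with R3 = 0 are marked complete (no area to reassign)")
  }
  agg$complete <- !(agg$R1 / pmax(agg$R3, .Machine$double.xmin) < t1 &
    agg$R2 / pmax(agg$R3, .Machine$double.xmin) > t2) | agg$R3 == 0
  agg
}

#' Augment incomplete streets with community-attributed buildings
#'
#' On streets where extraction is incomplete, residential buildings that have
#' a community attribution but no residential-quarter attribution are
#' regarded as residential houses: their areas are added to `R1` and to the
#' per-category design-matrix columns, and the street is flagged
#' `augmented`.
#'
#' @param agg Street aggregates; the `complete` column is computed via
#'   [extraction_complete()] if absent.
#' @param buildings The building tibble the aggregates came from.
#' @param t1,t2 Thresholds forwarded to [extraction_complete()] when needed.
#' @return Updated aggregate tibble.
#' @export
augment_residential <- function(agg, buildings, t1 = 0.20, t2 = 0.20) {
  if (!"complete" %in% names(agg)) agg <- extraction_complete(agg, t1, t2)
  todo <- agg$street_id[!agg$complete]
  if (length(todo) == 0) return(agg)
  b <- buildings
  extra <- b$category %in% .residential & !is.na(b$street_id) &
    is.na(b$rq_id) & !is.na(b$community_id) & b$street_id %in% todo
  for (sid in todo) {
    sel <- extra & b$street_id == sid
    k <- which(agg$street_id == sid)
    add <- vapply(.residential, function(cat) sum(b$area[sel & b$category == cat]), numeric(1))
    agg[k, area_cols4] <- agg[k, area_cols4] + add
    agg$R1[k] <- agg$R1[k] + sum(add)
    agg$augmented[k] <- TRUE
  }
  agg
}

merge_areas <- function(agg) {
  tibble(
    area_multi = agg$area_multi_floor + agg$area_multi_floor_independent,
    area_low = agg$area_low_floor + agg$area_low_floor_independent
  )
}

centered_r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - yhat)^2)
  if (sst == 0) {
    return(if (sse <= 1e-8 * max(1, sum(y^2))) 1 else NA_real_)
  }
  1 - sse / sst
}

fit_origin_ls <- function(y, X) {
  keep <- colSums(abs(X)) > 0
  if (!all(keep)) {
    warn(paste0(
      "category with all-zero area dropped from the design matrix: ",
      paste(colnames(X)[!keep], collapse = ", ")
    ))
  }
  Xk <- X[, keep, drop = FALSE]
  fit <- lm(y ~ 0 + Xk)
  a <- rep(NA_real_, ncol(X))
  names(a) <- colnames(X)
  ak <- coef(fit)
  names(ak) <- colnames(Xk)
  a[names(ak)] <- ak
  yhat <- as.numeric(Xk %*% ifelse(is.na(ak), 0, ak))
  list(
    coefficients = a, fitted = yhat, r_squared = centered_r2(y, yhat),
    dropped = colnames(X)[!keep]
  )
}

#' Fit the street density regression with dynamic category merging
#'
#' Fits the no-intercept least-squares model of street census population on
#' per-category residential areas. With four-category aggregates, the
#' four-class model is tried first; if any coefficient is negative or not
#' estimable (rank-deficient design), or the centred goodness of fit is
#' below `r2_min`, the classes are merged pairwise and the two-class model
#' refit (`merged = TRUE`). Aggregates that already carry merged areas
#' (`area_multi`, `area_low`) are fit directly as the merged model.
#'
#' @param agg Aggregate tibble with a `population` column and either the four
#'   `area_<category>` columns or merged `area_multi`/`area_low` columns.
#'   Rows whose areas are all zero are excluded from the fit.
#' @param r2_min Goodness-of-fit threshold triggering the merge (default
#'   0.5).
#' @return A `density_model` object: coefficients (persons/m2), per-street
#'   fitted populations and residuals, centred `r_squared`, `merged` flag,
#'   and the data used.
#' @export
fit_density_model <- function(agg, r2_min = 0.5) {
  has4 <- all(area_cols4 %in% names(agg))
  has2 <- all(area_cols2 %in% names(agg))
  if (!has4 && !has2) {
    abort("aggregate table lacks per-category area columns")
  }
  if (is.null(agg$population) || any(is.na(agg$population))) {
    abort("every street in the fit needs a census population")
  }
  cols <- if (has4) area_cols4 else area_cols2
  X_all <- as.matrix(agg[, cols])
  use <- rowSums(abs(X_all)) > 0
  if (sum(use) == 0) abort("no street with positive residential area")
  dat <- agg[use, , drop = FALSE]
  y <- dat$population
  X <- X_all[use, , drop = FALSE]

  merged <- !has4
  fit <- fit_origin_ls(y, X)
  # all-zero-area categories are merely absent; only a non-estimable
  # (rank-deficient) or negative coefficient among the present categories,
  # or a poor fit, triggers the merge
  present <- setdiff(names(fit$coefficients), fit$dropped)
  merge_trigger <- has4 && (
    any(is.na(fit$coefficients[present])) ||
      any(fit$coefficients[present] < 0, na.rm = TRUE) ||
      (!is.na(fit$r_squared) && fit$r_squared < r2_min)
  )
  initial <- NULL
  if (merge_trigger) {
    initial <- list(coefficients = fit$coefficients, r_squared = fit$r_squared)
    Xm <- as.matrix(merge_areas(dat))
    fit <- fit_origin_ls(y, Xm)
    merged <- TRUE
  }
  names(fit$coefficients) <- sub("^area_", "", names(fit$coefficients))

  structure(
    list(
      coefficients = fit$coefficients,
      merged = merged,
      r_squared = fit$r_squared,
      initial_fit = initial,
      streets = tibble(
        street_id = dat$street_id %||% paste0("s", seq_along(y)),
        population = y,
        fitted = fit$fitted,
        residual = y - fit$fitted
      ),
      data = dat
    ),
    class = "density_model"
  )
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf(
    "<density_model> %s, %d streets, R^2 = %.3f\n",
    if (x$merged) "merged (2 classes)" else "4 classes",
    nrow(x$streets), x$r_squared
  ))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
tidy.density_model <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    unit = "persons/m2"
  )
}

#' @export
glance.density_model <- function(x, ...) {
  ev <- evaluate_fit(x)
  tibble(
    r.squared = x$r_squared,
    merged = x$merged,
    nobs = nrow(x$streets),
    origin.slope = ev$slope,
    origin.r.squared = ev$r_squared
  )
}

#' Plot fitted against census street populations
#'
#' Scatter of the model's fitted street populations against the census
#' values, with the identity line and the through-origin fit.
#'
#' @param object A [fit_density_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_model <- function(object, ...) {
  ev <- evaluate_fit(object)
  ggplot2::ggplot(
    object$streets,
    ggplot2::aes(.data$population, .data$fitted)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_abline(slope = ev$slope, intercept = 0, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "census population", y = "fitted population",
      subtitle = sprintf("slope %.3f, R² %.3f", ev$slope, ev$r_squared)
    )
}

#' Through-origin agreement between fitted and census populations
#'
#' Regresses the fitted street populations on the census populations through
#' the origin: `slope = sum(y*yhat)/sum(y^2)`, and reports the goodness of
#' fit `1 - sum((yhat - slope*y)^2) / sum((yhat - mean(yhat))^2)`.
#'
#' @param model A [fit_density_model()] result.
#' @return One-row tibble `(slope, r_squared)`.
#' @export
evaluate_fit <- function(model) {
  y <- model$streets$population
  yhat <- model$streets$fitted
  if (length(y) < 2) abort("need at least two streets to evaluate the fit")
  slope <- sum(y * yhat) / sum(y^2)
  tibble(
    slope = slope,
    r_squared = 1 - sum((yhat - slope * y)^2) / sum((yhat - mean(yhat))^2)
  )
}

#' Per-street fitting errors
#'
#' `(y - yhat) / y * 100`: positive when the model underestimates the census
#' population.
#'
#' @param model A [fit_density_model()] result.
#' @return Tibble `(street_id, population, fitted, error_pct)`.
#' @export
fitting_errors <- function(model) {
  s <- model$streets
  if (any(s$population == 0)) abort("fitting error undefined for a street with zero census population")
  mutate(s[, c("street_id", "population", "fitted")],
    error_pct = (.data$population - .data$fitted) / .data$population * 100
  )
}

#' Per-street corrected density coefficients
#'
#' Scales every fitted category coefficient by the street's census/fitted
#' population ratio, `a'_k = (y_i / yhat_i) * a_k`, which makes the
#' subsequent grid disaggregation conserve the street censuses exactly.
#'
#' @param model A [fit_density_model()] result with positive fitted values.
#' @return Long tibble with one row per street and original category:
#'   `street_id`, `category`, `ratio`, `coefficient` (global),
#'   `corrected` (street-specific), `augmented`.
#' @export
correct_coefficients <- function(model) {
  s <- model$streets
  if (any(s$fitted <= 0)) {
    abort(paste0(
      "cannot correct coefficients: zero/negative fitted population for street(s) ",
      paste(s$street_id[s$fitted <= 0], collapse = ", ")
    ))
  }
  ratio <- s$population / s$fitted
  coefs <- model$coefficients
  cat_coef <- if (model$merged) {
    setNames(unname(coefs[.merge_map[.residential]]), .residential)
  } else {
    coefs[.residential]
  }
  augmented <- if ("augmented" %in% names(model$data)) {
    model$data$augmented
  } else {
    rep(FALSE, nrow(s))
  }
  tidyr::crossing(
    tibble(street_id = s$street_id, ratio = ratio, augmented = augmented),
    tibble(category = .residential, coefficient = unname(cat_coef))
  ) %>%
    mutate(corrected = .data$ratio * .data$coefficient) %>%
    select("street_id", "category", "ratio", "coefficient", "corrected", "augmented")
}

#' Disaggregate street populations to a grid
#'
#' Each residential building contributes `a'(street, category) * area`,
#' apportioned to cells by exact polygon-cell intersection-area fractions.
#' Buildings included are exactly those that formed the regression design
#' (residential-quarter-attributed, plus community-attributed buildings on
#' augmented streets), so per-street grid sums equal the street censuses to
#' float tolerance.
#'
#' @param buildings Preprocessed building tibble.
#' @param corrected Corrected coefficients from [correct_coefficients()].
#' @param spec A [grid_spec()] (250 m cells by default in the pipeline);
#'   derived from the building extent when `NULL`.
#' @param cell_size Used only when `spec` is `NULL`.
#' @return A [pop_grid()].
#' @export
disaggregate_district <- function(buildings, corrected, spec = NULL, cell_size = 250) {
  if (is.null(spec)) spec <- grid_from_extent(buildings$geometry, cell_size)
  aug <- unique(corrected$street_id[corrected$augmented])
  sel <- district_member(buildings, augmented_streets = aug)
  b <- buildings[sel, , drop = FALSE]
  missing <- setdiff(unique(b$street_id), unique(corrected$street_id))
  if (length(missing)) {
    abort(paste0(
      "building(s) on street(s) without corrected coefficients: ",
      paste(missing, collapse = ", ")
    ))
  }
  b <- left_join(
    b, corrected[, c("street_id", "category", "corrected")],
    by = c("street_id", "category")
  )
  if (any(b$corrected < 0, na.rm = TRUE)) {
    abort(paste0(
      "negative corrected density coefficient(s) on street(s) ",
      paste(unique(b$street_id[b$corrected < 0]), collapse = ", "),
      ": the fitted model assigns a negative density to an occupied ",
      "category, so a population surface would go negative; refit with ",
      "merged classes or revisit the street aggregates"
    ))
  }
  pop_grid(spec, apportion_to_grid(b$geometry, b$corrected * b$area, spec))
}
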