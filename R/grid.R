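#' Grid specification
#'
#' A regular square grid in a projected CRS. Cell `(i, j)` (both 0-based)
#' covers the half-open square
#' `[origin_x + i*s, origin_x + (i+1)*s) x [origin_y + j*s, origin_y + (j+1)*s)`
#' with `s = cell_size`, so a point on a shared edge belongs to exactly one
#' cell.
#'
#' @param origin_x,origin_y Lower-left corner of cell (0, 0), in metres.
#' @param cell_size Cell edge length in metres (250 for the district level,
#'   50 for the street level).
#' @param n_cols,n_rows Grid dimensions.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_cols, n_rows) {
  if (cell_size <= 0) abort("cell_size must be positive")
  if (n_cols < 1 || n_rows < 1) abort("grid must have at least one cell")
  structure(
    list(
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g m, origin (%g, %g)\n",
    x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y
  ))
  invisible(x)
}

#' Derive a grid covering a set of geometries
#'
#' The origin is the lower-left corner of the data extent snapped *down* to a
#' multiple of `cell_size`, so the grid layout is deterministic for a given
#' input and grids of nested cell sizes (e.g. 50 m and 250 m) share origins.
#'
#' @param geoms List of polygon matrices, or a tibble with a `geometry`
#'   list-column.
#' @param cell_size Cell edge length in metres.
#' @return A [grid_spec()].
#' @export
grid_from_extent <- function(geoms, cell_size) {
  if (is.data.frame(geoms)) geoms <- geoms$geometry
  bb <- vapply(geoms, poly_bbox, numeric(4))
  xmin <- min(bb[1, ]); ymin <- min(bb[2, ])
  xmax <- max(bb[3, ]); ymax <- max(bb[4, ])
  ox <- floor(xmin / cell_size) * cell_size
  oy <- floor(ymin / cell_size) * cell_size
  grid_spec(
    ox, oy, cell_size,
    n_cols = ceiling((xmax - ox) / cell_size),
    n_rows = ceiling((ymax - oy) / cell_size)
  )
}

#' Population grid
#'
#' A [grid_spec()] plus a non-negative per-cell population. Values are stored
#' as an `n_rows x n_cols` matrix indexed `[j + 1, i + 1]` for cell `(i, j)`.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix (`n_rows x n_cols`), or a scalar recycled to
#'   every cell.
#' @return A `pop_grid` object.
#' @export
pop_grid <- function(spec, values = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1) {
    values <- matrix(values, nrow = spec$n_rows, ncol = spec$n_cols)
  }
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    abort("values matrix does not match the grid dimensions")
  }
  if (any(values < -1e-9, na.rm = TRUE)) abort("cell populations must be non-negative")
  structure(list(spec = spec, values = values), class = "pop_grid")
}

#' @export
print.pop_grid <- function(x, ...) {
  cat(sprintf(
    "<pop_grid> %d x %d cells of %g m, total population %.2f\n",
    x$spec$n_cols, x$spec$n_rows, x$spec$cell_size, sum(x$values)
  ))
  invisible(x)
}

#' Total population of a grid
#' @param grid A [pop_grid()].
#' @return Scalar sum of all cells.
#' @export
grid_total <- function(grid) sum(grid$values)

#' @describeIn pop_grid Long-form view: one row per cell with 0-based cell
#'   indices `i` (column) and `j` (row), cell-centre coordinates and
#'   population, in row-major order from the origin.
#' @param x A `pop_grid`.
#' @param ... Unused.
#' @export
as_tibble.pop_grid <- function(x, ...) {
  s <- x$spec
  ij <- expand.grid(i = 0:(s$n_cols - 1), j = 0:(s$n_rows - 1))
  ij <- ij[order(ij$j, ij$i), ]
  tibble(
    i = ij$i, j = ij$j,
    x_center = s$origin_x + (ij$i + 0.5) * s$cell_size,
    y_center = s$origin_y + (ij$j + 0.5) * s$cell_size,
    population = x$values[cbind(ij$j + 1, ij$i + 1)]
  )
}

# 0-based cell index of a point under the half-open convention; NA outside.
cell_index <- function(spec, x, y) {
  i <- floor((x - spec$origin_x) / spec$cell_size)
  j <- floor((y - spec$origin_y) / spec$cell_size)
  bad <- i < 0 | i >= spec$n_cols | j < 0 | j >= spec$n_rows
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  list(i = as.integer(i), j = as.integer(j))
}

# Apportion each geometry's weight onto grid cells by exact polygon-cell
# intersection area fraction. Returns the values matrix.
apportion_to_grid <- function(geoms, weights, spec) {
  vals <- matrix(0, nrow = spec$n_rows, ncol = spec$n_cols)
  s <- spec$cell_size
  for (b in seq_along(geoms)) {
    g <- geoms[[b]]
    w <- weights[b]
    if (w == 0) next
    ga <- poly_area(g)
    if (ga <= 0) next
    bb <- poly_bbox(g)
    i0 <- max(0L, floor((bb["xmin"] - spec$origin_x) / s))
    i1 <- min(spec$n_cols - 1L, floor((bb["xmax"] - spec$origin_x - 1e-12) / s))
    j0 <- max(0L, floor((bb["ymin"] - spec$origin_y) / s))
    j1 <- min(spec$n_rows - 1L, floor((bb["ymax"] - spec$origin_y - 1e-12) / s))
    if (i1 < i0 || j1 < j0) next
    for (j in j0:j1) {
      for (i in i0:i1) {
        cell <- rect_poly(
          spec$origin_x + i * s, spec$origin_y + j * s,
          spec$origin_x + (i + 1) * s, spec$origin_y + (j + 1) * s
        )
        a <- intersection_area(g, cell)
        if (a > 0) vals[j + 1, i + 1] <- vals[j + 1, i + 1] + w * a / ga
      }
    }
  }
  vals
}

#' Write a population grid
#'
#' CSV output has columns `i,j,x_center,y_center,population`, one row per
#' cell in row-major order from the origin, and round-trips exactly. `"asc"`
#' writes an ESRI ASCII raster grid.
#'
#' @param grid A [pop_grid()].
#' @param path Output file.
#' @param format `"csv"` or `"asc"`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("csv", "asc")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "pop_grid"))
  s <- grid$spec
  if (format == "csv") {
    readr::write_csv(as_tibble(grid), path)
  } else {
    lines <- c(
      sprintf("ncols %d", s$n_cols),
      sprintf("nrows %d", s$n_rows),
      sprintf("xllcorner %.10g", s$origin_x),
      sprintf("yllcorner %.10g", s$origin_y),
      sprintf("cellsize %.10g", s$cell_size),
      "NODATA_value -9999",
      # ASCII grids list rows top to bottom
      vapply(
        s$n_rows:1,
        function(j) paste(format(grid$values[j, ], digits = 17), collapse = " "),
        character(1)
      )
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a population grid written by [write_grid()]
#'
#' @param path File path.
#' @param format `"csv"` or `"asc"`; guessed from the extension by default.
#' @return A [pop_grid()].
#' @export
read_grid <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  format <- format %||% if (grepl("\\.asc$", path, ignore.case = TRUE)) "asc" else "csv"
  if (format == "csv") {
    d <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("i", "j", "x_center", "y_center", "population")
    if (!all(need %in% names(d))) abort("grid CSV must have columns i,j,x_center,y_center,population")
    n_cols <- max(d$i) + 1L; n_rows <- max(d$j) + 1L
    cs <- if (n_cols > 1) {
      diff(sort(unique(d$x_center)))[1]
    } else if (n_rows > 1) {
      diff(sort(unique(d$y_center)))[1]
    } else {
      abort("cannot infer cell size from a 1x1 grid CSV")
    }
    spec <- grid_spec(
      min(d$x_center) - cs / 2, min(d$y_center) - cs / 2, cs, n_cols, n_rows
    )
    vals <- matrix(0, n_rows, n_cols)
    vals[cbind(d$j + 1, d$i + 1)] <- d$population
    pop_grid(spec, vals)
  } else {
    lines <- readLines(path)
    hdr <- strsplit(trimws(lines[1:6]), "\\s+")
    kv <- setNames(
      as.numeric(vapply(hdr, `[`, character(1), 2)),
      tolower(vapply(hdr, `[`, character(1), 1))
    )
    n_cols <- as.integer(kv[["ncols"]]); n_rows <- as.integer(kv[["nrows"]])
    vals <- do.call(rbind, lapply(lines[7:(6 + n_rows)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    vals <- vals[n_rows:1, , drop = FALSE]
    pop_grid(
      grid_spec(kv[["xllcorner"]], kv[["yllcorner"]], kv[["cellsize"]], n_cols, n_rows),
      vals
    )
  }
}

#' Block-aggregate a fine grid to a coarser one
#'
#' Sums `factor x factor` blocks of cells (e.g. factor 5 for 50 m to 250 m).
#' Origins are shared; a fine grid whose dimensions are not multiples of
#' `factor` is zero-padded at the top/right, so the total is conserved
#' exactly.
#'
#' @param fine A [pop_grid()].
#' @param factor Positive integer block size.
#' @return A [pop_grid()] with cell size `factor * fine cell size`.
#' @export
aggregate_grid <- function(fine, factor) {
  stopifnot(inherits(fine, "pop_grid"))
  factor <- as.integer(factor)
  if (factor < 1) abort("factor must be a positive integer")
  if (factor == 1) return(fine)
  s <- fine$spec
  nc <- ceiling(s$n_cols / factor); nr <- ceiling(s$n_rows / factor)
  padded <- matrix(0, nr * factor, nc * factor)
  padded[seq_len(s$n_rows), seq_len(s$n_cols)] <- fine$values
  out <- matrix(0, nr, nc)
  for (j in seq_len(nr)) {
    rows <- ((j - 1) * factor + 1):(j * factor)
    block <- padded[rows, , drop = FALSE]
    out[j, ] <- vapply(
      seq_len(nc),
      function(i) sum(block[, ((i - 1) * factor + 1):(i * factor)]),
      numeric(1)
    )
  }
  pop_grid(
    grid_spec(s$origin_x, s$origin_y, s$cell_size * factor, nc, nr),
    out
  )
}

#' Plot a population grid
#'
#' @param object A [pop_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pop_grid <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_center, .data$y_center, fill = .data$population)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "persons") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
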