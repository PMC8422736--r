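#' Minimum convex polygon home range
#'
#' Estimates a home range as the convex hull of the `level`% of fixes closest
#' to their centroid: the `ceiling((1 - level/100) * n)` points farthest
#' (Euclidean distance) from the centroid of *all* points are peeled off and
#' the convex hull of the remainder is returned. Distance ties are broken by
#' input order (earlier points are kept). `level = 100` is the plain convex
#' hull.
#'
#' @param points Data frame with numeric columns `x` and `y` (planar
#'   coordinates, same units as the land-cover grid).
#' @param level Percentage of points retained, in `(0, 100]`; default 95.
#'
#' @return An object of class `home_range`: list with `polygon` (tibble of
#'   hull vertices `x`, `y` in counter-clockwise order), `area` (squared
#'   coordinate units), `n_points_used`, `level` and `centroid`.
#' @export
#' @examples
#' sq <- data.frame(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5))
#' mcp_home_range(sq, level = 100)$area # 1
mcp_home_range <- function(points, level = 95) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x)
  y <- as.numeric(points$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite.", call. = FALSE)
  }
  if (!(level > 0 && level <= 100)) {
    stop("`level` must be in (0, 100].", call. = FALSE)
  }
  n <- length(x)
  if (nrow(unique(cbind(x, y))) < 5L) {
    stop("insufficient fixes: need at least 5 distinct points.",
      call. = FALSE
    )
  }
  cx <- mean(x)
  cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  m <- ceiling((1 - level / 100) * n)
  keep <- seq_len(n)
  if (m > 0) {
    # peel the m farthest; among tied distances the later point goes first
    drop <- order(-d, -seq_len(n))[seq_len(m)]
    keep <- setdiff(keep, drop)
  }
  xs <- x[keep]
  ys <- y[keep]
  hull <- grDevices::chull(xs, ys)
  if (length(hull) < 3L) {
    stop("degenerate hull: remaining points are collinear.", call. = FALSE)
  }
  hull <- rev(hull) # chull is clockwise; store counter-clockwise
  px <- xs[hull]
  py <- ys[hull]
  area <- polygon_area(px, py)
  if (!(area > 0)) {
    stop("degenerate hull: remaining points are collinear.", call. = FALSE)
  }
  structure(
    list(
      polygon = tibble::tibble(x = px, y = py),
      area = area, n_points_used = length(keep), level = level,
      centroid = c(x = cx, y = cy)
    ),
    class = "home_range"
  )
}

polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  abs(sum(px[j] * py - px * py[j])) / 2
}

# inclusion test for a convex polygon given in CCW order; points exactly on
# the boundary count as inside (within a small relative tolerance)
convex_contains <- function(px, py, qx, qy) {
  n <- length(px)
  scale <- max(abs(c(px, py)), 1)
  tol <- -1e-9 * scale^2
  inside <- rep(TRUE, length(qx))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (px[j] - px[i]) * (qy - py[i]) - (py[j] - py[i]) * (qx - px[i])
    inside <- inside & (cross >= tol)
  }
  inside
}

#' Construct a categorical land-cover grid
#'
#' @param codes Integer matrix of category codes; row 1 is the southernmost
#'   (lowest-`y`) row, column 1 the westernmost column.
#' @param cell_size Cell edge length in coordinate units (e.g. 10 for
#'   10 x 10 m cells).
#' @param origin Coordinates `(x0, y0)` of the grid's lower-left corner.
#' @param legend Named character vector mapping code (as name) to category
#'   label; defaults to the codes themselves.
#' @param reference Reference category label (by convention the most
#'   prevalent land-cover type).
#'
#' @return An object of class `land_cover_grid`.
#' @export
land_cover_grid <- function(codes, cell_size, origin = c(0, 0),
                            legend = NULL, reference = NULL) {
  stopifnot(is.matrix(codes), cell_size > 0, length(origin) == 2)
  codes <- matrix(as.integer(codes), nrow(codes), ncol(codes))
  present <- sort(unique(as.vector(codes)))
  if (is.null(legend)) {
    legend <- stats::setNames(as.character(present), present)
  }
  if (!all(as.character(present) %in% names(legend))) {
    stop("every code in the grid must appear in `legend`.", call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% legend) {
    stop("`reference` must be a category label in `legend`.", call. = FALSE)
  }
  structure(
    list(
      codes = codes, cell_size = cell_size,
      origin = as.numeric(origin), legend = legend, reference = reference
    ),
    class = "land_cover_grid"
  )
}

grid_cell_centers <- function(grid) {
  nr <- nrow(grid$codes)
  nc <- ncol(grid$codes)
  cs <- grid$cell_size
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = grid$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * cs,
    y = grid$origin[2] + (rep(seq_len(nr), times = nc) - 0.5) * cs,
    code = as.vector(grid$codes)
  )
}

#' Land-cover proportions within a home range
#'
#' Computes the relative availability of each category as the fraction of
#' grid cells whose *center* lies inside the home-range polygon (centers
#' exactly on the boundary count as inside).
#'
#' @param hr A [mcp_home_range()] result (or any list with a `polygon`
#'   element of `x`/`y` vertices in counter-clockwise order).
#' @param grid A [land_cover_grid()].
#'
#' @return A tibble with columns `category` and `proportion`, covering every
#'   category in the grid legend (zeros included); proportions sum to 1.
#' @export
land_cover_proportions <- function(hr, grid) {
  stopifnot(inherits(grid, "land_cover_grid"))
  poly <- hr$polygon
  cells <- grid_cell_centers(grid)
  # restrict to the polygon bounding box before the exact test
  bb <- cells$x >= min(poly$x) - grid$cell_size &
    cells$x <= max(poly$x) + grid$cell_size &
    cells$y >= min(poly$y) - grid$cell_size &
    cells$y <= max(poly$y) + grid$cell_size
  cand <- cells[bb, ]
  inside <- convex_contains(poly$x, poly$y, cand$x, cand$y)
  if (!any(inside)) {
    stop("no grid-cell centers fall inside the home range.", call. = FALSE)
  }
  codes_in <- cand$code[inside]
  labels <- unname(grid$legend[as.character(codes_in)])
  all_labels <- unique(unname(grid$legend))
  counts <- table(factor(labels, levels = all_labels))
  tibble::tibble(
    category = names(counts),
    proportion = as.numeric(counts) / sum(counts)
  )
}

#' Build the availability table from telemetry and a land-cover grid
#'
#' For each animal-month with enough fixes, computes the `level`% minimum
#' convex polygon and the land-cover proportions inside it, then excludes
#' animal-months with biologically unrealistic (outsized) home ranges: either
#' those above the sex-specific `cutoff_percentile` of monthly areas computed
#' from the data, or those above absolute per-sex `cutoff_area` thresholds.
#' With `cutoff_scope = "individual"` the size screen is applied to an
#' individual's mean monthly area, dropping all months of flagged
#' individuals.
#'
#' @param telemetry Tibble of fixes with columns `id`, `sex`, `year`,
#'   `month`, `x`, `y` (and optionally `hour`, `category`).
#' @param grid A [land_cover_grid()].
#' @param level MCP level (percent), default 95.
#' @param min_fixes Minimum fixes per animal-month (default 5, the minimum
#'   for a 2-D hull).
#' @param cutoff_percentile Percentile (0-100) of areas used as the size
#'   cut-off, computed per sex; default 90. Ignored when `cutoff_area` given.
#' @param cutoff_area Optional named numeric of absolute per-sex area
#'   thresholds in squared coordinate units, e.g.
#'   `c(female = 182e4, male = 459e4)` for 182/459 ha with metre coordinates.
#' @param cutoff_scope `"month"` (screen each animal-month) or
#'   `"individual"` (screen individuals by mean monthly area).
#'
#' @return A tibble with columns `id`, `sex`, `year`, `month`, `category`,
#'   `proportion` (each animal-month summing to 1 over categories), with
#'   attributes `"exclusions"` (tibble of dropped animal-months and reasons)
#'   and `"areas"` (tibble of retained home-range areas). See
#'   [exclusion_log()].
#' @export
build_availability_table <- function(telemetry, grid, level = 95,
                                     min_fixes = 5,
                                     cutoff_percentile = 90,
                                     cutoff_area = NULL,
                                     cutoff_scope = c("month", "individual")) {
  stopifnot(is.data.frame(telemetry), nrow(telemetry) > 0)
  cutoff_scope <- match.arg(cutoff_scope)
  groups <- telemetry |>
    dplyr::group_by(.data$id, .data$sex, .data$year, .data$month) |>
    tidyr::nest() |>
    dplyr::ungroup()

  excl <- list()
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    pts <- g$data[[1]]
    key <- tibble::tibble(
      id = g$id, sex = g$sex, year = g$year, month = g$month
    )
    if (nrow(pts) < min_fixes) {
      excl[[length(excl) + 1L]] <- dplyr::mutate(key,
        reason = "insufficient fixes", area = NA_real_
      )
      next
    }
    hr <- tryCatch(mcp_home_range(pts, level = level), error = function(e) e)
    if (inherits(hr, "error")) {
      excl[[length(excl) + 1L]] <- dplyr::mutate(key,
        reason = conditionMessage(hr), area = NA_real_
      )
      next
    }
    rows[[length(rows) + 1L]] <- dplyr::mutate(key, area = hr$area,
      hr = list(hr)
    )
  }
  kept <- dplyr::bind_rows(rows)
  if (nrow(kept) == 0L) {
    stop("no animal-month had enough usable fixes.", call. = FALSE)
  }

  # sex-specific home-range size screen
  if (!is.null(cutoff_area)) {
    thr <- cutoff_area[kept$sex]
    too_big <- kept$area > unname(thr)
  } else {
    thr_by_sex <- tapply(kept$area, kept$sex, stats::quantile,
      probs = cutoff_percentile / 100
    )
    too_big <- kept$area > unname(thr_by_sex[kept$sex])
  }
  if (cutoff_scope == "individual") {
    mean_area <- tapply(kept$area, kept$id, mean)
    if (!is.null(cutoff_area)) {
      flagged <- names(mean_area)[
        mean_area > unname(cutoff_area[kept$sex[match(names(mean_area), kept$id)]])
      ]
    } else {
      sex_of <- kept$sex[match(names(mean_area), kept$id)]
      thr_by_sex <- tapply(mean_area, sex_of, stats::quantile,
        probs = cutoff_percentile / 100
      )
      flagged <- names(mean_area)[mean_area > unname(thr_by_sex[sex_of])]
    }
    too_big <- kept$id %in% flagged
  }
  if (any(too_big)) {
    excl[[length(excl) + 1L]] <- kept[too_big, c("id", "sex", "year", "month", "area")] |>
      dplyr::mutate(reason = "home range above size cut-off")
    kept <- kept[!too_big, ]
  }
  if (nrow(kept) == 0L) {
    stop("size cut-off excluded every animal-month.", call. = FALSE)
  }

  avail <- purrr::pmap_dfr(
    list(kept$id, kept$sex, kept$year, kept$month, kept$hr),
    function(id, sex, year, month, hr) {
      dplyr::mutate(land_cover_proportions(hr, grid),
        id = id, sex = sex, year = year, month = month, .before = 1
      )
    }
  )
  attr(avail, "exclusions") <- dplyr::bind_rows(excl) %||%
    tibble::tibble(
      id = character(), sex = character(), year = integer(),
      month = integer(), reason = character(), area = numeric()
    )
  attr(avail, "areas") <- kept[, c("id", "sex", "year", "month", "area")]
  avail
}

#' Exclusion log of an availability table
#'
#' @param availability Result of [build_availability_table()].
#' @return Tibble of excluded animal-months with a `reason` column.
#' @export
exclusion_log <- function(availability) {
  attr(availability, "exclusions") %||% tibble::tibble()
}

#' Read an ESRI ASCII land-cover grid
#'
#' Reads the plain-text ESRI ASCII raster format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize` header followed by the value matrix,
#' northernmost row first) into a [land_cover_grid()].
#'
#' @param path File path.
#' @param legend,reference Passed to [land_cover_grid()].
#' @return A `land_cover_grid`.
#' @export
read_asc_grid <- function(path, legend = NULL, reference = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
    quiet = TRUE
  )
  nr <- hdr$nrows
  nc <- hdr$ncols
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE] # store south row first
  land_cover_grid(m,
    cell_size = hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner),
    legend = legend, reference = reference
  )
}
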