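test_that("the 100% MCP is the convex hull and small samples are rejected", {
  sq <- data.frame(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5))
  hr <- mcp_home_range(sq, level = 100)
  expect_equal(hr$area, 1)
  expect_identical(hr$n_points_used, 5L)
  expect_error(
    mcp_home_range(data.frame(x = c(0, 1, 2), y = c(0, 1, 0))),
    "insufficient fixes"
  )
  # 5 points but only 3 distinct
  expect_error(
    mcp_home_range(data.frame(x = c(0, 0, 1, 1, 2), y = c(0, 0, 1, 1, 0))),
    "insufficient fixes"
  )
  expect_error(
    mcp_home_range(data.frame(x = 1:6, y = 2 * (1:6))),
    "degenerate hull"
  )
})

test_that("peeling removes the points farthest from the centroid first", {
  withr::with_seed(11, {
    theta <- seq(0, 2 * pi, length.out = 21)[-21]
    pts <- data.frame(x = cos(theta), y = sin(theta))
    pts <- rbind(pts, data.frame(x = 10, y = 0)) # outlier, n = 21
  })
  hr <- mcp_home_range(pts, level = 95) # removes ceiling(0.05*21) = 2
  expect_identical(hr$n_points_used, 19L)
  expect_true(all(hr$polygon$x < 2)) # outlier gone
  expect_lt(hr$area, pi * 1.01)
  # independent check of which points go: ranked centroid distances
  cx <- mean(pts$x)
  cy <- mean(pts$y)
  d <- sqrt((pts$x - cx)^2 + (pts$y - cy)^2)
  worst2 <- order(d, decreasing = TRUE)[1:2]
  expect_true(21L %in% worst2) # the outlier is among the two removed
})

test_that("MCP area is monotone in the level", {
  withr::with_seed(12, {
    pts <- data.frame(x = rnorm(60), y = rnorm(60))
  })
  areas <- vapply(
    c(50, 70, 90, 95, 100),
    function(l) mcp_home_range(pts, l)$area, numeric(1)
  )
  expect_true(all(diff(areas) >= 0))
})

test_that("distance ties at the peeling threshold keep earlier fixes", {
  # 4 inner points + 2 points at identical distance; level forces removing 1
  pts <- data.frame(
    x = c(0.1, -0.1, 0, 0, 2, -2),
    y = c(0, 0, 0.1, -0.1, 0, 0)
  )
  hr <- mcp_home_range(pts, level = 90) # remove ceiling(0.1*6) = 1
  # the later of the two tied far points (row 6) must be the one removed
  expect_true(2 %in% hr$polygon$x)
  expect_false(-2 %in% hr$polygon$x)
})

test_that("land-cover proportions match symmetry and exhaustive enumeration", {
  # two-category checkerboard split left/right, polygon covering everything
  codes <- matrix(rep(c(1L, 2L), each = 50), nrow = 10)
  g <- land_cover_grid(codes, 1, legend = c("1" = "west", "2" = "east"))
  hr <- mcp_home_range(
    data.frame(x = c(0, 10, 10, 0, 5), y = c(0, 0, 10, 10, 5)), 100
  )
  pr <- land_cover_proportions(hr, g)
  expect_equal(sort(pr$proportion), c(0.5, 0.5))

  # polygon strictly inside one category
  hr_w <- mcp_home_range(
    data.frame(x = c(0.2, 4.2, 4.2, 0.2, 2), y = c(0.2, 0.2, 4.2, 4.2, 2)), 100
  )
  pr_w <- land_cover_proportions(hr_w, g)
  expect_equal(pr_w$proportion[pr_w$category == "west"], 1)
  expect_equal(pr_w$proportion[pr_w$category == "east"], 0)

  # random convex polygons on random grids vs. a ray-casting oracle
  withr::with_seed(13, {
    for (rep in 1:5) {
      codes <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
      g <- land_cover_grid(codes, 1)
      pts <- data.frame(x = runif(12, 1, 19), y = runif(12, 1, 19))
      hr <- mcp_home_range(pts, 100)
      pr <- land_cover_proportions(hr, g)
      centers <- expand.grid(
        y = seq(0.5, 19.5, by = 1), x = seq(0.5, 19.5, by = 1)
      )
      inside <- raycast_inside(
        hr$polygon$x, hr$polygon$y, centers$x, centers$y
      )
      code_at <- codes[cbind(
        match(centers$y, seq(0.5, 19.5, 1)),
        match(centers$x, seq(0.5, 19.5, 1))
      )]
      counts <- table(factor(code_at[inside], levels = 1:3))
      oracle <- as.numeric(counts) / sum(counts)
      expect_equal(
        pr$proportion[match(as.character(1:3), pr$category)],
        oracle,
        tolerance = 1e-12
      )
    }
  })
})

test_that("a polygon covering no cell centers errors", {
  codes <- matrix(1L, 10, 10)
  g <- land_cover_grid(codes, 10) # centers at 5, 15, ...
  hr <- list(polygon = tibble::tibble(
    x = c(0.1, 0.9, 0.9, 0.1), y = c(0.1, 0.1, 0.9, 0.9)
  ))
  expect_error(land_cover_proportions(hr, g), "no grid-cell centers")
})

test_that("availability tables exclude outsized home ranges and thin months", {
  # 10 animal-months with areas ~1..10: squares of increasing side
  mk <- function(i, id, sex) {
    s <- sqrt(i)
    tibble::tibble(
      id = id, sex = sex, year = 2020L, month = i, hour = 0L,
      x = c(0, s, s, 0, s / 2), y = c(0, 0, s, s, s / 2), category = "a"
    )
  }
  tel <- dplyr::bind_rows(lapply(1:10, function(i) mk(i, "a1", "female")))
  codes <- matrix(1L, 50, 50)
  g <- land_cover_grid(codes, 0.1, origin = c(-1, -1), legend = c("1" = "a"))
  av <- build_availability_table(tel, g,
    level = 100, cutoff_percentile = 90
  )
  ex <- exclusion_log(av)
  expect_identical(nrow(ex), 1L)
  expect_identical(ex$month, 10L) # only the largest area excluded
  expect_match(ex$reason, "size cut-off")
  expect_identical(length(unique(av$month)), 9L)

  # absolute thresholds above every area: nothing excluded
  av2 <- build_availability_table(tel, g,
    level = 100, cutoff_area = c(female = 182, male = 459)
  )
  expect_identical(nrow(exclusion_log(av2)), 0L)

  # an animal-month with too few fixes is logged, not fitted
  tel3 <- dplyr::bind_rows(tel, tibble::tibble(
    id = "a2", sex = "male", year = 2020L, month = 1L, hour = 0L,
    x = c(0, 1, 0.5), y = c(0, 1, 0), category = "a"
  ))
  av3 <- build_availability_table(tel3, g,
    level = 100, cutoff_area = c(female = 182, male = 459)
  )
  ex3 <- exclusion_log(av3)
  expect_identical(ex3$id, "a2")
  expect_match(ex3$reason, "insufficient fixes")
})

test_that("every emitted animal-month availability lies on the simplex", {
  withr::with_seed(14, {
    codes <- matrix(sample(1:4, 2500, replace = TRUE), 50, 50)
    g <- land_cover_grid(codes, 1)
    tel <- dplyr::bind_rows(lapply(1:6, function(i) {
      tibble::tibble(
        id = sprintf("a%d", i), sex = "female", year = 2020L, month = 6L,
        hour = 0L, x = runif(30, 5, 45), y = runif(30, 5, 45), category = "1"
      )
    }))
  })
  av <- build_availability_table(tel, g, level = 95)
  sums <- tapply(av$proportion, paste(av$id, av$month), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(av$proportion >= 0))
})

test_that("ESRI ASCII grids round-trip through the reader", {
  tf <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 3", "nrows 2", "xllcorner 100", "yllcorner 200",
    "cellsize 10", "NODATA_value -9999",
    "1 1 2", # northern row
    "2 3 3" # southern row
  ), tf)
  g <- read_asc_grid(tf)
  expect_identical(dim(g$codes), c(2L, 3L))
  expect_identical(g$codes[1, ], c(2L, 3L, 3L)) # south row stored first
  expect_identical(g$codes[2, ], c(1L, 1L, 2L))
  expect_equal(g$origin, c(100, 200))
  expect_equal(g$cell_size, 10)
})
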