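test_that("pairwise datasets code presence and join focal availability", {
  tel <- toy_telemetry(c("f", "f", "r", "r", "r", "other"))
  av <- toy_availability(c(f = 0.2, r = 0.5, other = 0.3))
  pd <- build_pairwise_data(tel, av, focal = "f", reference = "r")
  expect_identical(nrow(pd), 5L)
  expect_identical(pd$present, c(1L, 1L, 0L, 0L, 0L))
  expect_true(all(pd$rel_availability == 0.2)) # focal availability, always
  expect_identical(attr(pd, "n_dropped_zero_availability"), 0L)

  tel10 <- toy_telemetry(c(rep("f", 4), rep("r", 4), "x", "x"))
  av10 <- toy_availability(c(f = 0.3, r = 0.4, x = 0.3))
  expect_identical(nrow(build_pairwise_data(tel10, av10, "f", "r")), 8L)
})

test_that("zero focal availability drops the row and counts it", {
  tel <- toy_telemetry(c("f", "r"))
  av <- toy_availability(c(f = 0, r = 1))
  expect_error(build_pairwise_data(tel, av, "f", "r"), "no usable rows")
  # with a second animal-month where focal is available, rows survive
  tel2 <- dplyr::bind_rows(
    tel,
    dplyr::mutate(toy_telemetry(c("f", "r")), id = "a2")
  )
  av2 <- dplyr::bind_rows(av, dplyr::mutate(av, id = "a2",
    proportion = c(0.5, 0.5)
  ))
  pd <- build_pairwise_data(tel2, av2, "f", "r")
  expect_identical(nrow(pd), 2L)
  expect_identical(attr(pd, "n_dropped_zero_availability"), 2L)
})

test_that("pure proportionality yields a near-zero availability deviation", {
  # generative truth: OR exactly proportional to availability, so the
  # smooth deviation term should be flat
  withr::with_seed(15, {
    n <- 20000
    ra <- runif(n, 0.05, 0.8)
    p <- plogis(log(ra) + 0.3) # log OR = log(ra) + const
    pd <- tibble::tibble(
      present = rbinom(n, 1, p), rel_availability = ra,
      hour = sample(0:23, n, TRUE), month = sample(1:12, n, TRUE),
      sex = sample(c("female", "male"), n, TRUE),
      id = sample(sprintf("a%d", 1:25), n, TRUE), year = 2020L
    )
  })
  m <- fit_log_odds(pd, model_spec("smooth", "none"))
  xs <- seq(0.06, 0.79, length.out = 50)
  dev_term <- predict_log_or(m, xs) - log(xs) - coef(m$gam)[["(Intercept)"]]
  expect_lt(max(abs(dev_term - mean(dev_term))), 0.15)
})

test_that("a constant log OR is recovered by the parametric availability term", {
  # truth: log OR = -1 regardless of availability; with the offset in place
  # the parametric log-availability coefficient must cancel the offset
  withr::with_seed(16, {
    n <- 8000
    ra <- runif(n, 0.05, 0.8)
    pd <- tibble::tibble(
      present = rbinom(n, 1, plogis(-1)), rel_availability = ra,
      hour = 0L, month = 6L, sex = "female",
      id = sample(sprintf("a%d", 1:20), n, TRUE), year = 2020L
    )
  })
  m <- fit_log_odds(pd, model_spec("parametric_log", "none"))
  cf <- coef(m$gam)
  expect_lt(abs(cf[["log_ra"]] - (-1)), 0.1) # cancels the offset slope
  expect_lt(abs(cf[["(Intercept)"]] - (-1)), 0.1)
})

test_that("degenerate pairwise data is rejected", {
  pd <- tibble::tibble(
    present = rep(1L, 100), rel_availability = runif(100, 0.2, 0.8),
    hour = 0L, month = 6L, sex = "female", id = "a1", year = 2020L
  )
  expect_error(fit_log_odds(pd), "both response levels")
  expect_error(
    fit_log_odds(dplyr::mutate(pd, present = rep(0:1, 50)), min_n = 200),
    "too few rows"
  )
})

test_that("the offset makes predictions shift by exactly log(c) under rescaling", {
  withr::with_seed(17, {
    n <- 2000
    ra <- runif(n, 0.1, 0.5)
    pd <- tibble::tibble(
      present = rbinom(n, 1, plogis(log(ra))), rel_availability = ra,
      hour = 0L, month = 6L, sex = "female",
      id = sample(sprintf("a%d", 1:10), n, TRUE), year = 2020L
    )
  })
  m <- fit_log_odds(pd, model_spec("offset_only", "none"))
  xs <- c(0.12, 0.2, 0.3, 0.4, 0.48)
  expect_equal(
    predict_log_or(m, xs * 1.02) - predict_log_or(m, xs),
    rep(log(1.02), 5),
    tolerance = 1e-9
  )
  # null-model arithmetic: OR = availability * exp(intercept)
  expect_equal(
    predict_log_or(m, xs),
    log(xs) + coef(m$gam)[["(Intercept)"]],
    tolerance = 1e-9
  )
})

test_that("prediction outside the training availability range needs an explicit flag", {
  withr::with_seed(18, {
    n <- 500
    ra <- runif(n, 0.2, 0.6)
    pd <- tibble::tibble(
      present = rbinom(n, 1, 0.4), rel_availability = ra,
      hour = 0L, month = 6L, sex = "female",
      id = sample(sprintf("a%d", 1:8), n, TRUE), year = 2020L
    )
  })
  m <- fit_log_odds(pd, model_spec("offset_only", "none"))
  expect_error(predict_log_or(m, 0.05), "training range")
  expect_silent(predict_log_or(m, 0.05, extrapolate = TRUE))
  expect_identical(predict_log_or(m, 0.3), predict_log_or(m, 0.3))
})

test_that("cyclic temporal smooths fit and wrap around midnight and new year", {
  withr::with_seed(19, {
    n <- 6000
    hour <- sample(0:23, n, TRUE)
    month <- sample(1:12, n, TRUE)
    ra <- runif(n, 0.1, 0.6)
    eta <- log(ra) + 0.8 * sin(2 * pi * hour / 24) +
      0.5 * cos(2 * pi * month / 12)
    pd <- tibble::tibble(
      present = rbinom(n, 1, plogis(eta)), rel_availability = ra,
      hour = hour, month = month, sex = "female",
      id = sample(sprintf("a%d", 1:20), n, TRUE), year = 2020L
    )
  })
  m <- fit_log_odds(pd, model_spec("offset_only", "cyclic"))
  # continuity at the cyclic seams (hour 23.5 vs -0.5 is the same instant)
  f_a <- predict_log_or(m, 0.3, hour = 0, month = 6)
  f_b <- predict_log_or(m, 0.3, hour = 23.99, month = 6)
  expect_lt(abs(f_a - f_b), 0.15)
  # the daily cycle is actually picked up
  f_night <- predict_log_or(m, 0.3, hour = 6, month = 6)
  f_noon <- predict_log_or(m, 0.3, hour = 18, month = 6)
  expect_gt(f_night - f_noon, 0.8) # truth: 2 * 0.8 * sin amplitude
})

test_that("individual random-intercept variance is recovered across seeds", {
  # 30 animals x 300 fixes, prevalence sd 0.8 on the log-odds scale; small
  # baseline use keeps the reference near 1 so the generative shift is close
  # to a clean intercept shift
  sds <- vapply(1:10, function(s) {
    sc <- sim_scenario(
      n_individuals = 15, fixes_per_month = 300,
      categories = c("focal", "ref"),
      individual_prevalence_sd = 0.8, seed = 100 + s
    )
    tel <- simulate_telemetry(sc, list(truth_curve("focal", "II", 0.04, 0.05)))
    pd <- build_pairwise_data(tel, attr(tel, "availability"), "focal", "ref")
    m <- fit_log_odds(pd, model_spec("smooth", "none"))
    vc <- mgcv::gam.vcomp(m$gam)
    if (is.list(vc)) vc <- vc$vc
    unname(vc["s(id)", "std.dev"])
  }, numeric(1))
  # with 30 groups the SD estimator itself has sd ~ 0.1, so individual seeds
  # scatter; the ensemble must centre on the truth without gross attenuation
  expect_true(all(sds > 0.3 & sds < 1.3))
  expect_gte(mean(sds), 0.5)
  expect_lte(mean(sds), 1.1)
})

test_that("grouped cross-validation ranks structures and caps folds at the animal count", {
  withr::with_seed(20, {
    n <- 1200
    ra <- runif(n, 0.05, 0.8)
    pd <- tibble::tibble(
      present = rbinom(n, 1, plogis(log(ra) + 0.5)), rel_availability = ra,
      hour = 0L, month = 6L, sex = "female",
      id = sample(sprintf("a%d", 1:7), n, TRUE), year = 2020L
    )
  })
  specs <- list(
    offset = model_spec("offset_only", "none"),
    smooth = model_spec("smooth", "none")
  )
  expect_warning(
    cv <- cross_validate(pd, specs, k = 10, min_n = 50),
    "reducing folds"
  )
  expect_identical(nrow(cv), 2L)
  expect_identical(sum(cv$chosen), 1L)
  # chosen score is the minimum by construction
  expect_identical(
    unname(cv$mean_logloss[cv$chosen]), min(cv$mean_logloss)
  )
  # identical candidates score identically; tie-break keeps the first
  cv2 <- suppressWarnings(cross_validate(
    pd, list(a = specs$offset, b = specs$offset),
    k = 5, min_n = 50
  ))
  expect_equal(unname(cv2$mean_logloss[1]), unname(cv2$mean_logloss[2]))
  expect_identical(cv2$spec_id[cv2$chosen], "a")
})

test_that("cross-validation identifies the generative structure under a strong response", {
  # truth: strong type-II functional response => log OR far from offset-only
  wins <- 0L
  for (s in 1:3) {
    sc <- sim_scenario(
      n_individuals = 10, fixes_per_month = 250,
      categories = c("focal", "ref"),
      individual_prevalence_sd = 0.1, seed = 300 + s
    )
    tel <- simulate_telemetry(sc, list(truth_curve("focal", "II", 0.6, 0.05)))
    pd <- build_pairwise_data(tel, attr(tel, "availability"), "focal", "ref")
    cv <- cross_validate(pd, list(
      offset = model_spec("offset_only", "none"),
      smooth = model_spec("smooth", "none")
    ), k = 5, min_n = 50)
    wins <- wins + (attr(cv, "chosen")$availability == "smooth")
  }
  expect_identical(wins, 3L)
})

test_that("the default candidate grid has 18 structures and one offset is always present", {
  specs <- default_candidate_specs()
  expect_identical(length(specs), 18L)
  expect_identical(anyDuplicated(names(specs)), 0L)
  expect_error(
    model_spec("offset_only", availability_by_sex = TRUE),
    "availability deviation"
  )
})
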