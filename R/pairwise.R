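#' Build a focal-versus-reference pairwise dataset
#'
#' Restricts telemetry to fixes in the focal or reference category, codes the
#' binary response `present` (1 = focal used, 0 = reference used), and joins
#' the relative availability of the *focal* category in the recording
#' animal-month — also for reference fixes, since availability describes the
#' choice situation, not the outcome. Rows whose focal availability is zero
#' are dropped (their log-availability offset is undefined) and counted in
#' the `"n_dropped_zero_availability"` attribute.
#'
#' @param telemetry Tibble of fixes with columns `id`, `sex`, `year`,
#'   `month`, `hour`, `category`.
#' @param availability Availability table with columns `id`, `year`, `month`,
#'   `category`, `proportion` covering the telemetry animal-months.
#' @param focal,reference Category labels, `focal != reference`.
#'
#' @return Tibble with columns `present`, `focal_category`,
#'   `rel_availability`, `hour`, `month`, `sex`, `id`, `year`, in input fix
#'   order.
#' @export
build_pairwise_data <- function(telemetry, availability, focal, reference) {
  stopifnot(is.data.frame(telemetry), is.data.frame(availability))
  if (identical(focal, reference)) {
    stop("`focal` and `reference` must differ.", call. = FALSE)
  }
  av_focal <- availability |>
    dplyr::filter(.data$category == focal) |>
    dplyr::select("id", "year", "month", rel_availability = "proportion")
  out <- telemetry |>
    dplyr::filter(.data$category %in% c(focal, reference)) |>
    dplyr::mutate(present = as.integer(.data$category == focal)) |>
    dplyr::left_join(av_focal, by = c("id", "year", "month")) |>
    dplyr::select(
      "present", "rel_availability", "hour", "month", "sex", "id", "year"
    ) |>
    dplyr::mutate(focal_category = focal, .after = "present")
  if (anyNA(out$rel_availability)) {
    stop("availability table does not cover every telemetry animal-month.",
      call. = FALSE
    )
  }
  n0 <- sum(out$rel_availability <= 0)
  out <- dplyr::filter(out, .data$rel_availability > 0)
  if (nrow(out) == 0L) {
    stop("no usable rows: focal category absent from every home range.",
      call. = FALSE
    )
  }
  attr(out, "n_dropped_zero_availability") <- n0
  attr(out, "reference") <- reference
  out
}

#' Specify a baseline-category logit model structure
#'
#' Describes one candidate structure for the focal-versus-reference logit
#' model. The offset `log(rel_availability)` — the null of use proportional
#' to availability — is *always* included; the availability term captures
#' deviations from proportionality (the functional response):
#' `"offset_only"` (no deviation), `"parametric_log"` (a linear term in log
#' availability) or `"smooth"` (a penalized cubic regression spline with the
#' smoothing parameter fixed at `lambda`, default 2). The temporal term is a
#' cyclic tensor-product smooth in (hour, month) with periods 24 and 12,
#' optionally sex-specific. Random intercepts for individual and year are
#' penalized group-level intercepts with a shared variance per grouping
#' factor.
#'
#' @param availability One of `"offset_only"`, `"parametric_log"`,
#'   `"smooth"`.
#' @param temporal One of `"none"`, `"cyclic"`, `"cyclic_by_sex"`.
#' @param sex_main Include a sex main effect.
#' @param availability_by_sex Sex-specific availability deviation (requires
#'   `availability != "offset_only"`; implies a sex main effect).
#' @param lambda Fixed smoothing parameter of the availability spline.
#' @param re_id,re_year Random intercepts for individual / year.
#' @param k_avail,k_hour,k_month Basis dimensions of the availability spline
#'   and the cyclic hour and month marginals.
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(availability = c("smooth", "offset_only", "parametric_log"),
                       temporal = c("none", "cyclic", "cyclic_by_sex"),
                       sex_main = FALSE,
                       availability_by_sex = FALSE,
                       lambda = 2,
                       re_id = TRUE, re_year = TRUE,
                       k_avail = 6, k_hour = 8, k_month = 6) {
  availability <- match.arg(availability)
  temporal <- match.arg(temporal)
  if (availability_by_sex && availability == "offset_only") {
    stop("`availability_by_sex` requires an availability deviation term.",
      call. = FALSE
    )
  }
  stopifnot(lambda > 0, k_avail >= 3, k_hour >= 4, k_month >= 4)
  structure(
    list(
      availability = availability, temporal = temporal,
      sex_main = isTRUE(sex_main),
      availability_by_sex = isTRUE(availability_by_sex),
      lambda = lambda, re_id = isTRUE(re_id), re_year = isTRUE(re_year),
      k_avail = k_avail, k_hour = k_hour, k_month = k_month
    ),
    class = "model_spec"
  )
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(
    "avail=", x$availability,
    if (x$availability_by_sex) ":sex",
    " temporal=", x$temporal,
    if (x$sex_main) " +sex",
    " re=", paste(c("id", "year")[c(x$re_id, x$re_year)], collapse = "+")
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n")
  invisible(x)
}

#' Default candidate model structures
#'
#' The default grid spans every structure the modelling framework names:
#' the three availability terms crossed with the three temporal terms (9),
#' the sex-specific availability deviation where legal (6 more), and three
#' smooth-availability variants without the year random intercept, for 18
#' candidates in total.
#'
#' @param lambda Fixed availability smoothing parameter for all candidates.
#' @return Named list of [model_spec()]s.
#' @export
default_candidate_specs <- function(lambda = 2) {
  specs <- list()
  for (av in c("offset_only", "parametric_log", "smooth")) {
    for (tm in c("none", "cyclic", "cyclic_by_sex")) {
      specs[[length(specs) + 1L]] <- model_spec(av, tm,
        sex_main = (tm == "cyclic_by_sex"), lambda = lambda
      )
    }
  }
  for (av in c("parametric_log", "smooth")) {
    for (tm in c("none", "cyclic", "cyclic_by_sex")) {
      specs[[length(specs) + 1L]] <- model_spec(av, tm,
        sex_main = TRUE, availability_by_sex = TRUE, lambda = lambda
      )
    }
  }
  for (tm in c("none", "cyclic", "cyclic_by_sex")) {
    specs[[length(specs) + 1L]] <- model_spec("smooth", tm,
      sex_main = (tm == "cyclic_by_sex"), re_year = FALSE, lambda = lambda
    )
  }
  names(specs) <- vapply(specs, format, character(1))
  specs
}

spec_formula <- function(spec, data) {
  terms <- character()
  if (spec$sex_main || spec$availability_by_sex ||
    spec$temporal == "cyclic_by_sex") {
    terms <- c(terms, "sex")
  }
  if (spec$availability == "parametric_log") {
    terms <- c(terms, "log_ra")
    if (spec$availability_by_sex) terms <- c(terms, "log_ra:sex")
  } else if (spec$availability == "smooth") {
    if (spec$availability_by_sex) {
      terms <- c(terms, sprintf(
        "s(rel_availability, by = sex, bs = 'cr', k = %d, sp = %g)",
        spec$k_avail, spec$lambda
      ))
    } else {
      terms <- c(terms, sprintf(
        "s(rel_availability, bs = 'cr', k = %d, sp = %g)",
        spec$k_avail, spec$lambda
      ))
    }
  }
  if (spec$temporal != "none") {
    by <- if (spec$temporal == "cyclic_by_sex") ", by = sex" else ""
    terms <- c(terms, sprintf(
      "te(hour, month, bs = c('cc', 'cc'), k = c(%d, %d)%s)",
      spec$k_hour, spec$k_month, by
    ))
  }
  if (spec$re_id && nlevels(data$id) > 1L) {
    terms <- c(terms, "s(id, bs = 're')")
  }
  if (spec$re_year && nlevels(data$year) > 1L) {
    terms <- c(terms, "s(year, bs = 're')")
  }
  rhs <- paste(c("offset(log_ra)", terms), collapse = " + ")
  stats::as.formula(paste("present ~", rhs))
}

#' Fit a focal-versus-reference log-odds model
#'
#' Fits the binomial logit model described by a [model_spec()] to a pairwise
#' dataset from [build_pairwise_data()], via a penalized generalized additive
#' model (REML). The fixed offset `log(rel_availability)` encodes
#' proportional use; fitted availability terms describe the deviation from
#' proportionality. If the random-intercept fit fails, the model is refitted
#' without random effects and a warning is recorded.
#'
#' @param data Pairwise dataset (`present`, `rel_availability`, `hour`,
#'   `month`, `sex`, `id`, `year`).
#' @param spec A [model_spec()].
#' @param min_n Minimum number of rows required (default 50).
#'
#' @return An object of class `log_odds_model` wrapping the fitted
#'   `mgcv::gam` together with the spec, the training availability range and
#'   factor levels. Supports [predict_log_or()], [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_log_odds <- function(data, spec = model_spec(), min_n = 50) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"))
  req <- c("present", "rel_availability", "hour", "month", "sex", "id", "year")
  if (!all(req %in% names(data))) {
    stop(
      "pairwise data must have columns: ", paste(req, collapse = ", "), ".",
      call. = FALSE
    )
  }
  if (nrow(data) < min_n) {
    stop("too few rows (", nrow(data), " < ", min_n, ").", call. = FALSE)
  }
  if (length(unique(data$present)) < 2L) {
    stop("both response levels (focal and reference use) must be present.",
      call. = FALSE
    )
  }
  if (any(data$rel_availability <= 0)) {
    stop("`rel_availability` must be strictly positive.", call. = FALSE)
  }
  df <- data |>
    dplyr::mutate(
      log_ra = log(.data$rel_availability),
      sex = factor(.data$sex),
      id = factor(.data$id),
      year = factor(.data$year),
      hour = as.numeric(.data$hour),
      month = as.numeric(.data$month)
    )
  if (spec$temporal != "none" &&
    (length(unique(df$hour)) < 4L || length(unique(df$month)) < 4L)) {
    stop("temporal smooth needs at least 4 distinct hours and months.",
      call. = FALSE
    )
  }
  if (spec$availability == "smooth" &&
    length(unique(df$rel_availability)) < spec$k_avail + 1L) {
    stop("availability smooth needs more distinct availability values.",
      call. = FALSE
    )
  }

  knots <- NULL
  if (spec$temporal != "none") {
    knots <- list(hour = c(-0.5, 23.5), month = c(0.5, 12.5))
  }
  fit_once <- function(sp) {
    fml <- spec_formula(sp, df)
    mgcv::gam(fml,
      family = stats::binomial(), data = df, method = "REML", knots = knots
    )
  }
  re_dropped <- FALSE
  fit <- tryCatch(fit_once(spec), error = function(e) e)
  if (inherits(fit, "error") && (spec$re_id || spec$re_year)) {
    warning(
      "random-intercept fit failed (", conditionMessage(fit),
      "); refitting without random effects.",
      call. = FALSE
    )
    spec2 <- spec
    spec2$re_id <- FALSE
    spec2$re_year <- FALSE
    fit <- tryCatch(fit_once(spec2), error = function(e) e)
    re_dropped <- TRUE
  }
  if (inherits(fit, "error")) {
    stop("model fit failed: ", conditionMessage(fit), call. = FALSE)
  }
  n_para <- if (length(fit$smooth)) {
    fit$smooth[[1]]$first.para - 1L
  } else {
    length(stats::coef(fit))
  }
  para_cf <- stats::coef(fit)[seq_len(n_para)]
  if (any(!is.finite(para_cf)) || any(abs(para_cf) > 15)) {
    stop(
      "quasi-complete separation suspected (extreme coefficients); ",
      "use a coarser model spec or more data.",
      call. = FALSE
    )
  }
  structure(
    list(
      gam = fit, spec = spec,
      focal = if ("focal_category" %in% names(data)) {
        data$focal_category[1]
      } else {
        NA_character_
      },
      reference = attr(data, "reference") %||% NA_character_,
      train_range = range(df$rel_availability),
      sex_levels = levels(df$sex),
      id_levels = levels(df$id),
      year_levels = levels(df$year),
      n = nrow(df), deviance = stats::deviance(fit),
      re_dropped = re_dropped
    ),
    class = "log_odds_model"
  )
}

#' Predict the log odds ratio of focal versus reference use
#'
#' Population-level prediction on the link scale (random intercepts at
#' zero), including the log-availability offset: the result is the log odds
#' ratio `log(pi_focal / pi_reference)` for an animal encountering the focal
#' or reference type at the stated availability and time.
#'
#' @param object A fitted [fit_log_odds()] model (or a [log_or_stub()]).
#' @param rel_availability Focal-category availability; must lie within the
#'   training range unless `extrapolate = TRUE`.
#' @param hour,month,sex Time slot and sex (recycled against
#'   `rel_availability`).
#' @param extrapolate Allow availability outside the training range.
#' @param ... Unused.
#'
#' @return Numeric vector of log odds ratios.
#' @export
predict_log_or <- function(object, rel_availability, hour = 0, month = 6,
                           sex = NULL, extrapolate = FALSE, ...) {
  UseMethod("predict_log_or")
}

#' @export
predict_log_or.log_odds_model <- function(object, rel_availability, hour = 0,
                                          month = 6, sex = NULL,
                                          extrapolate = FALSE, ...) {
  ra <- as.numeric(rel_availability)
  if (any(ra <= 0)) stop("`rel_availability` must be positive.", call. = FALSE)
  rng <- object$train_range
  if (!extrapolate &&
    (any(ra < rng[1] - 1e-12) || any(ra > rng[2] + 1e-12))) {
    stop(
      sprintf(
        "availability outside the training range [%.4g, %.4g]; set `extrapolate = TRUE` to override.",
        rng[1], rng[2]
      ),
      call. = FALSE
    )
  }
  sex <- sex %||% object$sex_levels[1]
  nd <- tibble::tibble(
    rel_availability = ra, log_ra = log(ra),
    hour = as.numeric(hour), month = as.numeric(month),
    sex = factor(sex, levels = object$sex_levels),
    id = factor(object$id_levels[1], levels = object$id_levels),
    year = factor(object$year_levels[1], levels = object$year_levels)
  )
  if (anyNA(nd$sex)) {
    stop("unknown sex level; training levels: ",
      paste(object$sex_levels, collapse = ", "),
      call. = FALSE
    )
  }
  excl <- intersect(
    c("s(id)", "s(year)"),
    vapply(object$gam$smooth, `[[`, character(1), "label")
  )
  as.numeric(stats::predict(object$gam,
    newdata = nd, type = "link",
    exclude = if (length(excl)) excl else NULL,
    newdata.guaranteed = TRUE
  ))
}

#' Stub log-odds model with a fixed log-OR function
#'
#' Builds a minimal object usable wherever a fitted log-odds model is
#' expected, whose prediction is a user-supplied function of availability and
#' time slot. Useful for demonstrations and for testing the multinomial
#' combination step in isolation.
#'
#' @param fun `function(rel_availability, hour, month, sex)` returning the
#'   log odds ratio (the offset contribution, if wanted, must be part of
#'   `fun`).
#' @param focal,reference Category labels.
#' @param range Availability range the stub claims to cover.
#' @return An object of class `log_or_stub`.
#' @export
log_or_stub <- function(fun, focal, reference, range = c(1e-6, 1)) {
  stopifnot(is.function(fun))
  structure(
    list(fun = fun, focal = focal, reference = reference,
      train_range = range, sex_levels = c("female", "male")
    ),
    class = "log_or_stub"
  )
}

#' @export
predict_log_or.log_or_stub <- function(object, rel_availability, hour = 0,
                                       month = 6, sex = NULL,
                                       extrapolate = FALSE, ...) {
  ra <- as.numeric(rel_availability)
  rng <- object$train_range
  if (!extrapolate &&
    (any(ra < rng[1] - 1e-12) || any(ra > rng[2] + 1e-12))) {
    stop("availability outside the stub's declared range.", call. = FALSE)
  }
  sex <- sex %||% object$sex_levels[1]
  object$fun(ra, hour, month, sex)
}

#' @export
print.log_odds_model <- function(x, ...) {
  cat("<log_odds_model> ", x$focal %||% "?", " vs ", x$reference %||% "?",
    "\n  ", format(x$spec), "\n  n = ", x$n,
    ", availability range [", sprintf("%.3g", x$train_range[1]), ", ",
    sprintf("%.3g", x$train_range[2]), "]\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.log_odds_model <- function(x, ...) {
  sm <- summary(x$gam)
  pt <- sm$p.table
  out <- tibble::tibble(
    term = rownames(pt),
    estimate = pt[, "Estimate"],
    std.error = pt[, "Std. Error"],
    statistic = pt[, 3],
    p.value = pt[, 4]
  )
  if (!is.null(sm$s.table) && nrow(sm$s.table)) {
    st <- sm$s.table
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = rownames(st),
      estimate = NA_real_, std.error = NA_real_,
      statistic = st[, "Chi.sq"], p.value = st[, "p-value"]
    ))
  }
  out
}

#' @export
glance.log_odds_model <- function(x, ...) {
  tibble::tibble(
    focal = x$focal %||% NA_character_,
    reference = x$reference %||% NA_character_,
    n = x$n,
    deviance = x$deviance,
    edf = sum(x$gam$edf),
    aic = stats::AIC(x$gam),
    re_dropped = x$re_dropped
  )
}
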