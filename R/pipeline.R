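#' Run the full functional-response pipeline
#'
#' Orchestrates the analysis end to end: availability (from a simulation
#' scenario, a supplied availability table, or telemetry plus a land-cover
#' grid), one focal-versus-reference log-odds model per non-reference
#' category (optionally chosen by cross-validation), proportional-use curves
#' per category and time slot via the multinomial link, and a Holling
#' type I/II/III fit with ecological diagnostics for each curve.
#'
#' `config` is a list with elements:
#' \describe{
#'   \item{reference_category}{required; the baseline land-cover type.}
#'   \item{scenario, truths}{a [sim_scenario()] plus [truth_curve()]s for
#'     synthetic runs; *or*}
#'   \item{telemetry, availability}{observed fixes plus an availability
#'     table; *or* `telemetry` plus `grid` (a [land_cover_grid()]), in which
#'     case [build_availability_table()] is run with `level`, `min_fixes`,
#'     `cutoff_percentile` / `cutoff_area`, `cutoff_scope` from the config.}
#'   \item{spec}{a [model_spec()] (default: smooth availability deviation,
#'     no temporal term).}
#'   \item{candidates, cv_folds}{optional candidate list; when given, the
#'     structure is chosen per category by [cross_validate()].}
#'   \item{slots}{data frame of `month`/`hour` combinations to report
#'     (default months 6 and 12 by hours 0 and 12: summer/winter by
#'     midnight/noon).}
#'   \item{x_grid_size, x_quantiles}{use-curve grid resolution (default 200
#'     points between the 1st and 99th percentile of observed focal
#'     availability, clipped to the model's training range).}
#'   \item{min_n}{minimum rows per pairwise fit (default 50).}
#'   \item{out_dir}{optional output directory for per-stage CSVs and a JSON
#'     run manifest.}
#' }
#'
#' @param config Configuration list (see Details).
#'
#' @return An object of class `pipeline_result`: list with `summary` (one
#'   row per category, slot and sex: Holling type, `a`, `b`, `a_over_b`,
#'   `x_star`, crossings, inflection, regime, `rss`; absent tipping
#'   points/crossings are reported as 0 by convention), `curves` (long tibble
#'   of all use curves), `fits`, `models`, `availability`, `exclusions` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$reference_category)) {
    stop("config validation: `reference_category` is missing.", call. = FALSE)
  }
  reference <- config$reference_category

  if (!is.null(config$scenario)) {
    stopifnot(inherits(config$scenario, "sim_scenario"))
    if (!identical(config$scenario$reference, reference)) {
      stop("config validation: `reference_category` disagrees with the scenario reference.",
        call. = FALSE
      )
    }
    telemetry <- simulate_telemetry(config$scenario, config$truths)
    availability <- attr(telemetry, "availability")
    exclusions <- tibble::tibble()
  } else if (!is.null(config$telemetry)) {
    telemetry <- config$telemetry
    if (!is.null(config$availability)) {
      availability <- config$availability
      exclusions <- exclusion_log(availability)
    } else if (!is.null(config$grid)) {
      availability <- build_availability_table(
        telemetry, config$grid,
        level = config$level %||% 95,
        min_fixes = config$min_fixes %||% 5,
        cutoff_percentile = config$cutoff_percentile %||% 90,
        cutoff_area = config$cutoff_area,
        cutoff_scope = config$cutoff_scope %||% "month"
      )
      exclusions <- exclusion_log(availability)
    } else {
      stop("config validation: supply `availability` or `grid` with `telemetry`.",
        call. = FALSE
      )
    }
  } else {
    stop("config validation: supply either `scenario`+`truths` or `telemetry`.",
      call. = FALSE
    )
  }

  categories <- sort(unique(availability$category))
  if (!reference %in% categories) {
    stop("config validation: reference category not present in the availability table.",
      call. = FALSE
    )
  }
  nonref <- setdiff(categories, reference)
  spec <- config$spec %||% model_spec("smooth", "none")
  min_n <- config$min_n %||% 50

  models <- list()
  pairwise <- list()
  cv_tables <- list()
  for (focal in nonref) {
    pdat <- build_pairwise_data(telemetry, availability, focal, reference)
    sp <- spec
    if (!is.null(config$candidates)) {
      cv <- cross_validate(pdat, config$candidates,
        k = config$cv_folds %||% 10, min_n = min_n
      )
      cv_tables[[focal]] <- cv
      sp <- attr(cv, "chosen")
    }
    models[[focal]] <- fit_log_odds(pdat, sp, min_n = min_n)
    pairwise[[focal]] <- pdat
  }

  slots <- config$slots %||%
    tidyr::crossing(month = c(6L, 12L), hour = c(0L, 12L))
  uses_sex <- spec$sex_main || spec$availability_by_sex ||
    spec$temporal == "cyclic_by_sex" || !is.null(config$candidates)
  sexes <- if (uses_sex && "sex" %in% names(availability)) {
    sort(unique(availability$sex))
  } else {
    NA_character_
  }

  n_grid <- config$x_grid_size %||% 200
  qs <- config$x_quantiles %||% c(0.01, 0.99)

  curves <- list()
  fits <- list()
  summary_rows <- list()
  for (focal in nonref) {
    av_focal <- availability$proportion[availability$category == focal]
    rng <- models[[focal]]$train_range
    lo <- max(stats::quantile(av_focal, qs[1]), rng[1], 1e-6)
    hi <- min(stats::quantile(av_focal, qs[2]), rng[2], 1 - 1e-6)
    if (!(hi > lo)) {
      stop("degenerate availability range for category ", focal, ".",
        call. = FALSE
      )
    }
    x_grid <- seq(lo, hi, length.out = n_grid)
    for (sx in sexes) {
      sx_arg <- if (is.na(sx)) NULL else sx
      bg <- mean_availability(availability, sex = sx_arg)
      bg <- bg[setdiff(names(bg), focal)]
      for (si in seq_len(nrow(slots))) {
        hour <- slots$hour[si]
        month <- slots$month[si]
        # focal grid is clipped to the focal model's training range above;
        # background categories may then sit slightly outside their own
        # observed combinations, so their splines are allowed to extrapolate
        crv <- use_curve(models, focal, x_grid, bg,
          hour = hour, month = month, sex = sx_arg, extrapolate = TRUE
        )
        fit <- fit_holling(crv)
        dg <- holling_diagnostics(fit)
        key <- paste(focal, sx, month, hour, sep = "|")
        curves[[key]] <- dplyr::mutate(tibble::as_tibble(crv),
          focal = focal, sex = sx, month = month, hour = hour, .before = 1
        )
        fits[[key]] <- fit
        summary_rows[[key]] <- tibble::tibble(
          focal = focal, sex = sx, month = month, hour = hour,
          type = fit$type, a = fit$a,
          b = ifelse(is.na(fit$b), 0, fit$b),
          a_over_b = dg$a_over_b,
          x_star = ifelse(is.na(dg$x_star), 0, dg$x_star),
          x_cross_low = ifelse(is.na(dg$x_cross_low), 0, dg$x_cross_low),
          x_cross_high = ifelse(is.na(dg$x_cross_high), 0, dg$x_cross_high),
          inflection = dg$inflection,
          regime = dg$regime,
          rss = fit$rss
        )
      }
    }
  }
  summary <- dplyr::bind_rows(summary_rows)
  curves_tbl <- dplyr::bind_rows(curves)

  manifest <- list(
    package = "habresp",
    version = as.character(utils::packageVersion("habresp")),
    r_version = R.version.string,
    reference_category = reference,
    categories = categories,
    spec = unclass(spec)[c(
      "availability", "temporal", "sex_main", "availability_by_sex",
      "lambda", "re_id", "re_year", "k_avail", "k_hour", "k_month"
    )],
    cv_used = !is.null(config$candidates),
    mcp_level = config$level %||% 95,
    min_fixes = config$min_fixes %||% 5,
    cutoff_percentile = config$cutoff_percentile %||% 90,
    cutoff_area = config$cutoff_area,
    cutoff_scope = config$cutoff_scope %||% "month",
    min_n = min_n,
    x_grid_size = n_grid,
    x_quantiles = qs,
    slots = slots,
    seed = if (!is.null(config$scenario)) config$scenario$seed else NULL,
    conventions = list(
      mcp_peeling = "farthest-from-centroid, ties keep earlier fixes",
      cell_inclusion = "cell center in polygon, boundary counts inside",
      background = "proportional rescale of per-sex mean availabilities",
      x_star_report = "0 when no crossing exists",
      random_intercepts = "set to zero for population-level curves"
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(availability,
      file.path(config$out_dir, "availability.csv"),
      row.names = FALSE
    )
    utils::write.csv(curves_tbl,
      file.path(config$out_dir, "use_curves.csv"),
      row.names = FALSE
    )
    utils::write.csv(summary,
      file.path(config$out_dir, "holling_summary.csv"),
      row.names = FALSE
    )
    if (nrow(exclusions)) {
      utils::write.csv(exclusions,
        file.path(config$out_dir, "exclusions.csv"),
        row.names = FALSE
      )
    }
    jsonlite::write_json(manifest,
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
  }

  structure(
    list(
      summary = summary, curves = curves_tbl, fits = fits, models = models,
      availability = availability, exclusions = exclusions,
      cv = if (length(cv_tables)) cv_tables else NULL,
      manifest = manifest
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$models), " fitted categories, ",
    nrow(x$summary), " summary rows\n",
    sep = ""
  )
  print(x$summary, n = 20)
  invisible(x)
}
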