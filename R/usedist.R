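#' Build an availability scenario around one focal category
#'
#' Fixes the focal category's availability at `x` and rescales the remaining
#' categories proportionally so that the whole vector sums to 1 (the
#' constraint the multinomial combination requires).
#'
#' @param focal Focal category label.
#' @param x Focal availability in `(0, 1)`.
#' @param mean_background Named nonnegative numeric vector of availabilities
#'   of all *other* categories (typically per-sex means of the observed
#'   availability table; see [mean_availability()]); must not be all zero and
#'   must not contain `focal`.
#'
#' @return A tibble (class `avail_scenario`) with columns `category` and
#'   `availability`, focal first, summing to 1.
#' @export
#' @examples
#' make_scenario("meadow", 0.4, c(conifer = 0.3, mixed_old = 0.2))
make_scenario <- function(focal, x, mean_background) {
  stopifnot(length(x) == 1L, is.numeric(x))
  if (!(x > 0 && x < 1)) {
    stop("focal availability `x` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (is.null(names(mean_background)) || any(names(mean_background) == "")) {
    stop("`mean_background` must be a named vector.", call. = FALSE)
  }
  if (focal %in% names(mean_background)) {
    stop("`mean_background` must not contain the focal category.",
      call. = FALSE
    )
  }
  if (any(mean_background < 0) || all(mean_background == 0)) {
    stop("background availabilities must be nonnegative, not all zero.",
      call. = FALSE
    )
  }
  bg <- mean_background / sum(mean_background) * (1 - x)
  out <- tibble::tibble(
    category = c(focal, names(bg)),
    availability = c(x, unname(bg))
  )
  class(out) <- c("avail_scenario", class(out))
  attr(out, "focal") <- focal
  out
}

#' Mean observed availability per category
#'
#' @param availability Availability table (`id`, `year`, `month`, `category`,
#'   `proportion`), optionally with a `sex` column.
#' @param sex Optional sex filter (requires a `sex` column).
#' @return Named numeric vector of per-category mean proportions.
#' @export
mean_availability <- function(availability, sex = NULL) {
  av <- availability
  if (!is.null(sex)) {
    stopifnot("sex" %in% names(av))
    av <- dplyr::filter(av, .data$sex == !!sex)
  }
  out <- av |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(m = mean(.data$proportion), .groups = "drop")
  stats::setNames(out$m, out$category)
}

#' Combine per-category log odds ratios into the use distribution
#'
#' Applies the multinomial (baseline-category) logit link: with `f_s` the
#' predicted log odds ratio of category `s` versus the reference — each
#' evaluated at *its own* availability from the scenario — the probability
#' that the next used location falls in category `i` is
#' `pi_i = exp(f_i) / (1 + sum_s exp(f_s))`, and
#' `pi_ref = 1 / (1 + sum_s exp(f_s))` (the reference's `f` is 0 for
#' identifiability). The denominator is shared by all categories, so the
#' probabilities sum to 1 by construction.
#'
#' @param models List of fitted log-odds models (or [log_or_stub()]s), one
#'   per non-reference category, all sharing the same reference.
#' @param scenario An [make_scenario()] availability scenario covering every
#'   category.
#' @param hour,month,sex Time slot passed to [predict_log_or()].
#' @param extrapolate Allow availabilities outside each model's training
#'   range.
#'
#' @return A tibble (class `use_distribution`) with one row per category:
#'   `category`, `availability`, `log_or` (0 for the reference) and `use`
#'   (probabilities summing to 1).
#' @export
combine_use <- function(models, scenario, hour = 0, month = 6, sex = NULL,
                        extrapolate = FALSE) {
  stopifnot(is.list(models), length(models) >= 1L)
  focals <- vapply(models, `[[`, character(1), "focal")
  refs <- unique(vapply(models, `[[`, character(1), "reference"))
  if (length(refs) != 1L) {
    stop("all models must share one reference category.", call. = FALSE)
  }
  reference <- refs
  names(models) <- focals
  stopifnot(is.data.frame(scenario),
    all(c("category", "availability") %in% names(scenario))
  )
  if (abs(sum(scenario$availability) - 1) > 1e-12) {
    stop("scenario availabilities must sum to 1.", call. = FALSE)
  }
  nonref <- setdiff(scenario$category, reference)
  missing <- setdiff(nonref, focals)
  if (length(missing)) {
    stop("missing model for category: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  av <- stats::setNames(scenario$availability, scenario$category)
  f <- vapply(nonref, function(cat) {
    val <- predict_log_or(models[[cat]], av[[cat]],
      hour = hour, month = month, sex = sex, extrapolate = extrapolate
    )
    if (!is.finite(val)) {
      stop("non-finite log odds ratio for category ", cat, ".", call. = FALSE)
    }
    val
  }, numeric(1))
  z <- c(f, 0)
  m <- max(z)
  e <- exp(z - m)
  p <- e / sum(e)
  out <- tibble::tibble(
    category = c(nonref, reference),
    availability = unname(av[c(nonref, reference)]),
    log_or = z,
    use = unname(p)
  )
  class(out) <- c("use_distribution", class(out))
  attr(out, "slot") <- list(hour = hour, month = month, sex = sex)
  out
}

#' Proportional-use curve of one category over availability
#'
#' Evaluates the focal category's use probability over a grid of its
#' availability, holding the background composition proportional to
#' `mean_background` (rescaled to fill `1 - x` at each grid point). This is
#' the functional-response curve a Holling equation is fitted to.
#'
#' @param models List of per-category log-odds models sharing one reference.
#' @param focal Focal category.
#' @param x_grid Strictly increasing availabilities in `(0, 1)`.
#' @param mean_background Named background availabilities of the other
#'   categories (see [make_scenario()]).
#' @param hour,month,sex Time slot.
#' @param extrapolate Allow availabilities outside training ranges.
#'
#' @return A tibble (class `use_curve`) with columns `x` and `use`, plus
#'   `focal` and slot attributes.
#' @export
use_curve <- function(models, focal, x_grid, mean_background,
                      hour = 0, month = 6, sex = NULL, extrapolate = FALSE) {
  stopifnot(is.numeric(x_grid), length(x_grid) >= 1L)
  if (length(x_grid) > 1L && any(diff(x_grid) <= 0)) {
    stop("`x_grid` must be strictly increasing.", call. = FALSE)
  }
  use <- vapply(x_grid, function(x) {
    scen <- make_scenario(focal, x, mean_background)
    cu <- combine_use(models, scen,
      hour = hour, month = month, sex = sex, extrapolate = extrapolate
    )
    cu$use[cu$category == focal]
  }, numeric(1))
  out <- tibble::tibble(x = x_grid, use = use)
  class(out) <- c("use_curve", class(out))
  attr(out, "focal") <- focal
  attr(out, "slot") <- list(hour = hour, month = month, sex = sex)
  out
}

#' @export
autoplot.use_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$use)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::labs(
      x = "relative availability", y = "proportional use",
      title = attr(object, "focal") %||% NULL
    ) +
    ggplot2::theme_minimal()
}
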