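#' Define a ground-truth functional response for one land-cover type
#'
#' A truth curve fixes the expected proportional use of a (non-reference)
#' land-cover category as a Holling function of its relative availability,
#' optionally modulated multiplicatively by time of day/year and sex, and is
#' the generative target of [simulate_telemetry()].
#'
#' @param category Category label.
#' @param type Holling type `"I"`, `"II"` or `"III"`.
#' @param a Maximum-use parameter in `[0, 1]`.
#' @param b Half-saturation parameter in `[0, 1]` (types II/III only).
#' @param temporal_modifier Optional `function(hour, month)` returning a
#'   strictly positive multiplicative factor (vectorized over `hour`).
#' @param sex_modifier Named numeric factors per sex, strictly positive.
#'
#' @return An object of class `truth_curve`.
#' @export
#' @examples
#' truth_curve("meadow", "II", a = 0.3, b = 0.05)
truth_curve <- function(category, type, a, b = NULL,
                        temporal_modifier = NULL,
                        sex_modifier = c(female = 1, male = 1)) {
  type <- match_holling_type(type)
  check_holling_params(type, a, b)
  if (!is.null(temporal_modifier)) {
    stopifnot(is.function(temporal_modifier))
    probe <- temporal_modifier(c(0, 12, 23), c(1, 6, 12))
    if (any(!is.finite(probe)) || any(probe <= 0)) {
      stop("`temporal_modifier` must return strictly positive factors.",
        call. = FALSE
      )
    }
  }
  if (any(!is.finite(sex_modifier)) || any(sex_modifier <= 0)) {
    stop("`sex_modifier` factors must be strictly positive.", call. = FALSE)
  }
  structure(
    list(
      category = as.character(category), type = type, a = a,
      b = if (type == "I") NA_real_ else b,
      temporal_modifier = temporal_modifier,
      sex_modifier = sex_modifier
    ),
    class = "truth_curve"
  )
}

truth_eval <- function(truth, x) {
  holling_curve(x, truth$type, truth$a,
    if (truth$type == "I") NULL else truth$b
  )
}

#' Describe a simulation scenario
#'
#' Bundles the design of a synthetic telemetry study: how many individuals per
#' sex, how many months and fixes, the land-cover categories (with a
#' designated reference category), how per-animal-month availability vectors
#' are drawn, and the magnitude of individual- and year-level variation in
#' prevalence (log-scale standard deviations of multiplicative random
#' effects).
#'
#' @param n_individuals Individuals per sex.
#' @param n_months Number of months monitored per individual (months
#'   `1..n_months`).
#' @param fixes_per_month GPS fixes per animal-month.
#' @param categories Character vector of category labels (length >= 2).
#' @param reference Reference (baseline) category; defaults to the last
#'   element of `categories`.
#' @param availability_sampler `function(n, k, ref_index)` returning an
#'   `n x k` matrix of rows on the simplex; defaults to
#'   [dirichlet_availability_sampler()] with a minimum reference share of
#'   0.05 so the log-availability offset stays finite.
#' @param individual_prevalence_sd Standard deviation of per-individual,
#'   per-category log-scale random intercepts.
#' @param year_effect_sd Standard deviation of per-year, per-category
#'   log-scale random intercepts.
#' @param n_years Number of calendar years; individuals are assigned to years
#'   round-robin.
#' @param seed Integer seed; fixed seed makes every simulated table
#'   reproducible.
#'
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_individuals = 20, n_months = 1,
                         fixes_per_month = 400,
                         categories = c("meadow", "conifer", "mixed_old"),
                         reference = categories[length(categories)],
                         availability_sampler = dirichlet_availability_sampler(),
                         individual_prevalence_sd = 0.15,
                         year_effect_sd = 0,
                         n_years = 1,
                         seed = 1L) {
  categories <- as.character(categories)
  if (length(categories) < 2L) {
    stop("need at least 2 categories (one focal, one reference).",
      call. = FALSE
    )
  }
  if (anyDuplicated(categories)) stop("duplicate categories.", call. = FALSE)
  if (!reference %in% categories) {
    stop("`reference` must be one of `categories`.", call. = FALSE)
  }
  stopifnot(
    n_individuals >= 1, n_months >= 1, n_months <= 12,
    fixes_per_month >= 1, n_years >= 1,
    individual_prevalence_sd >= 0, year_effect_sd >= 0,
    is.function(availability_sampler)
  )
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_months = as.integer(n_months),
      fixes_per_month = as.integer(fixes_per_month),
      categories = categories, reference = reference,
      availability_sampler = availability_sampler,
      individual_prevalence_sd = individual_prevalence_sd,
      year_effect_sd = year_effect_sd,
      n_years = as.integer(n_years),
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' Symmetric Dirichlet availability sampler
#'
#' Returns a sampler drawing per-animal-month availability vectors from a
#' symmetric Dirichlet distribution, rejecting draws whose reference-category
#' share falls below `min_reference` (which keeps the reference's log
#' availability finite and bounded).
#'
#' @param alpha Dirichlet concentration (default 1: uniform on the simplex).
#' @param min_reference Minimum admissible reference-category share.
#' @return A `function(n, k, ref_index)` returning an `n x k` matrix whose
#'   rows are nonnegative and sum to 1.
#' @export
dirichlet_availability_sampler <- function(alpha = 1, min_reference = 0.05) {
  stopifnot(alpha > 0, min_reference >= 0, min_reference < 1)
  function(n, k, ref_index) {
    out <- matrix(NA_real_, n, k)
    need <- seq_len(n)
    while (length(need)) {
      g <- matrix(stats::rgamma(length(need) * k, shape = alpha), ncol = k)
      g <- g / rowSums(g)
      ok <- g[, ref_index] >= min_reference
      take <- need[ok]
      if (length(take)) out[take, ] <- g[ok, , drop = FALSE]
      need <- need[!ok]
    }
    out
  }
}

scenario_animals <- function(scenario) {
  n <- scenario$n_individuals
  ids <- c(sprintf("f%02d", seq_len(n)), sprintf("m%02d", seq_len(n)))
  tibble::tibble(
    id = ids,
    sex = rep(c("female", "male"), each = n),
    year = 2020L + (seq_along(ids) - 1L) %% scenario$n_years
  )
}

#' Simulate per-animal-month availability vectors
#'
#' Draws one relative-availability vector per animal-month from the
#' scenario's availability sampler. Deterministic given the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return A tibble with columns `id`, `sex`, `year`, `month`, `category`,
#'   `proportion`; proportions within each animal-month sum to 1.
#' @export
simulate_availability <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::with_seed(scenario$seed, {
    animals <- scenario_animals(scenario)
    k <- length(scenario$categories)
    ref_i <- match(scenario$reference, scenario$categories)
    cells <- tidyr::crossing(animals, month = seq_len(scenario$n_months))
    mat <- scenario$availability_sampler(nrow(cells), k, ref_i)
    if (!is.matrix(mat) || nrow(mat) != nrow(cells) || ncol(mat) != k ||
      any(mat < 0) || any(abs(rowSums(mat) - 1) > 1e-9)) {
      stop("availability sampler must return rows on the simplex.",
        call. = FALSE
      )
    }
    colnames(mat) <- scenario$categories
    dplyr::bind_cols(cells, tibble::as_tibble(mat)) |>
      tidyr::pivot_longer(dplyr::all_of(scenario$categories),
        names_to = "category", values_to = "proportion"
      ) |>
      dplyr::arrange(.data$id, .data$year, .data$month, .data$category)
  })
}

#' Simulate telemetry fixes with known functional-response truth
#'
#' For every animal-month the implied use distribution is built from the
#' truth curves: each non-reference category's probability is its Holling
#' curve evaluated at that month's availability, times its temporal and sex
#' modifiers and the animal's and year's multiplicative random effects; the
#' reference category absorbs the remaining probability mass. Scenarios whose
#' implied reference probability is not strictly positive fail loudly rather
#' than being renormalized. Each fix's category is then an independent draw
#' from that distribution (fix times are far enough apart that the whole home
#' range is reachable between fixes, so no movement model is simulated).
#'
#' @param scenario A [sim_scenario()].
#' @param truths List of [truth_curve()]s, exactly one per non-reference
#'   category.
#' @param availability Optional availability table from
#'   [simulate_availability()]; computed from the scenario when omitted.
#'
#' @return A tibble of fixes with columns `id`, `sex`, `year`, `month`,
#'   `hour`, `x`, `y`, `category` (`x`/`y` are placeholder coordinates). The
#'   attribute `"truth"` carries the expected proportional-use curve of each
#'   category on an availability grid (neutral modifiers, random effects at
#'   zero); `"availability"` carries the availability table used.
#' @export
simulate_telemetry <- function(scenario, truths, availability = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (inherits(truths, "truth_curve")) truths <- list(truths)
  nonref <- setdiff(scenario$categories, scenario$reference)
  truth_cats <- vapply(truths, `[[`, character(1), "category")
  if (!setequal(truth_cats, nonref) || anyDuplicated(truth_cats)) {
    stop("need exactly one truth curve per non-reference category.",
      call. = FALSE
    )
  }
  truths <- truths[match(nonref, truth_cats)]
  names(truths) <- nonref
  if (is.null(availability)) availability <- simulate_availability(scenario)

  avail_wide <- availability |>
    tidyr::pivot_wider(names_from = "category", values_from = "proportion")

  withr::with_seed(scenario$seed + 1L, {
    animals <- scenario_animals(scenario)
    eps <- matrix(
      stats::rnorm(nrow(animals) * length(nonref),
        sd = scenario$individual_prevalence_sd
      ),
      nrow(animals), length(nonref),
      dimnames = list(animals$id, nonref)
    )
    years <- sort(unique(animals$year))
    gam_year <- matrix(
      stats::rnorm(length(years) * length(nonref),
        sd = scenario$year_effect_sd
      ),
      length(years), length(nonref),
      dimnames = list(as.character(years), nonref)
    )
    has_temporal <- any(vapply(
      truths, function(tr) !is.null(tr$temporal_modifier), logical(1)
    ))

    fixes <- purrr::pmap(avail_wide, function(id, sex, year, month, ...) {
      x_av <- c(...)
      n_fix <- scenario$fixes_per_month
      hour <- sample(0:23, n_fix, replace = TRUE)
      base <- vapply(nonref, function(cat) {
        tr <- truths[[cat]]
        truth_eval(tr, x_av[[cat]]) * tr$sex_modifier[[sex]] *
          exp(eps[id, cat] + gam_year[as.character(year), cat])
      }, numeric(1))
      if (has_temporal) {
        p <- vapply(nonref, function(cat) {
          tr <- truths[[cat]]
          tm <- if (is.null(tr$temporal_modifier)) {
            1
          } else {
            tr$temporal_modifier(hour, rep(month, n_fix))
          }
          base[[cat]] * tm
        }, numeric(n_fix))
        p <- matrix(p, nrow = n_fix)
      } else {
        p <- matrix(base, nrow = n_fix, ncol = length(nonref), byrow = TRUE)
      }
      p_ref <- 1 - rowSums(p)
      if (any(p_ref <= 0) || any(p < 0)) {
        stop(sprintf(
          "implied reference-category probability <= 0 for animal %s, year %d, month %d; weaken truth curves or modifiers.",
          id, year, month
        ), call. = FALSE)
      }
      probs <- cbind(p, p_ref)
      colnames(probs) <- c(nonref, scenario$reference)
      cum <- t(apply(probs, 1, cumsum))
      u <- stats::runif(n_fix)
      idx <- rowSums(u > cum) + 1L
      tibble::tibble(
        id = id, sex = sex, year = year, month = month, hour = hour,
        x = 0, y = 0, category = colnames(probs)[idx]
      )
    })
    telemetry <- dplyr::bind_rows(fixes)
  })

  x_grid <- seq(0.01, 0.99, by = 0.01)
  truth_tab <- purrr::map_dfr(truths, function(tr) {
    tibble::tibble(
      category = tr$category, x = x_grid,
      expected_use = truth_eval(tr, x_grid)
    )
  })
  attr(telemetry, "truth") <- truth_tab
  attr(telemetry, "availability") <- availability
  telemetry
}

#' Simulate a noisy use-availability curve from a known Holling truth
#'
#' Generates points on a Holling curve with additive Gaussian noise; used to
#' exercise the curve-fitting and type-identification machinery directly.
#'
#' @param type,a,b Holling type and parameters (see [holling_curve()]).
#' @param n_points Number of grid points.
#' @param x_range Availability range covered by the grid.
#' @param noise_sd Standard deviation of the additive noise.
#'
#' @return A tibble with columns `x` and `use` (class `use_curve`).
#' @export
simulate_response_curve <- function(type, a, b = NULL, n_points = 50,
                                    x_range = c(0.01, 0.8),
                                    noise_sd = 0.005) {
  type <- match_holling_type(type)
  check_holling_params(type, a, b)
  stopifnot(n_points >= 3, noise_sd >= 0, length(x_range) == 2)
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  use <- holling_curve(x, type, a, b) + stats::rnorm(n_points, sd = noise_sd)
  out <- tibble::tibble(x = x, use = use)
  class(out) <- c("use_curve", class(out))
  attr(out, "truth") <- list(type = type, a = a, b = b)
  out
}
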