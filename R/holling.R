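#' Evaluate a Holling functional-response curve
#'
#' Computes proportional use as a function of relative availability under one
#' of Holling's three response forms: type I `a * x` (linear), type II
#' `a * x / (b + x)` (concave, saturating; the Michaelis-Menten form) and
#' type III `a * x^2 / (b^2 + x^2)` (sigmoid). `a` is the maximum proportional
#' use (the asymptote for types II/III, the slope for type I) and `b` the
#' availability at which use reaches half of its maximum.
#'
#' @param x Relative availability, numeric in `[0, 1]`.
#' @param type Holling type: `"I"`, `"II"` or `"III"` (or `1:3`).
#' @param a Maximum-use parameter in `[0, 1]`.
#' @param b Half-saturation parameter in `[0, 1]`; ignored for type I.
#'
#' @return Numeric vector of proportional use, the same length as `x`. The
#'   degenerate point `b = 0, x = 0` evaluates to 0 (the limit from the right)
#'   for types II and III.
#' @export
#' @examples
#' holling_curve(0.15, "II", a = 0.8, b = 0.15) # half of the maximum: 0.4
holling_curve <- function(x, type, a, b = NULL) {
  type <- match_holling_type(type)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric.", call. = FALSE)
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("`x` must lie in [0, 1].", call. = FALSE)
  }
  check_holling_params(type, a, b)
  switch(type,
    I = a * x,
    II = ifelse(b + x <= 0, 0, a * x / (b + x)),
    III = ifelse(b^2 + x^2 <= 0, 0, a * x^2 / (b^2 + x^2))
  )
}

match_holling_type <- function(type) {
  if (is.numeric(type)) type <- c("I", "II", "III")[type]
  type <- match.arg(as.character(type), c("I", "II", "III"))
  type
}

check_holling_params <- function(type, a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  if (a < -1e-12 || a > 1 + 1e-12) {
    stop("`a` must lie in [0, 1].", call. = FALSE)
  }
  if (type != "I") {
    stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
    if (b < -1e-12 || b > 1 + 1e-12) {
      stop("`b` must lie in [0, 1].", call. = FALSE)
    }
  }
  invisible(TRUE)
}

holling_rss <- function(type, a, b, x, y) {
  h <- switch(type,
    I = a * x,
    II = ifelse(b + x <= 0, 0, a * x / (b + x)),
    III = ifelse(b^2 + x^2 <= 0, 0, a * x^2 / (b^2 + x^2))
  )
  sum((h - y)^2)
}

#' Fit Holling response curves to a use-availability curve
#'
#' Fits Holling type I, II and III equations to points relating proportional
#' use to relative availability by least squares with parameters constrained
#' to the unit box, and (with `type = "auto"`) selects the type with the
#' smallest residual sum of squares.
#'
#' Type I has the closed-form constrained solution
#' `a = clamp(sum(x*y)/sum(x^2), 0, 1)`. Types II and III are fitted by
#' multi-start bounded quasi-Newton optimization (`optim` method
#' `"L-BFGS-B"`): a 3 x 3 grid of starting values over `(a, b)` plus two
#' data-driven starts (maximum observed use, availability at half-maximum).
#' Ties in RSS between types (within `1e-12`) are broken toward the lower
#' (simpler) type number.
#'
#' @param data Data frame with numeric columns `x` (relative availability) and
#'   `use` (proportional use), e.g. the output of [use_curve()] or
#'   [simulate_response_curve()].
#' @param type `"auto"` (fit all three and select by RSS) or one of `"I"`,
#'   `"II"`, `"III"`.
#'
#' @return An object of class `holling_fit`: a list with elements `type`, `a`,
#'   `b` (`NA` for type I), `rss`, `n_points`, `all_rss` (named RSS per fitted
#'   type when `type = "auto"`), `bound_active` (whether the box constraint is
#'   active at the optimum) and `data`. Use [holling_diagnostics()] for the
#'   derived ecological quantities and [generics::tidy()] /
#'   [generics::glance()] for tabular summaries.
#' @export
#' @examples
#' curve <- simulate_response_curve("II", a = 0.3, b = 0.05, noise_sd = 0)
#' fit_holling(curve)
fit_holling <- function(data, type = "auto") {
  stopifnot(is.data.frame(data), all(c("x", "use") %in% names(data)))
  x <- as.numeric(data$x)
  y <- as.numeric(data$use)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points to fit.", call. = FALSE)
  if (anyDuplicated(x)) stop("`x` values must be distinct.", call. = FALSE)

  type <- match.arg(type, c("auto", "I", "II", "III"))
  types <- if (type == "auto") c("I", "II", "III") else type
  fits <- lapply(types, function(tp) fit_one_type(tp, x, y))
  names(fits) <- types
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  # tie-break toward the simpler (lower-numbered) type
  best <- which(rss <= min(rss) + 1e-12)[1L]
  out <- fits[[best]]
  out$all_rss <- rss
  out$n_points <- length(x)
  out$data <- tibble::tibble(x = x, use = y)
  class(out) <- "holling_fit"
  out
}

fit_one_type <- function(tp, x, y) {
  if (tp == "I") {
    a_raw <- sum(x * y) / sum(x^2)
    a <- min(max(a_raw, 0), 1)
    return(list(
      type = "I", a = a, b = NA_real_,
      rss = holling_rss("I", a, NA_real_, x, y),
      bound_active = !isTRUE(all.equal(a, a_raw))
    ))
  }
  obj <- function(par) holling_rss(tp, par[1], par[2], x, y)
  grid <- as.matrix(expand.grid(a = c(0.25, 0.5, 0.75), b = c(0.25, 0.5, 0.75)))
  a0 <- min(max(max(y), 1e-3), 1)
  half <- which(y >= max(y) / 2)
  b0 <- if (length(half)) min(max(x[half[1L]], 1e-3), 1) else 0.5
  starts <- rbind(grid, c(a0, b0), c(a0, max(b0 / 4, 1e-3)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj,
        method = "L-BFGS-B",
        lower = c(0, 0), upper = c(1, 1),
        control = list(factr = 1e2, maxit = 1000)
      ),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("Holling type ", tp, " optimization failed from every start.",
      call. = FALSE
    )
  }
  # polish: `a` enters linearly, so profile it out and refine `b` in 1-D
  prof_a <- function(b) {
    g <- if (tp == "II") x / (b + x) else x^2 / (b^2 + x^2)
    min(max(sum(g * y) / sum(g^2), 0), 1)
  }
  prof_obj <- function(b) {
    a <- prof_a(b)
    holling_rss(tp, a, b, x, y)
  }
  b_hat <- best$par[2]
  lo <- max(0, b_hat - 0.05)
  hi <- min(1, b_hat + 0.05)
  opt1 <- stats::optimize(prof_obj, c(lo, hi), tol = 1e-10)
  cand <- rbind(
    c(best$par[1], best$par[2], best$value),
    c(prof_a(opt1$minimum), opt1$minimum, opt1$objective),
    c(prof_a(0), 0, prof_obj(0)),
    c(prof_a(1), 1, prof_obj(1))
  )
  w <- which.min(cand[, 3])
  par <- cand[w, 1:2]
  val <- cand[w, 3]
  at_bound <- any(abs(par - 0) < 1e-8) || any(abs(par - 1) < 1e-8)
  list(
    type = tp, a = unname(par[1]), b = unname(par[2]),
    rss = val, bound_active = at_bound
  )
}

#' Ecological diagnostics of a fitted Holling response
#'
#' Derives the interpretable quantities of a Holling fit: the attraction ratio
#' `a/b`; the tipping point `x* = a - b` where use switches from
#' disproportionately high to disproportionately low (type II, requires
#' `a > b`); the two use-availability crossings
#' `x_{1,2} = a/2 +/- sqrt((a/2)^2 - b^2)` (type III, requires `b < a/2`); the
#' inflection point `b/sqrt(3)` where a type III curve turns from convex to
#' concave; and the selection regime. When the relevant condition fails
#' (type II `b >= a`, type III `b >= a/2`, type I `a < 1`) use is below
#' availability over the whole range and the regime is
#' `"disproportionate_low_everywhere"`; where the crossing exists the regime is
#' `"switch_at_x_star"`; a type I curve with `a = 1` is
#' `"use_equals_availability"`.
#'
#' @param fit A `holling_fit` object from [fit_holling()], or a list with
#'   elements `type`, `a`, `b`.
#'
#' @return A one-row tibble with columns `type`, `a`, `b`, `a_over_b`
#'   (`Inf` when `b = 0`; `NA` for type I), `x_star`, `x_cross_low`,
#'   `x_cross_high`, `inflection` (type III only) and `regime`. Absent
#'   quantities are `NA`; a reporting convention of 0 for "no crossing" is
#'   applied only by the pipeline summary writer.
#' @export
#' @examples
#' holling_diagnostics(list(type = "II", a = 0.29, b = 0.03)) # x* = 0.26
holling_diagnostics <- function(fit) {
  type <- match_holling_type(fit$type)
  a <- fit$a
  b <- if (type == "I") NA_real_ else fit$b
  check_holling_params(type, a, if (type == "I") NULL else b)

  a_over_b <- NA_real_
  x_star <- NA_real_
  x1 <- NA_real_
  x2 <- NA_real_
  infl <- NA_real_
  regime <- NA_character_

  if (type == "I") {
    regime <- if (a < 1) "disproportionate_low_everywhere" else "use_equals_availability"
  } else {
    a_over_b <- if (b > 0) a / b else Inf
    if (type == "II") {
      if (a > b) {
        x_star <- a - b
        regime <- "switch_at_x_star"
      } else {
        regime <- "disproportionate_low_everywhere"
      }
    } else {
      infl <- b / sqrt(3)
      if (b < a / 2) {
        disc <- sqrt((a / 2)^2 - b^2)
        x1 <- a / 2 - disc
        x2 <- a / 2 + disc
        regime <- "switch_at_x_star"
      } else {
        regime <- "disproportionate_low_everywhere"
      }
    }
  }
  tibble::tibble(
    type = type, a = a, b = b, a_over_b = a_over_b, x_star = x_star,
    x_cross_low = x1, x_cross_high = x2, inflection = infl, regime = regime
  )
}

#' @export
print.holling_fit <- function(x, ...) {
  cat("Holling type ", x$type, " fit (", x$n_points, " points)\n", sep = "")
  if (x$type == "I") {
    cat(sprintf("  a = %.4f (slope), rss = %.3g\n", x$a, x$rss))
  } else {
    cat(sprintf(
      "  a = %.4f (max use), b = %.4f (half-saturation), rss = %.3g\n",
      x$a, x$b, x$rss
    ))
  }
  if (!is.null(x$all_rss) && length(x$all_rss) > 1L) {
    cat(
      "  candidate rss:",
      paste(sprintf("%s=%.3g", names(x$all_rss), x$all_rss), collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.holling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b)
  )[seq_len(if (x$type == "I") 1L else 2L), ]
}

#' @export
glance.holling_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type, a = x$a, b = x$b, rss = x$rss, n_points = x$n_points
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.holling_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
    length.out = 200
  ))
  grid$use <- holling_curve(grid$x, object$type, object$a,
    if (object$type == "I") NULL else object$b
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$use)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::labs(
      x = "relative availability", y = "proportional use",
      title = paste0("Holling type ", object$type, " fit")
    ) +
    ggplot2::theme_minimal()
}
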