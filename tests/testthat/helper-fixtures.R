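# Shared fixtures and independent oracles used across the test files.

# --- recovery study: the standard synthetic conditions used for end-to-end
# parameter recovery (type-II truth a = 0.3, b = 0.05 for the focal meadow
# category, a type-I companion category, 40 animals x 400 fixes)
recovery_truths <- function() {
  list(
    truth_curve("meadow", "II", a = 0.3, b = 0.05),
    truth_curve("conifer", "I", a = 0.2)
  )
}

recovery_scenario <- function(seed) {
  sim_scenario(
    n_individuals = 20, n_months = 1, fixes_per_month = 400,
    categories = c("meadow", "conifer", "mixed_old"),
    individual_prevalence_sd = 0.15, seed = seed
  )
}

run_recovery <- function(seed) {
  res <- run_pipeline(list(
    reference_category = "mixed_old",
    scenario = recovery_scenario(seed),
    truths = recovery_truths(),
    spec = model_spec("smooth", "none"),
    slots = data.frame(month = 6L, hour = 0L)
  ))
  res$summary[res$summary$focal == "meadow", ]
}

# --- independent oracle for the multinomial baseline-logit link:
# direct textbook formula, no shared code with combine_use()
softmax_baseline_oracle <- function(f) {
  denom <- 1 + sum(exp(f))
  c(exp(f) / denom, 1 / denom)
}

# --- independent point-in-polygon oracle (ray casting), used to check the
# convex-containment test used for cell counting
raycast_inside <- function(px, py, qx, qy) {
  n <- length(px)
  vapply(seq_along(qx), function(k) {
    x <- qx[k]
    y <- qy[k]
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if ((py[i] > y) != (py[j] > y)) {
        xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# --- exhaustive grid-search oracle for the Holling least-squares problem:
# minimum RSS over (a, b) in {0, step, ..., 1}^2, exploiting that `a` enters
# the model linearly so the a-dimension reduces to a quadratic
grid_min_rss <- function(type, x, y, step = 0.001) {
  ab <- seq(0, 1, by = step)
  g <- if (type == "II") {
    outer(x, ab, function(x, b) ifelse(b + x <= 0, 0, x / (b + x)))
  } else {
    outer(x, ab, function(x, b) ifelse(b^2 + x^2 <= 0, 0, x^2 / (b^2 + x^2)))
  }
  syy <- sum(y^2)
  sg2 <- colSums(g^2)
  sgy <- colSums(g * y)
  rss <- outer(ab^2, sg2) - 2 * outer(ab, sgy) + syy
  min(rss)
}

# small telemetry table with hand-set categories for pairwise-coding tests
toy_telemetry <- function(categories) {
  n <- length(categories)
  tibble::tibble(
    id = "a1", sex = "female", year = 2020L, month = 6L,
    hour = rep(0L, n), x = 0, y = 0, category = categories
  )
}

toy_availability <- function(props) {
  tibble::tibble(
    id = "a1", sex = "female", year = 2020L, month = 6L,
    category = names(props), proportion = unname(props)
  )
}
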