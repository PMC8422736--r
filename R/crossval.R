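#' Select a model structure by grouped k-fold cross-validation
#'
#' Scores each candidate [model_spec()] by k-fold cross-validation with folds
#' grouped by animal id (all fixes of one animal fall in the same fold, so a
#' model is never scored on individuals it has seen), using mean held-out
#' log loss of the population-level predictions. The chosen structure is the
#' best mean score; ties (within `1e-10`) are broken toward fewer effective
#' parameters, then toward the earlier candidate.
#'
#' @param data Pairwise dataset from [build_pairwise_data()].
#' @param specs List of [model_spec()] candidates (named or unnamed), e.g.
#'   [default_candidate_specs()].
#' @param k Number of folds (default 10); reduced with a warning when there
#'   are fewer animals than folds.
#' @param min_n Passed to [fit_log_odds()] for the per-fold fits.
#'
#' @return A tibble ranking (one row per candidate: `spec_id`, `spec`
#'   description, `mean_logloss`, `mean_edf`, `n_folds_failed`, `rank`,
#'   `chosen`), with attributes `"chosen"` (the winning `model_spec`) and
#'   `"folds"` (the animal-to-fold assignment).
#' @export
cross_validate <- function(data, specs, k = 10, min_n = 50) {
  stopifnot(is.data.frame(data), length(specs) >= 1L, k >= 2)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "model_spec")))
  if (is.null(names(specs)) || anyNA(names(specs)) || any(names(specs) == "")) {
    names(specs) <- sprintf("spec_%02d", seq_along(specs))
  }

  counts <- sort(table(data$id), decreasing = TRUE)
  animals <- names(counts)
  if (length(animals) < k) {
    warning(
      "only ", length(animals), " animals; reducing folds from ", k,
      " to ", length(animals), ".",
      call. = FALSE
    )
    k <- length(animals)
  }
  # deterministic greedy balancing: largest animal to the lightest fold
  fold_of <- integer(length(animals))
  load <- numeric(k)
  for (i in seq_along(animals)) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + counts[i]
  }
  folds <- stats::setNames(fold_of, animals)

  score_spec <- function(spec) {
    ll <- edf <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      test_ids <- animals[folds == f]
      train <- data[!data$id %in% test_ids, , drop = FALSE]
      test <- data[data$id %in% test_ids, , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(fit_log_odds(train, spec, min_n = min_n)),
        error = function(e) NULL
      )
      if (is.null(fit) || nrow(test) == 0L) next
      lp <- tryCatch(
        predict_log_or(fit, test$rel_availability,
          hour = test$hour, month = test$month, sex = test$sex,
          extrapolate = TRUE
        ),
        error = function(e) NULL
      )
      if (is.null(lp)) next
      p <- pmin(pmax(stats::plogis(lp), 1e-12), 1 - 1e-12)
      y <- test$present
      ll[f] <- -mean(y * log(p) + (1 - y) * log(1 - p))
      edf[f] <- sum(fit$gam$edf)
    }
    c(
      mean_logloss = if (all(is.na(ll))) Inf else mean(ll, na.rm = TRUE),
      mean_edf = mean(edf, na.rm = TRUE),
      n_failed = sum(is.na(ll))
    )
  }

  scores <- t(vapply(specs, score_spec, numeric(3)))
  ord <- order(scores[, "mean_logloss"], scores[, "mean_edf"],
    seq_along(specs)
  )
  # tie-break: near-equal loss resolved by effective parameters, then order
  best <- ord[1]
  near <- which(scores[, "mean_logloss"] <=
    scores[best, "mean_logloss"] + 1e-10)
  if (length(near) > 1L) {
    best <- near[order(scores[near, "mean_edf"], near)][1]
  }
  out <- tibble::tibble(
    spec_id = names(specs),
    spec = vapply(specs, format, character(1)),
    mean_logloss = unname(scores[, "mean_logloss"]),
    mean_edf = unname(scores[, "mean_edf"]),
    n_folds_failed = as.integer(unname(scores[, "n_failed"])),
    chosen = seq_along(specs) == best
  )
  out$rank <- rank(out$mean_logloss, ties.method = "first")
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "chosen") <- specs[[best]]
  attr(out, "folds") <- folds
  out
}
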