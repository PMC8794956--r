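#' Standard evaluation periods
#'
#' Analysis periods in minutes relative to the onset of the final 0.6\% step:
#' the full 100-min steady-state test span (minutes 30--130, beginning well
#' after the <= 12-min pharmacokinetic equilibration), and its first and last
#' 20 min used for the collapse-over-time comparison.
#'
#' @return Tibble with columns `period`, `start_min`, `end_min`.
#' @export
ni_periods <- function() {
  tibble::tibble(period = c("full", "early", "late"),
                 start_min = c(30, 30, 110),
                 end_min = c(130, 50, 130))
}

#' Evaluate a classifier ensemble over test periods
#'
#' Labels every unmasked test window (minutes 30--130 of the final 0.6\% step
#' of both arms) with every classifier and reports one balanced accuracy per
#' classifier per period, computed from the pooled per-period window counts
#' (one [prediction_summary()] per classifier-period, not an average of
#' sub-period accuracies).
#'
#' @param ensemble An `ni_ensemble`.
#' @param pca The individual's `ni_pca` (scores + meta); for population
#'   ensembles pass the projected scores and meta via `scores`/`meta`.
#' @param periods Tibble like [ni_periods()].
#' @param scores,meta Optional overrides of the test score matrix and meta.
#' @return A tibble of class `ni_trace` with columns `individual`, `method`,
#'   `null`, `classifier`, `period`, counts and `accuracy`.
#' @export
evaluate_ensemble <- function(ensemble, pca, periods = ni_periods(),
                              scores = pca$scores, meta = pca$meta) {
  stopifnot(inherits(ensemble, "ni_ensemble"))
  test_sel <- meta$source %in% c("induction", "emergence") &
    in_interval(meta$min_rel, 30, 130)
  x <- scores[test_sel, , drop = FALSE]
  meta <- meta[test_sel, ]
  truth <- factor(meta$source, levels = ni_class_levels)
  n_clf <- length(ensemble$classifiers)

  # All-window predictions, windows x classifiers.
  preds <- if (ensemble$method == "lda") {
    w <- vapply(ensemble$classifiers, function(c) c$w, numeric(ncol(x)))
    b <- vapply(ensemble$classifiers, function(c) c$b, numeric(1))
    sweep(x %*% w, 2, b, "+") > 0
  } else {
    vapply(ensemble$classifiers,
           function(c) predict(c, x) == "emergence", logical(nrow(x)))
  }

  out <- purrr::pmap(periods, function(period, start_min, end_min) {
    sel <- in_interval(meta$min_rel, start_min, end_min)
    i_t <- sum(truth[sel] == "induction")
    e_t <- sum(truth[sel] == "emergence")
    if (i_t == 0 || e_t == 0) {
      warning(sprintf("period '%s' has no windows in one class; omitted", period))
      return(NULL)
    }
    p <- preds[sel, , drop = FALSE]
    i_c <- colSums(!p[truth[sel] == "induction", , drop = FALSE])
    e_c <- colSums(p[truth[sel] == "emergence", , drop = FALSE])
    tibble::tibble(
      individual = ensemble$individual, method = ensemble$method,
      null = ensemble$null, classifier = seq_len(n_clf),
      period = period, start_min = start_min, end_min = end_min,
      i_c = i_c, i_t = i_t, e_c = e_c, e_t = e_t,
      accuracy = 0.5 * (i_c / i_t + e_c / e_t))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("ni_trace", class(out))
  out
}
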