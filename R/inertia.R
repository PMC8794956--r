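#' Percentile bootstrap confidence interval of the median
#'
#' @param x Numeric vector (n >= 10).
#' @param level Confidence level (default 0.95).
#' @param B Bootstrap resamples (default 10000).
#' @param seed Integer seed; deterministic per seed.
#' @return Tibble with `median`, `lo`, `hi`, `level`, `n`.
#' @export
bootstrap_median_ci <- function(x, level = 0.95, B = 10000, seed = 1) {
  n <- length(x)
  if (n < 10) stop("need at least 10 values for a bootstrap CI", call. = FALSE)
  meds <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    apply(matrix(x[idx], nrow = n), 2, median)
  })
  qs <- quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(median = median(x), lo = qs[1], hi = qs[2],
                 level = level, n = n)
}

#' Compare a real ensemble's accuracies to its shuffled-label null
#'
#' Kruskal-Wallis rank test (equivalent to the rank-sum test for two groups)
#' on per-classifier mean balanced accuracies. An individual is called
#' inertial when the real median exceeds the null median at p < 0.05: the
#' spectra carry recoverable information about the exposure history.
#'
#' @param real,null Numeric vectors of per-classifier accuracies for the same
#'   individual and method (sizes may differ).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `test`, `n_real`, `n_null`, `statistic`,
#'   `p_value`, `median_real`, `median_null`, `inertia_call`.
#' @export
compare_to_null <- function(real, null, alpha = 0.05) {
  kw <- kruskal.test(list(real, null))
  tibble::tibble(
    test = "Kruskal-Wallis", n_real = length(real), n_null = length(null),
    statistic = unname(kw$statistic), p_value = kw$p.value,
    median_real = median(real), median_null = median(null),
    inertia_call = median(real) > median(null) && kw$p.value < alpha)
}

#' Compare classifier methods across individuals (Friedman test)
#'
#' Friedman rank test of method differences blocked by individual, the
#' paired nonparametric check of whether LDA and SVM ensembles measure the
#' same inertia.
#'
#' @param accuracies Tibble with columns `individual`, `method`, `accuracy`
#'   (one summary accuracy per individual-method, e.g. the ensemble median).
#' @return One-row tibble with `test`, `n_individuals`, `n_methods`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_methods <- function(accuracies) {
  accuracies <- dplyr::distinct(accuracies, .data$individual, .data$method,
                                .keep_all = TRUE)
  n_ind <- length(unique(accuracies$individual))
  if (n_ind < 3) stop("Friedman test needs >= 3 individuals", call. = FALSE)
  ft <- friedman.test(accuracy ~ method | individual,
                      data = as.data.frame(accuracies))
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {
    # Fully tied blocks carry no rank information: no detectable difference.
    stat <- 0; p <- 1
  }
  tibble::tibble(test = "Friedman", n_individuals = n_ind,
                 n_methods = length(unique(accuracies$method)),
                 statistic = stat, df = unname(ft$parameter), p_value = p)
}

#' Early-versus-late change in classifier accuracy
#'
#' Tests whether neural inertia decays over steady-state anesthesia by
#' comparing each classifier's mean balanced accuracy over minutes 30--50
#' against minutes 110--130. Pooled across individuals the comparison is a
#' two-sided Wilcoxon matched-pairs signed-rank test over classifiers;
#' per-individual inference is a two-way ANOVA (period x individual) with
#' Sidak-corrected per-individual period contrasts, whose signs report which
#' individuals rose and which fell.
#'
#' @param trace An `ni_trace` containing periods `"early"` and `"late"`.
#' @return List of class `ni_early_late`: `pooled` (one-row tibble) and
#'   `per_individual` (tibble with Sidak-adjusted p-values and direction).
#' @export
early_late_comparison <- function(trace) {
  need <- c("early", "late")
  if (!all(need %in% trace$period))
    stop("trace must contain 'early' and 'late' periods", call. = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::select(dplyr::filter(trace, .data$period %in% need),
                  "individual", "classifier", "period", "accuracy"),
    names_from = "period", values_from = "accuracy")
  d <- wide$late - wide$early
  pooled <- if (all(d == 0)) {
    # Fully tied pairs carry no rank information; documented degenerate branch.
    tibble::tibble(test = "Wilcoxon signed-rank", n_pairs = length(d),
                   statistic = NA_real_, p_value = 1,
                   median_early = median(wide$early),
                   median_late = median(wide$late), note = "all pairs tied")
  } else {
    wt <- wilcox.test(wide$late, wide$early, paired = TRUE, exact = FALSE)
    tibble::tibble(test = "Wilcoxon signed-rank", n_pairs = length(d),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   median_early = median(wide$early),
                   median_late = median(wide$late), note = NA_character_)
  }
  long <- dplyr::mutate(
    tidyr::pivot_longer(wide, dplyr::all_of(need), names_to = "period",
                        values_to = "accuracy"),
    period = factor(.data$period, levels = need),
    individual = factor(.data$individual))
  per_ind <- if (length(unique(long$individual)) > 1) {
    fit <- aov(accuracy ~ period * individual, data = long)
    emm <- emmeans::emmeans(fit, ~ period | individual)
    ctr <- summary(emmeans::contrast(emm, method = "revpairwise"),
                   adjust = "sidak", by = NULL)
    tibble::tibble(individual = as.character(ctr$individual),
                   estimate = ctr$estimate, se = ctr$SE,
                   t_ratio = ctr$t.ratio, p_sidak = ctr$p.value,
                   direction = ifelse(ctr$estimate < 0, "decrease", "increase"))
  } else {
    tibble::tibble(individual = character(), estimate = numeric(),
                   se = numeric(), t_ratio = numeric(), p_sidak = numeric(),
                   direction = character())
  }
  structure(list(pooled = pooled, per_individual = per_ind),
            class = "ni_early_late")
}

#' @export
print.ni_early_late <- function(x, ...) {
  cat(sprintf("<ni_early_late> pooled Wilcoxon p = %.3g (early %.3f -> late %.3f, n = %d)\n",
              x$pooled$p_value, x$pooled$median_early, x$pooled$median_late,
              x$pooled$n_pairs))
  if (nrow(x$per_individual))
    cat(sprintf("  %d/%d individuals significantly decreased (Sidak p < 0.05)\n",
                sum(x$per_individual$p_sidak < 0.05 &
                      x$per_individual$direction == "decrease"),
                nrow(x$per_individual)))
  invisible(x)
}

#' Assemble the inertia report
#'
#' Summarizes a combined accuracy trace (real and null ensembles, one or two
#' methods, all individuals) into the study's statistics: per-individual
#' median accuracy with a 95\% bootstrap CI and a Kruskal-Wallis comparison
#' against the shuffled-label null (the inertia call), the LDA-vs-SVM
#' Friedman comparison when both methods are present, and the pooled and
#' per-individual early-vs-late collapse tests per method.
#'
#' @param trace An `ni_trace` with real and null ensembles.
#' @param ci_seed Seed for the bootstrap CIs.
#' @param alpha Significance level.
#' @return Object of class `ni_report` with elements `per_individual`,
#'   `methods`, `early_late` (list per method), `alpha`.
#' @export
inertia_report <- function(trace, ci_seed = 1, alpha = 0.05) {
  full <- dplyr::filter(trace, .data$period == "full")
  combos <- dplyr::distinct(dplyr::filter(full, !.data$null),
                            .data$individual, .data$method)
  per_ind <- purrr::pmap(combos, function(individual, method) {
    real <- full$accuracy[full$individual == individual &
                          full$method == method & !full$null]
    nul <- full$accuracy[full$individual == individual &
                         full$method == method & full$null]
    ci <- bootstrap_median_ci(real, seed = child_seed(ci_seed, individual))
    cmp <- if (length(nul)) compare_to_null(real, nul, alpha) else
      tibble::tibble(p_value = NA_real_, inertia_call = NA)
    tibble::tibble(individual = individual, method = method,
                   median_accuracy = ci$median, ci_lo = ci$lo, ci_hi = ci$hi,
                   null_p = cmp$p_value, inertia_call = cmp$inertia_call)
  })
  per_ind <- dplyr::bind_rows(per_ind)

  methods_cmp <- if (length(unique(per_ind$method)) >= 2 &&
                     length(unique(per_ind$individual)) >= 3) {
    compare_methods(dplyr::rename(per_ind, accuracy = "median_accuracy"))
  } else NULL

  early_late <- purrr::map(
    rlang::set_names(unique(combos$method)),
    function(m) {
      tr <- dplyr::filter(trace, .data$method == m, !.data$null)
      if (all(c("early", "late") %in% tr$period)) early_late_comparison(tr) else NULL
    })

  structure(list(per_individual = per_ind, methods = methods_cmp,
                 early_late = early_late, alpha = alpha),
            class = "ni_report")
}

#' @export
print.ni_report <- function(x, ...) {
  cat("<ni_report>\n")
  cat(sprintf("  inertia calls: %d/%d individual-method combinations\n",
              sum(x$per_individual$inertia_call, na.rm = TRUE),
              nrow(x$per_individual)))
  if (!is.null(x$methods))
    cat(sprintf("  LDA vs SVM Friedman p = %.3g\n", x$methods$p_value))
  for (m in names(x$early_late)) {
    el <- x$early_late[[m]]
    if (!is.null(el))
      cat(sprintf("  %s early vs late Wilcoxon p = %.3g\n", m, el$pooled$p_value))
  }
  invisible(x)
}

#' @rdname inertia_report
#' @param x An `ni_report`.
#' @param ... Unused.
#' @export
tidy.ni_report <- function(x, ...) {
  rows <- list(
    dplyr::transmute(x$per_individual,
                     statistic = "median_accuracy",
                     individual = as.character(.data$individual),
                     method = .data$method, value = .data$median_accuracy,
                     p_value = .data$null_p)
  )
  if (!is.null(x$methods))
    rows <- c(rows, list(tibble::tibble(
      statistic = "friedman_methods", individual = NA_character_,
      method = NA_character_, value = x$methods$statistic,
      p_value = x$methods$p_value)))
  for (m in names(x$early_late)) {
    el <- x$early_late[[m]]
    if (is.null(el)) next
    rows <- c(rows, list(
      tibble::tibble(statistic = "early_late_pooled",
                     individual = NA_character_, method = m,
                     value = el$pooled$median_late - el$pooled$median_early,
                     p_value = el$pooled$p_value),
      dplyr::transmute(el$per_individual, statistic = "early_late_individual",
                       individual = as.character(.data$individual), method = m,
                       value = .data$estimate, p_value = .data$p_sidak)))
  }
  dplyr::bind_rows(rows)
}

#' @rdname inertia_report
#' @export
glance.ni_report <- function(x, ...) {
  el <- purrr::compact(x$early_late)
  tibble::tibble(
    n_individuals = length(unique(x$per_individual$individual)),
    n_methods = length(unique(x$per_individual$method)),
    inertia_calls = sum(x$per_individual$inertia_call, na.rm = TRUE),
    friedman_p = if (is.null(x$methods)) NA_real_ else x$methods$p_value,
    min_early_late_p = if (length(el))
      min(purrr::map_dbl(el, ~ .x$pooled$p_value)) else NA_real_)
}
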