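test_that("bootstrap median CI handles constants, coverage, and small n", {
  ci <- bootstrap_median_ci(rep(0.7, 50), seed = 1)
  expect_equal(c(ci$median, ci$lo, ci$hi), c(0.7, 0.7, 0.7))
  expect_error(bootstrap_median_ci(rnorm(5)), "at least 10")

  ci1 <- bootstrap_median_ci(rnorm(100), seed = 2, B = 2000)
  ci2 <- bootstrap_median_ci(withr::with_seed(99, rnorm(100)), seed = 2, B = 2000)
  expect_true(ci1$lo <= ci1$median && ci1$median <= ci1$hi)

  # coverage of the true median over Gaussian replicates
  cover <- withr::with_seed(3, {
    mean(vapply(1:300, function(r) {
      x <- rnorm(40)
      ci <- bootstrap_median_ci(x, B = 400, seed = r)
      ci$lo <= 0 && 0 <= ci$hi
    }, logical(1)))
  })
  expect_gt(cover, 0.88)
  expect_lte(cover, 1)
})

test_that("null comparison calls inertia only for genuine shifts", {
  x <- withr::with_seed(4, rnorm(250, 0.5, 0.01))
  same <- compare_to_null(x, x)
  expect_gt(same$p_value, 0.9)
  expect_false(same$inertia_call)

  real <- withr::with_seed(5, rnorm(250, 0.8, 0.01))
  nul <- withr::with_seed(6, rnorm(250, 0.5, 0.01))
  shift <- compare_to_null(real, nul)
  expect_lt(shift$p_value, 1e-4)
  expect_true(shift$inertia_call)
  # inverted shift: significant but not called
  expect_false(compare_to_null(nul, real)$inertia_call)
})

test_that("inertia-call type-I error is controlled at the nominal level", {
  # both traces drawn from the same null; calls need p < 0.05 AND a higher
  # real median, so the false-call rate is ~2.5% and must stay below 5% + MC
  calls <- withr::with_seed(7, vapply(1:1000, function(r) {
    compare_to_null(rnorm(60, 0.5, 0.02), rnorm(60, 0.5, 0.02))$inertia_call
  }, logical(1)))
  expect_lte(mean(calls), 0.05)
})

test_that("Friedman method comparison detects consistent shifts only", {
  acc <- tibble::tibble(individual = rep(1:6, 2),
                        method = rep(c("lda", "svm"), each = 6),
                        accuracy = rep(0.7, 12))
  same <- compare_methods(acc)
  expect_equal(same$p_value, 1)
  expect_equal(same$n_individuals, 6)

  acc$accuracy[acc$method == "svm"] <- acc$accuracy[acc$method == "svm"] + 0.2
  shifted <- compare_methods(acc)
  expect_lt(shifted$p_value, 0.05)

  expect_error(compare_methods(acc[acc$individual < 3, ]), ">= 3 individuals")
})

test_that("early/late comparison flags collapse and respects ties", {
  mk_trace <- function(early, late) {
    n <- length(early)
    tibble::tibble(
      individual = rep(rep(1:2, each = n / 2), 2),
      method = "lda", null = FALSE,
      classifier = rep(seq_len(n), 2),
      period = rep(c("early", "late"), each = n),
      accuracy = c(early, late))
  }
  e <- withr::with_seed(8, rnorm(100, 0.8, 0.02))
  tied <- early_late_comparison(mk_trace(e, e))
  expect_equal(tied$pooled$p_value, 1)

  l <- e - 0.2
  coll <- early_late_comparison(mk_trace(e, l))
  expect_lt(coll$pooled$p_value, 1e-4)
  expect_lt(coll$pooled$median_late, coll$pooled$median_early)
  expect_true(all(coll$per_individual$direction == "decrease"))
  expect_true(all(coll$per_individual$p_sidak < 0.05))

  expect_error(early_late_comparison(mk_trace(e, l)[1:50, ]), "early")
})

test_that("static inertia rarely produces a spurious decrease", {
  # relaxation much longer than the recording: early and late accuracies
  # share a mean; a decrease should be declared in at most ~10% of runs
  hits <- withr::with_seed(9, vapply(1:20, function(r) {
    e <- rnorm(250, 0.8, 0.02)
    l <- 0.8 + 0.7 * (e - 0.8) + rnorm(250, 0, 0.014)
    tr <- tibble::tibble(individual = 1L, method = "lda", null = FALSE,
                         classifier = rep(1:250, 2),
                         period = rep(c("early", "late"), each = 250),
                         accuracy = c(e, l))
    el <- suppressWarnings(early_late_comparison(tr))
    el$pooled$p_value < 0.05 && el$pooled$median_late < el$pooled$median_early
  }, logical(1)))
  expect_lte(mean(hits), 0.1)
})

test_that("the report aggregates traces into study statistics", {
  withr::with_seed(10, {
    mk <- function(ind, method, is_null) {
      acc_full <- rnorm(40, if (is_null) 0.5 else 0.75, 0.02)
      shift <- if (is_null) 0 else 0.05
      tibble::tibble(individual = ind, method = method, null = is_null,
                     classifier = rep(1:40, 3),
                     period = rep(c("full", "early", "late"), each = 40),
                     accuracy = c(acc_full, acc_full + shift,
                                  acc_full - shift))
    }
    trace <- dplyr::bind_rows(purrr::map(1:3, function(i)
      dplyr::bind_rows(mk(i, "lda", FALSE), mk(i, "lda", TRUE),
                       mk(i, "svm", FALSE), mk(i, "svm", TRUE))))
  })
  rep <- inertia_report(trace)
  expect_equal(nrow(rep$per_individual), 6)      # 3 individuals x 2 methods
  expect_true(all(rep$per_individual$inertia_call))
  expect_gt(rep$methods$p_value, 0.05)
  expect_lt(rep$early_late$lda$pooled$p_value, 1e-4)
  td <- tidy(rep)
  expect_true(all(c("median_accuracy", "friedman_methods",
                    "early_late_pooled") %in% td$statistic))
  gl <- glance(rep)
  expect_equal(gl$inertia_calls, 6)
})
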