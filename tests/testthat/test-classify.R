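test_that("training sets are balanced, period-restricted, and reproducible", {
  pca <- mini_individual()$pca
  ts <- assemble_training_set(pca, n_per_class = 260, seed = 1)
  expect_equal(as.vector(table(ts$y)), c(260, 260))
  expect_true(all(in_interval(ts$meta$min_rel, 10, 30)))
  src_counts <- table(ts$meta$source)
  expect_equal(unname(src_counts[c("induction", "emergence_induction_arm")]),
               c(130, 130), ignore_attr = TRUE)
  expect_equal(unname(src_counts["emergence"]), 260, ignore_attr = TRUE)

  ts2 <- assemble_training_set(pca, n_per_class = 260, seed = 1)
  expect_identical(ts$x, ts2$x)
  ts3 <- assemble_training_set(pca, n_per_class = 260, seed = 2)
  expect_false(identical(ts$x, ts3$x))

  # minutes 10-30 at 4-s windows: at most 300 candidates per source
  expect_lte(sum(pca$meta$source == "emergence" &
                   in_interval(pca$meta$min_rel, 10, 30)), 300)

  # requesting more than available reduces the class size symmetrically
  expect_warning(big <- assemble_training_set(pca, n_per_class = 700, seed = 1),
                 "reduced")
  expect_equal(length(unique(table(big$y))), 1)
})

test_that("label shuffling permutes labels only", {
  pca <- mini_individual()$pca
  ts <- assemble_training_set(pca, n_per_class = 50, seed = 3)
  sh <- shuffle_labels(ts, seed = 4)
  expect_identical(sh$x, ts$x)
  expect_equal(sort(as.character(sh$y)), sort(as.character(ts$y)))
  expect_false(identical(sh$y, ts$y))
  # each row's label is ~50/50 over repeated shuffles
  hits <- rowMeans(vapply(1:400, function(i)
    shuffle_labels(ts, seed = i)$y == "emergence", logical(length(ts$y))))
  expect_lt(max(abs(hits - 0.5)), 0.15)
})

test_that("LDA separates separated clusters and sits at chance otherwise", {
  sep <- gaussian_problem(n = 200, p = 10, delta = 10 / sqrt(10))
  clf <- train_lda(x = sep$x, y = sep$y)
  acc <- balanced_accuracy(prediction_summary(sep$y, predict(clf, sep$x)))
  expect_equal(acc, 1.0)

  same <- gaussian_problem(n = 200, p = 10, delta = 0)
  clf0 <- train_lda(x = same$x, y = same$y)
  acc0 <- balanced_accuracy(prediction_summary(same$y, predict(clf0, same$x)))
  expect_lt(abs(acc0 - 0.5), 0.1)
  expect_error(train_lda(x = same$x[1:3, ], y = same$y[c(1, 2, 201)]), ">= 2 rows")
})

test_that("LDA weight direction matches the closed-form Fisher discriminant", {
  sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  ch <- chol(sigma)
  withr::with_seed(40, {
    x0 <- matrix(rnorm(4000 * 2), ncol = 2) %*% ch
    x1 <- sweep(matrix(rnorm(4000 * 2), ncol = 2) %*% ch, 2, c(1, 0.5), "+")
  })
  x <- rbind(x0, x1)
  y <- factor(rep(c("induction", "emergence"), each = 4000),
              levels = c("induction", "emergence"))
  clf <- train_lda(x = x, y = y, shrinkage = 0)
  w_ref <- solve(sigma, c(1, 0.5))
  cosine <- sum(clf$w * w_ref) / sqrt(sum(clf$w^2) * sum(w_ref^2))
  expect_gt(cosine, 0.999)
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  pr <- gaussian_problem(n = 150, p = 8, delta = 0.4)
  clf <- train_lda(x = pr$x, y = pr$y, shrinkage = 0)
  ref <- MASS::lda(pr$x, grouping = pr$y)
  w_ref <- as.numeric(ref$scaling)
  cosine <- abs(sum(clf$w * w_ref)) / sqrt(sum(clf$w^2) * sum(w_ref^2))
  expect_gt(cosine, 0.9999)
  agree <- mean(predict(clf, pr$x) == predict(ref, pr$x)$class)
  expect_gt(agree, 0.99)
})

test_that("SVM trains both kernels and separates separated clusters", {
  sep <- gaussian_problem(n = 100, p = 6, delta = 10 / sqrt(6))
  for (k in c("radial", "linear")) {
    clf <- train_svm(x = sep$x, y = sep$y, kernel = k)
    acc <- balanced_accuracy(prediction_summary(sep$y, predict(clf, sep$x)))
    expect_equal(acc, 1.0)
  }
})

test_that("ensembles have n members and are seed-reproducible", {
  pca <- mini_individual()$pca
  e1 <- train_ensemble(pca, n = 12, method = "lda", base_seed = 100,
                       n_per_class = 60)
  expect_length(e1$classifiers, 12)
  expect_equal(e1$seeds, 100 + 1:12)
  e2 <- train_ensemble(pca, n = 12, method = "lda", base_seed = 100,
                       n_per_class = 60)
  expect_identical(e1$classifiers[[5]]$w, e2$classifiers[[5]]$w)
})

test_that("balanced accuracy matches its formula and a brute-force oracle", {
  expect_equal(balanced_accuracy(90, 100, 70, 100), 0.80)
  expect_equal(balanced_accuracy(100, 100, 100, 100), 1)
  expect_equal(balanced_accuracy(100, 100, 0, 100), 0.5)
  expect_error(balanced_accuracy(0, 0, 1, 1), "both classes")

  # oracle: enumerate every truth/prediction pattern on 4 windows with both
  # classes present, and compare against direct per-class averaging
  lv <- c("induction", "emergence")
  for (tr_bits in 1:14) {          # exclude all-0 / all-15 (one-class truth)
    truth <- factor(lv[(bitwAnd(tr_bits, 2^(0:3)) > 0) + 1], levels = lv)
    for (pr_bits in 0:15) {
      pred <- factor(lv[(bitwAnd(pr_bits, 2^(0:3)) > 0) + 1], levels = lv)
      oracle <- mean(c(mean(pred[truth == "induction"] == "induction"),
                       mean(pred[truth == "emergence"] == "emergence")))
      expect_equal(balanced_accuracy(prediction_summary(truth, pred)), oracle)
    }
  }
})

test_that("balanced accuracy is invariant to test-set class imbalance", {
  withr::with_seed(41, {
    truth <- factor(rep(c("induction", "emergence"), c(40, 25)),
                    levels = c("induction", "emergence"))
    pred <- factor(sample(c("induction", "emergence"), 65, replace = TRUE),
                   levels = c("induction", "emergence"))
  })
  a1 <- balanced_accuracy(prediction_summary(truth, pred))
  dup <- truth == "emergence"
  a2 <- balanced_accuracy(prediction_summary(c(truth, truth[dup]),
                                             c(pred, pred[dup])))
  expect_equal(a1, a2)
})

test_that("population training excludes the held-out individual", {
  feats <- purrr::map(c(a = 51, b = 52, c = 53), function(s) {
    co <- generate_cohort(n_individuals = 1, seed = s, spans = mini_spans)
    features_for_individual(preprocess_recording(co[[1]]),
                            preprocess_recording(co[[2]]))
  })
  ts <- assemble_population_training_set(feats, "b",
                                         n_per_mouse_per_class = 40, seed = 9)
  expect_setequal(unique(ts$meta$pop_individual), c("a", "c"))
  expect_equal(as.vector(table(ts$y)), c(80, 80))       # 40 per mouse per class
  expect_equal(attr(ts, "held_out"), "b")
  pca <- attr(ts, "pca")
  sc <- project_pca(pca, feats$b)
  expect_equal(ncol(sc), pca$k)
  expect_error(assemble_population_training_set(feats, "zz"), "not found")
})
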