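ni_class_levels <- c("induction", "emergence")

#' Assemble a balanced training set for one individual
#'
#' Draws `n_per_class` windows per class from minutes 10--30 of the relevant
#' 0.6\% steps: the emergence class from the emergence arm, and the induction
#' class split equally (130 + 130 by default) between the induction recording
#' and the induction arm of the emergence recording, so that any systematic
#' between-recording difference cannot masquerade as an induction/emergence
#' difference. Sampling is without replacement and deterministic per seed; if
#' a source has too few unmasked windows the class sizes are reduced
#' symmetrically with a warning.
#'
#' @param pca An `ni_pca` fit for the individual (scores + window meta), or a
#'   list with elements `scores` and `meta`.
#' @param n_per_class Windows per class (default 260).
#' @param seed Integer seed.
#' @param train_window Minutes (relative to each source's 0.6\% step onset)
#'   from which training windows are drawn, half-open (default `c(10, 30)`).
#' @return Object of class `ni_training`: `x` (rows x k score matrix), `y`
#'   (factor induction/emergence), `meta`, `seed`.
#' @export
assemble_training_set <- function(pca, n_per_class = 260, seed = 1,
                                  train_window = c(10, 30)) {
  meta <- pca$meta
  stopifnot(!is.null(meta))
  cand <- function(src) which(meta$source == src &
                              in_interval(meta$min_rel, train_window[1], train_window[2]))
  ci <- cand("induction"); ce <- cand("emergence"); cei <- cand("emergence_induction_arm")
  half <- min(n_per_class %/% 2, length(ci), length(cei), length(ce) %/% 2)
  if (2 * half < n_per_class)
    warning(sprintf("insufficient unmasked training windows; class size reduced to %d", 2 * half))
  if (half < 1) stop("no usable training windows", call. = FALSE)
  idx <- withr::with_seed(seed, c(
    sample(ci, half), sample(cei, half), sample(ce, 2 * half)))
  y <- factor(rep(ni_class_levels, each = 2 * half), levels = ni_class_levels)
  structure(list(x = pca$scores[idx, , drop = FALSE], y = y,
                 meta = meta[idx, ], seed = seed),
            class = "ni_training")
}

#' Assemble a population (leave-one-out) training set
#'
#' Builds the training set used to classify one individual from the others:
#' a shared PC space is fitted to the pooled 482-dimensional features of the
#' contributing individuals, and each of them contributes an equal,
#' individually balanced draw (260 windows per class per mouse by default,
#' i.e. 1,300 per class from five mice), from the same sources and periods as
#' the individual training sets. The held-out individual contributes nothing.
#'
#' @param features_list Named list of `ni_features`, one per individual.
#' @param held_out Name (or index) of the individual to hold out.
#' @param n_per_mouse_per_class Windows per class drawn from each
#'   contributing individual (default 260).
#' @param k Number of population PCs (default 50).
#' @param seed Integer seed.
#' @return An `ni_training` whose attribute `pca` holds the population
#'   `ni_pca`; project the held-out individual's features with it.
#' @export
assemble_population_training_set <- function(features_list, held_out,
                                             n_per_mouse_per_class = 260,
                                             k = 50, seed = 1) {
  if (is.numeric(held_out)) held_out <- names(features_list)[held_out]
  if (!held_out %in% names(features_list))
    stop("held-out individual not found: ", held_out, call. = FALSE)
  if (length(features_list) < 2)
    stop("need at least two individuals", call. = FALSE)
  train_ids <- setdiff(names(features_list), held_out)
  pooled_x <- do.call(rbind, purrr::map(features_list[train_ids], "x"))
  pooled_meta <- dplyr::bind_rows(
    purrr::imap(features_list[train_ids],
                ~ dplyr::mutate(.x$meta, pop_individual = .y)))
  pca <- fit_pca(structure(list(x = pooled_x, meta = pooled_meta,
                                center = colMeans(pooled_x)),
                           class = "ni_features"), k = k)
  parts <- purrr::imap(train_ids, function(id, i) {
    rows <- which(pooled_meta$pop_individual == id)
    sub <- list(scores = pca$scores[rows, , drop = FALSE],
                meta = pooled_meta[rows, ])
    assemble_training_set(sub, n_per_class = n_per_mouse_per_class,
                          seed = child_seed(seed, i))
  })
  out <- structure(list(
    x = do.call(rbind, purrr::map(parts, "x")),
    y = factor(unlist(purrr::map(parts, ~ as.character(.x$y))),
               levels = ni_class_levels),
    meta = dplyr::bind_rows(purrr::map(parts, "meta")),
    seed = seed), class = "ni_training")
  attr(out, "pca") <- pca
  attr(out, "held_out") <- held_out
  out
}

#' Shuffle training labels (permutation null)
#'
#' Permutes the class labels uniformly at random, leaving the features and
#' the label multiset (class balance) untouched -- the shuffled-label null
#' that calibrates chance classifier performance.
#'
#' @param ts An `ni_training`.
#' @param seed Integer seed.
#' @return The training set with permuted `y`.
#' @export
shuffle_labels <- function(ts, seed = 1) {
  stopifnot(inherits(ts, "ni_training"))
  ts$y <- withr::with_seed(seed, sample(ts$y))
  ts$null <- TRUE
  ts
}

# Ledoit-Wolf-style shrinkage intensity toward the diagonal of S, estimated
# from the within-class residuals Z (n x p).
lw_lambda <- function(z) {
  n <- nrow(z)
  s <- crossprod(z) / (n - 1)
  wbar <- crossprod(z) / n
  m2 <- crossprod(z^2) / n
  var_s <- n / (n - 1)^3 * (m2 - wbar^2) * n
  off <- upper.tri(s) | lower.tri(s)
  lam <- sum(var_s[off]) / sum(s[off]^2)
  min(max(lam, 0), 1)
}

#' Train a linear discriminant classifier
#'
#' Classical (Fisher/Gaussian, equal priors) LDA: the weight vector is
#' \eqn{w = \Sigma^{-1}(\mu_{emergence} - \mu_{induction})} with the pooled
#' within-class covariance, shrunk toward its diagonal with an automatically
#' estimated (Ledoit-Wolf-style) intensity so near-singular cases remain
#' well-posed; the bias places the boundary at the projected midpoint of the
#' class means.
#'
#' @param ts An `ni_training` (or pass `x`/`y` directly).
#' @param x,y Feature matrix and label factor, used if `ts` is missing.
#' @param shrinkage `NULL` for automatic intensity, or a number in `[0, 1]`.
#' @return Object of class `ni_classifier` with elements `w`, `b`,
#'   `method = "lda"`, `lambda`.
#' @export
train_lda <- function(ts = NULL, x = ts$x, y = ts$y, shrinkage = NULL) {
  y <- factor(y, levels = ni_class_levels)
  if (any(table(y) < 2)) stop("need >= 2 rows per class", call. = FALSE)
  x0 <- x[y == ni_class_levels[1], , drop = FALSE]
  x1 <- x[y == ni_class_levels[2], , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  z <- rbind(sweep(x0, 2, mu0), sweep(x1, 2, mu1))
  s <- crossprod(z) / (nrow(z) - 2)
  lam <- if (is.null(shrinkage)) lw_lambda(z) else shrinkage
  s_shr <- (1 - lam) * s + lam * diag(diag(s), ncol(s))
  w <- tryCatch(solve(s_shr, mu1 - mu0), error = function(e) {
    warning("singular covariance; full diagonal shrinkage applied")
    solve(diag(diag(s) + 1e-12, ncol(s)), mu1 - mu0)
  })
  structure(list(w = as.numeric(w), b = -sum(w * (mu0 + mu1)) / 2,
                 method = "lda", lambda = lam),
            class = "ni_classifier")
}

#' Train a support-vector classifier
#'
#' SVM with a Gaussian RBF kernel by default (`gamma = 1 / (p * mean feature
#' variance)`, `C = 1`), the nonlinear counterpart to the linear
#' discriminant; a linear kernel is available by argument.
#'
#' @inheritParams train_lda
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost Soft-margin cost.
#' @return Object of class `ni_classifier` wrapping the fitted
#'   [e1071::svm()] model.
#' @export
train_svm <- function(ts = NULL, x = ts$x, y = ts$y,
                      kernel = c("radial", "linear"), cost = 1) {
  kernel <- match.arg(kernel)
  y <- factor(y, levels = ni_class_levels)
  if (any(table(y) < 2)) stop("need >= 2 rows per class", call. = FALSE)
  gam <- 1 / (ncol(x) * mean(apply(x, 2, var)))
  fit <- e1071::svm(x, y, kernel = kernel, gamma = gam, cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, method = paste0("svm-", kernel), gamma = gam,
                 cost = cost),
            class = "ni_classifier")
}

#' Predict class labels
#'
#' @param object An `ni_classifier`.
#' @param newdata Score matrix (windows x k).
#' @param ... Unused.
#' @return Factor of predicted labels (induction/emergence).
#' @export
predict.ni_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$method == "lda") {
    sc <- as.numeric(newdata %*% object$w + object$b)
    factor(ni_class_levels[(sc > 0) + 1L], levels = ni_class_levels)
  } else {
    predict(object$fit, newdata)
  }
}

#' Train an ensemble of classifiers
#'
#' Trains `n` classifiers (250 by default) that differ through independent
#' resampling of the training pool: member `i` is trained on a training set
#' assembled with seed `base_seed + i` (and, for null ensembles, with its
#' labels independently shuffled). Fully reproducible from `base_seed`.
#'
#' @param pca An `ni_pca` for the individual.
#' @param n Ensemble size (default 250).
#' @param method `"lda"` or `"svm"`.
#' @param base_seed Integer.
#' @param null Train on shuffled labels (permutation null).
#' @param n_per_class Training windows per class (default 260).
#' @param ... Passed to the trainer.
#' @return Object of class `ni_ensemble`.
#' @export
train_ensemble <- function(pca, n = 250, method = c("lda", "svm"),
                           base_seed = 1, null = FALSE, n_per_class = 260,
                           ...) {
  method <- match.arg(method)
  trainer <- switch(method, lda = train_lda, svm = train_svm)
  classifiers <- purrr::map(seq_len(n), function(i) {
    ts <- assemble_training_set(pca, n_per_class = n_per_class,
                                seed = base_seed + i)
    if (null) ts <- shuffle_labels(ts, seed = child_seed(base_seed + i, 13))
    trainer(ts, ...)
  })
  structure(list(classifiers = classifiers, method = method, null = null,
                 seeds = base_seed + seq_len(n),
                 individual = pca$meta$individual[1]),
            class = "ni_ensemble")
}

#' @export
print.ni_ensemble <- function(x, ...) {
  cat(sprintf("<ni_ensemble> %d %s classifiers%s (individual %s)\n",
              length(x$classifiers), x$method,
              if (x$null) " [shuffled-label null]" else "",
              x$individual))
  invisible(x)
}

#' Prediction summary for balanced accuracy
#'
#' Counts correct labels per class: `i_c` of `i_t` induction windows and
#' `e_c` of `e_t` emergence windows.
#'
#' @param truth,pred Factors with levels induction/emergence.
#' @return List of class `ni_prediction_summary`.
#' @export
prediction_summary <- function(truth, pred) {
  truth <- factor(truth, levels = ni_class_levels)
  pred <- factor(pred, levels = ni_class_levels)
  structure(list(
    i_c = sum(truth == "induction" & pred == "induction"),
    i_t = sum(truth == "induction"),
    e_c = sum(truth == "emergence" & pred == "emergence"),
    e_t = sum(truth == "emergence")),
    class = "ni_prediction_summary")
}

#' Balanced classifier accuracy
#'
#' The mean of the per-class correct fractions,
#' \deqn{\mathrm{Accuracy} = \tfrac{1}{2}\left(\frac{I_C}{I_T} +
#'   \frac{E_C}{E_T}\right),}
#' which is 0.5 for any classifier that carries no class information,
#' regardless of test-set class imbalance.
#'
#' @param summary An [prediction_summary()], or `i_c` directly.
#' @param i_t,e_c,e_t Counts, used when `summary` is numeric.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' balanced_accuracy(prediction_summary(
#'   factor(c("induction", "emergence")), factor(c("induction", "emergence"))))
#' @export
balanced_accuracy <- function(summary, i_t = NULL, e_c = NULL, e_t = NULL) {
  if (is.numeric(summary))
    summary <- list(i_c = summary, i_t = i_t, e_c = e_c, e_t = e_t)
  with(summary, {
    if (i_t <= 0 || e_t <= 0)
      stop("both classes must have test windows", call. = FALSE)
    0.5 * (i_c / i_t + e_c / e_t)
  })
}
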