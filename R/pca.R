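#' Spectral features for one individual
#'
#' Convenience wrapper assembling the three-source feature matrix for one
#' individual from its two preprocessed recordings: windows of the induction
#' recording, windows of the emergence recording's final 0.6\% step (the
#' emergence arm), and windows of that recording's first 0.6\% step (its
#' induction arm). Adds `min_rel` to the meta: window start in minutes
#' relative to the source's own 0.6\% step onset, the clock on which training
#' (minutes 10--30) and test (minutes 30--130) periods are defined.
#'
#' @param induction_rec,emergence_rec Preprocessed `ni_recording`s of the two
#'   paradigms for the same individual.
#' @return An `ni_features` object, see [build_feature_matrix()].
#' @export
features_for_individual <- function(induction_rec, emergence_rec) {
  stopifnot(induction_rec$arm == "induction", emergence_rec$arm == "emergence")
  ind <- psd_set(induction_rec)
  eme <- psd_set(emergence_rec)
  final_s <- attr(emergence_rec$schedule, "final_step_s")
  arm_sel <- eme$meta$start_s >= final_s
  split_set <- function(s, keep, step_onset_s) {
    meta <- s$meta[keep, ]
    meta$step_onset_s <- step_onset_s
    list(M2 = s$M2[keep, , drop = FALSE], V1 = s$V1[keep, , drop = FALSE],
         meta = meta)
  }
  ind$meta$step_onset_s <- attr(induction_rec$schedule, "final_step_s")
  sources <- list(
    induction = ind,
    emergence = split_set(eme, arm_sel, final_s),
    emergence_induction_arm = split_set(eme, !arm_sel, 1800))
  feats <- build_feature_matrix(sources)
  feats$meta$min_rel <- (feats$meta$start_s - feats$meta$step_onset_s) / 60
  feats
}

#' Principal-component reduction of the feature matrix
#'
#' Fits PCA to the 482-dimensional window features and keeps the leading `k`
#' components (default 50, which for the default generator carries >70\% of
#' the variance). Loadings are orthonormal; each component's sign is fixed so
#' its largest-magnitude loading element is positive, making outputs
#' reproducible across linear-algebra backends.
#'
#' @param features An `ni_features` object or a plain numeric matrix.
#' @param k Number of components (reduced with a warning if the matrix rank
#'   is lower).
#' @return Object of class `ni_pca`: `loadings` (482 x k), `scores`
#'   (windows x k), `evf` (explained-variance fractions, all components),
#'   `center`, `k`, `meta`.
#' @export
fit_pca <- function(features, k = 50) {
  x <- if (inherits(features, "ni_features")) features$x else as.matrix(features)
  meta <- if (inherits(features, "ni_features")) features$meta else NULL
  if (nrow(x) < k)
    stop("need at least as many windows as components", call. = FALSE)
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < k) {
    warning(sprintf("matrix rank %d < k = %d; k reduced", rank, k))
    k <- rank
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    loadings[which.max(abs(loadings[, j])), j] < 0
  }, logical(1))
  loadings[, flip] <- -loadings[, flip]
  scores <- xc %*% loadings
  ev <- sv$d^2 / (nrow(xc) - 1)
  structure(list(loadings = loadings, scores = scores,
                 evf = ev / sum(ev), eigenvalues = ev,
                 center = center, k = k, meta = meta),
            class = "ni_pca")
}

#' Project new windows into a fitted PC space
#'
#' Uses the training centering vector and loadings, so held-out windows are
#' mapped consistently with the training set.
#'
#' @param pca An `ni_pca` fit.
#' @param newdata An `ni_features` object or matrix with 482 columns.
#' @return Score matrix (windows x k).
#' @export
project_pca <- function(pca, newdata) {
  x <- if (inherits(newdata, "ni_features")) newdata$x else as.matrix(newdata)
  sweep(x, 2, pca$center) %*% pca$loadings
}

#' @export
print.ni_pca <- function(x, ...) {
  cat(sprintf("<ni_pca> %d components over %d windows; cumulative EV %.1f%%\n",
              x$k, nrow(x$scores), 100 * sum(x$evf[seq_len(x$k)])))
  invisible(x)
}

#' @rdname fit_pca
#' @param x An `ni_pca` object.
#' @param ... Unused.
#' @export
tidy.ni_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$evf),
                 eigenvalue = x$eigenvalues,
                 evf = x$evf,
                 cumulative_evf = cumsum(x$evf))
}

#' @rdname fit_pca
#' @export
glance.ni_pca <- function(x, ...) {
  tibble::tibble(k = x$k, n_windows = nrow(x$scores),
                 cumulative_evf_k = sum(x$evf[seq_len(x$k)]),
                 total_variance = sum(x$eigenvalues))
}
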