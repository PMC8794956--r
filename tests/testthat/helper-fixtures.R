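# Shared fixtures, built once per test run and cached. The "mini" individual
# uses shortened synthesis spans (full training periods, 16-min test slices)
# so feature/classifier tests run at desk scale; the statistics they feed are
# the same as for the full spans.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

mini_spans <- list(induction = list(c(40, 76)),
                   emergence = list(c(40, 60), c(130, 166)))

mini_individual <- function(seed = 42) {
  fixture(paste0("mini_", seed), function() {
    co <- generate_cohort(n_individuals = 1, seed = seed, spans = mini_spans)
    ind <- preprocess_recording(co[[1]])
    eme <- preprocess_recording(co[[2]])
    feats <- features_for_individual(ind, eme)
    list(cohort = co, induction = ind, emergence = eme,
         features = feats, pca = fit_pca(feats))
  })
}

# Full-scale default cohort run, shared by the acceptance-style checks.
acceptance_run <- function() {
  fixture("acceptance_run", function() {
    run_pipeline(default_config(seed = 1))
  })
}

# A tiny labeled Gaussian problem for classifier unit tests.
gaussian_problem <- function(n = 200, p = 10, delta = 0, seed = 7) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * p), n, p),
               matrix(rnorm(n * p, mean = delta), n, p))
    y <- factor(rep(c("induction", "emergence"), each = n),
                levels = c("induction", "emergence"))
    list(x = x, y = y)
  })
}
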