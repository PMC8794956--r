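#' Default pipeline configuration
#'
#' Mirrors the study design: 6 individuals, paired induction/emergence
#' exposures, 250-member LDA (and optionally SVM) ensembles with 260
#' training windows per class, a shuffled-label null per ensemble, and
#' occupancy memory relaxing with a 40-min time constant.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `ni_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    source = "simulate",
    n_individuals = 6,
    relaxation_target_min = 40,
    exchangeable = FALSE,
    spans = "analysis",
    artifact_rate_per_min = 0.1,
    methods = "lda",
    n_classifiers = 250,
    n_per_class = 260,
    include_null = TRUE,
    population = FALSE,
    n_pcs = 50,
    seed = 1)
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = c("ni_config", "list"))
}

stage_cached <- function(store, stage, cfg_hash, compute) {
  if (is.null(store)) return(compute())
  dir.create(store, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(store, paste0(stage, "_", cfg_hash, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- compute()
  saveRDS(val, path)
  val
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg[order(names(cfg))], NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full neural-inertia pipeline
#'
#' Executes simulate (or import) -> preprocess -> EMG tone -> spectral
#' features -> PCA -> classifier ensembles (real and shuffled-label null) ->
#' accuracy traces -> inertia report. Every stage derives its seeds from
#' `config$seed`, so identical configurations give identical reports. With a
#' `store` directory each stage's product is cached under a hash of the
#' configuration, making the run resumable stage by stage.
#'
#' @param config A [default_config()] (or list of overrides).
#' @param store Optional directory for stage caching.
#' @param recordings Optional pre-built list of recordings (e.g. from
#'   [read_edf()]), used when `config$source = "import"`.
#' @return List of class `ni_run`: `report` (an `ni_report`), `trace`,
#'   `pcas`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), store = NULL,
                         recordings = NULL) {
  if (!inherits(config, "ni_config")) config <- do.call(default_config, config)
  h <- config_hash(config)
  warnings_log <- character()

  cohort <- stage_cached(store, "cohort", h, function() {
    if (config$source == "import") {
      if (is.null(recordings)) stop("source = 'import' needs `recordings`", call. = FALSE)
      recordings
    } else {
      generate_cohort(n_individuals = config$n_individuals,
                      relaxation_target_min = config$relaxation_target_min,
                      seed = config$seed, spans = config$spans,
                      exchangeable = config$exchangeable,
                      artifact_rate_per_min = config$artifact_rate_per_min)
    }
  })

  prep <- stage_cached(store, "preprocess", h, function() {
    lapply(cohort, function(rec) {
      if (rec$fs > 250) {
        f <- rec$fs / 250
        rec$segments <- lapply(rec$segments, function(seg) {
          seg$eeg <- apply(seg$eeg, 2, function(x)
            as.numeric(decimate_signal(x, rec$fs, f)))
          seg$emg <- as.numeric(decimate_signal(seg$emg, rec$fs, f))
          seg
        })
        rec$fs <- 250
      }
      preprocess_recording(rec)
    })
  })

  pcas <- stage_cached(store, "features", h, function() {
    inds <- unique(purrr::map_int(prep, ~ as.integer(.x$individual)))
    feats <- purrr::map(inds, function(i) {
      recs <- prep[purrr::map_lgl(prep, ~ .x$individual == i)]
      arms <- purrr::map_chr(recs, "arm")
      features_for_individual(recs[[which(arms == "induction")]],
                              recs[[which(arms == "emergence")]])
    })
    names(feats) <- as.character(inds)
    list(features = feats,
         pcas = purrr::map(feats, fit_pca, k = config$n_pcs))
  })

  trace <- stage_cached(store, "evaluate", h, function() {
    parts <- list()
    for (id in names(pcas$pcas)) {
      pca <- pcas$pcas[[id]]
      for (m in config$methods) {
        for (nul in unique(c(FALSE, config$include_null))) {
          ens <- train_ensemble(
            pca, n = config$n_classifiers, method = m,
            base_seed = child_seed(config$seed,
                                   1e5 + 7 * as.integer(id) + (m == "svm") * 3 + nul),
            null = nul, n_per_class = config$n_per_class)
          parts[[length(parts) + 1]] <- evaluate_ensemble(ens, pca)
        }
      }
    }
    if (config$population && length(pcas$features) >= 2) {
      for (id in names(pcas$features)) {
        pop_ts <- assemble_population_training_set(
          pcas$features, id, seed = child_seed(config$seed, 2e5 + as.integer(id)))
        clf <- train_lda(pop_ts)
        pop_pca <- attr(pop_ts, "pca")
        scores <- project_pca(pop_pca, pcas$features[[id]])
        ens <- structure(list(classifiers = list(clf), method = "lda",
                              null = FALSE, seeds = pop_ts$seed,
                              individual = as.integer(id)),
                         class = "ni_ensemble")
        tr <- evaluate_ensemble(ens, NULL, scores = scores,
                                meta = pcas$features[[id]]$meta)
        tr$method <- "lda-population"
        parts[[length(parts) + 1]] <- tr
      }
    } else if (config$population) {
      warning("population training skipped: cohort has a single individual")
    }
    dplyr::bind_rows(parts)
  })

  report <- inertia_report(trace, ci_seed = child_seed(config$seed, 3e5))
  structure(list(report = report, trace = trace, pcas = pcas$pcas,
                 manifest = list(config = unclass(config), hash = h,
                                 n_recordings = length(cohort),
                                 version = as.character(utils::packageVersion("neuroinertia")))),
            class = "ni_run")
}

#' @export
print.ni_run <- function(x, ...) {
  cat(sprintf("<ni_run> %d recordings, config hash %s\n",
              x$manifest$n_recordings, substr(x$manifest$hash, 1, 8)))
  print(x$report)
  invisible(x)
}

#' Write a study object with a manifest
#'
#' Serializes any pipeline product to a single file and writes a JSON
#' manifest next to it (class, creation time, package version, content
#' hash), so every product can be traced to the run that made it.
#'
#' @param x Object to store.
#' @param path Destination (an `.rds` path; the manifest goes to
#'   `<path>.json`).
#' @param config Optional configuration snapshot to embed.
#' @return `path`, invisibly.
#' @export
write_study <- function(x, path, config = NULL) {
  saveRDS(x, path)
  manifest <- list(class = class(x)[1],
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   version = as.character(utils::packageVersion("neuroinertia")),
                   md5 = unname(tools::md5sum(path)),
                   config = config)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) readRDS(path)

#' Export report tables
#'
#' Writes the report as JSON plus per-table CSVs (per-individual medians and
#' calls, method comparison, early/late tests, and the full accuracy trace
#' when provided).
#'
#' @param run An `ni_run` or `ni_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- if (inherits(run, "ni_run")) run$report else run
  jsonlite::write_json(
    list(tidy = tidy(report), glance = glance(report)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  utils::write.csv(report$per_individual,
                   file.path(dir, "per_individual.csv"), row.names = FALSE)
  if (!is.null(report$methods))
    utils::write.csv(report$methods, file.path(dir, "methods.csv"),
                     row.names = FALSE)
  if (inherits(run, "ni_run"))
    utils::write.csv(run$trace, file.path(dir, "accuracy_trace.csv"),
                     row.names = FALSE)
  invisible(dir)
}
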