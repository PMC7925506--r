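#' Default pipeline configuration
#'
#' All stage parameters with their protocol defaults: 200 Hz common rate,
#' 4 wavelet levels, valley-search fraction 0.3, the classifier
#' hyperparameters, and the repeated stratified CV protocol. The list
#' round-trips through YAML/JSON unchanged.
#'
#' @param seed master seed: the cohort simulation and every CV partition are
#'   derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_healthy = 35L, n_pathological = 25L,
                  rate_pool = c(50, 100, 128, 200, 256, 350),
                  duration_split = 41 / 60, separation = 1),
    preprocess = list(target_rate = 200, levels = 4L),
    features = list(search_frac = 0.3, stride_factor = 2,
                    valley_stage = "filtered"),
    classifiers = list(k = 5L, spread = 0.1, influence = 0.5,
                       epochs = 100L, cost = 1, ridge = 1e-6),
    cv = list(test_size = 10L, repeats = 10L)
  )
}

#' Save / load a configuration (YAML)
#'
#' @param config configuration list.
#' @param path file path (`.yaml`).
#' @return `save_config` returns `path` invisibly; `load_config` the list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full gait-analysis pipeline
#'
#' Executes the flow in order: trial acquisition (simulation, or reading CSV
#' trials from `in_dir`), magnitude/resample/denoise/filter preprocessing,
#' PSD peak extraction, gait feature extraction, min-max normalization and
#' the nine-classifier exhaustive-subset benchmark. Per-trial failures are
#' quarantined and summarized; the run fails only if a class loses all its
#' trials. Fully reproducible from `(config)`.
#'
#' @param config configuration list from [default_config()].
#' @param in_dir optional directory of `*.csv` trials written by
#'   [write_trial()]; when `NULL` a synthetic cohort is simulated.
#' @param out_dir optional output directory; when given, `features.csv`,
#'   `results.csv`, `masks.csv`, `config.json` and `run_log.txt` are
#'   written there.
#' @param classifiers classifier names to benchmark.
#' @return object of class `gait_report`: list with `features` (data frame),
#'   `normalization`, `benchmark`, `quarantined`, `config_hash` and `log`.
#' @export
run_pipeline <- function(config = default_config(), in_dir = NULL,
                         out_dir = NULL, classifiers = classifier_names()) {
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  hash <- .config_hash(config)
  say("config hash %s", hash)

  if (is.null(in_dir)) {
    co <- config$cohort
    trials <- generate_cohort(co$n_healthy, co$n_pathological,
                              rate_pool = co$rate_pool,
                              duration_split = co$duration_split,
                              seed = config$seed,
                              separation = co$separation %||% 1)
    say("simulated %d trials", length(trials))
  } else {
    files <- sort(list.files(in_dir, pattern = "\\.csv$", full.names = TRUE))
    trials <- list()
    for (f in files) {
      tr <- tryCatch(read_trial(f), error = function(e) e)
      if (inherits(tr, "error")) {
        say("quarantined %s at stage 'read': %s", basename(f),
            conditionMessage(tr))
      } else {
        trials[[length(trials) + 1]] <- tr
      }
    }
    say("read %d of %d trial files", length(trials), length(files))
  }

  fp <- config$features
  pp <- config$preprocess
  feats <- withCallingHandlers(
    cohort_features(trials, target_rate = pp$target_rate, levels = pp$levels,
                    search_frac = fp$search_frac,
                    stride_factor = fp$stride_factor,
                    valley_stage = fp$valley_stage),
    warning = function(w) {
      say("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  quarantined <- attr(feats, "quarantined")
  say("extracted features for %d trials (%d quarantined)",
      nrow(feats), length(quarantined))

  counts <- table(feats$label)
  if (any(counts < 2) || length(counts) < 2) {
    stop("a class has fewer than 2 usable trials; cannot classify",
         call. = FALSE)
  }

  X <- as.matrix(feats[, feature_columns()])
  norm <- normalize_features(X)
  proto <- cv_protocol(test_size = config$cv$test_size,
                       repeats = config$cv$repeats, seed = config$seed)
  cl <- config$classifiers
  bench <- benchmark_all(norm$X, feats$label, proto, classifiers = classifiers,
                         k = cl$k, spread = cl$spread, influence = cl$influence,
                         epochs = cl$epochs, cost = cl$cost, ridge = cl$ridge)
  say("benchmarked %d classifiers over %d subsets",
      nrow(bench$results), nrow(bench$details[[1]]$all_subsets))

  report <- structure(list(features = feats, normalization = norm,
                           benchmark = bench, quarantined = quarantined,
                           config = config, config_hash = hash,
                           log = log_lines),
                      class = "gait_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    res <- bench$results
    res$config_hash <- hash
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(bench$masks),
                     file.path(out_dir, "masks.csv"))
    jsonlite::write_json(c(config, list(config_hash = hash)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("<gait_report> %d trials (%d quarantined), config %s\n",
              nrow(x$features), length(x$quarantined), x$config_hash))
  print(x$benchmark$results)
  invisible(x)
}
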