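#' Cross-validation protocol
#'
#' The benchmark protocol: disjoint stratified test sets of `test_size`
#' patterns covering the whole cohort (60 patterns with `test_size = 10`
#' gives 6 training passes per repetition), repeated `repeats` times with
#' fresh seeded partitions; reported accuracies are the mean and standard
#' deviation over the repeats.
#'
#' @param test_size patterns per test fold.
#' @param repeats number of repetitions of the whole CV pass.
#' @param seed integer seed driving the fold shuffles.
#' @return object of class `cv_protocol`.
#' @export
cv_protocol <- function(test_size = 10, repeats = 10, seed = 1L) {
  stopifnot(test_size >= 1, repeats >= 1)
  structure(list(test_size = test_size, repeats = repeats,
                 seed = as.integer(seed)),
            class = "cv_protocol")
}

#' Stratified fold partition
#'
#' Splits `length(labels)` patterns into `round(M / test_size)` disjoint,
#' exhaustive test folds whose per-fold class counts match the global class
#' ratio within one pattern. Within each class the extra patterns left by the
#' integer division are dealt to folds from opposite ends for the two
#' classes, so fold sizes stay within one of `test_size`.
#'
#' @param labels class labels (2 classes).
#' @param test_size target patterns per fold.
#' @param seed integer seed for the within-class shuffles.
#' @return list of folds, each a list with `train` and `test` index vectors.
#' @export
#' @examples
#' f <- stratified_folds(rep(c("a", "b"), c(35, 25)), test_size = 10, seed = 1)
#' length(f)  # 6
stratified_folds <- function(labels, test_size = 10, seed = 1L) {
  y <- .as_label_factor(labels)
  M <- length(y)
  if (M < 2 * test_size) {
    stop("need at least 2 * test_size patterns", call. = FALSE)
  }
  k <- max(2L, round(M / test_size))
  set.seed(as.integer(seed))

  lev <- levels(y)
  fold_of <- integer(M)
  for (ci in seq_along(lev)) {
    idx <- sample(which(y == lev[ci]))
    nc <- length(idx)
    if (nc < k) {
      warning("class '", lev[ci], "' has fewer members (", nc,
              ") than folds (", k, "); stratification is best-effort",
              call. = FALSE)
    }
    base <- nc %/% k
    rem <- nc - base * k
    counts <- rep(base, k)
    if (rem > 0) {
      extra_folds <- if (ci %% 2 == 1) seq_len(rem) else k + 1 - seq_len(rem)
      counts[extra_folds] <- counts[extra_folds] + 1
    }
    fold_of[idx] <- rep(seq_len(k), counts)
  }
  lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    list(train = which(fold_of != f), test = test)
  })
}

#' Evaluate one classifier on one feature subset
#'
#' For each repeat a fresh seeded stratified partition is drawn; the accuracy
#' of a repeat is the pooled fraction of correctly classified test patterns
#' across its folds, in percent. Returns the mean and the sample standard
#' deviation over repeats (zero, with a message, for a single repeat).
#'
#' @param spec a [classifier_spec()].
#' @param X normalized feature matrix (patterns by features).
#' @param y labels.
#' @param subset_mask logical or 0/1 vector selecting at least one feature
#'   column.
#' @param protocol a [cv_protocol()].
#' @return list with `mean_accuracy`, `std_accuracy` (percent) and
#'   `per_repeat`.
#' @export
evaluate_subset <- function(spec, X, y, subset_mask = rep(TRUE, ncol(X)),
                            protocol = cv_protocol()) {
  X <- as.matrix(X)
  mask <- as.logical(subset_mask)
  if (sum(mask) < 1) stop("subset_mask must select at least one feature",
                          call. = FALSE)
  y <- .as_label_factor(y)
  Xs <- X[, mask, drop = FALSE]

  acc <- vapply(seq_len(protocol$repeats), function(r) {
    folds <- stratified_folds(y, protocol$test_size,
                              seed = protocol$seed + r - 1L)
    correct <- 0L
    for (f in folds) {
      pred <- fit_predict(spec, Xs[f$train, , drop = FALSE], y[f$train],
                          Xs[f$test, , drop = FALSE])
      correct <- correct + sum(pred == y[f$test])
    }
    100 * correct / length(y)
  }, numeric(1))

  std <- if (protocol$repeats == 1) {
    message("single repeat: std_accuracy is 0 by convention")
    0
  } else {
    stats::sd(acc)
  }
  list(mean_accuracy = mean(acc), std_accuracy = std, per_repeat = acc)
}

.all_subset_masks <- function(n_features = 5) {
  masks <- lapply(seq_len(2^n_features - 1), function(i) {
    as.integer(intToBits(i)[seq_len(n_features)])
  })
  masks
}

.mask_string <- function(mask) paste0(as.integer(mask), collapse = "")

#' Exhaustive feature-subset search for one classifier
#'
#' Evaluates all `2^N - 1` non-empty feature subsets (31 for the five gait
#' features) under the CV protocol and returns the winner: highest mean
#' accuracy, ties broken by fewer features, then by lexicographic order of
#' the subset mask in canonical feature order. Subsets whose evaluation
#' fails are recorded and skipped.
#'
#' @inheritParams evaluate_subset
#' @return object of class `benchmark_result`: list with `classifier`,
#'   `subset_mask` (0/1 vector), `mean_accuracy`, `std_accuracy`,
#'   `n_features`, plus `all_subsets` (data frame over the full enumeration)
#'   and `failures`.
#' @export
exhaustive_search <- function(spec, X, y, protocol = cv_protocol()) {
  X <- as.matrix(X)
  masks <- .all_subset_masks(ncol(X))
  rows <- vector("list", length(masks))
  failures <- character(0)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    res <- tryCatch(evaluate_subset(spec, X, y, m, protocol),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(.mask_string(m), ": ",
                                     conditionMessage(res)))
      next
    }
    rows[[i]] <- data.frame(mask = .mask_string(m), n_features = sum(m),
                            mean_accuracy = res$mean_accuracy,
                            std_accuracy = res$std_accuracy,
                            stringsAsFactors = FALSE)
  }
  all_subsets <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(all_subsets) || nrow(all_subsets) == 0) {
    stop("every subset evaluation failed for ", spec$name, call. = FALSE)
  }
  ord <- order(-all_subsets$mean_accuracy, all_subsets$n_features,
               all_subsets$mask)
  best <- all_subsets[ord[1], ]
  structure(list(
    classifier = spec$name,
    subset_mask = as.integer(strsplit(best$mask, "")[[1]]),
    mean_accuracy = best$mean_accuracy,
    std_accuracy = best$std_accuracy,
    n_features = best$n_features,
    all_subsets = all_subsets,
    failures = failures
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s: %.2f%% +/- %.2f%% with mask %s (%d features)\n",
              x$classifier, x$mean_accuracy, x$std_accuracy,
              .mask_string(x$subset_mask), x$n_features))
  invisible(x)
}

#' Benchmark all nine classifiers over all feature subsets
#'
#' Runs [exhaustive_search()] for every classifier and assembles the two
#' summary tables: a per-classifier accuracy table (mean, standard
#' deviation, number of adopted features) and a features-by-classifiers 0/1
#' grid of winning subsets with per-feature occurrence counts.
#'
#' @param X normalized feature matrix; columns in [feature_columns()] order.
#' @param y labels.
#' @param protocol a [cv_protocol()].
#' @param classifiers character vector of classifier names to run.
#' @param ... hyperparameter overrides passed to [classifier_spec()].
#' @return list with `results` (data frame: classifier, mean_accuracy,
#'   std_accuracy, n_features, mask), `masks` (features x classifiers 0/1
#'   matrix with an `occurrences` column) and `details` (the per-classifier
#'   `benchmark_result`s); failed classifiers are reported in `failed`.
#' @export
benchmark_all <- function(X, y, protocol = cv_protocol(),
                          classifiers = classifier_names(), ...) {
  X <- as.matrix(X)
  details <- list()
  failed <- character(0)
  for (nm in classifiers) {
    res <- tryCatch(exhaustive_search(classifier_spec(nm, ...), X, y, protocol),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("classifier ", nm, " failed: ", conditionMessage(res),
              call. = FALSE)
      failed <- c(failed, nm)
    } else {
      details[[nm]] <- res
    }
  }
  if (length(details) == 0) stop("all classifiers failed", call. = FALSE)

  results <- do.call(rbind, lapply(details, function(r) {
    data.frame(classifier = r$classifier, mean_accuracy = r$mean_accuracy,
               std_accuracy = r$std_accuracy, n_features = r$n_features,
               mask = .mask_string(r$subset_mask), stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL

  feat <- if (ncol(X) == length(feature_columns()) && !is.null(colnames(X))) {
    colnames(X)
  } else {
    colnames(X) %||% paste0("feature_", seq_len(ncol(X)))
  }
  masks <- vapply(details, function(r) r$subset_mask, integer(ncol(X)))
  masks <- matrix(masks, nrow = ncol(X),
                  dimnames = list(feat, names(details)))
  masks <- cbind(masks, occurrences = rowSums(masks))

  list(results = results, masks = masks, details = details, failed = failed)
}
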