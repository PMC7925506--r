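#' Classifier specification
#'
#' Names one of the nine benchmark classifiers and carries its
#' hyperparameters. Defaults follow the benchmark protocol: KNN with K = 5
#' and Euclidean distance; naive Bayes with Gaussian-kernel density
#' estimation; SVM with an RBF kernel and box constraint 1; the neuro-fuzzy
#' model trained by scaled conjugate gradient for at most 100 epochs with one
#' cluster per class; CART with class priors from class frequencies and Gini
#' splits; PNN with radial-basis spread 0.1; FIS built by subtractive
#' clustering with cluster-center influence 0.5 in the normalized space and
#' one first-order rule per cluster.
#'
#' @param name one of `"LDA"`, `"QDA"`, `"KNN"`, `"NB"`, `"SVM"`, `"NF"`,
#'   `"CART"`, `"PNN"`, `"FIS"`.
#' @param ... hyperparameter overrides (`k`, `spread`, `influence`, `epochs`,
#'   `cost`, `ridge`).
#' @return object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("PNN", spread = 0.2)
classifier_spec <- function(name, ...) {
  name <- match.arg(name, classifier_names())
  hp <- utils::modifyList(
    list(k = 5L, spread = 0.1, influence = 0.5, epochs = 100L,
         cost = 1, ridge = 1e-6),
    list(...)
  )
  stopifnot(hp$spread > 0, hp$k >= 1, hp$k %% 2 == 1, hp$epochs >= 0)
  structure(list(name = name, hyperparams = hp), class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
classifier_names <- function() {
  c("LDA", "QDA", "KNN", "NB", "SVM", "NF", "CART", "PNN", "FIS")
}

.as_label_factor <- function(y) {
  if (is.factor(y)) factor(y) else factor(y, levels = unique(y))
}

#' Train on one split and predict the test patterns
#'
#' Dispatches to the classifier named by `spec`. Features are expected in the
#' normalized `[0, 1]` space; labels must be binary and both classes must be
#' present in the training set. All classifiers are deterministic given the
#' data.
#'
#' @param spec a [classifier_spec()].
#' @param X_train,X_test numeric matrices (patterns by features).
#' @param y_train training labels (factor or character, 2 classes).
#' @return factor of predicted labels, one per test row.
#' @export
fit_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  y <- .as_label_factor(y_train)
  if (nlevels(y) != 2) {
    stop("training set must contain exactly 2 classes, got ", nlevels(y),
         call. = FALSE)
  }
  hp <- spec$hyperparams
  pred <- switch(spec$name,
    LDA = .gaussian_da(X_train, y, X_test, pooled = TRUE, ridge = hp$ridge),
    QDA = .gaussian_da(X_train, y, X_test, pooled = FALSE, ridge = hp$ridge),
    KNN = .knn_predict(X_train, y, X_test, k = hp$k),
    NB = .kernel_nb(X_train, y, X_test),
    SVM = .svm_predict(X_train, y, X_test, cost = hp$cost),
    NF = nf_fit_predict(X_train, y, X_test, epochs = hp$epochs),
    CART = .cart_predict(X_train, y, X_test),
    PNN = pnn_predict(X_train, y, X_test, spread = hp$spread),
    FIS = fis_fit_predict(X_train, y, X_test, influence = hp$influence)
  )
  factor(as.character(pred), levels = levels(y))
}

# Gaussian discriminant analysis; pooled covariance = LDA, per-class = QDA.
# A small diagonal ridge keeps near-singular covariances invertible.
.gaussian_da <- function(X, y, X_test, pooled, ridge) {
  d <- ncol(X)
  lev <- levels(y)
  stats_c <- lapply(lev, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xc),
         S = if (nrow(Xc) >= 2) stats::cov(Xc) else matrix(0, d, d),
         n = nrow(Xc),
         prior = nrow(Xc) / nrow(X))
  })
  if (pooled) {
    Sp <- Reduce(`+`, lapply(stats_c, function(st) st$S * (st$n - 1))) /
      (nrow(X) - length(lev))
    for (i in seq_along(lev)) stats_c[[i]]$S <- Sp
  }
  scores <- vapply(stats_c, function(st) {
    S <- st$S + diag(ridge, d)
    Si <- solve(S)
    logdet <- determinant(S, logarithm = TRUE)$modulus
    dx <- sweep(X_test, 2, st$mu)
    -0.5 * rowSums((dx %*% Si) * dx) - 0.5 * as.numeric(logdet) + log(st$prior)
  }, numeric(nrow(X_test)))
  scores <- matrix(scores, nrow = nrow(X_test))
  lev[max.col(scores, ties.method = "first")]
}

# KNN with Euclidean distance; all neighbors tied at the K-th distance join
# the vote, and a vote tie goes to the first class level
.knn_predict <- function(X, y, X_test, k) {
  lev <- levels(y)
  apply(X_test, 1, function(xt) {
    d <- sqrt(colSums((t(X) - xt)^2))
    kth <- sort(d, partial = min(k, length(d)))[min(k, length(d))]
    nb <- which(d <= kth + 1e-12)
    votes <- table(factor(y[nb], levels = lev))
    lev[which.max(votes)]
  })
}

# naive Bayes with per-feature Gaussian-kernel densities (Silverman bandwidth)
.kernel_nb <- function(X, y, X_test, bw_floor = 1e-6) {
  lev <- levels(y)
  d <- ncol(X)
  models <- lapply(lev, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    bw <- vapply(seq_len(d), function(j) {
      h <- tryCatch(stats::bw.nrd0(Xc[, j]), error = function(e) bw_floor)
      max(h, bw_floor)
    }, numeric(1))
    list(X = Xc, bw = bw, prior = nrow(Xc) / nrow(X))
  })
  scores <- vapply(models, function(m) {
    ll <- rep(log(m$prior), nrow(X_test))
    for (j in seq_len(d)) {
      dens <- vapply(X_test[, j], function(v) {
        mean(stats::dnorm(v, mean = m$X[, j], sd = m$bw[j]))
      }, numeric(1))
      ll <- ll + log(pmax(dens, .Machine$double.xmin))
    }
    ll
  }, numeric(nrow(X_test)))
  scores <- matrix(scores, nrow = nrow(X_test))
  lev[max.col(scores, ties.method = "first")]
}

.svm_predict <- function(X, y, X_test, cost) {
  v <- mean(apply(X, 2, stats::var))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    tolerance = 1e-3)
  as.character(stats::predict(fit, X_test))
}

.cart_predict <- function(X, y, X_test) {
  df <- data.frame(X, check.names = TRUE)
  df$.y <- y
  test_df <- data.frame(X_test, check.names = TRUE)
  names(test_df) <- names(df)[seq_len(ncol(X))]
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini",
                                   prior = as.numeric(table(y) / length(y))),
                      control = rpart::rpart.control(minsplit = 2,
                                                     minbucket = 1,
                                                     cp = 0, xval = 0))
  as.character(stats::predict(fit, test_df, type = "class"))
}

#' Probabilistic neural network prediction
#'
#' Kernel-density Bayes classifier: the score of class `c` at a test point
#' `x` is the average over that class's training points of
#' `exp(-||x - x_i||^2 / (2 * spread^2))`; the predicted label is the argmax,
#' with exact ties broken toward the first class in label order.
#'
#' @param X_train,X_test numeric matrices.
#' @param y_train labels (2 classes, both present).
#' @param spread radial-basis spread (default 0.1, for features normalized
#'   to `[0, 1]`).
#' @return character vector of predicted labels.
#' @export
pnn_predict <- function(X_train, y_train, X_test, spread = 0.1) {
  stopifnot(spread > 0)
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  y <- .as_label_factor(y_train)
  lev <- levels(y)
  if (any(table(y) == 0)) stop("empty class in training data", call. = FALSE)
  scores <- vapply(lev, function(cl) {
    Xc <- X_train[y == cl, , drop = FALSE]
    apply(X_test, 1, function(xt) {
      mean(exp(-colSums((t(Xc) - xt)^2) / (2 * spread^2)))
    })
  }, numeric(nrow(X_test)))
  scores <- matrix(scores, nrow = nrow(X_test))
  lev[max.col(scores, ties.method = "first")]
}
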