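#' Subtractive clustering
#'
#' Density-based selection of cluster centers among the data points. Each
#' point `i` receives the potential
#' `P_i = sum_j exp(-4 ||x_i - x_j||^2 / r_a^2)` with `r_a` the influence
#' radius; the highest-potential point becomes a center and its neighborhood
#' potential is subtracted with squash radius `r_b = 1.5 * r_a`. Candidates
#' whose remaining potential exceeds `accept_ratio` of the first peak are
#' accepted outright; those below `reject_ratio` end the search; the gray
#' zone is resolved by the standard distance/potential trade-off rule.
#'
#' @param X numeric matrix (patterns by features), normally in `[0, 1]` per
#'   column.
#' @param influence_radius cluster-center influence `r_a` in the normalized
#'   data space (default 0.5).
#' @param accept_ratio,reject_ratio accept/reject thresholds relative to the
#'   first center's potential.
#' @param max_centers safety cap on the number of centers.
#' @return matrix of cluster centers (centers by features).
#' @export
#' @examples
#' X <- rbind(matrix(0.1, 5, 2), matrix(0.9, 5, 2))
#' subtractive_clustering(X)
subtractive_clustering <- function(X, influence_radius = 0.5,
                                   accept_ratio = 0.5, reject_ratio = 0.15,
                                   max_centers = nrow(X)) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("cannot cluster an empty matrix", call. = FALSE)
  ra <- influence_radius
  rb <- 1.5 * ra
  alpha <- 4 / ra^2
  beta <- 4 / rb^2

  D2 <- as.matrix(stats::dist(X))^2
  P <- rowSums(exp(-alpha * D2))
  centers <- NULL
  center_idx <- integer(0)
  P1 <- NULL

  repeat {
    i <- which.max(P)
    Pi <- P[i]
    if (is.null(P1)) {
      accept <- TRUE
      P1 <- Pi
    } else {
      ratio <- Pi / P1
      if (ratio > accept_ratio) {
        accept <- TRUE
      } else if (ratio < reject_ratio) {
        break
      } else {
        dmin <- sqrt(min(D2[i, center_idx]))
        if (dmin / ra + ratio >= 1) {
          accept <- TRUE
        } else {
          P[i] <- 0
          if (all(P <= reject_ratio * P1)) break
          next
        }
      }
    }
    if (accept) {
      centers <- rbind(centers, X[i, ])
      center_idx <- c(center_idx, i)
      P <- P - Pi * exp(-beta * D2[, i])
      P[P < 0] <- 0
      if (length(center_idx) >= max_centers) break
      if (all(P <= reject_ratio * P1)) break
    }
  }
  rownames(centers) <- NULL
  centers
}

#' First-order Sugeno fuzzy inference classifier
#'
#' Rule antecedents come from [subtractive_clustering()] on the training
#' inputs: one rule per center, with Gaussian memberships of per-feature
#' width `r_a * range_j / sqrt(8)`. Rule firing strengths are products of
#' memberships, normalized across rules; each rule's first-order (linear)
#' consequent is fit by least squares against the labels encoded 0/1, with a
#' ridge fallback (lambda = 1e-8) if the normal equations are
#' rank-deficient. The predicted label is the second class when the crisp
#' output reaches 0.5.
#'
#' @param X_train,X_test numeric matrices in the normalized feature space.
#' @param y_train labels: a 2-level factor/character vector, or a numeric
#'   0/1 vector (in which case 0/1 predictions are returned).
#' @param influence cluster-center influence radius.
#' @return predicted labels (same type as `y_train`).
#' @export
fis_fit_predict <- function(X_train, y_train, X_test, influence = 0.5) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  numeric_y <- is.numeric(y_train)
  if (numeric_y) {
    y01 <- as.numeric(y_train)
    lev <- NULL
  } else {
    y <- .as_label_factor(y_train)
    lev <- levels(y)
    y01 <- as.numeric(y) - 1
  }

  centers <- subtractive_clustering(X_train, influence_radius = influence)
  d <- ncol(X_train)
  rng <- apply(X_train, 2, function(v) max(v) - min(v))
  sigma <- influence * pmax(rng, 1e-6) / sqrt(8)

  firing <- function(X) {
    W <- vapply(seq_len(nrow(centers)), function(k) {
      exp(-rowSums(sweep(X, 2, centers[k, ])^2 /
                     matrix(2 * sigma^2, nrow(X), d, byrow = TRUE)))
    }, numeric(nrow(X)))
    W <- matrix(W, nrow = nrow(X))
    s <- rowSums(W)
    s[s < .Machine$double.eps] <- 1
    W / s
  }

  design <- function(X, Wn) {
    do.call(cbind, lapply(seq_len(ncol(Wn)), function(k) {
      Wn[, k] * cbind(X, 1)
    }))
  }

  Wn_tr <- firing(X_train)
  A <- design(X_train, Wn_tr)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    message("FIS consequent fit is rank-deficient; using ridge fallback")
    coef <- solve(crossprod(A) + diag(1e-8, ncol(A)), crossprod(A, y01))
  } else {
    coef <- qr.coef(qrA, y01)
  }

  yhat <- as.numeric(design(X_test, firing(X_test)) %*% coef)
  pred01 <- as.integer(yhat >= 0.5)
  if (numeric_y) pred01 else lev[pred01 + 1]
}

# cross-entropy loss and gradient of the one-Gaussian-cluster-per-class model
.nf_loss_grad <- function(theta, X, Y, K, d) {
  n <- nrow(X)
  C <- matrix(theta[seq_len(K * d)], K, d)
  W <- matrix(theta[K * d + seq_len(K * d)], K, d)   # log widths
  S2 <- exp(2 * W)
  logm <- vapply(seq_len(K), function(k) {
    -rowSums(sweep(X, 2, C[k, ])^2 /
               matrix(2 * S2[k, ], n, d, byrow = TRUE))
  }, numeric(n))
  logm <- matrix(logm, nrow = n)
  mmax <- apply(logm, 1, max)
  p <- exp(logm - mmax)
  p <- p / rowSums(p)
  loss <- -mean(log(pmax(rowSums(p * Y), 1e-300)))
  G <- (p - Y) / n
  gC <- matrix(0, K, d)
  gW <- matrix(0, K, d)
  for (k in seq_len(K)) {
    dx <- sweep(X, 2, C[k, ])
    s2 <- matrix(S2[k, ], n, d, byrow = TRUE)
    gC[k, ] <- colSums(G[, k] * dx / s2)
    gW[k, ] <- colSums(G[, k] * dx^2 / s2)
  }
  list(loss = loss, grad = c(gC, gW))
}

# Scaled conjugate gradient (Moller) minimizer; fn(theta) must return
# list(loss, grad). Only improving steps are accepted, so the sequence of
# accepted losses is non-increasing by construction.
.scg_minimize <- function(theta, fn, max_epochs = 100, grad_tol = 1e-8) {
  sigma0 <- 1e-4
  lambda <- 1e-6
  lambda_bar <- 0
  ev <- fn(theta)
  E <- ev$loss
  r <- -ev$grad
  p <- r
  success <- TRUE
  trace <- E
  n_par <- length(theta)
  delta <- 0
  s <- numeric(n_par)

  k <- 0
  while (k < max_epochs && sqrt(sum(r^2)) > grad_tol) {
    k <- k + 1
    p2 <- sum(p^2)
    if (p2 < 1e-300) break
    if (success) {
      sigma_k <- sigma0 / sqrt(p2)
      g2 <- fn(theta + sigma_k * p)$grad
      s <- (g2 - (-r)) / sigma_k
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    ev_new <- fn(theta + alpha * p)
    Delta <- 2 * delta * (E - ev_new$loss) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      theta <- theta + alpha * p
      E <- ev_new$loss
      trace <- c(trace, E)
      r_new <- -fn(theta)$grad
      lambda_bar <- 0
      success <- TRUE
      if (k %% n_par == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (!is.finite(E)) stop("non-finite loss in SCG training", call. = FALSE)
  }
  list(theta = theta, loss = E, trace = trace, epochs = k)
}

#' Neuro-fuzzy classifier (one Gaussian cluster per class, SCG training)
#'
#' The feature space is partitioned by one Gaussian fuzzy cluster per class,
#' initialized at the class means with per-feature class standard deviations
#' as widths. A pattern's membership of cluster `k` is the product of
#' per-feature Gaussians; class scores are memberships normalized across
#' clusters (a softmax over log-memberships). Centers and log-widths are
#' trained jointly by scaled conjugate gradient on the cross-entropy loss for
#' at most `epochs` iterations; only improving steps are accepted, so the
#' training loss is non-increasing.
#'
#' @param X_train,X_test numeric matrices in the normalized feature space.
#' @param y_train labels (2 classes).
#' @param epochs maximum SCG iterations (0 = keep the initialization).
#' @return character vector of predicted labels; the accepted-step loss
#'   trace is attached as `attr(, "loss_trace")`.
#' @export
nf_fit_predict <- function(X_train, y_train, X_test, epochs = 100) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  y <- .as_label_factor(y_train)
  lev <- levels(y)
  K <- length(lev)
  d <- ncol(X_train)
  Y <- outer(y, lev, `==`) * 1

  C0 <- t(vapply(lev, function(cl) colMeans(X_train[y == cl, , drop = FALSE]),
                 numeric(d)))
  S0 <- t(vapply(lev, function(cl) {
    Xc <- X_train[y == cl, , drop = FALSE]
    s <- if (nrow(Xc) >= 2) apply(Xc, 2, stats::sd) else rep(0.1, d)
    pmax(s, 0.02)
  }, numeric(d)))
  C0 <- matrix(C0, K, d)
  S0 <- matrix(S0, K, d)
  theta <- c(C0, log(S0))

  trace <- NULL
  if (epochs > 0) {
    fit <- .scg_minimize(theta, function(th) .nf_loss_grad(th, X_train, Y, K, d),
                         max_epochs = epochs)
    theta <- fit$theta
    trace <- fit$trace
  }

  C <- matrix(theta[seq_len(K * d)], K, d)
  S2 <- exp(2 * matrix(theta[K * d + seq_len(K * d)], K, d))
  logm <- vapply(seq_len(K), function(k) {
    -rowSums(sweep(X_test, 2, C[k, ])^2 /
               matrix(2 * S2[k, ], nrow(X_test), d, byrow = TRUE))
  }, numeric(nrow(X_test)))
  logm <- matrix(logm, nrow = nrow(X_test))
  pred <- lev[max.col(logm, ties.method = "first")]
  attr(pred, "loss_trace") <- trace
  pred
}
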