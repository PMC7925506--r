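test_that("every classifier separates well-separated blobs", {
  blobs <- make_blobs(n_per = 30, d = 2, seed = 1)
  proto <- cv_protocol(test_size = 10, repeats = 2, seed = 3)
  for (nm in classifier_names()) {
    res <- evaluate_subset(classifier_spec(nm), blobs$X, blobs$y,
                           protocol = proto)
    expect_gte(res$mean_accuracy, 95)
  }
})

test_that("classifier specs validate hyperparameters", {
  expect_error(classifier_spec("KNN", k = 4), "k")
  expect_error(classifier_spec("PNN", spread = 0), "spread")
  expect_error(classifier_spec("nonesuch"))
  expect_error(fit_predict(classifier_spec("LDA"),
                           matrix(rnorm(10), 5), rep("a", 5),
                           matrix(rnorm(4), 2)),
               "2 classes")
})

test_that("PNN scores match a brute-force double loop", {
  set.seed(9)
  X <- matrix(runif(20), 10, 2)
  y <- rep(c("u", "v"), 5)
  Xt <- matrix(runif(8), 4, 2)
  spread <- 0.3
  # independent double-loop computation
  oracle <- apply(Xt, 1, function(xt) {
    sc <- sapply(c("u", "v"), function(cl) {
      idx <- which(y == cl)
      s <- 0
      for (i in idx) s <- s + exp(-sum((xt - X[i, ])^2) / (2 * spread^2))
      s / length(idx)
    })
    names(sc)[which.max(sc)]
  })
  expect_equal(pnn_predict(X, y, Xt, spread = spread), unname(oracle))
})

test_that("PNN memorizes its training set as spread shrinks", {
  set.seed(10)
  X <- matrix(runif(30), 15, 2)
  y <- rep(c("a", "b", "a"), 5)
  expect_equal(pnn_predict(X, y, X, spread = 1e-3), y)
})

test_that("PNN breaks exact ties toward the first class level", {
  X <- rbind(c(0, 0), c(1, 0))
  y <- c("first", "second")
  mid <- rbind(c(0.5, 0))
  expect_equal(pnn_predict(X, y, mid, spread = 0.2), "first")
  # level order, not data order, decides
  expect_equal(pnn_predict(X, factor(y, levels = c("second", "first")),
                           mid, spread = 0.2), "second")
})

test_that("KNN matches a hand-enumerated 5-nearest-neighbour vote", {
  # 1-D points: neighbours of 0.45 are 0.4,0.5,0.3,0.6,0.2 -> 3 a's vs 2 b's
  X <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.9), ncol = 1)
  y <- c("a", "a", "a", "a", "b", "b", "b")
  p <- fit_predict(classifier_spec("KNN", k = 5), X, y, matrix(0.45))
  expect_equal(as.character(p), "a")
  # neighbours of 0.75: 0.6(b),0.9(b),0.5(b),0.4(a),0.3(a) -> b wins 3-2
  p2 <- fit_predict(classifier_spec("KNN", k = 5), X, y, matrix(0.75))
  expect_equal(as.character(p2), "b")
  # k=1 nearest
  p3 <- fit_predict(classifier_spec("KNN", k = 1), X, y, matrix(0.88))
  expect_equal(as.character(p3), "b")
})

test_that("KNN includes all neighbours tied at the K-th distance", {
  # test point at 0: distances 1,1,1,1 with k=3 -> all four vote, 3 b's win
  X <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c("a", "b", "b", "b")
  p <- fit_predict(classifier_spec("KNN", k = 3), X, y, matrix(0))
  expect_equal(as.character(p), "b")
})

test_that("KNN agrees with class::knn away from ties", {
  skip_if_not_installed("class")
  set.seed(11)
  X <- matrix(runif(60), 30, 2)
  y <- rep(c("a", "b"), 15)
  Xt <- matrix(runif(20), 10, 2)
  ours <- fit_predict(classifier_spec("KNN", k = 5), X, y, Xt)
  ref <- class::knn(X, Xt, factor(y), k = 5)
  expect_equal(as.character(ours), as.character(ref))
})

test_that("kernel naive Bayes matches a brute-force density computation", {
  set.seed(12)
  X <- matrix(runif(24), 12, 2)
  y <- rep(c("a", "b"), 6)
  Xt <- matrix(runif(6), 3, 2)
  oracle <- apply(Xt, 1, function(xt) {
    ll <- sapply(c("a", "b"), function(cl) {
      Xc <- X[y == cl, , drop = FALSE]
      total <- log(nrow(Xc) / nrow(X))
      for (j in 1:2) {
        h <- max(stats::bw.nrd0(Xc[, j]), 1e-6)
        dens <- mean(dnorm(xt[j], Xc[, j], h))
        total <- total + log(dens)
      }
      total
    })
    names(ll)[which.max(ll)]
  })
  ours <- fit_predict(classifier_spec("NB"), X, y, Xt)
  expect_equal(as.character(ours), unname(oracle))
})

test_that("ridge discriminants agree with MASS on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(13)
  blobs <- make_blobs(n_per = 25, d = 3, sd = 0.12, seed = 13)
  Xt <- matrix(runif(30), 10, 3)
  l_ours <- fit_predict(classifier_spec("LDA"), blobs$X, blobs$y, Xt)
  l_ref <- predict(MASS::lda(blobs$X, blobs$y), Xt)$class
  expect_equal(as.character(l_ours), as.character(l_ref))
  q_ours <- fit_predict(classifier_spec("QDA"), blobs$X, blobs$y, Xt)
  q_ref <- predict(MASS::qda(blobs$X, blobs$y), Xt)$class
  expect_equal(as.character(q_ours), as.character(q_ref))
})

test_that("discriminants survive a feature that is constant in training", {
  set.seed(14)
  X <- cbind(runif(20), 1)  # second feature degenerate
  y <- rep(c("a", "b"), each = 10)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  Xt <- cbind(c(0.5, 2.5), 1)
  expect_equal(as.character(fit_predict(classifier_spec("LDA"), X, y, Xt)),
               c("a", "b"))
  expect_equal(as.character(fit_predict(classifier_spec("QDA"), X, y, Xt)),
               c("a", "b"))
})

test_that("accuracy is invariant to a consistent feature permutation", {
  blobs <- make_blobs(n_per = 20, d = 4, sd = 0.2, seed = 15)
  proto <- cv_protocol(test_size = 8, repeats = 2, seed = 5)
  perm <- c(3, 1, 4, 2)
  for (nm in c("LDA", "KNN", "PNN")) {
    mask <- c(TRUE, TRUE, FALSE, TRUE)
    r1 <- evaluate_subset(classifier_spec(nm), blobs$X, blobs$y, mask, proto)
    r2 <- evaluate_subset(classifier_spec(nm), blobs$X[, perm], blobs$y,
                          mask[perm], proto)
    expect_equal(r1$mean_accuracy, r2$mean_accuracy)
  }
})
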