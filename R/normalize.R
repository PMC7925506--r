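#' Min-max feature normalization
#'
#' Features are heterogeneous (seconds, cycles/min, dB) so each column is
#' rescaled independently by the affine map `(x - b_j) / (a_j - b_j)` with
#' `a_j` the column maximum and `b_j` the column minimum over the patterns;
#' every normalized column then attains 0 and 1 exactly. The fitted `(a, b)`
#' pairs are stored so the same map can be applied to unseen data or
#' inverted.
#'
#' A constant column (`a_j == b_j`) is mapped to 0 with a warning instead of
#' failing the whole matrix.
#'
#' @param X numeric matrix or data frame of feature columns (M patterns by
#'   N features), M >= 2.
#' @return object of class `feature_norm`: list with `X` (normalized
#'   matrix), `a` (column maxima) and `b` (column minima).
#' @export
#' @examples
#' nf <- normalize_features(cbind(f1 = c(2, 4, 6), f2 = c(0, 1, 3)))
#' nf$X
normalize_features <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 patterns to normalize", call. = FALSE)
  a <- apply(X, 2, max)
  b <- apply(X, 2, min)
  structure(list(X = apply_normalization(list(a = a, b = b), X), a = a, b = b),
            class = "feature_norm")
}

#' @rdname normalize_features
#' @param norm a `feature_norm` (or any list with `a` and `b`).
#' @param newX matrix to transform with the stored per-column parameters.
#' @export
apply_normalization <- function(norm, newX) {
  newX <- as.matrix(newX)
  span <- norm$a - norm$b
  const <- span == 0
  if (any(const)) {
    warning("constant feature column(s) ",
            paste(which(const), collapse = ", "),
            " mapped to 0 during normalization", call. = FALSE)
    span[const] <- 1
  }
  out <- sweep(sweep(newX, 2, norm$b, "-"), 2, span, "/")
  out[, const] <- 0
  out
}

#' @rdname normalize_features
#' @param Xn normalized matrix to map back to raw feature units.
#' @export
invert_normalization <- function(norm, Xn) {
  Xn <- as.matrix(Xn)
  span <- norm$a - norm$b
  sweep(sweep(Xn, 2, span, "*"), 2, norm$b, "+")
}
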