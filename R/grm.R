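#' Compute the genomic relationship matrix
#'
#' Builds the realized additive relationship matrix from allele dosages by
#' the centered cross-product (VanRaden method 1),
#' \deqn{G = W W' / \sum_j 2 p_j (1 - p_j),}
#' where `W` is the column-centered dosage matrix and `p_j` the alternate
#' allele frequency estimated from the data. For panels of inbred lines the
#' raw diagonal approaches 2; with `normalize = TRUE` (default) the matrix
#' is rescaled to unit mean diagonal so that genetic variance components
#' estimated against it live on the phenotypic variance scale and per-trait
#' heritabilities are directly interpretable.
#'
#' If the smallest eigenvalue is below zero, a diagonal jitter of
#' `1e-6 * mean(diag(G))` is added once so the result is usable as a
#' covariance matrix.
#'
#' @param dosage a `dosage_matrix` from [code_and_impute()], or a plain
#'   samples x markers numeric matrix without missing values.
#' @param method relationship construction; only `"vanraden"` is currently
#'   implemented.
#' @param normalize rescale to unit mean diagonal.
#' @return an n x n symmetric numeric matrix with sample dimnames, carrying
#'   attributes `jitter` (the diagonal jitter applied, 0 if none) and
#'   `denominator` (the `sum 2pq` scaling).
#' @examples
#' W <- matrix(rbinom(40, 2, 0.4), nrow = 4)
#' G <- compute_grm(W)
#' @export
compute_grm <- function(dosage, method = c("vanraden"), normalize = TRUE) {
  method <- match.arg(method)
  W <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else as.matrix(dosage)
  if (anyNA(W)) stop("dosage matrix contains missing values; impute first")
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 samples to build a relationship matrix")
  if (ncol(W) < 1L) stop("need at least 1 marker")
  p <- colMeans(W) / 2
  den <- sum(2 * p * (1 - p))
  if (den <= 0) {
    stop("all markers are monomorphic; relationship denominator is zero")
  }
  Wc <- sweep(W, 2L, 2 * p, `-`)
  G <- tcrossprod(Wc) / den
  if (normalize) G <- G / mean(diag(G))
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  jitter <- 0
  if (ev_min < 0) {
    jitter <- 1e-6 * mean(diag(G))
    G <- G + diag(jitter, n)
  }
  if (!is.null(rownames(W))) dimnames(G) <- list(rownames(W), rownames(W))
  attr(G, "jitter") <- jitter
  attr(G, "denominator") <- den
  G
}
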