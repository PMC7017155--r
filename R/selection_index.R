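#' Covariance set for selection-index construction
#'
#' Bundles the covariance matrices entering a Smith optimum index: the
#' genetic covariance among the measured traits (`Gx`), among the selection
#' targets (`Gy`), between measured traits and targets (`Gxy`), and the
#' phenotypic covariance among the measured traits (`Px`). When targets and
#' measured traits coincide, `Gy` and `Gxy` default to `Gx`.
#'
#' @param Gx p x p genetic covariance of the measured traits.
#' @param Px p x p phenotypic covariance of the measured traits; must
#'   dominate `Gx` (their difference is a residual covariance).
#' @param Gy t x t genetic covariance of the targets (default `Gx`).
#' @param Gxy p x t genetic covariance between measured traits and targets
#'   (default `Gx`).
#' @return an object of class `cov_set`.
#' @export
cov_set <- function(Gx, Px, Gy = Gx, Gxy = Gx) {
  Gx <- as.matrix(Gx); Px <- as.matrix(Px)
  Gy <- as.matrix(Gy); Gxy <- as.matrix(Gxy)
  sym_psd <- function(S, what, tol = 1e-8) {
    if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
      stop(what, " is not symmetric")
    }
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(abs(ev), 1)) {
      stop(what, " is not positive semi-definite")
    }
  }
  sym_psd(Gx, "Gx"); sym_psd(Gy, "Gy"); sym_psd(Px, "Px")
  if (nrow(Gxy) != nrow(Gx) || ncol(Gxy) != nrow(Gy)) {
    stop("Gxy must be (measured x target): ",
         nrow(Gx), " x ", nrow(Gy))
  }
  sym_psd(Px - Gx, "Px - Gx (residual covariance)")
  out <- list(Gx = Gx, Gy = Gy, Gxy = Gxy, Px = Px)
  class(out) <- "cov_set"
  out
}

#' @export
print.cov_set <- function(x, ...) {
  cat("covariance set:", nrow(x$Gx), "measured trait(s),",
      nrow(x$Gy), "target trait(s)\n")
  cat("per-trait h2:", round(diag(x$Gx) / diag(x$Px), 3), "\n")
  invisible(x)
}

#' Economic weight vectors
#'
#' Builds the economic-weight vector `alpha` of the net genetic merit
#' `H = alpha' g`. `"unit"` expresses equal preference on the raw trait
#' scales; `"inverse_phenotypic_sd"` (the default used throughout the
#' package) weights each trait by `1 / sigma_P`, i.e. equal preference per
#' phenotypic standard deviation, which coincides with unit weights on
#' standardized traits.
#'
#' @param mode weight rule.
#' @param t number of traits (for `"unit"`).
#' @param Px phenotypic covariance (for `"inverse_phenotypic_sd"`).
#' @param values custom weights (for `"custom"`).
#' @return numeric weight vector.
#' @export
economic_weights <- function(mode = c("inverse_phenotypic_sd", "unit",
                                      "custom"),
                             t = NULL, Px = NULL, values = NULL) {
  mode <- match.arg(mode)
  w <- switch(mode,
    unit = {
      if (is.null(t)) stop("'t' required for unit weights")
      rep(1, t)
    },
    inverse_phenotypic_sd = {
      if (is.null(Px)) stop("'Px' required for inverse_phenotypic_sd")
      1 / sqrt(diag(as.matrix(Px)))
    },
    custom = {
      if (is.null(values)) stop("'values' required for custom weights")
      as.numeric(values)
    }
  )
  if (any(!is.finite(w)) || all(w == 0)) {
    stop("economic weights must be finite and not all zero")
  }
  w
}

#' Smith optimum index coefficients
#'
#' Solves `Px beta = Gxy alpha` (a linear solve, no explicit inverse) for
#' the coefficients of the index `I = beta' x` that is maximally correlated
#' with the net genetic merit `H = alpha' g`.
#'
#' @param cov a [cov_set()].
#' @param alpha economic weights (length = number of target traits).
#' @return numeric coefficient vector beta.
#' @export
smith_beta <- function(cov, alpha) {
  stopifnot(inherits(cov, "cov_set"))
  alpha <- as.numeric(alpha)
  if (length(alpha) != nrow(cov$Gy)) {
    stop("alpha has length ", length(alpha), ", expected ", nrow(cov$Gy))
  }
  b <- tryCatch(solve(cov$Px, cov$Gxy %*% alpha),
                error = function(e) stop("Px is singular: ",
                                         conditionMessage(e), call. = FALSE))
  drop(b)
}

#' Heritability of a selection index
#'
#' `h2_I = beta' Gx beta / beta' Px beta`: the fraction of index variance
#' that is genetic. Values outside `[0, 1]` by more than `1e-10` raise an
#' error; smaller violations are clipped.
#'
#' @param beta index coefficients (nonzero).
#' @param cov a [cov_set()].
#' @return scalar in `[0, 1]`.
#' @export
index_heritability <- function(beta, cov) {
  stopifnot(inherits(cov, "cov_set"))
  beta <- as.numeric(beta)
  if (all(beta == 0)) stop("beta must be nonzero")
  den <- drop(crossprod(beta, cov$Px %*% beta))
  if (den <= 0) stop("beta' Px beta must be positive")
  h2 <- drop(crossprod(beta, cov$Gx %*% beta)) / den
  if (h2 < -1e-10 || h2 > 1 + 1e-10) {
    stop("index heritability ", h2, " outside [0, 1]; covariances invalid")
  }
  min(max(h2, 0), 1)
}

#' Genetic correlation between index and net genetic merit
#'
#' `gencor = beta' Gxy alpha / sqrt((alpha' Gy alpha)(beta' Gx beta))`:
#' the correlation between the genetic value of the index and the target
#' aggregate genotype.
#'
#' @param beta index coefficients.
#' @param cov a [cov_set()].
#' @param alpha economic weights.
#' @return scalar in `[-1, 1]`.
#' @export
genetic_correlation <- function(beta, cov, alpha) {
  stopifnot(inherits(cov, "cov_set"))
  beta <- as.numeric(beta); alpha <- as.numeric(alpha)
  vH <- drop(crossprod(alpha, cov$Gy %*% alpha))
  vI <- drop(crossprod(beta, cov$Gx %*% beta))
  if (vH <= 0) stop("target has zero genetic variance (alpha' Gy alpha <= 0)")
  if (vI <= 0) stop("index has zero genetic variance (beta' Gx beta <= 0)")
  gc <- drop(crossprod(beta, cov$Gxy %*% alpha)) / sqrt(vH * vI)
  if (abs(gc) > 1 + 1e-10) {
    stop("genetic correlation ", gc, " outside [-1, 1]; covariances invalid")
  }
  min(max(gc, -1), 1)
}

#' Accuracy of index selection
#'
#' `acc = cor(I, g_H) = gencor * sqrt(h2_I)`.
#'
#' @param gencor genetic correlation between index and target.
#' @param h2_index index heritability.
#' @return scalar accuracy.
#' @export
index_accuracy <- function(gencor, h2_index) {
  stopifnot(abs(gencor) <= 1 + 1e-10, h2_index >= 0, h2_index <= 1 + 1e-10)
  gencor * sqrt(h2_index)
}

#' Construct a Smith optimum selection index
#'
#' Computes the optimum coefficients and the three derived statistics in
#' one step: index heritability, genetic correlation with the net merit,
#' and accuracy of selection (`acc = gencor * sqrt(h2)` by construction).
#'
#' @param cov a [cov_set()], e.g. from [extract_covariances()].
#' @param alpha economic weights; default equal preference per phenotypic
#'   standard deviation (see [economic_weights()]). A single-trait target
#'   within a multi-trait covariance set is expressed by a unit vector.
#' @return an object of class `smith_index` with fields `beta`,
#'   `h2_index`, `gencor`, `accuracy`, `alpha`.
#' @examples
#' cs <- cov_set(Gx = diag(c(0.6, 0.7)), Px = diag(2))
#' smith_index(cs, alpha = c(1, 1))
#' @export
smith_index <- function(cov, alpha = NULL) {
  stopifnot(inherits(cov, "cov_set"))
  if (is.null(alpha)) {
    alpha <- economic_weights("inverse_phenotypic_sd", Px = cov$Px)
  }
  beta <- smith_beta(cov, alpha)
  h2 <- index_heritability(beta, cov)
  gc <- genetic_correlation(beta, cov, alpha)
  out <- list(beta = beta, h2_index = h2, gencor = gc,
              accuracy = index_accuracy(gc, h2), alpha = as.numeric(alpha))
  class(out) <- "smith_index"
  out
}

#' @export
print.smith_index <- function(x, ...) {
  cat("Smith optimum index\n")
  cat("  beta:    ", paste(signif(x$beta, 4), collapse = "  "), "\n")
  cat("  h2_index:", round(x$h2_index, 4),
      " gencor:", round(x$gencor, 4),
      " accuracy:", round(x$accuracy, 4), "\n")
  invisible(x)
}

#' Rank selection candidates by predicted net genetic merit
#'
#' `H_i = alpha' gebv_i` per candidate, sorted descending; ties broken by
#' genotype identifier (lexicographic).
#'
#' @param gebv n x t matrix of genomic breeding values with row names.
#' @param alpha economic weights.
#' @return data frame (`genotype`, `merit`, `rank`) sorted by decreasing
#'   merit.
#' @export
rank_candidates <- function(gebv, alpha) {
  gebv <- as.matrix(gebv)
  if (anyNA(gebv)) stop("gebv must be complete")
  ids <- rownames(gebv)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(gebv)))
  H <- drop(gebv %*% as.numeric(alpha))
  ord <- order(-H, ids)
  out <- data.frame(genotype = ids[ord], merit = H[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify the magnitude of a correlation coefficient
#'
#' Standard agronomic interpretation scale on `|r|`: 0-0.1 zero, 0.1-0.5
#' low, 0.5-0.8 medium, 0.8-1 high, exactly 1 perfect. Boundaries belong to
#' the upper class (0.5 is medium).
#'
#' @param r correlation(s), `|r| <= 1`.
#' @return character vector of labels.
#' @examples
#' classify_correlation(c(-0.35, 0.60, 1))
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must not exceed 1")
  a <- abs(r)
  out <- ifelse(a == 1, "perfect",
         ifelse(a >= 0.8, "high",
         ifelse(a >= 0.5, "medium",
         ifelse(a >= 0.1, "low", "zero"))))
  out[is.na(r)] <- NA_character_
  out
}
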