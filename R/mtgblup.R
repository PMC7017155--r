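#' Fit a multi-trait Bayesian genomic model by Gibbs sampling
#'
#' Fits the model
#' \deqn{y_{ij} = \mu_j + g_{ij} + e_{ij}}
#' with genetic values `vec(g) ~ N(0, Sigma_g (x) K)` for a genomic
#' relationship matrix `K`, and independent row-wise residuals
#' `e_i ~ N(0, Sigma_e)`. Both trait covariance matrices carry
#' inverse-Wishart priors and are sampled from their full conditionals; the
#' genetic values are sampled on the eigenbasis of `K` (computed once,
#' eigenvalues below `1e-8` of the largest dropped), which together with a
#' simultaneous diagonalization of the current `Sigma_g` / `Sigma_e` makes
#' each Gibbs cycle a handful of dense matrix products.
#'
#' Missing phenotype entries are handled by data augmentation: each cycle
#' they are redrawn from their conditional normal given the observed traits
#' of the same individual, so completely unphenotyped individuals still
#' receive genomic breeding values through `K`. The update order per cycle
#' is genetic values, intercepts, missing entries, `Sigma_g`, `Sigma_e`.
#'
#' @param Y n x t numeric phenotype matrix; `NA` marks missing entries.
#'   Row names (if present) must match `K`'s.
#' @param K n x n positive semi-definite relationship matrix, e.g. from
#'   [compute_grm()].
#' @param n_iter total number of Gibbs cycles; production analyses in the
#'   35,000 / 5,000 range, see Details.
#' @param burn_in cycles discarded before accumulating the posterior.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed; identical seeds give bit-identical fits.
#' @param prior_df inverse-Wishart degrees of freedom for both priors;
#'   default `t + 2` (weakly informative, proper).
#' @param prior_scale_g,prior_scale_e prior scale matrices; default
#'   `0.5 * diag(sample variance of observed Y)` for both components.
#' @param fix_sigma_g,fix_sigma_e optionally fix a covariance component at
#'   a known matrix (its sampling step is skipped); used for noiseless
#'   limits and closed-form comparisons.
#' @param keep_chain store the thinned chains of `Sigma_g`, `Sigma_e`,
#'   `mu` and per-trait heritability.
#' @param verbose print progress every 1000 cycles.
#'
#' @details
#' The default chain for production runs mirrors common practice for this
#' model class (35,000 cycles, 5,000 burn-in); the test suite uses much
#' shorter chains, which is adequate for the structures tested but only the
#' long chain is recommended for real analyses.
#'
#' @return an object of class `mtgblup` with components `mu` (trait
#'   intercepts), `gebv` (n x t posterior-mean genetic values, trait
#'   scale, all individuals including unphenotyped ones), `gebv_sd`,
#'   `Sigma_g`, `Sigma_e` (posterior means), `Sigma_g_sd`, `Sigma_e_sd`,
#'   `h2` (per-trait heritability posterior mean), `h2_sd`, `ess`
#'   (effective sample sizes of the h2 chains), `n_kept`, `rank` (retained
#'   eigenvalues of `K`), `missing` (logical mask), and the call settings.
#' @seealso [extract_covariances()], [smith_index()], [run_holdout()]
#' @export
mtgblup <- function(Y, K, n_iter = 35000, burn_in = 5000, thin = 1,
                    seed = 1, prior_df = NULL,
                    prior_scale_g = NULL, prior_scale_e = NULL,
                    fix_sigma_g = NULL, fix_sigma_e = NULL,
                    keep_chain = FALSE, verbose = FALSE) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("Y must be numeric")
  n <- nrow(Y); t <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(t))
  traits <- colnames(Y)
  if (nrow(K) != n || ncol(K) != n) {
    stop("K must be ", n, " x ", n, " to match Y")
  }
  if (!is.null(rownames(Y)) && !is.null(rownames(K)) &&
      !identical(rownames(Y), rownames(K))) {
    stop("row names of Y and K disagree; align samples first")
  }
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (burn_in < 0 || thin < 1) stop("invalid chain settings")
  n_obs <- colSums(!is.na(Y))
  if (any(n_obs < 2L)) {
    stop("trait(s) with fewer than 2 observations: ",
         paste(traits[n_obs < 2L], collapse = ", "))
  }

  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-8 * max(eK$values)) {
    stop("K is not positive semi-definite; add a diagonal jitter ",
         "(see compute_grm)")
  }
  keep <- eK$values > 1e-8 * max(eK$values)
  U <- eK$vectors[, keep, drop = FALSE]
  d <- eK$values[keep]
  r <- length(d)

  if (is.null(prior_df)) prior_df <- t + 2
  if (prior_df <= t - 1) stop("prior_df must exceed t - 1")
  vY <- apply(Y, 2L, stats::var, na.rm = TRUE)
  if (is.null(prior_scale_g)) prior_scale_g <- diag(0.5 * vY, t)
  if (is.null(prior_scale_e)) prior_scale_e <- diag(0.5 * vY, t)
  check_spd <- function(S, what) {
    if (!isTRUE(all.equal(S, t(S))) ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop(what, " must be symmetric positive definite")
    }
  }
  check_spd(prior_scale_g, "prior_scale_g")
  check_spd(prior_scale_e, "prior_scale_e")

  miss <- is.na(Y)
  Yc <- Y
  for (j in seq_len(t)) Yc[miss[, j], j] <- mean(Y[, j], na.rm = TRUE)
  ## group rows by missingness pattern once
  pat <- apply(miss, 1L, function(z) paste(as.integer(z), collapse = ""))
  pat_groups <- split(seq_len(n), pat)
  pat_groups <- pat_groups[vapply(pat_groups,
                                  function(ix) any(miss[ix[1L], ]),
                                  logical(1))]

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  Sg <- if (is.null(fix_sigma_g)) prior_scale_g else as.matrix(fix_sigma_g)
  Se <- if (is.null(fix_sigma_e)) prior_scale_e else as.matrix(fix_sigma_e)
  mu <- colMeans(Yc)
  G <- matrix(0, n, t)
  Gstar <- matrix(0, r, t)

  acc <- list(G = matrix(0, n, t), G2 = matrix(0, n, t),
              Sg = matrix(0, t, t), Sg2 = matrix(0, t, t),
              Se = matrix(0, t, t), Se2 = matrix(0, t, t),
              mu = numeric(t))
  n_kept <- 0L
  kept_idx <- seq(burn_in + 1L, n_iter, by = thin)
  h2_chain <- matrix(NA_real_, length(kept_idx), t)
  chain <- if (keep_chain) {
    list(Sigma_g = array(NA_real_, c(length(kept_idx), t, t)),
         Sigma_e = array(NA_real_, c(length(kept_idx), t, t)),
         mu = matrix(NA_real_, length(kept_idx), t))
  } else NULL

  for (it in seq_len(n_iter)) {
    ## --- genetic values on the eigenbasis -------------------------------
    L <- t(chol(Se))                       # Se = L L'
    B <- forwardsolve(L, t(forwardsolve(L, Sg)))
    eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
    lam <- pmax(eB$values, 1e-12)
    Tm <- L %*% eB$vectors                 # Se = T T', Sg = T diag(lam) T'
    Tinv <- t(eB$vectors) %*% forwardsolve(L, diag(t))
    Ystar <- crossprod(U, sweep(Yc, 2L, mu, `-`))
    Z <- Ystar %*% t(Tinv)
    V <- outer(d, lam)                     # d_i * lam_k
    V <- V / (1 + V)
    Gz <- V * Z + sqrt(V) * matrix(stats::rnorm(r * t), r, t)
    Gstar <- Gz %*% t(Tm)
    G <- U %*% Gstar

    ## --- intercepts (flat prior) ----------------------------------------
    mu <- colMeans(Yc - G) + drop(L %*% stats::rnorm(t)) / sqrt(n)

    ## --- missing entries by data augmentation ---------------------------
    for (ix in pat_groups) {
      M <- miss[ix[1L], ]
      if (all(M)) {
        Yc[ix, ] <- sweep(G[ix, , drop = FALSE], 2L, mu, `+`) +
          matrix(stats::rnorm(length(ix) * t), ncol = t) %*% t(L)
      } else {
        O <- which(!M); Mi <- which(M)
        A <- Se[Mi, O, drop = FALSE] %*% solve(Se[O, O, drop = FALSE])
        Sc <- Se[Mi, Mi, drop = FALSE] - A %*% Se[O, Mi, drop = FALSE]
        Lc <- t(chol((Sc + t(Sc)) / 2))
        resO <- Yc[ix, O, drop = FALSE] -
          sweep(G[ix, O, drop = FALSE], 2L, mu[O], `+`)
        mn <- sweep(G[ix, Mi, drop = FALSE], 2L, mu[Mi], `+`) +
          resO %*% t(A)
        Yc[ix, Mi] <- mn +
          matrix(stats::rnorm(length(ix) * length(Mi)),
                 ncol = length(Mi)) %*% t(Lc)
      }
    }

    ## --- covariance components from inverse-Wishart full conditionals ---
    if (is.null(fix_sigma_g)) {
      S_g <- prior_scale_g + crossprod(Gstar, Gstar / d)
      Sg <- solve(stats::rWishart(1L, prior_df + r, solve(S_g))[, , 1L])
      Sg <- (Sg + t(Sg)) / 2
    }
    if (is.null(fix_sigma_e)) {
      E <- Yc - sweep(G, 2L, mu, `+`)
      S_e <- prior_scale_e + crossprod(E)
      Se <- solve(stats::rWishart(1L, prior_df + n, solve(S_e))[, , 1L])
      Se <- (Se + t(Se)) / 2
    }

    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      n_kept <- n_kept + 1L
      acc$G <- acc$G + G;   acc$G2 <- acc$G2 + G^2
      acc$Sg <- acc$Sg + Sg; acc$Sg2 <- acc$Sg2 + Sg^2
      acc$Se <- acc$Se + Se; acc$Se2 <- acc$Se2 + Se^2
      acc$mu <- acc$mu + mu
      h2_chain[n_kept, ] <- diag(Sg) / (diag(Sg) + diag(Se))
      if (keep_chain) {
        chain$Sigma_g[n_kept, , ] <- Sg
        chain$Sigma_e[n_kept, , ] <- Se
        chain$mu[n_kept, ] <- mu
      }
    }
    if (verbose && it %% 1000L == 0L) {
      message("iter ", it, "/", n_iter)
    }
  }

  post_sd <- function(s, s2) {
    v <- s2 / n_kept - (s / n_kept)^2
    sqrt(pmax(v, 0) * n_kept / max(1, n_kept - 1))
  }
  h2_chain <- h2_chain[seq_len(n_kept), , drop = FALSE]
  dn <- list(traits, traits)
  out <- list(
    mu = stats::setNames(acc$mu / n_kept, traits),
    gebv = structure(acc$G / n_kept,
                     dimnames = list(rownames(Y), traits)),
    gebv_sd = structure(post_sd(acc$G, acc$G2),
                        dimnames = list(rownames(Y), traits)),
    Sigma_g = structure(acc$Sg / n_kept, dimnames = dn),
    Sigma_e = structure(acc$Se / n_kept, dimnames = dn),
    Sigma_g_sd = structure(post_sd(acc$Sg, acc$Sg2), dimnames = dn),
    Sigma_e_sd = structure(post_sd(acc$Se, acc$Se2), dimnames = dn),
    h2 = stats::setNames(colMeans(h2_chain), traits),
    h2_sd = stats::setNames(apply(h2_chain, 2L, stats::sd), traits),
    ess = stats::setNames(apply(h2_chain, 2L, ess), traits),
    h2_chain = h2_chain,
    chain = chain,
    missing = miss,
    traits = traits,
    n = n, rank = r, n_kept = n_kept,
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = seed, prior_df = prior_df,
                    fixed_g = !is.null(fix_sigma_g),
                    fixed_e = !is.null(fix_sigma_e)),
    Y = Y
  )
  class(out) <- "mtgblup"
  out
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## effective sample size from the initial positive sequence of the ACF
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  a <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  neg <- which(a < 0)
  if (length(neg)) a <- a[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(a))
}

#' @export
print.mtgblup <- function(x, ...) {
  cat("Multi-trait genomic model (Gibbs sampler)\n")
  cat("  ", x$n, "individuals,", length(x$traits), "traits (",
      paste(x$traits, collapse = ", "), ")\n")
  cat("  chain:", x$settings$n_iter, "cycles,", x$settings$burn_in,
      "burn-in, thin", x$settings$thin, "->", x$n_kept, "samples\n")
  cat("  posterior mean heritability:\n")
  print(round(x$h2, 3))
  invisible(x)
}

#' @export
summary.mtgblup <- function(object, ...) {
  out <- list(
    traits = object$traits,
    h2 = cbind(mean = object$h2, sd = object$h2_sd, ess = object$ess),
    Sigma_g = object$Sigma_g,
    Sigma_e = object$Sigma_e,
    gencor = stats::cov2cor(object$Sigma_g),
    mu = object$mu,
    n = object$n,
    n_missing = sum(object$missing),
    settings = object$settings
  )
  class(out) <- "summary.mtgblup"
  out
}

#' @export
print.summary.mtgblup <- function(x, ...) {
  cat("Multi-trait genomic model:", x$n, "individuals,",
      length(x$traits), "traits;", x$n_missing, "masked phenotype cells\n")
  cat("\nPer-trait heritability (posterior mean, sd, ESS):\n")
  print(round(x$h2, 3))
  cat("\nGenetic correlations (posterior mean of Sigma_g, as correlation):\n")
  print(round(x$gencor, 3))
  cat("\nResidual covariance:\n")
  print(round(x$Sigma_e, 3))
  invisible(x)
}

#' @export
coef.mtgblup <- function(object, ...) object$mu

#' Predictions from a fitted multi-trait genomic model
#'
#' @param object an `mtgblup` fit.
#' @param type `"gebv"` for breeding-value deviations, `"response"` for
#'   `mu + gebv`, or `"merit"` for the net genetic merit `gebv %*% alpha`.
#' @param alpha economic weights for `type = "merit"`; defaults to equal
#'   weights per unit of phenotypic standard deviation.
#' @param ... unused.
#' @return matrix of predictions, or a named vector for `type = "merit"`.
#' @export
predict.mtgblup <- function(object, type = c("gebv", "response", "merit"),
                            alpha = NULL, ...) {
  type <- match.arg(type)
  g <- object$gebv
  if (type == "gebv") return(g)
  if (type == "response") return(sweep(g, 2L, object$mu, `+`))
  if (is.null(alpha)) {
    alpha <- 1 / sqrt(diag(object$Sigma_g + object$Sigma_e))
  }
  drop(g %*% alpha)
}

#' @export
fitted.mtgblup <- function(object, ...) {
  sweep(object$gebv, 2L, object$mu, `+`)
}

#' @export
residuals.mtgblup <- function(object, ...) {
  r <- object$Y - fitted(object)
  r[object$missing] <- NA
  r
}

#' Posterior-predictive draws from a fitted multi-trait genomic model
#'
#' Draws phenotype replicates `mu + gebv + e` with residuals from the
#' posterior-mean residual covariance.
#'
#' @param object an `mtgblup` fit.
#' @param nsim number of replicate matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` phenotype matrices.
#' @export
simulate.mtgblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  L <- t(chol(object$Sigma_e))
  f <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    f + matrix(stats::rnorm(length(f)), nrow(f)) %*% t(L)
  })
}

#' Extract the covariance set of a fitted model
#'
#' Packages the posterior-mean genetic and phenotypic covariances in the
#' form the Smith index machinery consumes. When the measured traits and
#' the selection targets are the same set (the usual case), `Gx`, `Gy` and
#' `Gxy` all equal the genetic covariance and `Px = Sigma_g + Sigma_e`;
#' all four slots are kept separate so unequal measured/target sets remain
#' expressible via [cov_set()].
#'
#' @param fit an `mtgblup` object.
#' @return a [cov_set()] object.
#' @export
extract_covariances <- function(fit) {
  stopifnot(inherits(fit, "mtgblup"))
  cov_set(Gx = fit$Sigma_g, Px = fit$Sigma_g + fit$Sigma_e)
}
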