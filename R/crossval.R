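#' Monte-Carlo hold-out splits
#'
#' Draws `n_repeats` independent train/test partitions of the panel.
#' Per-repeat seeds are derived deterministically from `master_seed`, so
#' the same master seed always yields the same list. When a `strata`
#' factor is supplied (e.g. subpopulation labels) the test fraction is
#' sampled within each stratum so both remain represented.
#'
#' @param ids genotype identifiers (panel).
#' @param frac_test test-set fraction, in (0, 1); default the classical
#'   70/30 split.
#' @param n_repeats number of repeats.
#' @param master_seed integer master seed.
#' @param strata optional factor aligned with `ids`.
#' @return list of splits, each a list
#'   `(repeat_index, seed, train_ids, test_ids)`.
#' @export
make_splits <- function(ids, frac_test = 0.3, n_repeats = 100,
                        master_seed = 1, strata = NULL) {
  ids <- as.character(ids)
  if (length(ids) < 10L) stop("panel too small (< 10 genotypes)")
  if (frac_test <= 0 || frac_test >= 1) stop("frac_test must be in (0, 1)")
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(ids))
    strata <- as.factor(strata)
  }
  n_test_of <- function(n) max(1L, min(n - 1L, round(frac_test * n)))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n_repeats)
  lapply(seq_len(n_repeats), function(r) {
    set.seed(seeds[r])
    test <- if (is.null(strata)) {
      sample(ids, n_test_of(length(ids)))
    } else {
      unlist(lapply(split(ids, strata), function(sub) {
        sample(sub, n_test_of(length(sub)))
      }), use.names = FALSE)
    }
    if (length(test) == 0L || length(test) == length(ids)) {
      stop("frac_test yields an empty train or test set")
    }
    list(repeat_index = r, seed = seeds[r],
         train_ids = setdiff(ids, test), test_ids = sort(test))
  })
}

## index metrics for the standard target set: one single-trait target per
## trait (unit target vector within the full index machinery) plus the
## multi-trait GSI with the configured economic weights
target_alphas <- function(traits, alpha_gsi) {
  t <- length(traits)
  out <- lapply(seq_len(t), function(j) {
    a <- numeric(t); a[j] <- 1; a
  })
  names(out) <- traits
  out$GSI <- alpha_gsi
  out
}

fit_target_metrics <- function(fit, weights_mode = "inverse_phenotypic_sd",
                               weights_values = NULL) {
  cs <- extract_covariances(fit)
  alpha_gsi <- economic_weights(weights_mode, t = length(fit$traits),
                                Px = cs$Px, values = weights_values)
  alphas <- target_alphas(fit$traits, alpha_gsi)
  res <- lapply(names(alphas), function(tg) {
    si <- smith_index(cs, alpha = alphas[[tg]])
    data.frame(target = tg, h2_index = si$h2_index, gencor = si$gencor,
               accuracy = si$accuracy, stringsAsFactors = FALSE)
  })
  list(metrics = do.call(rbind, res), alphas = alphas, cov = cs)
}

## empirical predictive correlation: Smith index evaluated on GEBVs vs the
## observed phenotypic index (alpha' y) in the test set
empirical_accuracy <- function(fit, cov, alphas, Y_obs, test_ids) {
  g <- fit$gebv[test_ids, , drop = FALSE]
  obs <- Y_obs[test_ids, , drop = FALSE]
  vapply(names(alphas), function(tg) {
    a <- alphas[[tg]]
    beta <- smith_beta(cov, a)
    pred <- drop(g %*% beta)
    o <- drop(obs %*% a)
    ok <- stats::complete.cases(pred, o)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(pred[ok], o[ok])
  }, numeric(1))
}

#' Repeated hold-out cross-validation of the genomic selection index
#'
#' For every split the test genotypes' phenotypes are masked (all traits at
#' once, mirroring prediction of fully unphenotyped candidates), the
#' multi-trait model is refit on the masked panel, and for each prediction
#' target (the three single-trait targets and the multi-trait GSI) the
#' Smith index statistics -- index heritability, genetic correlation with
#' the net merit, accuracy -- are computed from the training-fit
#' covariances. The empirical predictive correlation between the index
#' evaluated on test-set GEBVs and the observed phenotypic index is
#' recorded alongside as `pred_accuracy`.
#'
#' @param Y n x t phenotype matrix (genotype rownames matching `K`).
#' @param K relationship matrix.
#' @param splits list from [make_splits()].
#' @param n_iter,burn_in,thin Gibbs chain settings per repeat.
#' @param weights_mode,weights_values economic weights for the GSI target
#'   (see [economic_weights()]).
#' @param max_fail_frac abort when more than this fraction of repeats fail
#'   to fit.
#' @param verbose report progress.
#' @param ... further arguments (e.g. priors) passed to [mtgblup()].
#' @return an object of class `gs_cv`: `rows` (one row per repeat x
#'   target), `summary` (per-target mean and SD of each metric),
#'   `failed` repeat indices, and the settings echo.
#' @export
run_holdout <- function(Y, K, splits, n_iter = 2000, burn_in = 500,
                        thin = 1, weights_mode = "inverse_phenotypic_sd",
                        weights_values = NULL, max_fail_frac = 0.1,
                        verbose = FALSE, ...) {
  Y <- as.matrix(Y)
  stopifnot(!is.null(rownames(Y)), !is.null(rownames(K)))
  if (!all(rownames(Y) %in% rownames(K))) {
    stop("phenotyped genotypes missing from the relationship matrix")
  }
  K <- K[rownames(Y), rownames(Y)]
  rows <- NULL
  failed <- integer(0)
  for (sp in splits) {
    Ym <- Y
    Ym[rownames(Ym) %in% sp$test_ids, ] <- NA
    res <- tryCatch({
      fit <- mtgblup(Ym, K, n_iter = n_iter, burn_in = burn_in,
                     thin = thin, seed = sp$seed, ...)
      tm <- fit_target_metrics(fit, weights_mode, weights_values)
      emp <- empirical_accuracy(fit, tm$cov, tm$alphas, Y, sp$test_ids)
      cbind(data.frame(rep = sp$repeat_index), tm$metrics,
            pred_accuracy = emp[tm$metrics$target])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("repeat ", sp$repeat_index, " failed: ",
              conditionMessage(res))
      failed <- c(failed, sp$repeat_index)
    } else {
      rows <- rbind(rows, res)
    }
    if (verbose) message("repeat ", sp$repeat_index, " done")
  }
  if (length(failed) > max_fail_frac * length(splits)) {
    stop(length(failed), " of ", length(splits),
         " repeats failed to fit")
  }
  rownames(rows) <- NULL
  out <- list(rows = rows, summary = cv_summarize_rows(rows),
              failed = failed,
              settings = list(n_repeats = length(splits),
                              n_iter = n_iter, burn_in = burn_in,
                              thin = thin, weights_mode = weights_mode))
  class(out) <- "gs_cv"
  out
}

cv_summarize_rows <- function(rows, by = "target") {
  metrics <- intersect(c("h2_index", "gencor", "accuracy",
                         "pred_accuracy"), names(rows))
  groups <- unique(rows[, by, drop = FALSE])
  out <- NULL
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(rows))
    for (b in by) sel <- sel & rows[[b]] == groups[i, b]
    sub <- rows[sel, , drop = FALSE]
    rec <- groups[i, , drop = FALSE]
    for (mname in metrics) {
      rec[[paste0(mname, "_mean")]] <- mean(sub[[mname]], na.rm = TRUE)
      rec[[paste0(mname, "_sd")]] <- stats::sd(sub[[mname]], na.rm = TRUE)
    }
    out <- rbind(out, rec)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.gs_cv <- function(x, ...) {
  cat("Genomic selection cross-validation:",
      x$settings$n_repeats, "repeats",
      if (length(x$failed)) paste0("(", length(x$failed), " failed)"),
      "\n")
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, 3)
  print(s)
  invisible(x)
}

#' Summarize a cross-validation report
#'
#' Per-target mean and standard deviation of each index statistic, with
#' the correlation-magnitude interpretation label of the mean accuracy
#' (see [classify_correlation()]).
#'
#' @param object a `gs_cv` from [run_holdout()] or [run_scenario()].
#' @param ... unused.
#' @return a data frame, one row per target (and per scenario/test trial
#'   where present).
#' @export
summary.gs_cv <- function(object, ...) {
  by <- intersect(c("scenario", "test_trial", "target"),
                  names(object$rows))
  s <- cv_summarize_rows(object$rows, by = by)
  acc_col <- if ("pred_accuracy_mean" %in% names(s) &&
                 !all(is.na(s$pred_accuracy_mean))) {
    "pred_accuracy_mean"
  } else "accuracy_mean"
  s$accuracy_class <- classify_correlation(pmin(1, pmax(-1, s[[acc_col]])))
  s
}

#' Named train-to-test trial scenario validation
#'
#' Trains the multi-trait model on the across-environment combination of
#' the training trials only, then validates the trained index against each
#' test trial separately: test-trial phenotypes never enter the fit, and
#' each test trial contributes one row per target with the empirical
#' predictive correlation (`pred_accuracy`) between the index evaluated on
#' GEBVs and that trial's observed adjusted means. The training-fit Smith
#' statistics (`h2_index`, `gencor`, `accuracy`) are echoed on every row;
#' by construction they do not vary across test trials.
#'
#' @param pheno_long long adjusted-means table (`genotype`, `trial`,
#'   `trait`, `value`), e.g. `phenotype_table(..., combine = FALSE)`.
#' @param K relationship matrix covering the panel.
#' @param scenario list with `name`, `train` (trial names), `test`
#'   (trial names); train and test must be disjoint unless
#'   `allow_overlap = TRUE` (used for self-consistency checks).
#' @param n_iter,burn_in,thin,weights_mode,weights_values as in
#'   [run_holdout()].
#' @param seed chain seed.
#' @param allow_overlap permit train/test trial overlap.
#' @param ... further arguments passed to [mtgblup()].
#' @return a `gs_cv` object with one row per test trial x target.
#' @export
run_scenario <- function(pheno_long, K, scenario, n_iter = 2000,
                         burn_in = 500, thin = 1,
                         weights_mode = "inverse_phenotypic_sd",
                         weights_values = NULL, seed = 1,
                         allow_overlap = FALSE, ...) {
  stopifnot(all(c("genotype", "trial", "trait", "value") %in%
                  names(pheno_long)),
            all(c("name", "train", "test") %in% names(scenario)))
  trials <- unique(pheno_long$trial)
  missing_tr <- setdiff(c(scenario$train, scenario$test), trials)
  if (length(missing_tr)) {
    stop("scenario names unknown trial(s): ",
         paste(missing_tr, collapse = ", "))
  }
  if (!allow_overlap && length(intersect(scenario$train, scenario$test))) {
    stop("train and test trial sets overlap")
  }
  traits <- unique(pheno_long$trait)
  Y_train <- long_to_wide(pheno_long[pheno_long$trial %in% scenario$train,
                                     , drop = FALSE], traits,
                          combine = TRUE)
  test_geno <- unique(pheno_long$genotype[pheno_long$trial %in%
                                            scenario$test])
  if (!length(intersect(rownames(Y_train), test_geno))) {
    stop("no genotype overlap between training and test trials")
  }
  stopifnot(!is.null(rownames(K)))
  if (!all(rownames(Y_train) %in% rownames(K))) {
    stop("training genotypes missing from the relationship matrix")
  }
  ## fit on the whole panel; genotypes without training data enter as NA
  Yfit <- matrix(NA_real_, nrow(K), length(traits),
                 dimnames = list(rownames(K), traits))
  Yfit[rownames(Y_train), ] <- Y_train
  fit <- mtgblup(Yfit, K, n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, ...)
  tm <- fit_target_metrics(fit, weights_mode, weights_values)
  rows <- NULL
  for (tt in scenario$test) {
    Y_obs <- long_to_wide(pheno_long[pheno_long$trial == tt, ,
                                     drop = FALSE], traits,
                          combine = TRUE)
    common <- intersect(rownames(Y_obs), rownames(K))
    emp <- empirical_accuracy(fit, tm$cov, tm$alphas,
                              Y_obs[common, , drop = FALSE], common)
    rows <- rbind(rows,
                  cbind(data.frame(scenario = scenario$name,
                                   test_trial = tt,
                                   stringsAsFactors = FALSE),
                        tm$metrics,
                        pred_accuracy = emp[tm$metrics$target]))
  }
  rownames(rows) <- NULL
  out <- list(rows = rows,
              summary = cv_summarize_rows(rows,
                                          by = c("test_trial", "target")),
              failed = integer(0),
              settings = list(scenario = scenario, n_iter = n_iter,
                              burn_in = burn_in, thin = thin,
                              weights_mode = weights_mode, seed = seed),
              fit = fit)
  class(out) <- "gs_cv"
  out
}

## long (genotype, trial, trait, value) -> wide genotype x trait matrix;
## multiple trials per trait are combined with combine_trials(). The
## genomic stage consumes unshrunken (BLUE-like) environment-centered
## means by default; shrinkage would compress the phenotypic variance the
## model partitions.
long_to_wide <- function(long, traits, combine = TRUE, shrink = FALSE) {
  genos <- sort(unique(long$genotype))
  Y <- matrix(NA_real_, length(genos), length(traits),
              dimnames = list(genos, traits))
  for (tr in traits) {
    sub <- long[long$trait == tr & !is.na(long$value), , drop = FALSE]
    if (nrow(sub) == 0L) next
    if (combine && length(unique(sub$trial)) > 1L) {
      cmb <- combine_trials(sub, shrink = shrink)
      Y[cmb$genotype, tr] <- cmb$value
    } else {
      Y[sub$genotype, tr] <- sub$value
    }
  }
  Y
}
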