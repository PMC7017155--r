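test_that("make_splits: sizes, determinism, distinctness, stratification", {
  ids <- sprintf("G%02d", 1:10)
  sp <- make_splits(ids, frac_test = 0.3, n_repeats = 5, master_seed = 3)
  for (s in sp) {
    expect_length(s$test_ids, 3)
    expect_length(s$train_ids, 7)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_setequal(c(s$train_ids, s$test_ids), ids)
  }
  sp2 <- make_splits(ids, frac_test = 0.3, n_repeats = 5, master_seed = 3)
  expect_identical(sp, sp2)
  sp3 <- make_splits(sprintf("G%03d", 1:200), 0.3, 100, master_seed = 9)
  expect_length(sp3, 100)
  expect_equal(length(unique(vapply(sp3, function(s)
    paste(s$test_ids, collapse = ","), character(1)))), 100)
  ## stratified splits keep both groups represented in the test set
  strata <- rep(c("SB", "SH"), each = 100)
  ids2 <- sprintf("G%03d", 1:200)
  sp4 <- make_splits(ids2, 0.3, 5, master_seed = 4, strata = strata)
  for (s in sp4) {
    expect_equal(sum(s$test_ids %in% ids2[1:100]), 30)
    expect_equal(sum(s$test_ids %in% ids2[101:200]), 30)
  }
  expect_error(make_splits(ids[1:5], 0.3, 2, 1), "too small")
  expect_error(make_splits(ids, 1.2, 2, 1), "frac_test")
})

## small shared panel for the CV tests
cv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- quick_cfg()
      geno <- simulate_genotypes(cfg)
      truth <- simulate_architecture(cfg, geno)
      Y <- simulate_phenotypes(cfg, truth)
      cache <<- list(cfg = cfg, truth = truth, Y = Y, K = truth$K)
    }
    cache
  }
})

test_that("run_holdout produces coherent per-repeat rows and summaries", {
  fx <- cv_fixture()
  splits <- make_splits(rownames(fx$Y), 0.3, 3, master_seed = 21)
  cv <- run_holdout(fx$Y, fx$K, splits, n_iter = 400, burn_in = 100)
  expect_s3_class(cv, "gs_cv")
  expect_equal(nrow(cv$rows), 3 * 4)  # repeats x (3 single + GSI)
  expect_setequal(unique(cv$rows$target), c("DMY", "PH", "DMC", "GSI"))
  ## the identity acc = gencor * sqrt(h2) holds on every row
  expect_equal(cv$rows$accuracy,
               cv$rows$gencor * sqrt(cv$rows$h2_index), tolerance = 1e-10)
  ## summary means equal the arithmetic means of the rows
  for (tg in unique(cv$rows$target)) {
    expect_equal(cv$summary$accuracy_mean[cv$summary$target == tg],
                 mean(cv$rows$accuracy[cv$rows$target == tg]),
                 tolerance = 1e-12)
  }
  ## summary means lie within the observed row ranges
  for (m in c("h2_index", "gencor", "accuracy")) {
    mm <- cv$summary[[paste0(m, "_mean")]]
    expect_true(all(mm <= tapply(cv$rows[[m]], cv$rows$target, max)[
      cv$summary$target] + 1e-12))
    expect_true(all(mm >= tapply(cv$rows[[m]], cv$rows$target, min)[
      cv$summary$target] - 1e-12))
  }
  s <- summary(cv)
  expect_true("accuracy_class" %in% names(s))
})

test_that("run_holdout is deterministic and leak-free", {
  fx <- cv_fixture()
  splits <- make_splits(rownames(fx$Y), 0.3, 2, master_seed = 5)
  cv1 <- run_holdout(fx$Y, fx$K, splits, n_iter = 300, burn_in = 100)
  cv2 <- run_holdout(fx$Y, fx$K, splits, n_iter = 300, burn_in = 100)
  expect_identical(cv1$rows[names(cv1$rows) != "pred_accuracy"],
                   cv2$rows[names(cv2$rows) != "pred_accuracy"])
  expect_identical(cv1$rows$pred_accuracy, cv2$rows$pred_accuracy)
  ## perturbing the *masked* phenotypes changes no training-derived value
  Yp <- fx$Y
  Yp[splits[[1]]$test_ids, ] <- Yp[splits[[1]]$test_ids, ] + 50
  cv3 <- run_holdout(Yp, fx$K, splits[1], n_iter = 300, burn_in = 100)
  cv0 <- run_holdout(fx$Y, fx$K, splits[1], n_iter = 300, burn_in = 100)
  for (m in c("h2_index", "gencor", "accuracy")) {
    expect_identical(cv0$rows[[m]], cv3$rows[[m]])
  }
})

test_that("noiseless phenotypes give near-perfect formula accuracy", {
  ## homogeneous panel: the subpopulation variance scaling would itself
  ## register as residual variance under a single genetic covariance
  cfg <- quick_cfg(seed = 19, sh_scale = 1)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  ## phenotype = genetic value exactly
  Yg <- sweep(truth$g, 2, cfg$trait_means, `+`)
  splits <- make_splits(rownames(Yg), 0.3, 3, master_seed = 8)
  ## the noiseless limit needs the residual prior scale taken to zero as
  ## well: an inverse-Wishart prior at the default scale floors Sigma_e
  ## at roughly a tenth of the phenotypic variance
  cv <- run_holdout(Yg, truth$K, splits, n_iter = 500, burn_in = 200,
                    prior_scale_e = diag(1e-4 * apply(Yg, 2, var)))
  s <- cv$summary
  ## formula accuracies approach 1 (h2 -> 1, gencor -> 1). The empirical
  ## column is not assessed here: as Sigma_e -> 0 the data augmentation
  ## couples masked phenotypes to their genetic values one-to-one and the
  ## chain loses its kinship anchor for unobserved rows
  expect_true(all(s$accuracy_mean > 0.95))
})

test_that("run_scenario validates against each test trial separately", {
  fx <- cv_fixture()
  cfg <- fx$cfg
  panel <- simulate_panel(cfg)
  long <- phenotype_table(panel$plots, combine = FALSE)
  sc <- list(name = "sc1", train = cfg$env_names, test = cfg$rg_names)
  r <- run_scenario(long, panel$K, sc, n_iter = 400, burn_in = 100,
                    seed = 2)
  expect_equal(nrow(r$rows), 2 * 4)
  expect_setequal(unique(r$rows$test_trial), cfg$rg_names)
  ## training-fit statistics are identical across test trials
  for (tg in unique(r$rows$target)) {
    sub <- r$rows[r$rows$target == tg, ]
    expect_equal(sub$accuracy[1], sub$accuracy[2])
  }
  ## empirical accuracy differs between regrowth years (carryover decay)
  expect_false(isTRUE(all.equal(
    r$rows$pred_accuracy[r$rows$test_trial == cfg$rg_names[1]],
    r$rows$pred_accuracy[r$rows$test_trial == cfg$rg_names[2]])))
  ## unknown trials and empty overlap raise
  expect_error(run_scenario(long, panel$K,
                            list(name = "x", train = "nope", test = "RG1")),
               "unknown trial")
  expect_error(run_scenario(long, panel$K,
                            list(name = "x", train = cfg$env_names,
                                 test = cfg$env_names[1])),
               "overlap")
})

test_that("degenerate scenario (train = test trial) matches in-sample accuracy", {
  fx <- cv_fixture()
  cfg <- fx$cfg
  panel <- simulate_panel(cfg)
  long <- phenotype_table(panel$plots, combine = FALSE)
  sc <- list(name = "self", train = cfg$env_names[1],
             test = cfg$env_names[1])
  r <- run_scenario(long, panel$K, sc, n_iter = 400, burn_in = 100,
                    seed = 3, allow_overlap = TRUE)
  ## in-sample empirical correlation is high for every target
  expect_true(all(r$rows$pred_accuracy > 0.6))
})
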