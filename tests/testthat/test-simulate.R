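test_that("generator is deterministic and respects the configured sizes", {
  cfg <- quick_cfg(seed = 17)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_equal(nrow(g1$dosage), cfg$n_sb + cfg$n_sh)
  expect_equal(table(g1$subpop)[["SB"]], cfg$n_sb)
  t1 <- simulate_architecture(cfg, g1)
  t2 <- simulate_architecture(cfg, g1)
  expect_identical(t1$g, t2$g)
  ## default panel sizes match the study panel (180 + 189)
  dflt <- sim_config()
  expect_equal(dflt$n_sb + dflt$n_sh, 369)
})

test_that("zero divergence gives matching subpopulation frequency laws", {
  cfg <- quick_cfg(seed = 23, divergence = 0, m = 2000)
  g <- simulate_genotypes(cfg)
  p_sb <- colMeans(g$dosage[g$subpop == "SB", ]) / 2
  p_sh <- colMeans(g$dosage[g$subpop == "SH", ]) / 2
  expect_lt(abs(mean(p_sb - p_sh)), 0.01)
})

test_that("architecture: Sigma_g = 0 gives zero genetic values; moments match", {
  cfg <- quick_cfg(seed = 5)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  ## kinship-metric covariance of g equals Sigma_g exactly (calibrated)
  eK <- eigen(truth$K, symmetric = TRUE)
  keep <- eK$values > 1e-8 * max(eK$values)
  Gs <- crossprod(eK$vectors[, keep], truth$g)
  C <- crossprod(Gs, Gs / eK$values[keep]) / sum(keep)
  expect_equal(unname(C), unname(cfg$Sigma_g), tolerance = 1e-8)
  ## SH genetic variance is scaled down
  vr <- apply(truth$g[truth$subpop == "SH", ], 2, var) /
    apply(truth$g[truth$subpop == "SB", ], 2, var)
  expect_true(all(vr < 1))
})

test_that("realized sample genetic correlations track the targets at full scale", {
  cfg <- sim_config(seed = 11)  # default panel, m = 2000
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  target <- c(0.60, 0.23, -0.35)
  realized <- truth$realized_gencor[upper.tri(truth$realized_gencor)]
  expect_true(all(abs(realized - target) < 0.1))
})

test_that("trial records invert through derive_traits and validate the design", {
  cfg <- quick_cfg(seed = 29)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  plots <- simulate_trials(cfg, truth)
  ## every check in every block of every trial; entries unreplicated
  for (tl in unique(plots$trial)) {
    sub <- plots[plots$trial == tl, ]
    chk <- sub[sub$is_check, ]
    expect_equal(nrow(chk), cfg$n_checks * cfg$n_blocks)
    expect_true(all(table(chk$genotype, chk$block) == 1))
    expect_false(anyDuplicated(sub$genotype[!sub$is_check]) > 0)
  }
  ## round trip: derive_traits recovers the generator's intended values
  der <- derive_traits(plots$plot_wet_kg, plots$sample_wet_g,
                       plots$sample_dry_g, plots$plot_area_m2)
  expect_equal(der$dmc, 100 * plots$sample_dry_g / plots$sample_wet_g,
               tolerance = 1e-9)
  expect_equal(der$dmy,
               10 * plots$plot_wet_kg *
                 (plots$sample_dry_g / plots$sample_wet_g) /
                 plots$plot_area_m2,
               tolerance = 1e-9)
})

test_that("noise-free trials return mu + env + g exactly after adjustment", {
  cfg <- quick_cfg(seed = 31, block_sd_frac = 0)
  cfg$Sigma_e <- diag(1e-12, 3, 3)  # effectively noiseless
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  plots <- simulate_trials(cfg, truth)
  sub <- plots[plots$trial == cfg$env_names[1], ]
  adj <- adjust_augmented(data.frame(genotype = sub$genotype,
                                     block = sub$block,
                                     is_check = sub$is_check,
                                     value = sub$plant_height_cm))
  entries <- adj[!adj$is_check, ]
  expected <- truth$g[entries$genotype, "PH"] +
    cfg$trait_means["PH"] + cfg$env_shift_frac[1] * cfg$phen_sd["PH"]
  expect_equal(entries$value, unname(expected), tolerance = 1e-6)
})

test_that("regrowth carryover correlations are realized as configured", {
  cfg <- quick_cfg(seed = 37)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  rg <- simulate_regrowth(cfg, truth)
  for (k in seq_along(cfg$rg_names)) {
    realized <- diag(cor(truth$g, rg$truth$g_regrowth[[k]]))
    expect_true(all(abs(realized - cfg$rg_rho[, k]) < 0.08))
  }
  ## rho = 1 reproduces the seed-year values; rho = 0 decorrelates
  cfg1 <- quick_cfg(seed = 37, rg_names = "R", rg_rho = cbind(c(1, 1, 1)))
  rg1 <- simulate_regrowth(cfg1, simulate_architecture(cfg1,
                                   simulate_genotypes(cfg1)))
  tr1 <- rg1$truth
  expect_equal(tr1$g_regrowth[["R"]], tr1$g, tolerance = 1e-10)
  cfg0 <- quick_cfg(seed = 37, rg_names = "R", rg_rho = cbind(c(0, 0, 0)))
  rg0 <- simulate_regrowth(cfg0, simulate_architecture(cfg0,
                                   simulate_genotypes(cfg0)))
  expect_true(all(abs(diag(cor(rg0$truth$g,
                               rg0$truth$g_regrowth[["R"]]))) < 0.05))
  expect_error(quick_cfg(rg_rho = cbind(c(2, 0, 0))))
})

test_that("emitted VCF re-read through QC reproduces the dosages", {
  cfg <- quick_cfg(seed = 41, vcf_qual_range = c(50, 120),
                   vcf_missing_rate = 0.05)
  geno <- simulate_genotypes(cfg)
  path <- tempfile(fileext = ".vcf")
  write_synthetic_vcf(geno, path, cfg)
  rv <- read_vcf(path)
  expect_equal(rv$samples, rownames(geno$dosage))
  ## where calls are non-missing the dosages agree exactly
  emitted <- t(rv$gt)
  truthful <- geno$dosage
  ok <- !is.na(emitted)
  expect_equal(emitted[ok], truthful[ok])
  ## the QC path removes markers that exceed the missingness cap
  fv <- filter_variants(rv, maf_min = 0, qual_min = 0, max_missing = 0.02)
  expect_true(all(fv$variants$missing_frac <= 0.02))
  expect_gt(filter_report(fv)$removed$missing, 0)
})

test_that("simulate_phenotypes matches the configured residual covariance", {
  cfg <- quick_cfg(seed = 43)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  Y <- simulate_phenotypes(cfg, truth)
  E <- Y - sweep(truth$g, 2, cfg$trait_means, `+`)
  expect_equal(unname(cov(E)), unname(cfg$Sigma_e), tolerance = 1e-8)
})
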