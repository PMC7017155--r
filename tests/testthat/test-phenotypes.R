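test_that("derive_traits implements the DMC/DMY formulas and domain checks", {
  d <- derive_traits(60, 100, 20, 3.75)
  expect_equal(d$dmc, 20)
  d2 <- derive_traits(60, 100, 25, 3.75)
  expect_equal(d2$dmy, 40)  # (60 * 0.25 / 3.75) * 10
  expect_error(derive_traits(60, 100, 110, 3.75), "exceeds wet")
  expect_error(derive_traits(60, 0, 10, 3.75), "wet weight must be positive")
  expect_error(derive_traits(60, 100, 20, 0), "area must be positive")
})

test_that("derive_traits invariances: linear in plot weight, DMC scale-free", {
  base <- derive_traits(40, 200, 50, 3.75)
  doubled <- derive_traits(80, 200, 50, 3.75)
  expect_equal(doubled$dmy, 2 * base$dmy)
  ## scaling the subsample leaves DMC (and DMY) unchanged
  scaled <- derive_traits(40, 500, 125, 3.75)
  expect_equal(scaled$dmc, base$dmc)
  expect_equal(scaled$dmy, base$dmy)
})

make_augmented <- function(shifts, n_checks = 6, n_entries = 24,
                           entry_means = NULL, check_means = NULL,
                           noise = 0) {
  n_blocks <- length(shifts)
  if (is.null(entry_means)) entry_means <- rnorm(n_entries, 50, 5)
  if (is.null(check_means)) check_means <- rnorm(n_checks, 50, 5)
  blocks <- rep(seq_len(n_blocks), length.out = n_entries)
  entries <- data.frame(
    genotype = sprintf("E%02d", seq_len(n_entries)),
    block = blocks, is_check = FALSE,
    value = entry_means + shifts[blocks] + rnorm(n_entries, 0, noise)
  )
  checks <- expand.grid(chk = seq_len(n_checks), block = seq_len(n_blocks))
  checks <- data.frame(
    genotype = sprintf("C%d", checks$chk), block = checks$block,
    is_check = TRUE,
    value = check_means[checks$chk] + shifts[checks$block] +
      rnorm(nrow(checks), 0, noise)
  )
  list(plots = rbind(entries, checks), entry_means = entry_means,
       blocks = blocks)
}

test_that("Federer adjustment recovers constructed block shifts exactly", {
  set.seed(42)
  shifts <- c(2, -1, 0, 3.5, -2.25, 1)
  fx <- make_augmented(shifts)
  adj <- adjust_augmented(fx$plots)
  entries <- adj[!adj$is_check, ]
  ## centered block effects are removed; the mean shift is common to all
  expect_equal(entries$value[order(entries$genotype)],
               fx$entry_means + mean(shifts), tolerance = 1e-10)
  rep <- attr(adj, "adjustment_report")
  ## estimated block effects are the shifts, centered; they sum to zero
  expect_equal(as.numeric(rep$block_effects), shifts - mean(shifts),
               tolerance = 1e-10)
  expect_equal(sum(rep$block_effects), 0, tolerance = 1e-10)
  expect_equal(rep$n_check_plots, 36)
})

test_that("identical check values give zero block effects (no-op adjustment)", {
  set.seed(7)
  fx <- make_augmented(shifts = rep(0, 6))
  adj <- adjust_augmented(fx$plots)
  entries <- adj[!adj$is_check, ]
  expect_equal(entries$value[order(entries$genotype)], fx$entry_means,
               tolerance = 1e-10)
})

test_that("adjustment errors: missing check in a block, replicated entry", {
  set.seed(1)
  fx <- make_augmented(shifts = rep(0, 4), n_checks = 3, n_entries = 8)
  drop1 <- fx$plots[!(fx$plots$is_check & fx$plots$genotype == "C2" &
                        fx$plots$block == 3), ]
  expect_error(adjust_augmented(drop1), "block '3' is missing check.*C2")
  dup <- rbind(fx$plots, fx$plots[1, ])
  expect_error(adjust_augmented(dup), "replicated")
})

test_that("adjustment preserves the entry grand mean with equal block sizes", {
  set.seed(3)
  fx <- make_augmented(shifts = c(4, -4, 2, -2), n_entries = 16,
                       noise = 1)
  adj <- adjust_augmented(fx$plots)
  raw_entries <- fx$plots[!fx$plots$is_check, ]
  ## block effects sum to zero and blocks are balanced, so the grand mean
  ## of entries is unchanged
  expect_equal(mean(adj$value[!adj$is_check]), mean(raw_entries$value),
               tolerance = 1e-10)
})

test_that("combine_trials degenerate cases", {
  one <- data.frame(genotype = c("A", "B", "C"), trial = "T1",
                    value = c(1, 2, 3))
  out <- combine_trials(one)
  expect_equal(out$value[order(out$genotype)], c(1, 2, 3))
  ## identical centered values in two trials are returned untouched
  two <- data.frame(genotype = rep(c("A", "B", "C"), 2),
                    trial = rep(c("T1", "T2"), each = 3),
                    value = c(1, 2, 3, 11, 12, 13))
  out2 <- combine_trials(two)
  expect_equal(out2$value[order(out2$genotype)], c(1, 2, 3) + 5,
               tolerance = 1e-10)
})

test_that("combine_trials is equivariant to per-environment constants", {
  set.seed(9)
  df <- expand.grid(genotype = sprintf("G%02d", 1:15),
                    trial = c("T1", "T2", "T3"))
  df$value <- rnorm(nrow(df), 20, 3)
  base <- combine_trials(df)
  df2 <- df
  df2$value[df2$trial == "T2"] <- df2$value[df2$trial == "T2"] + 100
  shifted <- combine_trials(df2)
  ## the constant is absorbed into the environment effect, raising every
  ## genotype by its share of the grand mean only
  expect_equal(shifted$value - base$value,
               rep(100 / 3, nrow(base)), tolerance = 1e-10)
})

test_that("combine_trials recovers genotype effects from simulated trials", {
  set.seed(123)
  n_g <- 40; n_t <- 4
  cors <- replicate(20, {
    g <- rnorm(n_g, 0, 2)            # sigma2_G = 4
    env <- rnorm(n_t, 0, 3)
    df <- expand.grid(gi = seq_len(n_g), ti = seq_len(n_t))
    df <- data.frame(genotype = sprintf("G%02d", df$gi),
                     trial = paste0("T", df$ti),
                     value = 10 + g[df$gi] + env[df$ti] + rnorm(nrow(df)))
    out <- combine_trials(df)
    cor(out$value[order(out$genotype)], g)
  })
  expect_gte(mean(cors), 0.9)
  expect_gte(min(cors), 0.8)
})

test_that("phenotype_table derives, adjusts, combines and honours unscored trials", {
  cfg <- quick_cfg()
  panel <- simulate_panel(cfg)
  expect_message(
    Y <- phenotype_table(panel$plots[panel$plots$trial %in% cfg$env_names, ]),
    NA)
  expect_equal(colnames(Y), c("DMY", "PH", "DMC"))
  expect_equal(nrow(Y), cfg$n_sb + cfg$n_sh)  # checks dropped
  expect_false(any(is.na(Y)))
  long <- phenotype_table(panel$plots, combine = FALSE)
  expect_setequal(unique(long$trial), c(cfg$env_names, cfg$rg_names))
})
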