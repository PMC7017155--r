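#' Configuration for the synthetic sorghum-panel generator
#'
#' Assembles all knobs of the synthetic data generator with defaults that
#' emulate a structured biomass sorghum diversity panel: two subpopulations
#' (180 *S. bicolor*-like lines, "SB", and 189 interspecific RIL-like
#' lines, "SH") of inbred genotypes arranged in biparental families, three
#' traits (DMY t/ha, PH cm, DMC %) with heritabilities 0.60 / 0.70 / 0.65
#' and genetic correlations 0.60 (PH-DMY), 0.23 (DMC-DMY), -0.35 (DMC-PH),
#' multi-environment augmented RCBD trials with 6 checks x 6 blocks, one
#' seed trial unscored for DMC, and ratoon regrowth years whose genetic
#' values are imperfectly correlated with the seed-year values.
#'
#' @param seed master seed for all generator draws.
#' @param n_sb,n_sh subpopulation sizes.
#' @param sb_families,sh_families number of biparental families per
#'   subpopulation.
#' @param m marker count.
#' @param maf_range founder allele-frequency law (uniform on this range).
#' @param divergence Balding-Nichols differentiation of subpopulation
#'   allele frequencies from the base frequencies (0 = identical law).
#' @param traits trait names, order fixed.
#' @param trait_means,phen_sd trait means and phenotypic standard
#'   deviations on the combined (across-environment) scale.
#' @param h2 per-trait heritabilities on the combined scale.
#' @param gencor 3 x 3 genetic correlation matrix.
#' @param sh_scale genetic-variance scaling (< 1) of the SH subpopulation,
#'   emulating its narrower genetic base.
#' @param env_names seed-trial names.
#' @param env_shift_frac per-trial environment shifts, in units of
#'   phenotypic SD.
#' @param n_checks,n_blocks augmented design layout.
#' @param block_sd_frac block-effect SD, in units of plot residual SD.
#' @param unscored named list: traits not scored in given trials
#'   (emulates trials where a trait was not recorded).
#' @param rg_names regrowth trial names (chronological).
#' @param rg_rho traits x regrowth-years matrix of carryover genetic
#'   correlations between seed-year and regrowth genetic values.
#' @param exact_moments calibrate realized moments to the configured ones:
#'   genetic values are rescaled so their kinship-metric covariance equals
#'   `Sigma_g` exactly, residual draws are rescaled to their target
#'   covariance, and regrowth innovations are orthogonalized so realized
#'   carryover correlations equal `rg_rho` exactly.
#' @param vcf_missing_rate,vcf_qual_range call missingness and site-quality
#'   law used when rendering genotypes as a VCF.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 11,
                       n_sb = 180, n_sh = 189,
                       sb_families = 30, sh_families = 27,
                       m = 2000,
                       maf_range = c(0.05, 0.5),
                       divergence = 0.05,
                       traits = c("DMY", "PH", "DMC"),
                       trait_means = c(30, 300, 28),
                       phen_sd = c(5, 40, 4),
                       h2 = c(0.60, 0.70, 0.65),
                       gencor = matrix(c(1, 0.60, 0.23,
                                         0.60, 1, -0.35,
                                         0.23, -0.35, 1), 3, 3),
                       sh_scale = 0.6,
                       env_names = c("E1", "E2", "E3"),
                       env_shift_frac = c(-0.5, 0, 0.5),
                       n_checks = 6, n_blocks = 6,
                       block_sd_frac = 0.3,
                       unscored = list(E2 = "DMC"),
                       rg_names = c("RG1", "RG2"),
                       rg_rho = rbind(DMY = c(0.95, 0.95),
                                      PH = c(0.90, 0.50),
                                      DMC = c(0.85, 0.55)),
                       exact_moments = TRUE,
                       vcf_missing_rate = 0.02,
                       vcf_qual_range = c(30, 120)) {
  t <- length(traits)
  stopifnot(n_sb >= 2, n_sh >= 0, m >= 1,
            length(trait_means) == t, length(phen_sd) == t,
            length(h2) == t, all(h2 > 0 & h2 < 1),
            nrow(gencor) == t, ncol(gencor) == t,
            all(abs(gencor) <= 1), all(diag(gencor) == 1),
            sh_scale > 0, sh_scale <= 1,
            all(rg_rho >= 0 & rg_rho <= 1),
            nrow(rg_rho) == t, ncol(rg_rho) == length(rg_names))
  gsd <- phen_sd * sqrt(h2)
  Sigma_g <- diag(gsd, t) %*% gencor %*% diag(gsd, t)
  dimnames(Sigma_g) <- list(traits, traits)
  ev <- eigen(Sigma_g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("implied Sigma_g is not positive definite")
  Sigma_e <- diag(phen_sd^2 * (1 - h2), t)
  dimnames(Sigma_e) <- list(traits, traits)
  cfg <- list(seed = as.integer(seed), n_sb = n_sb, n_sh = n_sh,
              sb_families = sb_families, sh_families = sh_families,
              m = m, maf_range = maf_range, divergence = divergence,
              traits = traits,
              trait_means = stats::setNames(trait_means, traits),
              phen_sd = stats::setNames(phen_sd, traits),
              h2 = stats::setNames(h2, traits),
              Sigma_g = Sigma_g, Sigma_e = Sigma_e,
              sh_scale = sh_scale,
              env_names = env_names, env_shift_frac = env_shift_frac,
              n_checks = n_checks, n_blocks = n_blocks,
              block_sd_frac = block_sd_frac,
              unscored = unscored,
              rg_names = rg_names, rg_rho = rg_rho,
              exact_moments = exact_moments,
              vcf_missing_rate = vcf_missing_rate,
              vcf_qual_range = vcf_qual_range)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic panel config:", x$n_sb, "SB +", x$n_sh, "SH genotypes,",
      x$m, "markers, seed", x$seed, "\n")
  cat("  traits:", paste(x$traits, collapse = ", "),
      " h2:", paste(x$h2, collapse = "/"), "\n")
  cat("  trials:", paste(x$env_names, collapse = ", "),
      " regrowth:", paste(x$rg_names, collapse = ", "), "\n")
  invisible(x)
}

## inbred line panel: founders are fully inbred draws at the subpopulation
## allele frequencies; each family is a biparental cross whose offspring
## take either parent's (homozygous) genotype per marker, like advanced
## RILs. Marginal genotype frequencies stay at the founder law.
sim_subpop <- function(n, n_fam, m, p_sub, prefix) {
  sizes <- rep(n %/% n_fam, n_fam)
  if (n %% n_fam) sizes[seq_len(n %% n_fam)] <- sizes[seq_len(n %% n_fam)] + 1L
  W <- matrix(0L, n, m)
  fam <- integer(n)
  row <- 0L
  for (f in seq_len(n_fam)) {
    f1 <- 2L * stats::rbinom(m, 1L, p_sub)
    f2 <- 2L * stats::rbinom(m, 1L, p_sub)
    for (s in seq_len(sizes[f])) {
      row <- row + 1L
      pick <- stats::rbinom(m, 1L, 0.5) == 1L
      W[row, ] <- ifelse(pick, f1, f2)
      fam[row] <- f
    }
  }
  rownames(W) <- sprintf("%s%03d", prefix, seq_len(n))
  list(W = W, family = fam)
}

#' Simulate panel genotypes
#'
#' Draws founder allele frequencies from the configured law, differentiates
#' them between the two subpopulations by a Balding-Nichols model, and
#' builds inbred biparental families within each subpopulation (see
#' [sim_config()]). The resulting dosages are complete; missingness and
#' site quality are injected only when rendering to VCF with
#' [write_synthetic_vcf()].
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_geno`: list with `dosage` (n x m, 0/2
#'   integer dosages, rownames = genotype ids), `subpop` (factor SB/SH),
#'   `family`, `p_base` founder frequencies, `markers`, `chrom`, `pos`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed)
  m <- cfg$m
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  bn <- function(p, F) {
    if (F <= 0) return(p)
    a <- p * (1 - F) / F; b <- (1 - p) * (1 - F) / F
    pmin(pmax(stats::rbeta(length(p), a, b), 0.001), 0.999)
  }
  p_sb <- bn(p, cfg$divergence)
  p_sh <- bn(p, cfg$divergence)
  sb <- sim_subpop(cfg$n_sb, cfg$sb_families, m, p_sb, "SB")
  sh <- if (cfg$n_sh > 0) {
    sim_subpop(cfg$n_sh, cfg$sh_families, m, p_sh, "SH")
  } else list(W = NULL, family = integer(0))
  W <- rbind(sb$W, sh$W)
  markers <- sprintf("M%05d", seq_len(m))
  colnames(W) <- markers
  out <- list(
    dosage = W,
    subpop = factor(rep(c("SB", "SH"), c(cfg$n_sb, cfg$n_sh))),
    family = c(sb$family, cfg$sb_families + sh$family),
    p_base = p, markers = markers,
    chrom = as.character(1L + (seq_len(m) - 1L) %% 10L),
    pos = 1000L * (1L + (seq_len(m) - 1L) %/% 10L) +
      (seq_len(m) - 1L) %% 10L
  )
  class(out) <- "sim_geno"
  out
}

#' @export
print.sim_geno <- function(x, ...) {
  cat("synthetic genotypes:", nrow(x$dosage), "lines x", ncol(x$dosage),
      "markers;", sum(x$subpop == "SB"), "SB /", sum(x$subpop == "SH"),
      "SH\n")
  invisible(x)
}

#' Simulate the multi-trait genetic architecture
#'
#' Draws additive marker effects i.i.d. multivariate normal with covariance
#' `Sigma_g / sum(2 p q)` and forms genetic values on the centered dosages.
#' The SH subpopulation's genetic deviations are shrunk by
#' `sqrt(sh_scale)` to emulate its narrower genetic base. With
#' `exact_moments` the genetic values are then linearly recalibrated across
#' traits so that their covariance in the metric of the (unit-diagonal)
#' genomic relationship matrix equals `Sigma_g` exactly, making the
#' configured values the realized generating truth.
#'
#' @param cfg a [sim_config()].
#' @param geno a `sim_geno` from [simulate_genotypes()].
#' @return an object of class `sim_truth`: `g` (n x t genetic values),
#'   `marker_effects` (m x t, generating the pre-calibration values),
#'   `g_checks` (check genotypic values), `Sigma_g`, `Sigma_e`, `K`
#'   (the generator's own normalized GRM), `realized_gencor`.
#' @export
simulate_architecture <- function(cfg, geno) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "sim_geno"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  W <- geno$dosage
  n <- nrow(W); t <- length(cfg$traits)
  pj <- colMeans(W) / 2
  poly <- pj > 0 & pj < 1
  Wc <- sweep(W[, poly, drop = FALSE], 2L, 2 * pj[poly], `-`)
  den <- sum(2 * pj[poly] * (1 - pj[poly]))
  K <- tcrossprod(Wc) / den
  K <- K / mean(diag(K))
  B <- matrix(stats::rnorm(sum(poly) * t), ncol = t) %*%
    chol(cfg$Sigma_g / den)
  G <- Wc %*% B
  ## narrower genetic base in SH
  if (cfg$sh_scale < 1 && any(geno$subpop == "SH")) {
    ix <- geno$subpop == "SH"
    G[ix, ] <- sweep(sweep(G[ix, , drop = FALSE], 2L,
                           colMeans(G[ix, , drop = FALSE]), `-`) *
                       sqrt(cfg$sh_scale),
                     2L, colMeans(G[ix, , drop = FALSE]), `+`)
  }
  if (cfg$exact_moments) {
    eK <- eigen(K, symmetric = TRUE)
    keep <- eK$values > 1e-8 * max(eK$values)
    U <- eK$vectors[, keep, drop = FALSE]
    d <- eK$values[keep]
    Gs <- crossprod(U, G)
    C <- crossprod(Gs, Gs / d) / length(d)
    A <- solve(chol(C)) %*% chol(cfg$Sigma_g)
    G <- G %*% A
    B <- B %*% A
  }
  G <- sweep(G, 2L, colMeans(G), `-`)
  dimnames(G) <- list(rownames(W), cfg$traits)
  g_checks <- matrix(stats::rnorm(cfg$n_checks * t), ncol = t) %*%
    chol(cfg$Sigma_g)
  dimnames(g_checks) <- list(sprintf("CHK%d", seq_len(cfg$n_checks)),
                             cfg$traits)
  eff <- matrix(0, ncol(W), t,
                dimnames = list(colnames(W), cfg$traits))
  eff[poly, ] <- B
  out <- list(g = G, marker_effects = eff, g_checks = g_checks,
              Sigma_g = cfg$Sigma_g, Sigma_e = cfg$Sigma_e,
              K = K, realized_gencor = stats::cor(G),
              subpop = geno$subpop)
  class(out) <- "sim_truth"
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("synthetic truth:", nrow(x$g), "genotypes x", ncol(x$g), "traits\n")
  cat("  realized genetic correlations:\n")
  print(round(x$realized_gencor, 3))
  invisible(x)
}

## intended trait values -> raw plot measurements that derive_traits
## inverts exactly. Plot geometry follows a 5 m x 0.75 m single-row plot.
back_calculate_plots <- function(dmy, ph, dmc, area = 3.75,
                                 sample_wet = 1000) {
  if (any(dmc <= 0.5 | dmc >= 99.5)) {
    stop("generated DMC outside (0.5, 99.5)%; check config scales")
  }
  if (any(dmy <= 0)) stop("generated DMY non-positive; check config scales")
  data.frame(
    plot_wet_kg = dmy * area * 10 / dmc,
    sample_wet_g = sample_wet,
    sample_dry_g = sample_wet * dmc / 100,
    plant_height_cm = ph,
    plot_area_m2 = area
  )
}

## one augmented trial: entries once each, checks in every block
build_trial <- function(cfg, trial, g_entries, g_checks, env_shift,
                        resid_sd_plot, rng_offset) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed + rng_offset)
  t <- length(cfg$traits)
  n <- nrow(g_entries)
  nb <- cfg$n_blocks
  blocks <- rep(seq_len(nb), length.out = n)[sample.int(n)]
  block_eff <- matrix(stats::rnorm(nb * t, 0,
                                   rep(cfg$block_sd_frac * resid_sd_plot,
                                       each = nb)),
                      nb, t)
  ## entry plot residuals (GE + error), moment-matched per trial
  E <- matrix(stats::rnorm(n * t), n, t)
  if (cfg$exact_moments && n > t + 1) {
    E <- sweep(E, 2L, colMeans(E), `-`)
    E <- E %*% solve(chol(crossprod(E) / (n - 1)))
  }
  E <- sweep(E, 2L, resid_sd_plot, `*`)
  vals_e <- sweep(g_entries, 2L, cfg$trait_means + env_shift, `+`) +
    block_eff[blocks, , drop = FALSE] + E
  rec_e <- back_calculate_plots(vals_e[, "DMY"], vals_e[, "PH"],
                                vals_e[, "DMC"])
  entries <- cbind(data.frame(trial = trial, block = blocks,
                              genotype = rownames(g_entries),
                              is_check = FALSE, stringsAsFactors = FALSE),
                   rec_e)
  ## checks: every check in every block
  nc <- cfg$n_checks
  chk_block <- rep(seq_len(nb), each = nc)
  chk_geno <- rep(seq_len(nc), times = nb)
  Echk <- matrix(stats::rnorm(nb * nc * t, 0,
                              rep(resid_sd_plot, each = nb * nc)),
                 nb * nc, t)
  vals_c <- sweep(g_checks[chk_geno, , drop = FALSE], 2L,
                  cfg$trait_means + env_shift, `+`) +
    block_eff[chk_block, , drop = FALSE] + Echk
  rec_c <- back_calculate_plots(vals_c[, "DMY"], vals_c[, "PH"],
                                vals_c[, "DMC"])
  checks <- cbind(data.frame(trial = trial, block = chk_block,
                             genotype = rownames(g_checks)[chk_geno],
                             is_check = TRUE, stringsAsFactors = FALSE),
                  rec_c)
  rbind(entries, checks)
}

#' Simulate multi-environment augmented trials
#'
#' Builds plot-level records for each seed-year environment: phenotype =
#' trait mean + environment shift + genetic value + block effect + plot
#' residual, laid out as an augmented RCBD (unreplicated entries, all
#' checks in all blocks). Raw plot measurements (fresh weights, subsample
#' weights, areas) are back-calculated so that [derive_traits()] recovers
#' the intended DMC / DMY values exactly. The plot residual variance is
#' calibrated so that across-environment combination of Federer-adjusted
#' means realizes the configured heritabilities (including the variance the
#' block-effect estimate adds back).
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth` from [simulate_architecture()].
#' @return plot-level data frame in the [phenotype_table()] layout.
#' @export
simulate_trials <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  n_env <- length(cfg$env_names)
  ## per-plot residual SD such that the mean of n_env adjusted values has
  ## the target non-genetic variance; Federer adjustment adds back
  ## var(block-effect estimate) = sigma_plot^2 / n_checks
  resid_sd_plot <- sqrt(n_env * diag(cfg$Sigma_e) /
                          (1 + 1 / cfg$n_checks))
  plots <- NULL
  for (k in seq_len(n_env)) {
    shift <- cfg$env_shift_frac[k] * cfg$phen_sd
    plots <- rbind(plots,
                   build_trial(cfg, cfg$env_names[k], truth$g,
                               truth$g_checks, shift, resid_sd_plot,
                               rng_offset = 100L + k))
  }
  plots
}

#' Simulate ratoon regrowth trials
#'
#' Regrowth-year genetic values are `rho * g_seed + sqrt(1 - rho^2) *
#' g_new` per trait, with `g_new` an independent draw from the same
#' multivariate genetic law (under `exact_moments` the innovations are
#' orthogonalized against the seed-year values and variance-matched, so the
#' realized carryover correlations equal `rg_rho` exactly). Phenotypes are
#' then laid out exactly as in [simulate_trials()], one augmented trial per
#' regrowth year.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth`; regrowth genetic values are added to it.
#' @return list with `plots` (plot-level records for the regrowth trials)
#'   and `truth` (the input truth with a `g_regrowth` list added).
#' @export
simulate_regrowth <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed + 2L)
  n <- nrow(truth$g); t <- ncol(truth$g)
  n_env <- length(cfg$env_names)
  resid_sd_plot <- sqrt(n_env * diag(cfg$Sigma_e) /
                          (1 + 1 / cfg$n_checks))
  g_rg <- list()
  plots <- NULL
  for (k in seq_along(cfg$rg_names)) {
    rho <- cfg$rg_rho[, k]
    g_new <- matrix(stats::rnorm(n * t), n, t) %*% chol(cfg$Sigma_g)
    if (cfg$exact_moments) {
      ## orthogonalize innovations against seed-year values, then match
      ## their covariance, so cor(g_seed, g_rg) = rho exactly
      g_new <- g_new - truth$g %*%
        solve(crossprod(truth$g), crossprod(truth$g, g_new))
      g_new <- sweep(g_new, 2L, colMeans(g_new), `-`)
      g_new <- g_new %*% solve(chol(crossprod(g_new) / (n - 1))) %*%
        chol(cfg$Sigma_g)
    }
    g_k <- sweep(truth$g, 2L, rho, `*`) +
      sweep(g_new, 2L, sqrt(1 - rho^2), `*`)
    dimnames(g_k) <- dimnames(truth$g)
    g_rg[[cfg$rg_names[k]]] <- g_k
    plots <- rbind(plots,
                   build_trial(cfg, cfg$rg_names[k], g_k, truth$g_checks,
                               env_shift = rep(0, t),
                               resid_sd_plot, rng_offset = 200L + k))
  }
  truth$g_regrowth <- g_rg
  list(plots = plots, truth = truth)
}

#' Direct genotype-mean phenotypes from the generating truth
#'
#' Bypasses the trial layer: returns `Y = mean + g + e` on the combined
#' (across-environment) scale, with residual covariance `Sigma_e`
#' (moment-matched when configured). Useful for parameter-recovery studies
#' where the trial machinery is not under test.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth`.
#' @param seed_offset offset added to the master seed for the residual
#'   draw.
#' @return n x t phenotype matrix with genotype rownames.
#' @export
simulate_phenotypes <- function(cfg, truth, seed_offset = 3L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed + seed_offset)
  n <- nrow(truth$g); t <- ncol(truth$g)
  E <- matrix(stats::rnorm(n * t), n, t)
  if (cfg$exact_moments && n > t + 1) {
    E <- sweep(E, 2L, colMeans(E), `-`)
    E <- E %*% solve(chol(crossprod(E) / (n - 1)))
  }
  E <- E %*% chol(cfg$Sigma_e)
  Y <- sweep(truth$g + E, 2L, cfg$trait_means, `+`)
  dimnames(Y) <- dimnames(truth$g)
  Y
}

#' Generate a complete synthetic panel
#'
#' Runs [simulate_genotypes()], [simulate_architecture()],
#' [simulate_trials()] and [simulate_regrowth()] in sequence.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno`, `truth` (including regrowth genetic values),
#'   `plots` (seed + regrowth trials), `K` (the generator's normalized
#'   GRM) and the `cfg` echo.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  geno <- simulate_genotypes(cfg)
  truth <- simulate_architecture(cfg, geno)
  plots <- simulate_trials(cfg, truth)
  rg <- simulate_regrowth(cfg, truth)
  list(geno = geno, truth = rg$truth,
       plots = rbind(plots, rg$plots),
       K = rg$truth$K, cfg = cfg)
}

#' Render synthetic genotypes as a plain-text VCF
#'
#' Writes a minimal VCFv4.2 file (GT format, per-site QUAL) so the marker
#' quality-control path can be exercised end to end on synthetic data.
#' Site quality scores are drawn uniformly from `cfg$vcf_qual_range` and
#' calls are masked to `./.` independently at rate
#' `cfg$vcf_missing_rate`; where calls are not masked, re-reading the file
#' with [read_vcf()] reproduces the dosages exactly. The file is labelled
#' as synthetic in its header.
#'
#' @param geno a `sim_geno`.
#' @param path output path (`.vcf`).
#' @param cfg the [sim_config()] used to create `geno` (for the injection
#'   law and seed).
#' @return `path`, invisibly.
#' @export
write_synthetic_vcf <- function(geno, path, cfg) {
  stopifnot(inherits(geno, "sim_geno"), inherits(cfg, "sim_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed + 4L)
  W <- geno$dosage
  m <- ncol(W); n <- nrow(W)
  qual <- round(stats::runif(m, cfg$vcf_qual_range[1],
                             cfg$vcf_qual_range[2]), 1)
  gt <- matrix(c("0/0", "0/1", "1/1")[t(W) + 1L], m, n)
  miss <- matrix(stats::runif(m * n) < cfg$vcf_missing_rate, m, n)
  gt[miss] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsindex synthetic panel generator (simulated data)",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(W)), collapse = "\t")
  )
  body <- paste(geno$chrom, geno$pos, geno$markers, "A", "C", qual,
                "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
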