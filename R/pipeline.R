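#' Run the full genomic selection-index pipeline
#'
#' Wires the stages end to end: synthetic data generation (or user VCF +
#' plot files), marker QC and relationship matrix, adjusted means and
#' across-environment combination, the multi-trait Bayesian fit, Smith
#' index construction and candidate ranking, repeated hold-out
#' cross-validation and any named train-to-test scenarios. Every output
#' file carries the master seed; a `manifest.json` records stages, counts
#' and settings. Reruns with the same config and seed are numerically
#' identical.
#'
#' @param config a list (or a YAML file path, read with the `yaml`
#'   package) with any of:
#'   \describe{
#'     \item{seed}{master seed (default 1).}
#'     \item{sim}{`TRUE` or a list of [sim_config()] overrides for
#'       synthetic mode; omit to supply `vcf` and `plots` paths.}
#'     \item{vcf, plots}{input file paths (non-synthetic mode); `plots`
#'       is a CSV in the [phenotype_table()] layout.}
#'     \item{qc}{list of [filter_variants()] thresholds.}
#'     \item{chain}{list with `n_iter`, `burn_in`, `thin` for the full-fit
#'       stage.}
#'     \item{cv}{list with `n_repeats`, `frac_test`, `n_iter`, `burn_in`.}
#'     \item{scenarios}{list of scenario lists (`name`, `train`, `test`).}
#'     \item{weights}{economic weights mode.}
#'     \item{stages}{subset of
#'       `c("simulate","qc","pheno","fit","index","cv","scenario")`.}
#'   }
#' @param out_dir output directory, created if needed.
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage results
#'   (`grm`, `Y`, `fit`, `indices`, `cv`, `scenarios`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = TRUE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg_defaults <- list(
    seed = 1,
    qc = list(maf_min = 0.05, qual_min = 40, max_missing = 0.20),
    chain = list(n_iter = 2000, burn_in = 500, thin = 1),
    cv = list(n_repeats = 20, frac_test = 0.3, n_iter = 2000,
              burn_in = 500),
    weights = "inverse_phenotypic_sd",
    stages = c("simulate", "qc", "pheno", "fit", "index", "cv",
               "scenario")
  )
  config <- utils::modifyList(cfg_defaults, config)
  for (p in c("vcf", "plots")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("config references missing file: ", config[[p]])
    }
  }
  if (is.null(config$sim) && (is.null(config$vcf) || is.null(config$plots))) {
    stop("config must either set 'sim' or provide 'vcf' and 'plots' paths")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  manifest <- list(seed = config$seed, stages = list())
  stamp <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    say("stage ", stage, " complete")
  }
  res <- list()
  seed <- as.integer(config$seed)

  ## --- simulate -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim) && "simulate" %in% config$stages) {
    sim_args <- if (is.list(config$sim)) config$sim else list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    panel <- simulate_panel(scfg)
    truth <- panel$truth
    config$vcf <- file.path(out_dir, "synthetic_genotypes.vcf")
    write_synthetic_vcf(panel$geno, config$vcf, scfg)
    config$plots <- file.path(out_dir, "synthetic_plots.csv")
    write_csv_seeded(panel$plots, config$plots, seed)
    if (is.null(config$scenarios)) {
      config$scenarios <- list(list(name = "seed_to_regrowth",
                                    train = scfg$env_names,
                                    test = scfg$rg_names))
    }
    if (is.null(config$unscored)) config$unscored <- scfg$unscored
    res$sim <- panel
    stamp("simulate", n_genotypes = nrow(panel$geno$dosage),
          n_markers = ncol(panel$geno$dosage),
          n_plots = nrow(panel$plots))
  }

  ## --- marker QC and relationship matrix ------------------------------
  if ("qc" %in% config$stages) {
    rv <- read_vcf(config$vcf)
    fv <- do.call(filter_variants, c(list(rv), config$qc))
    dm <- code_and_impute(fv)
    G <- compute_grm(dm)
    jsonlite::write_json(filter_report(fv),
                         file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_matrix_tsv(G, file.path(out_dir, "grm.tsv"))
    res$grm <- G
    stamp("qc", n_input = nrow(rv$variants),
          n_retained = nrow(fv$variants))
  } else {
    res$grm <- read_matrix_tsv(file.path(out_dir, "grm.tsv"))
  }

  ## --- phenotypes ------------------------------------------------------
  if ("pheno" %in% config$stages) {
    plots <- utils::read.csv(config$plots, comment.char = "#",
                             stringsAsFactors = FALSE)
    long <- phenotype_table(plots, combine = FALSE)
    long <- drop_unscored(long, config$unscored)
    seed_trials <- setdiff(unique(long$trial),
                           unlist(lapply(config$scenarios, `[[`, "test")))
    Y <- long_to_wide(long[long$trial %in% seed_trials, , drop = FALSE],
                      traits = unique(long$trait))
    write_csv_seeded(long, file.path(out_dir, "adjusted_means.csv"), seed)
    write_csv_seeded(cbind(genotype = rownames(Y), as.data.frame(Y)),
                     file.path(out_dir, "combined_phenotypes.csv"), seed)
    res$pheno_long <- long
    res$Y <- Y
    stamp("pheno", n_rows = nrow(long), n_genotypes = nrow(Y))
  }

  ## align phenotyped panel with the relationship matrix
  common <- intersect(rownames(res$Y), rownames(res$grm))
  Y <- res$Y[common, , drop = FALSE]
  K <- res$grm[common, common]

  ## --- full-panel fit --------------------------------------------------
  if ("fit" %in% config$stages) {
    fit <- mtgblup(Y, K, n_iter = config$chain$n_iter,
                   burn_in = config$chain$burn_in,
                   thin = config$chain$thin, seed = seed)
    gebv_df <- cbind(genotype = rownames(fit$gebv),
                     as.data.frame(fit$gebv))
    write_csv_seeded(gebv_df, file.path(out_dir, "gebv.csv"), seed)
    jsonlite::write_json(
      list(seed = seed, mu = fit$mu, h2 = fit$h2, h2_sd = fit$h2_sd,
           Sigma_g = fit$Sigma_g, Sigma_e = fit$Sigma_e, ess = fit$ess),
      file.path(out_dir, "posterior_summary.json"),
      auto_unbox = TRUE, digits = NA)
    res$fit <- fit
    stamp("fit", n = fit$n, n_kept = fit$n_kept)
  }

  ## --- Smith indices and ranking --------------------------------------
  if ("index" %in% config$stages && !is.null(res$fit)) {
    tm <- fit_target_metrics(res$fit, config$weights)
    ranked <- rank_candidates(res$fit$gebv, tm$alphas$GSI)
    write_csv_seeded(ranked, file.path(out_dir, "ranked_candidates.csv"),
                     seed)
    jsonlite::write_json(tm$metrics, file.path(out_dir, "indices.json"),
                         auto_unbox = TRUE, digits = NA)
    res$indices <- tm$metrics
    stamp("index", n_targets = nrow(tm$metrics))
  }

  ## --- repeated hold-out CV -------------------------------------------
  if ("cv" %in% config$stages) {
    strata <- if (!is.null(res$sim)) {
      res$sim$geno$subpop[match(common, rownames(res$sim$geno$dosage))]
    } else NULL
    splits <- make_splits(common, frac_test = config$cv$frac_test,
                          n_repeats = config$cv$n_repeats,
                          master_seed = seed, strata = strata)
    cv <- run_holdout(Y, K, splits, n_iter = config$cv$n_iter,
                      burn_in = config$cv$burn_in,
                      weights_mode = config$weights, verbose = verbose)
    write_csv_seeded(cv$rows, file.path(out_dir, "cv_rows.csv"), seed)
    jsonlite::write_json(summary(cv), file.path(out_dir,
                                                "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res$cv <- cv
    stamp("cv", n_repeats = config$cv$n_repeats,
          n_failed = length(cv$failed))
  }

  ## --- named scenarios -------------------------------------------------
  if ("scenario" %in% config$stages && length(config$scenarios)) {
    sc_res <- list()
    for (sc in config$scenarios) {
      r <- run_scenario(res$pheno_long, K, sc,
                        n_iter = config$cv$n_iter,
                        burn_in = config$cv$burn_in,
                        weights_mode = config$weights, seed = seed)
      sc_res[[sc$name]] <- r
      write_csv_seeded(r$rows,
                       file.path(out_dir,
                                 paste0("scenario_", sc$name, ".csv")),
                       seed)
    }
    res$scenarios <- sc_res
    stamp("scenario", n_scenarios = length(sc_res))
  }

  manifest$settings <- config[setdiff(names(config), "sim")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

drop_unscored <- function(long, unscored) {
  if (is.null(unscored)) return(long)
  for (tl in names(unscored)) {
    sel <- long$trial == tl & long$trait %in% unscored[[tl]]
    if (any(sel)) {
      message("dropping ", sum(sel), " rows: trait(s) ",
              paste(unscored[[tl]], collapse = ","),
              " unscored in trial ", tl)
      long <- long[!sel, , drop = FALSE]
    }
  }
  long
}

## CSV with a seed-stamped header comment, so every numeric output is
## traceable to the master seed
write_csv_seeded <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gsindex output; master seed ", seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
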