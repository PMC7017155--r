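#' Derive dry mass content and dry matter yield from plot measurements
#'
#' Field plots are machine chopped and weighed fresh; a subsample is weighed
#' wet and again after oven drying. The two derived traits are
#' \deqn{DMC\% = 100 \cdot dry/wet}
#' \deqn{DMY\ (t\,ha^{-1}) = 10 \cdot
#'   \frac{plot\_wet\_kg \cdot dry/wet}{plot\_area\_m^2}}
#'
#' @param plot_wet_kg total fresh plot weight in kg.
#' @param sample_wet_g subsample fresh weight in g.
#' @param sample_dry_g subsample oven-dry weight in g.
#' @param plot_area_m2 harvested plot area in square meters.
#' @return a data frame with columns `dmc` (percent) and `dmy` (t/ha).
#' @examples
#' derive_traits(60, 100, 25, 3.75)  # DMC 25%, DMY 40 t/ha
#' @export
derive_traits <- function(plot_wet_kg, sample_wet_g, sample_dry_g,
                          plot_area_m2) {
  n <- max(length(plot_wet_kg), length(sample_wet_g),
           length(sample_dry_g), length(plot_area_m2))
  plot_wet_kg <- rep_len(plot_wet_kg, n)
  sample_wet_g <- rep_len(sample_wet_g, n)
  sample_dry_g <- rep_len(sample_dry_g, n)
  plot_area_m2 <- rep_len(plot_area_m2, n)
  if (any(sample_wet_g <= 0, na.rm = TRUE)) {
    stop("sample wet weight must be positive")
  }
  if (any(plot_area_m2 <= 0, na.rm = TRUE)) {
    stop("plot area must be positive")
  }
  if (any(plot_wet_kg <= 0, na.rm = TRUE)) {
    stop("plot wet weight must be positive")
  }
  if (any(sample_dry_g > sample_wet_g, na.rm = TRUE)) {
    stop("sample dry weight exceeds wet weight")
  }
  if (any(sample_dry_g <= 0, na.rm = TRUE)) {
    stop("sample dry weight must be positive")
  }
  frac <- sample_dry_g / sample_wet_g
  data.frame(dmc = 100 * frac,
             dmy = 10 * plot_wet_kg * frac / plot_area_m2)
}

#' Federer adjusted means for an augmented RCBD trial
#'
#' In an augmented randomized complete block design the replicated checks
#' estimate additive block effects; unreplicated test entries are adjusted
#' by subtracting the block effect of the block they occur in. Block effect
#' = (mean of checks in block) - (grand mean of checks); adjusted check
#' values are the check means across blocks.
#'
#' @param plots data frame with columns `genotype`, `block`, `is_check`
#'   (logical) and the trait value column named by `trait`.
#' @param trait name of the value column to adjust.
#' @return data frame (`genotype`, `value`, `is_check`) of adjusted means,
#'   one row per genotype, with an `adjustment_report` attribute carrying
#'   the per-block effects and the check coefficient of variation.
#' @export
adjust_augmented <- function(plots, trait = "value") {
  stopifnot(is.data.frame(plots),
            all(c("genotype", "block", "is_check", trait) %in% names(plots)))
  y <- plots[[trait]]
  blocks <- sort(unique(plots$block))
  checks <- unique(plots$genotype[plots$is_check])
  if (length(checks) == 0L) stop("trial contains no check plots")
  ## every check must appear in every block
  for (b in blocks) {
    present <- plots$genotype[plots$is_check & plots$block == b]
    miss <- setdiff(checks, present)
    if (length(miss)) {
      stop("block '", b, "' is missing check(s): ",
           paste(miss, collapse = ", "))
    }
  }
  entries <- plots[!plots$is_check, , drop = FALSE]
  if (anyDuplicated(entries$genotype)) {
    dup <- unique(entries$genotype[duplicated(entries$genotype)])
    stop("test entries replicated within trial: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  chk <- plots[plots$is_check, , drop = FALSE]
  grand <- mean(chk[[trait]])
  b_eff <- tapply(chk[[trait]], chk$block, mean) - grand
  adj_entries <- data.frame(
    genotype = entries$genotype,
    value = entries[[trait]] - b_eff[as.character(entries$block)],
    is_check = FALSE,
    stringsAsFactors = FALSE
  )
  adj_checks <- data.frame(
    genotype = checks,
    value = as.numeric(tapply(chk[[trait]], chk$genotype, mean)[checks]),
    is_check = TRUE,
    stringsAsFactors = FALSE
  )
  out <- rbind(adj_entries, adj_checks)
  rownames(out) <- NULL
  check_cv <- 100 * stats::sd(chk[[trait]]) / abs(grand)
  attr(out, "adjustment_report") <- list(
    block_effects = b_eff,
    check_grand_mean = grand,
    check_cv_percent = check_cv,
    n_check_plots = nrow(chk)
  )
  out
}

#' Combine adjusted trial means across environments
#'
#' Fits the two-way model `y_ik = mu + G_i + E_k + (GE + e)_ik` on adjusted
#' means, with fixed environment effects (environment means, centered) and
#' random genotype effects. Genotype values are shrunken means of the
#' environment-centered data, shrinkage `k_i = s2_g / (s2_g + s2_res/n_i)`
#' with variance components from an unbalanced one-way ANOVA
#' method-of-moments (floored at zero); GE interaction is absorbed into the
#' residual because unreplicated entries confound the two. Results are
#' returned on the original trait scale (`mu +` effect).
#'
#' @param adj data frame with columns `genotype`, `trial`, `value`
#'   (adjusted means; `NA` rows dropped).
#' @param shrink return shrunken genotype predictions (default) or plain
#'   environment-centered genotype means.
#' @return data frame (`genotype`, `value`, `n_env`) with a `varcomp`
#'   attribute (`sigma2_g`, `sigma2_res`, `mu`, environment effects).
#' @export
combine_trials <- function(adj, shrink = TRUE) {
  stopifnot(is.data.frame(adj),
            all(c("genotype", "trial", "value") %in% names(adj)))
  adj <- adj[!is.na(adj$value), , drop = FALSE]
  if (nrow(adj) == 0L) stop("no non-missing observations to combine")
  mu <- mean(adj$value)
  env_mean <- tapply(adj$value, adj$trial, mean)
  env_eff <- env_mean - mean(env_mean)
  centered <- adj$value - env_mean[as.character(adj$trial)]

  g <- factor(adj$genotype)
  n_i <- tabulate(g)
  means_i <- tapply(centered, g, mean)
  N <- length(centered)
  n_groups <- nlevels(g)

  if (N > n_groups) {
    ssw <- sum((centered - means_i[g])^2)
    s2_res <- ssw / (N - n_groups)
  } else {
    s2_res <- NA_real_  # single observation per genotype: undefined
  }
  if (n_groups > 1L) {
    ssb <- sum(n_i * (means_i - mean(centered))^2)
    msb <- ssb / (n_groups - 1L)
    n0 <- (N - sum(n_i^2) / N) / (n_groups - 1L)
    s2_g <- if (is.na(s2_res) || n0 <= 0) stats::var(as.numeric(means_i))
            else max(0, (msb - s2_res) / n0)
  } else {
    s2_g <- NA_real_
  }

  if (shrink && !is.na(s2_res) && !is.na(s2_g) && (s2_g + s2_res) > 0) {
    k_i <- s2_g / (s2_g + s2_res / n_i)
    eff <- k_i * as.numeric(means_i)
  } else {
    eff <- as.numeric(means_i)
  }
  out <- data.frame(genotype = levels(g), value = mu + eff, n_env = n_i,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "varcomp") <- list(sigma2_g = s2_g, sigma2_res = s2_res,
                               mu = mu, env_effects = env_eff,
                               shrunk = shrink)
  out
}

#' Build a genotype x trait phenotype matrix from plot data
#'
#' Convenience wrapper running [derive_traits()] where raw plot masses are
#' present, [adjust_augmented()] within each trial, and [combine_trials()]
#' across trials, for each trait in turn. Trials in which a trait was not
#' scored (all `NA`) are skipped for that trait with a message. Checks are
#' used for adjustment and then dropped from the output.
#'
#' @param plots plot-level data frame with columns `trial`, `block`,
#'   `genotype`, `is_check`, `plot_wet_kg`, `sample_wet_g`, `sample_dry_g`,
#'   `plant_height_cm`, `plot_area_m2`.
#' @param traits traits to extract; subset of `c("DMY", "PH", "DMC")`.
#' @param trials optional subset of trials to use.
#' @param shrink passed to [combine_trials()].
#' @param combine combine across trials (default); if `FALSE`, returns the
#'   long adjusted-means table (`genotype`, `trial`, `trait`, `value`).
#' @return a numeric genotype x trait matrix (combined values), or a long
#'   data frame when `combine = FALSE`.
#' @export
phenotype_table <- function(plots, traits = c("DMY", "PH", "DMC"),
                            trials = NULL, shrink = TRUE, combine = TRUE) {
  if (!is.null(trials)) {
    plots <- plots[plots$trial %in% trials, , drop = FALSE]
    if (nrow(plots) == 0L) stop("no plots left after trial subset")
  }
  der <- derive_traits(plots$plot_wet_kg, plots$sample_wet_g,
                       plots$sample_dry_g, plots$plot_area_m2)
  tr_val <- list(DMY = der$dmy, PH = plots$plant_height_cm, DMC = der$dmc)
  long <- NULL
  for (tr in traits) {
    v <- tr_val[[tr]]
    for (tl in unique(plots$trial)) {
      sel <- plots$trial == tl
      if (all(is.na(v[sel]))) {
        message("trait ", tr, " not scored in trial ", tl, "; skipped")
        next
      }
      sub <- data.frame(genotype = plots$genotype[sel],
                        block = plots$block[sel],
                        is_check = plots$is_check[sel],
                        value = v[sel], stringsAsFactors = FALSE)
      a <- adjust_augmented(sub, "value")
      a <- a[!a$is_check, , drop = FALSE]
      long <- rbind(long, data.frame(genotype = a$genotype, trial = tl,
                                     trait = tr, value = a$value,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(long)) stop("no trait was scored in any requested trial")
  if (!combine) return(long)
  genos <- sort(unique(long$genotype))
  Y <- matrix(NA_real_, length(genos), length(traits),
              dimnames = list(genos, traits))
  for (tr in traits) {
    sub <- long[long$trait == tr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    cmb <- combine_trials(sub, shrink = shrink)
    Y[cmb$genotype, tr] <- cmb$value
  }
  Y
}
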