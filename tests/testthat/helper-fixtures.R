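# Fixtures are built in code at test time; nothing binary is stored.

## a 3-sample, 5-record toy VCF exercising every filter criterion:
## one triallelic, one low-MAF, one high-missingness, one low-QUAL,
## one clean record
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1", "S2", "S3", "S4", "S5",
            "S6", "S7", "S8", "S9", "S10"), collapse = "\t"),
    ## triallelic (fails biallelic)
    paste(c("1", "100", "tri", "A", "C,G", "90", ".", ".", "GT",
            rep("0/1", 10)), collapse = "\t"),
    ## monomorphic: MAF 0 < 0.05 (fails MAF; one het would already be
    ## exactly 0.05 and inclusively retained)
    paste(c("1", "200", "rare", "A", "C", "80", ".", ".", "GT",
            rep("0/0", 10)), collapse = "\t"),
    ## 3 of 10 missing = 30% > 20% (fails missingness)
    paste(c("1", "300", "gappy", "A", "C", "70", ".", ".", "GT",
            "./.", "./.", "./.", "0/1", "1/1", "0/1", "1/1", "0/1",
            "0/0", "0/0"), collapse = "\t"),
    ## QUAL 30 < 40 (fails quality)
    paste(c("1", "400", "lowq", "A", "C", "30", ".", ".", "GT",
            "0/1", "1/1", "0/0", "0/1", "0/0", "1/1", "0/1", "0/0",
            "0/1", "1/1"), collapse = "\t"),
    ## clean
    paste(c("1", "500", "clean", "A", "C", "95", ".", ".", "GT",
            "0/0", "0/1", "1/1", "0/1", "0/0", "0/1", "1/1", "0/0",
            "0/1", "0/0"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

## small structured panel + truth + trials for fast end-to-end tests
quick_cfg <- function(seed = 11, m = 500, ...) {
  sim_config(seed = seed, n_sb = 60, n_sh = 63, sb_families = 10,
             sh_families = 9, m = m, ...)
}

## random positive-definite covariance set with t measured = t target
random_cov_set <- function(t) {
  A <- matrix(rnorm(t * t), t)
  Gx <- crossprod(A) + diag(0.1, t)
  B <- matrix(rnorm(t * t), t)
  Pe <- crossprod(B) + diag(0.1, t)
  cov_set(Gx = Gx, Px = Gx + Pe)
}

## tiny GBLUP panel with HWE markers
hwe_panel <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  W <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m, byrow = FALSE)
  rownames(W) <- sprintf("G%03d", seq_len(n))
  W
}
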