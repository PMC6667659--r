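# Shared fixtures and independent oracles, built in code.

# Simulation config matching the canonical in-silico experiment: Poisson
# depth around 100x, 0.5% read error.
poisson_config <- function(ploidy, snps, seed, mean_depth = 100,
                           error_rate = 0.005, ...) {
  sim_config(ploidy = ploidy, n_genes = as.integer(ceiling(snps / 20)),
             snps_per_gene = 20L, mean_depth = mean_depth,
             depth_dispersion = Inf, error_rate = error_rate, seed = seed,
             ...)
}

filtered_freqs <- function(sites, min_depth = 10, threshold = 0.2) {
  noise_filter(allele_frequencies(sites, min_depth), threshold)
}

# Independent oracle for the fixed-mean mixture likelihood: direct
# evaluation of the truncated-mixture log-likelihood over a dense grid of
# the only free parameter (the shared sd), bypassing EM entirely.
oracle_fixed_logL <- function(x, means, weights, lower = 0.2,
                              upper = 1 - lower,
                              sd_grid = exp(seq(log(1e-3), log(0.3),
                                                length.out = 4000))) {
  ll <- vapply(sd_grid, function(s) {
    dens <- rep(0, length(x))
    for (k in seq_along(means)) {
      z <- pnorm(upper, means[k], s) - pnorm(lower, means[k], s)
      dens <- dens + weights[k] * dnorm(x, means[k], s) / max(z, 1e-12)
    }
    dens[dens < .Machine$double.xmin] <- .Machine$double.xmin
    sum(log(dens))
  }, numeric(1))
  max(ll)
}

# Brute-force enumeration of allelic-ratio classes: every split of k genome
# copies into (j, k - j), deduplicated by the unordered ratio.
oracle_ratio_classes <- function(k) {
  j <- seq_len(k - 1)
  ratio <- pmax(j, k - j) / pmin(j, k - j)
  minor <- pmin(j, k - j) / k
  unique(data.frame(ratio = ratio, minor_freq = minor))
}

# Closed-form OLS of y on x (slope, intercept SE, R2, SSR).
oracle_ols <- function(y, x) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  ssr <- sum(res^2)
  se <- sqrt(ssr / (length(y) - 2) / sum((x - mean(x))^2))
  r2 <- 1 - ssr / sum((y - mean(y))^2)
  list(slope = b, SE = se, R2 = r2, SSR = ssr)
}

# Minimal single-sample VCF text with AD, including records every reader
# must skip.
fixture_vcf <- function(path, sample = "S1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=gene0001,length=2000>",
    "##contig=<ID=gene0002,length=2000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    paste("gene0001", "150", ".", "A", "G", "50", "PASS", ".", "GT:AD",
          "0/1:30,30", sep = "\t"),
    paste("gene0001", "300", ".", "C", "A,T", "50", "PASS", ".", "GT:AD",
          "1/2:10,20,30", sep = "\t"),                       # multiallelic
    paste("gene0001", "450", ".", "CT", "C", "50", "PASS", ".", "GT:AD",
          "0/1:25,25", sep = "\t"),                          # indel
    paste("gene0002", "120", ".", "G", "T", "50", "PASS", ".", "GT:AD",
          "0/1:75,25", sep = "\t"),
    paste("gene0002", "240", ".", "T", "C", "50", "PASS", ".", "GT",
          "0/1", sep = "\t")                                 # no AD value
  ), path)
  path
}
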