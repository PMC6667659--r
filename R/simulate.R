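#' Simulation settings for synthetic allele-depth data
#'
#' Builds a validated configuration for [simulate_sample()]. The defaults
#' describe a realistic target-capture experiment: a few thousand
#' heterozygous SNPs spread over a few hundred captured genes, a mean
#' coverage of 100 reads with negative-binomial overdispersion (capture
#' efficiency varies widely between loci and libraries), and a 0.5% chance
#' that a read reports the wrong allele.
#'
#' At a heterozygous site in a genome of ploidy `k`, the alternate allele is
#' present in `j` of the `k` homologous copies (`j` in `1..k-1`), so reads
#' sample it with probability `j/k`. `dosage_weights` gives the probability
#' of each dosage class `j = 1..k-1`; the default is uniform, i.e. every
#' allele configuration is equally likely.
#'
#' @param ploidy Integer number of genome copies, at least 2.
#' @param n_genes Number of captured genes.
#' @param snps_per_gene Heterozygous SNPs per gene.
#' @param mean_depth Mean read depth per site.
#' @param depth_dispersion Negative-binomial size parameter; site depth has
#'   variance `mean + mean^2/dispersion`. Use `Inf` for Poisson depths.
#' @param error_rate Per-read probability of reporting the wrong allele;
#'   must be below 0.1.
#' @param dosage_weights Probability vector over dosage classes `1..ploidy-1`
#'   (recycled from `NULL` to uniform). Need not be normalized.
#' @param sample_id Sample name written into the output.
#' @param seed Integer seed; the whole draw is deterministic given the
#'   configuration.
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_sample()], [simulate_autopolyploid()]
#' @export
sim_config <- function(ploidy = 2L, n_genes = 100L, snps_per_gene = 20L,
                       mean_depth = 100, depth_dispersion = 5,
                       error_rate = 0.005, dosage_weights = NULL,
                       sample_id = sprintf("sim_%dx", ploidy), seed = 1L) {
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 2L) {
    stop_input("'ploidy' must be an integer >= 2")
  }
  if (mean_depth < 1) stop_input("'mean_depth' must be >= 1")
  if (!is.numeric(depth_dispersion) || depth_dispersion <= 0) {
    stop_input("'depth_dispersion' must be positive (Inf for Poisson)")
  }
  if (error_rate < 0 || error_rate >= 0.1) {
    stop_input("'error_rate' must be in [0, 0.1)")
  }
  n_classes <- ploidy - 1L
  if (is.null(dosage_weights)) {
    dosage_weights <- rep(1 / n_classes, n_classes)
  }
  if (length(dosage_weights) != n_classes || any(dosage_weights < 0) ||
      sum(dosage_weights) <= 0) {
    stop_input("'dosage_weights' must be ", n_classes,
               " non-negative values with positive sum")
  }
  dosage_weights <- dosage_weights / sum(dosage_weights)
  structure(list(
    ploidy = ploidy,
    n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    dosage_weights = dosage_weights,
    sample_id = sample_id,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate per-site allele depths for a sample of known ploidy
#'
#' Draws `n_genes * snps_per_gene` heterozygous biallelic SNPs. For each
#' site: a dosage class `j` is drawn from `dosage_weights`, a read depth `d`
#' from a negative-binomial (or Poisson) law truncated below at 1, and the
#' alternate-allele read count from a binomial with success probability
#' `j/k` perturbed by the symmetric error model (a read flips allele with
#' probability `error_rate`). Ref/alt labelling is randomized per site so
#' the data carry no orientation signal, exactly as variant callers emit
#' them.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of allele-depth sites (columns `sample_id`,
#'   `gene_id`, `chrom`, `pos`, `ref_count`, `alt_count`) with the
#'   generating truth attached as `attr(x, "truth")`: per site the dosage of
#'   the alternate allele and its expected read frequency.
#' @examples
#' sites <- simulate_sample(sim_config(ploidy = 3, seed = 42))
#' head(sites)
#' head(attr(sites, "truth"))
#' @export
simulate_sample <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_input("'config' must be created by sim_config()")
  }
  with_seed(config$seed, {
    k <- config$ploidy
    n <- config$n_genes * config$snps_per_gene
    if (n < 1L) stop_input("configuration yields zero sites")
    gene_id <- rep(sprintf("gene%04d", seq_len(config$n_genes)),
                   each = config$snps_per_gene)
    pos <- rep(seq_len(config$snps_per_gene) * 10L, times = config$n_genes)

    j <- sample.int(k - 1L, n, replace = TRUE, prob = config$dosage_weights)
    depth <- if (is.finite(config$depth_dispersion)) {
      stats::rnbinom(n, mu = config$mean_depth, size = config$depth_dispersion)
    } else {
      stats::rpois(n, config$mean_depth)
    }
    depth <- pmax(depth, 1L)
    e <- config$error_rate
    p_read <- (j / k) * (1 - e) + (1 - j / k) * e
    a_count <- stats::rbinom(n, depth, p_read)

    # random ref/alt orientation: allele A becomes the alternate allele with
    # probability 1/2, otherwise the reference.
    flip <- stats::runif(n) < 0.5
    alt_count <- ifelse(flip, depth - a_count, a_count)
    dosage_alt <- ifelse(flip, k - j, j)

    sites <- data.frame(
      sample_id = config$sample_id,
      gene_id = gene_id,
      chrom = gene_id,
      pos = pos,
      ref_count = as.integer(depth - alt_count),
      alt_count = as.integer(alt_count),
      stringsAsFactors = FALSE
    )
    attr(sites, "truth") <- data.frame(
      gene_id = gene_id,
      pos = pos,
      dosage = as.integer(dosage_alt),
      true_freq = dosage_alt / k,
      stringsAsFactors = FALSE
    )
    sites
  })
}

#' Simulate a recent autopolyploid
#'
#' A freshly doubled genome still carries both ancestral alleles in equal
#' copy number at most heterozygous sites, so the balanced dosage class
#' `j = k/2` dominates (e.g. 2:2 rather than 3:1 in a tetraploid). This
#' wrapper overrides `dosage_weights` so the balanced class has probability
#' `balanced_fraction` and the remainder is spread uniformly over the other
#' classes, then delegates to [simulate_sample()].
#'
#' @param config A [sim_config()] object with even `ploidy`.
#' @param balanced_fraction Probability mass on the balanced class, in (0, 1].
#' @return As [simulate_sample()].
#' @export
simulate_autopolyploid <- function(config, balanced_fraction = 0.8) {
  if (!inherits(config, "sim_config")) {
    stop_input("'config' must be created by sim_config()")
  }
  if (config$ploidy %% 2L != 0L) {
    stop_input("autopolyploid simulation requires an even ploidy")
  }
  if (!is.numeric(balanced_fraction) || balanced_fraction <= 0 ||
      balanced_fraction > 1) {
    stop_input("'balanced_fraction' must be in (0, 1]")
  }
  k <- config$ploidy
  w <- if (k == 2L) 1 else rep((1 - balanced_fraction) / (k - 2L), k - 1L)
  w[k / 2L] <- balanced_fraction
  config$dosage_weights <- w / sum(w)
  simulate_sample(config)
}
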