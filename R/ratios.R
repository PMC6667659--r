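# Per-SNP allelic-ratio analytics.
#
# The allelic ratio — reads of the more frequent allele over reads of the
# less frequent — folds the mirrored frequency axis in half: a diploid
# clusters around 1 (1:1), a tetraploid around 1 (2:2) and 3 (3:1), a
# hexaploid around 1, 2 and 5. Because the ratio grows without bound as the
# minor frequency approaches the noise threshold, it separates ploidy
# classes that the bounded frequency axis squeezes together, and its median
# gives a one-number polyploidy indicator.

#' Per-SNP allelic ratios
#'
#' @param sites Data frame of allele-depth sites that already passed the
#'   noise filter (so both counts are positive).
#' @return `sites` with a `ratio` column appended:
#'   `max(ref, alt) / min(ref, alt)`, always >= 1; input order preserved.
#' @export
snp_ratios <- function(sites) {
  check_sites(sites)
  mn <- pmin(sites$ref_count, sites$alt_count)
  if (any(mn == 0)) {
    stop("internal contract violated: zero minor count reached snp_ratios(); ",
         "apply the noise filter first")
  }
  sites$ratio <- pmax(sites$ref_count, sites$alt_count) / mn
  sites
}

ratio_summary_row <- function(ratio, sample_id = NA_character_,
                              gene_id = NA_character_) {
  q <- stats::quantile(ratio, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(
    sample_id = sample_id,
    gene_id = gene_id,
    n = length(ratio),
    median_M = q[2],
    q1 = q[1],
    q3 = q[3],
    pct_below_2 = 100 * mean(ratio < 2),
    stringsAsFactors = FALSE
  )
}

#' Summarize allelic ratios per sample (and optionally per gene)
#'
#' Median ("M"), quartiles (linear-interpolation rule, R type 7) and the
#' percentage of SNPs with ratio below 2 — the statistics that separate
#' diploid-like from polyploid samples and expose recent autopolyploids.
#'
#' @param sites Output of [snp_ratios()].
#' @param by_gene If `TRUE`, also return one summary row per gene (rows with
#'   a missing gene are skipped for the per-gene table but kept in the
#'   sample-level row).
#' @return A data frame; the first row is the sample-level summary
#'   (`gene_id` NA), followed by per-gene rows when requested.
#' @export
summarize_ratios <- function(sites, by_gene = FALSE) {
  if (is.null(sites$ratio)) stop_input("'sites' must come from snp_ratios()")
  if (nrow(sites) < 1L) stop_input("no ratios to summarize")
  sid <- if (!is.null(sites$sample_id)) sites$sample_id[1] else NA_character_
  out <- ratio_summary_row(sites$ratio, sid)
  if (by_gene && !is.null(sites$gene_id)) {
    ok <- !is.na(sites$gene_id)
    per_gene <- lapply(split(sites$ratio[ok], sites$gene_id[ok]),
                       ratio_summary_row, sample_id = sid)
    for (g in names(per_gene)) per_gene[[g]]$gene_id <- g
    out <- rbind(out, do.call(rbind, per_gene))
    rownames(out) <- NULL
  }
  out
}

#' Expected allelic-ratio classes for a given ploidy
#'
#' Enumerates every dosage split of a heterozygous site in a genome of
#' ploidy `k`: the minor allele occupies `j` of the `k` copies
#' (`j = 1..floor(k/2)`), giving an expected ratio `(k - j)/j` at minor
#' frequency `j/k`. A class is detectable only when its minor frequency
#' reaches the sequencing-noise threshold — e.g. the hexaploid 5:1 class at
#' minor frequency 1/6 is shadowed by noise at the default 0.2 cutoff,
#' which is why ploidy above 4x cannot be pinned down exactly.
#'
#' @param ploidy_k Ploidy level, between 2 and `max_k`.
#' @param threshold Noise threshold on the minor frequency (default 0.2).
#' @param max_k Largest supported ploidy (default 16).
#' @return Data frame with one row per class: `ploidy_k`, `dosage_j`,
#'   `ratio`, `minor_freq`, `detectable`; ratios strictly decreasing in `j`.
#' @examples
#' expected_ratio_classes(6)   # ratios 5, 2, 1; the 5:1 class is shadowed
#' @export
expected_ratio_classes <- function(ploidy_k, threshold = 0.2, max_k = 16L) {
  if (length(ploidy_k) != 1L || is.na(ploidy_k) ||
      ploidy_k < 2 || ploidy_k > max_k || ploidy_k != round(ploidy_k)) {
    stop_input("'ploidy_k' must be an integer between 2 and ", max_k)
  }
  k <- as.integer(ploidy_k)
  j <- seq_len(k %/% 2L)
  data.frame(
    ploidy_k = k,
    dosage_j = j,
    ratio = (k - j) / j,
    minor_freq = j / k,
    detectable = j / k >= threshold,
    stringsAsFactors = FALSE
  )
}

#' Bootstrap density envelope from a diploid reference
#'
#' Resamples a known diploid's allelic ratios with replacement `n_boot`
#' times, evaluates a Gaussian kernel density (Silverman's bandwidth) for
#' each replicate on a shared grid, and stores the per-point mean and
#' standard deviation. A query sample whose ratio density rises above
#' `mean + 2 sd` carries peaks a diploid does not produce — evidence for
#' higher ploidy.
#'
#' @param ratio Numeric vector of allelic ratios from a known diploid
#'   (at least 2 distinct values).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the envelope is deterministic given it.
#' @param grid_points Number of grid points (default 512) spanning 1 to the
#'   99.5th percentile of the reference ratios plus 1.
#' @return A list of class `"density_envelope"`: `grid`, `mean_density`,
#'   `sd`, `n_boot`. Each replicate's density is renormalized to unit mass
#'   on the grid, so `mean_density` integrates to 1.
#' @export
bootstrap_density_envelope <- function(ratio, n_boot = 1000L, seed = 1L,
                                       grid_points = 512L) {
  ratio <- as.numeric(ratio)
  if (length(unique(ratio)) < 2L) {
    stop_input("degenerate reference: need at least 2 distinct ratio values")
  }
  if (n_boot < 1L) stop_input("'n_boot' must be >= 1")
  lo <- 1
  hi <- stats::quantile(ratio, 0.995, names = FALSE) + 1
  grid <- seq(lo, hi, length.out = grid_points)
  step <- grid[2] - grid[1]
  with_seed(seed, {
    acc <- matrix(0, nrow = grid_points, ncol = 2)  # sum, sum of squares
    n <- length(ratio)
    for (b in seq_len(n_boot)) {
      res <- ratio[sample.int(n, n, replace = TRUE)]
      d <- stats::density(res, bw = "nrd0", from = lo, to = hi,
                          n = grid_points)$y
      d <- d / (sum(d) * step)  # unit mass on the grid
      acc[, 1] <- acc[, 1] + d
      acc[, 2] <- acc[, 2] + d^2
    }
    m <- acc[, 1] / n_boot
    v <- pmax(acc[, 2] / n_boot - m^2, 0)
    structure(list(grid = grid, mean_density = m, sd = sqrt(v),
                   n_boot = as.integer(n_boot)),
              class = "density_envelope")
  })
}

#' Classify a sample from its allelic-ratio statistics
#'
#' Applies the empirical separation between cytotypes: samples with median
#' allelic ratio below 2 behave like diploids, samples at or above 2 like
#' polyploids (tetraploid or higher; the exact level above 4x is shadowed
#' by the noise filter). Two situations flag a possible recent
#' autopolyploid, whose balanced dosage mimics a diploid on the ratio axis:
#' a sub-2 median combined with a tetraploid mixture call, or a percentage
#' of ratios below 2 inside the 50-65% band (diploids sit clearly above
#' 65%, established polyploids clearly below 50%).
#'
#' @param summary One-row sample-level summary from [summarize_ratios()].
#' @param gene_summaries Optional per-gene summary rows; the fraction of
#'   genes with median >= 2 is reported as supporting evidence.
#' @param envelope Optional [bootstrap_density_envelope()] from a diploid
#'   reference; grid points where this sample's ratio density exceeds
#'   `mean + envelope_mult * sd` are reported as extra-peak evidence.
#' @param ratio Sample's ratio vector; required when `envelope` is given.
#' @param mixture_call Optional call from the mixture stage, used for the
#'   autopolyploid flag.
#' @param envelope_mult Envelope exceedance multiplier (default 2).
#' @param min_snps Below this many ratios the class is `"ambiguous"`
#'   (default 100).
#' @return A list of class `"ratio_class"`: `class` (one of `diploid-like`,
#'   `polyploid`, `possible-recent-autopolyploid`, `ambiguous`), `flags`,
#'   `median_M`, `pct_below_2`, `pct_genes_median_ge2`, `extra_peaks`.
#' @export
classify_by_ratios <- function(summary, gene_summaries = NULL,
                               envelope = NULL, ratio = NULL,
                               mixture_call = NULL, envelope_mult = 2,
                               min_snps = 100L) {
  if (is.null(summary$median_M)) {
    stop_input("'summary' must be a row from summarize_ratios()")
  }
  m <- summary$median_M[1]
  p2 <- summary$pct_below_2[1]
  flags <- character(0)
  if (summary$n[1] < min_snps) {
    cls <- "ambiguous"
    flags <- c(flags, sprintf("too few SNPs for ratio classification (%d)",
                              summary$n[1]))
  } else if (m < 2) {
    cls <- "diploid-like"
    if (!is.null(mixture_call) && identical(mixture_call, "tetraploid")) {
      cls <- "possible-recent-autopolyploid"
      flags <- c(flags, "median < 2 but mixture model calls tetraploid")
    } else if (p2 >= 50 && p2 <= 65) {
      cls <- "possible-recent-autopolyploid"
      flags <- c(flags, sprintf("pct of ratios < 2 in the 50-65%% band (%.1f%%)",
                                p2))
    }
  } else {
    cls <- "polyploid"
    if (m == 2) flags <- c(flags, "median exactly 2; boundary call")
    if (p2 >= 50 && p2 <= 65) {
      flags <- c(flags, sprintf("pct of ratios < 2 in the 50-65%% band (%.1f%%)",
                                p2))
    }
  }
  pct_genes <- NA_real_
  if (!is.null(gene_summaries) && nrow(gene_summaries) > 0L) {
    pct_genes <- 100 * mean(gene_summaries$median_M >= 2)
  }
  extra <- NULL
  if (!is.null(envelope)) {
    if (is.null(ratio)) {
      stop_input("'ratio' values are required when an envelope is supplied")
    }
    d <- stats::density(ratio, bw = "nrd0", from = min(envelope$grid),
                        to = max(envelope$grid), n = length(envelope$grid))$y
    step <- envelope$grid[2] - envelope$grid[1]
    d <- d / (sum(d) * step)
    over <- d > envelope$mean_density + envelope_mult * envelope$sd
    extra <- data.frame(grid = envelope$grid[over], density = d[over],
                        limit = (envelope$mean_density +
                                 envelope_mult * envelope$sd)[over])
    if (nrow(extra) > 0L && cls != "diploid-like") {
      flags <- c(flags, "density exceeds diploid bootstrap envelope")
    } else if (nrow(extra) > 0L) {
      flags <- c(flags, "extra ratio peaks above diploid envelope")
    }
  }
  structure(list(class = cls, flags = flags, median_M = m, pct_below_2 = p2,
                 pct_genes_median_ge2 = pct_genes, extra_peaks = extra),
            class = "ratio_class")
}

#' @export
print.ratio_class <- function(x, ...) {
  cat(sprintf("Allelic-ratio class: %s (median M = %.3f, %.1f%% of ratios < 2)\n",
              x$class, x$median_M, x$pct_below_2))
  for (f in x$flags) cat(" -", f, "\n")
  invisible(x)
}
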