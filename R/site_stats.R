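#' Convert allele depths to allele-frequency observations
#'
#' Each biallelic site with total depth at least `min_depth` yields one
#' observation: the minor-allele read frequency
#' `min(ref, alt) / (ref + alt)` together with its mirrored complement.
#' Sites below the depth floor are dropped and counted in the
#' `"n_depth_filtered"` attribute.
#'
#' @param sites Data frame of allele-depth sites with at least `ref_count`
#'   and `alt_count` columns (see [read_allele_depths()] or
#'   [simulate_sample()]).
#' @param min_depth Minimum total reads per site (default 10). Target-capture
#'   coverage is typically far higher; the floor guards against the tail of
#'   poorly captured positions where a frequency from a handful of reads is
#'   meaningless.
#' @return `sites` restricted to retained rows, with numeric columns
#'   `minor_freq` and `major_freq` appended (`minor_freq + major_freq == 1`);
#'   attribute `n_depth_filtered` counts exclusions.
#' @export
allele_frequencies <- function(sites, min_depth = 10L) {
  if (min_depth < 1) stop_input("'min_depth' must be >= 1")
  check_sites(sites)
  depth <- sites$ref_count + sites$alt_count
  keep <- depth >= min_depth
  out <- sites[keep, , drop = FALSE]
  d <- depth[keep]
  out$minor_freq <- pmin(out$ref_count, out$alt_count) / d
  out$major_freq <- 1 - out$minor_freq
  rownames(out) <- NULL
  attr(out, "n_depth_filtered") <- sum(!keep)
  out
}

#' Remove low-frequency observations as sequencing noise
#'
#' Minor-allele frequencies below the threshold cannot be distinguished from
#' frequencies created by sequencing errors, so every observation with
#' `minor_freq < threshold` is discarded before model fitting. The filter is
#' idempotent; an observation at exactly the threshold is kept.
#'
#' @param freqs Output of [allele_frequencies()].
#' @param threshold Minor-frequency cutoff in (0, 0.5); default 0.2.
#' @return The retained rows; attribute `n_noise_filtered` counts removals.
#' @export
noise_filter <- function(freqs, threshold = 0.2) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 0.5) {
    stop_input("'threshold' must lie strictly between 0 and 0.5")
  }
  if (is.null(freqs$minor_freq)) {
    stop_input("'freqs' must come from allele_frequencies()")
  }
  keep <- freqs$minor_freq >= threshold
  out <- freqs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_depth_filtered") <- attr(freqs, "n_depth_filtered")
  attr(out, "n_noise_filtered") <- sum(!keep)
  out
}

#' Mirrored frequency values for mixture fitting
#'
#' The fitted distributions are symmetric around 0.5 (every site contributes
#' an allele at frequency f and its partner at 1 - f), so each observation
#' enters the likelihood and the histograms twice, once per orientation.
#'
#' @param freqs Output of [allele_frequencies()] / [noise_filter()].
#' @return Numeric vector of length `2 * nrow(freqs)`.
#' @export
mirrored_freqs <- function(freqs) {
  if (is.null(freqs$minor_freq)) {
    stop_input("'freqs' must come from allele_frequencies()")
  }
  c(freqs$minor_freq, freqs$major_freq)
}

#' Percent polymorphic sites (relative heterozygosity)
#'
#' The heterozygosity proxy used to judge whether a sample carries enough
#' signal for ploidy calling: SNP positions as a percentage of the total
#' recovered target bases. Samples below the reliability floor tend to defeat
#' allele-balance methods (too few heterozygous sites shape the frequency
#' distribution), so their mixture calls are downgraded.
#'
#' @param snp_count Number of SNP positions retained for the sample.
#' @param total_bp Total recovered target length in base pairs (> 0).
#' @param reliability_floor Percentage below which the sample is flagged
#'   unreliable; default 0.50.
#' @param sample_id Optional sample name carried into the summary.
#' @return A list of class `"het_summary"` with fields `sample_id`,
#'   `snp_count`, `total_bp`, `pct_polymorphic` and `reliable`.
#' @examples
#' percent_polymorphic(1370, 100000)  # 1.37%
#' @export
percent_polymorphic <- function(snp_count, total_bp, reliability_floor = 0.50,
                                sample_id = NA_character_) {
  if (length(total_bp) != 1L || is.na(total_bp) || total_bp <= 0) {
    stop_input("'total_bp' must be a single positive number")
  }
  if (length(snp_count) != 1L || is.na(snp_count) || snp_count < 0) {
    stop_input("'snp_count' must be a single non-negative number")
  }
  pct <- 100 * snp_count / total_bp
  structure(list(
    sample_id = sample_id,
    snp_count = as.integer(snp_count),
    total_bp = as.numeric(total_bp),
    pct_polymorphic = pct,
    reliable = pct >= reliability_floor
  ), class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat(sprintf("Percent polymorphic sites: %.4f%% (%d SNPs / %g bp) - %s\n",
              x$pct_polymorphic, x$snp_count, x$total_bp,
              if (x$reliable) "reliable" else "below reliability floor"))
  invisible(x)
}
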