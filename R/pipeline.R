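#' Fit the ploidy model to one sample's allele depths
#'
#' The central estimator. Runs the full per-sample analysis in order:
#' allele frequencies with a depth floor, the sequencing-noise filter,
#' fixed-mean mixture fits (diploid, triploid, tetraploid) against the free
#' mixture with the three-factor validated call, per-SNP allelic-ratio
#' statistics with the diploid/polyploid classification, and the combined
#' ploidy call.
#'
#' The combined call reports `2x` when the mixture call and the ratio class
#' agree on diploid; `3x` when the mixture calls triploid and the ratio
#' statistics are consistent with it (median at or above 2 — the ratio axis
#' cannot separate 3x from higher levels, so the more specific mixture call
#' stands); `>=4x` when the mixture calls tetraploid and the ratio class is
#' polyploid (levels above 4x are shadowed by the noise filter, hence the
#' open-ended label). Any conflict, or an unresolved mixture stage, yields
#' `unresolved` with both sub-results and a note retained.
#'
#' @param sites Data frame of allele-depth sites for one sample (from
#'   [read_allele_depths()] or [simulate_sample()]).
#' @param min_depth Minimum reads per site (default 10).
#' @param threshold Noise threshold on the minor allele frequency
#'   (default 0.2).
#' @param bins Histogram bins for the fit statistics (default 50).
#' @param n_components Free-model component count (default 3).
#' @param restarts Free-model EM restarts (default 5).
#' @param min_snps Minimum retained SNPs for an accepted mixture call
#'   (default 500).
#' @param total_bp Optional recovered target length (bp) for the
#'   percent-polymorphic heterozygosity check; if omitted the check is
#'   reported unavailable, never guessed.
#' @param reliability_floor Percent-polymorphic floor below which calls are
#'   downgraded (default 0.50).
#' @param envelope Optional diploid [bootstrap_density_envelope()] used for
#'   extra-peak evidence.
#' @param seed Integer seed for the free-model restarts.
#' @return An object of class `"ploidy_fit"`; see [print.ploidy_fit()],
#'   [summary.ploidy_fit()], [coef.ploidy_fit()], [plot.ploidy_fit()],
#'   [residuals.ploidy_fit()]. Key pieces: `$call_table` (one-row data
#'   frame with the combined call), `$mixture` (the
#'   [call_mixture_ploidy()] report), `$ratio_class`, `$ratio_summary`,
#'   `$gene_summaries`, `$fits` (the four mixture fits), `$counts` (filter
#'   bookkeeping).
#' @examples
#' sites <- simulate_sample(sim_config(ploidy = 3, n_genes = 100,
#'                                     snps_per_gene = 20, seed = 7))
#' fit <- ploidy_fit(sites, seed = 7)
#' fit$call_table$combined_call
#' @export
ploidy_fit <- function(sites, min_depth = 10L, threshold = 0.2, bins = 50L,
                       n_components = 3L, restarts = 5L, min_snps = 500L,
                       total_bp = NULL, reliability_floor = 0.50,
                       envelope = NULL, seed = 1L) {
  check_sites(sites)
  if (!is.null(sites$sample_id) &&
      length(unique(sites$sample_id)) > 1L) {
    stop_input("'sites' must belong to a single sample")
  }
  sample_id <- if (!is.null(sites$sample_id)) sites$sample_id[1] else "sample"
  n_input <- nrow(sites)

  freqs <- allele_frequencies(sites, min_depth = min_depth)
  filtered <- noise_filter(freqs, threshold = threshold)
  counts <- c(
    input = n_input,
    depth_filtered = attr(freqs, "n_depth_filtered"),
    noise_filtered = attr(filtered, "n_noise_filtered"),
    retained = nrow(filtered)
  )

  het <- if (!is.null(total_bp)) {
    percent_polymorphic(nrow(filtered), total_bp,
                        reliability_floor = reliability_floor,
                        sample_id = sample_id)
  } else {
    NULL
  }

  empty_call <- function(reason) {
    structure(list(
      sample_id = sample_id,
      counts = counts,
      freqs = filtered,
      fits = NULL, mixture = NULL,
      ratio_summary = NULL, gene_summaries = NULL, ratio_class = NULL,
      heterozygosity = het,
      call_table = data.frame(
        sample_id = sample_id, mixture_call = "unresolved",
        ratio_class = "ambiguous", combined_call = "unresolved",
        median_M = NA_real_, pct_below_2 = NA_real_,
        n_snps = nrow(filtered),
        pct_polymorphic = if (is.null(het)) NA_real_ else het$pct_polymorphic,
        notes = reason, stringsAsFactors = FALSE),
      config = list(min_depth = min_depth, threshold = threshold,
                    bins = bins, n_components = n_components,
                    restarts = restarts, min_snps = min_snps, seed = seed)
    ), class = "ploidy_fit")
  }
  if (nrow(filtered) * 2L < MIN_FIT_OBS) {
    return(empty_call("no usable sites after filtering"))
  }

  x <- mirrored_freqs(filtered)
  fits <- lapply(stats::setNames(nm = names(HYPOTHESIS_MEANS)),
                 function(h) fit_fixed_mixture(x, h, threshold = threshold))
  free <- fit_free_mixture(x, n_components = n_components,
                           restarts = restarts, seed = seed,
                           threshold = threshold)
  hstats <- lapply(fits, function(f) {
    histogram_fit_stats(x, f, bins = bins, threshold = threshold)
  })
  mixture <- call_mixture_ploidy(fits, free, hstats, min_snps = min_snps,
                                 heterozygosity = het)

  with_ratio <- snp_ratios(filtered)
  summaries <- summarize_ratios(with_ratio, by_gene = TRUE)
  sample_summary <- summaries[1, , drop = FALSE]
  gene_summaries <- summaries[-1, , drop = FALSE]
  rclass <- classify_by_ratios(sample_summary, gene_summaries,
                               envelope = envelope,
                               ratio = with_ratio$ratio,
                               mixture_call = mixture$call)

  comb <- combine_calls(mixture$call, rclass$class,
                        sample_summary$pct_below_2)
  notes <- c(mixture$notes, rclass$flags, comb$notes)
  if (!is.na(mixture$reason)) notes <- c(mixture$reason, notes)

  call_table <- data.frame(
    sample_id = sample_id,
    mixture_call = mixture$call,
    ratio_class = rclass$class,
    combined_call = comb$call,
    median_M = sample_summary$median_M,
    pct_below_2 = sample_summary$pct_below_2,
    n_snps = nrow(filtered),
    pct_polymorphic = if (is.null(het)) NA_real_ else het$pct_polymorphic,
    notes = if (length(notes) > 0) paste(notes, collapse = "; ") else "",
    stringsAsFactors = FALSE
  )
  structure(list(
    sample_id = sample_id,
    counts = counts,
    freqs = filtered,
    fits = c(fits, list(free = free)),
    hist_stats = hstats,
    mixture = mixture,
    ratios = with_ratio,
    ratio_summary = sample_summary,
    gene_summaries = gene_summaries,
    ratio_class = rclass,
    heterozygosity = het,
    call_table = call_table,
    config = list(min_depth = min_depth, threshold = threshold, bins = bins,
                  n_components = n_components, restarts = restarts,
                  min_snps = min_snps, seed = seed)
  ), class = "ploidy_fit")
}

# Combination rule for the two independent lines of evidence. The triploid
# expectation (single ratio class 2:1) puts its median exactly on the
# diploid/polyploid cut, so for a triploid mixture call the discriminating
# ratio statistic is the fraction of ratios below 2 (~50% for a true
# triploid, >65% for a diploid), not the knife-edge median.
combine_calls <- function(mixture_call, ratio_class, pct_below_2 = NA_real_) {
  notes <- character(0)
  call <- "unresolved"
  if (mixture_call == "diploid" && ratio_class == "diploid-like") {
    call <- "2x"
  } else if (mixture_call == "triploid") {
    if (!is.na(pct_below_2) && pct_below_2 > 65) {
      notes <- sprintf(
        "conflict: mixture calls triploid but %.1f%% of ratios are < 2 (diploid signature)",
        pct_below_2)
    } else {
      call <- "3x"
      notes <- "ratio median sits at the triploid expectation (2:1); mixture call stands"
    }
  } else if (mixture_call == "tetraploid" && ratio_class == "polyploid") {
    call <- ">=4x"
  } else if (mixture_call == "tetraploid" &&
             ratio_class == "possible-recent-autopolyploid") {
    call <- ">=4x"
    notes <- "possible recent autopolyploid (balanced dosage)"
  } else if (mixture_call == "unresolved") {
    notes <- paste0("mixture stage unresolved; ratio evidence: ", ratio_class)
  } else {
    notes <- sprintf("conflict between mixture (%s) and ratio (%s) evidence",
                     mixture_call, ratio_class)
  }
  list(call = call, notes = notes)
}

#' @export
print.ploidy_fit <- function(x, ...) {
  ct <- x$call_table
  cat(sprintf("Ploidy fit for sample '%s'\n", x$sample_id))
  cat(sprintf("  sites: %d input, %d retained after depth >= %d and minor freq >= %g\n",
              x$counts["input"], x$counts["retained"],
              x$config$min_depth, x$config$threshold))
  cat(sprintf("  mixture call: %s   ratio class: %s (median M = %s)\n",
              ct$mixture_call, ct$ratio_class,
              ifelse(is.na(ct$median_M), "NA", sprintf("%.3f", ct$median_M))))
  cat(sprintf("  combined call: %s\n", ct$combined_call))
  if (nzchar(ct$notes)) cat("  notes:", ct$notes, "\n")
  invisible(x)
}

#' @rdname print.ploidy_fit
#' @param object,x A `"ploidy_fit"` object.
#' @param ... Unused.
#' @export
summary.ploidy_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$mixture)) {
    cat("\n")
    print(object$mixture)
  }
  if (!is.null(object$ratio_class)) {
    cat("\n")
    print(object$ratio_class)
  }
  if (!is.null(object$heterozygosity)) {
    cat("\n")
    print(object$heterozygosity)
  }
  invisible(object)
}

#' Mixture parameters of a ploidy fit
#'
#' @param object A `"ploidy_fit"`.
#' @param ... Unused.
#' @return Data frame of per-component means, weights and shared sd for
#'   each fitted hypothesis (including the free model).
#' @export
coef.ploidy_fit <- function(object, ...) {
  if (is.null(object$fits)) return(NULL)
  do.call(rbind, lapply(names(object$fits), function(h) {
    f <- object$fits[[h]]
    data.frame(hypothesis = h, component = seq_along(f$means),
               mean = f$means, weight = f$weights, sd = f$sd,
               logL = f$logL, stringsAsFactors = FALSE)
  }))
}

#' Log-likelihood of the best-supported fixed hypothesis
#'
#' @param object A `"ploidy_fit"`.
#' @param ... Unused.
#' @export
logLik.ploidy_fit <- function(object, ...) {
  if (is.null(object$fits)) return(NA)
  h <- object$mixture$call
  f <- if (h %in% names(object$fits)) object$fits[[h]] else object$fits$free
  structure(f$logL, df = length(f$means) + length(f$weights),
            nobs = f$n_obs, class = "logLik")
}

#' Histogram residuals of each ploidy hypothesis
#'
#' @param object A `"ploidy_fit"`.
#' @param ... Unused.
#' @return Matrix of empirical-minus-ideal bin-mass residuals (bins in
#'   rows, hypotheses in columns).
#' @export
residuals.ploidy_fit <- function(object, ...) {
  if (is.null(object$hist_stats)) return(NULL)
  vapply(object$hist_stats, function(s) s$empirical - s$ideal,
         numeric(length(object$hist_stats[[1]]$empirical)))
}

#' Diagnostic plots for a ploidy fit
#'
#' Left: mirrored allele-frequency histogram with the fitted fixed-mean
#' densities overlaid. Right: kernel density of the per-SNP allelic ratios
#' with the ratio-2 decision line.
#'
#' @param x A `"ploidy_fit"`.
#' @param which `1` (frequencies), `2` (ratios) or both.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.ploidy_fit <- function(x, which = 1:2, ...) {
  if (is.null(x$fits)) {
    stop_input("nothing to plot: the fit carried no usable sites")
  }
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  xs <- mirrored_freqs(x$freqs)
  if (1 %in% which) {
    graphics::hist(xs, breaks = 40, freq = FALSE,
                   main = sprintf("%s: allele frequencies", x$sample_id),
                   xlab = "mirrored allele frequency", ...)
    at <- seq(x$config$threshold, 1 - x$config$threshold, length.out = 200)
    cols <- c(diploid = "blue", triploid = "orange", tetraploid = "darkgreen")
    for (h in names(cols)) {
      graphics::lines(at, mixture_density(x$fits[[h]], at), col = cols[h])
    }
    graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                     cex = 0.8, bty = "n")
  }
  if (2 %in% which) {
    d <- stats::density(x$ratios$ratio, from = 1)
    graphics::plot(d, main = sprintf("%s: allelic ratios", x$sample_id),
                   xlab = "allelic ratio (major/minor)")
    graphics::abline(v = 2, col = "red", lty = 2)
  }
  invisible(x)
}

#' Run a batch of samples from a manifest
#'
#' @param manifest Data frame with columns `sample_id`, `path` and
#'   optionally `format` (`vcf`/`tsv`) and `total_bp`.
#' @param output_dir Directory for per-sample JSON reports and the batch
#'   TSV; created if needed.
#' @param seed Top-level seed; each sample gets a seed derived
#'   deterministically from it and the sample name.
#' @param ... Passed to [ploidy_fit()].
#' @return Invisibly, a list with `calls` (batch data frame), `fits`, and
#'   `failures` (named character vector of error messages). Per-sample
#'   failures are isolated: remaining samples still run.
#' @export
run_batch <- function(manifest, output_dir = NULL, seed = 1L, ...) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L ||
      !all(c("sample_id", "path") %in% names(manifest))) {
    stop_input("'manifest' must be a non-empty data frame with sample_id and path")
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  calls <- list()
  fits <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    res <- tryCatch({
      fmt <- if ("format" %in% names(manifest) &&
                 !is.na(manifest$format[i])) manifest$format[i] else "auto"
      sites <- read_allele_depths(manifest$path[i], format = fmt,
                                  sample = sid)
      tb <- if ("total_bp" %in% names(manifest) &&
                !is.na(manifest$total_bp[i])) manifest$total_bp[i] else NULL
      ploidy_fit(sites, total_bp = tb, seed = derive_seed(seed, sid), ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sid] <- conditionMessage(res)
      message("sample ", sid, " failed: ", conditionMessage(res))
      next
    }
    fits[[sid]] <- res
    calls[[sid]] <- res$call_table
    if (!is.null(output_dir)) {
      write_report(res$call_table,
                   file.path(output_dir, paste0(sid, ".json")), "json")
    }
  }
  batch <- if (length(calls) > 0) do.call(rbind, calls) else NULL
  if (!is.null(output_dir) && !is.null(batch)) {
    write_report(batch, file.path(output_dir, "batch_calls.tsv"), "tsv")
  }
  invisible(list(calls = batch, fits = fits, failures = failures))
}
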