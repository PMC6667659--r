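# Reading allele depths and writing reports.
#
# The analysis starts from per-site allele depths, not reads: a VCF with
# per-sample AD fields (any caller) or a plain tab-separated table. Only
# biallelic SNPs enter; multiallelic records and indels are counted and
# skipped, never decomposed.

TSV_COLUMNS <- c("sample_id", "gene_id", "chrom", "pos", "ref_count",
                 "alt_count")

#' Read per-sample allele depths from VCF or TSV
#'
#' From a VCF, extracts the AD (allelic depths) FORMAT field of one sample
#' and keeps biallelic SNP records only; multiallelic records, indels,
#' records lacking AD, and zero-depth entries are skipped and tallied in
#' `attr(x, "skipped")`. From a TSV, expects a header row with columns
#' `sample_id, gene_id, chrom, pos, ref_count, alt_count` (the same dialect
#' [write_sites_tsv()] and [simulate_sample()] produce).
#'
#' @param path File to read.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension if omitted.
#' @param sample Sample name. Mandatory for multi-sample VCFs (no silent
#'   first-sample default); for TSVs, restricts to that sample's rows.
#' @return Data frame of allele-depth sites in input order, with the skip
#'   tally as attribute `"skipped"` (named integer vector).
#' @export
read_allele_depths <- function(path, format = c("auto", "vcf", "tsv"),
                               sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("input file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "tsv"
    }
  }
  if (format == "vcf") read_ad_vcf(path, sample) else read_ad_tsv(path, sample)
}

read_ad_vcf <- function(path, sample = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!"AD" %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf)))) {
    stop_input("VCF has no AD FORMAT field: ", path)
  }
  samples <- colnames(vcf)
  if (length(samples) > 1L) {
    if (is.null(sample)) {
      stop_input("multi-sample VCF: choose one of ",
                 paste(samples, collapse = ", "))
    }
    if (!sample %in% samples) {
      stop_input("sample '", sample, "' not present in ", path)
    }
  } else {
    sample <- sample %||% samples[1]
    if (!sample %in% samples) {
      stop_input("sample '", sample, "' not present in ", path)
    }
  }
  n_total <- nrow(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  ref_len <- nchar(as.character(VariantAnnotation::ref(vcf)))
  multi <- n_alt != 1L
  alt1 <- rep(NA_character_, n_total)
  alt1[!multi] <- as.character(BiocGenerics::unlist(alt[!multi],
                                                    use.names = FALSE))
  snv <- !multi & ref_len == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T")

  ad <- VariantAnnotation::geno(vcf)$AD[, sample]
  if (is.matrix(ad)) ad <- lapply(seq_len(nrow(ad)), function(i) ad[i, ])
  ref_count <- vapply(ad, function(v) {
    if (length(v) >= 1 && !is.na(v[1])) as.numeric(v[1]) else NA_real_
  }, numeric(1))
  alt_count <- vapply(ad, function(v) {
    if (length(v) >= 2 && !is.na(v[2])) as.numeric(v[2]) else NA_real_
  }, numeric(1))
  no_ad <- is.na(ref_count) | is.na(alt_count)
  zero <- !no_ad & (ref_count + alt_count) <= 0
  keep <- snv & !no_ad & !zero
  out <- data.frame(
    sample_id = sample,
    gene_id = NA_character_,
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref_count = as.integer(ref_count[keep]),
    alt_count = as.integer(alt_count[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- c(
    multiallelic = sum(multi),
    not_snv = sum(!snv & !multi),
    no_ad = sum(no_ad & snv),
    zero_depth = sum(zero & snv)
  )
  out
}

read_ad_tsv <- function(path, sample = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing <- setdiff(TSV_COLUMNS, names(tab))
  if (length(missing) > 0L) {
    stop_input("TSV is missing columns: ", paste(missing, collapse = ", "))
  }
  tab <- tab[TSV_COLUMNS]
  bad <- which(tab$ref_count < 0 | tab$alt_count < 0)
  if (length(bad) > 0L) {
    stop_input("negative allele counts in ", path, " at data line ",
               paste(bad, collapse = ", "))
  }
  zero <- tab$ref_count + tab$alt_count <= 0
  low_pos <- tab$pos < 1
  keep <- !zero & !low_pos
  if (!is.null(sample)) keep <- keep & tab$sample_id == sample
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(zero_depth = sum(zero),
                            bad_position = sum(low_pos & !zero))
  out
}

#' Read gene intervals from a BED file
#'
#' Expects at least four columns: chrom, start, end (0-based, half-open)
#' and the gene name.
#'
#' @param path BED file.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end` (BED
#'   convention preserved).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop_input("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name)) {
    stop_input("BED file must carry a gene name in column 4: ", path)
  }
  data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Assign sites to gene intervals
#'
#' A site at 1-based position p matches the 0-based half-open interval
#' `[start, end)` when `start < p <= end`. Intervals must not overlap
#' within a chromosome; unmatched sites keep `gene_id` missing and are
#' counted in `attr(x, "n_unassigned")`.
#'
#' @param sites Data frame of allele-depth sites.
#' @param annotation Data frame from [read_gene_intervals()] (columns
#'   `gene_id`, `chrom`, `start`, `end`, BED convention).
#' @return `sites` with `gene_id` filled in where a match exists.
#' @export
assign_genes <- function(sites, annotation) {
  check_sites(sites)
  need <- c("gene_id", "chrom", "start", "end")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation))) {
    stop_input("'annotation' must have columns ", paste(need, collapse = ", "))
  }
  if (any(annotation$start >= annotation$end)) {
    stop_input("annotation intervals must satisfy start < end")
  }
  ann <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end)
  )
  self <- GenomicRanges::findOverlaps(ann, ann)
  dup <- self[S4Vectors::queryHits(self) < S4Vectors::subjectHits(self)]
  if (length(dup) > 0L) {
    i <- S4Vectors::queryHits(dup)[1]
    j <- S4Vectors::subjectHits(dup)[1]
    stop_input("overlapping annotation intervals: ",
               annotation$gene_id[i], " and ", annotation$gene_id[j])
  }
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(q, ann)
  gene <- rep(NA_character_, nrow(sites))
  gene[S4Vectors::queryHits(hits)] <-
    annotation$gene_id[S4Vectors::subjectHits(hits)]
  sites$gene_id <- gene
  attr(sites, "n_unassigned") <- sum(is.na(gene))
  sites
}

#' Write allele-depth sites in the package TSV dialect
#'
#' @param sites Data frame of allele-depth sites.
#' @param path Output file.
#' @export
write_sites_tsv <- function(sites, path) {
  check_sites(sites)
  utils::write.table(sites[TSV_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

REPORT_COLUMNS <- c("sample_id", "mixture_call", "ratio_class",
                    "combined_call", "median_M", "pct_below_2", "n_snps",
                    "pct_polymorphic", "notes")

#' Write ploidy-call reports
#'
#' Bit-stable output: fixed column order, floats at 4 decimals. TSV gets a
#' header row; JSON is a single document keyed by `sample_id`.
#'
#' @param calls Data frame of ploidy calls (rows as produced by
#'   [ploidy_fit()] / [run_batch()]); must be non-empty.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(calls, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(calls) || nrow(calls) == 0L) {
    stop_input("'calls' must be a non-empty data frame")
  }
  cols <- intersect(REPORT_COLUMNS, names(calls))
  extra <- setdiff(names(calls), cols)
  out <- calls[c(cols, extra)]
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer,
                                                       logical(1))
  if (format == "tsv") {
    out[num] <- lapply(out[num], fmt4)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out[num] <- lapply(out[num], function(v) round(v, 4))
    recs <- lapply(seq_len(nrow(out)), function(i) as.list(out[i, ]))
    names(recs) <- out$sample_id
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Export a frequency histogram or density envelope as TSV
#'
#' `write_histogram()` writes `bin_left, bin_right, count` for the mirrored
#' allele frequencies of a sample; `write_envelope()` writes
#' `grid, density, sd` for a bootstrap envelope. Both are plain TSVs meant
#' for downstream plotting.
#'
#' @param x Mirrored frequency values, or a `"density_envelope"`.
#' @param path Output file.
#' @param bins,threshold Histogram layout (as in [histogram_fit_stats()]).
#' @export
write_histogram <- function(x, path, bins = 50L, threshold = 0.2) {
  breaks <- seq(threshold, 1 - threshold, length.out = bins + 1L)
  cnt <- graphics::hist(pmin(pmax(as.numeric(x), threshold), 1 - threshold),
                        breaks = breaks, plot = FALSE)$counts
  utils::write.table(
    data.frame(bin_left = fmt4(breaks[-length(breaks)]),
               bin_right = fmt4(breaks[-1]), count = cnt),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
write_envelope <- function(x, path) {
  if (!inherits(x, "density_envelope")) {
    stop_input("'x' must be a density_envelope")
  }
  utils::write.table(
    data.frame(grid = fmt4(x$grid), density = fmt4(x$mean_density),
               sd = fmt4(x$sd)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
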