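#' Infer ploidy from a holoploid genome size and a monoploid reference
#'
#' Flow-cytometry arithmetic: the holoploid 1C value of a sample divided by
#' the monoploid 1Cx value of a reference (the same species with known
#' ploidy, or its closest diploid relative) gives the number of monoploid
#' genomes per gametic nucleus, so ploidy = 2 * 1C / 1Cx rounded to the
#' nearest integer. Odd levels are legitimate (triploids, pentaploids), so
#' rounding is to the nearest integer, with exact .5 ties rounded up and
#' flagged. A rounding residual above `max_residual` marks the record
#' ambiguous — the reference 1Cx may not fit the sample.
#'
#' @param c_value_1C Holoploid genome size of the sample, in pg (> 0).
#' @param reference_1Cx Monoploid genome size of the reference, in pg (> 0).
#' @param max_residual Largest acceptable distance from an integer ploidy
#'   (default 0.25).
#' @param sample_id Optional sample name(s).
#' @return Data frame with `sample_id`, `c_value_1C`, `reference_1Cx`,
#'   `inferred_ploidy`, `residual`, `ambiguous`. Vectorized over samples.
#' @examples
#' ploidy_from_genome_size(0.97, 0.32)  # hexaploid
#' @export
ploidy_from_genome_size <- function(c_value_1C, reference_1Cx,
                                    max_residual = 0.25,
                                    sample_id = NA_character_) {
  if (any(!is.finite(c_value_1C)) || any(c_value_1C <= 0) ||
      any(!is.finite(reference_1Cx)) || any(reference_1Cx <= 0)) {
    stop_input("'c_value_1C' and 'reference_1Cx' must be positive")
  }
  m <- 2 * c_value_1C / reference_1Cx
  # nearest integer, .5 ties up (not banker's rounding: odd ploidy is real)
  ploidy <- floor(m + 0.5)
  residual <- abs(m - ploidy)
  tie <- abs(m - floor(m) - 0.5) < 1e-12
  data.frame(
    sample_id = sample_id,
    c_value_1C = c_value_1C,
    reference_1Cx = reference_1Cx,
    inferred_ploidy = as.integer(ploidy),
    residual = residual,
    ambiguous = residual > max_residual | tie | ploidy < 2,
    stringsAsFactors = FALSE
  )
}
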