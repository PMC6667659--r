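# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-sample seed derived from a top-level seed and a sample
# name; kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, sample_id) {
  h <- 0
  for (b in utf8ToInt(as.character(sample_id))) {
    h <- (h * 131 + b) %% 2147483629
  }
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629L + 1L)
}

# Fixed 4-decimal formatting used by every report writer (bit-stable output).
fmt4 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.4f", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate the allele-depth site table contract shared by all modules.
check_sites <- function(sites) {
  need <- c("ref_count", "alt_count")
  if (!is.data.frame(sites) || !all(need %in% names(sites))) {
    stop_input("'sites' must be a data frame with ref_count and alt_count columns")
  }
  if (any(sites$ref_count < 0 | sites$alt_count < 0, na.rm = TRUE)) {
    stop_input("negative allele counts are invalid")
  }
  if (any(sites$ref_count + sites$alt_count <= 0, na.rm = TRUE)) {
    stop_input("every site must have at least one read")
  }
  invisible(sites)
}

stop_input <- function(...) stop(..., call. = FALSE)
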