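# Fixed-mean Gaussian mixture machinery.
#
# The ploidy hypotheses pin both the component means and the mixture
# weights at the values the mirrored allele-balance model implies under
# uniform dosage: 1/2 with weight 1 (diploid); 1/3, 2/3 with weights
# 1/2, 1/2 (triploid); 1/4, 1/2, 3/4 with weights 1/3 each (tetraploid) —
# each heterozygous site contributes both orientations, so dosage class j
# and its mirror k-j land on mirrored means with equal mass. Only the
# shared standard deviation is estimated for a named hypothesis; the
# "free" model estimates means, weights and spread, and its maximized
# log-likelihood is the yardstick each hypothesis is measured against
# (delta log-likelihood). Freeing the fixed models' weights would nest
# the diploid inside the tetraploid hypothesis (0.5 is one of its means)
# and make "lowest delta logL" undecidable, so the weights stay pinned.
#
# Because observations below the noise threshold t (and above 1 - t) are
# filtered out before fitting, every component is a Gaussian truncated to
# [t, 1 - t]; ignoring the truncation biases the outer tetraploid means
# away from 0.25/0.75. The EM below therefore uses truncated components:
# the E-step weighs each component by its renormalized density, and the
# M-step applies the standard truncated-normal moment corrections
# (fixed-point updates; the logL trace is monitored for monotonicity).

HYPOTHESIS_MEANS <- list(
  diploid    = 0.5,
  triploid   = c(1 / 3, 2 / 3),
  tetraploid = c(0.25, 0.5, 0.75)
)

HYPOTHESIS_WEIGHTS <- list(
  diploid    = 1,
  triploid   = c(0.5, 0.5),
  tetraploid = c(1, 1, 1) / 3
)

MIN_FIT_OBS <- 20L     # mirrored values; below this EM output is meaningless
SD_FLOOR <- 1e-3       # keeps the likelihood away from the singular sd -> 0
EM_TOL <- 1e-8         # relative logL change declaring convergence
EM_MAX_ITER <- 1000L

# Truncated-mixture log-likelihood at given parameters.
trunc_mix_logL <- function(x, means, weights, sdv, lower, upper) {
  dens <- rep(0, length(x))
  for (k in seq_along(means)) {
    z <- stats::pnorm(upper, means[k], sdv) - stats::pnorm(lower, means[k], sdv)
    dens <- dens + weights[k] * stats::dnorm(x, means[k], sdv) / max(z, 1e-12)
  }
  dens[dens < .Machine$double.xmin] <- .Machine$double.xmin
  sum(log(dens))
}

# Exact profile maximization for a fixed-mean, fixed-weight hypothesis: the
# shared sd is the only free parameter, so a coarse log-spaced scan (robust
# to the multimodal profiles misspecified hypotheses produce) followed by a
# golden-section refinement finds the global maximum directly. The
# best-so-far sequence is kept as the monotone optimization trace.
profile_fixed_fit <- function(x, means, weights, lower, upper,
                              sd_range = c(SD_FLOOR, 0.5), grid_n = 60L) {
  grid <- exp(seq(log(sd_range[1]), log(sd_range[2]), length.out = grid_n))
  ll <- vapply(grid, function(s) trunc_mix_logL(x, means, weights, s,
                                                lower, upper), numeric(1))
  i <- which.max(ll)
  bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, grid_n)])
  opt <- stats::optimize(function(ls) {
    trunc_mix_logL(x, means, weights, exp(ls), lower, upper)
  }, log(bracket), maximum = TRUE, tol = 1e-10)
  sdv <- exp(opt$maximum)
  logL <- opt$objective
  if (ll[i] > logL) {          # refinement never loses to the scan
    sdv <- grid[i]
    logL <- ll[i]
  }
  trace <- cummax(c(ll[seq_len(i)], logL))
  list(means = means, weights = weights, sd = max(sdv, SD_FLOOR),
       logL = logL, trace = trace, n_obs = length(x),
       iterations = length(trace), lower = lower, upper = upper)
}

# Shared-variance mixture EM with components truncated to [lower, upper].
# `means`/`weights` fixed unless the estimate_* flags are set.
# Deterministic given the initial values. Returns means, weights, sd, logL,
# the per-iteration logL trace and the observation count.
em_mixture <- function(x, means, weights = NULL,
                       estimate_means = FALSE, estimate_weights = FALSE,
                       lower = 0.2, upper = 1 - lower, sd0 = 0.05,
                       tol = EM_TOL, max_iter = EM_MAX_ITER) {
  n <- length(x)
  K <- length(means)
  w <- weights %||% rep(1 / K, K)
  sdv <- max(sd0, SD_FLOOR)
  mu <- means
  trace <- numeric(0)
  logL <- -Inf
  trunc_terms <- function(mu, sdv) {
    a <- (lower - mu) / sdv
    b <- (upper - mu) / sdv
    z <- pmax(stats::pnorm(b) - stats::pnorm(a), 1e-12)
    list(a = a, b = b, z = z,
         dphi = stats::dnorm(a) - stats::dnorm(b),          # phi(a) - phi(b)
         c = (a * stats::dnorm(a) - b * stats::dnorm(b)) / z)
  }
  best <- list(logL = -Inf, means = mu, weights = w, sd = sdv)
  for (iter in seq_len(max_iter)) {
    tt <- trunc_terms(mu, sdv)
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dnorm(x, mu[k], sdv) / tt$z[k],
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    new_logL <- sum(log(tot))
    trace <- c(trace, new_logL)
    if (new_logL > best$logL) {
      best <- list(logL = new_logL, means = mu, weights = w, sd = sdv)
    }
    if (is.finite(logL) &&
        abs(new_logL - logL) <= tol * (abs(logL) + 1)) {
      logL <- new_logL
      break
    }
    logL <- new_logL
    resp <- dens / tot
    nk <- pmax(colSums(resp), 1e-12)
    if (estimate_weights) w <- nk / n
    if (estimate_means) {
      # stationarity: responsibility mean equals the truncated-normal mean
      xbar <- colSums(resp * x) / nk
      mu <- pmin(pmax(xbar - sdv * tt$dphi / tt$z, lower - 0.25),
                 upper + 0.25)
    }
    # shared spread; (1 + c) corrects the second moment for the cut tails
    tt <- trunc_terms(mu, sdv)
    cbar <- sum(nk / n * tt$c)
    s2 <- sum(resp * (outer(x, mu, "-"))^2) / (n * max(1 + cbar, 0.05))
    sdv <- max(sqrt(s2), SD_FLOOR)
  }
  list(means = best$means, weights = best$weights, sd = best$sd,
       logL = best$logL, trace = trace, n_obs = n,
       iterations = length(trace), lower = lower, upper = upper)
}

new_mixture_fit <- function(fit, hypothesis) {
  structure(c(list(hypothesis = hypothesis), fit), class = "mixture_fit")
}

#' Fit a fixed-mean ploidy hypothesis to mirrored allele frequencies
#'
#' Component means and weights are pinned at the values the hypothesis
#' implies for mirrored data under uniform dosage (see
#' [expected_ratio_classes()] for the dosage view), leaving the shared
#' standard deviation as the only free parameter; it is maximized exactly
#' by a profile scan with golden-section refinement over Gaussians
#' truncated to the retained interval `[threshold, 1 - threshold]`. The
#' fit is deterministic.
#'
#' @param x Numeric vector of mirrored allele frequencies (see
#'   [mirrored_freqs()]), already noise-filtered.
#' @param hypothesis One of `"diploid"`, `"triploid"`, `"tetraploid"`.
#' @param threshold Noise threshold that delimited the data (default 0.2);
#'   sets the truncation bounds of every component.
#' @return An object of class `"mixture_fit"`: `hypothesis`, `means`,
#'   `weights`, shared `sd`, `logL`, `n_obs`, the per-iteration `trace`.
#' @export
fit_fixed_mixture <- function(x, hypothesis = c("diploid", "triploid",
                                                "tetraploid"),
                              threshold = 0.2) {
  hypothesis <- match.arg(hypothesis)
  x <- check_freq_values(x)
  new_mixture_fit(
    profile_fixed_fit(x, HYPOTHESIS_MEANS[[hypothesis]],
                      HYPOTHESIS_WEIGHTS[[hypothesis]],
                      lower = threshold, upper = 1 - threshold),
    hypothesis)
}

#' Fit a free Gaussian mixture to mirrored allele frequencies
#'
#' All parameters (means, weights, shared spread) are estimated. EM is run
#' from `restarts` seeded starting points — the first at canonical
#' allele-balance positions for the component count, the rest jittered — and
#' the best log-likelihood wins. With three components the free model nests
#' every fixed hypothesis, so its maximized log-likelihood bounds theirs
#' from above.
#'
#' @inheritParams fit_fixed_mixture
#' @param n_components Number of Gaussian components (default 3, matching
#'   the largest fixed hypothesis).
#' @param restarts Number of EM restarts (default 5).
#' @param seed Integer seed controlling the jittered restarts.
#' @return An object of class `"mixture_fit"` with `hypothesis = "free"`;
#'   components are sorted by mean.
#' @export
fit_free_mixture <- function(x, n_components = 3L, restarts = 5L, seed = 1L,
                             threshold = 0.2) {
  if (n_components < 1L) stop_input("'n_components' must be >= 1")
  if (restarts < 1L) stop_input("'restarts' must be >= 1")
  x <- check_freq_values(x)
  K <- as.integer(n_components)
  base_means <- switch(as.character(K),
    "1" = 0.5,
    "2" = c(1 / 3, 2 / 3),
    "3" = c(0.25, 0.5, 0.75),
    seq(min(x), max(x), length.out = K)
  )
  with_seed(seed, {
    best <- NULL
    consider <- function(fit) {
      if (is.null(best) || fit$logL > best$logL) best <<- fit
    }
    for (r in seq_len(restarts)) {
      mu0 <- if (r == 1L) base_means else {
        pmin(pmax(base_means + stats::rnorm(K, 0, 0.04), 0.01), 0.99)
      }
      consider(em_mixture(x, mu0, estimate_means = TRUE,
                          estimate_weights = TRUE,
                          lower = threshold, upper = 1 - threshold))
    }
    # warm starts at the fixed hypotheses' exact solutions: a hypothesis
    # with fewer than K components is embedded by duplicating its last mean
    # and splitting that weight, which leaves the density unchanged; EM can
    # only improve from there, so the free model provably nests every
    # hypothesis it can represent
    for (h in names(HYPOTHESIS_MEANS)) {
      L <- length(HYPOTHESIS_MEANS[[h]])
      if (L > K) next
      fx <- profile_fixed_fit(x, HYPOTHESIS_MEANS[[h]],
                              HYPOTHESIS_WEIGHTS[[h]],
                              lower = threshold, upper = 1 - threshold)
      mu0 <- c(fx$means, rep(fx$means[L], K - L))
      w0 <- c(fx$weights[-L], rep(fx$weights[L] / (K - L + 1), K - L + 1))
      consider(em_mixture(x, mu0, weights = w0,
                          estimate_means = TRUE, estimate_weights = TRUE,
                          sd0 = fx$sd,
                          lower = threshold, upper = 1 - threshold))
    }
    ord <- order(best$means)
    best$means <- best$means[ord]
    best$weights <- best$weights[ord]
    new_mixture_fit(best, "free")
  })
}

check_freq_values <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) < MIN_FIT_OBS) {
    stop_input("insufficient data: ", length(x),
               " observations (need >= ", MIN_FIT_OBS, ")")
  }
  if (any(x <= 0 | x >= 1)) {
    stop_input("allele frequencies must lie strictly inside (0, 1)")
  }
  x
}

#' @export
print.mixture_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s mixture fit (%d mirrored obs)\n", x$hypothesis, x$n_obs))
  tab <- rbind(mean = x$means, weight = x$weights)
  colnames(tab) <- paste0("comp", seq_along(x$means))
  print(round(tab, digits))
  cat(sprintf("shared sd %.4g  logL %.4f  (%d EM iterations)\n",
              x$sd, x$logL, x$iterations))
  invisible(x)
}

mixture_density <- function(fit, at) {
  lo <- fit$lower %||% 0.2
  hi <- fit$upper %||% 0.8
  rowSums(vapply(seq_along(fit$means), function(k) {
    z <- stats::pnorm(hi, fit$means[k], fit$sd) -
      stats::pnorm(lo, fit$means[k], fit$sd)
    fit$weights[k] * stats::dnorm(at, fit$means[k], fit$sd) / max(z, 1e-12)
  }, numeric(length(at))))
}

#' Delta log-likelihood of a fixed hypothesis against the free model
#'
#' The gap `logL(free) - logL(fixed)`; the best-supported hypothesis is the
#' one with the smallest gap. Both fits must be computed on the same
#' observations. A tiny negative gap (EM converged to within tolerance) is
#' clamped to zero.
#'
#' @param fixed,free `"mixture_fit"` objects on identical data.
#' @param tolerance Clamping tolerance for numerically negative gaps.
#' @return A single non-negative number (attribute `"note"` records a clamp).
#' @export
delta_log_likelihood <- function(fixed, free, tolerance = 1e-6) {
  if (!inherits(fixed, "mixture_fit") || !inherits(free, "mixture_fit")) {
    stop_input("'fixed' and 'free' must be mixture_fit objects")
  }
  if (fixed$n_obs != free$n_obs) {
    stop_input("fits are not comparable: ", fixed$n_obs, " vs ",
               free$n_obs, " observations")
  }
  d <- free$logL - fixed$logL
  if (d < 0 && d >= -tolerance) {
    return(structure(0, note = "free logL below fixed within tolerance"))
  }
  d
}

#' Histogram agreement between data and a fitted hypothesis
#'
#' The empirical histogram of mirrored frequencies (equal bins over the
#' retained interval, normalized to unit mass) is regressed on the ideal
#' histogram (model density mass per bin, renormalized over the same
#' interval) by ordinary least squares. A well-supported hypothesis shows a
#' low sum of squared residuals, a slope near one with small standard
#' error, and a high R squared.
#'
#' @param x Mirrored, noise-filtered allele frequencies.
#' @param fit A `"mixture_fit"` for the hypothesis under scrutiny.
#' @param bins Number of equal-width bins (default 50, minimum 10).
#' @param threshold Noise threshold delimiting the histogram support
#'   `[threshold, 1 - threshold]`.
#' @return A list with `SSR`, `slope`, `SE`, `R2` and the bin masses
#'   (`empirical`, `ideal`, `breaks`).
#' @export
histogram_fit_stats <- function(x, fit, bins = 50L, threshold = 0.2) {
  if (bins < 10L) stop_input("'bins' must be >= 10")
  if (!inherits(fit, "mixture_fit")) {
    stop_input("'fit' must be a mixture_fit object")
  }
  x <- as.numeric(x)
  breaks <- seq(threshold, 1 - threshold, length.out = bins + 1L)
  emp <- graphics::hist(pmin(pmax(x, threshold), 1 - threshold),
                        breaks = breaks, plot = FALSE)$counts
  emp <- emp / sum(emp)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ideal <- rowSums(vapply(seq_along(fit$means), function(k) {
    z <- stats::pnorm(fit$upper %||% (1 - threshold), fit$means[k], fit$sd) -
      stats::pnorm(fit$lower %||% threshold, fit$means[k], fit$sd)
    fit$weights[k] * (stats::pnorm(hi, fit$means[k], fit$sd) -
                      stats::pnorm(lo, fit$means[k], fit$sd)) / max(z, 1e-12)
  }, numeric(bins)))
  if (sum(ideal) <= 0 || stats::var(ideal) == 0) {
    stop_input("ideal histogram is degenerate; regression undefined")
  }
  ideal <- ideal / sum(ideal)
  ls <- stats::lm(emp ~ ideal)
  sm <- summary(ls)
  list(
    SSR = sum(stats::residuals(ls)^2),
    slope = unname(stats::coef(ls)[2]),
    SE = unname(sm$coefficients[2, 2]),
    R2 = sm$r.squared,
    empirical = emp,
    ideal = ideal,
    breaks = breaks
  )
}

#' Three-factor validated mixture ploidy call
#'
#' Combines the model comparison into a single call. The winning hypothesis
#' has the smallest delta log-likelihood; the call is accepted only when the
#' histogram factor agrees (the same hypothesis attains the smallest SSR and
#' the largest R squared), when enough SNPs survive filtering, and — if a
#' heterozygosity summary is supplied — when the sample is reliable.
#' Anything else is `"unresolved"` with the reason recorded; disagreement
#' between factors is a value, not an error.
#'
#' @param fits Named list of the three fixed `"mixture_fit"` objects
#'   (`diploid`, `triploid`, `tetraploid`) fitted on identical observations.
#' @param free The free-model `"mixture_fit"` on the same observations.
#' @param stats Named list of [histogram_fit_stats()] results, same names.
#' @param min_snps Minimum SNP count (sites, not mirrored values) for an
#'   accepted call; default 500.
#' @param heterozygosity Optional `"het_summary"`; an unreliable sample
#'   downgrades the call.
#' @param tolerance Ties in delta log-likelihood within this margin go to
#'   the lower ploidy, flagged.
#' @return A list of class `"model_fit_report"`: per-hypothesis table
#'   (`delta_logL`, `SSR`, `slope`, `SE`, `R2`), `call`, `factors_agree`,
#'   `reason`, `n_snps`.
#' @export
call_mixture_ploidy <- function(fits, free, stats, min_snps = 500L,
                                heterozygosity = NULL, tolerance = 1e-6) {
  hyps <- c("diploid", "triploid", "tetraploid")
  if (!all(hyps %in% names(fits)) || !all(hyps %in% names(stats))) {
    stop_input("'fits' and 'stats' must be named lists over the three hypotheses")
  }
  delta <- vapply(hyps, function(h) {
    as.numeric(delta_log_likelihood(fits[[h]], free, tolerance))
  }, numeric(1))
  tab <- data.frame(
    hypothesis = hyps,
    delta_logL = delta,
    SSR = vapply(hyps, function(h) stats[[h]]$SSR, numeric(1)),
    slope = vapply(hyps, function(h) stats[[h]]$slope, numeric(1)),
    SE = vapply(hyps, function(h) stats[[h]]$SE, numeric(1)),
    R2 = vapply(hyps, function(h) stats[[h]]$R2, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  n_snps <- free$n_obs %/% 2L
  notes <- character(0)

  # smallest delta wins; ties within tolerance resolved toward lower ploidy
  # (hypotheses are ordered by ploidy already).
  in_tie <- delta <= min(delta) + tolerance
  winner <- hyps[which(in_tie)[1]]
  if (sum(in_tie) > 1L) {
    notes <- c(notes, paste0("delta logL tie (", paste(hyps[in_tie],
               collapse = ", "), "); lower ploidy preferred"))
  }
  hist_winner_ssr <- hyps[which.min(tab$SSR)]
  hist_winner_r2 <- hyps[which.max(tab$R2)]
  factors_agree <- identical(winner, hist_winner_ssr) &&
    identical(winner, hist_winner_r2)

  call <- winner
  reason <- NA_character_
  if (!factors_agree) {
    call <- "unresolved"
    reason <- sprintf(
      "factor disagreement: delta logL favors %s, SSR favors %s, R2 favors %s",
      winner, hist_winner_ssr, hist_winner_r2)
  } else if (n_snps < min_snps) {
    call <- "unresolved"
    reason <- sprintf("insufficient SNPs: %d < %d", n_snps, min_snps)
  } else if (!is.null(heterozygosity) && !heterozygosity$reliable) {
    call <- "unresolved"
    reason <- sprintf("heterozygosity below reliability floor (%.3f%%)",
                      heterozygosity$pct_polymorphic)
  }
  structure(list(
    table = tab,
    call = call,
    factors_agree = factors_agree,
    reason = reason,
    notes = notes,
    n_snps = n_snps
  ), class = "model_fit_report")
}

#' @export
print.model_fit_report <- function(x, digits = 3, ...) {
  cat("Three-factor mixture model comparison\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("call: %s (factors %s, %d SNPs)\n", x$call,
              if (x$factors_agree) "agree" else "disagree", x$n_snps))
  if (!is.na(x$reason)) cat("reason:", x$reason, "\n")
  invisible(x)
}
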