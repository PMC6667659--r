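test_that("EM matches a grid-search oracle for fixed-mean likelihoods", {
  # degenerate: 500 mirrored values exactly at 0.5
  x05 <- rep(0.5, 500)
  fits <- lapply(c("diploid", "triploid", "tetraploid"),
                 function(h) fit_fixed_mixture(x05, h))
  names(fits) <- c("diploid", "triploid", "tetraploid")
  expect_true(fits$diploid$logL > fits$triploid$logL)
  expect_true(fits$diploid$logL > fits$tetraploid$logL)

  # realistic diploid data: EM's sd-profile maximum equals the oracle's
  x <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(2, 400, 2))))
  for (h in c("diploid", "triploid", "tetraploid")) {
    fit <- fit_fixed_mixture(x, h)
    oracle <- oracle_fixed_logL(x, fit$means, fit$weights)
    expect_gte(fit$logL, oracle - 0.01)
    expect_lt(abs(fit$logL - oracle), 0.05)
  }
})

test_that("the generating hypothesis attains the smallest delta logL", {
  for (case in list(list(k = 2, h = "diploid"), list(k = 3, h = "triploid"),
                    list(k = 4, h = "tetraploid"))) {
    x <- mirrored_freqs(filtered_freqs(
      simulate_sample(poisson_config(case$k, 1500, 21))))
    fits <- sapply(c("diploid", "triploid", "tetraploid"), function(h) {
      fit_fixed_mixture(x, h)
    }, simplify = FALSE)
    free <- fit_free_mixture(x, 3, seed = 21)
    delta <- vapply(fits, function(f) delta_log_likelihood(f, free),
                    numeric(1))
    expect_equal(names(which.min(delta)), case$h)
  }
})

test_that("insufficient or invalid data raise informative errors", {
  expect_error(fit_fixed_mixture(numeric(0), "diploid"), "insufficient data")
  expect_error(fit_fixed_mixture(rep(0.5, 5), "diploid"), "insufficient data")
  expect_error(fit_fixed_mixture(c(rep(0.5, 30), 1.2), "diploid"),
               "inside \\(0, 1\\)")
})

test_that("free-model fits recover simulated peak locations", {
  x3 <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(3, 2000, 4))))
  f2 <- fit_free_mixture(x3, 2, seed = 4)
  expect_lt(abs(max(f2$means) - 2 / 3), 0.015)
  x4 <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(4, 2000, 4))))
  f3 <- fit_free_mixture(x4, 3, seed = 4)
  expect_lt(abs(min(f3$means) - 0.25), 0.015)
  # degenerate single component on constant data: exact center, floored sd
  fd <- fit_free_mixture(rep(0.5, 100), 1, seed = 1)
  expect_equal(fd$means, 0.5)
  expect_equal(fd$sd, 1e-3)
})

test_that("free model nests the fixed hypotheses (delta >= 0)", {
  for (seed in 1:5) {
    k <- 2 + (seed %% 3)
    x <- mirrored_freqs(filtered_freqs(
      simulate_sample(poisson_config(k, 600, seed))))
    free <- fit_free_mixture(x, 3, seed = seed)
    for (h in c("diploid", "triploid", "tetraploid")) {
      d <- delta_log_likelihood(fit_fixed_mixture(x, h), free)
      expect_gte(as.numeric(d), 0)
    }
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  for (seed in 1:5) {
    k <- 2 + (seed %% 3)
    x <- mirrored_freqs(filtered_freqs(
      simulate_sample(poisson_config(k, 600, seed + 10))))
    fits <- c(lapply(c("diploid", "triploid", "tetraploid"),
                     function(h) fit_fixed_mixture(x, h)),
              list(fit_free_mixture(x, 3, seed = seed)))
    for (f in fits) {
      tr <- f$trace
      expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-length(tr)]) + 1)))
    }
  }
})

test_that("delta log-likelihood arithmetic, clamping and comparability", {
  x <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(2, 300, 6))))
  fit <- fit_fixed_mixture(x, "diploid")
  same <- fit
  expect_equal(as.numeric(delta_log_likelihood(fit, same)), 0)
  lower <- fit
  lower$logL <- fit$logL - 10
  expect_equal(as.numeric(delta_log_likelihood(lower, fit)), 10)
  above <- fit
  above$logL <- fit$logL + 1e-8   # numerically above free, within tolerance
  d <- delta_log_likelihood(above, fit)
  expect_equal(as.numeric(d), 0)
  expect_match(attr(d, "note"), "tolerance")
  other <- fit
  other$n_obs <- fit$n_obs - 2L
  expect_error(delta_log_likelihood(other, fit), "not comparable")
})

test_that("histogram statistics agree with a closed-form OLS oracle", {
  x <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(4, 1000, 7))))
  fit <- fit_fixed_mixture(x, "tetraploid")
  st <- histogram_fit_stats(x, fit, bins = 30)
  o <- oracle_ols(st$empirical, st$ideal)
  expect_equal(st$slope, o$slope)
  expect_equal(st$SE, o$SE)
  expect_equal(st$R2, o$R2)
  expect_equal(st$SSR, o$SSR)
  expect_lte(st$R2, 1)
  expect_gte(st$SSR, 0)
})

test_that("a matched hypothesis shows near-perfect histogram fit", {
  # stratified sample drawn from the diploid model itself: empirical bins
  # track ideal bins, so slope ~ 1, R2 ~ 1, SSR ~ 0
  mu <- 0.5
  sd0 <- 0.05
  p <- (seq_len(4000) - 0.5) / 4000
  lo <- pnorm(0.2, mu, sd0)
  hi <- pnorm(0.8, mu, sd0)
  x <- qnorm(lo + p * (hi - lo), mu, sd0)
  fit <- fit_fixed_mixture(x, "diploid")
  st <- histogram_fit_stats(x, fit, bins = 25)
  expect_gt(st$R2, 0.99)
  expect_lt(abs(st$slope - 1), 0.05)
  expect_lt(st$SSR, 1e-4)
})

test_that("histogram statistics are invariant under ref/alt swap", {
  sites <- simulate_sample(poisson_config(3, 800, 8))
  swapped <- sites
  swapped$ref_count <- sites$alt_count
  swapped$alt_count <- sites$ref_count
  xa <- sort(mirrored_freqs(filtered_freqs(sites)))
  xb <- sort(mirrored_freqs(filtered_freqs(swapped)))
  fa <- fit_fixed_mixture(xa, "triploid")
  sta <- histogram_fit_stats(xa, fa)
  stb <- histogram_fit_stats(xb, fit_fixed_mixture(xb, "triploid"))
  expect_identical(sta[c("SSR", "slope", "SE", "R2")],
                   stb[c("SSR", "slope", "SE", "R2")])
})

test_that("three-factor call demands agreement and enough SNPs", {
  x <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(2, 1500, 12))))
  fits <- sapply(c("diploid", "triploid", "tetraploid"),
                 function(h) fit_fixed_mixture(x, h), simplify = FALSE)
  free <- fit_free_mixture(x, 3, seed = 12)
  st <- lapply(fits, function(f) histogram_fit_stats(x, f))
  rep1 <- call_mixture_ploidy(fits, free, st, min_snps = 500)
  expect_s3_class(rep1, "model_fit_report")
  expect_equal(rep1$call, "diploid")
  expect_true(rep1$factors_agree)

  # forced factor disagreement: delta favors diploid, histogram tetraploid
  st2 <- st
  st2$diploid$SSR <- 1
  st2$diploid$R2 <- 0
  st2$tetraploid$SSR <- 0
  st2$tetraploid$R2 <- 1
  rep2 <- call_mixture_ploidy(fits, free, st2, min_snps = 500)
  expect_equal(rep2$call, "unresolved")
  expect_false(rep2$factors_agree)
  expect_match(rep2$reason, "disagreement")

  rep3 <- call_mixture_ploidy(fits, free, st, min_snps = 10000)
  expect_equal(rep3$call, "unresolved")
  expect_match(rep3$reason, "insufficient SNPs")

  het <- percent_polymorphic(100, 1e5)  # 0.1% < 0.50 floor
  rep4 <- call_mixture_ploidy(fits, free, st, min_snps = 500,
                              heterozygosity = het)
  expect_equal(rep4$call, "unresolved")
  expect_match(rep4$reason, "reliability")
})

test_that("fits are deterministic given identical input and seed", {
  x <- mirrored_freqs(filtered_freqs(simulate_sample(poisson_config(3, 500, 13))))
  f1 <- fit_free_mixture(x, 3, seed = 99)
  f2 <- fit_free_mixture(x, 3, seed = 99)
  expect_identical(f1, f2)
  g1 <- fit_fixed_mixture(x, "triploid")
  g2 <- fit_fixed_mixture(x, "triploid")
  expect_identical(g1, g2)
})
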