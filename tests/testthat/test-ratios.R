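test_that("per-SNP ratios are major over minor counts", {
  sites <- data.frame(ref_count = c(30L, 75L, 20L), alt_count = c(30L, 25L, 40L))
  r <- snp_ratios(sites)
  expect_equal(r$ratio, c(1, 3, 2))
  bad <- data.frame(ref_count = 10L, alt_count = 0L)
  expect_error(snp_ratios(bad), "contract")
})

test_that("ratio summaries use the linear-interpolation quantile rule", {
  s <- data.frame(sample_id = "s", ref_count = 1L, alt_count = 1L)
  mk <- function(r) {
    x <- data.frame(sample_id = "s", ratio = r)
    x$ref_count <- 1L
    x$alt_count <- 1L
    x
  }
  sm <- summarize_ratios(mk(c(1, 1, 3)))
  expect_equal(sm$median_M, 1)
  expect_equal(sm$pct_below_2, 100 * 2 / 3)
  # hand-computed type-7 quantiles of 1,2,3,4
  sm2 <- summarize_ratios(mk(c(1, 2, 3, 4)))
  expect_equal(sm2$q1, 1.75)
  expect_equal(sm2$median_M, 2.5)
  expect_equal(sm2$q3, 3.25)
  expect_true(sm2$q1 <= sm2$median_M && sm2$median_M <= sm2$q3)
})

test_that("per-gene summaries cover each gene plus the sample level", {
  sites <- snp_ratios(simulate_sample(sim_config(ploidy = 2, n_genes = 4,
                                                 snps_per_gene = 10, seed = 2)))
  sm <- summarize_ratios(sites, by_gene = TRUE)
  expect_equal(nrow(sm), 5L)
  expect_true(is.na(sm$gene_id[1]))
  expect_setequal(sm$gene_id[-1], unique(sites$gene_id))
  expect_equal(sm$n[1], sum(sm$n[-1]))
})

test_that("ratio and minor frequency are deterministically linked", {
  f <- filtered_freqs(simulate_sample(poisson_config(4, 500, 3)))
  r <- snp_ratios(f)
  expect_equal(r$ratio, (1 - f$minor_freq) / f$minor_freq)
})

test_that("expected ratio classes match the printed worked examples", {
  k4 <- expected_ratio_classes(4)
  expect_equal(nrow(k4), 2L)
  expect_equal(k4$ratio, c(3, 1))
  expect_true(all(k4$detectable))

  k6 <- expected_ratio_classes(6)
  expect_equal(k6$ratio, c(5, 2, 1))
  # 5:1 sits at minor frequency 1/6, under the 0.2 noise floor
  expect_equal(k6$detectable, c(FALSE, TRUE, TRUE))
  expect_equal(k6$minor_freq[1], 1 / 6)

  k2 <- expected_ratio_classes(2)
  expect_equal(nrow(k2), 1L)
  expect_equal(k2$ratio, 1)
  expect_true(k2$detectable)

  k16 <- expected_ratio_classes(16)
  expect_equal(nrow(k16), 8L)
  expect_equal(k16$detectable, k16$dosage_j >= 4)

  expect_error(expected_ratio_classes(1), "between 2 and")
  expect_error(expected_ratio_classes(17), "between 2 and")
})

test_that("class enumeration agrees with brute force for every k <= 16", {
  for (k in 2:16) {
    got <- expected_ratio_classes(k)
    oracle <- oracle_ratio_classes(k)
    oracle <- oracle[order(-oracle$ratio), ]
    expect_equal(got$ratio, oracle$ratio)
    expect_equal(got$minor_freq, oracle$minor_freq)
    expect_equal(nrow(got), k %/% 2)
    expect_true(all(diff(got$ratio) < 0))
    expect_equal(got$ratio, (1 - got$minor_freq) / got$minor_freq)
  }
})

test_that("bootstrap envelope is deterministic, normalized, degenerate-safe", {
  ratio <- snp_ratios(filtered_freqs(
    simulate_sample(poisson_config(2, 800, 5))))$ratio
  e1 <- bootstrap_density_envelope(ratio, n_boot = 50, seed = 7)
  e2 <- bootstrap_density_envelope(ratio, n_boot = 50, seed = 7)
  expect_identical(e1, e2)
  step <- e1$grid[2] - e1$grid[1]
  expect_lt(abs(sum(e1$mean_density) * step - 1), 0.01)
  expect_true(all(e1$mean_density >= 0))

  single <- bootstrap_density_envelope(ratio, n_boot = 1, seed = 7)
  expect_true(all(single$sd == 0))

  expect_error(bootstrap_density_envelope(rep(1, 50)), "degenerate")
})

test_that("doubling the reference shrinks the bootstrap envelope", {
  sd_mean <- function(n, seed) {
    r <- snp_ratios(filtered_freqs(
      simulate_sample(poisson_config(2, n, seed))))$ratio
    mean(bootstrap_density_envelope(r, n_boot = 80, seed = seed)$sd)
  }
  small <- vapply(1:3, function(s) sd_mean(400, s), numeric(1))
  large <- vapply(1:3, function(s) sd_mean(1600, s), numeric(1))
  expect_true(mean(large) < mean(small))
})

test_that("ratio classification applies the median-2 rule and flags", {
  row <- function(m, p2, n = 1000) {
    data.frame(sample_id = "s", gene_id = NA, n = n, median_M = m,
               q1 = 1, q3 = m + 1, pct_below_2 = p2)
  }
  expect_equal(classify_by_ratios(row(1.3, 98))$class, "diploid-like")
  expect_equal(classify_by_ratios(row(2.7, 30))$class, "polyploid")
  # tetraploid mixture call with sub-2 median: recent autopolyploid signature
  got <- classify_by_ratios(row(1.7, 61.7), mixture_call = "tetraploid")
  expect_equal(got$class, "possible-recent-autopolyploid")
  # the 50-65% band alone also flags it
  got2 <- classify_by_ratios(row(1.9, 59.1))
  expect_equal(got2$class, "possible-recent-autopolyploid")
  # boundary: exactly 2 is polyploid, flagged
  got3 <- classify_by_ratios(row(2, 40))
  expect_equal(got3$class, "polyploid")
  expect_match(got3$flags, "boundary", all = FALSE)
  expect_equal(classify_by_ratios(row(1.5, 99, n = 10))$class, "ambiguous")
})

test_that("simulated cytotypes land on the documented ratio signatures", {
  dip <- summarize_ratios(snp_ratios(filtered_freqs(
    simulate_sample(poisson_config(2, 2000, 31)))))
  expect_lt(dip$median_M, 2)
  expect_gt(dip$pct_below_2, 95)

  tet <- summarize_ratios(snp_ratios(filtered_freqs(
    simulate_sample(poisson_config(4, 2000, 31)))))
  expect_gte(tet$median_M, 2)
  expect_lt(tet$pct_below_2, 50)
})

test_that("envelope exceedance reports extra peaks for a tetraploid", {
  dip_ratio <- snp_ratios(filtered_freqs(
    simulate_sample(poisson_config(2, 1500, 41))))$ratio
  env <- bootstrap_density_envelope(dip_ratio, n_boot = 100, seed = 41)
  tet <- snp_ratios(filtered_freqs(simulate_sample(poisson_config(4, 1500, 41))))
  sm <- summarize_ratios(tet)
  got <- classify_by_ratios(sm, envelope = env, ratio = tet$ratio)
  expect_gt(nrow(got$extra_peaks), 0)
  # the tetraploid's exceedances concentrate in the ratio-3 region, far
  # beyond anything a second diploid produces there
  dip2 <- snp_ratios(filtered_freqs(simulate_sample(poisson_config(2, 1500, 42))))
  got2 <- classify_by_ratios(summarize_ratios(dip2), envelope = env,
                             ratio = dip2$ratio)
  in_peak <- function(g) sum(g$extra_peaks$grid > 2.5 & g$extra_peaks$grid < 4)
  expect_gt(in_peak(got), 5 * max(in_peak(got2), 1))
})
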