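---
title: "Ploidy inference from allele balance: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy inference from allele balance: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybploidy)
```

## The statistical model

At a heterozygous biallelic SNP in a genome of ploidy $k$, an allele
carried by $j$ of the $k$ homologous copies is sampled by sequencing reads
with probability $j/k$ (plus read error). With read depth $d$, the
observed allele frequency at a site is approximately Gaussian around $j/k$
with spread $\sqrt{(j/k)(1-j/k)/d}$. Pooling thousands of SNPs, the
frequency distribution is a finite mixture over the dosage classes the
ploidy admits.

Every site contributes *both* orientations — its minor frequency $f$ and
the mirror $1-f$ — so the fitted distribution is symmetric around $1/2$ by
construction, like the paired histogram peaks one inspects visually
(33%/67% for a triploid, 25%/75% for a tetraploid). Under this mirrored
representation and the assumption that each heterozygous allele
configuration is equally likely, the class weights are fully determined:

| hypothesis | means | weights |
|---|---|---|
| diploid | 1/2 | 1 |
| triploid | 1/3, 2/3 | 1/2, 1/2 |
| tetraploid | 1/4, 1/2, 3/4 | 1/3, 1/3, 1/3 |

`hybploidy` pins both the means *and* the weights of the named
hypotheses. This is a deliberate choice with a structural reason: $1/2$
is one of the tetraploid means, so if the weights were free the
tetraploid model would nest the diploid model and its maximized
likelihood could never fall below the diploid's — "smallest
$\Delta\log L$" would be systematically biased against the diploid
hypothesis (in our simulations, every diploid sample was misassigned to
tetraploid under free weights). With pinned weights each hypothesis is a
genuine point hypothesis about the dosage composition, and the only free
parameter is the shared spread $\sigma$, profiled out exactly (coarse
log-spaced scan, then golden-section refinement — the profile can be
multimodal when the hypothesis is badly misspecified, so a refinement-only
search is not safe). The cost of pinning is sensitivity to non-uniform
dosage: a recent autopolyploid with mostly balanced (2:2) sites fits none
of the three hypotheses well and is deliberately pushed toward
`unresolved`, where the ratio statistics take over.

## Truncation: respecting the noise filter

Minor frequencies below the noise threshold $t$ (default 0.2) cannot be
told apart from sequencing error and are removed before fitting. The data
handed to the mixture stage therefore live on $[t, 1-t]$, and the model
components are Gaussians *truncated* to that interval. Ignoring the
truncation is not harmless: the tetraploid outer components at $0.25$ lose
roughly the bottom tenth of their mass to the filter at 100x depth, and an
untruncated fit compensates by biasing the fitted mean upward to ~0.26.
With truncated components the free-mixture fit recovers 25/50/75 to the
nearest percent, which is also what the acceptance suite checks.

The free model (reference for $\Delta\log L$) estimates means, weights and
$\sigma$ by EM on the truncated mixture. The truncated M-step has no closed
form; we use the standard truncated-normal moment-corrected fixed-point
updates and retain the best-likelihood iterate. Restarts: the canonical
start (component means at 1/4, 1/2, 3/4 for the default three components)
plus four seeded jitters, *plus* warm starts at each fixed hypothesis'
exact solution (a hypothesis with fewer components is embedded by
duplicating a mean and splitting its weight, which leaves the density
unchanged). The warm starts guarantee
$\log L(\text{free}) \ge \log L(\text{fixed})$ up to machine precision, so
$\Delta\log L \ge 0$ holds by construction rather than by hope.

## The three-factor call

A hypothesis is called only when three factors agree:

1. smallest $\Delta\log L$ (ties within $10^{-6}$ go to the lower ploidy,
   flagged);
2. the histogram factor: the same hypothesis attains the smallest SSR and
   the largest $R^2$ when the empirical bin masses (50 equal bins on
   $[t, 1-t]$, unit mass) are regressed on the model's ideal bin masses by
   ordinary least squares. The published procedure leaves the regression's
   axes unstated; we regress empirical on ideal, so a perfect fit gives
   slope 1 with small standard error. This operationalizes the "direct
   observation of the histograms" step that cannot be automated as stated;
3. enough evidence: at least `min_snps` (default 500) retained SNPs, and,
   when callable-base totals are available, percent-polymorphic
   heterozygosity at or above 0.50% — below that floor allele-balance
   methods are known to become unreliable, so the call is downgraded
   rather than trusted.

Disagreement yields `unresolved`, a value, not an error.

## Allelic ratios

The per-SNP allelic ratio $r = \max(a, b)/\min(a, b)$ of the two allele
depths folds the mirrored frequency axis: the expected value for dosage
$j$ is $(k-j)/j$. `expected_ratio_classes()` enumerates all
$\lfloor k/2 \rfloor$ classes for any $k \le 16$ with their minor
frequencies $j/k$ and a detectability flag $j/k \ge t$: the hexaploid 5:1
class sits at $1/6 < 0.2$ and is shadowed, which is the precise reason the
pipeline reports `>=4x` rather than exact levels above tetraploid.

Sample-level summaries use the median ("M"), quartiles (linear
interpolation, R's type 7 — the convention is unstated in the source
material, so the R default is declared rather than guessed) and the
percentage of ratios below 2. The decision rules interpolate the empirical
separations observed in real capture data: median < 2 is diploid-like,
median ≥ 2 polyploid (a median of exactly 2 is polyploid, flagged);
a sub-2 median with a tetraploid mixture call, or a
percentage-below-2 inside the 50–65% band, flags a possible recent
autopolyploid (diploids sit clearly above 65%, established polyploids
clearly below 50%).

One subtlety drives the combination rule: a triploid's single ratio class
is 2:1, so its median sits *exactly on* the diploid/polyploid cut —
simulated triploids at 100x give medians 1.98–2.02, a coin flip around 2.
The ratio median therefore carries no information against a triploid
mixture call, and `ploidy_fit()` confirms triploid unless the percentage
of ratios below 2 exceeds 65% (a clear diploid signature). For all other
hypotheses the two lines of evidence must agree outright.

Bootstrap envelopes resample a known diploid's ratios with replacement
(default 1000 replicates), evaluate a Gaussian kernel density (Silverman's
bandwidth) on a shared 512-point grid from 1 to the reference's 99.5th
percentile + 1, and store the per-point mean and standard deviation. Each
replicate's density is renormalized to unit mass on the grid — the kernel
otherwise leaks mass below ratio 1, where no ratio can exist — so the mean
curve integrates to 1. A query sample exceeding mean + 2 sd (multiplier
configurable) shows ratio peaks a diploid does not produce.

## The simulator: what it emulates, what it does not

`simulate_sample()` draws, per heterozygous site: a dosage class $j$ from
`dosage_weights` over $1..k-1$ (uniform default — every allele
configuration equally likely), a depth from a negative binomial with mean
`mean_depth` (default 100, the order of magnitude of capture coverage)
and dispersion 5 (variance $\mu + \mu^2/5$, reproducing the wide
per-locus coverage spread of hybridization capture; `Inf` gives Poisson),
and an alternate-allele count from a binomial at $j/k$ perturbed by a
symmetric per-read error (default 0.5%, a realistic post-filter Illumina
substitution rate). Ref/alt orientation is randomized per site.
`simulate_autopolyploid()` concentrates `balanced_fraction` (default 0.8)
of the mass on the balanced class $j = k/2$.

It deliberately does **not** model capture bias along genes, mapping
artifacts, paralogy/collapsed duplicates, contamination, or herbarium DNA
damage (deamination). A green simulation test therefore establishes that
the estimator recovers ploidy when its dosage model holds — not that any
particular empirical dataset satisfies that model; paralogous capture in
particular can mimic polyploid dosage and must be judged per locus.

## Numerical choices and degenerate inputs

* EM convergence: relative log-likelihood change $< 10^{-8}$ or 1000
  iterations; shared $\sigma$ floored at $10^{-3}$ to avoid the singular
  likelihood spike.
* Minimum 20 mirrored observations for any fit; fewer is an
  insufficient-data error, and a sample with no usable sites yields an
  `unresolved` call with a reason, not an exception.
* The noise filter keeps frequencies exactly at the threshold ("below
  0.2" is removed strictly).
* Depth floor: 10 reads per site, configurable; per-site frequencies from
  a handful of reads are meaningless even though capture coverage is
  typically far higher.
* All randomness (free-model restarts, bootstrap, simulation) flows from
  explicit integer seeds; batch runs derive per-sample seeds from the
  top-level seed and the sample name, so reports are byte-identical across
  reruns.
* Reports format floats at 4 decimals in a fixed column order
  (bit-stable); the genome-size helper rounds $2 \cdot 1C/1Cx$ to the
  nearest integer (odd ploidy is real, so never to the nearest even),
  rounds exact .5 ties up and flags them, and marks residuals above 0.25
  ambiguous.

## Known limitations

* Ploidy above 4x is reported only as `>=4x`; the shadowed ratio classes
  make exact higher levels unidentifiable at threshold 0.2.
* Recent autopolyploids with strongly balanced dosage are expected to
  come out `unresolved` or flagged rather than called — this mirrors the
  biology, not a bug to be tuned away.
* Aneuploidy is invisible without a contiguous reference genome.
* The heterozygosity check needs externally supplied callable-base
  totals; the package refuses to guess them from SNP spans.
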