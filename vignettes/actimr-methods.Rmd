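---
title: "Methods: two-sample MR for accelerometer-measured physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for accelerometer-measured physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`actimr` implements two-sample summary-data Mendelian randomisation. The
structural model behind every estimator is: for SNP $j$ with true effect
$\gamma_j$ on the exposure (accelerometer-measured physical activity, SD
units) and possible direct effect $\alpha_j$ on the outcome,

$$\beta_{Yj} = \theta\,\gamma_j + \alpha_j + \varepsilon_{Yj}, \qquad
  \beta_{Xj} = \gamma_j + \varepsilon_{Xj},$$

where $\theta$ is the causal log odds ratio per exposure SD and the
$\varepsilon$ are GWAS sampling errors with known standard errors. Causal
interpretation needs the three instrumental-variable assumptions:
relevance ($\gamma_j \neq 0$, checked by F-statistics), independence from
confounders, and exclusion ($\alpha_j = 0$; probed, not provable, by the
Egger intercept, Cochran's $Q$, MR-PRESSO, leave-one-out, adiposity-SNP
exclusion and multivariable adjustment for BMI).

Estimation is staged as the field's packages do it: per-SNP Wald ratios
$\hat\theta_j = \beta_{Yj}/\beta_{Xj}$ with first-order delta-method
standard errors $se_j = se_{Yj}/|\beta_{Xj}|$ (the NOME convention: the
exposure beta treated as known, which makes fixed-effect IVW identical to
the inverse-variance-weighted regression of outcome on exposure betas
through the origin — an identity the test suite asserts to 1e-12), then
pooling. "Random effects" means the multiplicative model, inflating the
fixed-effect standard error by $\max\{1, \sqrt{Q/(J-1)}\}$, not additive
DerSimonian–Laird: it is the convention of the summary-data MR packages
and pairs naturally with the $Q$-based trigger (`effects = "auto"`
switches to random effects at $Q$ p-value $\le 0.05$).

## Tunable parameters that matter

* `sd_units = 8.14` — the exposure SD in milli-gravities. Estimates from
  milligravity-unit instruments are multiplied by it so every reported OR
  is per 1 SD of average acceleration. For instruments already on the SD
  scale it must be 1 (the pipeline handles this via the instrument's
  recorded `exposure_unit`).
* `palindrome_policy`, ambiguity window fixed at eaf in (0.42, 0.58) —
  A/T and C/G variants cannot be strand-resolved from allele letters;
  inside the window allele frequency cannot resolve them either, so
  `infer_by_eaf` drops them. The window is standard practice; the source
  analysis does not state one.
* `effects = "auto"` — see above; `fixed` and `random` are available for
  sensitivity.
* `n_boot = 10000`, `seed` — weighted-median parametric bootstrap:
  both betas of every SNP are resampled from normals with their own
  standard errors. Fully seeded, single stream, reproducible.
* `mr_presso(n_sim = 5000, significance = 0.05)` — the source analysis
  names the method but not its settings; 5,000 draws put the Monte-Carlo
  error of a 0.05-level p-value near 0.003, and the outlier threshold is
  the published MR-PRESSO convention (Bonferroni-corrected 0.05 across
  SNPs). Empirical p-values are floored at `1/n_sim` and flagged when
  floored. The distortion test is reported but never auto-removes SNPs:
  exclusion is an explicit user action, mirroring how the source study
  reports before/after estimates.
* `alpha = 0.05`, CI multiplier fixed at 1.959964 — all intervals are
  two-sided 95%.

## Exposure-unit ambiguity of the built-in instruments

The printed instrument table states that both instruments' betas are in
milligravities, yet the 5-SNP betas (0.03–0.04) are about 8 times smaller
than the 10-SNP betas (0.20–0.51) — exactly the SD-to-milligravity factor
(0.03 x 8.14 = 0.24). The package therefore records `doherty5` as
SD-scale and `klimentidis10` as milligravity-scale, never rescales
silently, and exposes the unit on the instrument object. Consistently,
per-variant R² uses the allele-frequency formula `2pq beta²` for
`doherty5` (valid only for SD-scale betas) and the unit-free
standard-error formula for `klimentidis10` — the same split the source
analysis describes. Recomputed totals are ~0.21% and ~0.37%, matching the
published "0.2% and 0.4%". Four of the ten printed F-statistics
(rs55657917 = 56, rs9293503 = 31, rs1550435 = 29, rs12045968 = 30)
reproduce exactly from the printed rounded inputs; the remainder evidently
used unrounded GWAS values, so only those four are pinned by tests.

## What the synthetic generator emulates — and what it does not

`simulate_two_sample()` draws, from one seeded stream: MAFs uniform on
`maf_range`; true exposure effects $\gamma_j$ half-normal with SD
`sigma_gamma`, rejected below `gamma_min = 0.01` (keeps Wald denominators
away from zero; configurable); exposure standard errors
$(2pq\,n_{exp})^{-1/2}$ (SD-scale linear GWAS); outcome standard errors
$(2pq\,n_{out}K(1-K))^{-1/2}$ (logistic-score approximation — it gives
log-OR standard errors of realistic magnitude for the printed case/control
mixes); observed betas normal around their truths; pleiotropy
$\alpha_j$ per mode (`none`, `balanced`, `directional`, `outliers`,
`correlated` = InSIDE violation $\alpha_j = \kappa\gamma_j +$ noise).
Scenario presets pin the study's printed dimensions: exposure GWAS
n = 91,084, colorectal outcome GWAS n = 98,715 with K = 0.5346, and
`causal` uses $\theta = -0.4$ (the colorectal scale, $\ln 0.66 = -0.42$).

Two deliberate conventions:

* **Orientation.** Effect alleles are the activity-increasing alleles
  ($\gamma_j > 0$), as in published instrument tables. MR-Egger is not
  orientation-invariant: with random signs, its non-negative-exposure
  flip would convert directional pleiotropy into balanced pleiotropy and
  the intercept would no longer estimate $\mu_\alpha$.
* **Instrument strength.** `sigma_gamma = 0.25` SD per allele gives
  per-SNP F around 2,000 — far stronger than the real instruments
  (F 27–56). This is intentional: the generator's role in the test suite
  is estimator validation (type-I error, parameter recovery within 2
  Monte-Carlo SEs over 1,000 replicates, CI coverage), and at realistic
  instrument strength the well-known weak-instrument attenuation of
  two-sample IVW (relative bias about $1/\bar F$, i.e. ~3% at F ≈ 33)
  exceeds the Monte-Carlo resolution of those calibration checks. A green
  calibration test therefore establishes that the estimators are coded
  correctly, **not** that IVW is unbiased with instruments as weak as the
  real ones. The `directional` preset sets $\theta = 0$ (pleiotropy
  masquerading as an effect) for the same isolation reason: a non-zero
  slope would leak dilution bias into the intercept.

The generator does not emulate: LD between instrument SNPs, sample
overlap between the two GWAS, individual-level genotypes, allele-frequency
differences between samples, or strand mix-ups (alleles are coded
identically in both samples, so harmonisation is the identity on
synthetic data — harmonisation logic is tested on constructed fixtures
instead). Draws are vectorised field-by-field rather than SNP-by-SNP;
reproducibility is guaranteed by seed + truth, not by a cross-language
draw order.

## Numerical choices

* BH q-values are computed by the step-up running minimum on the
  descending sort; invariants ($q \ge p$, $\max q = \max p$) hold to
  floating error in `p * m / rank`.
* `minimum_detectable_or()` brackets geometrically from OR = 1 outward,
  stops if the power approximation degenerates ($K(1-K) \le b^2$), and
  root-finds to |power − target| < 1e-6; a target at or below
  $\alpha/2$ (the power at the OR = 1 boundary) is an explicit error.
* MR-Egger and multivariable IVW use closed-form weighted least squares
  with multiplicative overdispersion floored at 1; the Egger intercept
  test uses t with $J-2$ df (small-J inference), all other p-values the
  normal reference.
* Weighted-median interpolation uses ordered ties (`approx(...,
  ties = "ordered")`); estimates at or beyond the extreme cumulative
  weights return the boundary ratio.
* Duplicated rsids in input files keep the first occurrence with a
  warning; invalid rows are rejected with row-indexed diagnostics rather
  than failing the whole file.
* Per-cell seeds in the pipeline are derived from the master seed as
  `seed + 7919 * cell_index` (kept below 2^31), so adding an outcome does
  not shift other cells' bootstrap streams.

## Design decisions that were genuinely open

* **FDR family**: all IVW tests of both instruments across all outcomes
  in one family of 20. This family reproduces every printed q-value that
  is internally consistent (0.04→0.062, 0.01→0.022, 0.054→0.077, …);
  per-instrument families do not. One printed q-value (ER+, 10-SNP
  instrument, 0.004 = its own p-value) is inconsistent with any family
  that reproduces the others and is treated as a typographical error.
* **Subgroup heterogeneity** is validated on the sex contrast (I² = 0%,
  robust to CI rounding); the printed subtype I² of 16% is not
  recoverable from the rounded table and is not asserted.
* **MR-PRESSO outlier sets**: a gross single outlier contaminates every
  leave-one-out slope, so neighbouring SNPs can be co-flagged; the tests
  assert that the injected SNP is flagged and is the most extreme, not
  that it is alone.
* **Multivariable MR** rejects an identically-zero exposure column as
  rank-deficient rather than returning the nested univariable fit; the
  nesting property is instead guaranteed (and tested, to 1e-12) for the
  single-exposure case.

## Known limitations

The Table-1 causal ORs themselves (e.g. breast 0.51, colorectal 0.66)
cannot be reproduced here: they require per-SNP outcome associations from
the BCAC and GECCO/CORECT/CCFR consortia, which are not printed and do
not ship with the package. The replication tests therefore validate every
computational stage against in-paper numbers (instrument strength, power
thresholds, q-values, subgroup I²) and against synthetic data with known
truth. Proxy-SNP lookup, genome-build liftover, external phenotype
scanning, and the milligravity-to-minutes conversion are out of scope.
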