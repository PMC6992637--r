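# Instrument strength (R2, F) and a priori power for binary outcomes.

#' Per-variant variance explained, allele-frequency formula
#'
#' `R2 = 2 * EAF * (1 - EAF) * beta^2`, valid when the exposure beta is on
#' the standardised (SD) scale. Symmetric in `eaf` and `1 - eaf`.
#'
#' @param eaf Effect-allele frequency in \[0, 1\].
#' @param beta Per-allele effect on the exposure, SD units.
#' @return Fraction of exposure variance explained. Vectorised.
#' @seealso [r2_from_se()] for unstandardised betas.
#' @export
r2_simple <- function(eaf, beta) {
  stopifnot(all(eaf >= 0 & eaf <= 1))
  2 * eaf * (1 - eaf) * beta^2
}

#' Per-variant variance explained, standard-error formula
#'
#' `R2 = (2 p q beta^2) / (2 p q beta^2 + 2 p q N se^2)` with `p = EAF`,
#' `q = 1 - EAF`. Unit-free (the beta scale cancels), hence usable when
#' betas are in raw exposure units such as milli-gravities.
#'
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param beta Per-allele effect on the exposure.
#' @param se Standard error of `beta`, > 0.
#' @param n GWAS sample size, >= 2.
#' @return Fraction in \[0, 1). Vectorised.
#' @export
r2_from_se <- function(eaf, beta, se, n) {
  if (any(eaf <= 0 | eaf >= 1))
    stop("degenerate variant: eaf must be strictly inside (0, 1)")
  stopifnot(all(se > 0), all(n >= 2))
  num <- 2 * eaf * (1 - eaf) * beta^2
  num / (num + 2 * eaf * (1 - eaf) * n * se^2)
}

#' Instrument F-statistic
#'
#' `F = R2 (N - 2) / (1 - R2)`; values below 10 conventionally indicate a
#' weak instrument.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n GWAS sample size, >= 2.
#' @return F value (>= 0). Vectorised.
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("domain error: r2 must lie in [0, 1)")
  stopifnot(all(n >= 2))
  r2 * (n - 2) / (1 - r2)
}

#' Strength report for an instrument
#'
#' Per-variant R-squared (using the instrument's own formula) and
#' F-statistic, with instrument totals. Warns when any variant falls below
#' the conventional weak-instrument threshold F < 10.
#'
#' @param instrument An `mr_instrument` (see [new_instrument()],
#'   [builtin_instrument()]).
#' @return A data.frame (`rsid`, `r2`, `f`) with attributes `total_r2` and
#'   `min_f`.
#' @export
#' @examples
#' instrument_strength(builtin_instrument("klimentidis10"))
instrument_strength <- function(instrument) {
  stopifnot(inherits(instrument, "mr_instrument"))
  v <- instrument$variants
  r2 <- instrument_r2(v, instrument$r2_method)
  f <- f_statistic(r2, v$n)
  if (any(f < 10))
    warning("weak instrument: F < 10 for ",
            paste(v$rsid[f < 10], collapse = ", "), call. = FALSE)
  structure(data.frame(rsid = v$rsid, r2 = r2, f = f,
                       stringsAsFactors = FALSE),
            total_r2 = sum(r2), min_f = min(f))
}

#' A priori power of an MR analysis with a binary outcome
#'
#' Non-centrality approximation for a two-sample MR test of an odds ratio
#' `or_alt` per SD of the exposure, given a case/control outcome GWAS:
#' `b = K (OR / (1 + K (OR - 1)) - 1)`, `v = (K (1 - K) - b^2) / (N R2)`,
#' `NCP = b^2 / v`, `power = Phi(sqrt(NCP) - z_{1 - alpha/2})` (one-tailed
#' form; the second tail is negligible at practical NCPs). At `or_alt = 1`
#' the power equals `alpha / 2`.
#'
#' @param n_total Total outcome-GWAS sample size (cases + controls).
#' @param case_fraction Proportion of cases K, in (0, 1).
#' @param r2 Instrument variance explained, in (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio per exposure SD, > 0.
#' @param alpha Two-sided type-1 error, default 0.05.
#' @return Power in \[0, 1\]. Vectorised over `or_alt`.
#' @export
#' @examples
#' power_binary(228951, 122977 / 228951, 0.002, 0.77)
power_binary <- function(n_total, case_fraction, r2, or_alt, alpha = 0.05) {
  stopifnot(case_fraction > 0, case_fraction < 1, r2 > 0, r2 < 1,
            all(or_alt > 0), alpha > 0, alpha < 1)
  k <- case_fraction
  b <- k * (or_alt / (1 + k * (or_alt - 1)) - 1)
  v <- (k * (1 - k) - b^2) / (n_total * r2)
  if (any(v <= 0))
    stop("degenerate parameters: K(1-K) <= b^2, power approximation invalid")
  pnorm(sqrt(b^2 / v) - qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [power_binary()] by root finding on the protective (OR < 1) or
#' risk (OR > 1) side until the achieved power matches `target_power`
#' within 1e-6.
#'
#' @inheritParams power_binary
#' @param target_power Power to reach, in (0, 1); default 0.80.
#' @param side `"protective"` or `"risk"`.
#' @return The detectable odds ratio.
#' @export
#' @examples
#' minimum_detectable_or(228951, 122977 / 228951, 0.002)
minimum_detectable_or <- function(n_total, case_fraction, r2,
                                  target_power = 0.80, alpha = 0.05,
                                  side = c("protective", "risk")) {
  side <- match.arg(side)
  stopifnot(target_power > 0, target_power < 1)
  if (target_power <= alpha / 2)
    stop("no solution: power approaches alpha/2 = ", alpha / 2,
         " at the OR = 1 boundary; target_power must exceed it")
  pw <- function(or) tryCatch(
    power_binary(n_total, case_fraction, r2, or, alpha),
    error = function(e) NA_real_)
  step <- if (side == "protective") 0.98 else 1 / 0.98
  lo <- 1 * step
  # march away from the null until the target power is bracketed
  repeat {
    p <- pw(lo)
    if (is.na(p))
      stop("no solution: power approximation degenerates before reaching ",
           "target_power = ", target_power)
    if (p >= target_power) break
    lo <- lo * step
    if (lo < 1e-4 || lo > 1e4)
      stop("no solution: target_power unreachable within the OR bracket")
  }
  f <- function(or) pw(or) - target_power
  bounds <- if (side == "protective") c(lo, 1 - 1e-9) else c(1 + 1e-9, lo)
  root <- uniroot(f, lower = min(bounds), upper = max(bounds),
                  tol = 1e-12)$root
  if (abs(pw(root) - target_power) > 1e-6)
    stop("no solution: root finding did not reach target_power within 1e-6")
  root
}
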