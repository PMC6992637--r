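# Pleiotropy diagnostics: MR-PRESSO, leave-one-SNP-out, SNP-set exclusion
# and multivariable MR adjusting for a second exposure.

#' The five adiposity-related SNPs of the extended instrument
#'
#' rsids in the 10-SNP physical-activity instrument previously associated
#' with BMI, waist circumference, weight or body/trunk fat percentage at
#' genome-wide significance; used by the adiposity-exclusion sensitivity
#' analysis.
#'
#' @return Character vector of 5 rsids.
#' @export
adiposity_snps <- function() {
  c("rs34517439", "rs6775319", "rs11012732", "rs1550435", "rs59499656")
}

#' Remove named variants from an instrument
#'
#' Returns a new instrument without the listed rsids; the variance
#' explained is recomputed with the instrument's own R-squared formula.
#' rsids absent from the instrument are ignored with a warning.
#'
#' @param instrument An `mr_instrument`.
#' @param rsids Character vector of rsids to drop.
#' @return A new `mr_instrument`.
#' @export
#' @examples
#' exclude_snps(builtin_instrument("klimentidis10"), adiposity_snps())
exclude_snps <- function(instrument, rsids) {
  stopifnot(inherits(instrument, "mr_instrument"))
  absent <- setdiff(rsids, instrument$variants$rsid)
  if (length(absent))
    warning("rsid(s) not in instrument, ignored: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- !instrument$variants$rsid %in% rsids
  if (!any(keep)) stop("empty instrument: all variants excluded")
  new_instrument(instrument$variants[keep, , drop = FALSE],
                 name = instrument$name,
                 exposure_unit = instrument$exposure_unit,
                 r2_method = instrument$r2_method)
}

# Leave-one-out fixed-effect IVW slopes of b_Y on b_X through the origin,
# weights 1/se_Y^2; returns one slope per left-out SNP.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO outlier and distortion test
#'
#' Simulation-based residual-sum-of-squares test for pleiotropic outliers.
#' The observed statistic is the weighted leave-one-out RSS
#' `sum_j w_j (b_Yj - beta_(-j) b_Xj)^2`, where `beta_(-j)` is the
#' fixed-effect IVW estimate without SNP j. Its null distribution is
#' simulated by drawing outcome betas from normals centred on the
#' leave-one-out predictions with the observed standard errors and
#' recomputing the statistic (leave-one-out slopes re-estimated on every
#' simulated dataset). Per-SNP outlier p-values are the empirical tail
#' probabilities of each observed squared residual, Bonferroni-corrected
#' across SNPs; SNPs below `significance` are flagged. The distortion test
#' compares the change in IVW estimate after outlier removal against a
#' null built by removing random SNP subsets of the same size. Outliers
#' are never removed automatically: both estimates are returned and
#' exclusion remains an explicit user action.
#'
#' @param harmonised An `mr_harmonised` data.frame with at least 4 SNPs.
#' @param n_sim Null-distribution draws, default 5,000. Empirical p-values
#'   are floored at `1 / n_sim`.
#' @param significance Outlier threshold on Bonferroni-corrected p-values,
#'   default 0.05.
#' @param seed Integer seed; the test is bit-reproducible given a seed.
#' @return List of class `mr_presso` with `global_rss_observed`,
#'   `global_pvalue`, `outlier_pvalues` (named, Bonferroni-corrected),
#'   `outlier_rsids`, `estimate_before`, `estimate_after`,
#'   `distortion_pvalue`, `n_sim`, `seed`.
#' @export
mr_presso <- function(harmonised, n_sim = 5000, significance = 0.05,
                      seed = NULL) {
  h <- as.data.frame(harmonised)
  j <- nrow(h)
  if (j < 4L) stop("insufficient variants: MR-PRESSO needs at least 4 SNPs")
  bx <- h$beta_exposure; by <- h$beta_outcome; sey <- h$se_outcome
  w <- sey^-2
  slopes <- loo_slopes(bx, by, w)
  resid_obs <- by - slopes * bx
  rss_obs <- sum(w * resid_obs^2)

  sim <- with_local_seed(seed, {
    pred <- slopes * bx
    rss_sim <- numeric(n_sim)
    exceed <- numeric(j)
    for (s in seq_len(n_sim)) {
      bys <- rnorm(j, pred, sey)
      sl <- loo_slopes(bx, bys, w)
      rs <- bys - sl * bx
      rss_sim[s] <- sum(w * rs^2)
      exceed <- exceed + (rs^2 >= resid_obs^2)
    }
    list(rss_sim = rss_sim, exceed = exceed)
  })

  floor_p <- 1 / n_sim
  global_p <- max(mean(sim$rss_sim >= rss_obs), floor_p)
  p_raw <- pmax(sim$exceed / n_sim, floor_p)
  p_out <- pmin(p_raw * j, 1)
  names(p_out) <- h$rsid
  outliers <- h$rsid[p_out < significance]

  before <- ivw(wald_ratios(h))
  if (length(outliers)) {
    keep <- !h$rsid %in% outliers
    after <- ivw(wald_ratios(h[keep, , drop = FALSE]))
    dist_p <- with_local_seed(if (is.null(seed)) NULL else seed + 1L, {
      n_d <- min(n_sim, 1000L)
      d_obs <- after$beta - before$beta
      d_sim <- vapply(seq_len(n_d), function(s) {
        drop_idx <- sample.int(j, length(outliers))
        sub <- ivw(wald_ratios(h[-drop_idx, , drop = FALSE]),
                   effects = "fixed")
        sub$beta - before$beta
      }, numeric(1))
      max(mean(abs(d_sim) >= abs(d_obs)), 1 / n_d)
    })
  } else {
    after <- before
    dist_p <- NA_real_
  }

  structure(list(global_rss_observed = rss_obs, global_pvalue = global_p,
                 global_pvalue_floored = global_p <= floor_p,
                 outlier_pvalues = p_out, outlier_rsids = outliers,
                 estimate_before = before, estimate_after = after,
                 distortion_pvalue = dist_p, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS %.4f, p %s %.4g (%d simulations)\n",
              x$global_rss_observed,
              if (isTRUE(x$global_pvalue_floored)) "<" else "=",
              x$global_pvalue, x$n_sim))
  if (length(x$outlier_rsids))
    cat("  outliers:", paste(x$outlier_rsids, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pvalue))
  else cat("  no outliers detected\n")
  invisible(x)
}

#' Leave-one-SNP-out analysis
#'
#' Re-estimates the IVW (auto effects) causal estimate with each SNP
#' excluded in turn, plus the all-SNP estimate labelled `"none"`.
#'
#' @param harmonised An `mr_harmonised` data.frame with at least 3 SNPs.
#' @return Data.frame with columns `excluded`, `beta`, `se`, `or_`,
#'   `ci_low`, `ci_high`, `pvalue`, `n_snps`.
#' @export
leave_one_out <- function(harmonised) {
  h <- as.data.frame(harmonised)
  j <- nrow(h)
  if (j < 3L)
    stop("insufficient variants: leave-one-out needs at least 3 SNPs")
  one <- function(res, label) {
    data.frame(excluded = label, beta = res$beta, se = res$se,
               or_ = res$or_, ci_low = res$ci_low, ci_high = res$ci_high,
               pvalue = res$pvalue, n_snps = res$n_snps,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(j), function(i)
    one(ivw(wald_ratios(h[-i, , drop = FALSE])), h$rsid[i]))
  rows <- c(rows, list(one(ivw(wald_ratios(h)), "none")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariable IVW regression
#'
#' Joint (direct) causal effects of two or more exposures: weighted least
#' squares of the outcome betas on the matrix of exposure betas without an
#' intercept, weights `1 / se_outcome^2`. Standard errors carry a
#' multiplicative overdispersion factor floored at 1 (the multivariable
#' analogue of the univariable multiplicative random-effects convention);
#' with a single exposure the result reproduces the univariable
#' random-effects [ivw()] exactly.
#'
#' @param multi Data.frame with columns `beta_<exposure>` for each
#'   exposure, plus `beta_outcome` and `se_outcome` (and optionally
#'   `rsid`); all blocks aligned to a common effect allele per SNP.
#' @param exposures Character vector naming the exposures to include;
#'   `NULL` uses every `beta_*` column except the outcome.
#' @return Named list of `mr_result`, one per exposure.
#' @export
multivariable_ivw <- function(multi, exposures = NULL) {
  m <- as.data.frame(multi)
  stopifnot(!is.null(m$beta_outcome), !is.null(m$se_outcome))
  if (is.null(exposures)) {
    bcols <- grep("^beta_", names(m), value = TRUE)
    exposures <- sub("^beta_", "", setdiff(bcols, "beta_outcome"))
  }
  k <- length(exposures)
  if (k < 1L) stop("no exposure columns found")
  j <- nrow(m)
  if (j < k + 1L)
    stop("insufficient variants: need more SNPs than exposures")
  X <- as.matrix(m[, paste0("beta_", exposures), drop = FALSE])
  if (qr(X)$rank < k)
    stop("collinearity error: exposure beta matrix is rank deficient")
  w <- m$se_outcome^-2
  y <- m$beta_outcome
  xtwx <- crossprod(X, w * X)
  coef <- unname(drop(solve(xtwx, crossprod(X, w * y))))
  resid <- y - drop(X %*% coef)
  sigma <- sqrt(sum(w * resid^2) / (j - k))
  se <- unname(sqrt(diag(solve(xtwx)))) * max(1, sigma)
  res <- lapply(seq_len(k), function(i)
    new_mr_result("multivariable_ivw", beta = coef[i], se = se[i],
                  n_snps = j, effects_model = "random"))
  names(res) <- exposures
  res
}

#' Read a multi-exposure summary table
#'
#' Reads a delimited file with suffixed column groups (`rsid`, then
#' `beta_<label>` / `se_<label>` per exposure and `beta_outcome` /
#' `se_outcome` for the outcome) for [multivariable_ivw()]. Exposure
#' standard errors are carried but not used in estimation (NOME).
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return Data.frame suitable for [multivariable_ivw()].
#' @export
read_multi_exposure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  m <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (is.null(m$beta_outcome) || is.null(m$se_outcome))
    stop("configuration error: beta_outcome/se_outcome columns required")
  m
}
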