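# Causal estimators on harmonised two-sample summary data: per-SNP Wald
# ratios, IVW (fixed / multiplicative random effects), MR-Egger, weighted
# median, Cochran's Q / I2, SD scaling, and subgroup heterogeneity.

#' Construct an MR result
#'
#' Internal constructor shared by all estimators. The odds ratio and 95%
#' confidence interval are derived from `beta` and `se` with the fixed
#' normal multiplier 1.959964; p-values use the normal reference unless a
#' t reference is requested via `pvalue_df`.
#'
#' @keywords internal
new_mr_result <- function(method, beta, se, n_snps,
                          effects_model = NA_character_,
                          q_stat = NA_real_, q_df = NA_real_,
                          q_pvalue = NA_real_, i2 = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_se = NA_real_,
                          egger_intercept_p = NA_real_,
                          pvalue_df = NULL, degenerate = FALSE) {
  pvalue <- if (is.null(pvalue_df)) 2 * pnorm(-abs(beta / se))
            else 2 * pt(-abs(beta / se), df = pvalue_df)
  structure(list(
    method = method, beta = beta, se = se, or_ = exp(beta),
    ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
    pvalue = pvalue, n_snps = n_snps, q_stat = q_stat, q_df = q_df,
    q_pvalue = q_pvalue, i2 = i2, egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    effects_model = effects_model, degenerate = degenerate),
    class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s (%s effects), J = %d\n", x$method,
              ifelse(is.na(x$effects_model), "-", x$effects_model),
              x$n_snps))
  cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f), beta %.4f (se %.4f), p = %.3g\n",
              x$or_, x$ci_low, x$ci_high, x$beta, x$se, x$pvalue))
  if (!is.na(x$q_stat))
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$q_stat, x$q_df, x$q_pvalue, x$i2))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept %.4f (se %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_p))
  invisible(x)
}

#' Per-SNP Wald ratios
#'
#' First-stage estimates `theta_j = beta_outcome / beta_exposure` with
#' first-order delta-method standard errors
#' `se_j = se_outcome / |beta_exposure|` (NOME: the exposure beta is
#' treated as known). SNPs with a zero exposure beta are excluded with a
#' warning.
#'
#' @param harmonised An `mr_harmonised` data.frame (see [harmonise()]), or
#'   any data.frame with `beta_exposure`, `beta_outcome`, `se_outcome`
#'   (and optionally `rsid`) columns.
#' @return Data.frame of class `mr_ratios` with columns `rsid`, `theta`,
#'   `se_theta`, `weight` (`= se_theta^-2`); excluded rsids in
#'   `attr(, "excluded")`.
#' @export
wald_ratios <- function(harmonised) {
  h <- as.data.frame(harmonised)
  if (is.null(h$rsid)) h$rsid <- paste0("snp", seq_len(nrow(h)))
  zero <- h$beta_exposure == 0
  if (any(zero))
    warning(sprintf("excluded %d variant(s) with zero exposure beta: %s",
                    sum(zero), paste(h$rsid[zero], collapse = ", ")),
            call. = FALSE)
  h <- h[!zero, , drop = FALSE]
  if (nrow(h) == 0L) stop("empty input: no usable variants")
  out <- data.frame(rsid = h$rsid,
                    theta = h$beta_outcome / h$beta_exposure,
                    se_theta = h$se_outcome / abs(h$beta_exposure),
                    stringsAsFactors = FALSE)
  out$weight <- out$se_theta^-2
  rownames(out) <- NULL
  structure(out, class = c("mr_ratios", "data.frame"),
            excluded = harmonised$rsid[zero])
}

as_ratios <- function(x) {
  if (inherits(x, "mr_ratios")) return(x)
  if (!is.null(x$theta) && !is.null(x$se_theta)) {
    x$weight <- x$se_theta^-2
    return(x)
  }
  wald_ratios(x)
}

#' Cochran's Q heterogeneity across per-SNP estimates
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` around the fixed-effect IVW
#' pooled estimate, with `df = J - 1`, a chi-square upper-tail p-value and
#' `I2 = max(0, (Q - df) / Q) * 100`.
#'
#' @param ratios An `mr_ratios` data.frame (or harmonised data, converted
#'   via [wald_ratios()]).
#' @return List with `q_stat`, `df`, `pvalue`, `i2`.
#' @export
cochran_q <- function(ratios) {
  r <- as_ratios(ratios)
  j <- nrow(r)
  if (j < 2L) stop("heterogeneity undefined for fewer than 2 variants")
  w <- r$weight
  pooled <- sum(w * r$theta) / sum(w)
  q <- sum(w * (r$theta - pooled)^2)
  df <- j - 1L
  list(q_stat = q, df = df,
       pvalue = pchisq(q, df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

#' Inverse-variance weighted estimator
#'
#' Pools per-SNP Wald ratios with weights `w_j = se_j^-2`:
#' `beta = sum(w theta) / sum(w)`. The fixed-effect standard error is
#' `(sum w)^-1/2`; the multiplicative random-effects standard error
#' inflates it by `max(1, sqrt(Q / (J - 1)))`. `effects = "auto"` (the
#' default, matching the source study's rule) selects random effects when
#' the Cochran's Q p-value is <= 0.05.
#'
#' @param ratios An `mr_ratios` data.frame, or harmonised data.
#' @param effects `"auto"`, `"fixed"` or `"random"`.
#' @return An `mr_result`. With a single ratio the result equals that
#'   ratio and is flagged `degenerate`.
#' @export
ivw <- function(ratios, effects = c("auto", "fixed", "random")) {
  effects <- match.arg(effects)
  r <- as_ratios(ratios)
  j <- nrow(r)
  if (j == 0L) stop("empty input: no ratios supplied")
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (j == 1L)
    return(new_mr_result("ivw_fixed", beta, se_fixed, 1L,
                         effects_model = "fixed", degenerate = TRUE))
  het <- cochran_q(r)
  model <- switch(effects,
                  fixed = "fixed", random = "random",
                  auto = if (het$pvalue <= 0.05) "random" else "fixed")
  se <- if (model == "random")
    se_fixed * max(1, sqrt(het$q_stat / (j - 1))) else se_fixed
  new_mr_result(paste0("ivw_", model), beta, se, j, effects_model = model,
                q_stat = het$q_stat, q_df = het$df, q_pvalue = het$pvalue,
                i2 = het$i2)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1 / se_outcome^2`, after orienting every SNP so its
#' exposure beta is non-negative (the estimator is not invariant to allele
#' orientation). The slope is the pleiotropy-adjusted causal estimate; a
#' non-zero intercept indicates directional pleiotropy and is tested
#' against a t reference with `J - 2` df. Standard errors carry a
#' multiplicative overdispersion factor floored at 1.
#'
#' @param harmonised An `mr_harmonised` data.frame with at least 3 SNPs.
#' @return An `mr_result` (slope) with the intercept estimate, standard
#'   error and p-value in the `egger_*` fields.
#' @export
mr_egger <- function(harmonised) {
  h <- as.data.frame(harmonised)
  j <- nrow(h)
  if (j < 3L) stop("insufficient variants: MR-Egger needs at least 3 SNPs")
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- abs(h$beta_exposure)
  by <- s * h$beta_outcome
  if (var(bx) == 0)
    stop("unidentifiable slope: all exposure betas identical")
  w <- h$se_outcome^-2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coef
  sigma <- sqrt(sum(w * resid^2) / (j - 2))
  vc <- solve(xtwx) * max(1, sigma)^2
  se <- sqrt(diag(vc))
  int_p <- 2 * pt(-abs(coef[1] / se[1]), df = j - 2)
  new_mr_result("egger", beta = coef[2], se = se[2], n_snps = j,
                egger_intercept = coef[1], egger_intercept_se = se[1],
                egger_intercept_p = int_p)
}

# Weighted-median point estimate: order theta ascending, standardise
# cumulative weights s_j = (cumsum(w) - w/2) / sum(w), interpolate theta
# against s at s = 0.5.
wm_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when SNPs carrying at least half of the total inverse-
#' variance weight are valid instruments. The point estimate interpolates
#' the ordered Wald ratios against standardised cumulative weights at the
#' 50% point; the standard error comes from a seeded parametric bootstrap
#' (each exposure and outcome beta resampled from a normal with its own
#' standard error).
#'
#' @param harmonised An `mr_harmonised` data.frame with at least 3 SNPs,
#'   or an `mr_ratios` data.frame (then only `theta` is resampled).
#' @param n_boot Bootstrap draws, default 10,000.
#' @param seed Integer seed for the bootstrap stream (reproducible); `NULL`
#'   uses the current RNG state.
#' @return An `mr_result`.
#' @export
weighted_median <- function(harmonised, n_boot = 10000, seed = NULL) {
  h <- as.data.frame(harmonised)
  j <- nrow(h)
  if (j < 3L)
    stop("insufficient variants: weighted median needs at least 3 SNPs")
  r <- as_ratios(harmonised)
  est <- wm_point(r$theta, r$weight)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      if (!is.null(h$beta_exposure)) {
        bx <- rnorm(j, h$beta_exposure, h$se_exposure)
        by <- rnorm(j, h$beta_outcome, h$se_outcome)
        bx[bx == 0] <- .Machine$double.eps
        th <- by / bx
        se <- h$se_outcome / abs(bx)
      } else {
        th <- rnorm(j, r$theta, r$se_theta)
        se <- r$se_theta
      }
      wm_point(th, se^-2)
    }, numeric(1))
  })
  new_mr_result("weighted_median", beta = est, se = sd(boots), n_snps = j)
}

#' Rescale an MR result to SD units of the exposure
#'
#' Multiplies the causal log odds ratio and its standard error by the
#' exposure SD (8.14 milli-gravities of average acceleration by default)
#' and recomputes the OR and confidence interval. Use when the instrument
#' betas are in raw exposure units; a no-op when `sd_units = 1`.
#'
#' @param result An `mr_result` expressed per raw exposure unit.
#' @param sd_units Exposure SD in those units, > 0; default 8.14.
#' @return The rescaled `mr_result`.
#' @export
scale_to_sd <- function(result, sd_units = 8.14) {
  stopifnot(inherits(result, "mr_result"))
  if (sd_units <= 0) stop("domain error: sd_units must be positive")
  result$beta <- result$beta * sd_units
  result$se <- result$se * sd_units
  result$or_ <- exp(result$beta)
  result$ci_low <- exp(result$beta - Z95 * result$se)
  result$ci_high <- exp(result$beta + Z95 * result$se)
  # z and p are scale-invariant; intercept stays in outcome units
  result
}

#' Heterogeneity of causal estimates across subgroups
#'
#' Fixed-effects Cochran's Q across a handful of subgroup estimates (e.g.
#' men vs women, ER+ vs ER-), with `df = G - 1`, a chi-square p-value and
#' `I2 = max(0, (Q - df)/Q) * 100`. Estimates may be given as
#' (`beta`, `se`) pairs or as (`or_`, `ci_low`, `ci_high`), in which case
#' `se = (log ci_high - log ci_low) / (2 * 1.959964)`.
#'
#' @param estimates Data.frame with columns `beta` + `se`, or `or_` +
#'   `ci_low` + `ci_high`; at least 2 rows.
#' @return List with `q_stat`, `df`, `pvalue`, `i2_percent`.
#' @export
#' @examples
#' subgroup_heterogeneity(data.frame(or_ = c(0.79, 0.57),
#'                                   ci_low = c(0.50, 0.36),
#'                                   ci_high = c(1.23, 0.90)))
subgroup_heterogeneity <- function(estimates) {
  e <- as.data.frame(estimates)
  if (nrow(e) < 2L) stop("at least 2 subgroup estimates are required")
  if (is.null(e$beta)) {
    if (is.null(e$or_) || is.null(e$ci_low) || is.null(e$ci_high))
      stop("supply either beta/se or or_/ci_low/ci_high columns")
    e$beta <- log(e$or_)
    e$se <- (log(e$ci_high) - log(e$ci_low)) / (2 * Z95)
  }
  w <- e$se^-2
  pooled <- sum(w * e$beta) / sum(w)
  q <- sum(w * (e$beta - pooled)^2)
  df <- nrow(e) - 1L
  list(q_stat = q, df = df,
       pvalue = pchisq(q, df, lower.tail = FALSE),
       i2_percent = if (q > 0) max(0, (q - df) / q) * 100 else 0)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
# Relies on lazy evaluation: `expr` is forced only after set.seed().
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
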