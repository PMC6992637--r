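# Seeded generator of two-sample GWAS summary statistics with known truth,
# emulating the structure of the physical-activity study: a continuous
# exposure GWAS of ~91,000 and a case/control outcome GWAS with the
# printed case mixes.
#
# Model, per SNP j:
#   maf p_j ~ Uniform(maf_range)
#   true exposure effect gamma_j ~ half-Normal(0, sigma_gamma^2),
#     rejected below gamma_min (effect allele = activity-increasing
#     allele, the orientation convention of published instrument tables)
#   se_Xj = (2 p q n_exposure)^(-1/2)           [exposure in SD units]
#   observed exposure beta ~ N(gamma_j, se_Xj^2)
#   direct effect alpha_j per pleiotropy mode (none/balanced/directional/
#     outliers/correlated)
#   se_Yj = (2 p q n_outcome K (1-K))^(-1/2)    [logistic-score log-OR SE]
#   observed outcome beta ~ N(theta gamma_j + alpha_j [+ theta_bmi
#     gamma_bmi_j], se_Yj^2)

#' Define the generating truth of a synthetic two-sample dataset
#'
#' @param n_snps Number of instrument SNPs J.
#' @param theta True causal log odds ratio per exposure SD.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (direct effects
#'   `N(0, sigma_alpha^2)`), `"directional"` (`N(mu_alpha, sigma_alpha^2)`,
#'   InSIDE holds), `"outliers"` (zero except the listed offsets), or
#'   `"correlated"` (`alpha = kappa * gamma + noise`, violating InSIDE).
#' @param mu_alpha,sigma_alpha Mean and SD of the pleiotropic effects.
#' @param kappa InSIDE-violation slope for mode `"correlated"`.
#' @param outlier_ids Integer indices of outlier SNPs.
#' @param outlier_offsets Pleiotropic offsets for `outlier_ids`.
#' @param theta_bmi Direct causal log OR per SD of BMI (0 disables the BMI
#'   exposure block).
#' @param kappa_bmi Slope of per-SNP BMI effects on the activity effects
#'   (activity-raising alleles lower BMI, hence negative by default).
#' @param sigma_bmi Residual SD of per-SNP BMI effects.
#' @param n_exposure,n_outcome,n_bmi GWAS sample sizes.
#' @param case_fraction Proportion of cases K in the outcome GWAS.
#' @param maf_range Range of minor-allele frequencies.
#' @param sigma_gamma SD of true exposure effects (SD units per allele).
#' @param gamma_min Rejection bound keeping true effects away from zero
#'   (avoids near-zero Wald denominators).
#' @param seed Integer seed; regeneration with the same truth is
#'   bit-identical.
#' @return List of class `simulation_truth`.
#' @seealso [scenario()] for documented presets, [simulate_two_sample()].
#' @export
simulation_truth <- function(n_snps = 30, theta = 0,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional", "outliers",
                                                 "correlated"),
                             mu_alpha = 0, sigma_alpha = 0, kappa = 0,
                             outlier_ids = integer(0),
                             outlier_offsets = numeric(0),
                             theta_bmi = 0, kappa_bmi = -0.25,
                             sigma_bmi = 0.05,
                             n_exposure = 91084, n_outcome = 98715,
                             n_bmi = 230000, case_fraction = 0.5346,
                             maf_range = c(0.05, 0.5),
                             sigma_gamma = 0.25, gamma_min = 0.01,
                             seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, case_fraction > 0, case_fraction < 1,
            sigma_alpha >= 0, length(outlier_ids) == length(outlier_offsets),
            length(maf_range) == 2, maf_range[1] < maf_range[2],
            maf_range[1] > 0, maf_range[2] < 1)
  if (sigma_gamma <= 0) stop("degenerate simulation: sigma_gamma must be > 0")
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 pleiotropy_mode = pleiotropy_mode, mu_alpha = mu_alpha,
                 sigma_alpha = sigma_alpha, kappa = kappa,
                 outlier_ids = as.integer(outlier_ids),
                 outlier_offsets = outlier_offsets, theta_bmi = theta_bmi,
                 kappa_bmi = kappa_bmi, sigma_bmi = sigma_bmi,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 n_bmi = n_bmi, case_fraction = case_fraction,
                 maf_range = maf_range, sigma_gamma = sigma_gamma,
                 gamma_min = gamma_min, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Documented simulation presets
#'
#' Named scenarios mirroring the study's printed dimensions (exposure GWAS
#' n = 91,084; colorectal outcome GWAS n = 98,715 with 52,775 cases,
#' K = 0.5346):
#'
#' * `"null"`: theta = 0, no pleiotropy.
#' * `"causal"`: theta = -0.4 (about the colorectal effect scale,
#'   log 0.66 = -0.415), no pleiotropy.
#' * `"balanced"`: theta = -0.4, balanced pleiotropy (sigma_alpha 0.05).
#' * `"directional"`: theta = 0, directional pleiotropy (mu_alpha 0.05,
#'   sigma_alpha 0.02) - pleiotropy masquerading as a causal effect.
#' * `"outlier"`: theta = -0.4, exactly one SNP with offset +1.
#' * `"bmi_mediated"`: theta = -0.4 direct, BMI effect +0.3 per SD with
#'   per-SNP BMI effects correlated with the activity effects.
#' * `"inside_violation"`: theta = 0, alpha = 0.25 gamma + noise.
#'
#' @param name Scenario name.
#' @param seed Integer seed stored in the truth.
#' @param ... Overrides passed to [simulation_truth()].
#' @return A `simulation_truth`.
#' @export
scenario <- function(name = c("null", "causal", "balanced", "directional",
                              "outlier", "bmi_mediated",
                              "inside_violation"),
                     seed = 1L, ...) {
  if (length(name) == 1L && !name %in% eval(formals(scenario)$name))
    stop("unknown scenario '", name, "'")
  name <- match.arg(name)
  args <- switch(name,
    null = list(theta = 0),
    causal = list(theta = -0.4),
    balanced = list(theta = -0.4, pleiotropy_mode = "balanced",
                    sigma_alpha = 0.05),
    directional = list(theta = 0, pleiotropy_mode = "directional",
                       mu_alpha = 0.05, sigma_alpha = 0.02),
    outlier = list(theta = -0.4, pleiotropy_mode = "outliers",
                   outlier_ids = 1L, outlier_offsets = 1.0),
    bmi_mediated = list(theta = -0.4, theta_bmi = 0.3),
    inside_violation = list(theta = 0, pleiotropy_mode = "correlated",
                            kappa = 0.25, sigma_alpha = 0.02))
  do.call(simulation_truth, modifyList(c(args, seed = seed), list(...)))
}

#' Simulate a two-sample GWAS summary dataset
#'
#' Draws a complete exposure/outcome pair of summary-statistic tables
#' under the generating model described in [simulation_truth()], from a
#' single seeded stream. Alleles are assigned from non-palindromic pairs
#' with identical coding in both samples, so harmonisation is the
#' identity; rsids match one-to-one.
#'
#' @param truth A `simulation_truth`.
#' @return List of class `synthetic_study` with elements `exposure`,
#'   `outcome` (canonical summary-statistic data.frames), `bmi` (present
#'   when `theta_bmi != 0`), and `truth`.
#' @export
#' @examples
#' study <- simulate_two_sample(scenario("causal", seed = 7))
#' ivw(wald_ratios(harmonise(study$exposure, study$outcome)))
simulate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  j <- truth$n_snps
  k <- truth$case_fraction
  with_local_seed(truth$seed, {
    p <- runif(j, truth$maf_range[1], truth$maf_range[2])
    gamma <- abs(rnorm(j, 0, truth$sigma_gamma))
    while (any(bad <- gamma < truth$gamma_min))
      gamma[bad] <- abs(rnorm(sum(bad), 0, truth$sigma_gamma))
    het2 <- 2 * p * (1 - p)
    se_x <- 1 / sqrt(het2 * truth$n_exposure)
    bx <- rnorm(j, gamma, se_x)
    alpha <- switch(truth$pleiotropy_mode,
      none = numeric(j),
      balanced = rnorm(j, 0, truth$sigma_alpha),
      directional = rnorm(j, truth$mu_alpha, truth$sigma_alpha),
      outliers = {
        a <- numeric(j)
        a[truth$outlier_ids] <- truth$outlier_offsets
        a
      },
      correlated = truth$kappa * gamma + rnorm(j, 0, truth$sigma_alpha))
    mu_y <- truth$theta * gamma + alpha
    bmi <- NULL
    if (truth$theta_bmi != 0) {
      gamma_b <- truth$kappa_bmi * gamma + rnorm(j, 0, truth$sigma_bmi)
      se_b <- 1 / sqrt(het2 * truth$n_bmi)
      bb <- rnorm(j, gamma_b, se_b)
      mu_y <- mu_y + truth$theta_bmi * gamma_b
    }
    se_y <- 1 / sqrt(het2 * truth$n_outcome * k * (1 - k))
    by <- rnorm(j, mu_y, se_y)

    pairs <- matrix(c("A", "G", "G", "A", "T", "C", "C", "T"), ncol = 2,
                    byrow = TRUE)
    idx <- ((seq_len(j) - 1L) %% 4L) + 1L
    base <- data.frame(
      rsid = sprintf("rs%07d", seq_len(j)),
      effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2],
      chromosome = as.character(((seq_len(j) - 1L) %% 22L) + 1L),
      position = seq_len(j) * 100000, eaf = p, stringsAsFactors = FALSE)
    assoc <- function(beta, se, n) {
      out <- base
      out$beta <- beta; out$se <- se; out$n <- n
      out$pvalue <- 2 * pnorm(-abs(beta / se))
      out[, .CANONICAL]
    }
    study <- list(exposure = assoc(bx, se_x, truth$n_exposure),
                  outcome = assoc(by, se_y, truth$n_outcome),
                  truth = truth)
    study$truth$gamma <- gamma
    study$truth$alpha <- alpha
    if (truth$theta_bmi != 0) {
      study$bmi <- assoc(bb, se_b, truth$n_bmi)
      study$truth$gamma_bmi <- gamma_b
    }
    structure(study, class = "synthetic_study")
  })
}

#' Write a synthetic study to disk
#'
#' Exposure and outcome tables as tab-delimited text plus a JSON sidecar
#' recording the generating truth (including the per-SNP true effects).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_synthetic_study <- function(study, dir, prefix = "synthetic") {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    exposure = file.path(dir, paste0(prefix, "_exposure.tsv")),
    outcome = file.path(dir, paste0(prefix, "_outcome.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_summary_stats(study$exposure, paths["exposure"], dialect = "short")
  write_summary_stats(study$outcome, paths["outcome"], dialect = "short")
  if (!is.null(study$bmi)) {
    paths["bmi"] <- file.path(dir, paste0(prefix, "_bmi.tsv"))
    write_summary_stats(study$bmi, paths["bmi"], dialect = "short")
  }
  truth <- study$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
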