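# Shared fixtures, built in code at test time.

# Small canonical summary-statistic frame.
toy_assoc <- function(rsid, ea, oa, eaf, beta, se, n = 10000) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             chromosome = "1", position = seq_along(rsid) * 1000,
             eaf = eaf, beta = beta, se = se, n = n, pvalue = NA_real_,
             stringsAsFactors = FALSE)
}

# Harmonised frame built directly (already-aligned betas), for estimator
# tests that need exact inputs.
toy_harmonised <- function(bx, by, se_y, se_x = rep(1e-6, length(bx)),
                           rsid = sprintf("rs%03d", seq_along(bx))) {
  structure(data.frame(
    rsid = rsid, effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = se_x, eaf_exposure = 0.3,
    n_exposure = 90000, beta_outcome = by, se_outcome = se_y,
    eaf_outcome = 0.3, n_outcome = 90000, flipped = FALSE,
    palindromic = FALSE, stringsAsFactors = FALSE),
    class = c("mr_harmonised", "data.frame"),
    dropped = data.frame(rsid = character(0), reason = character(0)),
    outcome = "toy")
}

# Ratio frame straight from theta/se pairs.
toy_ratios <- function(theta, se) {
  structure(data.frame(rsid = sprintf("rs%03d", seq_along(theta)),
                       theta = theta, se_theta = se, weight = se^-2,
                       stringsAsFactors = FALSE),
            class = c("mr_ratios", "data.frame"))
}

# One sim -> harmonise -> ratios, the standard pipeline used in
# property-style tests.
sim_ratios <- function(truth) {
  st <- simulate_two_sample(truth)
  wald_ratios(harmonise(st$exposure, st$outcome))
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
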