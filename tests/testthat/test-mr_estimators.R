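# mr_estimators: Wald ratios, IVW, Cochran's Q, MR-Egger, weighted
# median, SD scaling, subgroup heterogeneity.

test_that("wald_ratios applies the delta method and excludes zero betas", {
  h <- toy_harmonised(bx = c(0.03, -0.03, 0), by = c(-0.021, 0.021, 0.1),
                      se_y = c(0.012, 0.012, 0.05))
  expect_warning(r <- wald_ratios(h), "zero exposure beta")
  expect_equal(nrow(r), 2L)
  expect_equal(r$theta, c(-0.7, -0.7))
  expect_equal(r$se_theta, c(0.4, 0.4))
  expect_equal(r$weight, r$se_theta^-2, tolerance = 1e-12)
  expect_identical(attr(r, "excluded"), "rs003")
})

test_that("ivw pools ratios with fixed and random effects", {
  r <- toy_ratios(c(0.5, 1.0), c(0.1, 0.2))
  fit <- ivw(r, effects = "fixed")
  expect_equal(fit$beta, 0.6) # hand computation: w = 100, 25
  expect_equal(fit$se, sqrt(1 / 125), tolerance = 1e-9)
  expect_equal(fit$or_, exp(fit$beta), tolerance = 1e-12)
  expect_true(fit$ci_low < fit$or_ && fit$or_ < fit$ci_high)

  # homogeneous ratios: Q = 0, random equals fixed
  r0 <- toy_ratios(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(ivw(r0, effects = "fixed")$beta, 0.3)
  expect_equal(ivw(r0, effects = "random")$se,
               ivw(r0, effects = "fixed")$se)
  expect_equal(ivw(r0)$q_stat, 0)

  # single ratio: degenerate passthrough
  one <- ivw(toy_ratios(0.4, 0.1))
  expect_true(one$degenerate)
  expect_equal(one$beta, 0.4)
  expect_equal(one$se, 0.1)
  expect_error(ivw(toy_ratios(numeric(0), numeric(0))), "empty input")
})

test_that("auto effects switch to random under heterogeneity", {
  het <- toy_ratios(c(-2, 2, -2, 2), rep(0.1, 4))
  fit <- ivw(het, effects = "auto")
  expect_identical(fit$effects_model, "random")
  expect_equal(fit$se, ivw(het, effects = "fixed")$se *
                 sqrt(fit$q_stat / 3), tolerance = 1e-12)
  hom <- toy_ratios(c(0.49, 0.5, 0.51), rep(0.3, 3))
  expect_identical(ivw(hom, effects = "auto")$effects_model, "fixed")
  # random-effects inflation is floored at 1
  expect_equal(ivw(hom, effects = "random")$se,
               ivw(hom, effects = "fixed")$se)
})

test_that("cochran_q matches hand computations", {
  q <- cochran_q(toy_ratios(c(0, 1), c(1, 1)))
  expect_equal(q$q_stat, 0.5)
  expect_equal(q$df, 1L)
  expect_equal(q$i2, 0) # Q below df
  expect_equal(q$pvalue, pchisq(0.5, 1, lower.tail = FALSE))
  expect_gt(cochran_q(toy_ratios(c(-5, 5), c(0.1, 0.1)))$i2, 99)
  expect_equal(cochran_q(toy_ratios(rep(1, 3), rep(0.2, 3)))$q_stat, 0)
  expect_error(cochran_q(toy_ratios(1, 1)), "fewer than 2")
})

test_that("ivw equals the weighted origin regression slope (oracle)", {
  for (seed in 1:5) {
    set.seed(seed)
    j <- sample(5:20, 1)
    bx <- rnorm(j, 0.1, 0.05)
    bx[bx == 0] <- 0.01
    by <- rnorm(j, 0, 0.02)
    se_y <- runif(j, 0.01, 0.05)
    h <- toy_harmonised(bx, by, se_y)
    fit <- ivw(wald_ratios(h), effects = "fixed")
    oracle <- sum(by * bx / se_y^2) / sum(bx^2 / se_y^2)
    expect_equal(fit$beta, oracle, tolerance = 1e-12)
  }
})

test_that("estimates are invariant to SNP order", {
  set.seed(42)
  h <- toy_harmonised(rnorm(8, 0.2, 0.05), rnorm(8, -0.05, 0.02),
                      runif(8, 0.01, 0.04))
  perm <- sample(8)
  hp <- as.data.frame(h)[perm, ]
  expect_close(ivw(wald_ratios(h))$beta, ivw(wald_ratios(hp))$beta, 1e-12)
  expect_close(mr_egger(h)$beta, mr_egger(hp)$beta, 1e-12)
  expect_close(weighted_median(h, n_boot = 10, seed = 1)$beta,
               weighted_median(hp, n_boot = 10, seed = 1)$beta, 1e-12)
})

test_that("mr_egger recovers exact lines and flags degenerate input", {
  h <- toy_harmonised(bx = c(1, 2, 3), by = c(0.6, 1.1, 1.6),
                      se_y = rep(0.1, 3))
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.1, tolerance = 1e-10)
  # line through the origin: intercept 0
  h0 <- toy_harmonised(bx = c(1, 2, 3), by = c(-0.2, -0.4, -0.6),
                       se_y = rep(0.1, 3))
  expect_close(mr_egger(h0)$egger_intercept, 0, 1e-10)
  expect_close(mr_egger(h0)$beta, -0.2, 1e-10)
  expect_error(mr_egger(toy_harmonised(c(1, 2), c(1, 2), c(0.1, 0.1))),
               "at least 3")
  expect_error(mr_egger(toy_harmonised(rep(1, 4), 1:4 / 10, rep(0.1, 4))),
               "unidentifiable")
})

test_that("mr_egger slope equals fixed IVW when the intercept is zero", {
  # constructed data: by exactly proportional to bx, equal weights
  bx <- c(0.5, 1, 1.5, 2.5)
  h <- toy_harmonised(bx, -0.3 * bx, rep(0.2, 4))
  expect_close(mr_egger(h)$beta, ivw(wald_ratios(h), "fixed")$beta, 1e-10)
})

test_that("weighted median interpolates standardised cumulative weights", {
  # ordinary median under equal weights, odd J
  h <- toy_harmonised(rep(1, 3), c(0.2, 0.5, 0.9), rep(0.1, 3))
  expect_equal(weighted_median(h, n_boot = 10, seed = 1)$beta, 0.5)
  # brute-force s_j check: ratios {1,2,10}, weights {1,1,2}
  r <- toy_ratios(c(1, 2, 10), c(1, 1, sqrt(0.5)))
  wm <- weighted_median(r, n_boot = 10, seed = 1)
  expect_equal(wm$beta, 2 + (0.5 - 0.375) / (0.75 - 0.375) * 8,
               tolerance = 1e-12)
  # weight concentration: estimate collapses onto the dominant SNP
  rc <- toy_ratios(c(0.1, 0.5, 0.9), c(1, 1e-3, 1))
  expect_close(weighted_median(rc, n_boot = 10, seed = 1)$beta, 0.5, 1e-3)
  expect_error(weighted_median(toy_ratios(c(1, 2), c(1, 1))), "at least 3")
})

test_that("weighted median is seeded, bounded and bootstrap-stable", {
  set.seed(9)
  h <- toy_harmonised(rnorm(9, 0.25, 0.05), rnorm(9, -0.1, 0.03),
                      runif(9, 0.02, 0.05), se_x = rep(0.01, 9))
  a <- weighted_median(h, n_boot = 300, seed = 77)
  b <- weighted_median(h, n_boot = 300, seed = 77)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  r <- wald_ratios(h)
  expect_true(a$beta >= min(r$theta) && a$beta <= max(r$theta))
})

test_that("scale_to_sd rescales estimates and keeps them consistent", {
  r <- toy_ratios(c(-0.04, -0.06, -0.05), c(0.02, 0.03, 0.02))
  fit <- ivw(r, effects = "fixed")
  sc <- scale_to_sd(fit, 8.14)
  expect_equal(sc$beta, fit$beta * 8.14, tolerance = 1e-12)
  expect_equal(sc$se, fit$se * 8.14, tolerance = 1e-12)
  expect_equal(sc$or_, exp(sc$beta), tolerance = 1e-12)
  expect_equal(sc$pvalue, fit$pvalue, tolerance = 1e-12) # z unchanged
  expect_equal(scale_to_sd(fit, 1), fit)
  single <- scale_to_sd(ivw(toy_ratios(-0.05, 0.01)), 8.14)
  expect_equal(single$beta, -0.407, tolerance = 1e-12)
  expect_error(scale_to_sd(fit, 0), "domain")
})

test_that("subgroup_heterogeneity reproduces the sex contrast and oracle", {
  # published sex-specific colorectal IVW contrast: I2 = 0%
  sex <- subgroup_heterogeneity(data.frame(
    or_ = c(0.79, 0.57), ci_low = c(0.50, 0.36), ci_high = c(1.23, 0.90)))
  expect_equal(sex$i2_percent, 0)
  expect_lt(sex$q_stat, 1)
  # identical subgroups
  same <- subgroup_heterogeneity(data.frame(beta = c(-0.4, -0.4),
                                            se = c(0.1, 0.1)))
  expect_equal(same$q_stat, 0)
  expect_equal(same$i2_percent, 0)
  # ER subtype contrast against a brute-force two-group evaluation
  er <- subgroup_heterogeneity(data.frame(
    or_ = c(0.45, 0.95), ci_low = c(0.20, 0.44), ci_high = c(1.01, 2.04)))
  th <- log(c(0.45, 0.95))
  se <- (log(c(1.01, 2.04)) - log(c(0.20, 0.44))) / (2 * 1.959964)
  w <- se^-2
  m <- sum(w * th) / sum(w)
  q_oracle <- sum(w * (th - m)^2)
  expect_equal(er$q_stat, q_oracle, tolerance = 1e-12)
  expect_equal(er$i2_percent, max(0, (q_oracle - 1) / q_oracle) * 100,
               tolerance = 1e-12)
  expect_error(subgroup_heterogeneity(data.frame(beta = 1, se = 1)),
               "at least 2")
})
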