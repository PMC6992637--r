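# summary_stats: reader/writer, built-in instruments, harmonisation.

test_that("reader round-trips a small file and auto-detects dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,EA,OA,CHR,BP,EAF,BETA,SE,N",
               "rs1,A,G,1,100,0.25,0.031234567890123,0.005,91105",
               "rs2,T,C,2,200,0.66,-0.02,0.004,91105"), path)
  x <- read_summary_stats(path)
  expect_equal(nrow(x), 2L)
  expect_equal(x$rsid, c("rs1", "rs2"))
  expect_equal(x$beta[1], 0.031234567890123)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, out, dialect = "short")
  y <- read_summary_stats(out)
  for (cl in c("eaf", "beta", "se", "n", "position"))
    expect_equal(y[[cl]], x[[cl]], tolerance = 1e-12)
  expect_identical(y$effect_allele, x$effect_allele)
})

test_that("rows with unparseable fields are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ins <- builtin_instrument("klimentidis10")$variants
  ins$eaf[3] <- NA # will serialise as NA text
  suppressWarnings(write_summary_stats(ins, path, dialect = "short"))
  expect_warning(x <- read_summary_stats(path), "rejected 1 row")
  expect_equal(nrow(x), 9L)
  expect_false("rs6775319" %in% x$rsid)
})

test_that("reader errors on empty input and missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("SNP,EA,OA,EAF,BETA,SE,N", path)
  expect_error(read_summary_stats(path), "empty|no lines|no data")
  writeLines(c("SNP,EA,OA,BETA,SE", "rs1,A,G,0.1,0.01"), path)
  expect_error(read_summary_stats(path), "configuration error")
  expect_error(read_summary_stats(tempfile()), "not found")
})

test_that("duplicated rsids keep the first occurrence with a warning", {
  x <- toy_assoc(c("rs1", "rs1"), c("A", "A"), c("G", "G"),
                 c(0.2, 0.2), c(0.1, 0.9), c(0.01, 0.01))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path, dialect = "short")
  expect_warning(y <- read_summary_stats(path), "duplicated rsid")
  expect_equal(nrow(y), 1L)
  expect_equal(y$beta, 0.1)
})

test_that("built-in instruments reproduce the printed per-SNP values", {
  d5 <- builtin_instrument("doherty5")
  expect_equal(nrow(d5$variants), 5L)
  expect_true(all(d5$variants$n == 91105))
  v <- d5$variants[d5$variants$rsid == "rs2696625", ]
  expect_equal(v$eaf, 0.23)
  expect_equal(v$beta, 0.04)
  expect_equal(v$se, 0.005)
  expect_identical(d5$exposure_unit, "sd")

  k10 <- builtin_instrument("klimentidis10")
  expect_equal(nrow(k10$variants), 10L)
  expect_identical(k10$variants$rsid[1], "rs12045968")
  expect_true(all(k10$variants$n == 91084))
  v <- k10$variants[k10$variants$rsid == "rs55657917", ]
  expect_equal(v$eaf, 0.22)
  expect_equal(v$beta, 0.30)
  expect_equal(v$se, 0.04)
  expect_identical(k10$exposure_unit, "milligravity")

  expect_error(builtin_instrument("doherty4"), "unknown instrument")
})

test_that("instrument variance explained matches the published totals", {
  # about 0.2% (5-SNP) and 0.4% (10-SNP) of phenotypic variability
  expect_close(builtin_instrument("doherty5")$variance_explained,
               0.002, 2e-4)
  expect_close(builtin_instrument("klimentidis10")$variance_explained,
               0.004, 4e-4)
})

test_that("harmonise flips outcome betas to the exposure effect allele", {
  ex <- toy_assoc("rs1", "G", "A", 0.2, 0.04, 0.005)
  # identity case
  ou <- toy_assoc("rs1", "G", "A", 0.21, -0.01, 0.02)
  h <- harmonise(ex, ou)
  expect_equal(h$beta_outcome, -0.01)
  expect_false(h$flipped)
  # swapped alleles: sign flip, eaf complement
  ou2 <- toy_assoc("rs1", "A", "G", 0.79, 0.01, 0.02)
  h2 <- harmonise(ex, ou2)
  expect_equal(h2$beta_outcome, -0.01)
  expect_equal(h2$eaf_outcome, 0.21)
  expect_true(h2$flipped)
  # strand complement: exposure G/A vs outcome C/T
  ou3 <- toy_assoc("rs1", "C", "T", 0.21, -0.01, 0.02)
  expect_equal(harmonise(ex, ou3)$beta_outcome, -0.01)
  # incompatible alleles are a hard error naming the rsid
  ou4 <- toy_assoc("rs1", "C", "A", 0.2, 0.01, 0.02)
  expect_error(harmonise(ex, ou4), "rs1")
})

test_that("palindromic policies behave as documented", {
  ex <- toy_assoc("rs1", "A", "T", 0.50, 0.03, 0.005)
  ou <- toy_assoc("rs1", "T", "A", 0.50, -0.02, 0.01)
  # ambiguous eaf inside (0.42, 0.58): dropped under infer_by_eaf
  h <- harmonise(ex, ou, palindrome_policy = "infer_by_eaf")
  expect_error(wald_ratios(h), "empty input")
  expect_true("rs1" %in% attr(h, "dropped")$rsid)
  # drop_ambiguous drops regardless of eaf
  ex2 <- toy_assoc("rs1", "A", "T", 0.10, 0.03, 0.005)
  ou2 <- toy_assoc("rs1", "A", "T", 0.12, -0.02, 0.01)
  h2 <- harmonise(ex2, ou2, palindrome_policy = "drop_ambiguous")
  expect_equal(nrow(h2), 0L)
  # infer_by_eaf aligns by minor allele outside the window
  h3 <- harmonise(ex2, ou2, palindrome_policy = "infer_by_eaf")
  expect_equal(h3$beta_outcome, -0.02)
  expect_false(h3$flipped)
  ou3 <- toy_assoc("rs1", "A", "T", 0.88, -0.02, 0.01) # minor disagrees
  h4 <- harmonise(ex2, ou3, palindrome_policy = "infer_by_eaf")
  expect_true(h4$flipped)
  expect_equal(h4$beta_outcome, 0.02)
  # keep trusts the letters
  h5 <- harmonise(ex2, toy_assoc("rs1", "T", "A", 0.9, -0.02, 0.01),
                  palindrome_policy = "keep")
  expect_equal(h5$beta_outcome, 0.02)
})

test_that("harmonise is idempotent and invariant to outcome recoding", {
  set.seed(11)
  ex <- builtin_instrument("klimentidis10")$variants
  ou <- ex
  ou$beta <- rnorm(10, 0, 0.02)
  ou$se <- runif(10, 0.01, 0.03)
  h1 <- harmonise(ex, ou)
  # idempotence: re-harmonising the harmonised outcome changes nothing
  h2 <- harmonise(ex, harmonised_outcome(h1))
  expect_equal(h2$beta_outcome, h1$beta_outcome, tolerance = 1e-12)
  expect_false(any(h2$flipped))
  # swapping alleles + negating beta before harmonisation is a no-op
  ou_rec <- ou
  ou_rec$effect_allele <- ou$other_allele
  ou_rec$other_allele <- ou$effect_allele
  ou_rec$beta <- -ou$beta
  ou_rec$eaf <- 1 - ou$eaf
  h3 <- harmonise(ex, ou_rec)
  expect_equal(h3$beta_outcome, h1$beta_outcome, tolerance = 1e-12)
  expect_equal(h3$eaf_outcome, h1$eaf_outcome, tolerance = 1e-12)
})

test_that("SNPs absent from the outcome are reported as dropped", {
  ex <- builtin_instrument("doherty5")$variants
  ou <- ex[1:3, ]
  ou$beta <- c(0.01, -0.02, 0.003)
  h <- harmonise(ex, ou)
  expect_equal(nrow(h), 3L)
  d <- attr(h, "dropped")
  expect_setequal(d$rsid[d$reason == "absent_from_outcome"],
                  ex$rsid[4:5])
})

test_that("write_harmonised emits the table and a dropped-SNP manifest", {
  ex <- builtin_instrument("doherty5")$variants
  ou <- ex[1:4, ]
  ou$beta <- rep(0.01, 4)
  h <- harmonise(ex, ou)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonised(h, path)
  expect_true(file.exists(path))
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 4L)
  manifest <- jsonlite::read_json(paste0(path, ".dropped.json"),
                                  simplifyVector = TRUE)
  expect_true("rs59499656" %in% manifest$rsid)
})
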