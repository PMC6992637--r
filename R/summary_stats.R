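# Summary-statistic data model, file I/O and allele harmonisation.
#
# A SNP-association table is a plain data.frame with the canonical columns
#   rsid, effect_allele, other_allele, chromosome, position, eaf, beta, se,
#   n, pvalue
# (chromosome/position/pvalue optional, carried as metadata; rsid is the
# key used for matching between samples).

.CANONICAL <- c("rsid", "effect_allele", "other_allele", "chromosome",
                "position", "eaf", "beta", "se", "n", "pvalue")
.MANDATORY <- c("rsid", "effect_allele", "other_allele", "eaf", "beta",
                "se", "n")
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Built-in column dialects for GWAS summary-statistic files
#'
#' A dialect maps the canonical field names used internally to the column
#' headers found in a file. Two layouts ship with the package:
#' `"standard"` (`SNP/effect_allele/other_allele/eaf/beta/se/samplesize`)
#' and `"short"` (`SNP/EA/OA/CHR/BP/EAF/BETA/SE/N`, the layout of the
#' packaged instrument files).
#'
#' @param name `"standard"` or `"short"`.
#' @return Named character vector mapping canonical names to file headers.
#' @export
#' @examples
#' mr_dialect("short")
mr_dialect <- function(name = c("standard", "short")) {
  name <- match.arg(name)
  switch(name,
    standard = c(rsid = "SNP", effect_allele = "effect_allele",
                 other_allele = "other_allele", chromosome = "chr",
                 position = "pos", eaf = "eaf", beta = "beta", se = "se",
                 n = "samplesize", pvalue = "pval"),
    short = c(rsid = "SNP", effect_allele = "EA", other_allele = "OA",
              chromosome = "CHR", position = "BP", eaf = "EAF",
              beta = "BETA", se = "SE", n = "N", pvalue = "P"))
}

# Validate a canonical table row-wise; returns the table with invalid rows
# dropped (warning lists 1-based data-row indices) and duplicates resolved.
validate_summary_stats <- function(x, source = "summary statistics") {
  if (nrow(x) == 0L) stop("empty input: no data rows in ", source)
  num_cols <- intersect(c("eaf", "beta", "se", "n", "position", "pvalue"),
                        names(x))
  for (cl in num_cols) x[[cl]] <- suppressWarnings(as.numeric(x[[cl]]))
  x$effect_allele <- toupper(trimws(as.character(x$effect_allele)))
  x$other_allele <- toupper(trimws(as.character(x$other_allele)))
  x$rsid <- as.character(x$rsid)

  ok <- !is.na(x$eaf) & !is.na(x$beta) & !is.na(x$se) & !is.na(x$n) &
    x$eaf >= 0 & x$eaf <= 1 & x$se > 0 & x$n >= 2 &
    x$effect_allele %in% names(.COMPLEMENT) &
    x$other_allele %in% names(.COMPLEMENT) &
    x$effect_allele != x$other_allele & !is.na(x$rsid) & nzchar(x$rsid)
  if (any(!ok)) {
    warning(sprintf("%s: rejected %d row(s) with unparseable or invalid fields (rows %s)",
                    source, sum(!ok), paste(which(!ok), collapse = ", ")),
            call. = FALSE)
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("empty input: no valid rows in ", source)
  if (anyDuplicated(x$rsid)) {
    dup <- unique(x$rsid[duplicated(x$rsid)])
    warning(sprintf("%s: duplicated rsid(s) %s; keeping first occurrence",
                    source, paste(dup, collapse = ", ")), call. = FALSE)
    x <- x[!duplicated(x$rsid), , drop = FALSE]
  }
  for (cl in setdiff(.CANONICAL, names(x))) x[[cl]] <- NA_real_
  rownames(x) <- NULL
  x[, .CANONICAL]
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited file (delimiter auto-detected from the
#' header line) of per-SNP associations. Rows with unparseable numeric
#' fields, invalid alleles, non-positive standard errors or `n < 2` are
#' rejected with a row-indexed warning; alleles are upper-cased; duplicated
#' rsids keep the first occurrence with a warning.
#'
#' @param path Path to the file.
#' @param dialect Named character vector mapping canonical field names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`,
#'   optionally `chromosome`, `position`, `pvalue`) to column headers, or
#'   `NULL` to auto-detect among [mr_dialect()] layouts.
#' @return A data.frame with the canonical columns, one row per valid SNP.
#' @seealso [write_summary_stats()], [harmonise()]
#' @export
read_summary_stats <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header))
    stop("empty input: ", path, " has no header line")
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, quote = "\"", comment.char = "")
  if (is.null(dialect)) {
    for (cand in c("standard", "short")) {
      d <- mr_dialect(cand)
      if (all(d[.MANDATORY] %in% names(raw))) { dialect <- d; break }
    }
    if (is.null(dialect))
      stop("configuration error: could not match columns of ", path,
           " to a built-in dialect; supply `dialect` explicitly")
  }
  missing <- setdiff(.MANDATORY, names(dialect)[dialect %in% names(raw)])
  if (length(missing))
    stop("configuration error: mandatory column(s) missing from ", path,
         ": ", paste(dialect[missing], collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    matrix(nrow = nrow(raw), ncol = 0L))
  for (field in names(dialect)) {
    if (dialect[[field]] %in% names(raw)) out[[field]] <- raw[[dialect[[field]]]]
  }
  validate_summary_stats(out, source = basename(path))
}

#' Write a GWAS summary-statistic table
#'
#' Inverse of [read_summary_stats()]: numeric fields are serialised at 15
#' significant digits so that a read/write round-trip preserves every value
#' to at least 12 significant digits.
#'
#' @param x Canonical summary-statistic data.frame.
#' @param path Output path.
#' @param dialect Dialect name or named vector (see [mr_dialect()]).
#' @param sep Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, dialect = "standard", sep = "\t") {
  if (is.character(dialect) && length(dialect) == 1L)
    dialect <- mr_dialect(dialect)
  keep <- names(dialect)[names(dialect) %in% names(x)]
  keep <- keep[vapply(keep, function(f) !all(is.na(x[[f]])), logical(1))]
  out <- x[, keep, drop = FALSE]
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]))
      out[[cl]] <- formatC(out[[cl]], digits = 15, format = "g")
  }
  names(out) <- dialect[keep]
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Instrument --------------------------------------------------------------

#' Construct a genetic instrument
#'
#' An instrument bundles a set of SNP-exposure associations with the unit
#' its betas are expressed in and the R-squared formula appropriate to it.
#' `variance_explained` is the sum of per-variant R-squared (independence
#' assumed: instruments are LD-pruned genome-wide hits).
#'
#' @param variants Canonical summary-statistic data.frame (no duplicate
#'   rsids).
#' @param name Label for the instrument.
#' @param exposure_unit `"sd"` (betas per SD of mean acceleration) or
#'   `"milligravity"`.
#' @param r2_method `"simple"` (`2 EAF (1-EAF) beta^2`, see [r2_simple()])
#'   or `"from_se"` (standard-error based, see [r2_from_se()]).
#' @return An object of class `mr_instrument`.
#' @export
new_instrument <- function(variants, name,
                           exposure_unit = c("sd", "milligravity"),
                           r2_method = c("from_se", "simple")) {
  exposure_unit <- match.arg(exposure_unit)
  r2_method <- match.arg(r2_method)
  variants <- validate_summary_stats(variants, source = name)
  r2 <- instrument_r2(variants, r2_method)
  structure(list(name = name, variants = variants,
                 exposure_unit = exposure_unit, r2_method = r2_method,
                 variance_explained = sum(r2)),
            class = "mr_instrument")
}

instrument_r2 <- function(variants, r2_method) {
  if (r2_method == "simple")
    r2_simple(variants$eaf, variants$beta)
  else
    r2_from_se(variants$eaf, variants$beta, variants$se, variants$n)
}

#' @export
print.mr_instrument <- function(x, ...) {
  cat(sprintf("<mr_instrument> %s: %d variant(s), unit = %s, R2 = %.4g\n",
              x$name, nrow(x$variants), x$exposure_unit,
              x$variance_explained))
  print(x$variants[, c("rsid", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "n")])
  invisible(x)
}

#' Built-in physical-activity instruments
#'
#' Returns one of the two published instruments for accelerometer-measured
#' physical activity, exactly as printed in the source study:
#' `"doherty5"`, the 5 genome-wide-significant SNPs (GWAS n = 91,105;
#' betas on the SD scale, per-variant R-squared via [r2_simple()]), or
#' `"klimentidis10"`, the extended 10-SNP instrument (GWAS n = 91,084;
#' betas in milli-gravities, R-squared via [r2_from_se()]). The two
#' instruments explain about 0.2% and 0.4% of phenotypic variability.
#'
#' @param name `"doherty5"` or `"klimentidis10"`.
#' @return An `mr_instrument` (see [new_instrument()]).
#' @export
#' @examples
#' builtin_instrument("doherty5")
builtin_instrument <- function(name) {
  specs <- list(
    doherty5 = list(unit = "sd", r2 = "simple"),
    klimentidis10 = list(unit = "milligravity", r2 = "from_se"))
  if (!name %in% names(specs))
    stop("unknown instrument '", name, "'; available: ",
         paste(names(specs), collapse = ", "))
  path <- system.file("extdata", paste0(name, ".tsv"), package = "actimr",
                      mustWork = TRUE)
  variants <- read_summary_stats(path, dialect = mr_dialect("short"))
  new_instrument(variants, name = name,
                 exposure_unit = specs[[name]]$unit,
                 r2_method = specs[[name]]$r2)
}

# Harmonisation -----------------------------------------------------------

is_palindromic <- function(a1, a2) .COMPLEMENT[a1] == a2

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome associations of every SNP shared with the exposure to
#' the exposure's effect allele: when the outcome's effect allele equals the
#' exposure's other allele (directly or after strand complementing), the
#' outcome beta is negated and its allele frequency replaced by `1 - eaf`.
#' Strand complementing is attempted only when direct and swapped matching
#' both fail. Palindromic (A/T, C/G) SNPs cannot be resolved from allele
#' letters alone and are handled per `palindrome_policy`:
#'
#' * `"infer_by_eaf"` (default): drop when either sample's allele frequency
#'   lies in the ambiguity window (0.42, 0.58); otherwise align so the
#'   minor allele matches.
#' * `"drop_ambiguous"`: drop every palindromic SNP.
#' * `"keep"`: trust the allele letters at face value.
#'
#' @param exposure,outcome Canonical summary-statistic data.frames (see
#'   [read_summary_stats()]); `exposure` may also be an `mr_instrument`.
#' @param palindrome_policy Policy for palindromic SNPs, see above.
#' @param outcome_name Label stored on the result (used in reports).
#' @return A data.frame of class `mr_harmonised` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `n_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `n_outcome`, `flipped`, `palindromic`; dropped SNPs
#'   (with reasons) in `attr(, "dropped")`.
#' @export
harmonise <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop_ambiguous",
                                            "keep"),
                      outcome_name = "outcome") {
  palindrome_policy <- match.arg(palindrome_policy)
  if (inherits(exposure, "mr_instrument")) exposure <- exposure$variants
  exposure <- validate_summary_stats(exposure, "exposure")
  outcome <- validate_summary_stats(outcome, "outcome")

  dropped <- data.frame(rsid = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  absent <- setdiff(exposure$rsid, outcome$rsid)
  if (length(absent))
    dropped <- rbind(dropped, data.frame(rsid = absent,
                                         reason = "absent_from_outcome"))
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L)
    stop("empty input: no overlapping rsids between exposure and outcome")

  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]
  keep <- logical(length(shared))
  flipped <- logical(length(shared))
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)
  window <- c(0.42, 0.58)

  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (palin[i]) {
      if (palindrome_policy == "drop_ambiguous") {
        dropped <- rbind(dropped, data.frame(rsid = shared[i],
                                             reason = "palindromic"))
        next
      }
      same_letters <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x)
      if (!same_letters)
        stop("harmonisation error: incompatible alleles at ", shared[i])
      if (palindrome_policy == "keep") {
        keep[i] <- TRUE
        flipped[i] <- ea_y == oa_x
      } else { # infer_by_eaf
        ambiguous <- (ex$eaf[i] > window[1] && ex$eaf[i] < window[2]) ||
          (is.na(ou$eaf[i]) ||
             (ou$eaf[i] > window[1] && ou$eaf[i] < window[2]))
        if (ambiguous) {
          dropped <- rbind(dropped,
                           data.frame(rsid = shared[i],
                                      reason = "palindromic_ambiguous"))
          next
        }
        keep[i] <- TRUE
        # align by minor allele: flip when minor alleles disagree
        flipped[i] <- (ex$eaf[i] < 0.5) != (ou$eaf[i] < 0.5)
      }
    } else {
      if (ea_y == ea_x && oa_y == oa_x) {
        keep[i] <- TRUE; flipped[i] <- FALSE
      } else if (ea_y == oa_x && oa_y == ea_x) {
        keep[i] <- TRUE; flipped[i] <- TRUE
      } else {
        cea <- unname(.COMPLEMENT[ea_y]); coa <- unname(.COMPLEMENT[oa_y])
        if (cea == ea_x && coa == oa_x) {
          keep[i] <- TRUE; flipped[i] <- FALSE
        } else if (cea == oa_x && coa == ea_x) {
          keep[i] <- TRUE; flipped[i] <- TRUE
        } else {
          stop("harmonisation error: incompatible alleles at ", shared[i])
        }
      }
    }
  }

  ex <- ex[keep, ]; ou <- ou[keep, ]
  flp <- flipped[keep]
  res <- data.frame(
    rsid = ex$rsid,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se,
    eaf_exposure = ex$eaf, n_exposure = ex$n,
    beta_outcome = ifelse(flp, -ou$beta, ou$beta),
    se_outcome = ou$se,
    eaf_outcome = ifelse(flp, 1 - ou$eaf, ou$eaf),
    n_outcome = ou$n,
    flipped = flp,
    palindromic = palin[keep],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("mr_harmonised", "data.frame"),
            dropped = dropped, outcome = outcome_name,
            palindrome_policy = palindrome_policy)
}

#' Re-express a harmonised dataset as an outcome association table
#'
#' Convenience for round-trip checks and chained harmonisation: extracts
#' the outcome block of an [harmonise()] result as a canonical
#' summary-statistic data.frame keyed to the common effect allele.
#'
#' @param h An `mr_harmonised` data.frame.
#' @return A canonical summary-statistic data.frame.
#' @export
harmonised_outcome <- function(h) {
  stopifnot(inherits(h, "mr_harmonised"))
  validate_summary_stats(data.frame(
    rsid = h$rsid, effect_allele = h$effect_allele,
    other_allele = h$other_allele, eaf = h$eaf_outcome,
    beta = h$beta_outcome, se = h$se_outcome, n = h$n_outcome,
    stringsAsFactors = FALSE), "harmonised outcome")
}

#' Write a harmonised dataset and its dropped-SNP manifest
#'
#' @param h An `mr_harmonised` data.frame.
#' @param path Output path for the delimited table; the manifest of dropped
#'   SNPs is written next to it as `<path>.dropped.json`.
#' @return `path`, invisibly.
#' @export
write_harmonised <- function(h, path) {
  out <- as.data.frame(h)
  for (cl in names(out))
    if (is.numeric(out[[cl]])) out[[cl]] <- formatC(out[[cl]], digits = 15,
                                                    format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(h, "dropped"), paste0(path, ".dropped.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
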