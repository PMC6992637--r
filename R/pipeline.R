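# Pipeline: Benjamini-Hochberg FDR, the full instrument-by-outcome
# analysis grid, report serialisation and plot-data export.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min_{j : p_j >= p_i} p_j * m / rank_j`, order-preserving with the
#' input. Satisfies `q_i >= p_i`, `max(q) = max(p)` and `q <= 1`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `pvalues`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03, 0.5))
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("domain error: p-values must lie in (0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  # step-up: running minimum of p * m / rank from the largest p down
  q <- numeric(m)
  q[o] <- pmin(1, cummin(p[o] * m / (m:1)))
  q
}

#' Table-1 style IVW summary of the source study
#'
#' The published inverse-variance-weighted estimates (odds ratio, 95% CI
#' and p-value) for both physical-activity instruments across the ten
#' cancer outcomes, as printed. These feed the FDR family replication and
#' the subgroup-heterogeneity checks; the per-SNP outcome data behind them
#' are consortium summary statistics that do not ship with the package.
#'
#' @return Data.frame with columns `instrument`, `outcome`, `cases`,
#'   `or`, `ci_low`, `ci_high`, `pvalue` (20 rows).
#' @export
table1_ivw <- function() {
  read.table(system.file("extdata", "table1_ivw.csv", package = "actimr",
                         mustWork = TRUE),
             header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Assemble an analysis configuration
#'
#' @param instruments Named list; each element a built-in instrument name
#'   (see [builtin_instrument()]), an `mr_instrument`, or a list with
#'   `path` (summary-statistic file) plus optional `exposure_unit` and
#'   `r2_method` (see [new_instrument()]).
#' @param outcomes Named list of outcome summary statistics: file paths or
#'   canonical data.frames.
#' @param methods Estimators to run per cell, subset of `"ivw"`,
#'   `"egger"`, `"weighted_median"`.
#' @param effects Effects mode for IVW (see [ivw()]).
#' @param sd_units Exposure SD in milli-gravities used to rescale
#'   milligravity-unit instruments to per-SD estimates.
#' @param palindrome_policy Passed to [harmonise()].
#' @param n_boot Bootstrap draws for the weighted median.
#' @param include_presso Run [mr_presso()] per cell (needs >= 4 SNPs).
#' @param fdr_family Data.frame with columns `instrument`, `outcome`
#'   selecting the IVW cells adjusted jointly; `NULL` (default) uses every
#'   configured cell, the family that reproduces the published q-values.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return List of class `mr_config`.
#' @export
analysis_config <- function(instruments, outcomes,
                            methods = c("ivw", "egger", "weighted_median"),
                            effects = "auto", sd_units = 8.14,
                            palindrome_policy = "infer_by_eaf",
                            n_boot = 10000, include_presso = FALSE,
                            fdr_family = NULL, seed = 1L) {
  stopifnot(length(instruments) >= 1, length(outcomes) >= 1)
  bad <- setdiff(methods, c("ivw", "egger", "weighted_median"))
  if (length(bad))
    stop("configuration error: unknown method(s) ",
         paste(bad, collapse = ", "))
  if (is.null(names(instruments)) || anyDuplicated(names(instruments)))
    stop("configuration error: instruments must be uniquely named")
  if (is.null(names(outcomes)) || anyDuplicated(names(outcomes)))
    stop("configuration error: outcomes must be uniquely named")
  structure(list(instruments = instruments, outcomes = outcomes,
                 methods = methods, effects = effects, sd_units = sd_units,
                 palindrome_policy = palindrome_policy, n_boot = n_boot,
                 include_presso = include_presso, fdr_family = fdr_family,
                 seed = as.integer(seed)),
            class = "mr_config")
}

resolve_instrument <- function(x, name) {
  if (inherits(x, "mr_instrument")) return(x)
  if (is.character(x) && length(x) == 1L) return(builtin_instrument(x))
  if (is.list(x) && !is.null(x$path)) {
    variants <- read_summary_stats(x$path, dialect = x$dialect %||% NULL)
    return(new_instrument(variants, name = name,
                          exposure_unit = x$exposure_unit %||% "sd",
                          r2_method = x$r2_method %||% "from_se"))
  }
  stop("configuration error: cannot resolve instrument '", name, "'")
}

resolve_outcome <- function(x) {
  if (is.character(x) && length(x) == 1L) read_summary_stats(x) else
    validate_summary_stats(as.data.frame(x), "outcome")
}

result_row <- function(instrument, outcome, method, res, seed_cell) {
  data.frame(instrument = instrument, outcome = outcome, method = method,
             beta = res$beta, se = res$se, or_ = res$or_,
             ci_low = res$ci_low, ci_high = res$ci_high,
             pvalue = res$pvalue, qvalue = NA_real_, n_snps = res$n_snps,
             effects_model = res$effects_model %||% NA_character_,
             q_stat = res$q_stat, q_pvalue = res$q_pvalue, i2 = res$i2,
             egger_intercept = res$egger_intercept,
             egger_intercept_p = res$egger_intercept_p,
             stringsAsFactors = FALSE)
}

#' Run the full analysis grid
#'
#' For every instrument-by-outcome cell: harmonise, compute per-SNP Wald
#' ratios, run the configured estimators, rescale milligravity-unit
#' instruments to per-SD estimates, attach diagnostics (Cochran's Q, I2,
#' Egger intercept, optional MR-PRESSO, leave-one-out spread), and apply
#' BH-FDR over the IVW p-values of the configured family. Cells with fewer
#' than 2 harmonised SNPs are marked failed with a reason code and never
#' abort the run. Deterministic given the configuration and master seed.
#'
#' @param config An `mr_config` from [analysis_config()].
#' @return List of class `mr_report` with elements `grid` (one row per
#'   instrument x outcome x method), `cells` (per-cell detail: harmonised
#'   data, ratio table, diagnostics), `failed`, and `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  instruments <- lapply(names(config$instruments), function(nm)
    resolve_instrument(config$instruments[[nm]], nm))
  names(instruments) <- names(config$instruments)
  outcomes <- lapply(config$outcomes, resolve_outcome)

  grid <- list(); cells <- list(); failed <- list()
  cell_idx <- 0L
  for (ins_name in names(instruments)) {
    ins <- instruments[[ins_name]]
    for (out_name in names(outcomes)) {
      cell_idx <- cell_idx + 1L
      cell_name <- paste(ins_name, out_name, sep = ".")
      seed_cell <- (config$seed + 7919L * cell_idx) %% .Machine$integer.max
      cell <- tryCatch({
        h <- harmonise(ins, outcomes[[out_name]],
                       palindrome_policy = config$palindrome_policy,
                       outcome_name = out_name)
        if (nrow(h) < 2L) stop("fewer than 2 harmonised SNPs")
        ratios <- wald_ratios(h)
        sd_mult <- if (ins$exposure_unit == "milligravity")
          config$sd_units else 1
        res <- list()
        if ("ivw" %in% config$methods)
          res$ivw <- scale_to_sd(ivw(ratios, effects = config$effects),
                                 sd_mult)
        if ("egger" %in% config$methods && nrow(h) >= 3L)
          res$egger <- scale_to_sd(mr_egger(h), sd_mult)
        if ("weighted_median" %in% config$methods && nrow(h) >= 3L)
          res$weighted_median <- scale_to_sd(
            weighted_median(h, n_boot = config$n_boot, seed = seed_cell),
            sd_mult)
        diag <- list(loo = if (nrow(h) >= 3L) leave_one_out(h))
        if (config$include_presso && nrow(h) >= 4L)
          diag$presso <- mr_presso(h, seed = seed_cell + 1L)
        list(name = cell_name, instrument = ins_name, outcome = out_name,
             harmonised = h, ratios = ratios, results = res,
             diagnostics = diag, sd_mult = sd_mult, seed = seed_cell)
      }, error = function(e) {
        failed[[cell_name]] <<- conditionMessage(e)
        NULL
      })
      if (is.null(cell)) next
      cells[[cell_name]] <- cell
      for (m in names(cell$results))
        grid[[paste(cell_name, m, sep = ".")]] <-
          result_row(ins_name, out_name, m, cell$results[[m]], seed_cell)
    }
  }
  if (length(grid) == 0L) stop("no cell produced a result")
  grid <- do.call(rbind, grid)
  rownames(grid) <- NULL

  # BH family: IVW cells only, all of them unless restricted
  fam <- grid$method == "ivw"
  if (!is.null(config$fdr_family)) {
    key <- paste(grid$instrument, grid$outcome)
    fam <- fam & key %in% paste(config$fdr_family$instrument,
                                config$fdr_family$outcome)
  }
  if (any(fam)) grid$qvalue[fam] <- bh_fdr(grid$pvalue[fam])

  structure(list(grid = grid, cells = cells, failed = failed,
                 provenance = list(seed = config$seed,
                                   methods = config$methods,
                                   effects = config$effects,
                                   sd_units = config$sd_units,
                                   n_boot = config$n_boot,
                                   version = as.character(
                                     utils::packageVersion("actimr")),
                                   timestamp = format(Sys.time(),
                                                      tz = "UTC"))),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %d result(s) across %d cell(s), %d failed\n",
              nrow(x$grid), length(x$cells), length(x$failed)))
  show <- x$grid[, c("instrument", "outcome", "method", "or_", "ci_low",
                     "ci_high", "pvalue", "qvalue")]
  for (cl in c("or_", "ci_low", "ci_high", "pvalue", "qvalue"))
    show[[cl]] <- signif(show[[cl]], 2)
  print(show)
  invisible(x)
}

#' Write report files
#'
#' `report.json` (full-precision grid plus provenance), `table1.csv` (the
#' human-readable grid, rounded to 2 significant figures as in the
#' published table), and one per-SNP ratio table `ratios_<cell>.tsv` per
#' cell.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(list(grid = report$grid, failed = report$failed,
                            provenance = report$provenance),
                       paths[1], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  tab <- report$grid
  for (cl in c("or_", "ci_low", "ci_high", "pvalue", "qvalue"))
    tab[[cl]] <- signif(tab[[cl]], 2)
  p <- file.path(dir, "table1.csv")
  write.table(tab[, c("instrument", "outcome", "method", "or_", "ci_low",
                      "ci_high", "pvalue", "qvalue", "n_snps",
                      "effects_model")],
              p, sep = ",", quote = FALSE, row.names = FALSE, na = "")
  paths <- c(paths, p)
  for (cell in report$cells) {
    p <- file.path(dir, paste0("ratios_", cell$name, ".tsv"))
    write.table(as.data.frame(cell$ratios), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export data behind the standard MR figures
#'
#' Emits plain tables for external plotting:
#' * `forest`: per-SNP log OR and 95% CI plus the pooled IVW row;
#' * `funnel`: per-SNP estimate against precision `1/se`, with the pooled
#'   estimate repeated in a `pooled` column;
#' * `scatter`: exposure/outcome beta pairs with per-method slope (and
#'   Egger intercept) columns;
#' * `loo`: leave-one-out estimates.
#'
#' @param report An `mr_report`.
#' @param kind `"forest"`, `"funnel"`, `"scatter"` or `"loo"`.
#' @param cell Cell name `"<instrument>.<outcome>"`.
#' @return A data.frame.
#' @export
export_plot_data <- function(report, kind = c("forest", "funnel",
                                              "scatter", "loo"), cell) {
  kind <- match.arg(kind)
  stopifnot(inherits(report, "mr_report"))
  if (!cell %in% names(report$cells))
    stop("unknown cell '", cell, "'; available: ",
         paste(names(report$cells), collapse = ", "))
  cl <- report$cells[[cell]]
  r <- as.data.frame(cl$ratios)
  mult <- cl$sd_mult
  switch(kind,
    forest = {
      pooled <- cl$results$ivw
      rows <- data.frame(
        label = c(r$rsid, "IVW"),
        log_or = c(r$theta * mult, pooled$beta),
        ci_low = c((r$theta - Z95 * r$se_theta) * mult,
                   log(pooled$ci_low)),
        ci_high = c((r$theta + Z95 * r$se_theta) * mult,
                    log(pooled$ci_high)),
        pooled = c(rep(FALSE, nrow(r)), TRUE), stringsAsFactors = FALSE)
      rows
    },
    funnel = data.frame(rsid = r$rsid, theta = r$theta * mult,
                        precision = 1 / (r$se_theta * mult),
                        pooled = cl$results$ivw$beta,
                        stringsAsFactors = FALSE),
    scatter = {
      h <- cl$harmonised
      out <- data.frame(rsid = h$rsid, beta_exposure = h$beta_exposure,
                        se_exposure = h$se_exposure,
                        beta_outcome = h$beta_outcome,
                        se_outcome = h$se_outcome, stringsAsFactors = FALSE)
      for (m in names(cl$results)) {
        # slopes on the raw (per-unit) scale of the harmonised betas
        out[[paste0("slope_", m)]] <- cl$results[[m]]$beta / mult
        if (m == "egger")
          out$egger_intercept <- cl$results[[m]]$egger_intercept
      }
      out
    },
    loo = cl$diagnostics$loo)
}
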