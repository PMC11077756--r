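# one direction of the analysis: select -> clump -> exclude -> harmonize
# -> strength -> estimators -> diagnostics
run_direction <- function(exposure, outcome, config, exclude = NULL,
                          ld = NULL) {
  counts <- c(input = nrow(exposure))
  sel <- select_significant(exposure, config$p_threshold)
  counts["selected"] <- nrow(sel)
  if (nrow(sel) > 0L && !anyNA(sel$chr) && !anyNA(sel$pos)) {
    sel <- clump(sel, ld = ld, r2_threshold = config$clump_r2,
                 window_kb = config$clump_window_kb)
  }
  counts["clumped"] <- nrow(sel)
  if (!is.null(exclude)) sel <- apply_exclusion_list(sel, exclude)
  counts["after_exclusion"] <- nrow(sel)
  if (nrow(sel) < 1L) {
    return(list(estimable = FALSE, counts = counts,
                reason = "no instruments after selection"))
  }
  hs <- harmonize(sel, outcome,
                  palindrome_eaf_limit = config$palindrome_eaf_limit)
  n_iv <- nrow(kept_rows(hs))
  counts["harmonized"] <- n_iv
  if (n_iv < 1L) {
    return(list(estimable = FALSE, counts = counts,
                reason = "no instruments after harmonization"))
  }
  if (identical(attr(exposure, "trait_name"), attr(outcome, "trait_name"))) {
    warnf("exposure and outcome are the same trait; estimate is degenerate")
  }
  n_exp <- stats::median(kept_rows(hs)$n_exposure, na.rm = TRUE)
  strength <- if (is.finite(n_exp) && n_exp > 2) {
    instrument_strength(hs, n_exp)
  }
  fit <- mr_fit(hs, model = "auto", reps = config$bootstrap_reps,
                seed = config$seed, ci_level = config$ci_level)
  presso <- if (n_iv >= 4L && config$presso_sims >= 100L) {
    mr_presso(hs, n_sims = config$presso_sims, seed = config$seed)
  }
  loo <- if (n_iv >= 3L) leave_one_out(hs)
  list(estimable = TRUE, counts = counts, harmonized = hs,
       strength = strength, fit = fit, presso = presso, loo = loo,
       funnel = funnel_data(hs))
}

#' Bidirectional two-sample MR analysis
#'
#' Runs the full instrument pipeline and estimator panel in the forward
#' direction (exposure on outcome) and, with the roles swapped, in the
#' reverse direction. The reverse leg commonly has very few instruments;
#' IVW is reported from 2 instruments while Egger/median/mode are skipped
#' with a notice, and a direction with no usable instrument is reported as
#' not estimable rather than an error.
#'
#' @param exposure,outcome [trait_table()]s with genome-wide rows.
#' @param config An [mr_control()].
#' @param exclude Optional SNP exclusion list (applied in both
#'   directions).
#' @param ld Optional LD matrix for clumping.
#' @return An object of class `mr_report` with elements `forward` and
#'   `reverse` (each: counts, harmonized set, strength, `mr_result`,
#'   PRESSO, leave-one-out, funnel data) plus `config`.
#' @export
run_bidirectional <- function(exposure, outcome, config = mr_control(),
                              exclude = NULL, ld = NULL) {
  structure(list(forward = run_direction(exposure, outcome, config,
                                         exclude, ld),
                 reverse = run_direction(outcome, exposure, config,
                                         exclude, ld),
                 exposure_name = trait_name(exposure),
                 outcome_name = trait_name(outcome),
                 config = config),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  for (dir in c("forward", "reverse")) {
    leg <- x[[dir]]
    lab <- if (dir == "forward") {
      sprintf("%s -> %s", x$exposure_name, x$outcome_name)
    } else {
      sprintf("%s -> %s", x$outcome_name, x$exposure_name)
    }
    cat(sprintf("== %s direction (%s) ==\n", dir, lab))
    cat("  stage counts:", paste(names(leg$counts), leg$counts,
                                 sep = "=", collapse = ", "), "\n")
    if (!leg$estimable) {
      cat("  not estimable:", leg$reason, "\n")
      next
    }
    print(leg$fit)
    if (!is.null(leg$presso)) {
      cat(sprintf("  MR-PRESSO global p = %.3f, %d outlier(s)\n",
                  leg$presso$global_pvalue,
                  length(leg$presso$outlier_indices)))
    }
  }
  invisible(x)
}

report_tables <- function(report) {
  leg_table <- function(leg, exposure, outcome) {
    if (!leg$estimable) return(NULL)
    df <- as.data.frame(leg$fit)
    cbind(exposure = exposure, outcome = outcome, df)
  }
  list(forward = leg_table(report$forward, report$exposure_name,
                           report$outcome_name),
       reverse = leg_table(report$reverse, report$outcome_name,
                           report$exposure_name))
}

#' Export an analysis report as TSV + JSON + text
#'
#' Writes, under `path` with the given prefix: per-direction estimator
#' tables (TSV, one row per method with beta, SE, OR, CI, p), leave-one-
#' out and funnel tables, a JSON file carrying every number at full double
#' precision (reloading reproduces the floats exactly), and a compact
#' human-readable text summary using the conventional rounding (betas/SEs
#' to 4 decimals, ORs/CIs to 3, p-values to 3).
#'
#' @param report An `mr_report` from [run_bidirectional()].
#' @param path Output directory (created if needed).
#' @param prefix File-name prefix (default `"mr"`).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, path, prefix = "mr") {
  stopifnot(inherits(report, "mr_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tabs <- report_tables(report)
  for (dir in names(tabs)) {
    if (is.null(tabs[[dir]])) next
    f <- file.path(path, sprintf("%s_%s_estimates.tsv", prefix, dir))
    utils::write.table(tabs[[dir]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
    leg <- report[[dir]]
    if (!is.null(leg$loo)) {
      f <- file.path(path, sprintf("%s_%s_loo.tsv", prefix, dir))
      utils::write.table(leg$loo, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
    if (!is.null(leg$funnel) && nrow(leg$funnel) > 0L) {
      f <- file.path(path, sprintf("%s_%s_funnel.tsv", prefix, dir))
      utils::write.table(leg$funnel, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
  }

  json <- list(exposure = report$exposure_name,
               outcome = report$outcome_name,
               config = unclass(report$config))
  for (dir in c("forward", "reverse")) {
    leg <- report[[dir]]
    json[[dir]] <- if (!leg$estimable) {
      list(estimable = FALSE, counts = as.list(leg$counts),
           reason = leg$reason)
    } else {
      list(estimable = TRUE, counts = as.list(leg$counts),
           estimates = tabs[[dir]],
           heterogeneity = if (!is.null(leg$fit$heterogeneity)) {
             unclass(leg$fit$heterogeneity)
           },
           egger_intercept_p = if (!is.null(leg$fit$egger_intercept)) {
             leg$fit$egger_intercept$pvalue
           },
           presso = if (!is.null(leg$presso)) {
             list(global_pvalue = leg$presso$global_pvalue,
                  n_outliers = length(leg$presso$outlier_indices),
                  n_sims = leg$presso$n_sims, seed = leg$presso$seed)
           },
           notes = leg$fit$notes)
    }
  }
  fj <- file.path(path, paste0(prefix, "_report.json"))
  jsonlite::write_json(json, fj, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  written <- c(written, fj)

  ft <- file.path(path, paste0(prefix, "_report.txt"))
  con <- file(ft, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  written <- c(written, ft)
  invisible(written)
}
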