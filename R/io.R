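#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- (or otherwise) delimited file with a header into a
#' [trait_table()]. The canonical column names are `snp_id`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`;
#' files using other headers are mapped via `dialect`. Numeric parsing is
#' locale-independent (period decimal separator); missing values are
#' encoded `NA`. Input row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(beta = "BETA", se = "SE")`.
#' @param sep Field separator (default tab).
#' @inheritParams trait_table
#' @return A [trait_table()].
#' @export
read_summary_stats <- function(path, dialect = NULL, sep = "\t",
                               trait_name = NULL,
                               trait_type = c("continuous", "binary")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0L) stopf("empty input file: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L && ncol(df) == 0L) stopf("empty input file: %s", path)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df)) {
        stopf("dialect maps '%s' to column '%s', absent from file", canon, src)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  trait_table(df, trait_name = trait_name, trait_type = match.arg(trait_type))
}

#' Write a trait table as canonical summary-statistics TSV
#'
#' Serializes with full double precision (17 significant digits) so that
#' `read_summary_stats(write_summary_stats(t))` reproduces `t` exactly.
#' Missing fields are written as `NA`.
#'
#' @param table A [trait_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(table)
  num_cols <- c("eaf", "beta", "se", "pvalue", "n")
  for (col in num_cols) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", as.numeric(v)))
  }
  out$pos <- ifelse(is.na(out$pos), "NA", as.character(out$pos))
  out$chr <- ifelse(is.na(out$chr), "NA", as.character(out$chr))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, tab-separated fields `name`,
#' `description`, then gene symbols. Duplicate genes within a line are
#' deduplicated.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (term -> unique gene set).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stopf("GMT line %d has %d field(s); need at least name, description, one gene",
            i, length(fields))
    }
    nms[[i]] <- fields[[1]]
    genes <- unique(fields[-(1:2)])
    sets[[i]] <- genes[nzchar(genes)]
  }
  names(sets) <- nms
  sets
}

#' Read an LD matrix from square delimited text
#'
#' Expects a header row of SNP ids and a first column of SNP ids; values
#' are pairwise r-squared (or r; used as supplied by [clump_instruments()]).
#'
#' @param path Path to a square TSV.
#' @return A numeric matrix with dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stopf("LD matrix is not square: %d x %d", nrow(m), ncol(m))
  if (!identical(rownames(m), colnames(m))) {
    stopf("LD matrix row and column names differ")
  }
  m
}

#' Read a SNP exclusion list (one id per line)
#'
#' Stands in for confounder screening (e.g. removing SNPs associated with
#' adiposity traits identified in PhenoScanner).
#'
#' @param path Path to a text file, one snp_id per line.
#' @return Character vector of SNP ids.
#' @export
read_exclusion_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' Analysis configuration
#'
#' Collects the tunable thresholds of the MR pipeline with the
#' conventional defaults: genome-wide significance 5e-8, clumping r^2
#' 0.001 within a 10,000 kb window, palindromic-SNP frequency limit 0.42,
#' 1000 bootstrap replicates, 1000 MR-PRESSO simulations, 95% confidence
#' level.
#'
#' @param p_threshold Instrument significance threshold (strict `<`).
#' @param clump_r2 LD r-squared threshold for clumping.
#' @param clump_window_kb Clumping window in kilobases.
#' @param palindrome_eaf_limit Drop palindromic SNPs whose minor-allele
#'   frequency exceeds this in either study (strand unresolvable near 0.5).
#' @param bootstrap_reps Bootstrap replicates for median/mode SEs.
#' @param presso_sims MR-PRESSO simulation count.
#' @param ci_level Confidence level for intervals.
#' @param seed Integer seed recorded in and used by every stochastic step.
#' @return A list of class `mr_control`.
#' @export
mr_control <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                       clump_window_kb = 10000, palindrome_eaf_limit = 0.42,
                       bootstrap_reps = 1000, presso_sims = 1000,
                       ci_level = 0.95, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0,
            palindrome_eaf_limit >= 0, palindrome_eaf_limit <= 0.5,
            bootstrap_reps >= 0, presso_sims >= 0,
            ci_level > 0, ci_level < 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 palindrome_eaf_limit = palindrome_eaf_limit,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 presso_sims = as.integer(presso_sims),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "mr_control")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror [mr_control()] arguments.
#' @return An `mr_control` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mr_control))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(mr_control, vals)
}
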