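#' Construct a GWAS summary-statistics table for one trait
#'
#' A `trait_table` is a validated `data.frame` of per-SNP association
#' statistics for a single trait, the basic currency of two-sample MR.
#' Each row describes one SNP's association: identifier, genomic
#' coordinates, effect and other allele, effect-allele frequency, effect
#' estimate (log-odds for binary traits), its standard error, p-value and
#' sample size.
#'
#' Rows violating the record invariants (non-positive SE, p outside (0, 1],
#' frequency outside \[0, 1\], identical or multi-base alleles, missing
#' beta/se/p) are dropped with a warning giving the count; indels are not
#' retained since the estimators operate on biallelic SNPs. Positions are
#' 1-based. Missing `eaf` or `n` is allowed and encoded `NA`.
#'
#' @param x A data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; optionally `chr`, `pos`, `eaf`,
#'   `pvalue`, `n`.
#' @param trait_name Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"` (betas on the log-odds
#'   scale).
#' @return An object of class `trait_table` (a data.frame with canonical
#'   columns `snp_id`, `chr`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`), with attributes `trait_name` and
#'   `trait_type`.
#' @examples
#' tt <- trait_table(data.frame(
#'   snp_id = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.1, -0.05), se = c(0.01, 0.02),
#'   pvalue = c(1e-20, 1e-9)), trait_name = "exposure")
#' nrow(tt)
#' @export
trait_table <- function(x, trait_name = "trait",
                        trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  canon <- c("snp_id", "chr", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pvalue", "n")
  for (col in setdiff(canon, names(x))) x[[col]] <- NA
  x <- x[, canon]

  x$snp_id <- as.character(x$snp_id)
  x$chr <- as.character(x$chr)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$n <- suppressWarnings(as.numeric(x$n))

  ok <- !is.na(x$snp_id) & nzchar(x$snp_id) &
    x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele &
    !is.na(x$beta) & is.finite(x$beta) &
    !is.na(x$se) & x$se > 0 &
    (is.na(x$pvalue) | (x$pvalue > 0 & x$pvalue <= 1)) &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    (is.na(x$n) | x$n > 0)
  # pvalue may not be missing when the column is in use for selection;
  # treat NA pvalue as invalid (the contract: beta/se/p must be present)
  ok <- ok & !is.na(x$pvalue)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warnf("%s: dropped %d record(s) failing validation", trait_name, n_dropped)
  }
  x <- x[ok, , drop = FALSE]
  if (anyDuplicated(x$snp_id)) {
    stopf("%s: duplicate snp_id values: %s", trait_name,
          paste(unique(x$snp_id[duplicated(x$snp_id)])[1:3], collapse = ", "))
  }
  rownames(x) <- NULL
  structure(x,
            trait_name = trait_name,
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
  invisible(x)
}

# subsetting keeps the class and trait attributes
#' @export
`[.trait_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "trait_name") <- attr(x, "trait_name")
    attr(out, "trait_type") <- attr(x, "trait_type")
    class(out) <- c("trait_table", "data.frame")
  }
  out
}

trait_name <- function(x) attr(x, "trait_name") %||% "trait"

`%||%` <- function(a, b) if (is.null(a)) b else a
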