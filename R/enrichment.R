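#' Map instrument SNPs to genes via a cis-eQTL table
#'
#' Restricts a cis-eQTL association table (`snp_id`, `gene`, `pvalue`,
#' optional `fdr`) to the given SNPs, computes Benjamini-Hochberg FDR
#' across the restricted rows when no `fdr` column is supplied, keeps rows
#' with `pvalue < p_threshold` and `fdr < fdr_threshold`, and returns the
#' deduplicated gene symbols. Output is independent of eQTL row order.
#'
#' @param snps Character vector of instrument SNP ids.
#' @param eqtl data.frame with columns `snp_id`, `gene`, `pvalue` and
#'   optionally `fdr`.
#' @param p_threshold eQTL p-value screen (default 5e-8).
#' @param fdr_threshold FDR screen (default 0.05).
#' @return Character vector of unique gene symbols (possibly empty),
#'   sorted.
#' @export
annotate_genes <- function(snps, eqtl, p_threshold = 5e-8,
                           fdr_threshold = 0.05) {
  stopifnot(is.data.frame(eqtl),
            all(c("snp_id", "gene", "pvalue") %in% names(eqtl)))
  if (nrow(eqtl) == 0L) stopf("eQTL table is empty")
  sub <- eqtl[eqtl$snp_id %in% snps, , drop = FALSE]
  if (nrow(sub) == 0L) return(character(0))
  fdr <- if ("fdr" %in% names(sub)) sub$fdr else stats::p.adjust(sub$pvalue, "BH")
  keep <- sub$pvalue < p_threshold & fdr < fdr_threshold
  sort(unique(as.character(sub$gene[keep])))
}

#' Over-representation analysis against gene sets
#'
#' For each term, tests whether the selected genes contain more members of
#' the term than expected when drawing `n = |selected|` genes from the
#' `N`-gene background with `K` term members: the upper-tail
#' hypergeometric probability \eqn{P(X \ge k)}. Terms are intersected with
#' the background before testing; Benjamini-Hochberg FDR is computed
#' across terms and rows are sorted by p-value.
#'
#' @param selected Character vector of genes of interest (must be a subset
#'   of `background`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gene_sets()]).
#' @param background Character vector: the gene universe.
#' @return A data.frame of class `enrichment_table` with columns `term`,
#'   `k`, `K`, `n`, `N`, `pvalue`, `fdr`.
#' @export
ora_test <- function(selected, gene_sets, background) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  offenders <- setdiff(selected, background)
  if (length(offenders) > 0L) {
    stopf("selected gene(s) not in background: %s",
          paste(utils::head(offenders, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(selected)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), background)
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- if (k == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, "BH")
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}
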