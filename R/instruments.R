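#' Select genome-wide-significant instruments
#'
#' Keeps records with `pvalue < p_threshold` (strict inequality), the
#' conventional genome-wide significance screen for instrument candidates.
#' Input order is preserved.
#'
#' @param table A [trait_table()].
#' @param p_threshold Significance threshold, default 5e-8.
#' @return A [trait_table()] subset (possibly empty).
#' @export
select_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(is.data.frame(table), is_number(p_threshold))
  table[!is.na(table$pvalue) & table$pvalue < p_threshold, , drop = FALSE]
}

#' Remove SNPs on an exclusion list
#'
#' Drops records whose `snp_id` appears in `excluded` — typically SNPs
#' associated with potential confounders (e.g. adiposity traits) found by
#' screening a phenotype database.
#'
#' @param table A [trait_table()].
#' @param excluded Character vector of SNP ids to remove.
#' @return A [trait_table()] without the excluded records; the number
#'   removed is reported via `message()`.
#' @export
apply_exclusion_list <- function(table, excluded) {
  stopifnot(is.data.frame(table))
  drop <- table$snp_id %in% excluded
  if (any(drop)) msgf("excluded %d SNP(s) on the exclusion list", sum(drop))
  table[!drop, , drop = FALSE]
}

#' Greedy LD clumping of instrument candidates
#'
#' Implements the standard greedy clumping pass: SNPs are visited in order
#' of ascending p-value (ties broken by ascending `snp_id`); each visited
#' SNP is kept and all other SNPs on the same chromosome within
#' `window_kb` kilobases are removed when their LD r-squared with the kept
#' SNP exceeds `r2_threshold` — or unconditionally within the window when
#' no LD matrix is supplied (distance-only mode, an approximation used
#' when no reference panel is available). Deterministic; the kept set does
#' not depend on input row order.
#'
#' @param table A [trait_table()] whose records carry `chr` and `pos`.
#' @param ld Optional square named matrix of pairwise r-squared values.
#' @param r2_threshold LD threshold above which neighbours are removed.
#' @param window_kb Window size in kilobases.
#' @param missing_ld What to do when a SNP pair is absent from `ld`:
#'   `"error"` (default) or `"zero"` (treat as unlinked, with a warning).
#' @return The kept records, in input order.
#' @export
clump <- function(table, ld = NULL, r2_threshold = 0.001, window_kb = 10000,
                  missing_ld = c("error", "zero")) {
  missing_ld <- match.arg(missing_ld)
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) return(table)
  if (anyNA(table$chr) || anyNA(table$pos)) {
    stopf("clumping requires chromosome and position for every record")
  }
  ord <- order(table$pvalue, table$snp_id)
  window_bp <- window_kb * 1000
  removed <- rep(FALSE, nrow(table))
  kept <- rep(FALSE, nrow(table))
  warned_missing <- FALSE
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    near <- !kept & !removed &
      table$chr == table$chr[i] &
      abs(table$pos - table$pos[i]) <= window_bp
    near[i] <- FALSE
    if (!any(near)) next
    if (is.null(ld)) {
      removed[near] <- TRUE
    } else {
      ids <- table$snp_id[near]
      have <- table$snp_id[i] %in% rownames(ld) & ids %in% rownames(ld)
      if (any(!have)) {
        if (missing_ld == "error") {
          stopf("SNP pair absent from LD matrix: %s vs %s",
                table$snp_id[i], ids[!have][1])
        }
        if (!warned_missing) {
          warnf("SNP(s) absent from LD matrix treated as r^2 = 0")
          warned_missing <- TRUE
        }
      }
      r2 <- rep(0, length(ids))
      if (any(have)) r2[have] <- ld[table$snp_id[i], ids[have]]
      removed[which(near)[r2 > r2_threshold]] <- TRUE
    }
  }
  table[kept, , drop = FALSE]
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

# Align one secondary table's record to the exposure's effect allele.
# Returns list(action = "keep"/"flip"/"palindromic"/"unmatched",
#              freq_flip_needed = logical) where the palindromic branch is
# resolved by the caller using allele frequencies.
align_alleles <- function(ea_x, oa_x, ea_o, oa_o) {
  if (ea_o == ea_x && oa_o == oa_x) return("keep")
  if (ea_o == oa_x && oa_o == ea_x) return("flip")
  ea_c <- complement_allele(ea_o)
  oa_c <- complement_allele(oa_o)
  if (ea_c == ea_x && oa_c == oa_x) return("keep")
  if (ea_c == oa_x && oa_c == ea_x) return("flip")
  "unmatched"
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the tables on `snp_id` and aligns every secondary table's
#' effect to the exposure's effect allele: identical alleles are kept
#' as-is; swapped alleles flip the sign of the effect (and complement the
#' frequency); strand-complement records are complemented and re-checked.
#' Palindromic SNPs (A/T or C/G), whose strand cannot be read off the
#' alleles, are resolved by allele frequency — oriented so that the
#' effect-allele frequencies agree (both below or both above 0.5) — and
#' dropped when the frequency is missing or too close to 0.5
#' (`min(eaf, 1-eaf) > palindrome_eaf_limit`) in any table.
#'
#' Every exposure SNP receives exactly one provenance status: `kept`,
#' `flipped`, `dropped_palindromic`, or `dropped_unmatched`.
#'
#' @param exposure,outcome [trait_table()]s sharing a `snp_id` namespace.
#' @param more Optional named list of additional [trait_table()]s
#'   (mediator or extra exposures); each contributes `beta_<name>` and
#'   `se_<name>` columns and must align for a SNP to be kept.
#' @param palindrome_eaf_limit Frequency cutoff for palindromic SNPs
#'   (default 0.42).
#' @return A `harmonized_set`: a data.frame with one row per exposure SNP
#'   carrying `snp_id`, `chr`, `pos`, `eaf`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, any `beta_<name>` /
#'   `se_<name>` pairs, `status` and `flipped`. Estimators operate on the
#'   rows with status `kept`/`flipped`.
#' @export
harmonize <- function(exposure, outcome, more = NULL,
                      palindrome_eaf_limit = 0.42) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (anyDuplicated(exposure$snp_id)) stopf("duplicate snp_id in exposure table")
  if (anyDuplicated(outcome$snp_id)) stopf("duplicate snp_id in outcome table")
  if (!is.null(more)) {
    if (is.null(names(more)) || any(!nzchar(names(more)))) {
      stopf("'more' must be a named list of trait tables")
    }
    for (nm in names(more)) {
      if (anyDuplicated(more[[nm]]$snp_id)) {
        stopf("duplicate snp_id in table '%s'", nm)
      }
    }
  }
  secondary <- c(list(outcome = outcome), more)
  n <- nrow(exposure)
  status <- rep("kept", n)
  flipped <- rep(FALSE, n)
  betas <- ses <- vector("list", length(secondary))
  names(betas) <- names(ses) <- names(secondary)
  for (s in names(secondary)) {
    betas[[s]] <- rep(NA_real_, n)
    ses[[s]] <- rep(NA_real_, n)
  }

  for (j in seq_len(n)) {
    ea_x <- exposure$effect_allele[j]
    oa_x <- exposure$other_allele[j]
    eaf_x <- exposure$eaf[j]
    pal <- is_palindromic(ea_x, oa_x)
    for (s in names(secondary)) {
      tab <- secondary[[s]]
      k <- match(exposure$snp_id[j], tab$snp_id)
      if (is.na(k)) {
        status[j] <- "dropped_unmatched"
        break
      }
      act <- align_alleles(ea_x, oa_x, tab$effect_allele[k], tab$other_allele[k])
      if (act == "unmatched") {
        status[j] <- "dropped_unmatched"
        break
      }
      b <- tab$beta[k]
      f <- tab$eaf[k]
      if (act == "flip") {
        b <- -b
        f <- 1 - f
      }
      if (pal) {
        # strand is unreadable from the alleles; use frequencies
        if (is.na(eaf_x) || is.na(f) ||
            min(eaf_x, 1 - eaf_x) > palindrome_eaf_limit ||
            min(f, 1 - f) > palindrome_eaf_limit) {
          status[j] <- "dropped_palindromic"
          break
        }
        if ((eaf_x < 0.5) != (f < 0.5)) {
          b <- -b
          f <- 1 - f
          flipped[j] <- TRUE
        }
      }
      if (act == "flip") flipped[j] <- TRUE
      betas[[s]][j] <- b
      ses[[s]][j] <- tab$se[k]
    }
  }
  status[status == "kept" & flipped] <- "flipped"

  out <- data.frame(snp_id = exposure$snp_id,
                    chr = exposure$chr, pos = exposure$pos,
                    eaf = exposure$eaf,
                    beta_exposure = exposure$beta,
                    se_exposure = exposure$se,
                    pvalue_exposure = exposure$pvalue,
                    n_exposure = exposure$n,
                    stringsAsFactors = FALSE)
  out$beta_outcome <- betas$outcome
  out$se_outcome <- ses$outcome
  for (s in names(more %||% list())) {
    out[[paste0("beta_", s)]] <- betas[[s]]
    out[[paste0("se_", s)]] <- ses[[s]]
  }
  out$status <- status
  out$flipped <- flipped
  rownames(out) <- NULL
  structure(out,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            extra_names = names(more %||% list()),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("kept", "flipped",
                                           "dropped_palindromic",
                                           "dropped_unmatched")))
  cat(sprintf("Harmonized set: %s -> %s\n", attr(x, "exposure_name"),
              attr(x, "outcome_name")))
  cat(sprintf("  %d instrument(s) usable (%d as-is, %d flipped); %d palindromic, %d unmatched dropped\n",
              sum(tab[c("kept", "flipped")]), tab[["kept"]], tab[["flipped"]],
              tab[["dropped_palindromic"]], tab[["dropped_unmatched"]]))
  invisible(x)
}

# rows usable for estimation
kept_rows <- function(set) {
  stopifnot(is.data.frame(set))
  if (!is.null(set$status)) {
    set[set$status %in% c("kept", "flipped"), , drop = FALSE]
  } else {
    set
  }
}

#' Instrument strength: variance explained and F statistics
#'
#' For each instrument, the variance in the exposure explained is computed
#' from the widely used frequency-based formula
#' \deqn{R^2_j = \frac{2\beta_j^2 f_j(1-f_j)}{2\beta_j^2 f_j(1-f_j) + 2 n \sigma_j^2 f_j(1-f_j)}}
#' with \eqn{f_j} the effect-allele frequency, and
#' \eqn{F_j = R^2_j (n-2)/(1-R^2_j)}. When a row's frequency is missing
#' the approximation \eqn{F_j = (\beta_j/\sigma_j)^2},
#' \eqn{R^2_j = F_j/(F_j + n - 2)} is used instead. Instruments with
#' F < 10 are flagged as conventionally weak (flagged, not dropped).
#'
#' @param set A `harmonized_set` (or trait table with `beta`/`se`
#'   columns named `beta_exposure`/`se_exposure`).
#' @param n_exposure Exposure GWAS sample size (> 2).
#' @return An object of class `instrument_strength`: data.frame with
#'   `snp_id`, `r_squared`, `f_statistic`, `weak` plus attributes
#'   `total_r_squared`, `mean_f`, `min_f`.
#' @export
instrument_strength <- function(set, n_exposure) {
  if (!is_number(n_exposure) || n_exposure <= 2) {
    stopf("n_exposure must be a single number > 2")
  }
  ks <- kept_rows(set)
  beta <- ks$beta_exposure
  se <- ks$se_exposure
  eaf <- if (!is.null(ks$eaf)) ks$eaf else rep(NA_real_, nrow(ks))
  n <- n_exposure
  r2 <- f <- numeric(length(beta))
  has_f <- !is.na(eaf) & eaf > 0 & eaf < 1
  # frequency-based form: the 2 f(1-f) factor cancels between numerator
  # and denominator, leaving beta^2 / (beta^2 + n se^2)
  r2[has_f] <- beta[has_f]^2 / (beta[has_f]^2 + n * se[has_f]^2)
  f[has_f] <- r2[has_f] * (n - 2) / (1 - r2[has_f])
  z2 <- (beta[!has_f] / se[!has_f])^2
  f[!has_f] <- z2
  r2[!has_f] <- z2 / (z2 + n - 2)
  out <- data.frame(snp_id = ks$snp_id, r_squared = r2, f_statistic = f,
                    weak = f < 10, stringsAsFactors = FALSE)
  structure(out,
            total_r_squared = sum(r2),
            mean_f = mean(f),
            min_f = if (length(f)) min(f) else NA_real_,
            n_exposure = n,
            class = c("instrument_strength", "data.frame"))
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength (n = %g): total R^2 = %.4g, mean F = %.1f, min F = %.1f; %d/%d with F < 10\n",
              attr(x, "n_exposure"), attr(x, "total_r_squared"),
              attr(x, "mean_f"), attr(x, "min_f"), sum(x$weak), nrow(x)))
  invisible(x)
}
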