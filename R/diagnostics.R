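# leave-one-out IVW slopes computed by subtracting each SNP's terms from
# the full weighted sums (exact, O(n))
loo_slopes <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  r <- by / bx
  (sum(w * r) - w * r) / (sum(w) - w)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW (auto model) effect with each instrument removed
#' in turn, plus the full-set estimate; a single influential SNP shows up
#' as a row whose estimate departs from the rest.
#'
#' @param set A `harmonized_set` with at least 3 usable instruments.
#' @return A data.frame of class `loo_table`: one row per left-out SNP
#'   (`snp_id`, `beta`, `se`, `pvalue`, `n_snp`) plus an `"(all)"` row.
#' @export
leave_one_out <- function(set) {
  ks <- kept_rows(set)
  if (nrow(ks) < 3L) stopf("leave-one-out requires at least 3 instruments (got %d)", nrow(ks))
  rows <- lapply(seq_len(nrow(ks)), function(j) {
    est <- mr_ivw(ks[-j, , drop = FALSE], model = "auto")
    data.frame(snp_id = ks$snp_id[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  full <- mr_ivw(ks, model = "auto")
  out <- rbind(do.call(rbind, rows),
               data.frame(snp_id = "(all)", beta = full$beta, se = full$se,
                          pvalue = full$pvalue, n_snp = full$n_snp,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  structure(out, class = c("loo_table", "data.frame"))
}

#' MR-PRESSO: simulation-based pleiotropy residual sum of squares test
#'
#' Detects horizontal-pleiotropy outliers by comparing observed
#' leave-one-out residuals against parametric simulations. The observed
#' global statistic is \eqn{RSS = \sum_j (\beta_{Yj} - \hat\beta_{(-j)}
#' \beta_{Xj})^2} with \eqn{\hat\beta_{(-j)}} the leave-one-out IVW
#' slope. Each of `n_sims` replicates draws
#' \eqn{\beta^*_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj})} and
#' \eqn{\beta^*_{Yj} \sim N(\hat\beta_{(-j)}\beta_{Xj}, \sigma_{Yj})} and
#' recomputes the statistic. Empirical p-values carry an add-one
#' pseudocount so they are never exactly zero:
#' global p = (1 + #\{RSS* >= RSS\})/(n_sims + 1); per-SNP outlier
#' p-values compare squared residuals the same way and are multiplicity-
#' adjusted (Bonferroni by default). When outliers are flagged, a
#' distortion test compares the change in the IVW estimate after removing
#' them against a null built by removing random subsets of the same size.
#'
#' @param set A `harmonized_set` with at least 4 usable instruments.
#' @param n_sims Number of simulations (>= 100, default 1000).
#' @param outlier_alpha Adjusted-p threshold flagging outliers.
#' @param seed Integer seed; results are reproducible given (seed, n_sims).
#' @param adjust Multiplicity adjustment for outlier p-values
#'   (`"bonferroni"` or `"BH"`).
#' @return An object of class `presso_result`: `global_rss_obs`,
#'   `global_pvalue`, `outlier_table` (snp_id, raw and adjusted p),
#'   `outlier_indices`, `distortion_pvalue` (NA when no outliers),
#'   `estimate_all`, `estimate_outlier_corrected`, `n_sims`, `seed`.
#' @export
mr_presso <- function(set, n_sims = 1000, outlier_alpha = 0.05, seed = 1L,
                      adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  ks <- kept_rows(set)
  n <- nrow(ks)
  if (n < 4L) stopf("MR-PRESSO requires at least 4 instruments (got %d)", n)
  if (n_sims < 100) stopf("n_sims must be at least 100")
  bx <- ks$beta_exposure; sx <- ks$se_exposure
  by <- ks$beta_outcome; sy <- ks$se_outcome
  slopes <- loo_slopes(bx, by, sy)
  expected <- slopes * bx
  res_obs2 <- (by - expected)^2
  rss_obs <- sum(res_obs2)

  with_seed(seed, {
    exceed_global <- 0L
    exceed_snp <- integer(n)
    for (b in seq_len(n_sims)) {
      bxs <- stats::rnorm(n, bx, sx)
      bys <- stats::rnorm(n, expected, sy)
      sl <- loo_slopes(bxs, bys, sy)
      res2 <- (bys - sl * bxs)^2
      rss <- sum(res2)
      if (rss >= rss_obs) exceed_global <- exceed_global + 1L
      exceed_snp <- exceed_snp + (res2 >= res_obs2)
    }
    global_p <- (1 + exceed_global) / (n_sims + 1)
    outlier_p <- (1 + exceed_snp) / (n_sims + 1)
    outlier_adj <- stats::p.adjust(outlier_p, method = adjust)
    outliers <- which(outlier_adj < outlier_alpha)
    if (length(outliers) == n) {
      stopf("every instrument flagged as an outlier; instrument set unusable")
    }
    est_all <- mr_ivw(ks, model = "auto")
    est_corr <- NULL
    distortion_p <- NA_real_
    if (length(outliers) > 0L) {
      est_corr <- mr_ivw(ks[-outliers, , drop = FALSE], model = "auto")
      d_obs <- est_corr$beta - est_all$beta
      d_null <- vapply(seq_len(n_sims), function(b) {
        drop_idx <- sample.int(n, length(outliers))
        pt <- ivw_point(bx[-drop_idx], by[-drop_idx], sy[-drop_idx])
        pt$beta - est_all$beta
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sims + 1)
    }
    structure(list(global_rss_obs = rss_obs, global_pvalue = global_p,
                   outlier_table = data.frame(snp_id = ks$snp_id,
                                              pvalue = outlier_p,
                                              pvalue_adjusted = outlier_adj,
                                              stringsAsFactors = FALSE),
                   outlier_indices = outliers,
                   distortion_pvalue = distortion_p,
                   estimate_all = est_all,
                   estimate_outlier_corrected = est_corr,
                   n_sims = as.integer(n_sims), seed = seed),
              class = "presso_result")
  })
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d simulations, seed %s)\n", x$n_sims,
              format(x$seed)))
  cat(sprintf("  global RSS = %.4g, global p = %.4f\n",
              x$global_rss_obs, x$global_pvalue))
  if (length(x$outlier_indices) == 0L) {
    cat("  no outlier SNPs detected\n")
  } else {
    cat(sprintf("  outlier SNP(s): %s\n",
                paste(x$outlier_table$snp_id[x$outlier_indices],
                      collapse = ", ")))
    cat(sprintf("  distortion test p = %.4f\n", x$distortion_pvalue))
    cat("  outlier-corrected ")
    print(x$estimate_outlier_corrected)
  }
  invisible(x)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio against its precision (1/SE of the ratio), for
#' external plotting; asymmetry suggests directional pleiotropy.
#'
#' @param set A `harmonized_set`.
#' @return A data.frame with `snp_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(set) {
  ks <- kept_rows(set)
  if (nrow(ks) == 0L) {
    return(data.frame(snp_id = character(0), ratio = numeric(0),
                      precision = numeric(0), stringsAsFactors = FALSE))
  }
  se_ratio <- abs(ks$se_outcome / ks$beta_exposure)
  data.frame(snp_id = ks$snp_id,
             ratio = ks$beta_outcome / ks$beta_exposure,
             precision = 1 / se_ratio, stringsAsFactors = FALSE)
}
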