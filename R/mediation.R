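#' Indirect effect by the product of coefficients
#'
#' The indirect (mediated) effect of an exposure on an outcome through a
#' mediator is the product of the exposure-to-mediator effect
#' (\eqn{\theta_3}) and the mediator-to-outcome direct effect
#' (\eqn{\theta_4}). Its standard error comes from the multivariate delta
#' method with zero covariance between the two estimates (they arise from
#' different regressions on two-sample summary data):
#' \deqn{SE = \sqrt{\theta_4^2 SE_3^2 + \theta_3^2 SE_4^2}.}
#' Symmetric in its two (beta, se) argument pairs.
#'
#' @param theta3_beta,theta3_se Exposure-to-mediator effect and SE.
#' @param theta4_beta,theta4_se Mediator-to-outcome direct effect and SE.
#' @param ci_level Confidence level.
#' @return A list with `beta`, `se`, `or`, `or_lower`, `or_upper`,
#'   `pvalue`.
#' @examples
#' indirect_effect(-0.0534, 0.0162, 0.3208, 0.1044)
#' @export
indirect_effect <- function(theta3_beta, theta3_se, theta4_beta, theta4_se,
                            ci_level = 0.95) {
  stopifnot(theta3_se > 0, theta4_se > 0)
  beta <- theta3_beta * theta4_beta
  se <- sqrt(theta4_beta^2 * theta3_se^2 + theta3_beta^2 * theta4_se^2)
  if (se == 0) {
    # both point estimates zero: degenerate product, no sampling scale
    return(list(beta = 0, se = 0, or = 1, or_lower = 1, or_upper = 1,
                pvalue = 1))
  }
  orx <- transform_to_or(beta, se, ci_level)
  list(beta = beta, se = se, or = orx$or, or_lower = orx$or_lower,
       or_upper = orx$or_upper, pvalue = orx$pvalue)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * indirect / total` on the scale of the effects (log-odds for a
#' binary outcome). Warns on inconsistent mediation (opposite signs, or
#' magnitude above 100%), where the proportion is not interpretable as a
#' fraction.
#'
#' @param indirect_beta Indirect effect (product of coefficients).
#' @param total_beta Total effect (nonzero).
#' @return Percentage mediated.
#' @examples
#' proportion_mediated(-0.0171, -0.2871)  # 5.96
#' @export
proportion_mediated <- function(indirect_beta, total_beta) {
  if (total_beta == 0) stopf("total effect is zero; proportion undefined")
  p <- 100 * indirect_beta / total_beta
  if (p < 0) warnf("indirect and total effects have opposite signs (inconsistent mediation)")
  if (p > 100) warnf("indirect effect exceeds the total effect (proportion > 100%%)")
  p
}

# run selection -> clumping -> exclusion on one trait table
select_instruments <- function(table, config, exclude = NULL, ld = NULL) {
  sel <- select_significant(table, config$p_threshold)
  if (nrow(sel) > 0L && !anyNA(sel$chr) && !anyNA(sel$pos)) {
    sel <- clump(sel, ld = ld, r2_threshold = config$clump_r2,
                 window_kb = config$clump_window_kb)
  }
  if (!is.null(exclude)) sel <- apply_exclusion_list(sel, exclude)
  sel
}

#' Stepwise MR mediation analysis
#'
#' Decomposes the causal effect of an exposure X on an outcome Y through
#' one mediator M with the standard four-parameter framework:
#' \itemize{
#'   \item \eqn{\theta_1}: total X to Y effect, univariable IVW;
#'   \item \eqn{\theta_2}: direct X to Y effect, from multivariable MR of
#'     \{X, M\} on Y;
#'   \item \eqn{\theta_3}: X to M effect, univariable IVW;
#'   \item \eqn{\theta_4}: direct M to Y effect, from the same MVMR fit;
#' }
#' the indirect effect is \eqn{\theta_3\theta_4} with a delta-method SE
#' ([indirect_effect()]) and the proportion mediated is
#' \eqn{100\,\theta_3\theta_4/\theta_1} ([proportion_mediated()]).
#' Each leg runs the full instrument pipeline (significance filter,
#' clumping, exclusion list, harmonization). MVMR instruments are the
#' union of the exposure's and mediator's instruments after joint
#' harmonization. An adding-up check
#' \eqn{\theta_1 - (\theta_2 + \theta_3\theta_4)} with a delta-method SE
#' is reported and flagged when |z| > 2 (reported, not enforced).
#'
#' @param exposure,mediator,outcome [trait_table()]s.
#' @param config An [mr_control()] configuration.
#' @param exclude Optional character vector of SNP ids to exclude
#'   (confounder screen).
#' @param ld Optional LD matrix for clumping.
#' @return An object of class `mediation_result` with components `theta1`
#'   to `theta4` (each an `mr_estimate`-like row), `indirect`,
#'   `proportion_mediated`, `adding_up`, `instrument_counts`, `seed`.
#' @export
run_mediation <- function(exposure, mediator, outcome, config = mr_control(),
                          exclude = NULL, ld = NULL) {
  x_iv <- select_instruments(exposure, config, exclude, ld)
  if (nrow(x_iv) < 2L) stopf("exposure leg: too few instruments (%d)", nrow(x_iv))
  m_iv_tab <- select_instruments(mediator, config, exclude, ld)

  # theta1: total effect X -> Y
  h1 <- harmonize(x_iv, outcome,
                  palindrome_eaf_limit = config$palindrome_eaf_limit)
  if (nrow(kept_rows(h1)) < 2L) stopf("exposure-outcome leg: too few instruments after harmonization")
  theta1 <- mr_ivw(h1, model = "auto", ci_level = config$ci_level)

  # theta3: X -> M
  h3 <- harmonize(x_iv, mediator,
                  palindrome_eaf_limit = config$palindrome_eaf_limit)
  if (nrow(kept_rows(h3)) < 2L) stopf("exposure-mediator leg: too few instruments after harmonization")
  theta3 <- mr_ivw(h3, model = "auto", ci_level = config$ci_level)

  # theta2, theta4: MVMR of {X, M} on Y over the union of instruments
  union_ids <- union(x_iv$snp_id, m_iv_tab$snp_id)
  x_union <- exposure[exposure$snp_id %in% union_ids, , drop = FALSE]
  m_union <- mediator[mediator$snp_id %in% union_ids, , drop = FALSE]
  hmv <- harmonize(x_union, outcome, more = list(mediator = m_union),
                   palindrome_eaf_limit = config$palindrome_eaf_limit)
  n_mv <- nrow(kept_rows(hmv))
  if (n_mv < 3L) stopf("multivariable leg: too few instruments (%d)", n_mv)
  mv <- mvmr_ivw(hmv, exposures = c("exposure", "mediator"),
                 ci_level = config$ci_level)
  theta2 <- mv[mv$exposure == "exposure", ]
  theta4 <- mv[mv$exposure == "mediator", ]

  ind <- indirect_effect(theta3$beta, theta3$se, theta4$beta, theta4$se,
                         ci_level = config$ci_level)
  prop <- proportion_mediated(ind$beta, theta1$beta)

  # adding-up: theta1 - (theta2 + theta3*theta4), delta-method SE treating
  # the components as independent
  gap <- theta1$beta - (theta2$beta + ind$beta)
  gap_se <- sqrt(theta1$se^2 + theta2$se^2 + ind$se^2)
  adding_up <- list(gap = gap, se = gap_se, z = gap / gap_se,
                    flagged = abs(gap / gap_se) > 2)

  as_row <- function(e) {
    if (inherits(e, "mr_estimate")) {
      list(beta = e$beta, se = e$se, pvalue = e$pvalue, or = e$or,
           or_lower = e$or_lower, or_upper = e$or_upper, n_snp = e$n_snp)
    } else {
      list(beta = e$beta, se = e$se, pvalue = e$pvalue, or = e$or,
           or_lower = e$or_lower, or_upper = e$or_upper,
           n_snp = attr(mv, "n_snp"))
    }
  }
  structure(list(theta1 = as_row(theta1), theta2 = as_row(theta2),
                 theta3 = as_row(theta3), theta4 = as_row(theta4),
                 indirect = ind, proportion_mediated = prop,
                 adding_up = adding_up,
                 instrument_counts = c(exposure = nrow(x_iv),
                                       mediator = nrow(m_iv_tab),
                                       theta1 = theta1$n_snp,
                                       theta3 = theta3$n_snp,
                                       mvmr = attr(mv, "n_snp")),
                 conditional_f = stats::setNames(mv$conditional_f, mv$exposure),
                 seed = config$seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Stepwise MR mediation analysis\n")
  rows <- list("theta1 (total X->Y)" = x$theta1,
               "theta2 (direct X->Y)" = x$theta2,
               "theta3 (X->M)" = x$theta3,
               "theta4 (direct M->Y)" = x$theta4,
               "indirect (t3*t4)" = x$indirect)
  for (nm in names(rows)) {
    r <- rows[[nm]]
    cat(sprintf("  %-22s beta %s  SE %s  OR %s (%s-%s)  p %s\n", nm,
                fmt_num(r$beta, 4), fmt_num(r$se, 4), fmt_num(r$or, 3),
                fmt_num(r$or_lower, 3), fmt_num(r$or_upper, 3),
                format.pval(r$pvalue, digits = 3)))
  }
  cat(sprintf("  proportion mediated: %.2f%%\n", x$proportion_mediated))
  cat(sprintf("  adding-up gap: %.4f (z = %.2f)%s\n", x$adding_up$gap,
              x$adding_up$z, if (x$adding_up$flagged) " [flagged]" else ""))
  invisible(x)
}
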