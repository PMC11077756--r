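#' Convert a log-scale effect to an odds ratio with confidence interval
#'
#' Exponentiates the effect and its Wald interval
#' \eqn{\exp(\beta \mp z \cdot SE)} at the requested level, with a
#' two-sided normal p-value for \eqn{\beta/SE}.
#'
#' @param beta Log-scale effect (log-odds for binary outcomes).
#' @param se Standard error (> 0).
#' @param ci_level Confidence level, default 0.95.
#' @return A list with `or`, `or_lower`, `or_upper`, `pvalue`.
#' @examples
#' transform_to_or(-0.2871, 0.1253)  # OR 0.750 (0.587-0.959), p 0.022
#' @export
transform_to_or <- function(beta, se, ci_level = 0.95) {
  stopifnot(all(se > 0), ci_level > 0, ci_level < 1)
  z <- stats::qnorm((1 + ci_level) / 2)
  list(or = exp(beta),
       or_lower = exp(beta - z * se),
       or_upper = exp(beta + z * se),
       pvalue = z_pvalue(beta / se))
}

#' Upper-tail chi-square probability
#'
#' Convenience wrapper used for heterogeneity tests:
#' `P(X >= q)` for `X ~ chi-square(df)`.
#'
#' @param q Observed statistic.
#' @param df Degrees of freedom.
#' @return Upper-tail probability.
#' @export
chisq_tail_p <- function(q, df) stats::pchisq(q, df, lower.tail = FALSE)

# constructor for a single causal-effect estimate
new_mr_estimate <- function(method, beta, se, n_snp, ci_level = 0.95,
                            seed = NULL) {
  if (!is.na(se) && se <= 0) stopf("standard error must be positive")
  if (is.na(se)) {
    orx <- list(or = exp(beta), or_lower = NA_real_, or_upper = NA_real_,
                pvalue = NA_real_)
  } else {
    orx <- transform_to_or(beta, se, ci_level)
  }
  structure(list(method = method, beta = beta, se = se,
                 pvalue = orx$pvalue, n_snp = as.integer(n_snp),
                 or = orx$or, or_lower = orx$or_lower,
                 or_upper = orx$or_upper, ci_level = ci_level, seed = seed),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%-16s beta = %s (SE %s), OR = %s (%s-%s), p = %s, nSNP = %d\n",
              x$method, fmt_num(x$beta, 4),
              if (is.na(x$se)) "NA" else fmt_num(x$se, 4),
              fmt_num(x$or, 3),
              if (is.na(x$or_lower)) "NA" else fmt_num(x$or_lower, 3),
              if (is.na(x$or_upper)) "NA" else fmt_num(x$or_upper, 3),
              if (is.na(x$pvalue)) "NA" else format.pval(x$pvalue, digits = 3),
              x$n_snp))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  c(beta = object$beta, se = object$se)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect,
#' \eqn{\hat\theta = \beta_Y/\beta_X}. The default standard error is the
#' first-order approximation \eqn{|\sigma_Y/\beta_X|}; with
#' `second_order = TRUE` the term \eqn{\beta_Y^2\sigma_X^2/\beta_X^4} is
#' added under the square root.
#'
#' @param beta_x,se_x Exposure effect and SE (`beta_x` must be nonzero).
#' @param beta_y,se_y Outcome effect and SE.
#' @param second_order Include the exposure-uncertainty term in the SE.
#' @param ci_level Confidence level.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE,
                       ci_level = 0.95) {
  if (beta_x == 0) stopf("wald_ratio undefined for beta_x = 0")
  beta <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    abs(se_y / beta_x)
  }
  new_mr_estimate("wald_ratio", beta, se, 1L, ci_level)
}

# shared ingredients of the ratio-based estimators
ratio_components <- function(set) {
  ks <- kept_rows(set)
  if (nrow(ks) == 0L) stopf("no usable instruments in the harmonized set")
  if (any(ks$beta_exposure == 0)) {
    stopf("instrument(s) with zero exposure effect; remove before estimation")
  }
  list(bx = ks$beta_exposure, sx = ks$se_exposure,
       by = ks$beta_outcome, sy = ks$se_outcome,
       ratio = ks$beta_outcome / ks$beta_exposure,
       w = ks$beta_exposure^2 / ks$se_outcome^2,
       snp_id = ks$snp_id, n = nrow(ks))
}

ivw_point <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  r <- by / bx
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  list(beta = beta, se_fixed = sqrt(1 / sum(w)), q = q)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' The weighted average of per-SNP Wald ratios with weights
#' \eqn{w_j = \beta_{Xj}^2/\sigma_{Yj}^2} (equivalently, weighted
#' least squares of outcome on exposure effects through the origin).
#' Under `model = "auto"` the fixed-effect variant is used when Cochran's
#' Q heterogeneity test has p >= `q_alpha` and the multiplicative
#' random-effects variant (SE inflated by
#' \eqn{\sqrt{\max(1, Q/(J-1))}}) otherwise.
#'
#' @param set A `harmonized_set`.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param ci_level Confidence level.
#' @param q_alpha Heterogeneity-test threshold for `"auto"` (default 0.05).
#' @return An `mr_estimate` with method `"ivw_fixed"` or `"ivw_random"`
#'   and attributes `q`, `q_df`, `q_pvalue`.
#' @export
mr_ivw <- function(set, model = c("auto", "fixed", "random"),
                   ci_level = 0.95, q_alpha = 0.05) {
  model <- match.arg(model)
  rc <- ratio_components(set)
  pt <- ivw_point(rc$bx, rc$by, rc$sy)
  q_df <- rc$n - 1L
  q_p <- if (q_df >= 1L) chisq_tail_p(pt$q, q_df) else NA_real_
  if (model == "auto") {
    model <- if (!is.na(q_p) && q_p < q_alpha) "random" else "fixed"
  }
  se <- if (model == "random" && q_df >= 1L) {
    pt$se_fixed * sqrt(max(1, pt$q / q_df))
  } else {
    pt$se_fixed
  }
  est <- new_mr_estimate(paste0("ivw_", model), pt$beta, se, rc$n, ci_level)
  attr(est, "q") <- pt$q
  attr(est, "q_df") <- q_df
  attr(est, "q_pvalue") <- q_p
  est
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2} over the
#' per-SNP Wald ratios with IVW weights; referred to a chi-square with
#' `n_snp - 1` degrees of freedom.
#'
#' @param set A `harmonized_set` with at least 2 usable instruments.
#' @return A list of class `heterogeneity_result` with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(set) {
  rc <- ratio_components(set)
  if (rc$n < 2L) stopf("Cochran's Q requires at least 2 instruments")
  pt <- ivw_point(rc$bx, rc$by, rc$sy)
  structure(list(q = pt$q, df = rc$n - 1L,
                 pvalue = chisq_tail_p(pt$q, rc$n - 1L)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f, df = %d, p = %.3f\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights \eqn{1/\sigma_{Yj}^2}, after orienting every
#' instrument to a non-negative exposure effect. The intercept estimates
#' the average directional pleiotropy (its test is the pleiotropy test);
#' the slope is the causal estimate under the InSIDE assumption. Standard
#' errors use a multiplicative overdispersion scale floored at 1.
#'
#' @param set A `harmonized_set` with at least 3 usable instruments.
#' @param ci_level Confidence level.
#' @return A list of class `mr_egger` with elements `slope` and
#'   `intercept` (both `mr_estimate`s) and the overdispersion `scale`.
#' @export
mr_egger <- function(set, ci_level = 0.95) {
  rc <- ratio_components(set)
  if (rc$n < 3L) stopf("MR-Egger requires at least 3 instruments (got %d)", rc$n)
  sgn <- ifelse(rc$bx < 0, -1, 1)
  bx <- rc$bx * sgn
  by <- rc$by * sgn
  w <- 1 / rc$sy^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coefs
  rss_w <- sum(w * resid^2)
  scale <- max(1, rss_w / (rc$n - 2))
  vc <- scale * solve(xtwx)
  slope <- new_mr_estimate("egger_slope", unname(coefs["slope", 1]),
                           sqrt(vc["slope", "slope"]), rc$n, ci_level)
  intercept <- new_mr_estimate("egger_intercept",
                               unname(coefs["intercept", 1]),
                               sqrt(vc["intercept", "intercept"]), rc$n,
                               ci_level)
  structure(list(slope = slope, intercept = intercept, scale = scale),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression\n")
  print(x$slope)
  print(x$intercept)
  invisible(x)
}

# weighted-percentile interpolation at cumulative weight 0.5 over sorted
# ratio estimates; w need not be normalized
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord] / sum(w[ord])
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_draws <- function(rc, reps, seed, point_fun) {
  with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      bx <- stats::rnorm(rc$n, rc$bx, rc$sx)
      by <- stats::rnorm(rc$n, rc$by, rc$sy)
      point_fun(bx, by)
    }, numeric(1))
  })
}

#' Weighted or simple median estimate
#'
#' The weighted median of the per-SNP Wald ratios: consistent when
#' instruments contributing at least half the weight are valid. The
#' estimate interpolates the sorted ratios at standardized cumulative
#' weight 0.5; with `weights = "equal"` this is the simple median. The
#' standard error comes from a seeded parametric bootstrap resampling
#' \eqn{\beta_{Xj}, \beta_{Yj}} from normal distributions at their
#' observed values and SEs (`reps = 0` skips the bootstrap and returns
#' `NA` SE/p; `0 < reps < 100` warns).
#'
#' @param set A `harmonized_set` with at least 3 usable instruments.
#' @param weights `"inverse_variance"` (IVW weights) or `"equal"`.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param ci_level Confidence level.
#' @return An `mr_estimate` with method `"weighted_median"` or
#'   `"simple_median"`.
#' @export
mr_weighted_median <- function(set, weights = c("inverse_variance", "equal"),
                               reps = 1000, seed = 1L, ci_level = 0.95) {
  weights <- match.arg(weights)
  rc <- ratio_components(set)
  if (rc$n < 3L) stopf("median estimators require at least 3 instruments (got %d)", rc$n)
  if (reps > 0 && reps < 100) warnf("bootstrap reps < 100; standard error will be unstable")
  wt <- function(bx, sy) if (weights == "equal") rep(1, length(bx)) else bx^2 / sy^2
  beta <- weighted_median_point(rc$ratio, wt(rc$bx, rc$sy))
  se <- NA_real_
  if (reps > 0) {
    draws <- boot_draws(rc, reps, seed, function(bx, by) {
      weighted_median_point(by / bx, wt(bx, rc$sy))
    })
    se <- stats::sd(draws)
  }
  method <- if (weights == "equal") "simple_median" else "weighted_median"
  new_mr_estimate(method, beta, se, rc$n, ci_level,
                  seed = if (reps > 0) seed else NULL)
}

# weighted normal-kernel density argmax over a dense grid
mode_point <- function(ratio, w, phi, grid_n = 512L) {
  w <- w / sum(w)
  s <- stats::sd(ratio)
  m <- stats::mad(ratio)  # default constant 1.4826 = 1/0.6745
  h <- phi * 0.9 * min(s, m) * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(list(beta = ratio[1], h = 0))
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / h)) # / h omitted: argmax-invariant
  list(beta = grid[which.max(dens)], h = h)
}

#' Weighted mode estimate
#'
#' Clusters the per-SNP Wald ratios by a weighted normal-kernel density
#' and takes the density argmax: consistent when the largest group of
#' instruments sharing a causal estimate is valid (zero modal pleiotropy).
#' Bandwidth is `phi * 0.9 * min(sd, MAD) * n^(-1/5)` over the ratios
#' (MAD scaled to the normal); the density is maximized over a 512-point
#' grid spanning the ratios plus three bandwidths. SE by seeded parametric
#' bootstrap as in [mr_weighted_median()]. If all ratios coincide the
#' common ratio is returned without a density step.
#'
#' @param set A `harmonized_set` with at least 3 usable instruments.
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param reps Bootstrap replicates.
#' @param seed Integer seed.
#' @param ci_level Confidence level.
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(set, phi = 1, reps = 1000, seed = 1L,
                             ci_level = 0.95) {
  stopifnot(phi > 0)
  rc <- ratio_components(set)
  if (rc$n < 3L) stopf("weighted mode requires at least 3 instruments (got %d)", rc$n)
  if (reps > 0 && reps < 100) warnf("bootstrap reps < 100; standard error will be unstable")
  mp <- mode_point(rc$ratio, rc$w, phi)
  se <- NA_real_
  if (reps > 0) {
    draws <- boot_draws(rc, reps, seed, function(bx, by) {
      mode_point(by / bx, bx^2 / rc$sy^2, phi)$beta
    })
    se <- stats::sd(draws)
  }
  est <- new_mr_estimate("weighted_mode", mp$beta, se, rc$n, ci_level,
                         seed = if (reps > 0) seed else NULL)
  attr(est, "bandwidth") <- mp$h
  est
}

#' Fit the standard suite of univariable MR estimators
#'
#' Front end running IVW (auto fixed/random on Cochran's Q), MR-Egger,
#' weighted median, simple median and weighted mode on one harmonized set,
#' the estimator panel conventionally reported for a two-sample MR
#' analysis. Methods whose instrument minimum is not met are skipped with
#' a notice.
#'
#' @param set A `harmonized_set`.
#' @param methods Character vector from `c("ivw", "egger",
#'   "weighted_median", "simple_median", "weighted_mode")`.
#' @param model IVW model selection, see [mr_ivw()].
#' @param reps Bootstrap replicates for median/mode SEs.
#' @param seed Integer seed.
#' @param ci_level Confidence level.
#' @return An object of class `mr_result`: list of `mr_estimate`s plus the
#'   heterogeneity test and Egger intercept; has `print`, `summary` and
#'   `as.data.frame` methods.
#' @export
mr_fit <- function(set, methods = c("ivw", "egger", "weighted_median",
                                    "simple_median", "weighted_mode"),
                   model = "auto", reps = 1000, seed = 1L, ci_level = 0.95) {
  methods <- match.arg(methods, several.ok = TRUE)
  rc <- ratio_components(set)
  ests <- list()
  notes <- character(0)
  het <- if (rc$n >= 2L) cochran_q(set) else NULL
  egger_fit <- NULL
  for (m in methods) {
    need <- c(ivw = 1L, egger = 3L, weighted_median = 3L, simple_median = 3L,
              weighted_mode = 3L)[[m]]
    if (rc$n < need) {
      notes <- c(notes, sprintf("%s skipped: needs >= %d instruments, have %d",
                                m, need, rc$n))
      next
    }
    ests[[m]] <- switch(m,
      ivw = mr_ivw(set, model = model, ci_level = ci_level),
      egger = {
        egger_fit <- mr_egger(set, ci_level = ci_level)
        egger_fit$slope
      },
      weighted_median = mr_weighted_median(set, "inverse_variance",
                                           reps = reps, seed = seed,
                                           ci_level = ci_level),
      simple_median = mr_weighted_median(set, "equal", reps = reps,
                                         seed = seed, ci_level = ci_level),
      weighted_mode = mr_weighted_mode(set, reps = reps, seed = seed,
                                       ci_level = ci_level))
  }
  structure(list(estimates = ests, heterogeneity = het,
                 egger_intercept = if (!is.null(egger_fit)) egger_fit$intercept,
                 notes = notes, n_snp = rc$n, seed = seed,
                 exposure = attr(set, "exposure_name"),
                 outcome = attr(set, "outcome_name")),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n",
              x$exposure %||% "exposure", x$outcome %||% "outcome", x$n_snp))
  for (e in x$estimates) print(e)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept p = %.3f (pleiotropy test)\n",
                x$egger_intercept$pvalue))
  }
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' @export
summary.mr_result <- function(object, ...) as.data.frame(object)

#' @export
as.data.frame.mr_result <- function(x, ...) {
  rows <- lapply(x$estimates, function(e) {
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               pvalue = e$pvalue, or = e$or, or_lower = e$or_lower,
               or_upper = e$or_upper, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.mr_result <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}
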