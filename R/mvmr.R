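# extract the exposure-beta matrix (and SE matrix) from a harmonized set
# with one or more exposure columns
mvmr_matrices <- function(set, exposures = NULL) {
  ks <- kept_rows(set)
  extra <- attr(set, "extra_names") %||% character(0)
  if (is.null(exposures)) {
    exposures <- c(attr(set, "exposure_name") %||% "exposure", extra)
  }
  bcols <- scols <- character(length(exposures))
  for (i in seq_along(exposures)) {
    e <- exposures[i]
    bc <- if (paste0("beta_", e) %in% names(ks)) paste0("beta_", e) else "beta_exposure"
    sc <- if (paste0("se_", e) %in% names(ks)) paste0("se_", e) else "se_exposure"
    if (i > 1L && bc == "beta_exposure") {
      stopf("no beta column found for exposure '%s'", e)
    }
    bcols[i] <- bc; scols[i] <- sc
  }
  X <- as.matrix(ks[, bcols, drop = FALSE])
  SX <- as.matrix(ks[, scols, drop = FALSE])
  colnames(X) <- colnames(SX) <- exposures
  list(X = X, SX = SX, y = ks$beta_outcome, sy = ks$se_outcome,
       snp_id = ks$snp_id, exposures = exposures)
}

#' Multivariable MR (IVW-style weighted regression)
#'
#' Estimates the direct effect of each of K exposures on the outcome by
#' weighted least squares of the outcome effects on the K exposure-effect
#' columns, no intercept, weights \eqn{1/\sigma_{Yj}^2}. Standard errors
#' use the WLS covariance with multiplicative overdispersion
#' \eqn{\max(1, Q/(J-K))}, Q the weighted residual sum of squares.
#' Conditional F statistics (instrument strength of each exposure given
#' the others) are attached via [conditional_f()].
#'
#' Exposure columns with all-zero effects are dropped from the fit with a
#' warning (their coefficient is reported as `NA`); near-collinear
#' exposure pairs raise an error naming the pair.
#'
#' @param set A `harmonized_set` whose extra tables are the additional
#'   exposures (see [harmonize()]'s `more` argument).
#' @param exposures Optional character vector naming/ordering the exposure
#'   columns (defaults to the primary exposure plus all extras).
#' @param ci_level Confidence level.
#' @param kappa_max Condition-number threshold for the collinearity error.
#' @return An object of class `mvmr_result`: data.frame with one row per
#'   exposure (`exposure`, `beta`, `se`, `pvalue`, `or`, `or_lower`,
#'   `or_upper`, `conditional_f`) plus attributes `n_snp`, `df`, `q`,
#'   `q_pvalue`.
#' @export
mvmr_ivw <- function(set, exposures = NULL, ci_level = 0.95,
                     kappa_max = 1e8) {
  mm <- mvmr_matrices(set, exposures)
  X <- mm$X; y <- mm$y; w <- 1 / mm$sy^2
  n <- nrow(X); K <- ncol(X)
  if (n <= K) stopf("MVMR needs more instruments (%d) than exposures (%d)", n, K)
  zero_col <- apply(X, 2, function(col) all(col == 0))
  if (any(zero_col)) {
    warnf("exposure(s) with all-zero effects dropped from the fit: %s",
          paste(colnames(X)[zero_col], collapse = ", "))
  }
  fit_cols <- which(!zero_col)
  Xf <- X[, fit_cols, drop = FALSE]
  Xw <- sqrt(w) * Xf
  if (ncol(Xf) > 1L) {
    kap <- kappa(Xw, exact = TRUE)
    if (!is.finite(kap) || kap > kappa_max) {
      cors <- abs(stats::cor(Xf))
      diag(cors) <- 0
      worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
      stopf("collinear exposure effects: '%s' vs '%s' (condition number %.3g)",
            colnames(Xf)[worst[1]], colnames(Xf)[worst[2]], kap)
    }
  }
  xtwx <- crossprod(Xf, w * Xf)
  coefs <- solve(xtwx, crossprod(Xf, w * y))[, 1]
  resid <- y - Xf %*% coefs
  q <- sum(w * resid^2)
  df <- n - ncol(Xf)
  scale <- max(1, q / df)
  ses <- sqrt(scale * diag(solve(xtwx)))
  beta <- se <- rep(NA_real_, K)
  beta[fit_cols] <- coefs
  se[fit_cols] <- ses
  orx <- transform_to_or(ifelse(is.na(beta), 0, beta),
                         ifelse(is.na(se), 1, se), ci_level)
  cf <- conditional_f(set, exposures = mm$exposures)
  out <- data.frame(exposure = colnames(X), beta = beta, se = se,
                    pvalue = ifelse(is.na(se), NA, orx$pvalue),
                    or = ifelse(is.na(beta), NA, orx$or),
                    or_lower = ifelse(is.na(se), NA, orx$or_lower),
                    or_upper = ifelse(is.na(se), NA, orx$or_upper),
                    conditional_f = cf, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_snp = n, df = df, q = q,
            q_pvalue = chisq_tail_p(q, df), ci_level = ci_level,
            class = c("mvmr_result", "data.frame"))
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR: %d instruments, %d exposure(s); Q = %.2f (p = %.3f)\n",
              attr(x, "n_snp"), nrow(x), attr(x, "q"), attr(x, "q_pvalue")))
  df <- as.data.frame(x)
  df$beta <- round(df$beta, 4); df$se <- round(df$se, 4)
  df$or <- round(df$or, 3); df$or_lower <- round(df$or_lower, 3)
  df$or_upper <- round(df$or_upper, 3)
  df$pvalue <- signif(df$pvalue, 3)
  df$conditional_f <- round(df$conditional_f, 1)
  print.data.frame(df)
  invisible(x)
}

#' @export
coef.mvmr_result <- function(object, ...) {
  stats::setNames(object$beta, object$exposure)
}

#' Conditional F statistics for MVMR instrument strength
#'
#' Measures how much instrument signal each exposure retains after
#' conditioning on the other exposures. For exposure k the other
#' exposures' effect columns are regressed out of \eqn{\beta_{Xk}}
#' (weighted no-intercept regression, weights
#' \eqn{1/\sigma_{Xkj}^2}), the residual Q statistic
#' \eqn{Q_{xk} = \sum_j r_{jk}^2/\sigma_{Xkj}^2} is formed, and
#' \eqn{F_k = Q_{xk}/(J - K + 1)}. With a single exposure this reduces to
#' the mean univariable F statistic \eqn{(\beta/\sigma)^2}. Measurement
#' error is assumed independent across exposures (separate GWAS samples).
#'
#' @inheritParams mvmr_ivw
#' @return Named numeric vector of per-exposure conditional F statistics.
#' @export
conditional_f <- function(set, exposures = NULL) {
  mm <- mvmr_matrices(set, exposures)
  X <- mm$X; SX <- mm$SX
  n <- nrow(X); K <- ncol(X)
  if (n <= K) stopf("conditional F needs more instruments (%d) than exposures (%d)", n, K)
  out <- numeric(K)
  for (k in seq_len(K)) {
    wk <- 1 / SX[, k]^2
    if (K == 1L) {
      resid <- X[, k]
    } else {
      Z <- X[, -k, drop = FALSE]
      ok <- apply(Z, 2, function(col) any(col != 0))
      Z <- Z[, ok, drop = FALSE]
      if (ncol(Z) == 0L) {
        resid <- X[, k]
      } else {
        ztwz <- crossprod(Z, wk * Z)
        gam <- tryCatch(solve(ztwz, crossprod(Z, wk * X[, k])),
                        error = function(e) NULL)
        resid <- if (is.null(gam)) X[, k] else X[, k] - Z %*% gam
      }
    }
    qk <- sum(wk * resid^2)
    out[k] <- qk / (n - K + 1)
  }
  stats::setNames(out, colnames(X))
}
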