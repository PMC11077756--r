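# Builders used across the test files. Fixtures are constructed in code;
# nothing is read from disk unless a test writes it first.

# minimal harmonized set straight from effect vectors (all rows usable)
make_hset <- function(bx, sx, by, sy, eaf = NULL, ids = NULL,
                      extra = list()) {
  n <- length(bx)
  df <- data.frame(
    snp_id = ids %||% sprintf("rs%03d", seq_len(n)),
    chr = "1", pos = seq_len(n) * 1000000L,
    eaf = eaf %||% rep(NA_real_, n),
    beta_exposure = bx, se_exposure = sx,
    pvalue_exposure = NA_real_, n_exposure = NA_real_,
    beta_outcome = by, se_outcome = sy,
    stringsAsFactors = FALSE)
  for (nm in names(extra)) {
    df[[paste0("beta_", nm)]] <- extra[[nm]]$beta
    df[[paste0("se_", nm)]] <- extra[[nm]]$se
  }
  df$status <- "kept"
  df$flipped <- FALSE
  structure(df, exposure_name = "exposure", outcome_name = "outcome",
            extra_names = names(extra),
            class = c("harmonized_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small canonical trait table
make_trait <- function(n = 5, beta = NULL, se = NULL, pvalue = NULL,
                       eaf = NULL, name = "trait", chr = NULL, pos = NULL,
                       ea = NULL, oa = NULL, ids = NULL) {
  trait_table(data.frame(
    snp_id = ids %||% sprintf("rs%03d", seq_len(n)),
    chr = chr %||% rep("1", n),
    pos = pos %||% (seq_len(n) * 1000000L),
    effect_allele = ea %||% rep("A", n),
    other_allele = oa %||% rep("G", n),
    eaf = eaf %||% stats::runif(n, 0.1, 0.4),
    beta = beta %||% stats::rnorm(n, 0, 0.1),
    se = se %||% rep(0.01, n),
    pvalue = pvalue %||% rep(1e-10, n),
    n = 100000, stringsAsFactors = FALSE), trait_name = name)
}

# independent direct-summation IVW oracle (fixed-effect)
oracle_ivw <- function(bx, by, sy) {
  num <- 0; den <- 0
  for (j in seq_along(bx)) {
    w <- bx[j]^2 / sy[j]^2
    num <- num + w * (by[j] / bx[j])
    den <- den + w
  }
  list(beta = num / den, se = sqrt(1 / den))
}

# independent weighted-median oracle: manual cumulative-weight trace
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  w <- w / sum(w)
  s <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  below <- which(s < 0.5)
  k <- below[length(below)]
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}
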