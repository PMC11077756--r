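#' Configuration for the synthetic summary-statistics generator
#'
#' Describes a two-sample MR data-generating process on the summary-
#' statistic scale: per-SNP true exposure effects
#' \eqn{\gamma_j \sim N(0, \gamma_{sd}^2)}, GWAS sampling errors following
#' the \eqn{1/\sqrt{2 n f(1-f)}} law, an optional horizontal-pleiotropy
#' mixture (balanced when `pleio_mean = 0`, directional otherwise, drawn
#' independently of \eqn{\gamma} so InSIDE holds), and an optional
#' mediation triangle X -> M -> Y with a direct X -> Y path. The defaults
#' emulate a large vitamin-D-style exposure GWAS (143 discovered loci,
#' n = 417,580) against a biobank disease outcome (n = 233,397) with a
#' hormone mediator (n = 190,000). `gamma_sd = 0.05` makes the default
#' locus panel explain roughly 13% of exposure variance — the scale of
#' SNP-heritability captured by discovered loci for such traits — while
#' keeping selected instruments strong (typical F in the tens to
#' hundreds); `gamma_m_sd = 0.05` gives the mediator its own independent
#' genetic effects so that multivariable MR is identified.
#'
#' @param n_snps Number of SNPs to generate.
#' @param theta True causal effect of exposure on outcome (log-odds for a
#'   binary outcome). Ignored when `mediation` is supplied.
#' @param mediation Optional named numeric vector
#'   `c(theta_direct=, theta_xm=, theta_my=)`: direct X->Y, X->M and
#'   M->Y effects; the implied total effect is
#'   `theta_direct + theta_xm*theta_my`.
#' @param gamma_sd SD of true per-SNP exposure effects.
#' @param gamma_m_sd SD of true per-SNP mediator-specific effects
#'   (mediation only).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param n_x,n_y,n_m Exposure / outcome / mediator GWAS sample sizes (an
#'   effective-n approximation is used for binary outcomes).
#' @param pleio_prob Fraction of SNPs with a horizontal-pleiotropy effect.
#' @param pleio_mean,pleio_sd Pleiotropy distribution (mean 0 = balanced).
#' @param palindrome_prob Fraction of SNPs assigned palindromic (A/T)
#'   alleles, to exercise harmonization drops (default 0).
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 143, theta = -0.287, mediation = NULL,
                       gamma_sd = 0.05, gamma_m_sd = 0.05,
                       maf_range = c(0.05, 0.5),
                       n_x = 417580, n_y = 233397, n_m = 190000,
                       pleio_prob = 0, pleio_mean = 0, pleio_sd = 0,
                       palindrome_prob = 0, seed = 1L) {
  stopifnot(n_snps >= 1, gamma_sd >= 0, gamma_m_sd >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_x > 2, n_y > 2, n_m > 2,
            pleio_prob >= 0, pleio_prob <= 1, pleio_sd >= 0,
            palindrome_prob >= 0, palindrome_prob <= 1)
  if (!is.null(mediation)) {
    need <- c("theta_direct", "theta_xm", "theta_my")
    if (!all(need %in% names(mediation))) {
      stopf("mediation must be a named vector with %s", paste(need, collapse = ", "))
    }
  }
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 mediation = mediation, gamma_sd = gamma_sd,
                 gamma_m_sd = gamma_m_sd, maf_range = maf_range,
                 n_x = n_x, n_y = n_y, n_m = n_m,
                 pleio_prob = pleio_prob, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, palindrome_prob = palindrome_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# shared scaffolding: ids, positions (spaced beyond any clumping window),
# alleles, frequencies, sampling SDs
sim_scaffold <- function(config) {
  n <- config$n_snps
  snp_id <- sprintf("rs%05d", seq_len(n))
  chr <- as.character(rep_len(1:22, n))
  pos <- 1000000L + 20000000L * (seq_len(n) %/% 22L)
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  pal <- stats::runif(n) < config$palindrome_prob
  ea <- rep("A", n)
  oa <- ifelse(pal, "T", "G")
  list(snp_id = snp_id, chr = chr, pos = pos, maf = maf,
       effect_allele = ea, other_allele = oa,
       se_of = function(n_gwas) 1 / sqrt(2 * n_gwas * maf * (1 - maf)))
}

sim_trait <- function(sc, true_beta, n_gwas, name,
                      type = "continuous") {
  se <- sc$se_of(n_gwas)
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  p <- z_pvalue(beta / se)
  trait_table(data.frame(snp_id = sc$snp_id, chr = sc$chr, pos = sc$pos,
                         effect_allele = sc$effect_allele,
                         other_allele = sc$other_allele,
                         eaf = sc$maf, beta = beta, se = se, pvalue = p,
                         n = n_gwas, stringsAsFactors = FALSE),
              trait_name = name, trait_type = type)
}

draw_pleiotropy <- function(config, n) {
  alpha <- numeric(n)
  hit <- stats::runif(n) < config$pleio_prob
  alpha[hit] <- stats::rnorm(sum(hit), config$pleio_mean, config$pleio_sd)
  alpha
}

#' Simulate a univariable two-sample MR dataset
#'
#' Generates exposure and outcome summary statistics under the model
#' \eqn{\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)},
#' \eqn{\beta_{Yj} \sim N(\theta\gamma_j + sign(\gamma_j)\alpha_j,
#' \sigma_{Yj}^2)} with \eqn{\sigma = 1/\sqrt{2 n f(1-f)}} and
#' \eqn{\alpha_j} the pleiotropy draw (zero with probability
#' `1 - pleio_prob`). The pleiotropic shift is applied in the frame of the
#' exposure-increasing allele (hence the \eqn{sign(\gamma_j)} factor):
#' allele labels are arbitrary, so "directional" pleiotropy is only
#' meaningful relative to that orientation, which is also the frame in
#' which the Egger intercept estimates the mean pleiotropic effect.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `exposure` and `outcome` [trait_table()]s and
#'   `truth` (gamma, alpha, theta, maf, seed, config).
#' @export
simulate_uvmr <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sc <- sim_scaffold(config)
    gamma <- stats::rnorm(config$n_snps, 0, config$gamma_sd)
    alpha <- draw_pleiotropy(config, config$n_snps)
    exposure <- sim_trait(sc, gamma, config$n_x, "exposure")
    outcome <- sim_trait(sc, config$theta * gamma + sign(gamma) * alpha,
                         config$n_y, "outcome", type = "binary")
    list(exposure = exposure, outcome = outcome,
         truth = list(gamma = gamma, alpha = alpha, theta = config$theta,
                      maf = sc$maf, seed = config$seed, config = config))
  })
}

#' Simulate a two-sample MR mediation dataset
#'
#' Generates exposure, mediator and outcome summary statistics under the
#' triangle \eqn{\beta_{Mj} \sim N(\theta_{xm}\gamma_j + \gamma_{Mj},
#' \sigma_{Mj}^2)} and \eqn{\beta_{Yj} \sim N(\theta_{direct}\gamma_j +
#' \theta_{my}(\theta_{xm}\gamma_j + \gamma_{Mj}) + \alpha_j,
#' \sigma_{Yj}^2)}, where \eqn{\gamma_{Mj} \sim N(0, \gamma_{m,sd}^2)} are
#' mediator-specific genetic effects independent of \eqn{\gamma_j} (these
#' give the mediator its own instruments, without which the multivariable
#' step would be unidentified). The truth record carries the implied total
#' effect `theta_direct + theta_xm*theta_my`, the indirect effect
#' `theta_xm*theta_my` and the proportion mediated.
#'
#' @param config A [sim_config()] with `mediation` set.
#' @return A list with `exposure`, `mediator`, `outcome` trait tables and
#'   `truth`.
#' @export
simulate_mediation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$mediation)) stopf("config$mediation must be set")
  md <- config$mediation
  with_seed(config$seed, {
    sc <- sim_scaffold(config)
    gamma <- stats::rnorm(config$n_snps, 0, config$gamma_sd)
    gamma_m <- stats::rnorm(config$n_snps, 0, config$gamma_m_sd)
    alpha <- draw_pleiotropy(config, config$n_snps)
    true_m <- md[["theta_xm"]] * gamma + gamma_m
    true_y <- md[["theta_direct"]] * gamma + md[["theta_my"]] * true_m +
      sign(gamma) * alpha
    exposure <- sim_trait(sc, gamma, config$n_x, "exposure")
    mediator <- sim_trait(sc, true_m, config$n_m, "mediator")
    outcome <- sim_trait(sc, true_y, config$n_y, "outcome", type = "binary")
    total <- md[["theta_direct"]] + md[["theta_xm"]] * md[["theta_my"]]
    indirect <- md[["theta_xm"]] * md[["theta_my"]]
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = list(gamma = gamma, gamma_m = gamma_m, alpha = alpha,
                      theta_direct = md[["theta_direct"]],
                      theta_xm = md[["theta_xm"]],
                      theta_my = md[["theta_my"]],
                      theta_total = total, indirect = indirect,
                      proportion_mediated = 100 * indirect / total,
                      maf = sc$maf, seed = config$seed, config = config))
  })
}

#' Inject outlier instruments into a harmonized set
#'
#' Shifts the outcome effect of the chosen instruments by
#' `magnitude_sd` outcome standard errors, emulating horizontally
#' pleiotropic outliers for exercising MR-PRESSO.
#'
#' @param set A `harmonized_set`.
#' @param indices Row indices (into the usable rows) to perturb.
#' @param magnitude_sd Shift size in units of each SNP's outcome SE.
#' @return The modified `harmonized_set` with attribute `outlier_truth`.
#' @export
inject_outliers <- function(set, indices, magnitude_sd) {
  ks_idx <- which(set$status %in% c("kept", "flipped"))
  if (any(indices < 1 | indices > length(ks_idx))) {
    stopf("outlier index out of range (1..%d)", length(ks_idx))
  }
  rows <- ks_idx[indices]
  set$beta_outcome[rows] <- set$beta_outcome[rows] +
    magnitude_sd * set$se_outcome[rows]
  attr(set, "outlier_truth") <- indices
  set
}
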