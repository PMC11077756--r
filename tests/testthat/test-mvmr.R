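mvmr_toy <- function() {
  # 6 instruments, 2 exposures with distinct effect patterns
  set.seed(31)
  b1 <- c(0.12, 0.05, -0.08, 0.10, 0.07, -0.11)
  b2 <- c(0.02, 0.10, 0.04, -0.09, 0.12, 0.03)
  sy <- c(0.010, 0.015, 0.012, 0.020, 0.011, 0.016)
  by <- 0.4 * b1 - 0.2 * b2 + rnorm(6, 0, 0.01)
  make_hset(b1, rep(0.01, 6), by, sy,
            extra = list(m = list(beta = b2, se = rep(0.012, 6))))
}

test_that("MVMR coefficients equal the explicit weighted normal equations", {
  hs <- mvmr_toy()
  fit <- mvmr_ivw(hs, exposures = c("exposure", "m"))
  X <- cbind(hs$beta_exposure, hs$beta_m)
  w <- 1 / hs$se_outcome^2
  A <- t(X) %*% (w * X)
  bhat <- solve(A, t(X) %*% (w * hs$beta_outcome))[, 1]
  expect_equal(fit$beta, unname(bhat), tolerance = 1e-10)
  resid <- hs$beta_outcome - X %*% bhat
  q <- sum(w * resid^2)
  scl <- max(1, q / (6 - 2))
  expect_equal(fit$se, unname(sqrt(scl * diag(solve(A)))), tolerance = 1e-10)
  expect_equal(attr(fit, "q"), q, tolerance = 1e-10)
})

test_that("MVMR with one exposure reduces to univariable IVW", {
  set.seed(7)
  bx <- runif(5, 0.05, 0.2)
  by <- 0.3 * bx + rnorm(5, 0, 0.01)
  sy <- runif(5, 0.01, 0.02)
  hs <- make_hset(bx, rep(0.01, 5), by, sy)
  uv <- mr_ivw(hs, model = "fixed")
  uvr <- mr_ivw(hs, model = "random")
  mv <- mvmr_ivw(hs, exposures = "exposure")
  expect_equal(mv$beta, uv$beta, tolerance = 1e-14)
  # MVMR's floored overdispersion SE matches whichever IVW variant applies
  expect_equal(mv$se, max(uv$se, uvr$se * sqrt((5 - 1) / (5 - 1))),
               tolerance = 1e-10)
})

test_that("collinear and zero exposure columns are handled as documented", {
  hs <- mvmr_toy()
  dup <- hs
  dup$beta_m <- dup$beta_exposure
  dup$se_m <- dup$se_exposure
  expect_error(mvmr_ivw(dup, exposures = c("exposure", "m")), "collinear")
  zero <- hs
  zero$beta_m <- 0
  expect_warning(fit <- mvmr_ivw(zero, exposures = c("exposure", "m")),
                 "all-zero")
  uv <- mr_ivw(make_hset(hs$beta_exposure, hs$se_exposure,
                         hs$beta_outcome, hs$se_outcome), model = "fixed")
  expect_equal(fit$beta[1], uv$beta, tolerance = 1e-12)
  expect_true(is.na(fit$beta[2]))
  # more exposures than instruments
  expect_error(mvmr_ivw(hs[1:2, ], exposures = c("exposure", "m")),
               "more instruments")
})

test_that("conditional F matches a step-by-step residual oracle", {
  hs <- mvmr_toy()
  cf <- conditional_f(hs, exposures = c("exposure", "m"))
  # oracle for exposure 1: regress b1 on b2 (weights 1/sx1^2, no
  # intercept), scale weighted RSS by (J - K + 1)
  b1 <- hs$beta_exposure; b2 <- hs$beta_m
  w1 <- 1 / hs$se_exposure^2
  g <- sum(w1 * b1 * b2) / sum(w1 * b2^2)
  q1 <- sum(w1 * (b1 - g * b2)^2)
  expect_equal(unname(cf["exposure"]), q1 / (6 - 2 + 1), tolerance = 1e-10)
  w2 <- 1 / hs$se_m^2
  g2 <- sum(w2 * b2 * b1) / sum(w2 * b1^2)
  q2 <- sum(w2 * (b2 - g2 * b1)^2)
  expect_equal(unname(cf["m"]), q2 / (6 - 2 + 1), tolerance = 1e-10)
  # K = 1 reduces to the mean univariable F
  cf1 <- conditional_f(hs, exposures = "exposure")
  expect_equal(unname(cf1),
               mean((hs$beta_exposure / hs$se_exposure)^2),
               tolerance = 1e-12)
  # duplicating an exposure destroys its conditional strength
  dup <- hs
  dup$beta_m <- hs$beta_exposure + rnorm(6, 0, 1e-6)
  dup$se_m <- hs$se_exposure
  cfd <- conditional_f(dup, exposures = c("exposure", "m"))
  expect_lt(cfd["exposure"], 0.01 * conditional_f(hs, "exposure"))
})

test_that("MVMR recovers known direct effects on synthetic mediation data", {
  reps <- 60
  est <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_snps = 150,
                      mediation = c(theta_direct = -0.3, theta_xm = -0.05,
                                    theta_my = 0.32),
                      seed = 6000 + i)
    sim <- simulate_mediation(cfg)
    hs <- harmonize(sim$exposure, sim$outcome,
                    more = list(m = sim$mediator))
    fit <- mvmr_ivw(hs, exposures = c("exposure", "m"))
    est[i, ] <- fit$beta
  }
  m <- colMeans(est); mcse <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(m[1] - (-0.3)), 3 * mcse[1])
  # the mediator coefficient carries the documented ~1/F attenuation;
  # check it is recovered to within half a percent of the truth
  expect_lt(abs(m[2] - 0.32), 0.005 * abs(0.32) + 3 * mcse[2])
})
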