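test_that("odds-ratio transform reproduces hand-checked conversions", {
  res <- transform_to_or(-0.2871, 0.1253)
  expect_equal(round(res$or, 3), 0.750)
  expect_equal(round(res$or_lower, 3), 0.587)
  expect_equal(round(res$or_upper, 3), 0.959)
  expect_equal(round(res$pvalue, 3), 0.022)
  nul <- transform_to_or(0, 0.2)
  expect_equal(nul$or, 1)
  expect_equal(nul$pvalue, 1)
  # 90% interval uses the right quantile
  r90 <- transform_to_or(0.1, 0.05, ci_level = 0.90)
  expect_equal(r90$or_lower, exp(0.1 - qnorm(0.95) * 0.05))
})

test_that("Wald ratio matches its closed form, including second order", {
  e <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$beta, 0)
  e2 <- wald_ratio(0.1, 0.01, 0.05, 0.02, second_order = TRUE)
  expect_equal(e2$se, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "beta_x")
})

test_that("IVW equals the direct-summation oracle and its reductions", {
  bx <- c(0.12, -0.08, 0.05)
  sx <- c(0.010, 0.012, 0.011)
  by <- c(0.040, -0.030, 0.013)
  sy <- c(0.015, 0.020, 0.012)
  hs <- make_hset(bx, sx, by, sy)
  est <- mr_ivw(hs, model = "fixed")
  orc <- oracle_ivw(bx, by, sy)
  expect_equal(est$beta, orc$beta, tolerance = 1e-12)
  expect_equal(est$se, orc$se, tolerance = 1e-12)
  # J = 1 reduces to the Wald ratio
  one <- mr_ivw(make_hset(0.1, 0.01, 0.05, 0.02), model = "fixed")
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(one$beta, w$beta)
  expect_equal(one$se, w$se)
  # identical ratios: beta = common ratio, Q = 0, auto picks fixed
  hs0 <- make_hset(c(0.1, 0.2, 0.4), rep(0.01, 3),
                   c(0.05, 0.10, 0.20), rep(0.01, 3))
  auto <- mr_ivw(hs0, model = "auto")
  expect_equal(auto$beta, 0.5)
  expect_identical(auto$method, "ivw_fixed")
  expect_equal(attr(auto, "q"), 0, tolerance = 1e-20)
  # random-effects SE is never below fixed and shares the point estimate
  fx <- mr_ivw(hs, model = "fixed"); rd <- mr_ivw(hs, model = "random")
  expect_equal(fx$beta, rd$beta)
  expect_gte(rd$se, fx$se)
  # IVW slope equals origin-constrained WLS with weights 1/se_y^2
  wls <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(est$beta, unname(coef(wls)), tolerance = 1e-12)
})

test_that("Cochran's Q matches hand summation and its chi-square tail", {
  bx <- c(0.1, 0.2, 0.15); sy <- c(0.01, 0.02, 0.015)
  by <- c(0.05, 0.08, 0.09)
  hs <- make_hset(bx, rep(0.01, 3), by, sy)
  q <- cochran_q(hs)
  w <- bx^2 / sy^2
  r <- by / bx
  b_ivw <- sum(w * r) / sum(w)
  expect_equal(q$q, sum(w * (r - b_ivw)^2), tolerance = 1e-12)
  expect_identical(q$df, 2L)
  expect_equal(q$pvalue, pchisq(q$q, 2, lower.tail = FALSE))
  expect_equal(round(chisq_tail_p(81.42, 89), 3), 0.704)
  expect_error(cochran_q(make_hset(0.1, 0.01, 0.05, 0.02)), "at least 2")
})

test_that("MR-Egger matches the explicit normal-equations oracle", {
  # noiseless line: exact interpolation
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.3 * bx + 0.01
  hs <- make_hset(bx, rep(0.01, 4), by, c(0.01, 0.02, 0.015, 0.012))
  eg <- mr_egger(hs)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.01, tolerance = 1e-10)
  # noisy 4-instrument toy vs explicit 2x2 weighted solve
  by2 <- c(0.04, 0.05, 0.10, 0.14)
  sy2 <- c(0.01, 0.02, 0.015, 0.012)
  hs2 <- make_hset(bx, rep(0.01, 4), by2, sy2)
  w <- 1 / sy2^2
  s_w <- sum(w); s_wx <- sum(w * bx); s_wxx <- sum(w * bx^2)
  s_wy <- sum(w * by2); s_wxy <- sum(w * bx * by2)
  det <- s_w * s_wxx - s_wx^2
  b0 <- (s_wxx * s_wy - s_wx * s_wxy) / det
  b1 <- (s_w * s_wxy - s_wx * s_wy) / det
  eg2 <- mr_egger(hs2)
  expect_equal(eg2$slope$beta, b1, tolerance = 1e-10)
  expect_equal(eg2$intercept$beta, b0, tolerance = 1e-10)
  # SE oracle with the overdispersion floor
  rss_w <- sum(w * (by2 - b0 - b1 * bx)^2)
  scl <- max(1, rss_w / 2)
  expect_equal(eg2$slope$se, sqrt(scl * s_w / det), tolerance = 1e-10)
  expect_error(mr_egger(make_hset(1:2 / 10, c(0.01, 0.01),
                                  c(0.1, 0.2), c(0.01, 0.01))),
               "at least 3")
})

test_that("weighted median interpolates the cumulative-weight trace", {
  # odd count, equal weights, distinct ratios: middle ratio
  bx <- rep(0.1, 5)
  by <- c(0.011, 0.052, 0.030, 0.049, 0.020)
  hs <- make_hset(bx, rep(0.01, 5), by, rep(0.01, 5))
  est <- suppressWarnings(mr_weighted_median(hs, "equal", reps = 0))
  expect_equal(est$beta, median(by / bx))
  expect_identical(est$method, "simple_median")
  # unequal weights: hand-executed interpolation
  bx4 <- c(0.10, 0.20, 0.05, 0.08)
  sy4 <- c(0.010, 0.030, 0.020, 0.008)
  by4 <- c(0.030, 0.090, 0.005, 0.040)
  hs4 <- make_hset(bx4, rep(0.01, 4), by4, sy4)
  est4 <- suppressWarnings(mr_weighted_median(hs4, reps = 0))
  expect_equal(est4$beta,
               oracle_weighted_median(by4 / bx4, bx4^2 / sy4^2),
               tolerance = 1e-12)
  # identical ratios give that ratio with a bootstrap SE shrinking in noise
  hsc <- make_hset(c(0.1, 0.2, 0.3), rep(0.001, 3),
                   c(0.05, 0.10, 0.15), rep(0.001, 3))
  estc <- mr_weighted_median(hsc, reps = 200, seed = 9)
  expect_equal(estc$beta, 0.5)
  expect_lt(estc$se, 0.02)
  hsc2 <- make_hset(c(0.1, 0.2, 0.3), rep(0.01, 3),
                    c(0.05, 0.10, 0.15), rep(0.01, 3))
  estc2 <- mr_weighted_median(hsc2, reps = 200, seed = 9)
  expect_gt(estc2$se, estc$se)
})

test_that("weighted mode finds the dominant ratio cluster", {
  set.seed(14)
  bx <- rep(0.1, 10)
  by <- c(rep(0.03, 7), rep(0.10, 3)) + rnorm(10, 0, 0.0005)  # two clusters
  hs <- make_hset(bx, rep(0.005, 10), by, rep(0.01, 10))
  est <- suppressWarnings(mr_weighted_mode(hs, reps = 0))
  h <- attr(est, "bandwidth")
  expect_lt(abs(est$beta - 0.3), h)
  # independent density evaluation over the same 512-point span and a
  # much finer grid: argmax must agree to grid resolution
  ratio <- by / bx
  w <- bx^2 / 0.01^2; w <- w / sum(w)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratio) / h)),
                 numeric(1))
  expect_identical(est$beta, grid[which.max(dens)])
  fine <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 20001)
  densf <- vapply(fine, function(x) sum(w * dnorm((x - ratio) / h)),
                  numeric(1))
  expect_lt(abs(est$beta - fine[which.max(densf)]), diff(grid[1:2]) + 1e-3)
  # all ratios identical: the common ratio, no density step
  hsc <- make_hset(c(0.1, 0.2, 0.4), rep(0.01, 3),
                   c(0.05, 0.1, 0.2), rep(0.01, 3))
  expect_equal(suppressWarnings(mr_weighted_mode(hsc, reps = 0))$beta, 0.5)
})

test_that("mode estimate moves continuously in the bandwidth multiplier", {
  set.seed(5)
  bx <- runif(12, 0.05, 0.2)
  by <- 0.3 * bx + rnorm(12, 0, 0.002)
  by[1:3] <- 1.0 * bx[1:3]  # minority cluster at ratio 1
  hs <- make_hset(bx, rep(0.005, 12), by, rep(0.008, 12))
  phis <- seq(0.5, 4, by = 0.25)
  est <- vapply(phis, function(p) {
    suppressWarnings(mr_weighted_mode(hs, phi = p, reps = 0))$beta
  }, numeric(1))
  expect_true(all(abs(diff(est)) < 0.7))     # never jumps by the full gap
  expect_true(all(est > 0.2 & est < 1.1))
})

test_that("estimators are invariant to jointly negating an instrument", {
  set.seed(21)
  bx <- runif(8, 0.05, 0.2); sx <- rep(0.01, 8)
  by <- 0.4 * bx + rnorm(8, 0, 0.01); sy <- runif(8, 0.008, 0.02)
  hs <- make_hset(bx, sx, by, sy)
  flip <- c(1, -1, 1, 1, -1, 1, -1, 1)
  hsf <- make_hset(bx * flip, sx, by * flip, sy)
  expect_equal(mr_ivw(hsf, "fixed")$beta, mr_ivw(hs, "fixed")$beta)
  expect_equal(mr_egger(hsf)$slope$beta, mr_egger(hs)$slope$beta)
  expect_equal(suppressWarnings(mr_weighted_median(hsf, reps = 0))$beta,
               suppressWarnings(mr_weighted_median(hs, reps = 0))$beta)
  expect_equal(suppressWarnings(mr_weighted_mode(hsf, reps = 0))$beta,
               suppressWarnings(mr_weighted_mode(hs, reps = 0))$beta)
})

test_that("bootstrap standard errors are bit-reproducible given seed", {
  set.seed(3)
  hs <- make_hset(runif(6, 0.05, 0.2), rep(0.01, 6),
                  rnorm(6, 0.02, 0.01), rep(0.01, 6))
  a <- mr_weighted_median(hs, reps = 150, seed = 77)
  b <- mr_weighted_median(hs, reps = 150, seed = 77)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(hs, reps = 150, seed = 78)
  expect_false(identical(a$se, c$se))
  m1 <- mr_weighted_mode(hs, reps = 150, seed = 77)
  m2 <- mr_weighted_mode(hs, reps = 150, seed = 77)
  expect_identical(m1$se, m2$se)
  # and the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(mr_weighted_median(hs, reps = 150, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("mr_fit assembles the panel and respects method minimums", {
  sim <- simulate_uvmr(sim_config(n_snps = 60, theta = 0.2, seed = 8))
  hs <- harmonize(select_significant(sim$exposure), sim$outcome)
  fit <- mr_fit(hs, reps = 120, seed = 2)
  df <- as.data.frame(fit)
  expect_setequal(df$method, c("ivw_fixed", "egger_slope",
                               "weighted_median", "simple_median",
                               "weighted_mode"))
  expect_true(all(df$or_lower <= df$or & df$or <= df$or_upper))
  expect_true(all(df$pvalue > 0 & df$pvalue <= 1))
  # two instruments: IVW only, others skipped with a notice
  hs2 <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1), c(0.01, 0.01))
  fit2 <- mr_fit(hs2)
  expect_named(fit2$estimates, "ivw")
  expect_true(any(grepl("egger skipped", fit2$notes)))
})
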