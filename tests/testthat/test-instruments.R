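test_that("significance selection is a strict-threshold filter", {
  tt <- make_trait(3, pvalue = c(1e-9, 5e-8, 1e-7))
  expect_identical(select_significant(tt, 5e-8)$snp_id, "rs001")
  expect_equal(nrow(select_significant(tt, 1.0)), 3L)
  # recount against a brute-force filter on a simulated spectrum
  sim <- simulate_uvmr(sim_config(n_snps = 200, seed = 11))
  kept <- select_significant(sim$exposure, 5e-8)
  expect_equal(nrow(kept), sum(sim$exposure$pvalue < 5e-8))
  expect_identical(kept$snp_id, sim$exposure$snp_id[sim$exposure$pvalue < 5e-8])
})

test_that("exclusion lists remove exactly the listed SNPs", {
  tt <- make_trait(5)
  expect_identical(apply_exclusion_list(tt, character(0)), tt)
  expect_equal(nrow(suppressMessages(
    apply_exclusion_list(tt, tt$snp_id))), 0L)
  expect_message(out <- apply_exclusion_list(tt, c("rs002", "rs004")),
                 "excluded 2")
  expect_identical(out$snp_id, c("rs001", "rs003", "rs005"))
})

clump_fixture <- function() {
  make_trait(6, ids = paste0("s", 1:6),
             chr = rep("1", 6),
             pos = c(1.0e6, 1.5e6, 2.0e6, 50e6, 55e6, 120e6),
             pvalue = c(1e-10, 1e-9, 5e-9, 1e-12, 1e-8, 1e-7),
             beta = rep(0.1, 6), se = rep(0.01, 6))
}

clump_ld <- function() {
  ids <- paste0("s", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  diag(m) <- 1
  m["s1", "s2"] <- m["s2", "s1"] <- 0.5
  m["s1", "s3"] <- m["s3", "s1"] <- 0.0005
  m["s2", "s3"] <- m["s3", "s2"] <- 0.3
  m["s4", "s5"] <- m["s5", "s4"] <- 0.9
  m
}

test_that("greedy LD clumping matches a hand-executed trace", {
  tt <- clump_fixture()
  # trace: s4 kept (best p) removes s5 (5 Mb, r2 .9); s1 kept removes s2
  # (r2 .5) but not s3 (r2 .0005 <= .001); s3 kept; s6 kept (isolated)
  kept <- clump(tt, ld = clump_ld(), r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(kept$snp_id, c("s1", "s3", "s4", "s6"))
  # distance-only mode removes unconditionally within the window
  kept2 <- clump(tt, ld = NULL, r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(kept2$snp_id, c("s1", "s4", "s6"))
  # single SNP trivially kept; dominance of the smaller p within a pair
  expect_equal(nrow(clump(tt[1, ])), 1L)
  pair <- make_trait(2, ids = c("a", "b"), pos = c(1e6, 1.001e6),
                     pvalue = c(1e-9, 1e-10))
  expect_identical(clump(pair)$snp_id, "b")
})

test_that("clumping is order-invariant and ties break by snp_id", {
  tt <- clump_fixture()
  ld <- clump_ld()
  base <- sort(clump(tt, ld = ld)$snp_id)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- tt[sample(nrow(tt)), ]
    expect_identical(sort(clump(perm, ld = ld)$snp_id), base)
  }
  tie <- make_trait(2, ids = c("zz", "aa"), pos = c(1e6, 1.1e6),
                    pvalue = c(1e-9, 1e-9))
  expect_identical(clump(tie)$snp_id, "aa")
  # missing chromosome/position is an error
  bad <- clump_fixture()
  bad$pos[2] <- NA
  expect_error(clump(bad), "position")
  # SNP absent from the LD matrix: error by default, r2 = 0 on request
  expect_error(clump(tt, ld = ld[-3, -3]), "absent")
  expect_warning(ok <- clump(tt, ld = ld[-2, -2], missing_ld = "zero"),
                 "r\\^2 = 0")
  expect_true("s2" %in% ok$snp_id)  # unlinked by assumption, outside clumps
})

test_that("harmonization aligns, flips, complements and drops correctly", {
  expo <- make_trait(6, ids = sprintf("rs%d", 1:6),
                     ea = c("A", "A", "A", "A", "A", "A"),
                     oa = c("G", "G", "G", "T", "T", "G"),
                     beta = rep(0.1, 6), eaf = c(0.3, 0.3, 0.3, 0.5, 0.2, 0.3))
  outc <- make_trait(6, ids = sprintf("rs%d", 1:6),
                     ea = c("A", "G", "T", "A", "A", "A"),
                     oa = c("G", "A", "C", "T", "T", "C"),
                     beta = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
                     eaf = c(0.3, 0.7, 0.3, 0.5, 0.8, 0.3))
  hs <- harmonize(expo, outc)
  expect_identical(hs$status,
                   c("kept",                 # identical alleles
                     "flipped",              # swapped alleles
                     "kept",                 # strand complement of A/G
                     "dropped_palindromic",  # A/T at eaf 0.5
                     "flipped",              # A/T resolved by frequency
                     "dropped_unmatched"))   # allele sets disagree
  expect_equal(hs$beta_outcome[1:3], c(0.2, -0.2, 0.2))
  expect_equal(hs$beta_outcome[5], -0.2)  # frequency-flipped palindrome
  # provenance categories partition the input
  expect_equal(sum(table(hs$status)), nrow(expo))
  # missing SNP -> unmatched
  hs2 <- harmonize(expo, outc[-1, ])
  expect_identical(hs2$status[1], "dropped_unmatched")
  # duplicates are an error
  dup <- rbind(as.data.frame(outc), as.data.frame(outc[1, ]))
  expect_error(harmonize(expo, dup), "duplicate")
})

test_that("harmonizing an already-aligned pair is the identity", {
  sim <- simulate_uvmr(sim_config(n_snps = 40, seed = 3,
                                  palindrome_prob = 0.3))
  h1 <- harmonize(sim$exposure, sim$outcome)
  k1 <- h1[h1$status %in% c("kept", "flipped"), ]
  # rebuild trait tables from the harmonized rows and harmonize again
  rebuild <- function(beta, se) {
    trait_table(data.frame(snp_id = k1$snp_id, chr = k1$chr, pos = k1$pos,
                           effect_allele = "A", other_allele = "G",
                           eaf = k1$eaf, beta = beta, se = se,
                           pvalue = 0.5, n = 1000))
  }
  h2 <- harmonize(rebuild(k1$beta_exposure, k1$se_exposure),
                  rebuild(k1$beta_outcome, k1$se_outcome))
  expect_true(all(h2$status == "kept"))
  expect_equal(h2$beta_outcome, k1$beta_outcome)
  expect_equal(h2$beta_exposure, k1$beta_exposure)
})

test_that("instrument strength matches the closed forms", {
  # frequency-based form, written out in full as the oracle
  b <- 0.05; s <- 0.005; f <- 0.3; n <- 400000
  num <- 2 * b^2 * f * (1 - f)
  den <- num + 2 * n * s^2 * f * (1 - f)
  r2_expected <- num / den
  f_expected <- r2_expected * (n - 2) / (1 - r2_expected)
  hs <- make_hset(bx = b, sx = s, by = 0.1, sy = 0.01, eaf = f)
  st <- instrument_strength(hs, n)
  expect_equal(st$r_squared, r2_expected, tolerance = 1e-12)
  expect_equal(st$f_statistic, f_expected, tolerance = 1e-12)
  # fallback (no frequency): F = (beta/se)^2
  hs2 <- make_hset(bx = c(0.1, 0), sx = c(0.01, 0.01),
                   by = c(0, 0), sy = c(1, 1))
  st2 <- instrument_strength(hs2, 1000)
  expect_equal(st2$f_statistic, c(100, 0))
  expect_equal(st2$r_squared[2], 0)
  expect_true(st2$weak[2])
  expect_error(instrument_strength(hs2, 2), "> 2")
})

test_that("frequency-based and fallback F agree for GWAS-law SEs", {
  # when se ~ 1/sqrt(2 n f(1-f)) and R^2 << 1 the two forms coincide
  set.seed(42)
  n <- 200000
  f <- runif(50, 0.1, 0.45)
  beta <- rnorm(50, 0, 0.02)
  se <- 1 / sqrt(2 * n * f * (1 - f))
  with_f <- instrument_strength(make_hset(beta, se, beta * 0, se, eaf = f), n)
  without_f <- instrument_strength(make_hset(beta, se, beta * 0, se), n)
  expect_equal(without_f$f_statistic, with_f$f_statistic, tolerance = 0.02)
})
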