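test_that("Tajima's D is zero when kbar = S/a1, negative for star-like data", {
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(10, 7, 7 / a1), 0)
  # star-like: every mutation a singleton, kbar = 2S/n << S/a1
  n <- 10; S <- 9
  expect_lt(tajimas_d(n, S, 2 * S / n), 0)
  expect_error(tajimas_d(10, 0, 1), "S = 0")
  expect_error(tajimas_d(3, 5, 1), "n >= 4")
})

test_that("Tajima's D matches the constant-by-constant oracle on toy data", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(4:15, 1)
    mat <- random_alignment(n, 25)
    st <- observed_neutrality_stats(mat)
    if (st$S < 1) next
    expect_equal(tajimas_d(n, st$S, st$kbar), oracle_tajima(n, st$S, st$kbar),
                 tolerance = 1e-12)
  }
})

test_that("Fu's Fs reproduces the exact Ewens probabilities", {
  # n = 3, theta = 1: Pr(K=3) = 1/6, Fs = ln((1/6)/(5/6))
  expect_equal(fu_fs(3, 1, 3), -log(5), tolerance = 1e-12)
  expect_warning(got <- fu_fs(3, 1, 1), "degenerate")
  expect_identical(got, Inf)
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    theta <- runif(1, 0.2, 8)
    k_obs <- sample(2:n, 1)
    expect_equal(fu_fs(n, theta, k_obs), oracle_fs(n, theta, k_obs),
                 tolerance = 1e-9)
  }
})

test_that("Fu's Fs is overflow-safe for large samples", {
  for (n in c(40, 60, 120)) {
    v <- fu_fs(n, 5.3, round(n * 0.7))
    expect_true(is.finite(v))
  }
})

test_that("R2 handles its boundary cases and matches direct summation", {
  # n = 2, one singleton per sequence: U = (1,1), kbar = 2, S = 2 -> 0
  expect_equal(rozas_r2(2, 2, 2, c(1, 1)), 0)
  expect_error(rozas_r2(5, 0, 1, rep(0, 5)), "S = 0")
  set.seed(29)
  for (rep in 1:30) {
    mat <- random_alignment(sample(4:10, 1), 30)
    st <- observed_neutrality_stats(mat)
    if (st$S < 1) next
    expect_equal(rozas_r2(st$n, st$S, st$kbar, st$U), oracle_r2(mat),
                 tolerance = 1e-12)
  }
})

test_that("singleton counts attribute each unique variant to its carrier", {
  mat <- rbind(s1 = c("A", "A", "A", "C"),
               s2 = c("A", "C", "A", "C"),
               s3 = c("A", "A", "G", "T"),
               s4 = c("A", "A", "A", "C"))
  st <- observed_neutrality_stats(mat)
  expect_equal(st$S, 3L)
  # site 2: C unique to s2; site 3: G unique to s3; site 4: T unique to s3
  expect_equal(st$U, c(0L, 1L, 2L, 0L))
  expect_equal(st$k_obs, 3L)
})

test_that("an observed statistic at the simulated median gets p near 0.5", {
  null <- simulate_neutrality_null(12, 400, "fixed_s", S = 10, seed = 37)
  obs <- list(n = 12, S = 10,
              kbar = 10 / sum(1 / (1:11)), k_obs = 6, U = rep(1, 12))
  # choose kbar so that D equals the simulated median exactly
  medD <- median(null$D)
  a1 <- sum(1 / (1:11))
  # invert D for kbar: D = (kbar - S/a1)/denom
  i <- 1:11
  a2 <- sum(1 / i^2)
  b1 <- 13 / 33; b2 <- 2 * (144 + 12 + 3) / (9 * 12 * 11)
  c1 <- b1 - 1 / a1; c2 <- b2 - 14 / (12 * a1) + a2 / a1^2
  denom <- sqrt((c1 / a1) * 10 + (c2 / (a1^2 + a2)) * 90)
  obs$kbar <- medD * denom + 10 / a1
  pv <- simulate_null_pvalues(obs, null = null)
  expect_gt(pv$p_D, 0.5)  # two-tailed p of the median is ~1
  pR <- (sum(null$R2 <= median(null$R2)) + 1) / (nrow(null) + 1)
  expect_gt(pR, 0.4); expect_lt(pR, 0.62)
})

test_that("strong expansion produces significantly negative Fs in most samples", {
  set.seed(41)
  n <- 25
  hits <- 0; total <- 20
  null_cache <- new.env()
  for (r in 1:total) {
    sm <- simulate_sample(n, 2000, demog_stepwise(tau = 5, theta0 = 0.5, theta1 = 50),
                          mode = "theta")
    st <- observed_neutrality_stats(sm)
    if (st$S < 1) next
    key <- as.character(st$S)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- simulate_neutrality_null(n, 250, "fixed_s", S = st$S,
                                                    seed = 1000 + st$S)
    }
    pv <- simulate_null_pvalues(st, null = null_cache[[key]])
    if (!is.na(pv$p_Fs) && pv$p_Fs <= 0.02) hits <- hits + 1
  }
  expect_gt(hits / total, 0.8)
})

test_that("the neutrality summary flags Fs at the 0.02 level and D/R2 at 0.05", {
  set.seed(43)
  sm <- simulate_sample(12, 800, demog_constant(4))
  nt <- neutrality_test(sm, reps = 150, seed = 44)
  expect_s3_class(nt, "neutrality_summary")
  expect_equal(nt$sig_Fs, !is.na(nt$p_Fs) && nt$p_Fs <= 0.02)
  expect_equal(nt$sig_D, nt$p_D <= 0.05)
  expect_equal(nt$sig_R2, nt$p_R2 <= 0.05)
  expect_warning(neutrality_test(sm, reps = 50, seed = 44), "100 replicates")
})
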