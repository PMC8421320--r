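test_that("AHA segment model partitions all 17 segments across territories", {
  seg <- aha_segments()
  expect_equal(nrow(seg), 17)
  expect_equal(sum(seg$weight), 1, tolerance = 1e-12)
  expect_true(all(table(seg$territory) == c(LAD = 7, LCx = 5, RCA = 5)))
  expect_identical(territory_of(1), "LAD")
  expect_identical(territory_of(3), "RCA")
  expect_identical(territory_of(c(5, 16)), c("LCx", "LCx"))
  expect_error(territory_of(0), "unknown")
  expect_error(territory_of(18), "unknown")
})

test_that("myocardial flow reserve is the per-entry stress/rest ratio", {
  expect_equal(mfr(1.5, 1.5), 1.0)
  expect_equal(mfr(0.97, 3.19), 3.19 / 0.97, tolerance = 1e-12)
  expect_equal(mfr(0.97, 3.19), 3.2887, tolerance = 1e-4)
  expect_error(mfr(0, 3), "> 0")
  expect_error(mfr(c(1, -1), c(2, 2)), "> 0")
})

test_that("Bland-Altman bias and limits match hand computation", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # d = (0.1, -0.1): bias 0, loa = +/- 1.96 * sqrt(0.02)
  ba <- bland_altman(c(1.1, 1.9), c(1, 2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(0.02), tolerance = 1e-12)
  expect_equal(ba$loa_high, 0.27718, tolerance = 1e-4)
  # translation: constant offset moves bias, not the width
  x <- rnorm(20); y <- rnorm(20)
  b1 <- bland_altman(x, y); b2 <- bland_altman(x + 0.5, y)
  expect_equal(b2$bias, b1$bias + 0.5, tolerance = 1e-12)
  expect_equal(b2$loa_high - b2$loa_low, b1$loa_high - b1$loa_low,
               tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "2 pairs")
})

test_that("Spearman correlation: exact values, monotone limits, undefined cases", {
  x <- c(0.2, 1.1, 2.3, 5.9)
  expect_equal(spearman_cor(x, exp(x))$r, 1)
  expect_equal(spearman_cor(x, -x^3)$r, -1)
  # classic rank formula: 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 sum = 2
  s <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$r, 0.8, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "3 pairs")
})

test_that("paired t: zero-difference and hand-computed cases", {
  t0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(t0$t, t0$p), c(0, 1))
  t1 <- paired_t(c(2, 0), c(1, 1))          # d = (1, -1), zero mean
  expect_equal(c(t1$t, t1$p), c(0, 1))
  # d = (0.2, 0.4, 0.6): mean 0.4, sd 0.2, t = 0.4/(0.2/sqrt(3))
  t2 <- paired_t(c(1.2, 1.4, 1.6), c(1, 1, 1))
  expect_equal(t2$t, 0.4 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(t2$t, 3.4641, tolerance = 1e-4)
  expect_equal(t2$df, 2)
  # constant nonzero difference: infinite-statistic flag, not an error
  t3 <- paired_t(c(2, 3), c(1, 2))
  expect_true(t3$infinite)
  expect_equal(t3$t, Inf)
})

test_that("agreement statistics match brute-force formulas on random vectors", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(5:25, 1)
    x <- rnorm(n); y <- rnorm(n)          # continuous: ties a.s. absent
    # Bland-Altman via explicit formulas
    d <- x - y
    m <- sum(d) / n
    s <- sqrt(sum((d - m)^2) / (n - 1))
    ba <- bland_altman(x, y)
    stopifnot(abs(ba$bias - m) < 1e-12,
              abs(ba$loa_low - (m - 1.96 * s)) < 1e-12,
              abs(ba$loa_high - (m + 1.96 * s)) < 1e-12)
    # Spearman via the no-ties rank-difference formula
    rs <- 1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
    stopifnot(abs(spearman_cor(x, y)$r - rs) < 1e-12)
    # paired t via the explicit statistic
    stopifnot(abs(paired_t(x, y)$t - m / (s / sqrt(n))) < 1e-12)
  }
  succeed()
})

test_that("Spearman t-approximation agrees with the Pearson-on-ranks test", {
  set.seed(7)
  x <- rnorm(30); y <- x + rnorm(30)
  ours <- spearman_cor(x, y)
  ref <- cor.test(rank(x), rank(y))       # Pearson test on ranks = same t
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("modality comparison joins, excludes unreliable pairs, and reports", {
  pet <- data.frame(subject = rep(c("S01", "S02"), each = 2),
                    condition = rep(c("rest", "stress"), 2),
                    region = "global",
                    F = c(1.0, 3.0, 0.8, 2.5))
  mri <- pet
  mri$reliable <- TRUE
  rep <- compare_modalities(pet, mri, "global", "pooled")
  expect_equal(rep$n, 4)
  expect_equal(rep$bias, 0)
  expect_equal(c(rep$loa_low, rep$loa_high), c(0, 0))
  expect_equal(rep$spearman_r, 1)
  expect_equal(rep$excluded_count, 0)
  # exclusion markers drop pairs and are counted
  seg <- expand.grid(subject = c("S01", "S02"),
                     condition = c("rest", "stress"),
                     region = sprintf("seg%02d", 1:17),
                     stringsAsFactors = FALSE)
  seg$F <- runif(nrow(seg), 0.8, 3.5)
  mseg <- seg
  mseg$reliable <- TRUE
  mseg$reliable[sample(nrow(mseg), 6)] <- FALSE
  mseg$F <- mseg$F + rnorm(nrow(mseg), 0, 0.1)
  rep2 <- compare_modalities(seg, mseg, "segment", "pooled")
  expect_equal(rep2$excluded_count, 6)
  expect_equal(rep2$n, nrow(seg) - 6)
  expect_error(compare_modalities(pet[0, ], mri, "global", "rest"), "join")
})

test_that("MFR table pivots rest/stress and drops incomplete or flagged entries", {
  tab <- data.frame(subject = rep(c("S01", "S02", "S03"), each = 2),
                    condition = rep(c("rest", "stress"), 3),
                    region = "global",
                    F = c(1, 3, 0.8, 2.4, 1.1, 3.3),
                    reliable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  mt <- mfr_table(tab)
  expect_equal(nrow(mt), 2)                 # S03 dropped (unreliable stress)
  expect_equal(mt$mfr[mt$subject == "S01"], 3)
  expect_equal(mt$mfr[mt$subject == "S02"], 3)
})

test_that("MFR amplifies relative noise beyond the stress estimate alone", {
  set.seed(11)
  rel <- 0.08
  rest_true <- 1.0; stress_true <- 3.0
  rest <- rest_true * (1 + rnorm(4000, 0, rel))
  stress <- stress_true * (1 + rnorm(4000, 0, rel))
  keep <- rest > 0.2
  m <- mfr(rest[keep], stress[keep])
  rel_sd <- function(v) sd(v) / mean(v)
  expect_gt(rel_sd(m), rel_sd(stress))
  # and it is close to the independent-error prediction sqrt(2) * rel
  expect_equal(rel_sd(m), sqrt(2) * rel, tolerance = 0.15)
})

test_that("global fit equals the mean of segment fits for a homogeneous subject", {
  co <- noiseless_seg_cohort()
  tab <- fit_cohort_pet(co, level = "all")
  one <- tab[tab$subject == "S01" & tab$condition == "stress", ]
  segs <- one$F[grepl("^seg", one$region)]
  expect_equal(one$F[one$region == "global"], mean(segs), tolerance = 1e-6)
})
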