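test_that("reader averaging is the per-cell arithmetic mean", {
  tab <- data.frame(patient = c(1, 1, 2, 2), metric = "ADC_median",
                    reader = c(1, 2, 1, 2), pre = c(10, 14, 20, 22),
                    post = c(8, 10, 18, 18))
  avg <- average_readers(tab)
  expect_equal(avg$pre, c(12, 21))
  expect_equal(avg$post, c(9, 18))
  # single reader: unchanged
  one <- tab[tab$reader == 1, ]
  expect_equal(average_readers(one)$pre, one$pre)
  # random table against a brute-force per-cell mean
  set.seed(2)
  big <- expand.grid(patient = 1:8, metric = c("a", "b"), reader = 1:3)
  big$pre <- rnorm(nrow(big)); big$post <- rnorm(nrow(big))
  avg2 <- average_readers(big)
  for (i in sample(nrow(avg2), 5)) {
    sel <- big$patient == avg2$patient[i] & big$metric == avg2$metric[i]
    expect_equal(avg2$pre[i], mean(big$pre[sel]), tolerance = 1e-12)
  }
  expect_error(average_readers(big[0, ]), "empty")
})

test_that("paired t: zero net change gives t = 0, p = 1; random inputs match the oracle", {
  pre <- c(5, 6, 7); post <- c(6, 6, 6)   # diffs -1, 0, 1
  r <- paired_t(pre, post)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  set.seed(14)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    a <- rnorm(n, 10, 3); b <- a - rnorm(n, 1, 2)
    got <- paired_t(a, b)
    exp_ <- oracle_paired_t(a, b)
    for (f in names(exp_)) expect_equal(got[[f]], exp_[[f]], tolerance = 1e-12)
    expect_true(got$ci_low <= got$mean_change && got$mean_change <= got$ci_high)
  }
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("paired t p-value agrees with a sign-flip permutation test", {
  set.seed(21)
  pre <- rnorm(12, 10, 2); post <- pre - rnorm(12, 0.8, 1.5)
  p_t <- paired_t(pre, post)$p_value
  d <- pre - post
  t_obs <- abs(mean(d) / (sd(d) / sqrt(length(d))))
  B <- 20000
  t_perm <- replicate(B, {
    s <- sample(c(-1, 1), length(d), replace = TRUE)
    ds <- d * s
    abs(mean(ds) / (sd(ds) / sqrt(length(ds))))
  })
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  expect_lt(abs(p_perm - p_t), 3 * sqrt(p_t * (1 - p_t) / B) + 0.01)
})

test_that("SRM equals mean/SD of changes, is banded correctly, and is monotone in shift", {
  expect_equal(srm(c(1, -1))$srm, 0)
  expect_equal(srm(c(1, -1))$band, "negligible")
  set.seed(4)
  x <- rnorm(40)
  vals <- vapply(c(0, 0.5, 1, 2), function(c) srm(x + c)$srm, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(srm_band(0.19), "negligible")
  expect_equal(srm_band(0.2), "small")
  expect_equal(srm_band(0.5), "moderate")
  expect_equal(srm_band(0.8), "large")
  expect_equal(srm_band(-0.9), "large")
  expect_error(srm(rep(2, 5)), "zero variance")
})

test_that("SRM of 1e5 standard-normal changes shifted by 0.5 is close to 0.5", {
  set.seed(99)
  x <- rnorm(1e5, 0.5, 1)
  r <- srm(x)
  expect_lt(abs(r$srm - 0.5), 0.02)
  # the estimate sits at the small/moderate boundary; the exact banding of
  # the true value is asserted in the banding test above
  expect_true(r$band %in% c("small", "moderate"))
})

test_that("srm and srm_from_summary are a round-trip identity through the paired-t CI", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    pre <- rnorm(n, 20, 5); post <- pre - rnorm(n, 1.5, 3)
    tt <- paired_t(pre, post)
    direct <- srm(pre - post)$srm
    rec <- srm_from_summary(mean(pre), mean(post), tt$ci_low, tt$ci_high, n)
    expect_equal(rec, direct, tolerance = 1e-9)
  }
  # symmetric CI about 0 with equal means reconstructs exactly 0
  expect_equal(srm_from_summary(5, 5, -1.2, 1.2, 30), 0)
  expect_error(srm_from_summary(5, 4, 2, 2, 30), "width")
})

test_that("Pearson correlation handles exact linear relations and matches the oracle", {
  x <- c(1, 2, 3, 5, 9)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 3), -1)
  set.seed(11)
  for (i in 1:15) {
    a <- rnorm(sample(4:80, 1)); b <- 0.3 * a + rnorm(length(a))
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Bland-Altman bias and limits of agreement are exact on closed-form cases", {
  r <- bland_altman(c(1, 5, 9), c(3, 7, 11))   # reader2 = reader1 + 2
  expect_equal(r$bias, -2)
  expect_equal(r$loa_low, -2)
  expect_equal(r$loa_high, -2)
  r2 <- bland_altman(c(0, 1, 2), c(1, 1, 1))   # diffs -1, 0, 1 -> SD 1
  expect_equal(r2$bias, 0)
  expect_equal(r2$loa_low, -1.96)
  expect_equal(r2$loa_high, 1.96)
  set.seed(18)
  for (i in 1:15) {
    a <- rnorm(sample(3:50, 1), 100, 20); b <- a + rnorm(length(a), 1, 4)
    got <- bland_altman(a, b)
    exp_ <- oracle_bland_altman(a, b)
    expect_equal(got$bias, exp_$bias, tolerance = 1e-12)
    expect_equal(got$loa_low, exp_$loa_low, tolerance = 1e-12)
    expect_equal(got$loa_high, exp_$loa_high, tolerance = 1e-12)
    # LoA width invariant under a common shift of both readers
    sh <- bland_altman(a + 17.3, b + 17.3)
    expect_equal(sh$loa_high - sh$loa_low, got$loa_high - got$loa_low,
                 tolerance = 1e-9)
  }
})

test_that("ICC(2,1): perfect agreement gives 1, independence gives ~0, ANOVA oracle agrees", {
  set.seed(6)
  a <- rnorm(20, 50, 10)
  expect_equal(icc(cbind(a, a)), 1)
  ind <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(icc(ind)), 0.1)
  # canonical worked 6 x 4 reliability matrix (published value 0.29)
  m <- matrix(c(9, 2, 5, 8, 6, 1, 3, 2, 8, 4, 6, 8, 7, 1, 2, 6,
                10, 5, 6, 9, 6, 2, 4, 7), ncol = 4, byrow = TRUE)
  expect_equal(round(icc(m), 2), 0.29)
  for (i in 1:10) {
    x <- matrix(rnorm(15 * 3, 10, 4), 15, 3) + rnorm(15, 0, 6)
    expect_equal(icc(x), oracle_icc_aov(x), tolerance = 1e-10)
  }
  expect_error(icc(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("logistic response model: null covers OR 1, separation errors, effect recovered", {
  set.seed(33)
  x <- rnorm(500)
  y <- rbinom(500, 1, 0.4)          # independent of x
  fit <- logistic_response(y, x)
  z <- abs(log(fit$odds_ratio)) / fit$se
  expect_lt(z, 2.5)                  # OR within its CI of 1
  # separable data
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_error(logistic_response(ys, xs), "separation")
  # planted log-odds ratio 0.7
  x2 <- rnorm(2000)
  y2 <- rbinom(2000, 1, plogis(-0.3 + 0.7 * x2))
  fit2 <- logistic_response(y2, x2)
  expect_lt(abs(fit2$coef - 0.7), 0.1)
  expect_error(logistic_response(rep(1, 50), rnorm(50)), "classes")
})

test_that("clinical response classifiers follow the stated inequalities exactly", {
  mk <- function(basdai, vas, asdas) list(basdai = basdai, spinal_vas = vas,
                                          asdas_crp = asdas)
  # boundary: BASDAI improvement exactly 1.2 and VAS exactly 1 -> responder
  r <- classify_clinical_response(mk(6.0, 5.0, 3.0), mk(4.8, 4.0, 1.9))
  expect_true(r$nice_response)
  expect_false(r$cii_asdas)         # ASDAS improvement exactly 1.1 is not > 1.1
  r2 <- classify_clinical_response(mk(6.0, 5.0, 3.0), mk(4.9, 4.0, 1.9))
  expect_false(r2$nice_response)    # BASDAI improvement 1.1 < 1.2
  # ASDAS change exactly 1.1 is NOT a clinically important improvement
  r3 <- classify_clinical_response(mk(6, 5, 3.0), mk(6, 5, 1.9))
  expect_false(r3$cii_asdas)
  # post ASDAS exactly 1.3 is NOT inactive disease
  expect_false(r3$asdas_id)
  r4 <- classify_clinical_response(mk(6, 5, 3.0), mk(6, 5, 1.89))
  expect_true(r4$cii_asdas)
  expect_true(classify_clinical_response(mk(6, 5, 3), mk(6, 5, 1.29))$asdas_id)
  # BASDAI 50
  expect_true(classify_clinical_response(mk(6, 5, 3), mk(3, 5, 3))$basdai50)
  expect_false(classify_clinical_response(mk(6, 5, 3), mk(3.1, 5, 3))$basdai50)
  # missing component -> NA flag
  r5 <- classify_clinical_response(list(basdai = 6, spinal_vas = 5),
                                   list(basdai = 4, spinal_vas = 3))
  expect_true(is.na(r5$cii_asdas))
  expect_true(r5$nice_response)
})

test_that("responsiveness table reproduces by-hand SRM and flips PDFF sign convention", {
  set.seed(44)
  tab <- rbind(
    data.frame(patient = 1:12, metric = "ADC_median", reader = 1,
               pre = rnorm(12, 195, 30), post = rnorm(12, 170, 30)),
    data.frame(patient = 1:12, metric = "PDFF_median", reader = 1,
               pre = rnorm(12, 57, 5), post = rnorm(12, 59, 5)))
  rs <- responsiveness(tab)
  adc <- rs[rs$metric == "ADC_median", ]
  sub <- tab[tab$metric == "ADC_median", ]
  expect_equal(adc$srm, srm(sub$pre - sub$post)$srm, tolerance = 1e-12)
  pdff <- rs[rs$metric == "PDFF_median", ]
  subp <- tab[tab$metric == "PDFF_median", ]
  # PDFF rises with treatment: reported change is post - pre
  expect_equal(pdff$mean_change, mean(subp$post - subp$pre), tolerance = 1e-12)
  expect_equal(pdff$srm, srm(subp$post - subp$pre)$srm, tolerance = 1e-12)
})
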