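test_that("Clopper-Pearson intervals reproduce the printed small-cohort CIs", {
  expect_equal(unname(round(clopperPearson(6, 6, 0.95), 3)),
               c(0.541, 1.000))
  expect_equal(unname(round(clopperPearson(5, 7, 0.95), 3)),
               c(0.290, 0.963))
  expect_equal(unname(clopperPearson(0, 10, 0.95)["lower"]), 0)
  expect_equal(unname(clopperPearson(10, 10, 0.95)["upper"]), 1)
  expect_error(clopperPearson(5, 4), "domain error")
})

test_that("beta-quantile inversion matches binomial tail-sum and binom.test oracles", {
  for (n in 1:8) for (k in 0:n) {
    got <- clopperPearson(k, n, 0.95)
    grid <- gridClopperPearson(k, n, 0.95)
    expect_lt(abs(got["lower"] - grid["lower"]), 2e-6)
    expect_lt(abs(got["upper"] - grid["upper"]), 2e-6)
    bt <- stats::binom.test(k, n)$conf.int
    expect_equal(unname(got), c(bt[1], bt[2]), tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson coverage is at least nominal", {
  n <- 10
  for (p in seq(0.1, 0.9, by = 0.1)) {
    set.seed(round(p * 1000))
    ks <- rbinom(20000, n, p)
    lo <- ifelse(ks == 0, 0, qbeta(0.025, ks, n - ks + 1))
    hi <- ifelse(ks == n, 1, qbeta(0.975, ks + 1, n - ks))
    expect_gte(mean(lo <= p & p <= hi), 0.95)
  }
})

test_that("sensitivity and specificity with exact intervals", {
  r <- sensSpec(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # 6/6 deaths predicted, 5/7 survivors correctly negative
  pred <- c(rep(TRUE, 6), rep(FALSE, 5), TRUE, TRUE)
  act <- c(rep(TRUE, 6), rep(FALSE, 7))
  r2 <- sensSpec(pred, act, conf = 0.95)
  expect_equal(r2$sensitivity, 1)
  expect_equal(round(r2$specificity, 3), 0.714)
  expect_equal(unname(round(r2$ciSens, 3)), c(0.541, 1.000))
  expect_equal(unname(round(r2$ciSpec, 3)), c(0.290, 0.963))
  expect_equal(r2$tp + r2$fp + r2$tn + r2$fn, r2$n)

  # degenerate: everything predicted positive
  r3 <- sensSpec(rep(TRUE, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(r3$sensitivity, 1)
  expect_equal(r3$specificity, 0)

  # a class absent from the truth flags the metric instead of zeroing it
  r4 <- sensSpec(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(r4$specificity))
  expect_match(r4$flags, "specificity undefined")
})

test_that("signed-rank test matches exact enumeration and wilcox.test", {
  x <- c(5.1, 3.2, 7.7, 1.1, 9.8)
  y <- c(4.0, 4.5, 5.5, 1.9, 4.2)
  got <- wilcoxonSignedRank(x, y)
  expect_equal(got$p_value, enumSignedRankP(x - y))
  expect_equal(got$p_value,
               stats::wilcox.test(x, y, paired = TRUE,
                                  exact = TRUE)$p.value)

  # tied absolute differences: exact enumeration with midranks
  xt <- c(3, 5, 9, 2, 8, 6)
  yt <- c(1, 3, 11, 4, 6, 3)
  gt <- wilcoxonSignedRank(xt, yt)
  expect_equal(gt$p_value, enumSignedRankP(xt - yt))
  expect_match(gt$method, "exact")

  # degenerate: identical samples
  gd <- wilcoxonSignedRank(1:5, 1:5)
  expect_equal(gd$p_value, 1)
  expect_match(gd$flags, "all differences zero")
})

test_that("signed-rank normal approximation holds its nominal size", {
  set.seed(99)
  rej <- mean(replicate(2000, {
    x <- rnorm(50); y <- rnorm(50)
    wilcoxonSignedRank(x, y)$p_value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  # all censored: flat at 1
  k0 <- kmCurve(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(k0$surv == 1))

  # no censoring: drops of exactly 1/n
  k1 <- kmCurve(c(2, 5, 9, 13), c(1, 1, 1, 1))
  expect_equal(k1$surv, c(0.75, 0.5, 0.25, 0))

  # mixed 10-subject case against the independent hand computation
  tt <- c(3, 5, 5, 7, 8, 10, 10, 12, 14, 15)
  ee <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km <- kmCurve(tt, ee)
  hand <- handKm(tt, ee)
  evt <- km$nEvent > 0
  expect_equal(km$time[evt], hand$time)
  expect_equal(km$surv[evt], hand$surv, tolerance = 1e-12)
  expect_error(kmCurve(numeric(0), numeric(0)), "empty-sample")
})

test_that("log-rank test matches the hand O-E computation and is symmetric", {
  # identical groups: statistic 0, p = 1
  r0 <- logrankTest(c(2, 4, 6), c(1, 1, 0), c(2, 4, 6), c(1, 1, 0))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  # tiny worked instance
  tA <- c(2, 4); eA <- c(1, 1)
  tB <- c(6, 8); eB <- c(1, 0)
  got <- logrankTest(tA, eA, tB, eB)
  hand <- handLogrank(tA, eA, tB, eB)
  expect_equal(got$statistic, hand$chisq, tolerance = 1e-9)
  expect_equal(got$p_value, hand$p, tolerance = 1e-9)

  swapped <- logrankTest(tB, eB, tA, eA)
  expect_equal(swapped$statistic, got$statistic, tolerance = 1e-12)

  # no events anywhere: undefined, flagged
  rn <- logrankTest(c(5, 6), c(0, 0), c(7, 8), c(0, 0))
  expect_true(is.na(rn$p_value))
  expect_match(rn$flags, "undefined-test")
})

test_that("study-like survival separation is strongly significant", {
  # six deaths around days 13-15 vs six censored at day 70, plus one
  # censored animal in the death-direction group
  tA <- c(13, 13, 14, 14, 15, 15, 70); eA <- c(1, 1, 1, 1, 1, 1, 0)
  tB <- rep(70, 6); eB <- rep(0, 6)
  expect_lt(logrankTest(tA, eA, tB, eB)$p_value, 0.01)
})

test_that("pearson correlation behaves on exact and generated data", {
  expect_equal(pearsonR(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearsonR(1:10, -(1:10)), -1)
  expect_error(pearsonR(rep(1, 5), 1:5), "undefined-correlation")

  # coupled generator: growth rate vs 48-h tumour Lac/Bic in treated
  # animals; with n = 13 the per-seed estimate scatters (sd ~0.15), so
  # the band is checked on the 100-seed mean and on most single seeds
  rs <- vapply(1:100, function(s) {
    co <- makeCohort(cohortSpec(seed = s))
    tr <- co$group != "control"
    pearsonR(co$vol_post_mm3[tr] / co$vol_pre_mm3[tr],
             co$post_lacbic_tumor[tr])
  }, numeric(1))
  expect_gte(mean(rs), 0.5)
  expect_lte(mean(rs), 0.9)
  expect_gte(mean(rs >= 0.5 & rs <= 0.9), 0.75)
  expect_true(all(rs > 0))
})

test_that("cohort summary reports mean and standard error per cell", {
  co <- makeCohort(cohortSpec(seed = 2))
  co$pre_lacbic_tumor <- 4  # identical animals in one variable
  sm <- summarizeCohort(co)
  cell <- sm[sm$variable == "lacbic" & sm$region == "tumor" &
               sm$timepoint == "baseline", ]
  expect_true(all(cell$mean == 4))
  expect_true(all(cell$se == 0))

  toy <- data.frame(id = c("a", "b"), group = "deceased",
                    pre_lacbic_tumor = c(1, 3), post_lacbic_tumor = c(1, 3),
                    pre_lacbic_normal = c(1, 3),
                    post_lacbic_normal = c(1, 3),
                    vol_pre_mm3 = c(1, 3), vol_post_mm3 = c(1, 3),
                    survival_day = c(10, 12), event = c(1, 1))
  smt <- summarizeCohort(toy)
  expect_true(all(smt$mean == 2))
  expect_true(all(smt$se == 1))

  one <- toy[1, ]
  sm1 <- summarizeCohort(one)
  expect_true(all(is.na(sm1$se)))
  expect_match(sm1$flag[1], "size 1")

  # generator consistency: deceased tumour 48-h mean near its target
  ms <- vapply(1:10, function(s) {
    cc <- makeCohort(cohortSpec(seed = s))
    mean(cc$post_lacbic_tumor[cc$group == "deceased"])
  }, numeric(1))
  expect_lt(abs(mean(ms) - 17.767), 2 * sd(ms) / sqrt(length(ms)))
})
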