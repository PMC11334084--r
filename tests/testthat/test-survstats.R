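test_that("Kaplan-Meier matches hand product-limit values", {
  # {1 event, 2 event, 3 censored}: S(1) = 2/3, S(2) = 1/3
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)

  # all censored: S identically 1
  km0 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # replication invariance
  t6 <- rep(c(1, 2, 3), 2); s6 <- rep(c(1, 1, 0), 2)
  km2 <- kmEstimate(t6, s6)
  expect_equal(km2$surv[km2$time == 2], 1 / 3)

  # survival is non-increasing and within [0, 1]
  set.seed(5)
  kmr <- kmEstimate(rexp(50), rbinom(50, 1, 0.7))
  expect_true(all(diff(kmr$surv) <= 1e-12))
  expect_true(all(kmr$surv >= 0 & kmr$surv <= 1))

  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches the explicit risk-set computation", {
  # duplicated single group: statistic 0
  tt <- c(1, 3, 5, 7); ss <- c(1, 1, 0, 1)
  lr0 <- logrankTest(c(tt, tt), c(ss, ss), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # 8-subject toy against the oracle over risk sets
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  status <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), 4)
  lr <- logrankTest(time, status, group)
  orc <- oracle_logrank(time, status, group)
  expect_equal(lr$chisq, orc$chisq, tolerance = 1e-9)

  # invariant to monotone time transformation
  lr2 <- logrankTest(exp(time), status, group)
  expect_equal(lr2$chisq, lr$chisq, tolerance = 1e-12)

  expect_error(logrankTest(time, status, rep("a", 8)), "2 groups")
})

test_that("log-rank and Cox Wald tests hold their type-I error under the null", {
  set.seed(321)
  n <- 200
  rej_lr <- rej_cox <- logical(2000)
  for (i in 1:2000) {
    time <- rexp(n, 0.1)
    status <- rbinom(n, 1, 0.8)
    grp <- rep(c("a", "b"), each = n / 2)
    x <- rnorm(n)
    rej_lr[i] <- logrankTest(time, status, grp)$p < 0.05
    fit <- survival::coxph(survival::Surv(time, status) ~ x)
    rej_cox[i] <- summary(fit)$coefficients[1, "Pr(>|z|)"] < 0.05
  }
  expect_gt(mean(rej_lr), 0.035); expect_lt(mean(rej_lr), 0.065)
  expect_gt(mean(rej_cox), 0.035); expect_lt(mean(rej_cox), 0.065)
})

test_that("cutpoint search equals the exhaustive-scan oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    score <- rnorm(n)
    time <- rexp(n, 0.1 * exp(0.3 * score))
    status <- rbinom(n, 1, 0.8)
    if (sum(status) == 0) status[1] <- 1L
    cp <- optimalCutpoint(score, time, status, minprop = 0.1)
    orc <- oracle_cutpoint(score, time, status, minprop = 0.1)
    expect_equal(cp$cutpoint, orc$cutpoint)
    expect_equal(abs(cp$statistic), abs(orc$statistic), tolerance = 1e-9)
  }
})

test_that("cutpoint separates short from long survivors; minprop saturates", {
  # uncensored toy where the score is the survival-time rank
  time <- 1:20
  status <- rep(1L, 20)
  score <- rank(-time)  # high score = short survival
  cp <- optimalCutpoint(score, time, status, minprop = 0.1)
  expect_gt(mean(time[score <= cp$cutpoint]), mean(time[score > cp$cutpoint]))

  # minprop = 0.5 with even n: only the median split is admissible
  set.seed(2)
  sc <- rnorm(20)
  cp5 <- optimalCutpoint(sc, time, status, minprop = 0.5)
  expect_equal(cp5$n_low, 10)
  expect_equal(cp5$n_high, 10)
  expect_equal(nrow(cp5$scan), 1L)

  expect_error(optimalCutpoint(rep(1, 20), time, status), "identical")
})

test_that("multivariable Cox: oracle recovery and aliased-column handling", {
  time <- c(2, 4, 6, 8, 10, 12); status <- rep(1L, 6)
  x <- c(1, 0, 0, 1, 0, 1)
  fit <- coxFit(data.frame(x = x), time, status)
  opt <- optimize(function(b) -oracle_coxpl(b, x, time, status), c(-5, 5),
                  tol = 1e-8)
  expect_equal(fit$coefficients$beta, opt$minimum, tolerance = 1e-4)

  # duplicated covariate: aliased column dropped, fit unchanged
  expect_warning(
    fit2 <- coxFit(data.frame(x = x, x_dup = x), time, status), "aliased")
  expect_equal(fit2$coefficients$beta, fit$coefficients$beta, tolerance = 1e-8)

  # baseline cumulative hazard is non-decreasing
  expect_true(all(diff(fit$basehaz$hazard) >= -1e-12))

  # planted-coefficient recovery across seeds
  bhat <- vapply(1:20, function(s) {
    d <- make_ph_data(400, beta = c(0.7, 0.3), cens_max = 40, seed = s)
    coxFit(d[c("x1", "x2")], d$time, d$status)$coefficients$beta
  }, numeric(2))
  expect_lt(abs(mean(bhat[1, ]) - 0.7) / 0.7, 0.10)
  expect_lt(abs(mean(bhat[2, ]) - 0.3) / 0.3, 0.10)
})

test_that("time-dependent AUC: perfect ranking, pair-counting oracle, null mean", {
  set.seed(12)
  time <- rexp(60, 0.2); status <- rep(1L, 60)
  # score = -time anti-ranks survival perfectly
  expect_equal(timeDependentAUC(-time, time, status, median(time)), 1)

  # uncensored estimate equals direct pair counting
  score <- rnorm(60)
  t0 <- median(time)
  expect_equal(timeDependentAUC(score, time, status, t0),
               oracle_cd_auc(score, time, t0), tolerance = 1e-12)

  # independent score: mean AUC near 1/2
  aucs <- vapply(1:500, function(i) {
    tt <- rexp(100, 0.2); st <- rbinom(100, 1, 0.8)
    sc <- rnorm(100)
    h <- quantile(tt, 0.5)
    timeDependentAUC(sc, tt, st, h)
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)

  expect_error(timeDependentAUC(score, time, status, 1e9), "survivors")
})

test_that("clinical association dispatches the right test", {
  # balanced 2x2: chi-square 0, p = 1
  a <- rep(c("high", "low"), each = 20)
  f <- rep(c("m", "f", "m", "f"), each = 10)
  res <- clinicalAssociation(a, f)
  expect_equal(res$test, "chi-square")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # strongly unbalanced small table: Fisher exact, enumerated tail
  x <- rep(c("high", "low"), c(10, 10))
  g <- c(rep("m", 1), rep("f", 9), rep("m", 9), rep("f", 1))
  res2 <- clinicalAssociation(x, g)
  expect_equal(res2$test, "fisher")
  expect_equal(res2$p, 202 / 184756, tolerance = 1e-9)

  # numeric score vs 2 levels: Wilcoxon; vs 3 identical groups: KW p = 1
  set.seed(3)
  sc <- rnorm(30)
  expect_equal(clinicalAssociation(sc, rep(c("a", "b"), 15))$test, "wilcoxon")
  sc3 <- rep(rnorm(10), 3)
  lev <- rep(c("a", "b", "c"), each = 10)
  res3 <- clinicalAssociation(sc3, lev)
  expect_equal(res3$test, "kruskal-wallis")
  expect_equal(res3$p, 1, tolerance = 1e-9)

  expect_error(clinicalAssociation(sc, rep(NA, 30)), "missing")
  expect_error(clinicalAssociation(sc, rep("a", 30)), "constant")
})
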