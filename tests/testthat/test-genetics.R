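test_that("Hardy-Weinberg test matches hand-computed chi-squares", {
  # exact equilibrium
  h0 <- hweTest(25, 50, 25)
  expect_equal(h0$chisq, 0, tolerance = 1e-12)
  expect_equal(h0$p, 1)

  # (30, 40, 30): allele freq 0.5, expected (25, 50, 25), chi-square 4
  h1 <- hweTest(30, 40, 30)
  expect_equal(h1$chisq, 4.0, tolerance = 1e-12)
  expect_equal(h1$expected, c(25, 50, 25))

  expect_warning(h2 <- hweTest(100, 0, 0), "monomorphic")
  expect_equal(h2$chisq, 0)
  expect_error(hweTest(0, 0, 0), "zero")
})

test_that("odds ratio: direct formula, symmetry, zero-cell correction", {
  # ad/bc = 2*2/(1*1)
  est <- oddsRatio(2, 1, 1, 2)
  expect_equal(est$or, 4.0)

  # balanced table: OR 1, CI symmetric on the log scale
  est1 <- oddsRatio(10, 10, 10, 10)
  expect_equal(est1$or, 1)
  expect_equal(log(est1$ci_high), -log(est1$ci_low), tolerance = 1e-12)

  # swapping case/control rows inverts the OR exactly
  a <- 13; b <- 7; cc <- 5; d <- 19
  expect_equal(oddsRatio(cc, d, a, b)$or, 1 / oddsRatio(a, b, cc, d)$or,
               tolerance = 1e-12)

  # zero cell: Haldane-Anscombe correction flagged
  est0 <- oddsRatio(0, 10, 5, 5)
  expect_true(est0$corrected)
  expect_equal(est0$or, (0.5 * 5.5) / (10.5 * 5.5))

  expect_error(oddsRatio(0, 0, 5, 5), "zero row")
})

test_that("odds ratio and the saturated logistic fit agree on random tables", {
  set.seed(71)
  for (i in 1:20) {
    cells <- sample(5:60, 4)
    est <- oddsRatio(cells[1], cells[2], cells[3], cells[4])
    subj <- expandCounts(cells[1], cells[2], cells[3], cells[4])
    fit <- logisticFit(subj, case ~ carrier)
    row <- fit$coefficients[fit$coefficients$term == "carrier", ]
    expect_equal(row$or, est$or, tolerance = 1e-6)
    expect_equal(row$ci_low, est$ci_low, tolerance = 1e-6)
    expect_equal(row$ci_high, est$ci_high, tolerance = 1e-6)
  }
})

test_that("logistic fit rejects aliased terms and holds its type-I error", {
  subj <- simulateCaseControl(caseControlSpec(seed = 5))
  subj$dup <- subj$carrier
  expect_error(logisticFit(subj, case ~ carrier + dup), "aliased")

  set.seed(72)
  rej <- vapply(1:2000, function(i) {
    x <- rbinom(2000, 1, 0.3)
    y <- rbinom(2000, 1, 0.4)
    fit <- logisticFit(data.frame(x = x, y = y), y ~ x)
    fit$coefficients$p[fit$coefficients$term == "x"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("planted genotype, exposure and interaction effects are recovered", {
  covered <- vapply(1:50, function(s) {
    subj <- simulateCaseControl(caseControlSpec(
      n_cases = 10000, n_controls = 10000, maf = 0.2, or_g = 0.6,
      exposure_prev = 0.3, or_e = 1.8, or_int = 2, seed = s))
    fit <- logisticFit(subj, case ~ carrier * exposed)
    tab <- fit$coefficients
    g_row <- tab[tab$term == "carrier", ]
    e_row <- tab[tab$term == "exposed", ]
    mi <- multiplicativeInteraction(fit)
    c(g = g_row$ci_low <= 0.6 && 0.6 <= g_row$ci_high,
      e = e_row$ci_low <= 1.8 && 1.8 <= e_row$ci_high,
      int = mi$ci_low <= 2 && 2 <= mi$ci_high)
  }, logical(3))
  expect_gte(mean(covered["g", ]), 0.9)
  expect_gte(mean(covered["e", ]), 0.9)
  expect_gte(mean(covered["int", ]), 0.9)
})

test_that("crossover analysis: null case, collapsibility, planted joint effects", {
  # all four cells with identical case fractions: every joint OR = 1
  d <- expand.grid(carrier = c(0, 1), exposed = c(0, 1), rep = 1:50)
  d$case <- as.integer(d$rep <= 25)   # every cell: 25 cases / 25 controls
  co <- crossoverAnalysis(d)
  expect_equal(co$or, rep(1, 3), tolerance = 1e-8)

  # no-confounding construction: collapsing exposure reproduces the marginal OR
  set.seed(73)
  subj <- simulateCaseControl(caseControlSpec(
    n_cases = 8000, n_controls = 8000, maf = 0.2, or_g = 0.6,
    exposure_prev = 0.3, or_e = 1, or_int = 1, seed = 4))
  tab <- table(subj$carrier, subj$case)
  marg <- oddsRatio(tab["1", "1"], tab["0", "1"], tab["1", "0"], tab["0", "0"])
  fit <- logisticFit(subj, case ~ carrier)
  expect_equal(fit$coefficients$or[2], marg$or, tolerance = 1e-6)

  # planted joint odds ratios are covered by their CIs in most seeds
  covered <- vapply(1:50, function(s) {
    subj <- simulateCaseControl(caseControlSpec(
      n_cases = 10000, n_controls = 10000, maf = 0.3, or_g = 2,
      exposure_prev = 0.3, or_e = 1.5, or_int = 1, seed = 100 + s))
    co <- crossoverAnalysis(subj)
    truth <- c(g_only = 2, e_only = 1.5, both = 2 * 1.5 * 1)
    setNames(co$ci_low <= truth[co$category] & truth[co$category] <= co$ci_high,
             co$category)
  }, logical(3))
  expect_gte(mean(covered["g_only", ]), 0.9)
  expect_gte(mean(covered["e_only", ]), 0.9)
  expect_gte(mean(covered["both", ]), 0.9)
})

test_that("additive interaction: identities, direct values, delta vs bootstrap CI", {
  # build a fit with prescribed joint odds ratios via a large balanced design
  make_fit <- function(or_g, or_e, or_int, n = 40000, seed = 74) {
    subj <- simulateCaseControl(caseControlSpec(
      n_cases = n / 2, n_controls = n / 2, maf = 0.35, or_g = or_g,
      exposure_prev = 0.4, or_e = or_e, or_int = or_int, seed = seed))
    logisticFit(subj, case ~ carrier * exposed)
  }

  # exact additivity at the coefficient level: RERI = 0, AP = 0, S = 1
  fit <- make_fit(2, 2, 1.5, seed = 75)
  b <- setNames(fit$coefficients$beta, fit$coefficients$term)
  V <- fit$vcov
  # overwrite with exact values but keep the covariance structure
  fit_add <- fit
  fit_add$coefficients$beta[fit_add$coefficients$term == "carrier"] <- log(2)
  fit_add$coefficients$beta[fit_add$coefficients$term == "exposed"] <- log(3)
  fit_add$coefficients$beta[fit_add$coefficients$term == "carrier:exposed"] <-
    log(4) - log(2) - log(3)
  ai_add <- additiveInteraction(fit_add)
  expect_equal(ai_add$reri, 0, tolerance = 1e-12)
  expect_equal(ai_add$ap, 0, tolerance = 1e-12)
  expect_equal(ai_add$s, 1, tolerance = 1e-12)

  # direct formula evaluation: OR10 = 2, OR01 = 2, OR11 = 6
  fit_dir <- fit
  fit_dir$coefficients$beta[fit_dir$coefficients$term == "carrier"] <- log(2)
  fit_dir$coefficients$beta[fit_dir$coefficients$term == "exposed"] <- log(2)
  fit_dir$coefficients$beta[fit_dir$coefficients$term == "carrier:exposed"] <-
    log(6) - log(4)
  ai <- additiveInteraction(fit_dir)
  expect_equal(ai$reri, 3)
  expect_equal(ai$ap, 0.5)
  expect_equal(ai$s, 2.5)

  # RERI = 0 <=> AP = 0 <=> S = 1 on random coefficient sets where S is defined
  set.seed(76)
  for (i in 1:20) {
    f2 <- fit
    bg <- runif(1, 0.1, 1); be <- runif(1, 0.1, 1)
    f2$coefficients$beta[f2$coefficients$term == "carrier"] <- bg
    f2$coefficients$beta[f2$coefficients$term == "exposed"] <- be
    f2$coefficients$beta[f2$coefficients$term == "carrier:exposed"] <-
      log(exp(bg) + exp(be) - 1) - bg - be   # forces RERI = 0
    a2 <- additiveInteraction(f2)
    expect_equal(a2$reri, 0, tolerance = 1e-10)
    expect_equal(a2$ap, 0, tolerance = 1e-10)
    expect_equal(a2$s, 1, tolerance = 1e-10)
  }

  # delta-method CI vs parametric bootstrap from the same covariance
  fit_int <- make_fit(1.6, 1.6, 1.8, seed = 77)
  ai2 <- additiveInteraction(fit_int)
  terms <- c("carrier", "exposed", "carrier:exposed")
  bhat <- setNames(fit_int$coefficients$beta, fit_int$coefficients$term)[terms]
  Vt <- fit_int$vcov[terms, terms]
  set.seed(78)
  draws <- MASS::mvrnorm(10000, bhat, Vt)
  reri_draws <- exp(rowSums(draws)) - exp(draws[, 1]) - exp(draws[, 2]) + 1
  boot_ci <- quantile(reri_draws, c(0.025, 0.975))
  width <- diff(ai2$reri_ci)
  expect_lt(abs(ai2$reri_ci[1] - boot_ci[1]) / width, 0.05)
  expect_lt(abs(ai2$reri_ci[2] - boot_ci[2]) / width, 0.05)

  # S undefined when both main-effect ORs are protective
  fit_und <- fit
  fit_und$coefficients$beta[fit_und$coefficients$term %in%
                              c("carrier", "exposed")] <- log(0.7)
  ai_und <- additiveInteraction(fit_und)
  expect_true(is.na(ai_und$s))
  expect_match(ai_und$s_note, "undefined")
})

test_that("multiplicative interaction reports the product-term OR", {
  subj <- simulateCaseControl(caseControlSpec(
    n_cases = 20000, n_controls = 20000, maf = 0.3, or_g = 1.5,
    exposure_prev = 0.4, or_e = 1.5, or_int = 1, seed = 79))
  fit <- logisticFit(subj, case ~ carrier * exposed)
  mi <- multiplicativeInteraction(fit)
  # multiplicative null: interaction OR near 1, CI covers 1
  expect_lte(mi$ci_low, 1)
  expect_gte(mi$ci_high, 1)

  fit2 <- logisticFit(subj, case ~ carrier + exposed)
  expect_error(multiplicativeInteraction(fit2), "absent")

  # a product column identical to a main effect is aliased
  subj$ge <- subj$carrier  # exposure constant at 1 would make g:e == g
  expect_error(logisticFit(subj, case ~ carrier + ge), "aliased")
})
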