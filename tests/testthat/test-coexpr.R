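test_that("topological overlap matches hand values and the triple-loop oracle", {
  # fully connected 3-node unit adjacency: TOM_ij = (1 + 1)/(2 + 1 - 1) = 1
  a3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(tomSimilarity(a3), matrix(1, 3, 3))

  # two isolated nodes with no shared neighbors: TOM = 0
  a0 <- matrix(0, 2, 2)
  t0 <- tomSimilarity(a0)
  expect_equal(t0[1, 2], 0)
  expect_equal(diag(t0), c(1, 1))

  # random 6-node networks against the naive implementation
  set.seed(61)
  for (i in 1:10) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tomSimilarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }

  expect_error(tomSimilarity(matrix(c(0, 1, 0.5, 0), 2, 2)), "symmetric")
  expect_error(tomSimilarity(matrix(c(0, 2, 2, 0), 2, 2)), "\\[0, 1\\]")
  expect_error(tomSimilarity(diag(2)), "diagonal")
})

test_that("scale-free fit rises with the power on structured data, falls back on noise", {
  e <- simulateFactorExpression(n_samples = 100,
                                block_sizes = c(80, 50, 30, 20, 10),
                                n_noise_genes = 110, noise_sd = 1, seed = 2)
  ps <- suppressWarnings(pickSoftThreshold(e))
  r2 <- ps$fit_table$r_squared
  expect_gt(cor(ps$fit_table$beta, r2), 0.7)     # fit improves with power
  expect_gt(max(r2), r2[1])
  # reproducible with the same seed
  ps2 <- suppressWarnings(pickSoftThreshold(
    simulateFactorExpression(n_samples = 100,
                             block_sizes = c(80, 50, 30, 20, 10),
                             n_noise_genes = 110, noise_sd = 1, seed = 2)))
  expect_identical(ps$beta, ps2$beta)

  # independent Gaussian genes never reach the target: argmax fallback warns
  set.seed(3)
  null <- matrix(rnorm(300 * 100), 300, 100,
                 dimnames = list(sprintf("g%03d", 1:300), sprintf("s%03d", 1:100)))
  expect_warning(pn <- pickSoftThreshold(null), "argmax")
  expect_false(pn$reached_target)
  expect_true(all(pn$fit_table$r_squared < 0.9))

  # the fit table is invariant to gene order
  perm <- sample(nrow(e))
  ps3 <- suppressWarnings(pickSoftThreshold(e[perm, ]))
  expect_equal(ps3$fit_table, ps$fit_table, tolerance = 1e-12)
})

test_that("module detection recovers planted blocks and honors merge_height", {
  e <- simulateFactorExpression(n_samples = 100, block_sizes = c(100, 100),
                                n_noise_genes = 0, noise_sd = 0.5, seed = 6)
  blocks <- attr(e, "blocks")
  tom <- tomSimilarity(ERSScore:::.adjacency(e, 3))
  mods <- suppressMessages(detectModules(e, tom, min_size = 50,
                                         merge_height = 0.3))
  lab <- mods$modules
  expect_equal(length(setdiff(unique(lab), "grey")), 2L)
  # membership accuracy vs planted blocks (majority label per block)
  acc <- vapply(1:2, function(b) {
    tab <- table(lab[blocks == b])
    max(tab) / sum(tab)
  }, numeric(1))
  expect_true(all(acc >= 0.95))

  # merge_height 0: no merging
  mods0 <- suppressMessages(detectModules(e, tom, min_size = 50,
                                          merge_height = 0))
  expect_gte(length(setdiff(unique(mods0$modules), "grey")), 2L)

  # one perfect block: a single module, nothing grey
  e1 <- simulateFactorExpression(n_samples = 80, block_sizes = 60,
                                 n_noise_genes = 0, noise_sd = 0.2, seed = 7)
  tom1 <- tomSimilarity(ERSScore:::.adjacency(e1, 3))
  mods1 <- suppressMessages(detectModules(e1, tom1, min_size = 50,
                                          merge_height = 0.3,
                                          cut_height = 0.99))
  expect_equal(unique(unname(mods1$modules)), "turquoise")

  expect_error(detectModules(e1, tom1, min_size = 1000), "min_size")
})

test_that("module-trait correlation: identity, planted recovery, permutation null", {
  e <- simulateFactorExpression(n_samples = 100, block_sizes = c(80, 80),
                                n_noise_genes = 40, noise_sd = 0.8, seed = 8)
  tom <- tomSimilarity(ERSScore:::.adjacency(e, 3))
  mods <- suppressMessages(detectModules(e, tom, min_size = 50,
                                         merge_height = 0.3))
  E <- mods$eigengenes
  # trait equal to an eigengene correlates at |r| = 1 with its own module
  mt <- moduleTraitCorrelation(mods, E[, 1])
  expect_equal(abs(mt$r[mt$module == colnames(E)[1]]), 1, tolerance = 1e-9)

  # planted trait-linked module beats the others across seeds
  hits <- vapply(1:20, function(s) {
    ee <- simulateFactorExpression(n_samples = 80, block_sizes = c(60, 60),
                                   n_noise_genes = 30, noise_sd = 0.8,
                                   seed = s)
    trait <- attr(ee, "factors")[, 1] + rnorm(80, sd = 0.5)
    tt <- tomSimilarity(ERSScore:::.adjacency(ee, 3))
    mm <- suppressMessages(detectModules(ee, tt, min_size = 40,
                                         merge_height = 0.3))
    mt2 <- moduleTraitCorrelation(mm, trait)
    planted <- names(which.max(table(mm$modules[attr(ee, "blocks") == 1])))
    mt2$module[which.max(abs(mt2$r))] == planted
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # permuted trait gives uniform p (first module's eigengene)
  set.seed(9)
  ps <- vapply(1:200, function(i)
    moduleTraitCorrelation(mods, sample(E[, 1]))$p[1], numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(moduleTraitCorrelation(mods, rep(1, 100)), "constant")
})

test_that("hub ranking puts the planted hub first and ignores sample order", {
  hits <- vapply(1:20, function(s) {
    ee <- simulateFactorExpression(n_samples = 80, block_sizes = 50,
                                   n_noise_genes = 20, noise_sd = 1, seed = s)
    # plant a hub: a gene that is almost the latent factor itself
    hub <- "gene0001"
    ee[hub, ] <- attr(ee, "factors")[, 1] + rnorm(80, sd = 0.05)
    tt <- tomSimilarity(ERSScore:::.adjacency(ee, 3))
    mm <- suppressMessages(detectModules(ee, tt, min_size = 40,
                                         merge_height = 0.3,
                                         cut_height = 0.99))
    md <- mm$modules[hub]
    if (md == "grey") return(FALSE)
    hubRanking(mm, ee, md)$gene[1] == hub
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # ranking invariant to sample order
  ee <- simulateFactorExpression(n_samples = 60, block_sizes = c(40, 40),
                                 n_noise_genes = 0, noise_sd = 0.5, seed = 10)
  tt <- tomSimilarity(ERSScore:::.adjacency(ee, 3))
  mm <- suppressMessages(detectModules(ee, tt, min_size = 30, merge_height = 0.3))
  md <- setdiff(unique(mm$modules), "grey")[1]
  r1 <- hubRanking(mm, ee, md)
  perm <- sample(ncol(ee))
  mm_perm <- mm
  mm_perm$eigengenes <- mm$eigengenes[perm, , drop = FALSE]
  r2 <- hubRanking(mm_perm, ee[, perm], md)
  expect_equal(r2$gene, r1$gene)

  expect_error(hubRanking(mm, ee, "grey"), "grey")
})
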