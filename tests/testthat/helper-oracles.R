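# Independent reference implementations used as oracles. These are
# deliberately naive (explicit loops, direct formulas) and share no code
# with the package internals they check.

# Cox partial likelihood for a single covariate, no ties assumed.
oracle_coxpl <- function(beta, x, time, status) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-group log-rank via explicit risk sets: observed minus expected in
# group 1 with the hypergeometric variance.
oracle_logrank <- function(time, status, group) {
  g1 <- group == sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chisq = (O - E)^2 / V, O = O, E = E, V = V)
}

# Exhaustive maximally-selected cutpoint scan, coded independently:
# Nelson-Aalen scores by explicit loop, then the standardized linear
# rank statistic at every admissible threshold.
oracle_cutpoint <- function(score, time, status, minprop = 0.1) {
  n <- length(score)
  H <- numeric(n)
  for (i in seq_len(n)) {
    h <- 0
    for (t in sort(unique(time[status == 1]))) {
      if (t <= time[i]) h <- h + sum(time == t & status == 1) / sum(time >= t)
    }
    H[i] <- h
  }
  a <- status - H
  abar <- mean(a)
  cuts <- sort(unique(score))
  cuts <- cuts[-length(cuts)]
  best <- NULL
  for (cc in cuts) {
    high <- score > cc
    n1 <- sum(high)
    if (min(n1, n - n1) < ceiling(minprop * n)) next
    L <- sum(a[high])
    v <- n1 * (n - n1) / (n * (n - 1)) * sum((a - abar)^2)
    z <- (L - n1 * abar) / sqrt(v)
    if (is.null(best) || abs(z) > abs(best$statistic))
      best <- list(cutpoint = cc, statistic = z)
  }
  best
}

# Brute-force weighted running-sum enrichment score on a ranked list.
oracle_gsea_es <- function(scores, set, exponent = 1) {
  ord <- order(scores, decreasing = TRUE)
  g <- names(scores)[ord]; s <- scores[ord]
  nr <- sum(abs(s[g %in% set])^exponent)
  n_out <- sum(!g %in% set)
  run <- 0; best <- 0
  for (i in seq_along(g)) {
    if (g[i] %in% set) run <- run + abs(s[i])^exponent / nr
    else run <- run - 1 / n_out
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Naive single-sample enrichment score for one set in one sample.
oracle_ssgsea <- function(values, genes, set, exponent) {
  r <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  gg <- genes[ord]; rr <- r[ord]
  inset <- gg %in% set
  denom_in <- sum(rr[inset]^exponent)
  n_out <- sum(!inset)
  cdf_in <- cdf_out <- 0; total <- 0
  for (i in seq_along(gg)) {
    if (inset[i]) cdf_in <- cdf_in + rr[i]^exponent / denom_in
    else cdf_out <- cdf_out + 1 / n_out
    total <- total + (cdf_in - cdf_out)
  }
  unname(total)
}

# Triple-loop topological overlap.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Cumulative/dynamic AUC by direct pair counting (no censoring).
oracle_cd_auc <- function(score, time, horizon) {
  cases <- which(time <= horizon)
  controls <- which(time > horizon)
  tot <- 0
  for (i in cases) for (j in controls)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(cases) * length(controls))
}

# Harrell C by exhaustive usable-pair counting.
oracle_cindex <- function(score, time, status) {
  conc <- ties <- usable <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    early <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
    if (is.na(early)) next                      # tied times: skip
    late <- if (early == i) j else i
    if (status[early] != 1) next                # earlier subject censored
    usable <- usable + 1
    if (score[early] > score[late]) conc <- conc + 1
    else if (score[early] == score[late]) ties <- ties + 1
  }
  (conc + 0.5 * ties) / usable
}

# Proportional-hazards survival data with two covariates and optional
# uniform censoring; used by the risk-model tests.
make_ph_data <- function(n, beta = c(0.7, 0.3), h0 = 0.05, cens_max = NULL,
                         seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  t_event <- rexp(n, rate = h0 * exp(beta[1] * x1 + beta[2] * x2))
  if (is.null(cens_max)) {
    time <- t_event; status <- rep(1L, n)
  } else {
    cens <- runif(n, 0, cens_max)
    time <- pmin(t_event, cens); status <- as.integer(t_event <= cens)
  }
  data.frame(x1 = x1, x2 = x2, time = time, status = status)
}
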