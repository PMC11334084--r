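# Survival machinery: Kaplan-Meier, log-rank, maximally selected
# rank-statistic cutpoint, multivariable Cox, IPCW time-dependent ROC,
# and the clinical-feature association tests.

#' Kaplan-Meier estimate (product-limit, Greenwood variance, log-log CI)
#'
#' @param time,status follow-up time and 0/1 event indicator.
#' @param group optional per-sample group labels (one curve per level).
#' @return data.frame per group: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `ci_low`, `ci_high`.
#' @export
kmEstimate <- function(time, status, group = NULL) {
  .check_time_status(time, status)
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, status) ~ group,
                           conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep("all", length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor, surv = sm$surv,
             ci_low = sm$lower, ci_high = sm$upper,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-rank test across groups
#'
#' @param time,status follow-up time and event indicator.
#' @param group per-sample group labels (>= 2 non-empty levels).
#' @return list: `chisq`, `df`, `p`.
#' @export
logrankTest <- function(time, status, group) {
  .check_time_status(time, status)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(time, status) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

# Log-rank scores (martingale-residual form): a_i = status_i - H(t_i)
# with H the Nelson-Aalen cumulative hazard.
.logrank_scores <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  d <- vapply(ut, function(t) sum(time == t & status == 1), numeric(1L))
  n <- vapply(ut, function(t) sum(time >= t), numeric(1L))
  H_step <- cumsum(d / n)
  H_at <- function(t) {
    idx <- findInterval(t, ut)
    ifelse(idx == 0L, 0, H_step[pmax(idx, 1L)])
  }
  status - H_at(time)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans every threshold on the score that leaves at least
#' `minprop * n` samples on each side and selects the one maximizing the
#' absolute standardized log-rank statistic (linear rank statistic on
#' log-rank scores with its conditional permutation variance). The
#' reported log-rank p-value at the chosen split is the ordinary test
#' and is selection-biased; it is returned flagged as such.
#'
#' @param score numeric per-sample score.
#' @param time,status follow-up and event indicator.
#' @param minprop minimum group proportion (default 0.1).
#' @return list of class `CutpointResult`: `cutpoint` (largest score in
#'   the low group), `statistic` (standardized, at the chosen split),
#'   `n_low`, `n_high`, `logrank_p` (selection-biased), and the full
#'   `scan` table.
#' @export
optimalCutpoint <- function(score, time, status, minprop = 0.1) {
  .check_time_status(time, status)
  n <- length(score)
  if (length(unique(score)) < 2L) stop("all scores identical")
  if (sum(status) < 1L) stop("at least one event required")
  if (n < 2 / minprop) stop("too few samples for the requested minprop")
  a <- .logrank_scores(time, status)
  abar <- mean(a); ss <- sum((a - abar)^2)
  ord <- order(score)
  s_sorted <- score[ord]; a_sorted <- a[ord]
  cum_a <- cumsum(a_sorted)
  # candidate cuts after position k (low group = first k ordered samples),
  # only where the score actually changes
  ks <- which(diff(s_sorted) > 0)
  lo <- ceiling(minprop * n); hi <- n - ceiling(minprop * n)
  ks <- ks[ks >= lo & ks <= hi]
  if (!length(ks)) stop("no admissible split under minprop")
  stat <- vapply(ks, function(k) {
    n_high <- n - k
    L <- sum(a_sorted) - cum_a[k]           # sum over the high group
    v <- n_high * k / (n * (n - 1)) * ss
    (L - n_high * abar) / sqrt(v)
  }, numeric(1L))
  best <- which.max(abs(stat))
  k <- ks[best]
  cut <- s_sorted[k]
  grp <- factor(ifelse(score > cut, "high", "low"), levels = c("low", "high"))
  lr <- logrankTest(time, status, grp)
  structure(list(cutpoint = cut, statistic = stat[best],
                 n_low = k, n_high = n - k,
                 logrank_p = lr$p, logrank_p_note = "selection-biased",
                 scan = data.frame(cut = s_sorted[ks], statistic = stat)),
            class = "CutpointResult")
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; aliased (linearly
#' dependent) covariate columns are dropped with a warning. The Breslow
#' baseline cumulative hazard is retained for risk-model predictions.
#'
#' @param covariates data.frame or matrix of covariates (numeric or
#'   factors).
#' @param time,status follow-up and event indicator.
#' @param ties "efron" (default) or "breslow".
#' @return list of class `CoxModelFit`: `model` (the underlying fit),
#'   `coefficients` table with HR and Wald 95% CI, `loglik`,
#'   `basehaz` (Breslow cumulative hazard at the covariate means),
#'   `means`.
#' @export
coxFit <- function(covariates, time, status, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_time_status(time, status)
  if (sum(status) < 1L) stop("at least one event required")
  df <- as.data.frame(covariates)
  df$.time <- time; df$.status <- status
  fit <- survival::coxph(
    survival::Surv(.time, .status) ~ .,
    data = df, ties = ties, x = TRUE)
  if (!fit$iter || is.null(coef(fit))) stop("Cox fit failed")
  cf <- coef(fit)
  if (any(is.na(cf))) {
    warning("aliased covariate(s) dropped: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (any(!is.finite(cf[!is.na(cf)])) || any(abs(cf[!is.na(cf)]) > 20))
    stop("Cox fit did not converge (possible separation); |beta| diverges")
  ok <- !is.na(cf)
  v <- diag(fit$var)
  # coxph keeps a full-dimension variance with zero rows for aliased terms
  se <- if (length(v) == length(cf)) sqrt(v[ok]) else sqrt(v)
  tab <- data.frame(term = names(cf)[ok], beta = unname(cf[ok]),
                    hr = exp(unname(cf[ok])),
                    ci_low = exp(unname(cf[ok]) - qnorm(0.975) * se),
                    ci_high = exp(unname(cf[ok]) + qnorm(0.975) * se),
                    p = 2 * pnorm(-abs(unname(cf[ok]) / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  bh <- survival::basehaz(fit, centered = TRUE)
  if (any(diff(bh$hazard) < -1e-12)) stop("baseline cumulative hazard not monotone")
  structure(list(model = fit, coefficients = tab,
                 loglik = fit$loglik[length(fit$loglik)],
                 basehaz = bh, means = fit$means),
            class = "CoxModelFit")
}

#' Time-dependent AUC (cumulative/dynamic, IPCW)
#'
#' Cases are subjects with an observed event by the horizon, controls
#' those still under observation past it; case contributions are
#' weighted by the inverse probability of remaining uncensored
#' (Kaplan-Meier of the censoring distribution). Without censoring this
#' reduces to the empirical cumulative/dynamic AUC by pair counting.
#'
#' @param score risk score (higher = higher risk).
#' @param time,status follow-up and event indicator.
#' @param horizon evaluation time t.
#' @return AUC(t) as numeric(1).
#' @export
timeDependentAUC <- function(score, time, status, horizon) {
  .check_time_status(time, status)
  cases <- which(time <= horizon & status == 1)
  controls <- which(time > horizon)
  if (!length(cases)) stop("no events by the horizon")
  if (!length(controls)) stop("no survivors past the horizon")
  cfit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  G <- function(t) {
    # left-continuous censoring survival G(t-)
    vapply(t, function(ti) {
      idx <- which(cfit$time < ti)
      if (!length(idx)) 1 else max(min(cfit$surv[idx]), .Machine$double.eps)
    }, numeric(1L))
  }
  w <- 1 / G(time[cases])
  sc <- score[cases]; sk <- score[controls]
  conc <- vapply(seq_along(sc), function(i)
    sum((sc[i] > sk) + 0.5 * (sc[i] == sk)), numeric(1L))
  sum(w * conc) / (sum(w) * length(sk))
}

#' Association between a score (or its groups) and a clinical feature
#'
#' Categorical vs categorical: Pearson chi-square, switching to Fisher's
#' exact test for small tables (any expected count below 5, or total n
#' below 40 for a 2x2). Numeric score vs a 2-level feature: Wilcoxon
#' rank-sum; vs 3+ levels: Kruskal-Wallis.
#'
#' @param x score values (numeric) or group labels (character/factor).
#' @param feature clinical feature (character/factor).
#' @return list: `test`, `statistic`, `p`, `table` (categorical case).
#' @export
clinicalAssociation <- function(x, feature) {
  if (all(is.na(feature))) stop("feature is all missing")
  keep <- !is.na(feature)
  x <- x[keep]; feature <- as.factor(as.character(feature[keep]))
  if (nlevels(feature) < 2L) stop("feature is constant")
  if (is.numeric(x)) {
    if (nlevels(feature) == 2L) {
      ht <- suppressWarnings(wilcox.test(x ~ feature))
      return(list(test = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value))
    }
    ht <- kruskal.test(x, feature)
    return(list(test = "kruskal-wallis", statistic = unname(ht$statistic), p = ht$p.value))
  }
  x <- as.factor(as.character(x))
  tab <- table(x, feature)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- any(expected < 5) || (all(dim(tab) == 2L) && sum(tab) < 40)
  if (small) {
    ht <- fisher.test(tab)
    return(list(test = "fisher", statistic = NA_real_, p = ht$p.value, table = tab))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(test = "chi-square", statistic = unname(ht$statistic), p = ht$p.value,
       table = tab)
}
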