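# Nomogram-equivalent risk model: Cox-based survival prediction at fixed
# horizons, Harrell concordance with bootstrap CI, bootstrap calibration,
# and decision-curve net benefit.

#' Build a risk model from a Cox fit
#'
#' Fits a multivariable Cox model (score + age + stage by default) and
#' derives the nomogram ingredients: a 0-100 points scale per covariate
#' (the covariate with the largest |beta| x range spans 100 points) and
#' the Breslow baseline survival at the requested horizons.
#'
#' @param covariates data.frame of numeric covariates (factors must be
#'   pre-coded numerically for the points scale).
#' @param time,status follow-up and event indicator.
#' @param horizons prediction horizons in the cohort's time unit.
#' @return list of class `RiskModel`: the underlying `CoxModelFit`,
#'   `points` (per-covariate scale), `baseline_surv` at the horizons,
#'   `ranges` of the training covariates.
#' @export
buildRiskModel <- function(covariates, time, status, horizons = c(12, 36, 60)) {
  covariates <- as.data.frame(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1L))))
    stop("covariates must be numeric (code factors before fitting)")
  fit <- coxFit(covariates, time, status)
  cf <- setNames(fit$coefficients$beta, fit$coefficients$term)
  rng <- vapply(covariates[names(cf)], function(x) diff(range(x)), numeric(1L))
  span <- abs(cf) * rng
  pts <- 100 * span / max(span)
  bh <- fit$basehaz
  S0 <- vapply(horizons, function(h) {
    idx <- which(bh$time <= h)
    if (!length(idx)) 1 else exp(-bh$hazard[max(idx)])
  }, numeric(1L))
  structure(list(fit = fit, points = pts,
                 baseline_surv = setNames(S0, paste0("t", horizons)),
                 horizons = horizons,
                 ranges = vapply(covariates[names(cf)], range, numeric(2L))),
            class = "RiskModel")
}

#' Predict survival probability at a horizon
#'
#' `S(t | x) = S0(t)^exp(beta . (x - xbar))` with the Breslow baseline
#' cumulative hazard at the training covariate means. Covariate values
#' outside the training range are predicted with a warning.
#'
#' @param model a `RiskModel` (or `CoxModelFit`).
#' @param newdata data.frame of covariates.
#' @param horizon evaluation time.
#' @return numeric vector of survival probabilities in (0, 1].
#' @export
predictSurvival <- function(model, newdata, horizon) {
  fit <- if (inherits(model, "RiskModel")) model$fit else model
  stopifnot(inherits(fit, "CoxModelFit"))
  bh <- fit$basehaz
  if (horizon > max(bh$time)) stop("horizon beyond observed follow-up")
  cf <- setNames(fit$coefficients$beta, fit$coefficients$term)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(names(cf), colnames(newdata))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(newdata[names(cf)])
  if (inherits(model, "RiskModel")) {
    out_of_range <- vapply(names(cf), function(nm)
      any(newdata[[nm]] < model$ranges[1L, nm] | newdata[[nm]] > model$ranges[2L, nm]),
      logical(1L))
    if (any(out_of_range))
      warning("covariate(s) outside the training range: ",
              paste(names(cf)[out_of_range], collapse = ", "))
  }
  lp <- drop(x %*% cf) - sum(cf * fit$means[names(cf)])
  idx <- which(bh$time <= horizon)
  H0 <- if (!length(idx)) 0 else bh$hazard[max(idx)]
  unname(exp(-H0)^exp(lp))
}

#' Harrell concordance index with percentile bootstrap CI
#'
#' C over usable pairs: among pairs where ordering is determinable
#' (the earlier subject experienced the event), the fraction in which
#' the higher-risk subject fails earlier, ties in the score counting
#' one half. The CI resamples subjects.
#'
#' @param score risk score (higher = higher risk).
#' @param time,status follow-up and event indicator.
#' @param B bootstrap replicates for the CI (default 200; 0 skips it).
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return list: `c_index`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
concordanceIndex <- function(score, time, status, B = 200L, conf = 0.95,
                             seed = NULL) {
  .check_time_status(time, status)
  cc <- survival::concordance(survival::Surv(time, status) ~ score,
                              reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no usable pairs")
  ci <- c(NA_real_, NA_real_)
  if (B > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(time)
    boots <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, replace = TRUE)
      if (sum(status[idx]) == 0L || length(unique(score[idx])) < 2L) return(NA_real_)
      survival::concordance(survival::Surv(time[idx], status[idx]) ~ score[idx],
                            reverse = TRUE)$concordance
    }, numeric(1L))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(c_index = unname(cc$concordance), ci_low = ci[1L], ci_high = ci[2L],
       n_pairs = unname(n_pairs))
}

#' Calibration of predicted vs observed survival at a horizon
#'
#' Subjects are binned into quantile groups of predicted survival;
#' observed survival per group is the Kaplan-Meier estimate at the
#' horizon. With `B > 0`, a bootstrap-refit optimism correction is
#' subtracted from the apparent predictions (the mean gap between each
#' refitted model's predictions on its bootstrap sample and on the
#' original data, averaged within group).
#'
#' @param covariates training covariates (numeric data.frame).
#' @param time,status follow-up and event indicator.
#' @param horizon evaluation time.
#' @param n_groups number of quantile groups (>= 2).
#' @param B bootstrap replicates (0 = apparent calibration only).
#' @param seed optional seed.
#' @return data.frame per group: `group`, `n`, `predicted`, `observed`,
#'   `flagged` (no events and no survivors past the horizon).
#' @export
calibrationTable <- function(covariates, time, status, horizon,
                             n_groups = 3L, B = 0L, seed = NULL) {
  if (n_groups < 2L) stop("n_groups must be >= 2")
  covariates <- as.data.frame(covariates)
  if (all(vapply(covariates, sd, numeric(1L)) == 0)) {
    # constant predictor: one effective group, observed = overall KM
    km <- kmEstimate(time, status)
    idx <- which(km$time <= horizon & km$n_event > 0)
    s <- if (!length(idx)) 1 else km$surv[max(idx)]
    return(data.frame(group = 1L, n = length(time), predicted = s,
                      observed = s, flagged = FALSE))
  }
  fit <- coxFit(covariates, time, status)
  pred <- predictSurvival(fit, covariates, horizon)
  if (length(unique(pred)) < n_groups) {
    grp <- factor(rep(1L, length(pred)))
  } else {
    brk <- unique(quantile(pred, probs = seq(0, 1, length.out = n_groups + 1L)))
    grp <- cut(pred, breaks = brk, include.lowest = TRUE, labels = FALSE)
    grp <- factor(grp)
  }
  optimism <- rep(0, nlevels(grp))
  if (B > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(time)
    acc <- matrix(NA_real_, nrow = B, ncol = nlevels(grp))
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      bfit <- tryCatch(coxFit(covariates[idx, , drop = FALSE], time[idx], status[idx]),
                       error = function(e) NULL, warning = function(w) NULL)
      if (is.null(bfit)) next
      p_boot <- predictSurvival(bfit, covariates[idx, , drop = FALSE], horizon)
      p_orig <- predictSurvival(bfit, covariates, horizon)
      g_boot <- grp[idx]
      for (g in seq_len(nlevels(grp))) {
        acc[b, g] <- mean(p_boot[g_boot == levels(grp)[g]]) -
          mean(p_orig[grp == levels(grp)[g]])
      }
    }
    optimism <- colMeans(acc, na.rm = TRUE)
    optimism[is.nan(optimism)] <- 0
  }
  rows <- lapply(seq_len(nlevels(grp)), function(g) {
    sel <- grp == levels(grp)[g]
    km <- kmEstimate(time[sel], status[sel])
    idx <- which(km$time <= horizon & km$n_event > 0)
    obs <- if (!length(idx)) 1 else km$surv[max(idx)]
    flagged <- sum(status[sel] == 1 & time[sel] <= horizon) == 0 &&
      sum(time[sel] > horizon) == 0
    data.frame(group = g, n = sum(sel),
               predicted = mean(pred[sel]) - optimism[g], observed = obs,
               flagged = flagged)
  })
  do.call(rbind, rows)
}

#' Decision-curve net benefit
#'
#' At each risk threshold `p_t`, subjects whose predicted event risk at
#' the horizon reaches the threshold are "treated"; net benefit is
#' `TP/n - FP/n * p_t / (1 - p_t)`. Event status at the horizon is
#' estimated by Kaplan-Meier within the treated (and overall, for the
#' treat-all reference), which accounts for censoring; with complete
#' follow-up this reduces to direct counting. Treat-none is identically
#' zero.
#'
#' @param risk predicted event risk per subject (1 - predicted survival).
#' @param time,status follow-up and event indicator.
#' @param horizon evaluation time.
#' @param thresholds grid of thresholds, all in (0, 1).
#' @return data.frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decisionCurve <- function(risk, time, status, horizon,
                          thresholds = seq(0.05, 0.6, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be in (0, 1)")
  .check_time_status(time, status)
  n <- length(risk)
  event_prob <- function(sel) {
    if (!any(sel)) return(0)
    km <- kmEstimate(time[sel], status[sel])
    idx <- which(km$time <= horizon & km$n_event > 0)
    s <- if (!length(idx)) 1 else km$surv[max(idx)]
    1 - s
  }
  prev <- event_prob(rep(TRUE, n))
  rows <- lapply(thresholds, function(pt) {
    treated <- risk >= pt
    odds <- pt / (1 - pt)
    p_treat <- mean(treated)
    pe <- event_prob(treated)
    nb <- p_treat * pe - p_treat * (1 - pe) * odds
    nb_all <- prev - (1 - prev) * odds
    data.frame(threshold = pt, nb_model = nb, nb_all = nb_all, nb_none = 0)
  })
  do.call(rbind, rows)
}
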