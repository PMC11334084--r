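# Case-control genetics: Hardy-Weinberg testing, odds ratios, logistic
# regression, crossover analysis, and additive (RERI/AP/S) and
# multiplicative interaction with delta-method confidence intervals.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the allele frequency from the genotype counts, forms the
#' expected counts `n * (p^2, 2pq, q^2)`, and reports the Pearson
#' chi-square with 1 degree of freedom. A monomorphic sample returns
#' chi-square 0 with a warning.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote,
#'   heterozygote, minor homozygote).
#' @return list: `chisq`, `df`, `p`, `allele_freq` (minor), `expected`.
#' @export
hweTest <- function(n_AA, n_Aa, n_aa) {
  obs <- c(n_AA, n_Aa, n_aa)
  if (any(obs < 0)) stop("negative count")
  n <- sum(obs)
  if (n == 0) stop("all counts zero")
  q <- (2 * n_aa + n_Aa) / (2 * n)
  p <- 1 - q
  if (q == 0 || q == 1) {
    warning("monomorphic sample")
    return(list(chisq = 0, df = 1L, p = 1, allele_freq = q,
                expected = n * c(p^2, 2 * p * q, q^2)))
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((obs - expected)^2 / expected)
  list(chisq = chisq, df = 1L, p = pchisq(chisq, 1L, lower.tail = FALSE),
       allele_freq = q, expected = expected)
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `OR = ad/bc` with the log-normal (Woolf) interval
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided Wald
#' p-value. Any zero cell triggers the Haldane-Anscombe +0.5 correction
#' (flagged); a fully zero row or column is an error.
#'
#' @param a,b cases: comparison-group count, reference-group count.
#' @param c,d controls: comparison-group count, reference-group count.
#' @param conf confidence level (default 0.95).
#' @return list of class `OrEstimate`: `or`, `ci_low`, `ci_high`, `p`,
#'   `corrected`, `coding`.
#' @export
oddsRatio <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("a full zero row or column makes the odds ratio undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  structure(list(or = exp(lor), ci_low = exp(lor - z * se),
                 ci_high = exp(lor + z * se),
                 p = 2 * pnorm(-abs(lor / se)), corrected = corrected,
                 coding = "comparison vs reference"),
            class = "OrEstimate")
}

#' Unconditional logistic regression with a coefficient/odds-ratio table
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least
#' squares) of a binary outcome on the supplied terms; each term is
#' reported as an odds ratio with Wald CI and p, and the full
#' variance-covariance matrix is retained for interaction confidence
#' intervals. Aliased terms and (quasi-)separation are errors.
#'
#' @param data data.frame of subjects.
#' @param formula model formula with a 0/1 outcome on the left.
#' @param conf confidence level.
#' @return list of class `LogisticFit`: `coefficients` (`term`, `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`), `vcov`, `model`.
#' @export
logisticFit <- function(data, formula, conf = 0.95) {
  fit <- glm(formula, data = data, family = binomial(),
             control = stats::glm.control(epsilon = 1e-10, maxit = 100L))
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("aliased term(s): ", paste(names(cf)[is.na(cf)], collapse = ", "))
  if (!fit$converged || any(abs(cf) > 15))
    stop("logistic fit did not converge (possible separation); |beta| = ",
         format(max(abs(cf)), digits = 3))
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf) / 2)
  tab <- data.frame(term = names(cf), beta = unname(cf), se = unname(se),
                    or = exp(unname(cf)),
                    ci_low = exp(unname(cf) - z * se),
                    ci_high = exp(unname(cf) + z * se),
                    p = 2 * pnorm(-abs(unname(cf) / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, vcov = vcov(fit), model = fit),
            class = "LogisticFit")
}

#' Crossover analysis of joint genotype-exposure categories
#'
#' Forms the four joint categories of a binary genetic factor and a
#' binary exposure and estimates the odds ratio of each non-reference
#' category against the chosen reference cell via logistic regression
#' with category indicators (optionally age-adjusted). When a
#' non-reference cell is empty the per-category odds ratios fall back
#' to 2x2 tables with the Haldane correction, flagged in the output.
#'
#' @param data subject data.frame with 0/1 columns for the genetic
#'   factor, the exposure and the case status.
#' @param g,e,case column names of the genetic factor, exposure and
#'   outcome.
#' @param reference length-2 0/1 vector `c(g, e)` naming the reference
#'   cell (default `c(0, 0)`).
#' @param adjust optional covariate column names (e.g. "age").
#' @return data.frame per non-reference category: `category` ("g_only",
#'   "e_only", "both"), `or`, `ci_low`, `ci_high`, `p`, `corrected`;
#'   the underlying `LogisticFit` (when used) in `attr(, "fit")`.
#' @export
crossoverAnalysis <- function(data, g = "carrier", e = "exposed",
                              case = "case", reference = c(0, 0),
                              adjust = NULL) {
  gi <- as.integer(data[[g]] != reference[1L])
  ei <- as.integer(data[[e]] != reference[2L])
  y <- data[[case]]
  cat4 <- factor(paste0(gi, ei), levels = c("00", "10", "01", "11"),
                 labels = c("ref", "g_only", "e_only", "both"))
  if (sum(cat4 == "ref") == 0L) stop("reference cell is empty")
  counts <- table(cat4, y)
  empty <- rownames(counts)[rowSums(counts) == 0]
  if (length(setdiff(empty, "ref"))) {
    warning("empty non-reference cell; falling back to Haldane-corrected 2x2 tables")
    rows <- lapply(c("g_only", "e_only", "both"), function(lv) {
      a <- sum(y == 1 & cat4 == lv); b <- sum(y == 1 & cat4 == "ref")
      cc <- sum(y == 0 & cat4 == lv); dd <- sum(y == 0 & cat4 == "ref")
      est <- oddsRatio(a, b, cc, dd)
      data.frame(category = lv, or = est$or, ci_low = est$ci_low,
                 ci_high = est$ci_high, p = est$p, corrected = TRUE,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  df <- data.frame(.y = y, .cat = cat4)
  rhs <- ".cat"
  if (!is.null(adjust)) {
    for (v in adjust) df[[v]] <- data[[v]]
    rhs <- paste(c(".cat", adjust), collapse = " + ")
  }
  fit <- logisticFit(df, as.formula(paste(".y ~", rhs)))
  tab <- fit$coefficients
  sel <- grepl("^\\.cat", tab$term)
  out <- data.frame(category = sub("^\\.cat", "", tab$term[sel]),
                    or = tab$or[sel], ci_low = tab$ci_low[sel],
                    ci_high = tab$ci_high[sel], p = tab$p[sel],
                    corrected = FALSE, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Additive-scale interaction: RERI, AP and synergy index S
#'
#' From a logistic fit containing the two main effects and their
#' product, the joint odds ratios are `OR10 = exp(bg)`,
#' `OR01 = exp(be)` and `OR11 = exp(bg + be + bge)`, giving
#' `RERI = OR11 - OR10 - OR01 + 1`, `AP = RERI / OR11` and
#' `S = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))`. Confidence intervals
#' use the delta method on the fitted covariance (the standard
#' epidemiological formulation; S on the log scale). S is reported as
#' undefined when its denominator is not positive.
#'
#' @param fit a `LogisticFit` containing the three terms.
#' @param g,e,ge term names of the main effects and the product.
#' @param conf confidence level.
#' @return list of class `InteractionEstimate`: `reri`, `ap`, `s`, each
#'   with `*_ci`; `or10`, `or01`, `or11`; `s_note` when S is undefined.
#' @export
additiveInteraction <- function(fit, g = "carrier", e = "exposed",
                                ge = "carrier:exposed", conf = 0.95) {
  stopifnot(inherits(fit, "LogisticFit"))
  terms <- c(g, e, ge)
  miss <- setdiff(terms, fit$coefficients$term)
  if (length(miss)) stop("term(s) absent from the fit: ", paste(miss, collapse = ", "))
  b <- setNames(fit$coefficients$beta, fit$coefficients$term)[terms]
  V <- fit$vcov[terms, terms]
  z <- qnorm(1 - (1 - conf) / 2)
  or10 <- exp(b[1L]); or01 <- exp(b[2L]); or11 <- exp(sum(b))

  reri <- or11 - or10 - or01 + 1
  h_reri <- c(or11 - or10, or11 - or01, or11)
  se_reri <- sqrt(drop(t(h_reri) %*% V %*% h_reri))

  ap <- reri / or11
  h_ap <- c((or01 - 1) / or11, (or10 - 1) / or11, (or10 + or01 - 1) / or11)
  se_ap <- sqrt(drop(t(h_ap) %*% V %*% h_ap))

  denom <- (or10 - 1) + (or01 - 1)
  if (denom <= 0 || or11 <= 1) {
    s <- NA_real_; s_ci <- c(NA_real_, NA_real_)
    s_note <- "synergy index undefined (denominator or OR11 - 1 not positive)"
  } else {
    s <- (or11 - 1) / denom
    h_lns <- c(or11 / (or11 - 1) - or10 / denom,
               or11 / (or11 - 1) - or01 / denom,
               or11 / (or11 - 1))
    se_lns <- sqrt(drop(t(h_lns) %*% V %*% h_lns))
    s_ci <- exp(log(s) + c(-1, 1) * z * se_lns)
    s_note <- NULL
  }
  structure(list(
    reri = unname(reri), reri_ci = unname(reri + c(-1, 1) * z * se_reri),
    ap = unname(ap), ap_ci = unname(ap + c(-1, 1) * z * se_ap),
    s = unname(s), s_ci = unname(s_ci), s_note = s_note,
    or10 = unname(or10), or01 = unname(or01), or11 = unname(or11)),
    class = "InteractionEstimate")
}

#' Multiplicative interaction odds ratio
#'
#' The exponentiated product-term coefficient with its Wald CI and p.
#'
#' @param fit a `LogisticFit` containing the product term.
#' @param ge product-term name.
#' @return list of class `OrEstimate`: `or`, `ci_low`, `ci_high`, `p`.
#' @export
multiplicativeInteraction <- function(fit, ge = "carrier:exposed") {
  stopifnot(inherits(fit, "LogisticFit"))
  row <- fit$coefficients[fit$coefficients$term == ge, ]
  if (!nrow(row)) stop("product term absent from the fit: ", ge)
  structure(list(or = row$or, ci_low = row$ci_low, ci_high = row$ci_high,
                 p = row$p, corrected = FALSE,
                 coding = "departure from the multiplicative model"),
            class = "OrEstimate")
}

#' Expand pre-tabulated 2x2 counts to a subject table
#'
#' Convenience for feeding tabulated case-control genotype counts into
#' [logisticFit()].
#'
#' @param case_comparison,case_reference,control_comparison,control_reference
#'   the four cell counts (comparison = e.g. variant carriers).
#' @return data.frame with 0/1 columns `carrier` and `case`.
#' @export
expandCounts <- function(case_comparison, case_reference,
                         control_comparison, control_reference) {
  data.frame(
    carrier = rep(c(1L, 0L, 1L, 0L),
                  c(case_comparison, case_reference,
                    control_comparison, control_reference)),
    case = rep(c(1L, 1L, 0L, 0L),
               c(case_comparison, case_reference,
                 control_comparison, control_reference))
  )
}
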