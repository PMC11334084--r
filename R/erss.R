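# The core statistic: univariate Cox screening, sign-split gene
# clusters, and the PC1-difference score.

#' Univariate Cox screen per gene
#'
#' Fits a one-covariate proportional-hazards model per gene (partial
#' likelihood, Efron tie handling by default) and retains genes whose
#' Wald p-value is below `alpha`, partitioned by the sign of the
#' coefficient: cluster A collects hazard-increasing genes (beta > 0),
#' cluster B protective genes (beta < 0). Genes whose fit does not
#' converge are excluded with a warning.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param clinical data.frame with `time` and `status` (taken from
#'   `colData` when `expr` is a SummarizedExperiment).
#' @param alpha Wald significance threshold (default 0.05).
#' @param genes optional subset of genes to screen.
#' @param ties tie handling, "efron" (default) or "breslow".
#' @return data.frame (`gene`, `beta`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `retained`, `cluster`) with clusters also in
#'   `attr(, "clusters")`.
#' @export
univariateCoxScreen <- function(expr, clinical = NULL, alpha = 0.05,
                                genes = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  m <- .as_expr_matrix(expr)
  clin <- .get_clinical(expr, clinical)
  .check_time_status(clin$time, clin$status)
  if (sum(clin$status) < 1L) stop("no events in the cohort")
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) stop("gene(s) absent: ", paste(utils::head(miss, 5L), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  surv <- survival::Surv(clin$time, clin$status)
  out <- lapply(rownames(m), function(g) {
    x <- m[g, ]
    if (sd(x) == 0) return(data.frame(gene = g, beta = NA_real_, hr = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    fit <- tryCatch(
      survival::coxph(surv ~ x, ties = ties),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[1L])) {
      return(data.frame(gene = g, beta = NA_real_, hr = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    b <- unname(coef(fit)[1L]); se <- sqrt(fit$var[1L, 1L])
    data.frame(gene = g, beta = b, hr = exp(b),
               ci_low = exp(b - qnorm(0.975) * se),
               ci_high = exp(b + qnorm(0.975) * se),
               p = 2 * pnorm(-abs(b / se)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(is.na(res$beta)))
    warning(sum(is.na(res$beta)), " gene(s) excluded (constant or non-converged fit)")
  res$retained <- !is.na(res$p) & res$p < alpha
  res$cluster <- ifelse(!res$retained, NA_character_,
                        ifelse(res$beta > 0, "A", "B"))
  attr(res, "clusters") <- list(A = res$gene[res$retained & res$beta > 0],
                                B = res$gene[res$retained & res$beta < 0])
  res
}

# Shared worker: score a cohort given clusters, returning an ERSSModel.
.erss_fit <- function(m, clusterA, clusterB, mode) {
  all_genes <- c(clusterA, clusterB)
  if (!length(all_genes)) stop("both clusters empty")
  miss <- setdiff(all_genes, rownames(m))
  if (length(miss))
    stop("cluster gene(s) absent from the matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  if (length(intersect(clusterA, clusterB))) stop("clusters A and B overlap")
  sub <- m[all_genes, , drop = FALSE]
  mu <- rowMeans(sub); sdev <- apply(sub, 1L, sd)
  loadings <- list(); orientations <- numeric()
  comp <- function(cl) {
    if (!length(cl)) return(rep(0, ncol(m)))
    z <- (m[cl, , drop = FALSE] - mu[cl]) / sdev[cl]
    if (any(sdev[cl] == 0) || sum(apply(z, 1L, sd)) == 0)
      stop("cluster with zero total variance")
    pc <- .pc1_scores(z)
    key <- if (identical(cl, clusterA)) "A" else "B"
    loadings[[key]] <<- setNames(pc$loading, cl)
    orientations[key] <<- pc$orientation
    pc$scores
  }
  pa <- comp(clusterA)
  pb <- comp(clusterB)
  scores <- setNames(pa - pb, colnames(m))
  new("ERSSModel", clusterA = clusterA, clusterB = clusterB,
      loadings = loadings, orientations = orientations,
      center = mu, scale = sdev, scores = scores, mode = mode)
}

#' Compute the PC1-difference score
#'
#' Genes are z-scored across samples; each non-empty cluster's
#' samples x genes submatrix is decomposed and every sample receives its
#' coordinate on the cluster's first principal component, orientation-
#' fixed to correlate positively with the cluster's mean expression.
#' The score is `PC1A - PC1B` (an empty cluster contributes 0).
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param clusterA hazard-increasing gene ids.
#' @param clusterB protective gene ids (may be empty).
#' @return an [ERSSModel-class].
#' @export
computeERSS <- function(expr, clusterA, clusterB = character()) {
  m <- .as_expr_matrix(expr)
  .erss_fit(m, as.character(clusterA), as.character(clusterB), mode = "fit")
}

#' Score a new cohort with a trained signature
#'
#' `mode = "refit"` (default) re-runs the PC1 decomposition on the new
#' cohort using the training gene clusters — the usual way such
#' signatures are transferred when only the gene lists are considered
#' portable. `mode = "project"` applies the frozen training loadings and
#' orientations to the new cohort's z-scores, a strict signature
#' transfer.
#'
#' @param expr new cohort, genes x samples matrix or SummarizedExperiment.
#' @param ref trained [ERSSModel-class].
#' @param mode "refit" or "project".
#' @return an [ERSSModel-class] for the new cohort.
#' @export
scoreNewCohort <- function(expr, ref, mode = c("refit", "project")) {
  mode <- match.arg(mode)
  stopifnot(is(ref, "ERSSModel"))
  m <- .as_expr_matrix(expr)
  if (mode == "refit")
    return(.erss_fit(m, ref@clusterA, ref@clusterB, mode = "refit"))
  all_genes <- c(ref@clusterA, ref@clusterB)
  miss <- setdiff(all_genes, rownames(m))
  if (length(miss))
    stop("cluster gene(s) absent from the matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  sub <- m[all_genes, , drop = FALSE]
  mu <- rowMeans(sub); sdev <- apply(sub, 1L, sd)
  if (any(sdev == 0)) stop("cluster gene with zero variance in the new cohort")
  proj <- function(key, cl) {
    if (!length(cl)) return(rep(0, ncol(m)))
    z <- (m[cl, , drop = FALSE] - mu[cl]) / sdev[cl]
    drop(t(z) %*% ref@loadings[[key]]) * ref@orientations[[key]]
  }
  scores <- setNames(proj("A", ref@clusterA) - proj("B", ref@clusterB), colnames(m))
  new("ERSSModel", clusterA = ref@clusterA, clusterB = ref@clusterB,
      loadings = ref@loadings, orientations = ref@orientations,
      center = mu, scale = sdev, scores = scores, mode = "project")
}
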