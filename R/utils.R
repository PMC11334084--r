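# Internal helpers shared across modules.

#' @importFrom methods new validObject is
#' @importFrom stats sd cor cor.test prcomp rnorm runif rexp rpois rbinom
#'   quantile median pchisq pnorm qnorm phyper p.adjust wilcox.test
#'   kruskal.test chisq.test fisher.test glm binomial coef vcov uniroot
#'   setNames complete.cases plogis hclust cutree as.dist lm predict
#'   as.formula model.matrix aggregate
#' @importFrom utils read.delim write.table packageVersion head
NULL

# Extract a genes x samples numeric matrix from a matrix or a
# SummarizedExperiment (first assay).
.as_expr_matrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, 1L)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("expression input must be a matrix or a SummarizedExperiment")
  }
  if (!is.numeric(m)) stop("expression values must be numeric")
  if (is.null(rownames(m))) stop("expression matrix must have gene ids as rownames")
  m
}

.get_clinical <- function(x, clinical = NULL) {
  if (!is.null(clinical)) return(as.data.frame(clinical))
  if (is(x, "SummarizedExperiment")) {
    return(as.data.frame(SummarizedExperiment::colData(x)))
  }
  stop("clinical table required (supply `clinical` or a SummarizedExperiment)")
}

# Row-wise z-score; genes with zero variance raise an error unless
# `allow_constant`, in which case they are centred only.
.zscore_rows <- function(m, allow_constant = FALSE) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  if (any(s == 0)) {
    if (!allow_constant) {
      stop("gene(s) with zero variance: ",
           paste(utils::head(rownames(m)[s == 0], 5L), collapse = ", "))
    }
    s[s == 0] <- 1
  }
  (m - mu) / s
}

# First principal component scores of a genes x samples submatrix
# (already z-scored per gene). Orientation is fixed so that the scores
# correlate positively with the per-sample mean expression of the block,
# removing the usual PC sign ambiguity.
.pc1_scores <- function(zsub) {
  x <- t(zsub)                       # samples x genes, column-centred
  dec <- svd(x, nu = 1L, nv = 1L)
  loading <- dec$v[, 1L]
  scores <- drop(x %*% loading)
  ref <- colMeans(zsub)              # per-sample mean over block genes
  cc <- suppressWarnings(cor(scores, ref))
  if (is.na(cc) || abs(cc) < 1e-8) {
    # PC1 orthogonal to the mean-expression direction (e.g. a two-gene
    # anticorrelated cluster, whose PC1 is the difference contrast):
    # anchor the sign to the lexicographically first gene's loading,
    # which is invariant to gene and sample order.
    ord <- order(rownames(zsub))
    nz <- which(abs(loading[ord]) > 1e-12)[1L]
    orient <- if (loading[ord][nz] < 0) -1 else 1
  } else {
    orient <- if (cc < 0) -1 else 1
  }
  list(scores = scores * orient, loading = loading, orientation = orient)
}

.check_time_status <- function(time, status) {
  if (any(is.na(time)) || any(is.na(status))) stop("missing survival time or status")
  if (any(time < 0)) stop("negative survival time")
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  invisible(TRUE)
}
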