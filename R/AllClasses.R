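#' ERSSModel: a fitted PC1-difference signature score
#'
#' Holds everything needed to reproduce and transfer an endoplasmic
#' reticulum stress score: the two sign-split gene clusters (cluster A,
#' genes whose univariate Cox coefficient is positive, i.e. hazard
#' increasing; cluster B, hazard decreasing), the unit-norm PC1 loading
#' vector and orientation sign per cluster, the per-gene centring and
#' scaling used for the z-scores, the per-sample scores, and (once
#' assigned) the high/low cutpoint.
#'
#' The score for sample \eqn{i} is \eqn{ERSS_i = PC1A_i - PC1B_i}: the
#' difference between the sample's coordinates on the first principal
#' components of the two clusters, each orientation-fixed to correlate
#' positively with the cluster's mean expression.
#'
#' @slot clusterA,clusterB character vectors of gene ids (either may be empty,
#'   not both).
#' @slot loadings named list with per-cluster unit-norm loading vectors.
#' @slot orientations named numeric (+1/-1) per cluster.
#' @slot center,scale named per-gene means / standard deviations used for
#'   z-scoring the cluster genes.
#' @slot scores named per-sample ERSS values.
#' @slot mode how the scores were obtained: "fit", "refit" or "project".
#' @slot cutpoint numeric(1); NA until assigned.
#'
#' @aliases ERSSModel
#' @exportClass ERSSModel
setClass("ERSSModel",
  representation(
    clusterA = "character",
    clusterB = "character",
    loadings = "list",
    orientations = "numeric",
    center = "numeric",
    scale = "numeric",
    scores = "numeric",
    mode = "character",
    cutpoint = "numeric"
  ),
  prototype(cutpoint = NA_real_, mode = "fit")
)

setValidity("ERSSModel", function(object) {
  msg <- character()
  if (length(object@clusterA) + length(object@clusterB) == 0L)
    msg <- c(msg, "both gene clusters are empty")
  if (length(intersect(object@clusterA, object@clusterB)) > 0L)
    msg <- c(msg, "clusters A and B overlap")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "non-finite score")
  for (nm in names(object@loadings)) {
    v <- object@loadings[[nm]]
    if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
      msg <- c(msg, sprintf("loading vector for cluster %s is not unit-norm", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ERSSModel compact display
#' @param object an ERSSModel
#' @export
setMethod("show", "ERSSModel", function(object) {
  cat("ERSSModel (", object@mode, ")\n", sep = "")
  cat("  cluster A (risk):      ", length(object@clusterA), "gene(s)\n")
  cat("  cluster B (protective):", length(object@clusterB), "gene(s)\n")
  cat("  samples scored:        ", length(object@scores), "\n")
  if (!is.na(object@cutpoint))
    cat("  high/low cutpoint:     ", format(object@cutpoint, digits = 4), "\n")
})

#' Accessors for ERSSModel
#'
#' `erssScores` returns the named per-sample scores, `geneClusters` the
#' two gene clusters, `erssCutpoint` the assigned high/low threshold
#' (NA until set by [optimalCutpoint()] / [assignCutpoint()]).
#'
#' @param object an [ERSSModel-class]
#' @return numeric vector, list of two character vectors, or numeric(1).
#' @export
erssScores <- function(object) {
  stopifnot(is(object, "ERSSModel"))
  object@scores
}

#' @rdname erssScores
#' @export
geneClusters <- function(object) {
  stopifnot(is(object, "ERSSModel"))
  list(A = object@clusterA, B = object@clusterB)
}

#' @rdname erssScores
#' @export
erssCutpoint <- function(object) {
  stopifnot(is(object, "ERSSModel"))
  object@cutpoint
}

#' @rdname erssScores
#' @param value numeric(1) threshold
#' @export
assignCutpoint <- function(object, value) {
  stopifnot(is(object, "ERSSModel"), is.numeric(value), length(value) == 1L)
  object@cutpoint <- as.numeric(value)
  object
}
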