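# Single-sample GSEA immune scores, ESTIMATE-style stromal/immune/purity
# scores, and tumor mutational burden with composite stratification.

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression (highest expression =
#' largest rank) and each set's score is the sum, down the ranked list,
#' of the difference between the rank-weighted in-set empirical CDF
#' (weights `rank^exponent`) and the unweighted out-of-set CDF. Scores
#' depend on expression only through within-sample ranks. Optional
#' min-max normalization rescales the whole matrix by its score range.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param sets named list of gene sets; genes absent from the matrix are
#'   dropped with a warning, a fully absent set is an error.
#' @param exponent rank weight (default 0.25).
#' @param normalize rescale all scores by the global score range.
#' @return sets x samples matrix with attributes `exponent` and
#'   `normalized`.
#' @export
ssgseaScores <- function(expr, sets, exponent = 0.25, normalize = FALSE) {
  m <- .as_expr_matrix(expr)
  genes <- rownames(m)
  sets_use <- lapply(sets, intersect, genes)
  absent <- vapply(sets_use, length, integer(1L)) == 0L
  if (any(absent))
    stop("set(s) with no genes in the matrix: ",
         paste(names(sets)[absent], collapse = ", "))
  dropped <- sum(vapply(sets, length, integer(1L))) -
    sum(vapply(sets_use, length, integer(1L)))
  if (dropped > 0L)
    warning(dropped, " set gene(s) absent from the matrix dropped")
  N <- nrow(m)
  out <- matrix(NA_real_, nrow = length(sets_use), ncol = ncol(m),
                dimnames = list(names(sets_use), colnames(m)))
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")      # largest value -> rank N
    ord <- order(m[, j], decreasing = TRUE)
    r_ord <- r[ord]
    gene_ord <- genes[ord]
    for (i in seq_along(sets_use)) {
      inset <- gene_ord %in% sets_use[[i]]
      w <- r_ord^exponent * inset
      cdf_in <- cumsum(w) / sum(w)
      cdf_out <- cumsum(!inset) / (N - sum(inset))
      out[i, j] <- sum(cdf_in - cdf_out)
    }
  }
  if (normalize) out <- out / (max(out) - min(out))
  attr(out, "exponent") <- exponent
  attr(out, "normalized") <- normalize
  out
}

#' ESTIMATE-style stromal, immune and purity scores
#'
#' Stromal and immune scores are single-sample enrichment scores
#' (exponent 0.25, unnormalized) of the two signatures; their sum is the
#' combined score, mapped to tumor purity through the published cosine
#' transform `cos(0.6049872018 + 0.0001467884 * score)`. Purity values
#' outside [0, 1] are flagged in the `purity_flag` column.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param stromal_set,immune_set signature gene-id vectors. The package
#'   ships synthetic stand-in signatures
#'   (`system.file("extdata", "estimate_signatures_synthetic.gmt",
#'   package = "ERSScore")`) for pipeline testing; substitute the
#'   published signatures for real analyses.
#' @return data.frame per sample: `sample_id`, `stromal`, `immune`,
#'   `estimate`, `purity`, `purity_flag`.
#' @export
estimateScores <- function(expr, stromal_set, immune_set) {
  sc <- ssgseaScores(expr, list(stromal = stromal_set, immune = immune_set),
                     exponent = 0.25, normalize = FALSE)
  est <- sc["stromal", ] + sc["immune", ]
  purity <- cos(0.6049872018 + 0.0001467884 * est)
  data.frame(sample_id = colnames(sc), stromal = unname(sc["stromal", ]),
             immune = unname(sc["immune", ]), estimate = unname(est),
             purity = unname(purity),
             purity_flag = purity < 0 | purity > 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tumor mutational burden per sample
#'
#' Mutations in the counted classes divided by the callable size in
#' megabases; samples absent from the mutation table get 0. The high/low
#' label splits at the median by default.
#'
#' @param mutations mutation table (see [readMutationTable()] /
#'   [simulateMutations()]).
#' @param samples sample ids to report (defaults to those in the table).
#' @param callable_mb callable genome size in megabases (default 38).
#' @param counted_classes variant classes counted; default all
#'   nonsynonymous classes (everything in the vocabulary except
#'   `Silent`).
#' @param cutoff high/low threshold; default the median TMB.
#' @return data.frame: `sample_id`, `n_mutations`, `tmb`, `tmb_group`.
#' @export
computeTMB <- function(mutations, samples = NULL, callable_mb = 38,
                       counted_classes = setdiff(.variant_vocabulary, "Silent"),
                       cutoff = NULL) {
  if (callable_mb <= 0) stop("callable_mb must be positive")
  bad <- setdiff(counted_classes, .variant_vocabulary)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (is.null(samples)) {
    samples <- attr(mutations, "samples")
    if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  }
  keep <- mutations$variant_classification %in% counted_classes
  counts <- table(factor(mutations$sample_id[keep], levels = samples))
  tmb <- as.numeric(counts) / callable_mb
  if (is.null(cutoff)) cutoff <- median(tmb)
  data.frame(sample_id = samples, n_mutations = as.integer(counts),
             tmb = tmb,
             tmb_group = ifelse(tmb > cutoff, "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Composite score/TMB survival strata
#'
#' Crosses the score grouping with the mutational-burden grouping into
#' up to four strata, drops empty strata with a warning, and runs a
#' Kaplan-Meier comparison with an overall log-rank test.
#'
#' @param score_group,tmb_group per-sample labels covering the same
#'   samples, in the same order as `time`/`status`.
#' @param time,status follow-up and event indicator.
#' @return list: `strata` (per-sample label), `km` (curve table),
#'   `logrank` (chisq, df, p), `sizes`.
#' @export
compositeStrata <- function(score_group, tmb_group, time, status) {
  if (length(score_group) != length(tmb_group))
    stop("groupings must cover the same samples")
  lab <- paste(score_group, tmb_group, sep = "/")
  sizes <- table(lab)
  if (any(sizes == 0)) warning("empty stratum dropped")
  lab <- factor(lab)
  if (nlevels(lab) < 2L) stop("need at least two strata")
  list(strata = as.character(lab), km = kmEstimate(time, status, lab),
       logrank = logrankTest(time, status, lab), sizes = sizes)
}
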