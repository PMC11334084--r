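# Differential expression, intersection with a curated gene list,
# over-representation, and preranked gene-set enrichment.

#' Tumor-vs-normal differential expression (Wilcoxon rank-sum)
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value and log2 fold change
#' computed as mean(tumor) - mean(normal) on the (assumed log-scale)
#' matrix. Raw p-values are flagged at the threshold (the conventional
#' unadjusted screen) and Benjamini-Hochberg adjusted values reported
#' alongside.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param groups per-sample labels; `tumor_level` picks the tumor group.
#' @param p_threshold significance flag threshold on raw p (default 0.05).
#' @param tumor_level label treated as tumor (default "tumor").
#' @return data.frame: `gene`, `log2fc`, `p`, `p_adj`, `direction`,
#'   `significant`.
#' @export
differentialExpression <- function(expr, groups, p_threshold = 0.05,
                                   tumor_level = "tumor") {
  m <- .as_expr_matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("one group label per sample required")
  tum <- groups == tumor_level
  if (sum(tum) < 2L || sum(!tum) < 2L) stop("each group needs at least 2 samples")
  p <- apply(m, 1L, function(v)
    suppressWarnings(wilcox.test(v[tum], v[!tum])$p.value))
  lfc <- rowMeans(m[, tum, drop = FALSE]) - rowMeans(m[, !tum, drop = FALSE])
  res <- data.frame(gene = rownames(m), log2fc = lfc, p = p,
                    p_adj = p.adjust(p, "BH"),
                    direction = ifelse(lfc > 0, "up", "down"),
                    significant = p < p_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  res
}

#' Intersect significant DE genes with a curated gene list
#'
#' @param de result of [differentialExpression()].
#' @param genes curated gene ids (e.g. a stress-response list).
#' @param use_adjusted intersect on BH-adjusted significance instead of raw.
#' @return character vector ordered by ascending p; warns when empty.
#' @export
intersectGeneList <- function(de, genes, use_adjusted = FALSE) {
  sig <- if (use_adjusted) de$gene[de$p_adj < 0.05] else de$gene[de$significant]
  hit <- intersect(sig, genes)
  if (!length(hit)) {
    warning("empty intersection with the supplied gene list")
    return(character())
  }
  hit[order(de$p[match(hit, de$gene)])]
}

#' Over-representation test (hypergeometric)
#'
#' One-sided upper-tail hypergeometric p per set against the supplied
#' universe, BH-adjusted across sets.
#'
#' @param query significant genes (must all be in `universe`).
#' @param universe background gene ids.
#' @param sets named list of gene sets (see [readGMT()]).
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `p_adj`.
#' @export
overRepresentation <- function(query, universe, sets) {
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) absent from universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    m <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], query))
    p <- if (m == 0L) 1 else phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, "BH")
  res
}

# Weighted Kolmogorov-Smirnov enrichment score for one set on an ordered
# ranking. `ord_scores` are the scores sorted decreasing, `inset` a
# logical along that order.
.gsea_es <- function(ord_scores, inset, exponent = 1) {
  w <- abs(ord_scores)^exponent
  hit_w <- w * inset
  denom_hit <- sum(hit_w)
  if (denom_hit == 0) denom_hit <- 1
  p_hit <- cumsum(hit_w) / denom_hit
  n_out <- sum(!inset)
  p_miss <- cumsum(!inset) / max(n_out, 1L)
  running <- p_hit - p_miss
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment with permutation NES
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score over a
#' ranked gene list; the null is built by gene-label permutation
#' (random sets of matching size). NES is ES divided by the mean
#' magnitude of same-sign permuted scores; nominal p comes from the
#' same-sign permutation tail and the FDR q from the pooled permutation
#' null, as in the standard GSEA procedure.
#'
#' @param ranked named numeric vector, gene-level ranking scores.
#' @param sets named list of gene sets; all member genes must be present
#'   in the ranking.
#' @param n_perm number of gene-label permutations (>= 100).
#' @param exponent weight on |score| (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov statistic).
#' @param seed optional integer seed for the permutations.
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p`, `q`.
#' @export
prerankedGSEA <- function(ranked, sets, n_perm = 1000L, exponent = 1,
                          seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.null(names(ranked))) stop("ranking must be a named vector")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(ranked, decreasing = TRUE)
  s <- ranked[ord]
  genes <- names(s)
  N <- length(genes)
  bad <- names(sets)[!vapply(sets, function(g) all(g %in% genes), logical(1L))]
  if (length(bad))
    stop("set(s) with genes absent from the ranking: ", paste(bad, collapse = ", "))
  sizes <- vapply(sets, length, integer(1L))
  if (any(sizes > N)) stop("set larger than the ranking")

  es <- vapply(sets, function(g) .gsea_es(s, genes %in% g, exponent), numeric(1L))

  # one permutation null per distinct set size
  perm_by_size <- lapply(unique(sizes), function(k) {
    vapply(seq_len(n_perm), function(b) {
      inset <- logical(N); inset[sample.int(N, k)] <- TRUE
      .gsea_es(s, inset, exponent)
    }, numeric(1L))
  })
  names(perm_by_size) <- as.character(unique(sizes))

  nes <- p <- numeric(length(sets))
  perm_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    null_es <- perm_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(null_es[null_es > 0]); neg_mean <- mean(abs(null_es[null_es < 0]))
    norm_null <- ifelse(null_es > 0,
                        null_es / ifelse(is.nan(pos_mean), 1, pos_mean),
                        null_es / ifelse(is.nan(neg_mean), 1, neg_mean))
    same <- if (es[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- if (es[i] >= 0) pos_mean else neg_mean
    nes[i] <- if (is.nan(denom) || denom == 0) NA_real_ else es[i] / denom
    p[i] <- (sum(abs(same) >= abs(es[i])) + 1L) / (length(same) + 1L)
    perm_nes[[i]] <- norm_null
  }
  pooled <- unlist(perm_nes)
  q <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pooled[pooled >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pooled[pooled < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1L))
  data.frame(set = names(sets), size = sizes, ES = es, NES = nes, p = p, q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}
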