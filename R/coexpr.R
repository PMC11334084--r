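# Co-expression network analysis: soft threshold by scale-free fit,
# topological overlap, static-cut module detection with eigengene
# merging, module-trait correlation and hub ranking.

.module_palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                     "black", "pink", "magenta", "purple", "greenyellow",
                     "tan", "salmon", "cyan", "midnightblue")

# Unsigned adjacency |cor|^beta with zero diagonal.
.adjacency <- function(expr, beta) {
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  a
}

# Signed scale-free topology fit: R^2 of log10(freq) ~ log10(mean k) over
# connectivity bins, negated when the slope is positive.
.scale_free_fit <- function(k, n_bins = 10L) {
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)   # equal-width bins
  if (brk[1L] == brk[n_bins + 1L]) return(NA_real_)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- as.vector(table(bin))
  mk <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(mk) & mk > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- lm(log10(freq[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(coef(fit)[2L]) * r2)
}

#' Pick a soft threshold by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency
#' `|cor|^beta`, computes per-gene connectivity, and regresses the log
#' connectivity-bin frequency on log mean connectivity; the signed fit
#' R^2 (negated for a positive slope) measures scale-free topology.
#' Returns the smallest power reaching the target R^2, or the argmax
#' with a warning when none does.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param betas candidate powers (default 1:6; at much higher powers even
#'   unstructured data can look scale-free as the network degenerates).
#' @param target signed R^2 target (default 0.9).
#' @return list: `beta`, `fit_table` (`beta`, `r_squared`,
#'   `mean_connectivity`), `reached_target`.
#' @export
pickSoftThreshold <- function(expr, betas = 1:6, target = 0.9) {
  m <- .as_expr_matrix(expr)
  if (nrow(m) < 30L) warning("fewer than 30 genes: scale-free fit is unstable")
  cc <- abs(cor(t(m)))
  diag(cc) <- 0
  if (all(cc == 0)) stop("all gene-gene correlations are zero")
  tab <- do.call(rbind, lapply(betas, function(b) {
    a <- cc^b; diag(a) <- 0
    k <- rowSums(a)
    data.frame(beta = b, r_squared = .scale_free_fit(k),
               mean_connectivity = mean(k))
  }))
  hit <- which(!is.na(tab$r_squared) & tab$r_squared >= target)
  if (length(hit)) {
    beta <- tab$beta[hit[1L]]
    reached <- TRUE
  } else {
    warning("no power reached the scale-free fit target; using the argmax")
    beta <- tab$beta[which.max(tab$r_squared)]
    reached <- FALSE
  }
  list(beta = beta, fit_table = tab, reached_target = reached)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' with unit diagonal: the neighborhood-sharing similarity used to
#' cluster co-expression networks.
#'
#' @param adjacency symmetric matrix in [0, 1] with zero diagonal.
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1)) stop("adjacency entries must be in [0, 1]")
  if (any(abs(diag(adjacency)) > 1e-12)) stop("adjacency diagonal must be zero")
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# Eigengene (orientation-fixed PC1 across samples) of a gene block.
.eigengene <- function(expr, genes) {
  z <- .zscore_rows(expr[genes, , drop = FALSE], allow_constant = TRUE)
  .pc1_scores(z)$scores
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height; branches smaller than `min_size` are demoted to "grey".
#' Modules whose eigengenes (orientation-fixed PC1 of the module's
#' z-scored genes) have dissimilarity `1 - cor` below `merge_height` are
#' merged iteratively. When no cut height is given, the highest height
#' on a fixed grid that yields at least two non-grey modules is used and
#' reported in a message.
#'
#' @param expr genes x samples matrix or SummarizedExperiment.
#' @param tom TOM matrix from [tomSimilarity()] (genes must match `expr`
#'   rownames).
#' @param min_size minimum module size (default 50).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.3; 0 disables merging).
#' @param cut_height static cut height on the dendrogram, or NULL for
#'   the automatic choice.
#' @return list of class `ModuleAssignment`: `modules` (named gene ->
#'   label, "grey" for unassigned), `eigengenes` (samples x modules),
#'   `cut_height`, `dendrogram`.
#' @export
detectModules <- function(expr, tom, min_size = 50L, merge_height = 0.3,
                          cut_height = NULL) {
  m <- .as_expr_matrix(expr)
  genes <- rownames(m)
  if (min_size > length(genes)) stop("min_size exceeds the number of genes")
  stopifnot(identical(rownames(tom), genes))
  hc <- hclust(as.dist(1 - tom), method = "average")
  assign_at <- function(h) {
    cl <- cutree(hc, h = h)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= min_size]
    lab <- rep("grey", length(genes))
    ord <- keep[order(-sizes[keep])]
    for (i in seq_along(ord))
      lab[cl == as.integer(ord[i])] <-
        if (i <= length(.module_palette)) .module_palette[i] else paste0("module", i)
    lab
  }
  if (is.null(cut_height)) {
    grid <- sort(unique(quantile(hc$height, probs = seq(0.98, 0.02, by = -0.04))),
                 decreasing = TRUE)
    cut_height <- grid[1L]
    for (h in grid) {
      lab <- assign_at(h)
      if (length(setdiff(unique(lab), "grey")) >= 2L) { cut_height <- h; break }
    }
    message("static cut height chosen automatically: ",
            format(cut_height, digits = 4))
  }
  labels <- setNames(assign_at(cut_height), genes)

  eg <- function(labels) {
    mods <- setdiff(unique(labels), "grey")
    sapply(mods, function(md) .eigengene(m, genes[labels == md]))
  }
  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L || merge_height <= 0) break
    E <- eg(labels)
    d <- 1 - cor(E)
    diag(d) <- Inf
    if (min(d) >= merge_height) break
    pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
    keep_lab <- colnames(d)[pair[2L]]; drop_lab <- rownames(d)[pair[1L]]
    labels[labels == drop_lab] <- keep_lab
  }
  mods <- setdiff(unique(labels), "grey")
  eigengenes <- if (length(mods)) {
    e <- sapply(mods, function(md) .eigengene(m, genes[labels == md]))
    rownames(e) <- colnames(m); e
  } else matrix(numeric(), nrow = ncol(m), ncol = 0L)
  structure(list(modules = labels, eigengenes = eigengenes,
                 cut_height = cut_height, dendrogram = hc),
            class = "ModuleAssignment")
}

#' Correlate module eigengenes with a sample trait
#'
#' Pearson correlation of each module eigengene with the (numeric or
#' binary-coded) trait, with the two-sided p-value.
#'
#' @param assignment a `ModuleAssignment` from [detectModules()].
#' @param trait numeric per-sample trait (code binary traits 0/1).
#' @return data.frame: `module`, `r`, `p`.
#' @export
moduleTraitCorrelation <- function(assignment, trait) {
  trait <- as.numeric(trait)
  if (sd(trait) == 0) stop("trait is constant")
  E <- assignment$eigengenes
  rows <- lapply(colnames(E), function(md) {
    ct <- cor.test(E[, md], trait)
    data.frame(module = md, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank a module's genes by membership (hub ranking)
#'
#' Genes ranked by module membership — the correlation of each gene's
#' expression with the module eigengene — with ties broken by
#' intramodular connectivity (sum of absolute correlations with the
#' other module genes).
#'
#' @param assignment a `ModuleAssignment`.
#' @param expr the expression matrix the assignment was built from.
#' @param module module label to rank (not "grey").
#' @return data.frame ordered by rank: `gene`, `membership`,
#'   `connectivity`.
#' @export
hubRanking <- function(assignment, expr, module) {
  if (module == "grey") stop("the grey (unassigned) pseudo-module cannot be ranked")
  m <- .as_expr_matrix(expr)
  genes <- names(assignment$modules)[assignment$modules == module]
  if (!length(genes)) stop("module not found: ", module)
  E <- assignment$eigengenes[, module]
  kme <- apply(m[genes, , drop = FALSE], 1L, cor, y = E)
  cc <- abs(cor(t(m[genes, , drop = FALSE])))
  conn <- rowSums(cc) - 1
  out <- data.frame(gene = genes, membership = unname(kme),
                    connectivity = unname(conn), stringsAsFactors = FALSE)
  out[order(-out$membership, -out$connectivity), , drop = FALSE]
}
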