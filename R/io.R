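# Readers/writers for the package's plain-text table dialects, plus the
# simplified batch adjustment used before cross-cohort merging.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Rows containing missing values are dropped (and counted in a message),
#' as are genes that are zero across every sample (non-expressed genes).
#'
#' @param path TSV file path.
#' @param drop_zero_rows drop all-zero genes (default TRUE).
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path, drop_zero_rows = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression matrix needs at least 2 sample columns")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   if (is.na(bad)) 1L else bad, colnames(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample id(s) in header")
  keep <- complete.cases(m)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) with missing values dropped")
    m <- m[keep, , drop = FALSE]
  }
  if (drop_zero_rows) {
    zero <- rowSums(m != 0) == 0L
    if (any(zero)) {
      message(sum(zero), " non-expressed (all-zero) gene(s) dropped")
      m <- m[!zero, , drop = FALSE]
    }
  }
  if (ncol(m) < 2L) stop("need at least 2 samples")
  m
}

#' Write an expression matrix to TSV
#'
#' @param m genes x samples matrix.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `time`, `status`; keeps any further
#' covariate columns. Samples with missing time or status are rejected,
#' as are negative times, statuses outside \{0,1\} and duplicated ids.
#'
#' @param path TSV file path.
#' @return data.frame with one row per sample.
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "status")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (any(is.na(df$time)) || any(is.na(df$status)))
    stop("samples with missing survival time or status are not allowed")
  .check_time_status(df$time, df$status)
  df
}

#' Read a gene-set collection in GMT format
#'
#' Standard dialect: `name TAB description TAB gene TAB gene ...`.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors; set descriptions are
#'   kept in `attr(, "description")`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': duplicate gene(s) removed", f[1L]))
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to set names).
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Variant classes recognised in mutation tables (MAF-subset vocabulary).
.variant_vocabulary <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site", "Silent"
)

#' Read a mutation table (MAF-subset TSV)
#'
#' Columns `sample_id`, `gene`, `variant_classification`; the
#' classification must come from the declared vocabulary. An empty table
#' is allowed.
#'
#' @param path TSV file path.
#' @return data.frame of mutation records.
#' @export
readMutationTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "variant_classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$variant_classification), .variant_vocabulary)
  if (length(bad)) stop("unknown variant classification(s): ", paste(bad, collapse = ", "))
  df
}

#' Location/scale batch adjustment
#'
#' Aligns, per gene, each batch's mean and standard deviation to the
#' pooled mean and standard deviation, a simplified form of batch
#' correction suitable as preprocessing before cross-cohort merging.
#' Genes with zero variance inside a batch are location-shifted only
#' (with a warning). A single batch passes through unchanged.
#'
#' @param expr genes x samples matrix (assumed log-scale).
#' @param batch batch label per sample.
#' @return adjusted matrix, same dimensions.
#' @export
adjustBatches <- function(expr, batch) {
  expr <- .as_expr_matrix(expr)
  batch <- as.character(batch)
  if (length(batch) != ncol(expr)) stop("one batch label per sample required")
  tab <- table(batch)
  if (any(tab < 2L))
    stop("batch(es) with a single sample: ", paste(names(tab)[tab < 2L], collapse = ", "))
  if (length(tab) == 1L) return(expr)
  out <- expr
  pooled_mu <- rowMeans(expr)
  pooled_sd <- apply(expr, 1L, sd)
  warned <- FALSE
  for (b in names(tab)) {
    idx <- which(batch == b)
    sub <- expr[, idx, drop = FALSE]
    mu_b <- rowMeans(sub)
    sd_b <- apply(sub, 1L, sd)
    degenerate <- sd_b == 0 | pooled_sd == 0
    if (any(degenerate) && !warned) {
      warning(sum(degenerate), " gene(s) with zero within-batch variance: location shift only")
      warned <- TRUE
    }
    scale_fac <- ifelse(degenerate, 1, pooled_sd / sd_b)
    out[, idx] <- (sub - mu_b) * scale_fac + pooled_mu
  }
  out
}

#' Bundle expression and clinical data into a SummarizedExperiment
#'
#' @param expr genes x samples matrix.
#' @param clinical data.frame with a `sample_id` column matching the
#'   matrix columns.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`.
#' @export
asCohort <- function(expr, clinical) {
  expr <- .as_expr_matrix(expr)
  clinical <- as.data.frame(clinical)
  if (!"sample_id" %in% colnames(clinical)) stop("clinical table needs sample_id")
  if (!setequal(clinical$sample_id, colnames(expr)))
    stop("clinical sample ids do not match expression columns")
  clinical <- clinical[match(colnames(expr), clinical$sample_id), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr),
    colData = S4Vectors::DataFrame(clinical, row.names = clinical$sample_id)
  )
}
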