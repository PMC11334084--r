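# Configuration and the end-to-end pipeline driver.

.default_config <- function() {
  list(
    stages = c("simulate", "de", "score", "survival"),
    seed = 1L,
    time_unit = "months",
    inputs = list(expression = NULL, clinical = NULL, mutations = NULL,
                  gene_sets = NULL, ers_genes = NULL),
    simulate = list(n_tumor = 400L, n_normal = 100L, n_genes = 2000L,
                    n_de_up = 150L, n_de_down = 150L, de_effect = 1,
                    cluster_A_size = 12L, cluster_B_size = 2L,
                    beta_A = 0.8, beta_B = -0.8, baseline_hazard = 0.02,
                    censor_rate = 0.3, noise_sd = 1),
    de = list(p_threshold = 0.05),
    score = list(alpha = 0.05, ties = "efron"),
    survival = list(minprop = 0.1),
    immune = list(exponent = 0.25, normalize = FALSE, n_sets = 28L,
                  set_size = 15L),
    tmb = list(callable_mb = 38, mean_mutations = 76),
    nomogram = list(horizons = c(12, 36, 60), bootstrap = 200L),
    wgcna = list(betas = 1:6, min_size = 50L, merge_height = 0.3,
                 top_genes = 500L),
    snp = list(n_cases = 467L, n_controls = 395L, maf = 0.06, or_g = 0.596,
               exposure_prev = 0.304, or_e = 1.803, or_int = 1.173)
  )
}

#' Build a validated pipeline configuration
#'
#' Every parameter has a default; unknown keys (at the top level or
#' inside a stage block) are rejected so that typos fail before any
#' stage runs.
#'
#' @param ... overrides, e.g. `seed = 7`,
#'   `simulate = list(n_tumor = 100)`.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- .default_config()
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      bad <- setdiff(names(user[[key]]), names(cfg[[key]]))
      if (length(bad))
        stop("unknown config key(s) in '", key, "': ", paste(bad, collapse = ", "))
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  known_stages <- c("simulate", "de", "score", "survival", "immune", "tmb",
                    "nomogram", "wgcna", "snp")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "PipelineConfig")
}

# Deterministically derive gene sets from a matrix's gene universe; used
# when no GMT is configured (synthetic signatures for simulated cohorts).
.synthetic_sets <- function(genes, n_sets, set_size, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  names(sets) <- sprintf("synthetic_set_%02d", seq_len(n_sets))
  sets
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order (simulate -> de ->
#' score -> survival -> immune / tmb / nomogram / wgcna; snp is
#' independent), writing one TSV per stage plus a JSON run manifest
#' (seed, package version, parameters, stages run). A stage whose
#' upstream output is missing is an error naming the stage. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_order <- c("simulate", "de", "score", "survival", "immune", "tmb",
                   "nomogram", "wgcna", "snp")
  stages <- stage_order[stage_order %in% config$stages]
  res <- list()
  outputs <- character()
  set.seed(config$seed)

  need <- function(what, from_stage) {
    if (is.null(res[[what]]))
      stop("stage '", from_stage, "' requires upstream output '", what,
           "' (run the producing stage or configure an input file)")
    res[[what]]
  }

  for (st in stages) {
    if (st == "simulate") {
      spec <- do.call(cohortSpec, c(config$simulate, list(seed = config$seed)))
      se <- simulateExpressionCohort(spec)
      res$cohort <- se
      outputs["expression"] <- writeExpressionMatrix(
        SummarizedExperiment::assay(se), file.path(out_dir, "expression.tsv"))
      outputs["clinical"] <- .write_tsv(
        as.data.frame(SummarizedExperiment::colData(se)),
        file.path(out_dir, "clinical.tsv"))
      jsonlite::write_json(
        S4Vectors::metadata(se)$truth[c("clusterA", "clusterB", "beta_A", "beta_B")],
        file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    } else if (st == "de") {
      if (is.null(res$cohort) && !is.null(config$inputs$expression)) {
        expr <- readExpressionMatrix(config$inputs$expression)
        clin <- readClinicalTable(config$inputs$clinical)
        res$cohort <- asCohort(expr, clin)
      }
      se <- need("cohort", "de")
      clin <- as.data.frame(SummarizedExperiment::colData(se))
      de <- differentialExpression(se, clin$group,
                                   p_threshold = config$de$p_threshold)
      res$de <- de
      outputs["de"] <- .write_tsv(de, file.path(out_dir, "de.tsv"))
    } else if (st == "score") {
      se <- need("cohort", "score")
      clin <- as.data.frame(SummarizedExperiment::colData(se))
      tum <- clin$group == "tumor"
      genes <- if (!is.null(res$de)) {
        cand <- res$de$gene[res$de$significant]
        if (!is.null(config$inputs$ers_genes)) intersect(cand, config$inputs$ers_genes)
        else cand
      } else rownames(se)
      if (!length(genes)) stop("stage 'score': no candidate genes")
      expr_t <- SummarizedExperiment::assay(se)[, tum, drop = FALSE]
      screen <- univariateCoxScreen(expr_t, clin[tum, ],
                                    alpha = config$score$alpha, genes = genes,
                                    ties = config$score$ties)
      cl <- attr(screen, "clusters")
      if (!length(cl$A) && !length(cl$B)) stop("stage 'score': no prognostic genes retained")
      model <- computeERSS(expr_t, cl$A, cl$B)
      res$screen <- screen; res$erss <- model
      outputs["score"] <- .write_tsv(
        data.frame(sample_id = names(erssScores(model)), erss = unname(erssScores(model))),
        file.path(out_dir, "erss.tsv"))
    } else if (st == "survival") {
      model <- need("erss", "survival")
      se <- need("cohort", "survival")
      clin <- as.data.frame(SummarizedExperiment::colData(se))
      clin <- clin[match(names(erssScores(model)), clin$sample_id), ]
      cp <- optimalCutpoint(erssScores(model), clin$time, clin$status,
                            minprop = config$survival$minprop)
      model <- assignCutpoint(model, cp$cutpoint)
      res$erss <- model
      grp <- ifelse(erssScores(model) > cp$cutpoint, "high", "low")
      res$erss_group <- grp
      lr <- logrankTest(clin$time, clin$status, grp)
      cox <- coxFit(data.frame(erss = unname(erssScores(model)), age = clin$age),
                    clin$time, clin$status)
      res$survival <- list(cutpoint = cp, logrank = lr, cox = cox)
      outputs["survival"] <- .write_tsv(
        data.frame(cutpoint = cp$cutpoint, statistic = cp$statistic,
                   logrank_chisq = lr$chisq, logrank_p = lr$p),
        file.path(out_dir, "survival.tsv"))
    } else if (st == "immune") {
      se <- need("cohort", "immune")
      genes <- rownames(se)
      sets <- if (!is.null(config$inputs$gene_sets)) readGMT(config$inputs$gene_sets)
        else .synthetic_sets(genes, config$immune$n_sets,
                             config$immune$set_size, config$seed + 1L)
      sc <- ssgseaScores(se, sets, exponent = config$immune$exponent,
                         normalize = config$immune$normalize)
      res$immune <- sc
      outputs["immune"] <- .write_tsv(
        data.frame(set = rownames(sc), sc, check.names = FALSE),
        file.path(out_dir, "immune.tsv"))
    } else if (st == "tmb") {
      se <- need("cohort", "tmb")
      mut <- if (!is.null(config$inputs$mutations)) readMutationTable(config$inputs$mutations)
        else simulateMutations(ncol(se), config$tmb$mean_mutations,
                               config$tmb$callable_mb, seed = config$seed + 2L)
      tmb <- computeTMB(mut, samples = colnames(se),
                        callable_mb = config$tmb$callable_mb)
      res$tmb <- tmb
      outputs["tmb"] <- .write_tsv(tmb, file.path(out_dir, "tmb.tsv"))
    } else if (st == "nomogram") {
      model <- need("erss", "nomogram")
      se <- need("cohort", "nomogram")
      clin <- as.data.frame(SummarizedExperiment::colData(se))
      clin <- clin[match(names(erssScores(model)), clin$sample_id), ]
      stage_num <- as.integer(factor(clin$stage, levels = c("I", "II", "III", "IV")))
      cov <- data.frame(erss = unname(erssScores(model)), age = clin$age,
                        stage = stage_num)
      rm_horizons <- config$nomogram$horizons
      rm_horizons <- rm_horizons[rm_horizons <= max(clin$time)]
      rmod <- buildRiskModel(cov, clin$time, clin$status, horizons = rm_horizons)
      ci <- concordanceIndex(predict(rmod$fit$model, type = "lp"),
                             clin$time, clin$status,
                             B = config$nomogram$bootstrap, seed = config$seed + 3L)
      res$nomogram <- list(model = rmod, concordance = ci)
      outputs["nomogram"] <- .write_tsv(
        data.frame(horizon = rm_horizons,
                   baseline_surv = unname(rmod$baseline_surv),
                   c_index = ci$c_index, c_low = ci$ci_low, c_high = ci$ci_high),
        file.path(out_dir, "nomogram.tsv"))
    } else if (st == "wgcna") {
      se <- need("cohort", "wgcna")
      m <- SummarizedExperiment::assay(se)
      vars <- apply(m, 1L, sd)
      top <- rownames(m)[order(-vars)][seq_len(min(config$wgcna$top_genes, nrow(m)))]
      sub <- m[top, , drop = FALSE]
      pick <- suppressWarnings(pickSoftThreshold(sub, betas = config$wgcna$betas))
      tom <- tomSimilarity(.adjacency(sub, pick$beta))
      assign <- suppressMessages(detectModules(
        sub, tom, min_size = config$wgcna$min_size,
        merge_height = config$wgcna$merge_height))
      clin <- as.data.frame(SummarizedExperiment::colData(se))
      trait <- as.integer(clin$group == "tumor")
      mt <- if (ncol(assign$eigengenes))
        moduleTraitCorrelation(assign, trait) else
        data.frame(module = character(), r = numeric(), p = numeric())
      res$wgcna <- list(beta = pick$beta, assignment = assign, trait = mt)
      outputs["wgcna"] <- .write_tsv(
        data.frame(gene = names(assign$modules), module = unname(assign$modules)),
        file.path(out_dir, "wgcna_modules.tsv"))
    } else if (st == "snp") {
      spec <- do.call(caseControlSpec,
                      c(config$snp, list(seed = config$seed + 4L)))
      subjects <- simulateCaseControl(spec)
      fit <- logisticFit(subjects, case ~ carrier)
      row <- fit$coefficients[fit$coefficients$term == "carrier", ]
      geno <- table(subjects$genotype[subjects$case == 0])
      hwe <- hweTest(geno["CC"], if (is.na(geno["CT"])) 0 else geno["CT"],
                     if (is.na(geno["TT"])) 0 else geno["TT"])
      res$snp <- list(subjects = subjects, fit = fit, hwe = hwe)
      outputs["snp"] <- .write_tsv(
        data.frame(term = "carrier", or = row$or, ci_low = row$ci_low,
                   ci_high = row$ci_high, p = row$p,
                   hwe_chisq = hwe$chisq, hwe_p = hwe$p),
        file.path(out_dir, "snp.tsv"))
    }
  }
  manifest <- list(seed = config$seed, time_unit = config$time_unit,
                   package_version = as.character(packageVersion("ERSScore")),
                   stages = stages, outputs = as.list(outputs),
                   parameters = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(results = res, manifest = manifest))
}
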