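# Synthetic cohort generators. These define the study conditions under
# which every downstream stage is exercised: tumor/normal expression with
# planted differentially expressed genes, two co-expressed prognostic
# clusters driving proportional-hazards survival, Poisson mutation
# counts, and Hardy-Weinberg case-control genotype/exposure tables with
# planted odds ratios. Each generator is a pure function of (spec, seed)
# and returns its ground truth alongside the data.

#' Specification of a synthetic expression cohort
#'
#' Defaults emulate the structure of a two-subtype tumor cohort at a
#' scale suitable for simulation studies: 400 tumors vs 100 normals,
#' 2000 genes of which 150 are shifted up and 150 down in tumors by one
#' log-unit, a hazard-increasing cluster of 12 genes and a protective
#' cluster of 2 genes (each cluster co-expressed through a shared
#' latent factor of unit variance), per-cluster log-hazard coefficients
#' +0.8/-0.8 on the cluster mean expression, exponential baseline
#' hazard 0.02 per month and roughly 30% uniform censoring.
#'
#' @param n_tumor,n_normal,n_genes cohort dimensions.
#' @param n_de_up,n_de_down planted differentially expressed gene counts.
#' @param de_effect mean log-expression shift in tumors.
#' @param cluster_A_size,cluster_B_size planted prognostic cluster sizes;
#'   A (hazard increasing) is drawn from the up-regulated genes, B
#'   (protective) from the down-regulated genes, so the clusters are
#'   disjoint subsets of the DE genes.
#' @param beta_A,beta_B log-hazard coefficients on the per-sample mean
#'   expression of each cluster (beta_A > 0, beta_B < 0).
#' @param baseline_hazard exponential baseline hazard (events per time unit).
#' @param censor_rate target fraction censored, in [0, 1).
#' @param noise_sd per-gene Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return a list of class `CohortSpec`.
#' @export
cohortSpec <- function(n_tumor = 400L, n_normal = 100L, n_genes = 2000L,
                       n_de_up = 150L, n_de_down = 150L, de_effect = 1,
                       cluster_A_size = 12L, cluster_B_size = 2L,
                       beta_A = 0.8, beta_B = -0.8,
                       baseline_hazard = 0.02, censor_rate = 0.3,
                       noise_sd = 1, seed = 1L) {
  spec <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
               n_genes = as.integer(n_genes), n_de_up = as.integer(n_de_up),
               n_de_down = as.integer(n_de_down), de_effect = de_effect,
               cluster_A_size = as.integer(cluster_A_size),
               cluster_B_size = as.integer(cluster_B_size),
               beta_A = beta_A, beta_B = beta_B,
               baseline_hazard = baseline_hazard, censor_rate = censor_rate,
               noise_sd = noise_sd, seed = as.integer(seed))
  with(spec, {
    if (any(c(n_tumor, n_normal, n_genes) <= 0L)) stop("all sizes must be positive")
    if (n_de_up + n_de_down > n_genes) stop("more DE genes than genes")
    if (cluster_A_size > n_de_up || cluster_B_size > n_de_down)
      stop("cluster sizes exceed planted DE gene counts")
    if (beta_A < 0 || beta_B > 0) stop("expect beta_A >= 0 and beta_B <= 0")
    if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
    if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  })
  structure(spec, class = "CohortSpec")
}

# Solve for the upper bound of a Uniform(0, tau) censoring distribution
# so that the expected censored fraction over realised event times T
# equals the target rate: P(C < T_i) = min(T_i / tau, 1).
.solve_censor_tau <- function(times, rate) {
  f <- function(tau) mean(pmin(times / tau, 1)) - rate
  lo <- min(times) * 1e-3; hi <- max(times) * 1e4
  if (f(hi) > 0) return(hi)
  uniroot(f, c(lo, hi))$root
}

#' Simulate a tumor/normal expression cohort with planted survival signal
#'
#' Normal samples are Gaussian around per-gene baselines; tumor samples
#' are shifted by `+/- de_effect` on the planted DE genes. Genes in the
#' two prognostic clusters additionally share a per-sample latent factor
#' (one factor per cluster, unit variance), giving the within-cluster
#' correlation a first principal component can pick up. The latent score
#' `s_i = beta_A * meanexpr(A)_i + beta_B * meanexpr(B)_i` drives
#' exponential event times with hazard `h0 * exp(s_i)`; independent
#' uniform censoring is calibrated to the target censoring fraction.
#'
#' @param spec a [cohortSpec()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`, clinical columns in `colData` (`sample_id`, `time`,
#'   `status`, `group`, `age`, `sex`, `stage`, `batch`) and the truth
#'   record in `metadata(.)$truth` (planted memberships, coefficients,
#'   per-sample latent score, attained censoring).
#' @export
simulateExpressionCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- spec$n_tumor + spec$n_normal
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  samples <- sprintf("s%04d", seq_len(n))
  group <- rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal))

  de_up <- genes[seq_len(spec$n_de_up)]
  de_down <- genes[spec$n_de_up + seq_len(spec$n_de_down)]
  clusterA <- de_up[seq_len(spec$cluster_A_size)]
  clusterB <- de_down[seq_len(spec$cluster_B_size)]

  baseline <- rnorm(spec$n_genes, mean = 6, sd = 1)
  expr <- matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd),
                 nrow = spec$n_genes, dimnames = list(genes, samples)) + baseline
  tum <- group == "tumor"
  expr[de_up, tum] <- expr[de_up, tum] + spec$de_effect
  expr[de_down, tum] <- expr[de_down, tum] - spec$de_effect

  fA <- rnorm(n); fB <- rnorm(n)
  expr[clusterA, ] <- expr[clusterA, ] + rep(fA, each = length(clusterA))
  expr[clusterB, ] <- expr[clusterB, ] + rep(fB, each = length(clusterB))

  latent <- spec$beta_A * colMeans(expr[clusterA, , drop = FALSE]) +
    spec$beta_B * colMeans(expr[clusterB, , drop = FALSE])
  rate <- spec$baseline_hazard * exp(latent - mean(latent))
  t_event <- rexp(n, rate = rate)
  if (spec$censor_rate > 0) {
    tau <- .solve_censor_tau(t_event, spec$censor_rate)
    t_cens <- runif(n, 0, tau)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  status <- as.integer(t_event <= t_cens)

  clinical <- data.frame(
    sample_id = samples, time = time, status = status, group = group,
    age = round(rnorm(n, 63, 9)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.45, 0.25, 0.2, 0.1)),
    batch = "b1", stringsAsFactors = FALSE
  )
  se <- asCohort(expr, clinical)
  S4Vectors::metadata(se)$truth <- list(
    de_up = de_up, de_down = de_down,
    clusterA = clusterA, clusterB = clusterB,
    beta_A = spec$beta_A, beta_B = spec$beta_B,
    latent = setNames(latent, samples),
    attained_censoring = mean(status == 0), spec = spec
  )
  se
}

#' Simulate per-sample somatic mutation records
#'
#' Per-sample mutation counts are Poisson with the given mean; gene
#' labels are arbitrary and variant classes are drawn from the declared
#' vocabulary (mostly missense, a fraction silent).
#'
#' @param n_samples number of samples.
#' @param mean_mutations Poisson mean mutation count per sample.
#' @param size_mb callable genome size in megabases (recorded as an
#'   attribute for downstream mutational-burden computation).
#' @param seed integer seed.
#' @return data.frame (`sample_id`, `gene`, `variant_classification`)
#'   with attribute `size_mb`; empty when `mean_mutations` is 0.
#' @export
simulateMutations <- function(n_samples, mean_mutations = 76, size_mb = 38,
                              seed = 1L) {
  if (mean_mutations < 0) stop("mean_mutations must be >= 0")
  set.seed(seed)
  samples <- sprintf("s%04d", seq_len(n_samples))
  counts <- rpois(n_samples, mean_mutations)
  cls_prob <- setNames(rep(0.02, length(.variant_vocabulary)), .variant_vocabulary)
  cls_prob["Missense_Mutation"] <- 0.6
  cls_prob["Silent"] <- 0.24
  df <- data.frame(
    sample_id = rep(samples, counts),
    gene = sprintf("gene%04d", sample.int(5000L, sum(counts), replace = TRUE)),
    variant_classification = sample(.variant_vocabulary, sum(counts),
                                    replace = TRUE, prob = cls_prob),
    stringsAsFactors = FALSE
  )
  attr(df, "size_mb") <- size_mb
  attr(df, "samples") <- samples
  df
}

#' Specification of a synthetic case-control genotype/exposure study
#'
#' Defaults mirror a non-smoking-female NSCLC case-control design: 467
#' cases vs 395 controls, minor-allele frequency 0.06 (carrier frequency
#' about 11.6% under Hardy-Weinberg), dominant-coded genotype odds ratio
#' 0.596, exposure prevalence 0.304 with odds ratio 1.803, and
#' interaction odds ratio 1.173.
#'
#' @param n_cases,n_controls target group sizes (the generator draws
#'   `n_cases + n_controls` subjects and solves the logistic intercept to
#'   hit the case fraction in expectation).
#' @param maf minor-allele frequency q in (0, 0.5].
#' @param or_g genotype odds ratio, dominant coding (carrier vs
#'   homozygous reference).
#' @param exposure_prev exposure prevalence.
#' @param or_e exposure odds ratio.
#' @param or_int interaction odds ratio (departure from the
#'   multiplicative model).
#' @param age_mean,age_sd Gaussian age distribution parameters.
#' @param seed integer seed.
#' @return a list of class `CaseControlSpec`.
#' @export
caseControlSpec <- function(n_cases = 467L, n_controls = 395L, maf = 0.06,
                            or_g = 0.596, exposure_prev = 0.304,
                            or_e = 1.803, or_int = 1.173,
                            age_mean = 56.5, age_sd = 11.5, seed = 1L) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (any(c(or_g, or_e, or_int) <= 0)) stop("all odds ratios must be positive")
  if (exposure_prev <= 0 || exposure_prev >= 1) stop("exposure_prev must be in (0,1)")
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 maf = maf, or_g = or_g, exposure_prev = exposure_prev,
                 or_e = or_e, or_int = or_int, age_mean = age_mean,
                 age_sd = age_sd, seed = as.integer(seed)),
            class = "CaseControlSpec")
}

#' Simulate a case-control subject table under Hardy-Weinberg
#'
#' Genotypes are drawn under Hardy-Weinberg with the given minor-allele
#' frequency; case status follows a logistic model with log-odds terms
#' `log(or_g) * carrier + log(or_e) * exposed + log(or_int) * carrier *
#' exposed`, the intercept solved so that the expected case fraction
#' equals `n_cases / (n_cases + n_controls)`.
#'
#' @param spec a [caseControlSpec()].
#' @return data.frame (`subject_id`, `genotype` in CC/CT/TT, `carrier`
#'   0/1, `exposed` 0/1, `age`, `case` 0/1) with the truth record in
#'   `attr(, "truth")`.
#' @export
simulateCaseControl <- function(spec = caseControlSpec()) {
  stopifnot(inherits(spec, "CaseControlSpec"))
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  q <- spec$maf
  geno <- sample(c("CC", "CT", "TT"), n, replace = TRUE,
                 prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  carrier <- as.integer(geno != "CC")
  exposed <- rbinom(n, 1L, spec$exposure_prev)
  age <- round(rnorm(n, spec$age_mean, spec$age_sd))
  lp <- log(spec$or_g) * carrier + log(spec$or_e) * exposed +
    log(spec$or_int) * carrier * exposed
  target <- spec$n_cases / n
  f <- function(b0) mean(plogis(b0 + lp)) - target
  if (f(-30) > 0 || f(30) < 0) stop("target case fraction unattainable")
  b0 <- uniroot(f, c(-30, 30))$root
  case <- rbinom(n, 1L, plogis(b0 + lp))
  df <- data.frame(subject_id = sprintf("p%04d", seq_len(n)), genotype = geno,
                   carrier = carrier, exposed = exposed, age = age, case = case,
                   stringsAsFactors = FALSE)
  attr(df, "truth") <- list(spec = spec, intercept = b0)
  df
}

#' Simulate expression driven by block latent factors
#'
#' A compact generator for co-expression analyses: each block of genes
#' loads on its own latent factor (per-sample, unit variance) plus
#' Gaussian noise; remaining genes are pure noise. Useful for planting
#' recoverable modules and hubs.
#'
#' @param n_samples samples.
#' @param block_sizes integer vector of module sizes.
#' @param n_noise_genes unstructured genes appended after the blocks.
#' @param factor_sd latent factor standard deviation (signal strength).
#' @param noise_sd residual noise standard deviation.
#' @param seed integer seed.
#' @return genes x samples matrix with `attr(, "blocks")` giving the
#'   planted gene-to-block assignment and `attr(, "factors")` the
#'   latent factors (samples x blocks).
#' @export
simulateFactorExpression <- function(n_samples = 100L, block_sizes = c(60L, 60L),
                                     n_noise_genes = 30L, factor_sd = 1,
                                     noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  n_genes <- sum(block_sizes) + n_noise_genes
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n_samples))
  fac <- matrix(rnorm(n_samples * length(block_sizes), sd = factor_sd),
                nrow = n_samples)
  expr <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), nrow = n_genes,
                 dimnames = list(genes, samples))
  blocks <- rep(c(seq_along(block_sizes), 0L), c(block_sizes, n_noise_genes))
  for (b in seq_along(block_sizes)) {
    idx <- which(blocks == b)
    expr[idx, ] <- expr[idx, ] + rep(fac[, b], each = length(idx))
  }
  attr(expr, "blocks") <- setNames(blocks, genes)
  attr(expr, "factors") <- fac
  expr
}
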