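## Multi-cohort synthetic data with planted ground truth.
##
## A single bimodal latent activity per sample drives (i) a block of
## co-expressed program genes, (ii) proportional-hazards survival, and
## (iii) metastasis probability. A companion gene set collection plants
## program-enriched, heavily overlapping sets among random ones. This is
## the minimal structure under which the whole pipeline
## (score -> Cox screen -> overlap network -> core set -> ablation) has
## a known right answer.

#' Build and validate a simulation configuration
#'
#' Defaults describe a mid-sized microarray cohort: 2000 genes, 200
#' samples, a 60-gene expression program driven by a two-component
#' Gaussian latent activity (means -1.2/+1.2, sd 0.4, equal weights),
#' exponential survival with baseline hazard 0.05 per month and log
#' hazard ratio 0.6 per latent unit, administrative censoring uniform on
#' [0, 120] months, and a 150-set collection of which 20 sets draw
#' 30-70% of their genes from the program.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param program_size number of planted program genes.
#' @param latent_means,latent_sd,latent_weight two-component Gaussian
#'   mixture of the per-sample latent activity.
#' @param loading expression loading of program genes on the latent.
#' @param noise_sd residual expression noise sd (all genes).
#' @param n_sets,n_program_sets collection size and planted-set count.
#' @param program_fraction_range fraction of a program set's genes drawn
#'   from the program pool.
#' @param set_size_range inclusive integer range of set sizes.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param beta_latent log hazard ratio per latent unit.
#' @param censor_horizon uniform administrative censoring horizon, months.
#' @param metastasis_intercept,metastasis_slope logistic model of the
#'   metastasis label on the latent activity.
#' @param grade_cor target latent/grade correlation (weak by design so
#'   multivariate adjustment is exercised without making GSAS redundant).
#' @param seed master seed; every derived stream hangs off it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_samples = 200L,
                              program_size = 60L,
                              latent_means = c(-1.2, 1.2),
                              latent_sd = 0.4, latent_weight = 0.5,
                              loading = 0.8, noise_sd = 1.0,
                              n_sets = 150L, n_program_sets = 20L,
                              program_fraction_range = c(0.3, 0.7),
                              set_size_range = c(20L, 100L),
                              baseline_hazard = 0.05, beta_latent = 0.6,
                              censor_horizon = 120,
                              metastasis_intercept = -0.5,
                              metastasis_slope = 1.0,
                              grade_cor = 0.3,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              program_size = as.integer(program_size),
              latent_means = as.numeric(latent_means),
              latent_sd = as.numeric(latent_sd),
              latent_weight = as.numeric(latent_weight),
              loading = as.numeric(loading), noise_sd = as.numeric(noise_sd),
              n_sets = as.integer(n_sets),
              n_program_sets = as.integer(n_program_sets),
              program_fraction_range = as.numeric(program_fraction_range),
              set_size_range = as.integer(set_size_range),
              baseline_hazard = as.numeric(baseline_hazard),
              beta_latent = as.numeric(beta_latent),
              censor_horizon = as.numeric(censor_horizon),
              metastasis_intercept = as.numeric(metastasis_intercept),
              metastasis_slope = as.numeric(metastasis_slope),
              grade_cor = as.numeric(grade_cor),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0L, n_samples > 1L, program_size > 0L,
              program_size < n_genes, n_program_sets <= n_sets,
              n_sets > 0L, length(latent_means) == 2L, latent_sd > 0,
              latent_weight > 0, latent_weight < 1, noise_sd > 0,
              length(program_fraction_range) == 2L,
              program_fraction_range[1] > 0, program_fraction_range[2] <= 1,
              program_fraction_range[1] <= program_fraction_range[2],
              length(set_size_range) == 2L, set_size_range[1] >= 1L,
              set_size_range[1] <= set_size_range[2],
              set_size_range[2] < n_genes,
              baseline_hazard > 0, censor_horizon > 0)
  })
  structure(cfg, class = "simulation_config")
}

## Program gene identity is keyed to the master seed only, so every
## cohort of a benchmark (seed offsets) plants the same program.
.program_genes <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  with_seed(derive_seed(config$seed, "program-genes"),
            sample(genes, config$program_size))
}

#' Generate one synthetic cohort
#'
#' Expression for program genes is `loading * a_s + noise`; all other
#' genes are pure noise. Survival times are exponential with hazard
#' `baseline_hazard * exp(beta_latent * a_s)`, censored uniformly on
#' `[0, censor_horizon]`. Metastasis is Bernoulli on a logistic link of
#' the latent. Age, tumor size, ER and lymph-node status are drawn
#' independently; grade is weakly positively associated with the latent.
#'
#' @param config a [simulation_config()].
#' @param cohort integer cohort index (1-based seed offset); cohort
#'   `k > 1` redraws samples but shares gene identities with cohort 1.
#' @return list(expr, clinical, truth) where `truth` carries the planted
#'   `program_genes`, per-sample `latent_activity`, and the uncensored
#'   event/censor times.
#' @export
generate_cohort <- function(config, cohort = 1L) {
  stopifnot(inherits(config, "simulation_config"), cohort >= 1L)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  program <- .program_genes(config)
  samples <- sprintf("c%d_s%03d", cohort, seq_len(config$n_samples))
  n <- config$n_samples

  res <- with_seed(derive_seed(config$seed, paste0("cohort-", cohort)), {
    comp <- rbinom(n, 1L, 1 - config$latent_weight) # 1 = high component
    a <- rnorm(n, mean = config$latent_means[comp + 1L], sd = config$latent_sd)
    expr <- matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
                   config$n_genes, n, dimnames = list(genes, samples))
    expr[program, ] <- expr[program, , drop = FALSE] +
      matrix(config$loading * a, length(program), n, byrow = TRUE)

    event_time <- rexp(n, rate = config$baseline_hazard *
                            exp(config$beta_latent * a))
    censor_time <- runif(n, 0, config$censor_horizon)
    time <- pmin(event_time, censor_time)
    event <- as.numeric(event_time <= censor_time)

    metastasis <- rbinom(n, 1L, plogis(config$metastasis_intercept +
                                         config$metastasis_slope * a))
    age <- round(rnorm(n, 55, 10), 1)
    tumor_size <- round(pmax(0.2, rnorm(n, 2.5, 1.0)), 2)
    er_status <- rbinom(n, 1L, 0.7)
    ln_status <- rbinom(n, 1L, 0.4)
    rho <- config$grade_cor
    z <- rho * (a - mean(a)) / max(sd(a), 1e-12) +
      sqrt(max(0, 1 - rho^2)) * rnorm(n)
    grade <- cut(z, c(-Inf, qnorm(1 / 3), qnorm(2 / 3), Inf), labels = FALSE)
    list(a = a, expr = expr, time = time, event = event,
         event_time = event_time, censor_time = censor_time,
         metastasis = metastasis, age = age, tumor_size = tumor_size,
         er_status = er_status, ln_status = ln_status, grade = grade)
  })

  clinical <- validate_clinical(data.frame(
    sample = samples, time = res$time, event = res$event, age = res$age,
    tumor_size = res$tumor_size, grade = as.numeric(res$grade),
    er_status = res$er_status, ln_status = res$ln_status,
    metastasis = res$metastasis, stringsAsFactors = FALSE))

  truth <- list(program_genes = program,
                latent_activity = setNames(res$a, samples),
                event_time = setNames(res$event_time, samples),
                censor_time = setNames(res$censor_time, samples))
  list(expr = validate_expression(res$expr), clinical = clinical,
       truth = truth)
}

#' Generate the gene set collection companion to a simulated cohort
#'
#' `n_program_sets` sets draw a uniform fraction in
#' `program_fraction_range` of their genes from the planted program pool
#' (uniformly, capped at the pool size) and the remainder from the
#' background; the other sets are fully random. Because set sizes reach
#' above the program pool size, program sets share many program genes and
#' a large fraction of their pairwise Jaccard overlaps exceed 0.20.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element of [generate_cohort()] from the same
#'   configuration (supplies the program gene identities).
#' @return list(collection, program_set_names).
#' @export
generate_collection <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  program <- truth$program_genes
  if (!setequal(program, .program_genes(config)))
    stopf("truth does not match this configuration's program genes")
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  background <- setdiff(genes, program)
  fr <- config$program_fraction_range
  if (ceiling(fr[1] * config$set_size_range[1]) > length(program))
    stopf("program_size too small for program_fraction_range")

  sets <- with_seed(derive_seed(config$seed, "collection"), {
    out <- vector("list", config$n_sets)
    szr <- config$set_size_range
    for (i in seq_len(config$n_sets)) {
      ## sample.int avoids the sample(x, 1) scalar trap when the range
      ## is degenerate
      sz <- szr[1] + sample.int(szr[2] - szr[1] + 1L, 1L) - 1L
      if (i <= config$n_program_sets) {
        npr <- min(round(runif(1, fr[1], fr[2]) * sz), length(program), sz)
        out[[i]] <- c(sample(program, npr),
                      sample(background, sz - npr))
      } else {
        out[[i]] <- sample(genes, sz)
      }
    }
    out
  })
  names(sets) <- sprintf("SET_%03d", seq_len(config$n_sets))
  prog_names <- names(sets)[seq_len(config$n_program_sets)]
  desc <- ifelse(names(sets) %in% prog_names, "program", "random")
  list(collection = gene_set_collection(sets, desc),
       program_set_names = prog_names)
}

#' Generate a multi-cohort benchmark with shared ground truth
#'
#' Cohorts differ only by a per-cohort seed offset; the planted program
#' genes, the program set names, and the gene set collection are shared,
#' emulating independent patient cohorts screened against one database
#' of gene sets.
#'
#' @param config a [simulation_config()].
#' @param n_cohorts number of cohorts (>= 1).
#' @return list(cohorts, collection, program_set_names, truth) where
#'   `truth` is cohort 1's ground truth augmented with the shared
#'   program identities; each element of `cohorts` is a
#'   [generate_cohort()] result.
#' @export
generate_benchmark <- function(config, n_cohorts = 3L) {
  stopifnot(n_cohorts >= 1L)
  cohorts <- lapply(seq_len(n_cohorts), function(k) generate_cohort(config, k))
  coll <- generate_collection(config, cohorts[[1]]$truth)
  stage_log("benchmark: %d cohorts x %d samples, %d sets (%d program)",
            n_cohorts, config$n_samples, config$n_sets,
            config$n_program_sets)
  list(cohorts = cohorts, collection = coll$collection,
       program_set_names = coll$program_set_names,
       truth = cohorts[[1]]$truth)
}

#' BIC comparison of one- vs two-component Gaussian fits
#'
#' Tiny EM for a two-component, equal-variance-free Gaussian mixture,
#' used to check the planted bimodality of score distributions. Returns
#' TRUE when the two-component fit is BIC-preferred.
#'
#' @param x numeric vector.
#' @param n_iter EM iterations.
#' @return logical.
#' @export
bic_prefers_mixture <- function(x, n_iter = 200L) {
  n <- length(x)
  stopifnot(n >= 10L)
  ll1 <- sum(dnorm(x, mean(x), sd(x) * sqrt((n - 1) / n), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  mu <- quantile(x, c(0.25, 0.75), names = FALSE)
  sg <- rep(sd(x) / 2, 2); pi1 <- 0.5
  for (it in seq_len(n_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], sg[1]); d2 <- (1 - pi1) * dnorm(x, mu[2], sg[2])
    g <- d1 / pmax(d1 + d2, 1e-300)
    pi1 <- mean(g)
    mu[1] <- sum(g * x) / sum(g); mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sg[1] <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
    sg[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    sg <- pmax(sg, 1e-3 * sd(x))
  }
  ll2 <- sum(log(pmax(pi1 * dnorm(x, mu[1], sg[1]) +
                        (1 - pi1) * dnorm(x, mu[2], sg[2]), 1e-300)))
  bic2 <- -2 * ll2 + 5 * log(n)
  bic2 < bic1
}
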