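## Survival association of gene set activity scores: Cox proportional
## hazards (univariate and covariate-adjusted, Efron ties), dichotomized
## Kaplan-Meier / log-rank comparison, Benjamini-Hochberg adjustment,
## cross-cohort robust intersection, and sample clustering by score
## profiles.

.covariate_names <- c("age", "tumor_size", "grade", "grade_binary",
                      "er_status", "ln_status")

#' Binarize tumor grade
#'
#' Grade 2 and 3 tumors form one group (1), grade 1 the other (0);
#' missing stays missing.
#'
#' @param grade numeric vector with values in {1,2,3} or NA.
#' @return 0/1/NA numeric vector.
#' @export
grade_binary <- function(grade) {
  out <- ifelse(is.na(grade), NA_real_, as.numeric(grade >= 2))
  out
}

#' Fit a Cox proportional hazards model of survival on a score
#'
#' Partial-likelihood maximization with Efron tie handling (Breslow by
#' option) and per-covariate Wald tests. `covariates` may include
#' `age`, `tumor_size`, `grade` (binarized grade 2/3 vs 1), `er_status`,
#' `ln_status`; samples missing any used covariate are dropped and
#' counted. A zero-variance score yields the exact degenerate answer
#' (coefficient 0, hazard ratio 1, p 1) rather than a failed fit.
#'
#' @param scores named numeric vector (names = sample ids) or numeric
#'   aligned with `clinical$sample`.
#' @param clinical a `clinical_table`.
#' @param covariates character vector of clinical adjustment covariates
#'   (empty = univariate).
#' @param ties "efron" (default) or "breslow".
#' @return `cox_result`: list with `coefficients` (term, coef,
#'   hazard_ratio, se, z, wald_p), `n`, `n_events`, `n_dropped`,
#'   `ties`, `converged`, `score_test` (chi-square of the score test).
#' @export
fit_cox <- function(scores, clinical, covariates = character(0),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(clinical, "data.frame"))
  bad <- setdiff(covariates, .covariate_names)
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  if (!is.null(names(scores))) scores <- scores[clinical$sample]
  if (length(scores) != nrow(clinical))
    stopf("scores do not align with clinical samples")

  df <- data.frame(time = clinical$time, event = clinical$event,
                   score = as.numeric(scores))
  for (cv in covariates) {
    df[[cv]] <- if (cv %in% c("grade", "grade_binary"))
      grade_binary(clinical$grade) else clinical[[cv]]
  }
  usable <- complete.cases(df)
  n_dropped <- sum(!usable)
  if (n_dropped) stage_log("cox: dropped %d sample(s) with missing data", n_dropped)
  df <- df[usable, , drop = FALSE]
  n_events <- sum(df$event)
  if (n_events < 2) stopf("fewer than 2 events among usable samples")

  terms <- c("score", covariates)
  if (var(df$score) == 0) {
    coefs <- data.frame(term = "score", coef = 0, hazard_ratio = 1,
                        se = NA_real_, z = 0, wald_p = 1,
                        stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs, n = nrow(df),
                          n_events = n_events, n_dropped = n_dropped,
                          ties = ties, converged = TRUE,
                          score_test = 0, note = "constant score"),
                     class = "cox_result"))
  }

  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|singular|loglik", conditionMessage(w),
                ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  cf <- sm$coefficients
  coefs <- data.frame(term = rownames(cf), coef = cf[, "coef"],
                      hazard_ratio = cf[, "exp(coef)"],
                      se = cf[, "se(coef)"], z = cf[, "z"],
                      wald_p = cf[, "Pr(>|z|)"], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n = nrow(df), n_events = n_events,
                 n_dropped = n_dropped, ties = ties, converged = converged,
                 score_test = unname(sm$sctest["test"])),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result: n=%d, events=%d, ties=%s, converged=%s\n",
              x$n, x$n_events, x$ties, x$converged))
  print(x$coefficients)
  invisible(x)
}

#' Kaplan-Meier comparison of high vs low score groups
#'
#' Scores are dichotomized about 0 (`> 0` high, `<= 0` low), per-group
#' product-limit curves are estimated, and a two-group log-rank test is
#' run.
#'
#' @param scores named or aligned numeric vector.
#' @param clinical a `clinical_table`.
#' @return `km_comparison`: list with `groups` (per-sample factor),
#'   `curves` (group/time/n_risk/n_event/survival), `chisq`, `p`, `n`.
#' @export
km_logrank <- function(scores, clinical) {
  if (!is.null(names(scores))) scores <- scores[clinical$sample]
  stopifnot(length(scores) == nrow(clinical))
  grp <- factor(ifelse(scores > 0, "high", "low"), levels = c("low", "high"))
  if (any(tabulate(grp, 2L) == 0L))
    stopf("one score group is empty after dichotomization at 0; use the continuous Cox model instead")
  df <- data.frame(time = clinical$time, event = clinical$event, grp = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  curves <- data.frame(
    group = rep(sub("^grp=", "", names(sf$strata)), sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  chisq <- unname(sd$chisq)
  structure(list(groups = setNames(grp, clinical$sample), curves = curves,
                 chisq = chisq,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE),
                 n = nrow(df)),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat(sprintf("km_comparison: n=%d (low=%d, high=%d), log-rank chisq=%.3f, p=%.3g\n",
              x$n, sum(x$groups == "low"), sum(x$groups == "high"),
              x$chisq, x$p))
  invisible(x)
}

#' Plot the Kaplan-Meier curves of a high/low score comparison
#'
#' Base-graphics step plot of the two product-limit curves from
#' [km_logrank()] (low group first).
#'
#' @param km a `km_comparison`.
#' @param main plot title.
#' @param col two line colors (low, high).
#' @return invisibly, `km`.
#' @export
plot_km <- function(km, main = "", col = c("forestgreen", "firebrick")) {
  stopifnot(inherits(km, "km_comparison"))
  plot(NA, xlim = c(0, max(km$curves$time)), ylim = c(0, 1),
       xlab = "time (months)", ylab = "survival", main = main)
  for (i in seq_along(levels(km$groups))) {
    g <- levels(km$groups)[i]
    cv <- km$curves[km$curves$group == g, , drop = FALSE]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)),
                    do.points = FALSE, col = col[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = levels(km$groups), col = col,
                   lwd = 2, bty = "n")
  invisible(km)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  pmin(q, 1)
}

#' Screen every gene set of a GSAS matrix against survival
#'
#' One Cox model per set with the continuous GSAS as the covariate of
#' interest (the Kaplan-Meier dichotomization is presentational only).
#' Univariate by default; `covariates` adds clinical adjustment with
#' per-model complete-case analysis.
#'
#' @param gsas a `gsas_matrix` (sets x samples).
#' @param clinical a `clinical_table` covering the matrix samples.
#' @param covariates clinical covariates for adjustment (empty =
#'   univariate screen).
#' @param dataset label attached to the screen.
#' @return `survival_screen` data.frame: set, coef, hazard_ratio,
#'   wald_p, fdr_q, n, events, converged; q-values are BH across the
#'   screened collection.
#' @export
screen_survival <- function(gsas, clinical, covariates = character(0),
                            dataset = "dataset") {
  stopifnot(inherits(gsas, "gsas_matrix") || is.matrix(gsas))
  shared <- intersect(colnames(gsas), clinical$sample)
  if (!length(shared)) stopf("no shared samples between scores and clinical")
  clin <- clinical[match(shared, clinical$sample), , drop = FALSE]
  stage_log("survival screen '%s': %d sets x %d samples (%s)", dataset,
            nrow(gsas), length(shared),
            if (length(covariates)) paste("adjusted:", paste(covariates, collapse = ","))
            else "univariate")
  rows <- lapply(rownames(gsas), function(s) {
    cr <- fit_cox(gsas[s, shared], clin, covariates = covariates)
    sc <- cr$coefficients[cr$coefficients$term == "score", , drop = FALSE]
    data.frame(set = s, coef = sc$coef, hazard_ratio = sc$hazard_ratio,
               wald_p = sc$wald_p, n = cr$n, events = cr$n_events,
               converged = cr$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$wald_p)
  out <- out[, c("set", "coef", "hazard_ratio", "wald_p", "fdr_q",
                 "n", "events", "converged")]
  rownames(out) <- NULL
  structure(out, dataset = dataset, covariates = covariates,
            class = c("survival_screen", "data.frame"))
}

#' Intersect significant sets across cohort screens
#'
#' A set is robust when its univariate Cox Wald p is below `alpha` in
#' every screen.
#'
#' @param screens list of [screen_survival()] results over a shared
#'   collection.
#' @param alpha per-screen significance level (default 0.05).
#' @return data.frame with one row per robust set and per-screen
#'   `p.<dataset>` / `hr.<dataset>` columns; the `set` column holds the
#'   robust names.
#' @export
robust_intersection <- function(screens, alpha = 0.05) {
  stopifnot(length(screens) >= 2L)
  labels <- vapply(seq_along(screens), function(i)
    attr(screens[[i]], "dataset") %||% paste0("screen", i), "")
  shared <- Reduce(intersect, lapply(screens, function(s) s$set))
  if (!length(shared)) stopf("screens cover disjoint collections")
  sig <- lapply(screens, function(s) s$set[s$wald_p < alpha])
  robust <- Reduce(intersect, c(list(shared), sig))
  out <- data.frame(set = robust, stringsAsFactors = FALSE)
  for (i in seq_along(screens)) {
    s <- screens[[i]]
    out[[paste0("p.", labels[i])]] <- s$wald_p[match(robust, s$set)]
    out[[paste0("hr.", labels[i])]] <- s$hazard_ratio[match(robust, s$set)]
  }
  attr(out, "alpha") <- alpha
  out
}

#' Cluster samples by their GSAS profiles over a set subset
#'
#' Agglomerative clustering (Euclidean distance, average linkage) on the
#' uncapped scores, cut into two groups. For display, the returned heat
#' matrix caps scores to [-3, 3]; clustering itself is never capped.
#'
#' @param gsas a `gsas_matrix`.
#' @param set_subset set names to cluster on (e.g. the robust sets).
#' @param cap display cap (default 3).
#' @return list with `groups` (named 1/2 vector), `heat` (capped matrix,
#'   samples in dendrogram order), `hclust`.
#' @export
cluster_gsas <- function(gsas, set_subset, cap = 3) {
  set_subset <- intersect(set_subset, rownames(gsas))
  if (!length(set_subset)) stopf("set_subset matches no scored sets")
  if (ncol(gsas) < 2L) stopf("need at least 2 samples to cluster")
  m <- unclass(gsas)[set_subset, , drop = FALSE]
  hc <- hclust(dist(t(m)), method = "average")
  groups <- cutree(hc, k = 2)
  heat <- pmin(pmax(m, -cap), cap)[, hc$order, drop = FALSE]
  list(groups = groups, heat = heat, hclust = hc)
}
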