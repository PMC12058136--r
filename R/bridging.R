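#' Model specification for the bridging-disease regression
#'
#' Describes the gender-stratified logistic model for the complex
#' (multisystem) phenotype: which disease indicators enter as predictors
#' (typically the top bridging candidates from [rank_bridges()] — the cutoff
#' is the analyst's, never hard-coded), which demographic covariates are
#' controlled for, and their reference levels.
#'
#' @param predictors Character vector of disease codes used as predictors.
#' @param covariates Demographic covariates (default age group, income
#'   quartile, education).
#' @param reference Named list of reference levels for the covariates
#'   (defaults: age 50-64, income Q1, education Primary).
#' @param stratify_by Stratification column (default `"gender"`; `NULL` fits
#'   one pooled model).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(predictors,
                       covariates = c("age_group", "income_q", "education"),
                       reference = list(age_group = "50-64", income_q = "Q1",
                                        education = "Primary"),
                       stratify_by = "gender") {
  stopifnot(is.character(predictors), length(predictors) >= 1)
  structure(list(predictors = predictors, covariates = covariates,
                 reference = reference, stratify_by = stratify_by),
            class = "model_spec")
}

star_for <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

fit_logistic_one <- function(data, formula) {
  fit <- suppressWarnings(stats::glm(
    formula, data = data, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  sm <- summary(fit)
  cf <- sm$coefficients
  separation <- any(abs(cf[, "Estimate"]) > 15) || any(cf[, "Std. Error"] > 1e3)
  if (separation) {
    warning("possible separation: coefficients or standard errors are extreme")
  }
  zcrit <- stats::qnorm(0.975)
  est <- unname(cf[, "Estimate"])
  se <- unname(cf[, "Std. Error"])
  pv <- unname(cf[, "Pr(>|z|)"])
  tibble::tibble(
    term = rownames(cf),
    estimate = est,
    std_error = se,
    OR = exp(est),
    CI_low = exp(est - zcrit * se),
    CI_high = exp(est + zcrit * se),
    p_value = pv,
    stars = star_for(pv),
    converged = fit$converged,
    separation = separation,
    n = stats::nobs(fit)
  )
}

#' Gender-stratified logistic regression for the complex phenotype
#'
#' Maximum-likelihood logistic regression (IRLS, convergence tolerance 1e-10,
#' up to 100 iterations) of the complex multimorbidity flag on bridging
#' disease indicators plus demographic controls, fitted separately per
#' stratum. Standard errors come from the inverse observed information;
#' odds ratios carry 95% Wald intervals and significance stars at
#' 0.05 / 0.01 / 0.001. Persons with missing covariates are dropped listwise
#' (count recorded per stratum). A stratum whose outcome is single-class is
#' skipped with an error record; suspected separation (any |coefficient| > 15
#' or SE > 1000) is flagged but estimates are still reported.
#'
#' @param cohort A validated cohort tibble.
#' @param assignment A [assign_patterns()] result aligned with `cohort`
#'   (source of the `complex_flag` outcome), or `NULL` if `cohort` already
#'   has a `complex_flag` column.
#' @param spec A [model_spec()].
#' @return An object of class `mm_logistic`: list with `results` (tibble of
#'   per-term estimates across strata), `skipped` (tibble of skipped strata
#'   and reasons) and `n_dropped` (listwise deletions per stratum).
#' @export
fit_logistic <- function(cohort, assignment = NULL, spec) {
  stopifnot(inherits(spec, "model_spec"))
  data <- tibble::as_tibble(cohort)
  if (!is.null(assignment)) {
    stopifnot(identical(assignment$person_id, cohort$person_id))
    data$complex_flag <- assignment$complex_flag
  }
  if (!"complex_flag" %in% names(data)) {
    stop("no outcome: supply an assignment or a complex_flag column",
         call. = FALSE)
  }
  miss <- setdiff(c(spec$predictors, spec$covariates), names(data))
  if (length(miss) > 0) {
    stop("missing model column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in names(spec$reference)) {
    if (v %in% spec$covariates) {
      if (!spec$reference[[v]] %in% levels(data[[v]])) {
        stop("reference level ", spec$reference[[v]], " absent for ", v,
             call. = FALSE)
      }
      data[[v]] <- stats::relevel(data[[v]], ref = spec$reference[[v]])
    }
  }
  # constant predictor columns carry no information and break the fit
  keep_pred <- spec$predictors[vapply(spec$predictors, function(v)
    length(unique(data[[v]])) > 1, logical(1))]
  dropped_pred <- setdiff(spec$predictors, keep_pred)
  if (length(dropped_pred) > 0) {
    warning("constant predictor(s) dropped: ",
            paste(dropped_pred, collapse = ", "))
  }
  rhs <- paste(c(keep_pred, spec$covariates), collapse = " + ")
  formula <- stats::as.formula(paste("complex_flag ~", rhs))
  strata <- if (is.null(spec$stratify_by)) list(pooled = data) else
    split(data, data[[spec$stratify_by]])
  results <- list()
  skipped <- list()
  n_dropped <- list()
  for (sname in names(strata)) {
    d <- strata[[sname]]
    cc <- stats::complete.cases(d[c("complex_flag", keep_pred, spec$covariates)])
    n_dropped[[sname]] <- sum(!cc)
    d <- d[cc, , drop = FALSE]
    if (nrow(d) == 0 || length(unique(d$complex_flag)) < 2) {
      skipped[[sname]] <- tibble::tibble(
        stratum = sname, reason = "outcome single-class or empty stratum")
      next
    }
    res <- fit_logistic_one(d, formula)
    res$stratum <- sname
    results[[sname]] <- res
  }
  structure(list(
    results = dplyr::bind_rows(results),
    skipped = dplyr::bind_rows(skipped),
    n_dropped = tibble::tibble(stratum = names(n_dropped),
                               n_dropped = unname(unlist(n_dropped))),
    spec = spec, formula = formula
  ), class = "mm_logistic")
}

#' @export
print.mm_logistic <- function(x, ...) {
  cat("<mm_logistic>\n")
  print(tidy.mm_logistic(x))
  invisible(x)
}

#' @export
#' @method tidy mm_logistic
tidy.mm_logistic <- function(x, ...) {
  dplyr::select(x$results, "stratum", "term", "OR", "CI_low", "CI_high",
                "stars", "estimate", "std_error", "p_value", "separation")
}

#' @export
#' @method glance mm_logistic
glance.mm_logistic <- function(x, ...) {
  if (nrow(x$results) == 0) {
    return(tibble::tibble(stratum = character(), n = integer(),
                          converged = logical(), separation = logical()))
  }
  dplyr::summarize(dplyr::group_by(x$results, .data$stratum),
                   n = .data$n[1], converged = all(.data$converged),
                   separation = any(.data$separation), .groups = "drop")
}

#' Write regression results as CSV
#'
#' One row per term per stratum: OR, 95% CI, stars — the usual reporting
#' shape for multimorbidity odds-ratio tables.
#'
#' @param fit An `mm_logistic`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regression <- function(fit, path) {
  readr::write_csv(tidy.mm_logistic(fit), path, progress = FALSE)
  invisible(path)
}

#' Odds-ratio recovery against planted truth
#'
#' Simulation harness for the regression stage: repeatedly generates cohorts
#' with a known logistic outcome ([generate_regression_cohort()]), refits the
#' model, and reports per-predictor mean odds ratio, bias on the log scale,
#' 95% CI coverage of the truth, and how often separation was flagged.
#'
#' @param spec A [demographic_spec()] with `outcome_link` set.
#' @param prevalence Named predictor prevalences.
#' @param n Cohort size per replicate.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A tibble `term`, `true_OR`, `mean_OR`, `log_bias`, `coverage`,
#'   `n_separation`, `n_reps`.
#' @export
recover_planted_ors <- function(spec, prevalence, n = 2000, n_reps = 20,
                                seed = 1) {
  link <- spec$outcome_link
  stopifnot(!is.null(link))
  beta <- link$beta
  preds <- names(beta)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    coh <- generate_regression_cohort(spec, n = n, prevalence = prevalence,
                                      seed = seed + r)
    coh$complex_flag <- coh$outcome == 1
    ms <- model_spec(preds, covariates = character(), reference = list(),
                     stratify_by = NULL)
    fit <- suppressWarnings(fit_logistic(coh, assignment = NULL, spec = ms))
    res <- fit$results[fit$results$term %in% preds, ]
    res$rep <- r
    res
  })
  dplyr::summarize(
    dplyr::group_by(reps, .data$term),
    true_OR = exp(beta[.data$term[1]]),
    mean_OR = mean(.data$OR),
    log_bias = mean(.data$estimate) - beta[.data$term[1]],
    coverage = mean(.data$CI_low <= exp(beta[.data$term[1]]) &
                      exp(beta[.data$term[1]]) <= .data$CI_high),
    n_separation = sum(.data$separation),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
}
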