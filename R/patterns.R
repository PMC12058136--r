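#' Assign persons to multimorbidity patterns
#'
#' A person is assigned to pattern `P` iff they carry at least `min_count`
#' diseases whose community is `P`. Assignment is non-exclusive: one person
#' may hold several patterns, and their prevalences may therefore sum to more
#' than 1. The complex (multisystem) phenotype is derived, never supplied:
#' `complex_flag` is `TRUE` exactly when a person holds two or more patterns.
#' Communities smaller than `min_count` are unreachable under this rule and
#' trigger a warning.
#'
#' @param cohort A validated cohort tibble.
#' @param partition A `community_partition` (from [detect_communities()]) or a
#'   named vector mapping disease codes to community ids; must cover the
#'   catalog's network nodes.
#' @param min_count Diseases required within a community to hold its pattern
#'   (default 2, the conventional multimorbidity threshold).
#' @return An object of class `pattern_assignment`: tibble with `person_id`,
#'   `patterns` (";"-joined community ids, "" if none), `n_patterns`,
#'   `complex_flag`; attributes keep the membership and `min_count`.
#' @export
assign_patterns <- function(cohort, partition, min_count = 2) {
  stopifnot(min_count >= 1)
  if (inherits(partition, "community_partition")) {
    membership <- stats::setNames(partition$membership$community,
                                  partition$membership$disease)
  } else {
    membership <- partition
  }
  catalog <- cohort_catalog(cohort)
  covered <- intersect(catalog$code, names(membership))
  if (length(covered) == 0) stop("partition covers no catalog disease", call. = FALSE)
  sizes <- table(membership[covered])
  small <- names(sizes)[sizes < min_count]
  if (length(small) > 0) {
    warning("community(ies) ", paste(small, collapse = ", "),
            " have fewer than min_count diseases and are unreachable")
  }
  X <- disease_matrix(cohort, catalog)[, covered, drop = FALSE]
  comms <- sort(unique(membership[covered]))
  # person x community matrix of disease counts
  if (nrow(X) == 0) {
    M <- matrix(0L, 0, length(comms), dimnames = list(NULL, as.character(comms)))
  } else {
    M <- vapply(comms, function(cm) {
      cols <- covered[membership[covered] == cm]
      as.integer(rowSums(X[, cols, drop = FALSE]))
    }, integer(nrow(X)))
    M <- matrix(M, nrow = nrow(X), dimnames = list(NULL, as.character(comms)))
  }
  A <- M >= min_count
  patterns <- if (nrow(X) == 0) character(0) else
    apply(A, 1, function(r) paste(comms[r], collapse = ";"))
  n_patterns <- as.integer(rowSums(A))
  out <- tibble::tibble(
    person_id = cohort$person_id,
    patterns = as.character(patterns),
    n_patterns = n_patterns,
    complex_flag = n_patterns >= 2
  )
  attr(out, "membership") <- membership
  attr(out, "min_count") <- min_count
  attr(out, "indicator") <- A
  class(out) <- c("pattern_assignment", class(out))
  out
}

#' Pattern prevalence by stratum
#'
#' Proportion of persons holding each pattern (and the complex phenotype),
#' overall or within strata of a categorical cohort field.
#'
#' @param assignment A [assign_patterns()] result.
#' @param cohort The cohort it was computed from (same person order).
#' @param stratify Optional categorical cohort column name.
#' @return A tibble `pattern`, `stratum`, `count`, `n`, `prevalence`. The
#'   complex phenotype appears as pattern `"complex"`.
#' @export
pattern_prevalence <- function(assignment, cohort, stratify = NULL) {
  stopifnot(identical(assignment$person_id, cohort$person_id))
  A <- attr(assignment, "indicator")
  A <- cbind(A, complex = assignment$complex_flag)
  if (is.null(stratify)) {
    groups <- list(overall = seq_len(nrow(cohort)))
  } else {
    lv <- levels(cohort[[stratify]])
    groups <- stats::setNames(lapply(lv, function(l)
      which(cohort[[stratify]] == l)), lv)
  }
  purrr::map_dfr(names(groups), function(g) {
    idx <- groups[[g]]
    nn <- length(idx)
    cnt <- if (nn == 0) rep(0L, ncol(A)) else colSums(A[idx, , drop = FALSE])
    tibble::tibble(pattern = colnames(A), stratum = g,
                   count = as.integer(unname(cnt)), n = nn,
                   prevalence = if (nn == 0) NA_real_ else unname(cnt) / nn)
  })
}

#' Compare pattern prevalences between genders
#'
#' Pooled-variance two-proportion z-test per pattern (and for the complex
#' phenotype), two-sided at the 95% confidence level:
#' `z = (p_M - p_F) / sqrt(p(1-p)(1/n_M + 1/n_F))` with `p` the pooled
#' proportion. When the pooled variance is zero (both prevalences 0 or both
#' 1) the z statistic is undefined and the pattern is reported as
#' non-significant with `degenerate = TRUE`.
#'
#' @inheritParams pattern_prevalence
#' @param alpha Two-sided significance level (default 0.05).
#' @return A tibble `pattern`, `prevalence_M`, `prevalence_F`, `z`,
#'   `significant`, `degenerate`.
#' @export
compare_prevalence <- function(assignment, cohort, alpha = 0.05) {
  prev <- pattern_prevalence(assignment, cohort, stratify = "gender")
  wide <- tidyr::pivot_wider(prev, id_cols = "pattern",
                             names_from = "stratum",
                             values_from = c("count", "n", "prevalence"))
  if (any(is.na(wide$n_M)) || any(wide$n_M == 0) || any(wide$n_F == 0)) {
    stop("both gender strata must be nonempty", call. = FALSE)
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  out <- dplyr::mutate(
    wide,
    pooled = (.data$count_M + .data$count_F) / (.data$n_M + .data$n_F),
    se = sqrt(.data$pooled * (1 - .data$pooled) *
                (1 / .data$n_M + 1 / .data$n_F)),
    z = ifelse(.data$se > 0,
               (.data$prevalence_M - .data$prevalence_F) / .data$se, NA_real_),
    significant = !is.na(.data$z) & abs(.data$z) >= zcrit,
    degenerate = .data$se == 0
  )
  dplyr::select(out, "pattern", prevalence_M = "prevalence_M",
                prevalence_F = "prevalence_F", "z", "significant",
                "degenerate")
}

#' Write a pattern assignment as CSV
#'
#' @param assignment A [assign_patterns()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  readr::write_csv(tibble::as_tibble(assignment)[
    c("person_id", "patterns", "n_patterns", "complex_flag")], path,
    progress = FALSE)
  invisible(path)
}
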