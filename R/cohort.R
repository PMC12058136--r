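#' @importFrom rlang .data
NULL

DEMOGRAPHIC_LEVELS <- list(
  gender = c("M", "F"),
  age_group = c("50-64", "65-74", "75plus"),
  income_q = c("Q1", "Q2", "Q3", "Q4"),
  education = c("Primary", "Secondary", "Tertiary")
)

#' Validate a cohort data frame
#'
#' A cohort is a tibble with one row per person: `person_id`, the categorical
#' demographics `gender` (M/F), `age_group` (50-64 / 65-74 / 75plus),
#' `income_q` (Q1..Q4), `education` (Primary/Secondary/Tertiary), and one 0/1
#' column per catalog disease code. Disease values must be complete and
#' strictly binary; missing demographic values are allowed but flagged (they
#' are dropped listwise only at the regression stage). The catalog is attached
#' as an attribute so disease columns are always addressed by code.
#'
#' @param data A data frame.
#' @param catalog A [disease_catalog()]; defaults to [default_catalog()].
#' @return The validated cohort tibble with attribute `"catalog"`.
#' @export
validate_cohort <- function(data, catalog = default_catalog()) {
  stopifnot(is.data.frame(data), inherits(catalog, "disease_catalog"))
  need <- c("person_id", names(DEMOGRAPHIC_LEVELS), catalog$code)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$person_id <- as.character(data$person_id)
  if (anyDuplicated(data$person_id)) {
    stop("person_id values must be unique", call. = FALSE)
  }
  for (v in names(DEMOGRAPHIC_LEVELS)) {
    x <- as.character(data[[v]])
    bad <- !is.na(x) & !(x %in% DEMOGRAPHIC_LEVELS[[v]])
    if (any(bad)) {
      stop(sprintf("invalid %s value(s): %s", v,
                   paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
    data[[v]] <- factor(x, levels = DEMOGRAPHIC_LEVELS[[v]])
  }
  n_na_demo <- sum(!stats::complete.cases(data[names(DEMOGRAPHIC_LEVELS)]))
  if (n_na_demo > 0) {
    message(n_na_demo, " person(s) have missing demographic values; ",
            "retained (listwise deletion happens at the regression stage)")
  }
  for (code in catalog$code) {
    x <- data[[code]]
    if (is.character(x)) x <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(x) | !(x %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf(
        "disease column %s has non-binary value(s) in row(s): %s",
        code, paste(utils::head(bad, 10), collapse = ", ")
      ), call. = FALSE)
    }
    data[[code]] <- as.integer(x)
  }
  attr(data, "catalog") <- catalog
  data
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, headered cohort file with columns
#' `person_id, gender, age_group, income_q, education, <disease codes>` (an
#' `id` header is accepted as an alias for `person_id`) and validates it with
#' [validate_cohort()].
#'
#' @param path Path to the cohort CSV.
#' @inheritParams validate_cohort
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if ("id" %in% names(data) && !"person_id" %in% names(data)) {
    names(data)[names(data) == "id"] <- "person_id"
  }
  validate_cohort(data, catalog)
}

#' Write a cohort CSV
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Extract the person x disease 0/1 matrix from a cohort
#'
#' @inheritParams write_cohort
#' @param catalog Optional catalog; defaults to the one attached to `cohort`.
#' @return An integer matrix, rows named by `person_id`, columns by code.
#' @export
disease_matrix <- function(cohort, catalog = NULL) {
  catalog <- catalog %||% attr(cohort, "catalog") %||% default_catalog()
  X <- as.matrix(cohort[catalog$code])
  storage.mode(X) <- "integer"
  rownames(X) <- cohort$person_id
  X
}

cohort_catalog <- function(cohort) {
  attr(cohort, "catalog") %||% default_catalog()
}

#' Restrict a cohort to people with multimorbidity
#'
#' Keeps exactly the persons carrying at least `min_diseases` of the catalog
#' conditions (the usual multimorbidity criterion is two or more chronic
#' diseases). Row order is preserved; the filter is always explicit, never
#' applied implicitly by other functions.
#'
#' @inheritParams disease_matrix
#' @param min_diseases Minimum disease count to retain a person (default 2).
#' @return The filtered cohort tibble.
#' @export
filter_multimorbid <- function(cohort, min_diseases = 2) {
  stopifnot(is.numeric(min_diseases), min_diseases >= 0)
  keep <- rowSums(disease_matrix(cohort)) >= min_diseases
  out <- cohort[keep, , drop = FALSE]
  attr(out, "catalog") <- cohort_catalog(cohort)
  out
}

#' Per-disease prevalence, optionally stratified
#'
#' Counts and proportions of each catalog disease, overall or within the
#' levels of one categorical cohort field. Empty strata yield `NA` proportions
#' with `undefined = TRUE` rather than propagating NaN.
#'
#' @inheritParams disease_matrix
#' @param stratify Optional name of a categorical cohort column
#'   (e.g. `"gender"`).
#' @return A tibble with columns `disease`, `stratum`, `count`, `n`,
#'   `proportion`, `undefined`.
#' @export
summarize_prevalence <- function(cohort, stratify = NULL) {
  catalog <- cohort_catalog(cohort)
  X <- disease_matrix(cohort, catalog)
  if (is.null(stratify)) {
    groups <- list(overall = seq_len(nrow(cohort)))
  } else {
    if (!stratify %in% names(DEMOGRAPHIC_LEVELS)) {
      stop("stratify must be one of: ",
           paste(names(DEMOGRAPHIC_LEVELS), collapse = ", "), call. = FALSE)
    }
    lv <- levels(cohort[[stratify]])
    groups <- lapply(lv, function(l) which(cohort[[stratify]] == l))
    names(groups) <- lv
  }
  purrr::map_dfr(names(groups), function(g) {
    idx <- groups[[g]]
    nn <- length(idx)
    count <- if (nn == 0) rep(0L, ncol(X)) else colSums(X[idx, , drop = FALSE])
    tibble::tibble(
      disease = catalog$code,
      stratum = g,
      count = as.integer(count),
      n = nn,
      proportion = if (nn == 0) NA_real_ else count / nn,
      undefined = nn == 0
    )
  })
}
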