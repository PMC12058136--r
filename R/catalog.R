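#' Disease catalog
#'
#' A disease catalog is a tibble with columns `code` and `label` fixing the
#' identity and order of the binary disease indicators. All downstream
#' functions address disease columns by catalog code, never by position.
#'
#' @param code Character vector of unique disease codes (e.g. `"D1"`).
#' @param label Character vector of human-readable names, same length.
#'
#' @return A tibble with columns `code`, `label` and class `disease_catalog`.
#' @export
#' @examples
#' disease_catalog(c("D1", "D2"), c("Hypertension", "Infarction"))
disease_catalog <- function(code, label) {
  stopifnot(is.character(code), is.character(label))
  if (length(code) < 2) {
    stop("a disease catalog needs at least 2 codes", call. = FALSE)
  }
  if (anyDuplicated(code)) {
    stop("disease codes must be unique", call. = FALSE)
  }
  if (length(label) != length(code) || anyNA(label) || any(label == "")) {
    stop("every code needs a non-empty label", call. = FALSE)
  }
  out <- tibble::tibble(code = code, label = label)
  class(out) <- c("disease_catalog", class(out))
  out
}

#' The default 32-condition chronic disease catalog
#'
#' Thirty-two self-reported diagnosed chronic conditions commonly used in
#' survey-based multimorbidity studies of adults aged 50+, coded D1..D32.
#'
#' @return A `disease_catalog` tibble with 32 rows.
#' @export
default_catalog <- function() {
  disease_catalog(
    code = paste0("D", 1:32),
    label = c(
      "Hypertension", "Infarction", "Coronary disease", "Other heart",
      "Varicose veins", "Arthrosis", "Cervical pain", "Lumbar pain",
      "Allergy", "Asthma", "Respiratory disease", "Diabetes",
      "Stomach ulcer", "Urinary incontinence", "Cholesterol", "Cataracts",
      "Skin condition", "Constipation", "Hepatic dysfunction", "Depression",
      "Anxiety", "Other mental", "Stroke", "Migraine",
      "Haemorrhoids", "Cancer", "Osteoporosis", "Thyroid disease",
      "Kidney disease", "Prostate/Menopausal problems", "Accidents", "Obesity"
    )
  )
}

#' Read or write a disease catalog as JSON
#'
#' The on-disk format is a single JSON object mapping code to label, in
#' catalog order.
#'
#' @param catalog A `disease_catalog`.
#' @param path File path.
#' @return `read_catalog()` returns a `disease_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "disease_catalog"))
  x <- as.list(stats::setNames(catalog$label, catalog$code))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path)
  disease_catalog(names(x), vapply(x, as.character, character(1)))
}
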