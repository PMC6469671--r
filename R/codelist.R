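#' Read a codelist
#'
#' A codelist maps abstract clinical concepts to a single category (the unit
#' all classification and ascertainment rules operate on) and to illustrative
#' per-dialect code strings. Real ICD/Read/NDC vocabularies are deliberately
#' out of scope: every rule in the package runs on concepts and categories,
#' and the code strings exist only so that written bundles look like coded
#' data. A concept is *active* in a dialect when it carries a non-empty code
#' string for that dialect (e.g. overdose is a recordable suicidal-behavior
#' concept in the EMR dialect only).
#'
#' @param path path to a CSV with columns
#'   `concept,label,category,dod_codes,cprd_codes`.
#' @return a tibble of class `msphen_codelist`.
#' @export
read_codelist <- function(path) {
  cl <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("concept", "label", "category", "dod_codes", "cprd_codes")
  missing <- setdiff(required, names(cl))
  if (length(missing) > 0) {
    stop("codelist is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cl$dod_codes[is.na(cl$dod_codes)] <- ""
  cl$cprd_codes[is.na(cl$cprd_codes)] <- ""
  if (anyDuplicated(cl$concept)) {
    stop("codelist concepts must be unique", call. = FALSE)
  }
  class(cl) <- c("msphen_codelist", class(cl))
  cl
}

#' Packaged illustrative codelist
#'
#' @return the codelist shipped with the package (see [read_codelist()]).
#' @export
default_codelist <- function() {
  read_codelist(system.file("extdata", "codelist.csv", package = "msphen"))
}

#' Concepts belonging to one or more categories
#'
#' @param codelist a codelist.
#' @param categories character vector of category names; `infection:*`-style
#'   prefixes can be matched with `prefix = TRUE`.
#' @param prefix match categories as prefixes (e.g. `"infection:"`).
#' @return character vector of concept identifiers.
#' @export
concepts_in <- function(codelist, categories, prefix = FALSE) {
  if (prefix) {
    hit <- Reduce(`|`, lapply(categories, function(p) startsWith(codelist$category, p)))
  } else {
    known <- unique(codelist$category)
    unknown <- setdiff(categories, known)
    if (length(unknown) > 0) {
      stop("unknown concept category: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    hit <- codelist$category %in% categories
  }
  codelist$concept[hit]
}

#' Concepts active (codable) in a dialect
#'
#' @inheritParams concepts_in
#' @param dialect `"CLAIMS_DOD"` or `"EMR_CPRD"`.
#' @return character vector of concepts with a non-empty code string in the
#'   dialect.
#' @export
active_concepts <- function(codelist, dialect) {
  dialect <- match_dialect(dialect)
  col <- if (dialect == "CLAIMS_DOD") "dod_codes" else "cprd_codes"
  codelist$concept[nzchar(codelist[[col]])]
}

match_dialect <- function(dialect) {
  match.arg(dialect, c("CLAIMS_DOD", "EMR_CPRD"))
}

category_of <- function(codelist, concepts) {
  codelist$category[match(concepts, codelist$concept)]
}
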