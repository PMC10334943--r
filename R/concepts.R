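#' Create a concept set
#'
#' A concept set is a named collection of vocabulary concept identifiers
#' (opaque integers) that defines which clinical codes a phenotype
#' algorithm treats as qualifying.  No vocabulary-hierarchy expansion is
#' performed: the identifiers listed are the identifiers matched.
#'
#' @param name Character label for the set.
#' @param concept_ids Integer vector of concept identifiers; must be
#'   non-empty and free of duplicates.
#' @return An object of class `concept_set`.
#' @examples
#' concept_set("hs", c(4241223, 434119))
#' @export
concept_set <- function(name, concept_ids) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_domain("concept set 'name' must be a single non-empty string")
  }
  ids <- as.integer(concept_ids)
  if (length(ids) == 0L || anyNA(ids)) {
    stop_domain("concept set '%s' must contain at least one concept id", name)
  }
  if (anyDuplicated(ids)) {
    stop_domain("concept set '%s' contains duplicate concept ids", name)
  }
  structure(list(name = name, concept_ids = ids), class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat(sprintf("<concept_set> %s: %d concepts\n", x$name, length(x$concept_ids)))
  cat(" ", paste(utils::head(x$concept_ids, 10L), collapse = ", "),
      if (length(x$concept_ids) > 10L) "..." else "", "\n")
  invisible(x)
}

#' The hidradenitis suppurativa concept set
#'
#' The two standard-vocabulary concepts for hidradenitis suppurativa:
#' 4241223 ("hidradenitis suppurativa", mapping from ICD-10 L73.2) and
#' 434119 ("hidradenitis", mapping from ICD-9 705.83).  Additional
#' user-supplied identifiers may be appended.
#'
#' @param extra Optional integer vector of additional concept ids.
#' @return A `concept_set`.
#' @export
hs_concept_set <- function(extra = integer()) {
  concept_set("hidradenitis suppurativa",
              unique(c(4241223L, 434119L, as.integer(extra))))
}

#' Read a concept set from a two-column CSV
#'
#' Expects columns `concept_id` and `concept_name` (the latter is kept
#' only for display; matching is on the id).
#'
#' @param path Path to a CSV file.
#' @param name Name for the set; defaults to the file name.
#' @return A `concept_set`.
#' @export
read_concept_set <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"concept_id" %in% names(df)) {
    stop_domain("concept set file '%s' lacks required column 'concept_id'", path)
  }
  concept_set(name %||% sub("\\.csv$", "", basename(path)),
              df$concept_id)
}
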