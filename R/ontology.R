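#' Construct a gene-to-category ontology map
#'
#' Maps each gene family to exactly one functional category (a two-level
#' hierarchy collapsed to the level under test, in the style of a FOAM
#' functional sublevel).  Single membership keeps per-category core-gene
#' counts well defined and the permutation null exact.
#'
#' @param x A data frame with character columns `gene_id` and
#'   `category_id`; each `gene_id` must appear exactly once.
#' @param categories Optional character vector fixing the category order
#'   (and possibly naming categories with no assigned gene).  Defaults to
#'   first-appearance order in `x`.
#'
#' @return A tibble of class `ontology_map` with a `categories` attribute.
#' @export
ontology_map <- function(x, categories = NULL) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)[, c("gene_id", "category_id")]
  x$gene_id <- as.character(x$gene_id)
  x$category_id <- as.character(x$category_id)
  if (anyNA(x)) abort("Ontology map may not contain missing values.")
  if (anyDuplicated(x$gene_id)) {
    abort(sprintf("Each gene maps to exactly one category; duplicated: %s",
                  paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", ")))
  }
  categories <- categories %||% unique(x$category_id)
  if (anyDuplicated(categories)) abort("`categories` must be unique.")
  missing_cat <- setdiff(x$category_id, categories)
  if (length(missing_cat)) {
    abort(sprintf("Categories used in assignments but absent from `categories`: %s",
                  paste(missing_cat, collapse = ", ")))
  }
  class(x) <- c("tbl_df", "tbl", "data.frame")
  structure(x, class = c("ontology_map", class(x)), categories = as.character(categories))
}

check_ontology <- function(ontology) {
  if (!inherits(ontology, "ontology_map")) {
    abort("Expected an `ontology_map` (see `ontology_map()` or `read_ontology()`).")
  }
  invisible(ontology)
}

#' @rdname ontology_map
#' @param ontology An `ontology_map`.
#' @export
category_ids <- function(ontology) {
  check_ontology(ontology)
  attr(ontology, "categories")
}

#' Read an ontology map from a two-column TSV file
#'
#' Expects a header and two tab-separated columns, `gene_id` and
#' `category_id`; `#` comment lines are skipped.  Errors name the
#' offending file line.
#'
#' @param path Path to the TSV file.
#' @return An [ontology_map()].
#' @export
read_ontology <- function(path) {
  parsed <- parse_tsv_lines(path, min_cols = 2L)
  recs <- parsed$body
  for (rec in recs) {
    if (length(rec$fields) != 2L) {
      abort(sprintf("%s:%d: expected 2 tab-separated fields, found %d.",
                    path, rec$line, length(rec$fields)))
    }
  }
  df <- tibble(
    gene_id = vapply(recs, function(r) r$fields[1L], character(1)),
    category_id = vapply(recs, function(r) r$fields[2L], character(1))
  )
  dup <- which(duplicated(df$gene_id))
  if (length(dup)) {
    abort(sprintf("%s:%d: duplicate gene identifier '%s'.",
                  path, recs[[dup[1L]]]$line, df$gene_id[dup[1L]]))
  }
  ontology_map(df)
}

#' @rdname read_ontology
#' @param ontology An [ontology_map()].
#' @return For `write_ontology()`, `path` invisibly.
#' @export
write_ontology <- function(ontology, path) {
  check_ontology(ontology)
  writeLines(c("gene_id\tcategory_id",
               paste(ontology$gene_id, ontology$category_id, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}
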