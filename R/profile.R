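#' Construct a functional profile
#'
#' A functional profile is a gene-family-by-sample table of non-negative
#' hit counts (or, after [relative_abundance()], per-sample proportions).
#' It is stored as a tibble whose first column, `gene_id`, holds unique
#' gene-family identifiers and whose remaining columns hold one sample
#' each.  Zeros are explicit: a gene absent from a sample has count 0,
#' never `NA`.
#'
#' @param x A data frame with a `gene_id` character column followed by one
#'   numeric column per sample.
#' @param normalized Logical; `TRUE` if the columns are per-sample
#'   proportions (each sample column must then sum to 1 within 1e-9).
#'
#' @return A tibble of class `functional_profile`.
#' @seealso [read_profile()], [relative_abundance()], [filter_rare()]
#' @export
#' @examples
#' functional_profile(
#'   tibble::tibble(gene_id = c("K00001", "K00002"), s1 = c(3, 1), s2 = c(2, 2))
#' )
functional_profile <- function(x, normalized = FALSE) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "normalized") <- NULL
  if (ncol(x) < 2L) abort("A profile needs a `gene_id` column and at least one sample column.")
  if (names(x)[1L] != "gene_id") names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  validate_profile(x, normalized = normalized)
  structure(x, class = c("functional_profile", class(x)), normalized = isTRUE(normalized))
}

validate_profile <- function(x, normalized) {
  genes <- x$gene_id
  if (anyDuplicated(genes)) {
    abort(sprintf("Duplicate gene identifiers: %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  samples <- names(x)[-1L]
  if (anyDuplicated(samples)) {
    abort(sprintf("Duplicate sample identifiers: %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("Sample columns must be numeric.")
  if (anyNA(m)) abort("Profiles may not contain missing values; encode absence as 0.")
  if (any(m < 0)) abort("Profiles may not contain negative values.")
  if (isTRUE(normalized)) {
    sums <- colSums(m)
    bad <- samples[abs(sums - 1) > 1e-9]
    if (length(bad)) {
      abort(sprintf("Normalized profile columns must sum to 1: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Is a profile normalized to relative abundances?
#'
#' @param profile A [functional_profile()].
#' @return `TRUE` if the profile holds per-sample proportions.
#' @export
is_normalized <- function(profile) {
  check_profile(profile)
  isTRUE(attr(profile, "normalized"))
}

check_profile <- function(profile) {
  if (!inherits(profile, "functional_profile")) {
    abort("Expected a `functional_profile` (see `functional_profile()` or `read_profile()`).")
  }
  invisible(profile)
}

#' Gene and sample identifiers of a profile
#'
#' @param profile A [functional_profile()].
#' @return A character vector in table order.
#' @export
gene_ids <- function(profile) {
  check_profile(profile)
  profile$gene_id
}

#' @rdname gene_ids
#' @export
sample_ids <- function(profile) {
  check_profile(profile)
  names(profile)[-1L]
}

# gene x sample numeric matrix with gene ids as rownames
profile_matrix <- function(profile) {
  m <- as.matrix(profile[, -1L, drop = FALSE])
  rownames(m) <- profile$gene_id
  m
}

#' Read a gene-by-sample hit table from a TSV file
#'
#' The file is UTF-8 tab-separated with a header row of sample
#' identifiers, a first column of gene identifiers, and non-negative
#' numeric body cells.  Lines starting with `#` are skipped.  Parse
#' failures (ragged rows, negative or non-numeric cells, duplicate gene
#' or sample identifiers) raise an error naming the offending file line.
#'
#' @param path Path to the TSV file.
#' @return A [functional_profile()] with `normalized = FALSE`, preserving
#'   the row and column order of the file.
#' @export
read_profile <- function(path) {
  parsed <- parse_tsv_lines(path, min_cols = 2L)
  header <- parsed$header
  if (header$fields[1L] == "" ) {
    abort(sprintf("%s:%d: malformed header: empty gene-id column name.", path, header$line))
  }
  samples <- header$fields[-1L]
  if (anyDuplicated(samples)) {
    abort(sprintf("%s:%d: duplicate sample identifier '%s' in header.",
                  path, header$line, samples[duplicated(samples)][1L]))
  }
  n_fields <- length(header$fields)
  genes <- character(0)
  seen_at <- new.env(parent = emptyenv())
  rows <- vector("list", length(parsed$body))
  for (i in seq_along(parsed$body)) {
    rec <- parsed$body[[i]]
    if (length(rec$fields) != n_fields) {
      abort(sprintf("%s:%d: ragged row: expected %d fields, found %d.",
                    path, rec$line, n_fields, length(rec$fields)))
    }
    g <- rec$fields[1L]
    if (!is.null(seen_at[[g]])) {
      abort(sprintf("%s:%d: duplicate gene identifier '%s' (first seen on line %d).",
                    path, rec$line, g, seen_at[[g]]))
    }
    seen_at[[g]] <- rec$line
    vals <- suppressWarnings(as.numeric(rec$fields[-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      abort(sprintf("%s:%d: non-numeric value '%s' in column '%s'.",
                    path, rec$line, rec$fields[-1L][bad], samples[bad]))
    }
    if (any(vals < 0)) {
      bad <- which(vals < 0)[1L]
      abort(sprintf("%s:%d: negative value %s in column '%s'.",
                    path, rec$line, format(vals[bad]), samples[bad]))
    }
    genes[i] <- g
    rows[[i]] <- vals
  }
  if (!length(rows)) abort(sprintf("%s: no data rows.", path))
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  functional_profile(tibble(gene_id = genes, as_tibble(m)), normalized = FALSE)
}

# Shared minimal TSV reader: returns header + body records with original
# file line numbers ('#' comment lines and blank lines skipped).
parse_tsv_lines <- function(path, min_cols) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) abort(sprintf("%s: no content.", path))
  recs <- lapply(keep, function(i) list(line = i, fields = strsplit(raw[i], "\t", fixed = TRUE)[[1L]]))
  header <- recs[[1L]]
  if (length(header$fields) < min_cols) {
    abort(sprintf("%s:%d: malformed header: expected at least %d tab-separated fields.",
                  path, header$line, min_cols))
  }
  list(header = header, body = recs[-1L])
}

#' Write a profile to a TSV file
#'
#' Integer counts round-trip bit-identically through
#' [read_profile()]/[write_profile()].
#'
#' @param profile A [functional_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  check_profile(profile)
  m <- profile_matrix(profile)
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
                                         collapse = "\t"))
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Convert hit counts to per-sample relative abundances
#'
#' Divides every count by its sample-column total, so that each sample's
#' abundances sum to 1.  The relative abundance of a gene in a sample is
#' its number of hits divided by the total number of hits in that sample.
#' Calling this twice is an error rather than a silent renormalization.
#'
#' @param profile A count [functional_profile()]; every sample column
#'   must have a positive total.
#' @return A normalized [functional_profile()].
#' @export
relative_abundance <- function(profile) {
  check_profile(profile)
  if (is_normalized(profile)) {
    abort("Profile is already normalized; relative_abundance() operates on counts.")
  }
  m <- profile_matrix(profile)
  sums <- colSums(m)
  if (any(sums == 0)) {
    abort(sprintf("Cannot normalize: sample(s) with zero total hits: %s",
                  paste(colnames(m)[sums == 0], collapse = ", ")))
  }
  m <- sweep(m, 2L, sums, "/")
  functional_profile(tibble(gene_id = profile$gene_id, as_tibble(m)), normalized = TRUE)
}

#' Remove rare gene families
#'
#' Drops gene families observed fewer than `min_total` times summed
#' across all samples, keeping exactly the genes with total count
#' `>= min_total`.  The filter is defined on raw counts and therefore
#' precedes normalization in the pipeline.
#'
#' @param profile A count [functional_profile()] (not yet normalized).
#' @param min_total Minimum total count across samples for a gene to be
#'   retained (default 100, i.e. genes observed less than 100 times are
#'   removed).
#' @return A [functional_profile()] restricted to the surviving genes, in
#'   their original order, with the sample set unchanged.
#' @export
filter_rare <- function(profile, min_total = 100) {
  check_profile(profile)
  if (is_normalized(profile)) {
    abort("filter_rare() is defined on counts; apply it before relative_abundance().")
  }
  stopifnot_scalar_number(min_total, "min_total", lower = 0)
  totals <- rowSums(profile_matrix(profile))
  keep <- totals >= min_total
  if (!any(keep)) abort("No gene family reaches `min_total`; nothing would remain.")
  functional_profile(profile[keep, , drop = FALSE], normalized = FALSE)
}

#' @export
print.functional_profile <- function(x, ...) {
  kind <- if (isTRUE(attr(x, "normalized"))) "relative abundances" else "counts"
  cat(sprintf("# Functional profile: %d gene families x %d samples (%s)\n",
              nrow(x), ncol(x) - 1L, kind))
  NextMethod()
}
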