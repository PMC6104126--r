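#' Summarize glycoside hydrolase family assignments
#'
#' Consumes a read-level top-hit table (read, GH family, E-value) from an
#' upstream sequence search.  Reads with multiple rows are reduced to
#' their minimum-E-value row (ties: first occurrence in the table), rows
#' with E-value above the cutoff are dropped, and the surviving reads
#' are tallied into per-family fractions.  With a family catalog, each
#' family also gets its fraction within its functional group -- for
#' example among families targeting plant structural polysaccharides,
#' which are conventionally evaluated apart from the rest.
#'
#' @param tophits Data frame with columns `read_id`, `family_id`,
#'   `evalue` (non-negative).
#' @param catalog Optional data frame `(family_id, group)` mapping GH
#'   families to functional groups; families not listed get group `NA`.
#' @param evalue_max E-value cutoff; hits with `evalue <= evalue_max`
#'   are kept (default 1e-5).
#' @return A tibble of class `gh_summary` with columns `family_id`,
#'   `n_reads`, `fraction`, `group`, `group_fraction`, sorted by
#'   decreasing fraction.  Fractions sum to 1 overall and within each
#'   group.
#' @export
summarize_gh <- function(tophits, catalog = NULL, evalue_max = 1e-5) {
  if (!is.data.frame(tophits) ||
      !all(c("read_id", "family_id", "evalue") %in% names(tophits))) {
    abort("`tophits` must have columns `read_id`, `family_id`, `evalue`.")
  }
  stopifnot_scalar_number(evalue_max, "evalue_max", lower = 0)
  hits <- as_tibble(tophits)
  if (anyNA(hits$evalue) || any(hits$evalue < 0)) {
    abort("E-values must be non-negative and non-missing.")
  }
  # top-hit reduction: minimum E-value per read, first occurrence on ties
  hits$.row <- seq_len(nrow(hits))
  hits <- hits |>
    dplyr::arrange(.data$evalue, .data$.row) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(hits)) {
    abort(sprintf("No hit survives the E-value cutoff %g.", evalue_max))
  }
  fam <- hits |>
    dplyr::count(family_id = as.character(.data$family_id), name = "n_reads") |>
    dplyr::mutate(fraction = .data$n_reads / sum(.data$n_reads))
  if (!is.null(catalog)) {
    if (!is.data.frame(catalog) || !all(c("family_id", "group") %in% names(catalog))) {
      abort("`catalog` must have columns `family_id` and `group`.")
    }
    catalog <- as_tibble(catalog)
    if (anyDuplicated(catalog$family_id)) {
      abort("`catalog` must map each family to a single group.")
    }
    fam$group <- catalog$group[match(fam$family_id, catalog$family_id)]
  } else {
    fam$group <- NA_character_
  }
  fam <- fam |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(group_fraction = ifelse(is.na(.data$group), NA_real_,
                                          .data$n_reads / sum(.data$n_reads))) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$family_id)
  structure(fam, class = c("gh_summary", class(fam)),
            evalue_max = evalue_max, n_reads_total = sum(fam$n_reads))
}

#' Read a GH family catalog from a two-column TSV file
#'
#' Columns `family_id` and `group`; `#` comment lines skipped.  A small
#' illustrative catalog (starch-active families such as GH13/GH15 and a
#' plant-structural-polysaccharide group with cellulases, xylanases and
#' arabinofuranosidases) ships under `inst/extdata/gh_groups.tsv`.
#'
#' @param path Path to the TSV file.
#' @return A tibble `(family_id, group)`.
#' @export
read_gh_catalog <- function(path) {
  parsed <- parse_tsv_lines(path, min_cols = 2L)
  for (rec in parsed$body) {
    if (length(rec$fields) != 2L) {
      abort(sprintf("%s:%d: expected 2 tab-separated fields.", path, rec$line))
    }
  }
  tibble(
    family_id = vapply(parsed$body, function(r) r$fields[1L], character(1)),
    group = vapply(parsed$body, function(r) r$fields[2L], character(1))
  )
}

#' @export
print.gh_summary <- function(x, ...) {
  cat(sprintf("# GH summary: %d families over %d reads (E <= %g)\n",
              nrow(x), attr(x, "n_reads_total"), attr(x, "evalue_max")))
  NextMethod()
}

#' @rdname summarize_gh
#' @param object A `gh_summary`.
#' @param ... Unused.
#' @method autoplot gh_summary
#' @export
autoplot.gh_summary <- function(object, ...) {
  df <- as_tibble(object)
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df$family_id <- factor(df$family_id, levels = rev(df$family_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$fraction,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fraction of GH-assigned reads", fill = "Group") +
    ggplot2::theme_minimal()
}
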