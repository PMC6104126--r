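#' Arcsine square-root transform of proportions
#'
#' The classical variance-stabilizing transform for proportion data such
#' as lipid mol% (divided by 100 upstream): `asin(sqrt(p))`, mapping
#' \[0, 1\] onto \[0, pi/2\].
#'
#' @param proportions Numeric vector with values in \[0, 1\].
#' @return Transformed values.
#' @export
arcsine_sqrt <- function(proportions) {
  if (!is.numeric(proportions)) abort("`proportions` must be numeric.")
  bad <- !is.na(proportions) & (proportions < 0 | proportions > 1)
  if (any(bad)) {
    abort(sprintf("Proportions outside [0, 1]: %s",
                  paste(format(utils::head(proportions[bad], 3)), collapse = ", ")))
  }
  asin(sqrt(proportions))
}

#' Spearman correlation matrix between taxa and metadata
#'
#' Computes the Spearman rank coefficient between every taxon-abundance
#' column and every metadata column over their shared samples
#' (pairwise-complete observations, tie-corrected ranks).  Pairs with
#' fewer than 3 complete observations get `NA` with the observation
#' count recorded.  Two-sided p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`; they are reported for
#' annotation but play no role in [filter_correlations()], which acts on
#' `|rho|` alone.
#'
#' @param taxa Data frame: `sample_id` column plus one numeric column
#'   per taxon (relative abundances at any pre-aggregated level).
#' @param metadata Data frame: `sample_id` column plus one numeric
#'   column per chemical/lipid variable.
#' @return An object of class `correlation_matrix` holding matrices
#'   `rho`, `n_obs`, `p_value` (taxa as rows, variables as columns) and
#'   unset retention masks.
#' @export
spearman_matrix <- function(taxa, metadata) {
  tm <- as_sample_matrix(taxa, "taxa")
  mm <- as_sample_matrix(metadata, "metadata")
  shared <- intersect(rownames(tm), rownames(mm))
  if (length(shared) < 3L) {
    abort(sprintf("Only %d shared sample(s); need at least 3.", length(shared)))
  }
  tm <- tm[shared, , drop = FALSE]
  mm <- mm[shared, , drop = FALSE]
  rho <- suppressWarnings(cor(tm, mm, method = "spearman",
                              use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(tm), !is.na(mm))
  rho[n_obs < 3L] <- NA_real_
  tstat <- rho * sqrt(pmax(n_obs - 2, 0) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = pmax(n_obs - 2, 1), lower.tail = FALSE)
  p[is.na(rho)] <- NA_real_
  structure(
    list(rho = rho, n_obs = n_obs, p_value = p,
         taxa = colnames(tm), variables = colnames(mm),
         threshold = NULL, retained_rows = NULL, retained_cols = NULL),
    class = "correlation_matrix"
  )
}

as_sample_matrix <- function(x, what) {
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column.", what))
  }
  ids <- as.character(x$sample_id)
  if (anyDuplicated(ids)) abort(sprintf("Duplicate sample ids in `%s`.", what))
  m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("Non-numeric columns in `%s`.", what))
  rownames(m) <- ids
  m
}

#' Retention filter on a correlation matrix
#'
#' Marks for retention exactly the rows (taxa) and columns (variables)
#' containing at least one correlation of absolute value at or above the
#' threshold.  The coefficients themselves are untouched; only the masks
#' are set, and exports write the reduced matrix.  The operation is
#' idempotent.
#'
#' @param matrix A `correlation_matrix` from [spearman_matrix()].
#' @param threshold Absolute-correlation threshold in (0, 1\]
#'   (default 0.60).
#' @return The `correlation_matrix` with `retained_rows`/`retained_cols`
#'   masks and `threshold` set.  If nothing survives, a warning is
#'   emitted and the masks are all-`FALSE`.
#' @export
filter_correlations <- function(matrix, threshold = 0.60) {
  if (!inherits(matrix, "correlation_matrix")) {
    abort("Expected a `correlation_matrix` from spearman_matrix().")
  }
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must lie in (0, 1].")
  hit <- !is.na(matrix$rho) & abs(matrix$rho) >= threshold
  matrix$retained_rows <- setNames(apply(hit, 1L, any), matrix$taxa)
  matrix$retained_cols <- setNames(apply(hit, 2L, any), matrix$variables)
  matrix$threshold <- threshold
  if (!any(matrix$retained_rows)) {
    warn(sprintf("No row or column reaches |rho| >= %g; retained set is empty.", threshold))
  }
  matrix
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("# Spearman correlation matrix: %d taxa x %d variables\n",
              length(x$taxa), length(x$variables)))
  if (!is.null(x$threshold)) {
    cat(sprintf("# Retention at |rho| >= %g: %d/%d rows, %d/%d columns\n",
                x$threshold, sum(x$retained_rows), length(x$taxa),
                sum(x$retained_cols), length(x$variables)))
  }
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x,object A `correlation_matrix`.
#' @param ... Unused.
#' @return `tidy()` returns one row per (taxon, variable) pair with
#'   `rho`, `n_obs`, `p_value` and (after [filter_correlations()])
#'   a `retained` flag for pairs whose row and column both survive.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  out <- tibble(
    taxon = rep(x$taxa, times = length(x$variables)),
    variable = rep(x$variables, each = length(x$taxa)),
    rho = as.vector(x$rho),
    n_obs = as.vector(x$n_obs),
    p_value = as.vector(x$p_value)
  )
  if (!is.null(x$threshold)) {
    out$retained <- as.vector(outer(x$retained_rows, x$retained_cols, "&"))
  }
  out
}

#' @rdname spearman_matrix
#' @method glance correlation_matrix
#' @export
glance.correlation_matrix <- function(x, ...) {
  tibble(
    n_taxa = length(x$taxa),
    n_variables = length(x$variables),
    max_abs_rho = max(abs(x$rho), na.rm = TRUE),
    threshold = x$threshold %||% NA_real_,
    n_retained_taxa = if (is.null(x$retained_rows)) NA_integer_ else sum(x$retained_rows),
    n_retained_variables = if (is.null(x$retained_cols)) NA_integer_ else sum(x$retained_cols)
  )
}

#' @rdname spearman_matrix
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tidy(object)
  if (!is.null(object$threshold)) df <- df[df$retained, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$taxon,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write full and filtered correlation matrices as TSV
#'
#' @param matrix A `correlation_matrix` (filtered or not).
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_correlations <- function(matrix, dir) {
  if (!inherits(matrix, "correlation_matrix")) {
    abort("Expected a `correlation_matrix`.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "correlations_full.tsv")
  write_named_matrix(matrix$rho, "taxon", paths)
  if (!is.null(matrix$threshold)) {
    reduced <- matrix$rho[matrix$retained_rows, matrix$retained_cols, drop = FALSE]
    p2 <- file.path(dir, "correlations_filtered.tsv")
    write_named_matrix(reduced, "taxon", p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

write_named_matrix <- function(m, id_name, path) {
  lines <- c(paste(c(id_name, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i],
                       format(m[i, ], trim = TRUE, digits = 15)), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
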