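#' Within-sample abundance ranks
#'
#' Converts a profile into a rank-abundance matrix: within each sample
#' independently, genes are ranked by descending abundance, rank 1 being
#' the most abundant; ties receive the average of the tied positions.
#' Ranking is invariant to per-sample monotone transforms, so ranks on
#' relative abundances equal ranks on the underlying counts.
#'
#' @param profile A [functional_profile()] with at least 2 genes and 2
#'   samples.
#' @return A tibble of class `rank_matrix` (columns `gene_id` then one
#'   rank column per sample) carrying the per-gene total abundance as a
#'   `totals` attribute for downstream tie-breaking.
#' @export
rank_transform <- function(profile) {
  check_profile(profile)
  m <- profile_matrix(profile)
  if (nrow(m) < 2L) abort("rank_transform() needs at least 2 gene families.")
  if (ncol(m) < 2L) abort("rank_transform() needs at least 2 samples.")
  r <- apply(m, 2L, function(col) rank(-col, ties.method = "average"))
  out <- tibble(gene_id = profile$gene_id, as_tibble(r))
  structure(out, class = c("rank_matrix", class(out)), totals = rowSums(m))
}

#' Cross-sample variance of abundance ranks
#'
#' The core-gene statistic: for each gene, the sample variance
#' (denominator n - 1) of its within-sample abundance ranks across
#' samples.  Genes with near-constant rank across samples score low and
#' are candidates for the core set.
#'
#' @param ranks A `rank_matrix` from [rank_transform()].
#' @return A tibble `(gene_id, rank_variance, total_abundance)` in gene
#'   order.
#' @export
rank_variance <- function(ranks) {
  if (!inherits(ranks, "rank_matrix")) {
    abort("Expected a `rank_matrix` from rank_transform().")
  }
  m <- as.matrix(ranks[, -1L, drop = FALSE])
  if (ncol(m) < 2L) abort("rank_variance() needs at least 2 samples.")
  totals <- attr(ranks, "totals") %||% rep(NA_real_, nrow(m))
  tibble(
    gene_id = ranks$gene_id,
    rank_variance = apply(m, 1L, var),
    total_abundance = as.numeric(totals)
  )
}

#' Select the core gene set
#'
#' Flags the `floor(core_fraction * G)` genes with the smallest
#' cross-sample rank variance as core.  Ties at the selection boundary
#' are broken deterministically: larger total abundance first, then
#' lexicographic `gene_id` (C-locale).
#'
#' @param variances A tibble with columns `gene_id`, `rank_variance` and
#'   (optionally) `total_abundance`, as from [rank_variance()].
#' @param core_fraction Fraction of genes to flag (default 0.10, the top
#'   10% of genes varying the least in rank abundance).
#' @return A tibble of class `core_gene_result` with a logical `core`
#'   column and attributes `core_fraction` and `n_core`.
#' @export
select_core <- function(variances, core_fraction = 0.10) {
  variances <- check_variances(variances)
  stopifnot_scalar_number(core_fraction, "core_fraction")
  if (core_fraction <= 0 || core_fraction >= 1) {
    abort("`core_fraction` must lie strictly between 0 and 1.")
  }
  g <- nrow(variances)
  n_core <- floor(core_fraction * g)
  if (n_core < 1L) {
    abort(sprintf(
      "floor(core_fraction * G) = 0 with G = %d, core_fraction = %g; use more genes or a larger fraction.",
      g, core_fraction))
  }
  tb <- variances$total_abundance
  tb[is.na(tb)] <- -Inf  # unknown totals lose variance ties deterministically
  ord <- radix_order(variances$rank_variance, -tb, variances$gene_id)
  core <- logical(g)
  core[ord[seq_len(n_core)]] <- TRUE
  out <- variances
  out$core <- core
  structure(out, class = c("core_gene_result", class(variances)),
            core_fraction = core_fraction, n_core = as.integer(n_core))
}

check_variances <- function(variances) {
  if (!is.data.frame(variances) ||
      !all(c("gene_id", "rank_variance") %in% names(variances))) {
    abort("`variances` must have columns `gene_id` and `rank_variance`.")
  }
  variances <- as_tibble(variances)
  if (!"total_abundance" %in% names(variances)) {
    variances$total_abundance <- NA_real_
  }
  if (anyNA(variances$rank_variance)) abort("`rank_variance` may not contain NA.")
  if (any(variances$rank_variance < 0)) abort("`rank_variance` must be non-negative.")
  variances
}

#' Count core genes per functional category
#'
#' @param core A `core_gene_result` from [select_core()].
#' @param ontology An [ontology_map()] covering every gene in `core`.
#' @return A tibble `(category_id, size, observed)` over all ontology
#'   categories (zero counts included), in ontology category order.
#'   `size` is the number of profiled genes in the category, `observed`
#'   the number of those flagged core.
#' @export
category_core_counts <- function(core, ontology) {
  if (!inherits(core, "core_gene_result")) {
    abort("Expected a `core_gene_result` from select_core().")
  }
  check_ontology(ontology)
  missing <- setdiff(core$gene_id, ontology$gene_id)
  if (length(missing)) {
    abort(sprintf("Gene(s) absent from the ontology map: %s",
                  paste(missing, collapse = ", ")))
  }
  cats <- category_ids(ontology)
  assign <- setNames(ontology$category_id, ontology$gene_id)[core$gene_id]
  code <- match(assign, cats)
  tibble(
    category_id = cats,
    size = tabulate(code, nbins = length(cats)),
    observed = tabulate(code[core$core], nbins = length(cats))
  )
}

#' Convenience wrapper: profile to core gene result
#'
#' Chains [rank_transform()], [rank_variance()] and [select_core()].
#'
#' @inheritParams rank_transform
#' @inheritParams select_core
#' @return A `core_gene_result`.
#' @export
core_gene_analysis <- function(profile, core_fraction = 0.10) {
  select_core(rank_variance(rank_transform(profile)), core_fraction = core_fraction)
}

#' @export
print.core_gene_result <- function(x, ...) {
  cat(sprintf("# Core gene result: %d of %d genes flagged (fraction %g)\n",
              attr(x, "n_core"), nrow(x), attr(x, "core_fraction")))
  NextMethod()
}

#' @rdname select_core
#' @param x A `core_gene_result`.
#' @param ... Unused.
#' @method tidy core_gene_result
#' @export
tidy.core_gene_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname select_core
#' @method glance core_gene_result
#' @export
glance.core_gene_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_core = attr(x, "n_core"),
    core_fraction = attr(x, "core_fraction"),
    max_core_variance = max(x$rank_variance[x$core]),
    min_noncore_variance = if (any(!x$core)) min(x$rank_variance[!x$core]) else NA_real_
  )
}

#' @rdname select_core
#' @param object A `core_gene_result`.
#' @method autoplot core_gene_result
#' @export
autoplot.core_gene_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[radix_order(df$rank_variance, -df$total_abundance, df$gene_id), ]
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$rank_variance,
                                   colour = .data$core)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "Genes ordered by rank variance",
                  y = "Cross-sample rank variance (log1p scale)",
                  colour = "Core") +
    ggplot2::theme_minimal()
}
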