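#' Permutation test for category enrichment in core genes
#'
#' Tests whether functional categories hold more core genes than expected
#' if rank variances were unrelated to category membership.  For each of
#' `permutations` replicates the observed set of variances is reassigned
#' to the genes uniformly at random, the core set is re-selected with the
#' same fraction and tie-break, and core genes are re-counted per
#' category.  The null 95% interval is the empirical 2.5th/97.5th
#' percentile (nearest rank on the sorted integer counts), the p-value is
#' the upper-tail estimate `(1 + #(null >= observed)) / (B + 1)`, and
#' q-values are Benjamini-Hochberg adjusted across categories.
#'
#' When all variances are distinct the permuted core set is a uniformly
#' random subset of `n_core` genes, so each category's null count is
#' exactly hypergeometric -- see [hypergeometric_null()], which serves as
#' an independent check.
#'
#' @param variances A tibble `(gene_id, rank_variance, total_abundance)`
#'   from [rank_variance()].
#' @param ontology An [ontology_map()] covering every gene.
#' @param core_fraction Fraction of genes flagged core (default 0.10).
#' @param permutations Number of permutation replicates `B` (default
#'   10000).
#' @param seed Integer seed; required so that identical inputs give
#'   bit-identical output.  The caller's RNG state is left untouched.
#' @return A tibble of class `enrichment_result` with columns
#'   `category_id`, `size`, `observed`, `null_mean`, `null_lo`,
#'   `null_hi`, `p_value`, `q_value` and attributes `core_fraction`,
#'   `n_core`, `permutations`, `seed`, `n_genes`.
#' @export
permutation_enrichment <- function(variances, ontology, core_fraction = 0.10,
                                   permutations = 10000, seed) {
  if (missing(seed)) abort("`seed` is required: the permutation null is stochastic.")
  stopifnot_scalar_number(permutations, "permutations", lower = 1)
  b <- as.integer(permutations)
  core <- select_core(variances, core_fraction = core_fraction)
  counts <- category_core_counts(core, ontology)
  g <- nrow(core)
  k <- attr(core, "n_core")
  n_cat <- nrow(counts)

  v <- core$rank_variance
  tb <- core$total_abundance
  tb[is.na(tb)] <- -Inf
  # genes ranked once by the tie-break key; within equal permuted variances
  # order() then resolves exactly as select_core() would
  tie_rank <- integer(g)
  tie_rank[radix_order(-tb, core$gene_id)] <- seq_len(g)
  cats <- counts$category_id
  code <- match(setNames(ontology$category_id, ontology$gene_id)[core$gene_id], cats)

  null_counts <- with_seed(seed, {
    out <- matrix(0L, nrow = n_cat, ncol = b)
    for (i in seq_len(b)) {
      vp <- v[sample.int(g)]
      sel <- order(vp, tie_rank, method = "radix")[seq_len(k)]
      out[, i] <- tabulate(code[sel], nbins = n_cat)
    }
    out
  })

  lo_i <- max(1L, ceiling(0.025 * b))
  hi_i <- ceiling(0.975 * b)
  sorted <- matrix(apply(null_counts, 1L, sort), nrow = b, ncol = n_cat)  # b x n_cat
  p <- (1 + rowSums(null_counts >= counts$observed)) / (b + 1)
  out <- tibble(
    category_id = cats,
    size = counts$size,
    observed = counts$observed,
    null_mean = rowMeans(null_counts),
    null_lo = as.numeric(sorted[lo_i, ]),
    null_hi = as.numeric(sorted[hi_i, ]),
    p_value = p,
    q_value = fdr_adjust(p)
  )
  structure(out, class = c("enrichment_result", class(out)),
            core_fraction = core_fraction, n_core = k,
            permutations = b, seed = as.integer(seed), n_genes = g)
}

#' Exact null distribution of a category's core-gene count
#'
#' Under random reassignment of distinct variances, the core set is a
#' simple random `k`-subset of the `G` genes, so the number of core genes
#' falling in a category of size `m` is hypergeometric with mean
#' `k * m / G`.  This closed form is the independent oracle against which
#' the permutation machinery is validated.
#'
#' @param G Total number of genes.
#' @param m Category size, `0 <= m <= G`.
#' @param k Core-set size, `0 <= k <= G`.
#' @return A tibble `(count, probability)` over the support, with the
#'   distribution mean as attribute `mean`.
#' @export
hypergeometric_null <- function(G, m, k) {
  for (nm in c("G", "m", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      abort(sprintf("`%s` must be a single non-negative integer.", nm))
    }
  }
  if (m > G || k > G) abort("Impossible counts: need m <= G and k <= G.")
  support <- max(0, k + m - G):min(k, m)
  structure(
    tibble(count = support, probability = dhyper(support, m, G - m, k)),
    mean = k * m / G
  )
}

# Upper-tail P(X >= x) for the hypergeometric null (internal oracle helper).
hypergeometric_upper_tail <- function(G, m, k, x) {
  phyper(x - 1, m, G - m, k, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, clipped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) abort("`p_values` must be non-empty.")
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "# Enrichment result: %d categories, %d core of %d genes, B = %d, seed = %d\n",
    nrow(x), attr(x, "n_core"), attr(x, "n_genes"),
    attr(x, "permutations"), attr(x, "seed")))
  NextMethod()
}

#' @rdname permutation_enrichment
#' @param x,object An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname permutation_enrichment
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_genes = attr(x, "n_genes"),
    n_core = attr(x, "n_core"),
    permutations = attr(x, "permutations"),
    seed = attr(x, "seed"),
    n_significant = sum(x$q_value <= 0.05)
  )
}

#' @rdname permutation_enrichment
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  df$category_id <- factor(df$category_id, levels = df$category_id[order(df$observed)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category_id)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$null_lo, ymax = .data$null_hi),
                            colour = "grey60", linewidth = 1.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$q_value <= 0.05), size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Core genes in category",
                  colour = "q <= 0.05",
                  subtitle = "Points: observed; bars: permutation null 95% interval") +
    ggplot2::theme_minimal()
}
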