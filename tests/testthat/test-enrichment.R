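random_variances <- function(g) {
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(g)),
    rank_variance = stats::runif(g, 0, 100),
    total_abundance = stats::runif(g, 1, 1000)
  )
}

test_that("degenerate single-category ontology gives p = 1 and a point null", {
  v <- random_variances(10)
  ont <- small_ontology(v$gene_id, rep("all", 10))
  e <- permutation_enrichment(v, ont, core_fraction = 0.2, permutations = 200, seed = 1)
  k <- attr(e, "n_core")
  expect_equal(e$observed, k)
  expect_equal(e$null_lo, k)
  expect_equal(e$null_hi, k)
  expect_equal(e$p_value, 1)
})

test_that("an observed count of zero yields p = 1 under the +1 estimator", {
  # force the two lowest-variance genes into category A; test category B
  v <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                      rank_variance = 1:10, total_abundance = rep(1, 10))
  ont <- small_ontology(v$gene_id, c("A", "A", rep("B", 8)))
  e <- permutation_enrichment(v, ont, core_fraction = 0.2, permutations = 100, seed = 2)
  expect_equal(e$observed[e$category_id == "B"], 0L)
  expect_equal(e$p_value[e$category_id == "B"], 1)
})

test_that("permutation p-values track the exact hypergeometric tail", {
  # G = 10, category size 5, k = 2: exact P(X >= 2) = C(5,2)/C(10,2) = 10/45
  withr::local_seed(42)
  v <- random_variances(10)
  ont <- small_ontology(v$gene_id, rep(c("in", "out"), each = 5))
  b <- 10000
  e <- permutation_enrichment(v, ont, core_fraction = 0.2, permutations = b, seed = 7)
  obs <- e$observed[e$category_id == "in"]
  p_exact <- phyper(obs - 1, 5, 5, 2, lower.tail = FALSE)
  p_hat <- e$p_value[e$category_id == "in"]
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / b))
  expect_equal(phyper(2 - 1, 5, 5, 2, lower.tail = FALSE), 10 / 45)
})

test_that("null category counts have the hypergeometric mean", {
  withr::local_seed(9)
  v <- random_variances(30)
  ont <- small_ontology(v$gene_id, rep(c("a", "b", "c"), each = 10))
  b <- 4000
  e <- permutation_enrichment(v, ont, core_fraction = 0.2, permutations = b, seed = 11)
  k <- attr(e, "n_core")
  for (i in seq_len(nrow(e))) {
    m <- e$size[i]
    mean_exact <- k * m / 30
    var_exact <- k * (m / 30) * (1 - m / 30) * (30 - k) / 29
    expect_lt(abs(e$null_mean[i] - mean_exact), 3 * sqrt(var_exact / b) + 1e-12)
  }
})

test_that("enrichment is bit-identical under the same seed and differs across seeds", {
  v <- random_variances(40)
  ont <- small_ontology(v$gene_id, rep(c("x", "y"), 20))
  e1 <- permutation_enrichment(v, ont, permutations = 500, seed = 123, core_fraction = 0.2)
  e2 <- permutation_enrichment(v, ont, permutations = 500, seed = 123, core_fraction = 0.2)
  expect_identical(tidy(e1), tidy(e2))
  e3 <- permutation_enrichment(v, ont, permutations = 500, seed = 124, core_fraction = 0.2)
  expect_false(identical(e1$null_mean, e3$null_mean))
  # and the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(permutation_enrichment(v, ont, permutations = 50,
                                                seed = 99, core_fraction = 0.2))
  expect_identical(rnorm(1), before)
})

test_that("p-values are valid and q-values are BH-monotone", {
  withr::local_seed(17)
  v <- random_variances(50)
  ont <- block_ontology(v$gene_id, 5)
  e <- permutation_enrichment(v, ont, core_fraction = 0.1, permutations = 999, seed = 3)
  expect_true(all(e$p_value > 0 & e$p_value <= 1))
  expect_true(all(e$q_value <= 1))
  ord <- order(e$p_value)
  expect_true(all(diff(e$q_value[ord]) >= -1e-12))
})

test_that("hypergeometric_null matches closed forms", {
  h <- hypergeometric_null(10, 5, 2)
  expect_equal(h$probability[h$count == 2], 10 / 45)
  expect_equal(sum(h$probability), 1)
  expect_equal(attr(h, "mean"), 2 * 5 / 10)

  all_in <- hypergeometric_null(8, 8, 3)
  expect_equal(all_in$count, 3L)
  expect_equal(all_in$probability, 1)

  none <- hypergeometric_null(8, 5, 0)
  expect_equal(none$count, 0L)
  expect_equal(none$probability, 1)

  expect_error(hypergeometric_null(5, 6, 2), "Impossible")
  expect_error(hypergeometric_null(5, 2, -1), "non-negative")
})

test_that("fdr_adjust reproduces step-up BH and validates input", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  # hand-worked staggered example: p_(i) * m / i, cumulative minimum from the top
  p <- c(0.005, 0.04, 0.03, 0.9)
  # sorted 0.005, 0.03, 0.04, 0.9 -> p * 4 / i = 0.02, 0.06, 0.0533..., 0.9,
  # then running minimum from the top gives 0.02, 0.0533..., 0.0533..., 0.9
  expect_equal(fdr_adjust(p), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.9),
               tolerance = 1e-10)
  expect_error(fdr_adjust(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(fdr_adjust(c(0.5, 1.2)), "in \\(0, 1\\]")
  expect_error(fdr_adjust(numeric(0)), "non-empty")
})
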