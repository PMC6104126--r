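small_config <- function(...) {
  generator_config(genes = 200, samples = 6, depth = 4e4, n_categories = 5,
                   stable_min_count = 20, ...)
}

test_that("generated counts conserve the configured depth and are reproducible", {
  cfg <- small_config()
  sim1 <- generate_profile(cfg, seed = 71)
  sim2 <- generate_profile(cfg, seed = 71)
  expect_identical(sim1$profile, sim2$profile)
  expect_identical(sim1$ontology, sim2$ontology)
  expect_identical(sim1$truth$core_gene_ids, sim2$truth$core_gene_ids)

  m <- as.matrix(sim1$profile[, -1])
  expect_equal(unname(colSums(m)), rep(4e4, 6))  # multinomial conservation
  expect_equal(length(sim1$truth$core_gene_ids), round(0.10 * 200))

  sim3 <- generate_profile(cfg, seed = 72)
  expect_false(identical(sim1$profile, sim3$profile))
})

test_that("category sizes and planted bookkeeping are consistent", {
  cfg <- small_config(enrichment = list(cat02 = 0.3))
  sim <- generate_profile(cfg, seed = 5)
  tab <- table(sim$ontology$category_id)
  expect_equal(unname(as.integer(tab[sprintf("cat%02d", 1:5)])), cfg$category_sizes)
  # quota: round(20 * (40/200 + 0.3)) = 10 planted-stable genes in cat02
  expect_equal(sim$truth$category_counts[["cat02"]], 10L)
  expect_equal(sum(sim$truth$category_counts), 20L)

  # infeasible enrichment errors out
  expect_error(generate_profile(small_config(enrichment = list(cat01 = 0.95)), seed = 1),
               "Infeasible enrichment")
  expect_error(generate_profile(small_config(enrichment = list(nope = 0.1)), seed = 1),
               "unknown category")
})

test_that("equal noise scales are flagged non-identifiable", {
  cfg <- small_config(stable_noise = 0.5, unstable_noise = 0.5)
  expect_false(cfg$identifiable)
  sim <- generate_profile(cfg, seed = 2)
  expect_false(sim$truth$identifiable)
  expect_error(small_config(stable_noise = 1, unstable_noise = 0.1), "not exceed")
})

test_that("without planted enrichment, stable genes spread uniformly over categories", {
  # pool planted-category counts over replicates; chi-square against uniform
  counts <- numeric(5)
  for (i in 1:60) {
    sim <- generate_profile(small_config(), seed = 1000 + i)
    counts <- counts + sim$truth$category_counts
  }
  gof <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 5, 5)))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted rank-stable genes have visibly lower rank variance", {
  sim <- generate_profile(small_config(), seed = 31)
  v <- rank_variance(rank_transform(sim$profile))
  is_core <- v$gene_id %in% sim$truth$core_gene_ids
  expect_lt(median(v$rank_variance[is_core]), median(v$rank_variance[!is_core]) / 10)
})

test_that("concentrating all planted genes in one matched category recovers ~n_core there", {
  # category sizes 40; put the full planted-stable share (20 genes) in cat01
  cfg <- generator_config(genes = 200, samples = 6, depth = 4e4, n_categories = 10,
                          stable_min_count = 20,
                          enrichment = list(cat01 = 1 - 20 / 200))
  sim <- generate_profile(cfg, seed = 13)
  expect_equal(sim$truth$category_counts[["cat01"]], 20L)
  core <- core_gene_analysis(relative_abundance(filter_rare(sim$profile)))
  counts <- category_core_counts(core, sim$ontology)
  expect_gte(counts$observed[counts$category_id == "cat01"],
             0.8 * attr(core, "n_core"))
})

test_that("taxa/metadata generation is seeded and respects planted extremes", {
  g1 <- generate_taxa_metadata(20, n_taxa = 8, n_vars = 3,
                               planted = list(list(taxon = 2, variable = 1, rho = 1)),
                               seed = 4)
  g2 <- generate_taxa_metadata(20, n_taxa = 8, n_vars = 3,
                               planted = list(list(taxon = 2, variable = 1, rho = 1)),
                               seed = 4)
  expect_identical(g1$taxa, g2$taxa)
  expect_identical(g1$metadata, g2$metadata)
  expect_equal(rowSums(as.matrix(g1$taxa[, -1])), rep(1, 20))  # proportions

  expect_equal(cor(g1$taxa$taxon02, g1$metadata$var01, method = "spearman"), 1.0)
  g3 <- generate_taxa_metadata(20, n_taxa = 8, n_vars = 3,
                               planted = list(list(taxon = 1, variable = 2, rho = -1)),
                               seed = 9)
  expect_equal(cor(g3$taxa$taxon01, g3$metadata$var02, method = "spearman"), -1.0)
  expect_error(generate_taxa_metadata(3, seed = 1), "must be a single number")
  expect_error(generate_taxa_metadata(10, planted = list(list(taxon = 1, variable = 1, rho = 2)),
                                      seed = 1),
               "<= 1")
})

test_that("unplanted pairs are uncorrelated on average", {
  rhos <- vapply(1:300, function(i) {
    g <- generate_taxa_metadata(30, n_taxa = 3, n_vars = 2, seed = 5000 + i)
    cor(g$taxa$taxon01, g$metadata$var01, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("planted associations reach the retention threshold as often as designed", {
  target <- 0.61
  s <- 63
  # independent oracle implementing the same design from scratch:
  # normal scores for the taxon ranks, latent correlation 2 sin(pi rho / 6)
  r <- 2 * sin(pi * target / 6)
  oracle <- withr::with_seed(42, {
    scores <- stats::qnorm((seq_len(s) - 0.5) / s)
    mean(vapply(1:2000, function(i) {
      z1 <- sample(scores)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(s)
      abs(cor(z1, z2, method = "spearman")) >= 0.60
    }, logical(1)))
  })
  hits <- vapply(1:400, function(i) {
    g <- generate_taxa_metadata(s, n_taxa = 10, n_vars = 2,
                                planted = list(list(taxon = 1, variable = 1, rho = target)),
                                seed = 20000 + i)
    abs(cor(g$taxa$taxon01, g$metadata$var01, method = "spearman")) >= 0.60
  }, logical(1))
  expect_lt(abs(mean(hits) - oracle), 0.05)
})
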