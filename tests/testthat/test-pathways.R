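toy_cycle <- function() {
  cycle_definition(
    "toy_n",
    steps = list(denitrification = c("nirK", "nirS", "norC", "norB", "nosZ"),
                 assimilation = c("glnA", "gltB"),
                 fixation = c("nifH")),
    branches = list(nitrite_to_n2 = c("nirK", "nirS", "norC", "norB", "nosZ"),
                    whole = c("nirK", "nirS", "norC", "norB", "nosZ",
                              "glnA", "gltB", "nifH"),
                    ghost = c("nifH"))
  )
}

test_that("summarize_cycle normalizes within sample then averages across samples", {
  # single sample: percentages are plain proportions x 100
  m1 <- matrix(c(18, 3.4, 40, 38.6, 0), ncol = 1)
  p1 <- make_profile(m1, gene_ids = c("nirK", "nosZ", "glnA", "gltB", "nifH"))
  s1 <- summarize_cycle(p1, toy_cycle())
  expect_equal(s1$mean_pct[s1$gene_id == "nirK"], 18.0)
  expect_equal(sum(s1$mean_pct), 100)

  # two samples: 10% and 30% of cycle genes -> 20% reported
  m2 <- cbind(c(10, 90), c(30, 70))
  p2 <- make_profile(m2, gene_ids = c("nirK", "glnA"))
  s2 <- summarize_cycle(p2, toy_cycle())
  expect_equal(s2$mean_pct[s2$gene_id == "nirK"], 20)

  # roster genes absent from the profile appear with 0
  expect_equal(s2$mean_pct[s2$gene_id == "nosZ"], 0)

  # depth imbalance: per-sample percentages are equally weighted...
  m3 <- cbind(c(10, 90), c(3000, 7000))
  p3 <- make_profile(m3, gene_ids = c("nirK", "glnA"))
  expect_equal(summarize_cycle(p3, toy_cycle())$mean_pct[1], (10 + 30) / 2)
  # ...unless pooled mode is requested
  expect_equal(summarize_cycle(p3, toy_cycle(), average = "pooled")$mean_pct[1],
               3010 / 10100 * 100)

  # a sample with no cycle-gene hits is an error naming the sample
  m4 <- cbind(c(5, 1), c(0, 0))
  p4 <- make_profile(m4, gene_ids = c("nirK", "glnA"))
  expect_error(summarize_cycle(p4, toy_cycle()), "zero total cycle-gene counts: s2")
})

test_that("cycle summaries agree with relative abundance and ignore sample order", {
  set.seed(8)
  genes <- cycle_genes(toy_cycle())
  m <- matrix(rpois(length(genes) * 4, 50) + 1, ncol = 4)
  p <- make_profile(m, gene_ids = genes)
  s <- summarize_cycle(p, toy_cycle())
  ra <- relative_abundance(p)
  expect_equal(s$mean_pct, unname(rowMeans(as.matrix(ra[, -1])) * 100))

  pr <- make_profile(m[, c(3, 1, 4, 2)], gene_ids = genes)
  expect_equal(summarize_cycle(pr, toy_cycle())$mean_pct, s$mean_pct)
})

test_that("branch_fraction pools member percentages", {
  pcts <- c(nirK = 18, nirS = 3.1, norC = 6.5, norB = 2.0, nosZ = 3.4)
  s <- as_cycle_summary(pcts, nitrogen_cycle())
  expect_equal(branch_fraction(s, "nitrite_to_n2"), 33.0)
  expect_error(branch_fraction(s, "no_such_branch"), "Unknown branch")

  # whole-roster branch of a full summary returns 100
  genes <- cycle_genes(toy_cycle())
  p <- make_profile(matrix(seq_along(genes), ncol = 1), gene_ids = genes)
  sfull <- summarize_cycle(p, toy_cycle())
  expect_equal(branch_fraction(sfull, "whole"), 100)

  # defined branch whose genes are absent from the summary: 0 with warning
  s5 <- as_cycle_summary(pcts, toy_cycle())
  expect_warning(z <- branch_fraction(s5, "ghost"), "returning 0")
  expect_equal(z, 0)
})

test_that("cycle definitions validate structure", {
  expect_error(cycle_definition("x", list(a = "g1", b = "g1")), "at most one step")
  expect_error(cycle_definition("x", list(a = character(0))), "at least one gene")
  expect_error(cycle_definition("x", list(a = "g1"), branches = list(b = "g9")),
               "not in any step")
  nc <- nitrogen_cycle()
  expect_s3_class(nc, "cycle_definition")
  expect_true(all(c("nirK", "nirS", "norB", "norC", "nosZ") %in% cycle_genes(nc)))
  expect_equal(sort(nc$branches$nitrite_to_n2),
               sort(c("nirK", "nirS", "norB", "norC", "nosZ")))
})

test_that("summarize_gh reduces to top hits, applies the E-value cutoff, and tallies", {
  # 100 reads, 36 of them GH13
  tophits <- tibble::tibble(
    read_id = sprintf("r%03d", 1:100),
    family_id = c(rep("GH13", 36), rep("GH15", 8), rep("GH5", 26), rep("GH1", 30)),
    evalue = rep(1e-10, 100)
  )
  gh <- summarize_gh(tophits)
  expect_equal(gh$fraction[gh$family_id == "GH13"], 0.36)
  expect_equal(sum(gh$fraction), 1)

  # a read with two rows is counted once, under its lowest-E-value family
  two <- tibble::tibble(read_id = c("r1", "r1", "r2"),
                        family_id = c("GH5", "GH13", "GH13"),
                        evalue = c(1e-10, 1e-6, 1e-8))
  g2 <- summarize_gh(two)
  expect_equal(sum(g2$n_reads), 2L)
  expect_equal(g2$n_reads[g2$family_id == "GH5"], 1L)

  # strict <= threshold: 1e-5 is kept, larger is dropped
  edge <- tibble::tibble(read_id = c("a", "b"), family_id = c("GH5", "GH13"),
                         evalue = c(1e-5, 2e-5))
  ge <- summarize_gh(edge)
  expect_equal(ge$family_id, "GH5")
  expect_error(summarize_gh(tibble::tibble(read_id = "a", family_id = "GH5",
                                           evalue = 1e-4)),
               "No hit survives")
  expect_error(summarize_gh(tibble::tibble(read_id = "a", family_id = "GH5",
                                           evalue = -1)),
               "non-negative")
})

test_that("summarize_gh group fractions sum to one within groups and ignore row order", {
  set.seed(21)
  tophits <- tibble::tibble(
    read_id = sprintf("r%03d", 1:60),
    family_id = sample(c("GH13", "GH15", "GH5", "GH9", "GH51"), 60, replace = TRUE),
    evalue = 10^-sample(6:20, 60, replace = TRUE)
  )
  catalog <- read_gh_catalog(system.file("extdata", "gh_groups.tsv",
                                         package = "corefun", mustWork = TRUE))
  gh <- summarize_gh(tophits, catalog)
  by_group <- split(gh$group_fraction, gh$group)
  for (grp in names(by_group)) expect_equal(sum(by_group[[grp]]), 1)

  shuffled <- tophits[sample(nrow(tophits)), ]
  gh2 <- summarize_gh(shuffled, catalog)
  expect_equal(as.data.frame(gh)[order(gh$family_id), ],
               as.data.frame(gh2)[order(gh2$family_id), ],
               ignore_attr = TRUE)
})
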