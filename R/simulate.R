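#' Configuration for the synthetic functional-profile generator
#'
#' The generator emulates the statistical structure that the core-gene
#' analysis relies on: a heavy-tailed (log-normal) abundance law over
#' gene families, a planted subset of genes whose cross-sample ranks are
#' stable, multinomial counting at fixed per-sample depth, and category
#' labels that may concentrate the planted-stable genes in chosen
#' categories.
#'
#' Defaults mirror a six-metagenome functional survey: `samples = 6`,
#' `genes = 2000`, `depth = 5e5` hits per sample (so the rare-gene
#' filter at 100 bites without eroding the gene set), and a planted
#' stable fraction equal to the 10% core fraction under test.
#' Planted-stable genes are drawn among genes whose expected per-sample
#' count is at least `stable_min_count`: rank stability is a property
#' one can only express (and measure) above the counting-noise floor,
#' and core functions in real surveys are abundant gene families.
#'
#' @param genes Number of gene families `G`.
#' @param samples Number of samples `S`.
#' @param depth Total hits per sample (multinomial size).
#' @param n_categories Number of ontology categories.
#' @param category_sizes Optional integer vector summing to `genes`;
#'   defaults to (near-)equal sizes.
#' @param core_fraction_true Fraction of genes planted as rank-stable.
#' @param enrichment Named numeric vector/list: category -> excess
#'   proportion of planted-stable genes placed there beyond its
#'   size-proportional share.
#' @param abundance_sigma Log-scale dispersion of base abundances.
#' @param stable_noise,unstable_noise Per-sample log-normal perturbation
#'   scales for planted-stable vs other genes; the planted structure is
#'   identifiable only when `stable_noise < unstable_noise`.
#' @param stable_min_count Minimum expected per-sample count for a gene
#'   to be eligible as planted-stable (default 300).
#' @param check_depth If `TRUE` (default) require `depth >= 100 * genes`
#'   so the rare filter operates in its intended regime.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(genes = 2000, samples = 6, depth = 5e5,
                             n_categories = 25, category_sizes = NULL,
                             core_fraction_true = 0.10, enrichment = list(),
                             abundance_sigma = 1.0, stable_noise = 0.05,
                             unstable_noise = 1.0, stable_min_count = 300,
                             check_depth = TRUE) {
  stopifnot_scalar_number(genes, "genes", lower = 10)
  stopifnot_scalar_number(samples, "samples", lower = 2)
  stopifnot_scalar_number(depth, "depth", lower = 1)
  stopifnot_scalar_number(n_categories, "n_categories", lower = 1)
  stopifnot_scalar_number(core_fraction_true, "core_fraction_true")
  if (core_fraction_true <= 0 || core_fraction_true >= 1) {
    abort("`core_fraction_true` must lie strictly between 0 and 1.")
  }
  stopifnot_scalar_number(abundance_sigma, "abundance_sigma", lower = 0)
  stopifnot_scalar_number(stable_noise, "stable_noise", lower = 0)
  stopifnot_scalar_number(unstable_noise, "unstable_noise", lower = 0)
  if (stable_noise > unstable_noise) {
    abort("`stable_noise` must not exceed `unstable_noise`.")
  }
  if (isTRUE(check_depth) && depth < 100 * genes) {
    abort("`depth` < 100 * genes: the rare filter would dominate; pass check_depth = FALSE to override.")
  }
  genes <- as.integer(genes); samples <- as.integer(samples)
  n_categories <- as.integer(n_categories)
  if (is.null(category_sizes)) {
    category_sizes <- rep(genes %/% n_categories, n_categories)
    rem <- genes - sum(category_sizes)
    if (rem > 0) category_sizes[seq_len(rem)] <- category_sizes[seq_len(rem)] + 1L
  }
  if (length(category_sizes) != n_categories || sum(category_sizes) != genes) {
    abort("`category_sizes` must have length `n_categories` and sum to `genes`.")
  }
  enrichment <- unlist(enrichment) %||% numeric(0)
  if (length(enrichment)) {
    if (is.null(names(enrichment)) || any(names(enrichment) == "")) {
      abort("`enrichment` must be named by category.")
    }
    if (any(enrichment < 0) || sum(enrichment) > 1) {
      abort("Enrichment excesses must be non-negative and sum to at most 1.")
    }
  }
  structure(
    list(genes = genes, samples = samples, depth = depth,
         n_categories = n_categories, category_sizes = as.integer(category_sizes),
         core_fraction_true = core_fraction_true, enrichment = enrichment,
         abundance_sigma = abundance_sigma, stable_noise = stable_noise,
         unstable_noise = unstable_noise, stable_min_count = stable_min_count,
         identifiable = stable_noise < unstable_noise),
    class = "generator_config"
  )
}

#' Generate a synthetic functional profile with planted truth
#'
#' Draws per-gene base abundances from a log-normal law, perturbs them
#' per sample on the log scale (small scale for planted-stable genes,
#' large for the rest), and samples counts multinomially at the
#' configured depth, so each sample column sums to `depth` exactly.
#' Category labels honor the enrichment mapping: enriched categories
#' receive their size-proportional share of planted-stable genes plus
#' the configured excess; all remaining labels are assigned uniformly at
#' random, so with an empty mapping the planted genes are uniform over
#' categories.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical seed and config give identical
#'   tables.
#' @return A list with elements `profile` (a count
#'   [functional_profile()]), `ontology` (an [ontology_map()]) and
#'   `truth` (planted core gene ids, per-category planted/expected core
#'   counts, the `identifiable` flag, config and seed).
#' @export
generate_profile <- function(config, seed) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must come from generator_config().")
  }
  if (missing(seed)) abort("`seed` is required.")
  g <- config$genes; s <- config$samples
  gene_id <- sprintf("gene%05d", seq_len(g))
  cats <- sprintf("cat%02d", seq_len(config$n_categories))
  n_true <- round(config$core_fraction_true * g)

  with_seed(seed, {
    mu <- rnorm(g, 0, config$abundance_sigma)
    expected_per_sample <- config$depth * exp(mu) / sum(exp(mu))
    eligible <- which(expected_per_sample >= config$stable_min_count)
    if (length(eligible) < n_true) {
      abort(sprintf(
        "Only %d gene(s) reach stable_min_count = %g but %d planted-stable genes requested; lower `stable_min_count` or `abundance_sigma`.",
        length(eligible), config$stable_min_count, n_true))
    }
    core_idx <- sort(sample(eligible, n_true))
    sd_gene <- rep(config$unstable_noise, g)
    sd_gene[core_idx] <- config$stable_noise
    eps <- matrix(rnorm(g * s, 0, 1), g, s) * sd_gene
    lambda <- exp(mu + eps)
    counts <- vapply(seq_len(s),
                     function(j) as.numeric(rmultinom(1L, config$depth, lambda[, j])),
                     numeric(g))
    colnames(counts) <- sprintf("S%d", seq_len(s))

    assignment <- assign_categories(g, core_idx, cats, config$category_sizes,
                                    config$enrichment, n_true)
    profile <- functional_profile(tibble(gene_id = gene_id, as_tibble(counts)))
    ontology <- ontology_map(tibble(gene_id = gene_id,
                                    category_id = assignment$labels),
                            categories = cats)
    truth <- list(
      core_gene_ids = gene_id[core_idx],
      category_counts = assignment$planted_counts,
      expected_core_counts = assignment$expected_counts,
      identifiable = config$identifiable,
      seed = as.integer(seed),
      config = config
    )
    list(profile = profile, ontology = ontology, truth = truth)
  })
}

# Allocate category labels over genes. Enriched categories hold exactly
# their planted-stable quota (proportional share + excess); the remaining
# planted-stable genes spread uniformly over the slots of non-enriched
# categories, and all other genes fill the remaining slots at random.
assign_categories <- function(g, core_idx, cats, sizes, enrichment, n_true) {
  n_cat <- length(cats)
  names(sizes) <- cats
  quota <- integer(n_cat); names(quota) <- cats
  if (length(enrichment)) {
    unknown <- setdiff(names(enrichment), cats)
    if (length(unknown)) {
      abort(sprintf("Enrichment names unknown category(ies): %s",
                    paste(unknown, collapse = ", ")))
    }
    for (cat in names(enrichment)) {
      want <- round(n_true * (sizes[[cat]] / g + enrichment[[cat]]))
      if (want > sizes[[cat]]) {
        abort(sprintf(
          "Infeasible enrichment: %d planted-stable genes requested in '%s' of size %d.",
          want, cat, sizes[[cat]]))
      }
      quota[cat] <- as.integer(want)
    }
    if (sum(quota) > n_true) {
      abort("Infeasible enrichment: quotas exceed the number of planted-stable genes.")
    }
  }
  labels <- character(g)
  core_pool <- sample(core_idx)  # random order for quota draws
  used <- 0L
  for (cat in names(quota)[quota > 0L]) {
    take <- core_pool[seq.int(used + 1L, used + quota[[cat]])]
    labels[take] <- cat
    used <- used + quota[[cat]]
  }
  free_core <- n_true - used
  plain <- setdiff(cats, names(quota)[quota > 0L])
  plain_slots <- rep(plain, sizes[plain])
  if (free_core > length(plain_slots)) {
    abort("Infeasible enrichment: not enough non-enriched slots for the remaining planted-stable genes.")
  }
  if (free_core > 0L) {
    labels[core_pool[seq.int(used + 1L, n_true)]] <-
      sample(plain_slots, free_core)
  }
  core_labels <- labels[core_idx]
  remaining_slots <- rep(cats, sizes - tabulate(match(labels[labels != ""], cats),
                                               nbins = length(cats)))
  labels[labels == ""] <- sample(remaining_slots)
  planted <- table(factor(core_labels, levels = cats))
  expected <- quota
  expected[plain] <- sizes[plain] * free_core / max(1L, length(plain_slots))
  list(labels = labels,
       planted_counts = setNames(as.integer(planted), cats),
       expected_counts = setNames(as.numeric(expected), cats))
}

#' Generate taxa and metadata tables with planted associations
#'
#' Builds a sample-by-taxon relative-abundance table and a
#' sample-by-variable metadata table.  Unplanted pairs are independent;
#' each planted `(taxon, variable, rho)` pair is generated through a
#' Gaussian copula whose latent Pearson correlation `2 sin(pi rho / 6)`
#' yields the target Spearman coefficient in expectation.  Taxon
#' abundances are exponentiated latent normals renormalized to
#' per-sample proportions; with `n_taxa` large the renormalization
#' perturbs ranks only marginally.
#'
#' @param samples Number of samples (at least 4).
#' @param n_taxa Number of taxa.
#' @param n_vars Number of metadata variables.
#' @param planted List of `list(taxon =, variable =, rho =)` entries
#'   (indices or generated names, `|rho| <= 1`); at most one planted
#'   association per taxon/variable.
#' @param seed Integer seed.
#' @return A list with tibbles `taxa` (`sample_id` + taxon proportions)
#'   and `metadata` (`sample_id` + variables), and `truth` recording the
#'   planted associations.
#' @export
generate_taxa_metadata <- function(samples, n_taxa = 20, n_vars = 8,
                                   planted = list(), seed) {
  stopifnot_scalar_number(samples, "samples", lower = 4)
  stopifnot_scalar_number(n_taxa, "n_taxa", lower = 1)
  stopifnot_scalar_number(n_vars, "n_vars", lower = 1)
  if (missing(seed)) abort("`seed` is required.")
  s <- as.integer(samples)
  taxa_names <- sprintf("taxon%02d", seq_len(n_taxa))
  var_names <- sprintf("var%02d", seq_len(n_vars))
  planted <- lapply(planted, function(p) {
    ti <- if (is.character(p$taxon)) match(p$taxon, taxa_names) else as.integer(p$taxon)
    vi <- if (is.character(p$variable)) match(p$variable, var_names) else as.integer(p$variable)
    if (is.na(ti) || ti < 1 || ti > n_taxa) abort("Planted taxon out of range.")
    if (is.na(vi) || vi < 1 || vi > n_vars) abort("Planted variable out of range.")
    if (abs(p$rho) > 1) abort("|target rho| must be <= 1.")
    list(taxon = ti, variable = vi, rho = p$rho)
  })
  if (anyDuplicated(vapply(planted, `[[`, integer(1), "taxon")) ||
      anyDuplicated(vapply(planted, `[[`, integer(1), "variable"))) {
    abort("At most one planted association per taxon and per variable.")
  }
  with_seed(seed, {
    zt <- matrix(rnorm(s * n_taxa), s, n_taxa)
    zv <- matrix(rnorm(s * n_vars), s, n_vars)
    abund <- exp(1.0 * zt)
    abund <- abund / rowSums(abund)
    # Gaussian-copula rank construction on the *final* (renormalized)
    # proportions, so a target of +/-1 is exactly comonotone/antitone.
    for (p in planted) {
      r <- 2 * sin(pi * p$rho / 6)  # latent Pearson for target Spearman
      u <- (rank(abund[, p$taxon], ties.method = "average") - 0.5) / s
      zv[, p$variable] <- r * stats::qnorm(u) + sqrt(1 - r^2) * rnorm(s)
    }
    taxa <- tibble(sample_id = sprintf("S%03d", seq_len(s)),
                   as_tibble(setNames(as.data.frame(abund), taxa_names)))
    metadata <- tibble(sample_id = taxa$sample_id,
                       as_tibble(setNames(as.data.frame(zv), var_names)))
    truth <- list(
      planted = lapply(planted, function(p) {
        list(taxon = taxa_names[p$taxon], variable = var_names[p$variable],
             target_rho = p$rho)
      }),
      seed = as.integer(seed)
    )
    list(taxa = taxa, metadata = metadata, truth = truth)
  })
}
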