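#' Run the analysis pipeline from a configuration
#'
#' Orchestrates the stages over a YAML configuration (or equivalent
#' list): `simulate` (synthetic inputs), `filter` then `normalize` on
#' the profile (the rare filter is defined on counts, so the order is
#' fixed), `core`, `enrichment`, `cycle`, `cazy` and `correlate`.
#' Configuration problems -- a missing input file, an unknown stage, or
#' a missing seed when a stochastic stage is requested -- abort before
#' any computation.  Every run writes a `manifest.json` recording the
#' package version, stages, full parameter set, MD5 digests of the
#' input files, the seed, timestamps, per-stage durations and success
#' flags; identical config and seed reproduce identical outputs.
#'
#' Config keys: `stages` (character vector); `profile`, `ontology`,
#' `cycle`, `tophits`, `catalog`, `taxa`, `metadata` (input paths);
#' `min_total`, `core_fraction`, `permutations`, `evalue_max`,
#' `threshold`, `seed`; `simulate` (a list of [generator_config()]
#' arguments).
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out`.
#' @param seed Overrides `config$seed`.
#' @return Invisibly, a list of stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    if (!file.exists(cfg_path)) abort(sprintf("Config file not found: %s", cfg_path))
    config <- yaml::read_yaml(cfg_path)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a named list.")
  out_dir <- out_dir %||% config$out %||% abort("An output directory is required (`out_dir` or config `out`).")
  seed <- seed %||% config$seed
  stages <- unlist(config$stages) %||% abort("Config must name at least one stage.")

  known <- c("simulate", "filter", "normalize", "core", "enrichment",
             "cycle", "cazy", "correlate")
  unknown <- setdiff(stages, known)
  if (length(unknown)) {
    abort(sprintf("Unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  stages <- known[known %in% stages]  # canonical order
  if (any(c("enrichment", "simulate") %in% stages) && is.null(seed)) {
    abort("Stochastic stage requested (simulate/enrichment) but no seed given.")
  }
  # core selection and enrichment operate on the filtered profile
  if ("enrichment" %in% stages && !"core" %in% stages) {
    abort("The enrichment stage requires the core stage.")
  }

  inputs <- character(0)
  need_input <- function(key, required_by) {
    p <- config[[key]]
    if (is.null(p)) {
      abort(sprintf("Stage '%s' requires config key '%s'.", required_by, key))
    }
    if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
    inputs[[key]] <<- p
    p
  }
  if (!"simulate" %in% stages) {
    if (any(c("filter", "normalize", "core", "cycle") %in% stages)) {
      need_input("profile", "profile stages")
    }
    if ("enrichment" %in% stages) need_input("ontology", "enrichment")
  }
  if ("cazy" %in% stages) need_input("tophits", "cazy")
  if ("correlate" %in% stages) { need_input("taxa", "correlate"); need_input("metadata", "correlate") }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "corefun",
    version = as.character(utils::packageVersion("corefun")),
    config_file = cfg_path,
    stages = stages,
    parameters = config[setdiff(names(config), "stages")],
    input_digests = as.list(tools::md5sum(unname(unlist(inputs)))),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_log = list()
  )
  results <- list()
  profile <- NULL; ontology <- NULL

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      manifest$stage_log[[name]] <<- list(ok = FALSE, error = conditionMessage(e),
                                          seconds = as.numeric(Sys.time() - t0, units = "secs"))
      manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      manifest$status <<- "partial"
      write_manifest(manifest, out_dir)
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stage_log[[name]] <<- list(ok = TRUE,
                                        seconds = as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", function() {
      gc_args <- config$simulate %||% list()
      generate_profile(do.call(generator_config, gc_args), seed = seed)
    })
    profile <- sim$profile; ontology <- sim$ontology
    write_profile(profile, file.path(out_dir, "hits.tsv"))
    write_ontology(ontology, file.path(out_dir, "ontology.tsv"))
    jsonlite::write_json(sim$truth[c("core_gene_ids", "category_counts",
                                     "expected_core_counts", "identifiable", "seed")],
                         file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    results$simulate <- sim
  } else if (!is.null(config$profile)) {
    profile <- read_profile(config$profile)
  }
  raw_profile <- profile  # cycle summaries use unfiltered counts
  if (!is.null(config$ontology) && is.null(ontology)) {
    ontology <- read_ontology(config$ontology)
  }

  if ("filter" %in% stages) {
    profile <- run_stage("filter", function() {
      filter_rare(profile, min_total = config$min_total %||% 100)
    })
    results$filtered_profile <- profile
  }
  normalized <- NULL
  if ("normalize" %in% stages) {
    normalized <- run_stage("normalize", function() relative_abundance(profile))
    write_profile(normalized, file.path(out_dir, "relative_abundance.tsv"))
    results$normalized_profile <- normalized
  }
  variances <- NULL
  if ("core" %in% stages) {
    core <- run_stage("core", function() {
      variances <<- rank_variance(rank_transform(normalized %||% profile))
      select_core(variances, core_fraction = config$core_fraction %||% 0.10)
    })
    readr_write_tsv(tidy(core), file.path(out_dir, "core_genes.tsv"))
    results$core <- core
  }
  if ("enrichment" %in% stages) {
    enr <- run_stage("enrichment", function() {
      permutation_enrichment(variances, ontology,
                             core_fraction = config$core_fraction %||% 0.10,
                             permutations = config$permutations %||% 10000,
                             seed = seed)
    })
    readr_write_tsv(tidy(enr), file.path(out_dir, "enrichment.tsv"))
    results$enrichment <- enr
  }
  if ("cycle" %in% stages) {
    cyc <- run_stage("cycle", function() {
      cdef <- if (is.null(config$cycle)) nitrogen_cycle() else read_cycle_definition(config$cycle)
      summarize_cycle(raw_profile, cdef)
    })
    readr_write_tsv(as_tibble(cyc), file.path(out_dir, "cycle_summary.tsv"))
    readr_write_tsv(attr(cyc, "branches"), file.path(out_dir, "cycle_branches.tsv"))
    results$cycle <- cyc
  }
  if ("cazy" %in% stages) {
    gh <- run_stage("cazy", function() {
      tophits <- read_tophits(config$tophits)
      catalog <- if (!is.null(config$catalog)) read_gh_catalog(config$catalog)
      summarize_gh(tophits, catalog, evalue_max = config$evalue_max %||% 1e-5)
    })
    readr_write_tsv(as_tibble(gh), file.path(out_dir, "gh_summary.tsv"))
    results$gh <- gh
  }
  if ("correlate" %in% stages) {
    cm <- run_stage("correlate", function() {
      taxa <- read_sample_table(config$taxa)
      metadata <- read_sample_table(config$metadata)
      filter_correlations(spearman_matrix(taxa, metadata),
                          threshold = config$threshold %||% 0.60)
    })
    write_correlations(cm, out_dir)
    results$correlations <- cm
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$status <- "complete"
  write_manifest(manifest, out_dir)
  results$manifest <- manifest
  invisible(results)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# plain TSV writer for tibbles (no quoting needed for our identifiers)
readr_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a read-level top-hit table
#'
#' TSV with header `read_id`, `family_id`, `evalue`.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_tophits <- function(path) {
  parsed <- parse_tsv_lines(path, min_cols = 3L)
  for (rec in parsed$body) {
    if (length(rec$fields) != 3L) {
      abort(sprintf("%s:%d: expected 3 tab-separated fields.", path, rec$line))
    }
  }
  ev <- suppressWarnings(as.numeric(vapply(parsed$body, function(r) r$fields[3L], character(1))))
  bad <- which(is.na(ev))
  if (length(bad)) {
    abort(sprintf("%s:%d: non-numeric E-value.", path, parsed$body[[bad[1L]]]$line))
  }
  tibble(
    read_id = vapply(parsed$body, function(r) r$fields[1L], character(1)),
    family_id = vapply(parsed$body, function(r) r$fields[2L], character(1)),
    evalue = ev
  )
}

#' Read a sample-by-variable table (taxa abundances or metadata)
#'
#' TSV with a `sample_id` first column and numeric variable columns;
#' empty cells become `NA` (handled pairwise-complete downstream).
#'
#' @param path Path to the TSV file.
#' @return A tibble with `sample_id` plus numeric columns.
#' @export
read_sample_table <- function(path) {
  parsed <- parse_tsv_lines(path, min_cols = 2L)
  vars <- parsed$header$fields[-1L]
  n_fields <- length(parsed$header$fields)
  rows <- lapply(parsed$body, function(rec) {
    if (length(rec$fields) != n_fields) {
      abort(sprintf("%s:%d: ragged row.", path, rec$line))
    }
    vals <- rec$fields[-1L]
    vals[vals %in% c("", "NA")] <- NA
    suppressWarnings(as.numeric(vals))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- vars
  tibble(sample_id = vapply(parsed$body, function(r) r$fields[1L], character(1)),
         as_tibble(m))
}
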