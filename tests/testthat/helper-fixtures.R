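# Shared fixture builders: everything is generated in code at test time.

make_profile <- function(m, gene_ids = NULL, sample_ids = NULL, normalized = FALSE) {
  gene_ids <- gene_ids %||% sprintf("g%02d", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% sprintf("s%d", seq_len(ncol(m)))
  colnames(m) <- sample_ids
  functional_profile(tibble::tibble(gene_id = gene_ids, tibble::as_tibble(m)),
                     normalized = normalized)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

small_ontology <- function(gene_ids, categories) {
  ontology_map(tibble::tibble(gene_id = gene_ids, category_id = categories))
}

# Equal-split ontology over n genes: categories c1..c_k in blocks.
block_ontology <- function(gene_ids, n_categories) {
  k <- length(gene_ids) %/% n_categories
  cats <- rep(sprintf("c%02d", seq_len(n_categories)), length.out = length(gene_ids))
  small_ontology(gene_ids, sort(cats))
}
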