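#' Define a biogeochemical cycle
#'
#' A cycle definition names ordered pathway steps, each a non-empty set
#' of marker gene families (a gene belongs to at most one step), plus
#' optional named branches: gene subsets whose pooled percentage is of
#' interest, such as the denitrification segment converting nitrite to
#' dinitrogen gas.
#'
#' @param name Cycle name.
#' @param steps Named list of character vectors of gene identifiers.
#' @param branches Optional named list of character vectors; every
#'   branch gene must belong to some step.
#' @return An object of class `cycle_definition`.
#' @seealso [nitrogen_cycle()], [read_cycle_definition()],
#'   [summarize_cycle()]
#' @export
cycle_definition <- function(name, steps, branches = list()) {
  if (!is.character(name) || length(name) != 1L) abort("`name` must be a string.")
  if (!is.list(steps) || !length(steps) || is.null(names(steps)) ||
      any(names(steps) == "")) {
    abort("`steps` must be a non-empty named list of gene-id vectors.")
  }
  steps <- lapply(steps, as.character)
  if (any(lengths(steps) == 0L)) abort("Every step must contain at least one gene.")
  all_genes <- unlist(steps, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    abort(sprintf("A gene may appear in at most one step; duplicated: %s",
                  paste(unique(all_genes[duplicated(all_genes)]), collapse = ", ")))
  }
  branches <- lapply(branches, as.character)
  if (length(branches)) {
    if (is.null(names(branches)) || any(names(branches) == "")) {
      abort("`branches` must be named.")
    }
    stray <- setdiff(unlist(branches, use.names = FALSE), all_genes)
    if (length(stray)) {
      abort(sprintf("Branch gene(s) not in any step: %s", paste(stray, collapse = ", ")))
    }
  }
  structure(list(name = name, steps = steps, branches = branches),
            class = "cycle_definition")
}

check_cycle <- function(cycle) {
  if (!inherits(cycle, "cycle_definition")) {
    abort("Expected a `cycle_definition` (see `cycle_definition()` or `nitrogen_cycle()`).")
  }
  invisible(cycle)
}

#' @rdname cycle_definition
#' @param cycle A `cycle_definition`.
#' @export
cycle_genes <- function(cycle) {
  check_cycle(cycle)
  unlist(cycle$steps, use.names = FALSE)
}

#' Read a cycle definition from a YAML file
#'
#' The file holds `name`, a `steps` mapping of step name to gene list,
#' and an optional `branches` mapping.
#'
#' @param path Path to the YAML file.
#' @return A [cycle_definition()].
#' @export
read_cycle_definition <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$steps)) {
    abort(sprintf("%s: cycle YAML must define `name` and `steps`.", path))
  }
  cycle_definition(y$name, y$steps, y$branches %||% list())
}

#' The packaged nitrogen-cycle definition
#'
#' Marker genes for the major nitrogen-cycle processes (fixation,
#' nitrification, dissimilatory and assimilatory nitrate reduction,
#' denitrification, ammonia assimilation), with a `nitrite_to_n2` branch
#' covering the denitrification steps from nitrite to dinitrogen gas
#' (nirK/nirS, norB/norC, nosZ).  The roster ships as an editable YAML
#' file under `inst/extdata/` and is deliberately user-extensible: real
#' surveys detect additional cycle genes.
#'
#' @return A [cycle_definition()].
#' @export
nitrogen_cycle <- function() {
  read_cycle_definition(system.file("extdata", "nitrogen_cycle.yaml",
                                    package = "corefun", mustWork = TRUE))
}

#' Summarize cycle-gene abundances across samples
#'
#' Within each sample, every cycle gene's count is divided by the total
#' count of all cycle genes in that sample and expressed as a
#' percentage; percentages are then averaged across samples with equal
#' weight (sequencing depth varies between metagenomes, so each sample
#' contributes one vote).  A pooled mode that sums counts over samples
#' before normalizing is available behind `average = "pooled"`.
#' Roster genes absent from the profile count as zero.
#'
#' @param profile A count [functional_profile()].
#' @param cycle A [cycle_definition()].
#' @param average `"samples"` (default: mean of per-sample percentages)
#'   or `"pooled"` (percentages of summed counts).
#' @return A tibble of class `cycle_summary` with columns `step`,
#'   `gene_id`, `mean_pct` (summing to 100 over the roster) and
#'   attributes `cycle`, `n_samples`, `branches` (per-branch subtotals).
#' @export
summarize_cycle <- function(profile, cycle, average = c("samples", "pooled")) {
  check_profile(profile)
  check_cycle(cycle)
  average <- match.arg(average)
  if (is_normalized(profile)) {
    abort("summarize_cycle() expects counts; pass the unnormalized profile.")
  }
  genes <- cycle_genes(cycle)
  m <- profile_matrix(profile)
  cm <- matrix(0, nrow = length(genes), ncol = ncol(m),
               dimnames = list(genes, colnames(m)))
  present <- intersect(genes, rownames(m))
  cm[present, ] <- m[present, , drop = FALSE]
  totals <- colSums(cm)
  if (any(totals == 0)) {
    abort(sprintf("Sample(s) with zero total cycle-gene counts: %s",
                  paste(colnames(cm)[totals == 0], collapse = ", ")))
  }
  mean_pct <- if (average == "samples") {
    rowMeans(sweep(cm, 2L, totals, "/")) * 100
  } else {
    rowSums(cm) / sum(totals) * 100
  }
  step_of <- rep(names(cycle$steps), lengths(cycle$steps))
  out <- tibble(step = step_of, gene_id = genes, mean_pct = as.numeric(mean_pct))
  new_cycle_summary(out, cycle, n_samples = ncol(cm), average = average)
}

new_cycle_summary <- function(tbl, cycle, n_samples, average = "samples") {
  branches <- tibble(
    branch = names(cycle$branches) %||% character(0),
    pct = vapply(cycle$branches, function(g) sum(tbl$mean_pct[tbl$gene_id %in% g]),
                 numeric(1), USE.NAMES = FALSE)
  )
  structure(tbl, class = c("cycle_summary", class(tbl)),
            cycle = cycle, n_samples = n_samples, average = average,
            branches = branches)
}

#' Build a cycle summary from stated per-gene percentages
#'
#' Constructs a `cycle_summary` directly from per-gene percentages of
#' all cycle genes (for example the values reported in a publication or
#' computed elsewhere), so that branch subtotals can be taken without
#' the underlying count table.  Genes of the roster not mentioned are
#' assumed to carry the remaining share.
#'
#' @param percentages Named numeric vector (or two-column data frame
#'   `gene_id`, `mean_pct`) of per-gene percentages, each in \[0, 100\].
#' @param cycle A [cycle_definition()] whose roster covers the named
#'   genes.
#' @return A `cycle_summary` restricted to the stated genes.
#' @export
#' @examples
#' s <- as_cycle_summary(
#'   c(nirK = 18, nirS = 3.1, norC = 6.5, norB = 2.0, nosZ = 3.4),
#'   nitrogen_cycle()
#' )
#' branch_fraction(s, "nitrite_to_n2")
as_cycle_summary <- function(percentages, cycle) {
  check_cycle(cycle)
  if (is.data.frame(percentages)) {
    df <- as_tibble(percentages)[, c("gene_id", "mean_pct")]
  } else {
    if (is.null(names(percentages))) abort("`percentages` must be named by gene.")
    df <- tibble(gene_id = names(percentages), mean_pct = as.numeric(percentages))
  }
  if (anyNA(df$mean_pct) || any(df$mean_pct < 0) || any(df$mean_pct > 100)) {
    abort("Percentages must lie in [0, 100].")
  }
  if (sum(df$mean_pct) > 100 + 1e-6) abort("Percentages exceed 100 in total.")
  roster <- cycle_genes(cycle)
  stray <- setdiff(df$gene_id, roster)
  if (length(stray)) {
    abort(sprintf("Gene(s) not in the cycle roster: %s", paste(stray, collapse = ", ")))
  }
  step_of <- setNames(rep(names(cycle$steps), lengths(cycle$steps)), roster)
  out <- tibble(step = unname(step_of[df$gene_id]), gene_id = df$gene_id,
                mean_pct = df$mean_pct)
  new_cycle_summary(out, cycle, n_samples = NA_integer_)
}

#' Pooled percentage of a named branch
#'
#' Sums the mean percentages of the branch's member genes; for instance
#' the `nitrite_to_n2` denitrification branch of the packaged nitrogen
#' cycle pools nirK, nirS, norB, norC and nosZ.
#'
#' @param summary A `cycle_summary`.
#' @param branch Branch name defined in the summary's cycle.
#' @return The branch subtotal as a percentage of all cycle genes.
#' @export
branch_fraction <- function(summary, branch) {
  if (!inherits(summary, "cycle_summary")) {
    abort("Expected a `cycle_summary` from summarize_cycle() or as_cycle_summary().")
  }
  cycle <- attr(summary, "cycle")
  if (!branch %in% names(cycle$branches)) {
    abort(sprintf("Unknown branch '%s'; defined: %s", branch,
                  paste(names(cycle$branches), collapse = ", ") %||% "(none)"))
  }
  members <- cycle$branches[[branch]]
  hit <- summary$gene_id %in% members
  if (!any(hit)) {
    warn(sprintf("No branch '%s' gene present in the summary; returning 0.", branch))
    return(0)
  }
  sum(summary$mean_pct[hit])
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat(sprintf("# Cycle summary: %s (%s samples)\n", attr(x, "cycle")$name,
              ifelse(is.na(attr(x, "n_samples")), "stated, no", attr(x, "n_samples"))))
  NextMethod()
  br <- attr(x, "branches")
  if (nrow(br)) {
    cat("# Branch subtotals:\n")
    for (i in seq_len(nrow(br))) cat(sprintf("#   %s: %.1f%%\n", br$branch[i], br$pct[i]))
  }
  invisible(x)
}

#' @rdname summarize_cycle
#' @param object A `cycle_summary`.
#' @param ... Unused.
#' @method autoplot cycle_summary
#' @export
autoplot.cycle_summary <- function(object, ...) {
  df <- as_tibble(object)
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$mean_pct,
                                   fill = .data$step)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of all cycle genes (mean across samples)",
                  fill = "Step") +
    ggplot2::theme_minimal()
}
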