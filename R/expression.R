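#' Harmonize probe-level platforms onto a common gene universe
#'
#' Collapses each platform's probe rows to genes by taking the arithmetic
#' mean of a gene's probes per sample, then restricts every dataset to the
#' intersection of the platforms' mapped genes (the "common genes").
#'
#' @param datasets List of [expression_dataset()]s (probe-level rows when a
#'   probe map is given, gene-level otherwise).
#' @param probe_maps Optional list (parallel to `datasets`) of data frames
#'   `probe`, `gene`; `NULL` entries mean rows are already genes.
#' @return List of gene-level [expression_dataset()]s on the common gene
#'   universe, rows in identical (radix-sorted) order.
#' @export
harmonize_platforms <- function(datasets, probe_maps = NULL) {
  if (length(datasets) == 0) stop("at least one dataset is required")
  if (is.null(probe_maps)) probe_maps <- vector("list", length(datasets))
  if (length(probe_maps) != length(datasets))
    stop("probe_maps must parallel datasets")
  gene_level <- mapply(function(d, pm) {
    v <- d$values
    if (!is.null(pm)) {
      missing <- setdiff(rownames(v), pm$probe)
      if (length(missing) > 0)
        stop(sprintf("probe map for platform '%s' does not cover %d probe rows",
                     d$platform_id, length(missing)))
      gene <- pm$gene[match(rownames(v), pm$probe)]
      sums <- rowsum(v, group = gene)
      counts <- as.vector(table(gene)[rownames(sums)])
      v <- sums / counts
    }
    expression_dataset(d$platform_id, v, d$groups)
  }, datasets, probe_maps, SIMPLIFY = FALSE)
  common <- Reduce(intersect, lapply(gene_level, function(d) rownames(d$values)))
  if (length(common) == 0) {
    counts <- vapply(gene_level, function(d) nrow(d$values), integer(1))
    ids <- vapply(gene_level, function(d) d$platform_id, character(1))
    stop(sprintf("platforms share no genes (per-platform gene counts: %s)",
                 paste(sprintf("%s=%d", ids, counts), collapse = ", ")))
  }
  common <- sort(common, method = "radix")
  lapply(gene_level, function(d)
    expression_dataset(d$platform_id, d$values[common, , drop = FALSE], d$groups))
}

group_means <- function(dataset) {
  v <- dataset$values
  list(case = rowMeans(v[, dataset$groups == "case", drop = FALSE]),
       control = rowMeans(v[, dataset$groups == "control", drop = FALSE]))
}

#' Fold-change filter on case/control mean ratios
#'
#' Retains a gene iff its ratio of group means (case over control) is at
#' most `low` or at least `high`; genes with ratios strictly inside
#' `(low, high)` are filtered out.  A zero control mean yields an infinite
#' ratio: the gene is retained with a warning.
#'
#' @param dataset Gene-level [expression_dataset()].
#' @param low,high Ratio bounds (defaults 0.67 = 1/1.5 and 1.5).
#' @return Character vector of retained gene identifiers.
#' @export
fold_change_filter <- function(dataset, low = 0.67, high = 1.5) {
  m <- group_means(dataset)
  ratio <- m$case / m$control
  zero_ctrl <- m$control == 0 & m$case > 0
  if (any(zero_ctrl)) {
    warning(sprintf("%d genes have zero control mean; retained with ratio = Inf",
                    sum(zero_ctrl)))
    ratio[zero_ctrl] <- Inf
  }
  ratio[m$control == 0 & m$case == 0] <- 1  # flat zero gene: filtered out
  rownames(dataset$values)[ratio <= low | ratio >= high]
}

#' Within-sample rank transform
#'
#' Replaces each sample column by the ranks of its values over the common
#' genes (1 = lowest), ties receiving the average rank.
#'
#' @param dataset Gene-level [expression_dataset()].
#' @return An [expression_dataset()] of ranks.
#' @export
rank_transform <- function(dataset) {
  ranked <- apply(dataset$values, 2, rank, ties.method = "average")
  rownames(ranked) <- rownames(dataset$values)
  expression_dataset(dataset$platform_id, ranked, dataset$groups)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when `min(n1, n2) <= 8` and the pooled values are
#' tie-free; otherwise the normal approximation with tie-corrected variance
#' and continuity correction.  Degenerate input with all pooled values
#' equal returns p = 1.
#'
#' @param case_values,control_values Non-empty numeric vectors.
#' @return Two-sided p-value in \[0, 1\].
#' @export
wilcoxon_rank_sum <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0)
    stop("both groups must be non-empty")
  pooled <- c(case_values, control_values)
  if (length(unique(pooled)) == 1) return(1)
  has_ties <- anyDuplicated(pooled) > 0
  exact <- !has_ties && min(length(case_values), length(control_values)) <= 8
  suppressWarnings(
    stats::wilcox.test(case_values, control_values, exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: monotone non-decreasing in sorted-p order and
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return Numeric vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  # adjust over the tested (non-NA) p-values only
  stats::p.adjust(p_values, method = "BH", n = sum(ok))
}

#' Differential-expression table for one dataset
#'
#' Implements the two-stage screen on a harmonized dataset: fold filter on
#' raw group-mean ratios, within-sample rank transform over all common
#' genes, Wilcoxon rank-sum test of case vs control ranks for the genes
#' passing the filter, and Benjamini-Hochberg FDR over the tested genes.
#' Genes removed by the fold filter carry `NA` p/q and are never selected.
#'
#' @param dataset Gene-level [expression_dataset()].
#' @param fdr_level FDR selection level (default 0.10).
#' @param low,high Fold-filter bounds (see [fold_change_filter()]).
#' @return Data frame `gene`, `mean_ratio`, `p_value`, `q_value`,
#'   `selected`, one row per gene.
#' @export
de_table <- function(dataset, fdr_level = 0.10, low = 0.67, high = 1.5) {
  genes <- rownames(dataset$values)
  m <- group_means(dataset)
  ratio <- m$case / m$control
  retained <- fold_change_filter(dataset, low = low, high = high)
  ranked <- rank_transform(dataset)
  is_case <- ranked$groups == "case"
  p <- rep(NA_real_, length(genes))
  names(p) <- genes
  p[retained] <- vapply(retained, function(g)
    wilcoxon_rank_sum(ranked$values[g, is_case], ranked$values[g, !is_case]),
    numeric(1))
  q <- fdr_adjust(p)
  data.frame(gene = genes, mean_ratio = as.numeric(ratio),
             p_value = as.numeric(p), q_value = as.numeric(q),
             selected = !is.na(q) & q <= fdr_level,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differentially expressed genes across datasets
#'
#' Runs the [de_table()] screen per dataset (fold filter, rank transform,
#' Wilcoxon, FDR within that dataset) and returns the union of selected
#' genes.  With `pooled = TRUE` the FDR adjustment is instead computed over
#' the pooled p-values of all datasets.
#'
#' @param datasets List of gene-level (harmonized) [expression_dataset()]s.
#' @param fdr_level FDR selection level (default 0.10).
#' @param low,high Fold-filter bounds.
#' @param pooled Pool p-values across datasets before the FDR step?
#' @return Sorted character vector of selected genes, with the per-dataset
#'   tables attached as attribute `"tables"`.
#' @export
select_de_genes <- function(datasets, fdr_level = 0.10,
                            low = 0.67, high = 1.5, pooled = FALSE) {
  if (length(datasets) == 0) stop("at least one dataset is required")
  tables <- lapply(datasets, de_table, fdr_level = fdr_level,
                   low = low, high = high)
  if (pooled) {
    all_p <- unlist(lapply(tables, `[[`, "p_value"))
    all_q <- fdr_adjust(all_p)
    at <- 0L
    tables <- lapply(tables, function(tb) {
      tb$q_value <- all_q[at + seq_len(nrow(tb))]
      at <<- at + nrow(tb)
      tb$selected <- !is.na(tb$q_value) & tb$q_value <= fdr_level
      tb
    })
  }
  selected <- sort(unique(unlist(lapply(tables, function(tb)
    tb$gene[tb$selected]))), method = "radix")
  attr(selected, "tables") <- tables
  selected
}

#' Assemble a provenance-tagged seed collection
#'
#' Combines the three seed sources (causative-list, proteomics-derived and
#' microarray-derived genes) keeping provenance; overlapping genes are
#' permitted and counted once in the union.
#'
#' @param omim_genes,proteomics_genes,de_genes Character vectors sharing
#'   one identifier namespace.
#' @return Object of class `seed_collection` with elements `omim`,
#'   `proteomics`, `microarray`.
#' @seealso [seed_union()]
#' @export
assemble_seeds <- function(omim_genes, proteomics_genes, de_genes) {
  structure(list(omim = sort(unique(as.character(omim_genes)), method = "radix"),
                 proteomics = sort(unique(as.character(proteomics_genes)),
                                   method = "radix"),
                 microarray = sort(unique(as.character(de_genes)),
                                   method = "radix")),
            class = "seed_collection")
}

#' Union of all seed sources
#'
#' @param seeds A `seed_collection`.
#' @return Sorted character vector of the union of the three sources.
#' @export
seed_union <- function(seeds) {
  sort(unique(c(seeds$omim, seeds$proteomics, seeds$microarray)),
       method = "radix")
}

#' @export
print.seed_collection <- function(x, ...) {
  cat(sprintf("seed_collection: %d causative + %d proteomics + %d microarray = %d genes in union\n",
              length(x$omim), length(x$proteomics), length(x$microarray),
              length(seed_union(x))))
  invisible(x)
}
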