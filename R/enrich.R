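#' Gene-set collection
#'
#' A flat collection of annotation terms (GO/KEGG/Biocarta-style), each a
#' non-empty member gene set with a unique identifier.
#'
#' @param terms Named list; each element a list with `name` (character)
#'   and `genes` (non-empty character vector).
#' @return Object of class `gene_set_collection` (the validated list).
#' @export
gene_set_collection <- function(terms) {
  if (length(terms) == 0 || is.null(names(terms)) || any(names(terms) == ""))
    stop("terms must be a non-empty named list")
  if (anyDuplicated(names(terms)))
    stop("term identifiers must be unique")
  for (id in names(terms)) {
    if (is.null(terms[[id]]$genes) || length(terms[[id]]$genes) == 0)
      stop(sprintf("term '%s' has an empty member set", id))
    terms[[id]]$genes <- unique(as.character(terms[[id]]$genes))
    if (is.null(terms[[id]]$name)) terms[[id]]$name <- id
  }
  structure(terms, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(t) length(t$genes), integer(1))
  cat(sprintf("gene_set_collection: %d terms, member sizes %d-%d\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

check_hyper_args <- function(N, K, n) {
  if (any(c(N, K, n) != floor(c(N, K, n))) || N < 0 || K < 0 || n < 0)
    stop("N, K, n must be nonnegative integers")
  if (K > N || n > N)
    stop("require K <= N and n <= N")
}

#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `i` feature-carrying items when `n` items
#' are drawn without replacement from a set of `N` items of which `K` carry
#' the feature: `C(K,i) C(N-K,n-i) / C(N,n)`, evaluated via log-space
#' binomial coefficients.  Out-of-support `i` gives 0.
#'
#' @param i Number of feature-carrying draws (vectorized).
#' @param N Background set size.
#' @param K Feature-carrying items in the background.
#' @param n Draw (query) size.
#' @return Probability (vector along `i`).
#' @export
hypergeom_pmf <- function(i, N, K, n) {
  check_hyper_args(N, K, n)
  stats::dhyper(i, m = K, n = N - K, k = n)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k) = 1 - sum_{i=0}^{k-1} f(i)`: the probability of drawing at
#' least `k` feature-carrying items by chance.  `k <= 0` gives 1.
#'
#' @param k Observed overlap.
#' @inheritParams hypergeom_pmf
#' @return p-value in \[0, 1\].
#' @export
hypergeom_tail_p <- function(k, N, K, n) {
  check_hyper_args(N, K, n)
  ifelse(k <= 0, 1,
         stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Hypergeometric enrichment of a query gene set
#'
#' Tests every annotation term for over-representation in the query: with
#' `N` background genes of which `K` carry the term and a query of size
#' `n` overlapping the term in `k` genes, the p-value is the upper-tail
#' probability [hypergeom_tail_p()].  Query genes missing from the
#' background are clipped with a warning.  No multiple-testing correction
#' is applied unless `adjust = TRUE` (then significance is on BH q-values).
#'
#' @param query_genes Character vector of query genes.
#' @param collection A [gene_set_collection()].
#' @param background Character vector of background genes (non-empty).
#' @param alpha Significance level (default 0.05).
#' @param min_overlap Minimum overlap `k` for a term to be reported
#'   (default 1; use 0 to report all terms).
#' @param adjust Apply Benjamini-Hochberg adjustment?
#' @return Data frame sorted by ascending p-value with columns `term_id`,
#'   `name`, `N`, `K`, `n`, `k`, `p_value` (and `q_value` when
#'   `adjust = TRUE`), `significant`.
#' @export
enrich <- function(query_genes, collection, background, alpha = 0.05,
                   min_overlap = 1L, adjust = FALSE) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background gene set is empty")
  query_genes <- unique(as.character(query_genes))
  outside <- setdiff(query_genes, background)
  if (length(outside) > 0) {
    warning(sprintf("%d query genes are outside the background and were clipped",
                    length(outside)))
    query_genes <- intersect(query_genes, background)
  }
  N <- length(background)
  n <- length(query_genes)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]]$genes, background)
    K <- length(members)
    k <- length(intersect(members, query_genes))
    data.frame(term_id = id, name = collection[[id]]$name,
               N = N, K = K, n = n, k = k,
               p_value = if (K > 0) hypergeom_tail_p(k, N, K, n) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$k >= min_overlap, , drop = FALSE]
  out <- out[order(out$p_value, out$term_id, method = "radix"), , drop = FALSE]
  if (adjust) {
    out$q_value <- fdr_adjust(out$p_value)
    out$significant <- out$q_value <= alpha
  } else {
    out$significant <- out$p_value <= alpha
  }
  rownames(out) <- NULL
  out
}

#' Overlap of a subnetwork with a reference gene set
#'
#' Intersects the subnetwork nodes with a reference network's genes
#' (innate-immune-like, drug-target-like, ...) and tests the overlap's
#' composition against the subnetwork as background: is the overlap
#' enriched with inner-core nodes, and with non-seed nodes?
#'
#' @param sub A `subnetwork`.
#' @param reference_genes Genes of the reference network/list.
#' @param inner_core Genes of the subnetwork's inner core.
#' @param seeds Seed genes (the non-seed test uses their complement).
#' @return List with `overlap` (character vector) and `tests` (data frame
#'   `feature`, `N`, `K`, `n`, `k`, `p_value`).
#' @export
overlap_subnetwork <- function(sub, reference_genes, inner_core = character(0),
                               seeds = character(0)) {
  nodes <- sub$nodes
  overlap <- sort(intersect(nodes, reference_genes), method = "radix")
  feat <- list(inner_core = intersect(nodes, inner_core),
               non_seed = setdiff(nodes, seeds))
  tests <- do.call(rbind, lapply(names(feat), function(f) {
    K <- length(feat[[f]])
    k <- length(intersect(overlap, feat[[f]]))
    data.frame(feature = f, N = length(nodes), K = K,
               n = length(overlap), k = k,
               p_value = hypergeom_tail_p(k, length(nodes), K, length(overlap)),
               stringsAsFactors = FALSE)
  }))
  list(overlap = overlap, tests = tests)
}

#' Tissue-abundance composition of a subnetwork
#'
#' Maps subnetwork nodes onto a four-level abundance table
#' (negative/weak/moderate/strong).  Coverage is the fraction of nodes
#' present in the table; a node counts as "detected" when its level is
#' weak, moderate or strong.
#'
#' @param sub A `subnetwork` (or character vector of genes).
#' @param table Data frame `gene`, `level`.
#' @return List with `coverage`, `counts` (named integer over the four
#'   levels), `fractions` (of covered nodes), `detected_fraction` (of all
#'   nodes).
#' @export
abundance_distribution <- function(sub, table) {
  nodes <- if (inherits(sub, "subnetwork")) sub$nodes else as.character(sub)
  levels4 <- c("negative", "weak", "moderate", "strong")
  if (!all(table$level %in% levels4))
    stop("abundance levels must be one of negative/weak/moderate/strong")
  lv <- table$level[match(nodes, table$gene)]
  covered <- !is.na(lv)
  counts <- table(factor(lv[covered], levels = levels4))
  counts <- stats::setNames(as.integer(counts), levels4)
  list(coverage = if (length(nodes)) mean(covered) else 0,
       counts = counts,
       fractions = if (sum(covered) > 0) counts / sum(covered) else
         stats::setNames(rep(NA_real_, 4), levels4),
       detected_fraction = if (length(nodes))
         sum(counts[c("weak", "moderate", "strong")]) / length(nodes) else 0)
}
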