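#' Weighted gene-gene interaction network
#'
#' A `weighted_network` holds an undirected, weighted interaction network as
#' a symmetric sparse matrix with zero diagonal and weights in \[0, 1\]
#' (STRING-style confidence scores rescaled to the unit interval).  It is the
#' substrate of the seeded propagation in [katz_score_direct()].
#'
#' @param genes Character vector of unique gene identifiers, one per node.
#' @param W Symmetric n x n matrix (dense or [Matrix::sparseMatrix()]) of
#'   interaction weights in \[0, 1\] with zero diagonal.
#'
#' @return An object of class `weighted_network` with elements `genes`
#'   (ordered identifiers) and `W` (sparse symmetric weight matrix with
#'   `dimnames` set to the genes).
#' @export
weighted_network <- function(genes, W) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(W) != length(genes) || ncol(W) != length(genes))
    stop("W must be square with one row/column per gene")
  if (!Matrix::isSymmetric(W, tol = 0))
    stop("W must be symmetric")
  if (any(Matrix::diag(W) != 0))
    stop("W must have a zero diagonal")
  if (any(W@x < 0) || any(W@x > 1))
    stop("all weights must lie in [0, 1]")
  dimnames(W) <- list(genes, genes)
  structure(list(genes = genes, W = W), class = "weighted_network")
}

#' Build a weighted network from an undirected edge table
#'
#' Duplicate undirected edges are collapsed keeping the maximum weight and
#' self-loops are dropped, so the result always satisfies the
#' [weighted_network()] contract.
#'
#' @param edges Data frame with columns `gene1`, `gene2`, `weight`.
#' @param genes Optional character vector fixing the node universe and order;
#'   defaults to the sorted set of genes appearing in `edges`.
#' @return A [weighted_network()].
#' @export
weighted_network_from_edges <- function(edges, genes = NULL) {
  stopifnot(all(c("gene1", "gene2", "weight") %in% names(edges)))
  g1 <- as.character(edges$gene1)
  g2 <- as.character(edges$gene2)
  w <- as.numeric(edges$weight)
  keep <- g1 != g2
  g1 <- g1[keep]; g2 <- g2[keep]; w <- w[keep]
  if (is.null(genes))
    genes <- sort(unique(c(g1, g2)), method = "radix")
  genes <- as.character(genes)
  i <- match(g1, genes)
  j <- match(g2, genes)
  if (anyNA(i) || anyNA(j))
    stop("edge table mentions genes outside the supplied universe")
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    lo <- as.integer(sub(" .*", "", names(w)))
    hi <- as.integer(sub(".* ", "", names(w)))
    w <- as.numeric(w)
  }
  n <- length(genes)
  W <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                            dims = c(n, n), dimnames = list(genes, genes))
  weighted_network(genes, W)
}

#' Edge table of a weighted network
#'
#' @param network A [weighted_network()].
#' @return Data frame `gene1`, `gene2`, `weight`, one row per undirected
#'   edge, with `gene1 < gene2` and rows in deterministic order.
#' @export
network_edges <- function(network) {
  W <- methods::as(Matrix::triu(network$W), "TsparseMatrix")
  i <- W@i + 1L
  j <- W@j + 1L
  ord <- order(i, j)
  data.frame(gene1 = network$genes[i[ord]],
             gene2 = network$genes[j[ord]],
             weight = W@x[ord],
             stringsAsFactors = FALSE)
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- Matrix::nnzero(x$W) / 2
  cat(sprintf("weighted_network: %d genes, %d edges, weights in [%.3g, %.3g]\n",
              length(x$genes), m,
              if (m > 0) min(x$W@x) else 0,
              if (m > 0) max(x$W@x) else 0))
  invisible(x)
}
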