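# Independent brute-force oracles used to freeze expected values.

# Two-sided Wilcoxon rank-sum p by full enumeration of group assignments.
wilcoxon_enum_oracle <- function(case_values, control_values) {
  pooled <- c(case_values, control_values)
  n1 <- length(case_values)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2, function(ii) sum(r[ii]))
  p_lo <- mean(stats <= obs)
  p_hi <- mean(stats >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Benjamini-Hochberg step-up from its definition: q_(i) = min_{j >= i} p_(j) m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric pmf/tail by enumerating all C(N, n) draws from a labelled urn.
hyper_enum_oracle <- function(N, K, n) {
  if (n == 0) {
    pmf <- c(1, rep(0, N))
  } else {
    urn <- c(rep(TRUE, K), rep(FALSE, N - K))
    draws <- utils::combn(N, n)
    counts <- apply(draws, 2, function(ii) sum(urn[ii]))
    pmf <- tabulate(counts + 1L, nbins = N + 1L) / ncol(draws)
  }
  list(pmf = function(i) ifelse(i >= 0 & i <= N, pmf[i + 1L], 0),
       tail = function(k) {
         if (k <= 0) return(1)
         if (k > N) return(0)
         sum(pmf[(k + 1L):(N + 1L)])
       })
}

# k-core by the maximal-subgraph definition: union of every vertex subset in
# which all members have >= k neighbors inside the subset.
kcore_subset_oracle <- function(nodes, edges, k) {
  n <- length(nodes)
  A <- matrix(0L, n, n)
  if (nrow(edges) > 0) {
    i <- match(edges$gene1, nodes)
    j <- match(edges$gene2, nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  core <- rep(FALSE, n)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(S) == 0) next
    deg_in <- rowSums(A[S, S, drop = FALSE])
    if (all(deg_in >= k)) core[S] <- TRUE
  }
  sort(nodes[core], method = "radix")
}

# Random simple graph as a subnetwork-shaped object (unit weights).
random_graph_sub <- function(n, p) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(gene1 = nodes[pairs[keep, 1]],
                      gene2 = nodes[pairs[keep, 2]],
                      weight = rep(1, sum(keep)), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, weight_floor = 0),
            class = "subnetwork")
}

# Random weighted network for solver tests.
random_network <- function(n, density = 0.05, wmax = 1) {
  genes <- sprintf("r%04d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  w <- stats::runif(nrow(pairs), 0.05, wmax)
  W <- Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                            j = c(pairs[, 2], pairs[, 1]),
                            x = c(w, w), dims = c(n, n))
  weighted_network(genes, W)
}
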