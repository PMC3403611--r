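#' Seed activity vector over a network
#'
#' Encodes a set of a-priori disease-active genes ("seeds") as a 0/1
#' indicator over the nodes of a network.  Seeds that are absent from the
#' network are reported (via a message and the `missing` element) rather
#' than silently dropped, since the fraction of seeds present is itself a
#' quantity of interest.
#'
#' @param network A [weighted_network()].
#' @param seeds Character vector of seed gene identifiers.
#' @return An object of class `activity_vector`: list with `x` (named 0/1
#'   numeric vector over network genes), `seeds_used` and `missing`.
#' @export
build_activity_vector <- function(network, seeds) {
  seeds <- unique(as.character(seeds))
  present <- seeds[seeds %in% network$genes]
  missing <- setdiff(seeds, present)
  if (length(missing) > 0)
    message(sprintf("%d of %d seed genes not present in the network",
                    length(missing), length(seeds)))
  x <- stats::setNames(as.numeric(network$genes %in% present), network$genes)
  structure(list(x = x, seeds_used = present, missing = missing),
            class = "activity_vector")
}

as_activity_x <- function(network, x) {
  if (inherits(x, "activity_vector")) x <- x$x
  x <- as.numeric(x)
  if (length(x) != length(network$genes))
    stop("activity vector length does not match the network")
  x
}

#' Spectral radius estimate by power iteration
#'
#' For a symmetric nonnegative weight matrix the dominant eigenvalue is the
#' spectral radius; it bounds the admissible propagation strength
#' (`phi < 1/rho`).  Estimated by plain power iteration from a constant
#' start vector (deterministic).
#'
#' @param W Symmetric nonnegative matrix.
#' @param iterations Number of power-iteration steps.
#' @return Nonnegative scalar estimate of the spectral radius.
#' @export
spectral_radius <- function(W, iterations = 100L) {
  n <- nrow(W)
  if (n == 0L || Matrix::nnzero(W) == 0L) return(0)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(iterations)) {
    v_new <- as.numeric(W %*% v)
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) return(0)
    v <- v_new / nv
  }
  as.numeric(t(v) %*% (W %*% v))
}

check_phi <- function(phi, rho) {
  if (phi < 0) stop("phi must be nonnegative")
  if (rho > 0 && phi >= 1 / rho)
    stop(sprintf(paste0("phi = %g is at or beyond the divergence bound ",
                        "1/spectral_radius(W) = %g; the propagation series ",
                        "does not converge"), phi, 1 / rho))
}

score_result <- function(network, s, phi, iterations, residual, method) {
  s <- stats::setNames(as.numeric(s), network$genes)
  structure(list(genes = network$genes, s = s, phi = phi,
                 iterations = iterations, residual = residual,
                 ranks = rank_genes(s), method = method),
            class = "score_result")
}

#' Katz propagation scores by direct linear solve
#'
#' Solves `(I - phi W) s = x` for the seeded Katz score vector
#' `s = sum_t phi^t W^t x`: each gene's score accumulates walks of every
#' length from the seed set, down-weighted by `phi` per step.  `phi` trades
#' off the prior activity `x` against network coupling and must stay below
#' `1/spectral_radius(W)` for the series to converge (checked with a
#' power-iteration estimate).
#'
#' @param network A [weighted_network()].
#' @param x An [build_activity_vector()] result or numeric vector over the
#'   network genes.
#' @param phi Nonnegative propagation strength.
#' @return An object of class `score_result`: named score vector `s`, the
#'   `phi` used, solver `residual` (max-norm of `(I - phi W)s - x`),
#'   `iterations` (`NA` for the direct solve) and descending-score `ranks`
#'   (ties broken by gene identifier).
#' @seealso [katz_score_jacobi()] for the iterative solver.
#' @export
katz_score_direct <- function(network, x, phi) {
  x <- as_activity_x(network, x)
  rho <- spectral_radius(network$W)
  check_phi(phi, rho)
  n <- length(network$genes)
  # I - phi*W is symmetric positive definite for phi < 1/rho: take the
  # sparse Cholesky path rather than the general LU
  A <- Matrix::forceSymmetric(Matrix::Diagonal(n) - phi * network$W)
  s <- as.numeric(Matrix::solve(A, x))
  residual <- max(abs(as.numeric(A %*% s) - x))
  score_result(network, s, phi, NA_integer_, residual, "direct")
}

#' Katz propagation scores by Jacobi iteration
#'
#' Iterates `s_i <- x_i + phi * sum_{j != i} w_ij s_j` from `s = x` until
#' the max-norm update falls below `tol`.  Because the diagonal of `W` is
#' zero this fixed-point iteration is exactly the Jacobi method for
#' `(I - phi W) s = x` and converges whenever `phi < 1/spectral_radius(W)`.
#'
#' @inheritParams katz_score_direct
#' @param tol Convergence tolerance on the max-norm update (default 1e-10).
#' @param max_iter Maximum number of sweeps before erroring.
#' @return A `score_result` (see [katz_score_direct()]) with the iteration
#'   count and the final update norm as `residual`.
#' @export
katz_score_jacobi <- function(network, x, phi, tol = 1e-10, max_iter = 10000L) {
  x <- as_activity_x(network, x)
  if (tol <= 0) stop("tol must be positive")
  rho <- spectral_radius(network$W)
  check_phi(phi, rho)
  s <- x
  for (it in seq_len(max_iter)) {
    s_new <- x + phi * as.numeric(network$W %*% s)
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol)
      return(score_result(network, s, phi, it, delta, "jacobi"))
  }
  stop(sprintf("Jacobi iteration did not converge in %d iterations (last update %g)",
               max_iter, delta))
}

#' Rank genes by descending score
#'
#' Rank 1 is the highest-scoring gene.  Ties are broken deterministically
#' by gene identifier (C-locale radix order).
#'
#' @param s A `score_result` or a named numeric score vector.
#' @return Integer vector of ranks (a permutation of `1..n`), named by gene.
#' @export
rank_genes <- function(s) {
  if (inherits(s, "score_result")) s <- s$s
  genes <- names(s)
  if (is.null(genes)) genes <- as.character(seq_along(s))
  ord <- order(-as.numeric(s), genes, method = "radix")
  ranks <- integer(length(s))
  ranks[ord] <- seq_along(s)
  stats::setNames(ranks, genes)
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score_result (%s): %d genes, phi = %g, residual = %.3g\n",
              x$method, length(x$s), x$phi, x$residual))
  invisible(x)
}

#' Locus candidate set around a disease gene
#'
#' Takes the `N` genes nearest to a disease gene by genomic coordinate
#' (base-pair midpoint distance) on its chromosome, the disease gene
#' included; if the chromosome region holds fewer than `N` genes, all of
#' them are taken.  Candidate sets are the unit over which the propagation
#' strength is calibrated via r-ratios.
#'
#' @param loci Data frame with columns `chrom`, `start`, `end`, `gene`
#'   (BED-like, 0-based half-open coordinates).
#' @param disease_gene Gene identifier present in `loci`.
#' @param N Target candidate-set size (about 100 in typical use).
#' @return Object of class `candidate_set`: `disease_gene`, `members`
#'   (character vector), `N = length(members)`.
#' @export
build_candidate_set <- function(loci, disease_gene, N = 100L) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(loci)))
  row <- which(loci$gene == disease_gene)
  if (length(row) == 0)
    stop(sprintf("disease gene '%s' absent from the locus table", disease_gene))
  row <- row[1]
  region <- loci[loci$chrom == loci$chrom[row], , drop = FALSE]
  mid <- (region$start + region$end) / 2
  d <- abs(mid - (loci$start[row] + loci$end[row]) / 2)
  ord <- order(d, region$gene, method = "radix")
  members <- region$gene[ord][seq_len(min(N, nrow(region)))]
  structure(list(disease_gene = disease_gene,
                 members = members, N = length(members)),
            class = "candidate_set")
}

#' r-ratio of a disease gene within its candidate set
#'
#' The disease gene's descending-score rank `r` among its `N` locus
#' candidates, divided by `N`.  Values near `1/N` mean the gene is ranked
#' at the top of its locus; values near 0.5 are what a random gene attains.
#'
#' @param candidate_set A [build_candidate_set()] result.
#' @param score A `score_result`.
#' @return A scalar in `(0, 1]`.
#' @export
r_ratio <- function(candidate_set, score) {
  members <- candidate_set$members
  scored <- members[members %in% names(score$s)]
  if (!candidate_set$disease_gene %in% scored)
    stop("disease gene has no score; it must be present in the scored network")
  if (length(scored) < length(members))
    warning(sprintf("%d candidate genes have no score and were dropped",
                    length(members) - length(scored)))
  r <- rank_genes(score$s[scored])[[candidate_set$disease_gene]]
  r / length(scored)
}

#' Logarithmic grid of propagation strengths
#'
#' @param min,max Grid bounds; `points` values are log-spaced in
#'   `[min, max)` (the upper bound itself is excluded).
#' @param points Number of grid points.
#' @return Increasing numeric vector of length `points`.
#' @export
phi_grid <- function(min = 1e-6, max = 1e-2, points = 30L) {
  if (min <= 0 || max <= min || points < 1) stop("invalid phi grid")
  10^(seq(log10(min), log10(max), length.out = points + 1L)[seq_len(points)])
}

#' Calibrate the propagation strength by locus r-ratios
#'
#' For each `phi` on the grid, scores the network from the seed set
#' (held-out disease genes excluded), extracts each held-out gene's rank
#' within its locus candidate set, and averages the resulting r-ratios.
#' Returns the `phi` minimizing the average r-ratio; ties go to the
#' smallest `phi`.
#'
#' @param network A [weighted_network()].
#' @param seeds Seed genes used to build the activity vector; must be
#'   disjoint from `holdout`.
#' @param holdout Known disease genes held out for calibration.
#' @param loci Locus table (see [build_candidate_set()]).
#' @param grid Increasing vector of candidate `phi` values.
#' @param N Candidate-set size.
#' @return Object of class `calibration_result`: `grid`, `mean_r_ratio`
#'   (per grid point), `phi_star`, and a `table` data frame.
#' @export
calibrate_phi <- function(network, seeds, holdout, loci,
                          grid = phi_grid(), N = 100L) {
  if (length(grid) == 0) stop("phi grid is empty")
  holdout <- unique(as.character(holdout))
  if (length(holdout) == 0) stop("holdout gene set is empty")
  if (length(intersect(seeds, holdout)) > 0)
    stop("holdout genes must be disjoint from the seeds")
  grid <- sort(as.numeric(grid))
  usable <- holdout[holdout %in% network$genes & holdout %in% loci$gene]
  if (length(usable) < length(holdout))
    warning(sprintf("%d holdout genes missing from network or loci were skipped",
                    length(holdout) - length(usable)))
  if (length(usable) == 0) stop("no holdout gene is scorable")
  csets <- lapply(usable, function(g) {
    cs <- build_candidate_set(loci, g, N)
    # locus neighbors outside the interactome carry no score: clip once here
    cs$members <- cs$members[cs$members %in% network$genes]
    cs$N <- length(cs$members)
    cs
  })
  x <- build_activity_vector(network, seeds)
  mean_rr <- vapply(grid, function(phi) {
    sc <- katz_score_direct(network, x, phi)
    mean(vapply(csets, r_ratio, numeric(1), score = sc))
  }, numeric(1))
  best <- which.min(mean_rr)  # first minimum = smallest phi on the sorted grid
  structure(list(grid = grid, mean_r_ratio = mean_rr,
                 phi_star = grid[best],
                 table = data.frame(phi = grid, mean_r_ratio = mean_rr)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %d grid points, phi* = %g (mean r-ratio %.4f)\n",
              length(x$grid), x$phi_star, min(x$mean_r_ratio)))
  invisible(x)
}

#' Select the top-ranked fraction of genes
#'
#' Takes the `ceiling(q * denominator)` highest-scoring genes.  The
#' denominator is explicit: either all genes in the network or only genes
#' with a strictly positive score (relevant when many genes are untouched
#' by the propagation).
#'
#' @param score A `score_result`.
#' @param q Fraction in `(0, 1]` (default 0.10).
#' @param denominator `"all_genes"` or `"positive_score"`.
#' @return Character vector of selected gene identifiers (rank order).
#' @export
select_top_fraction <- function(score, q = 0.10,
                                denominator = c("all_genes", "positive_score")) {
  denominator <- match.arg(denominator)
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  base <- switch(denominator,
                 all_genes = length(score$s),
                 positive_score = sum(score$s > 0))
  m <- ceiling(q * base)
  names(sort(score$ranks, method = "radix"))[seq_len(m)]
}
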