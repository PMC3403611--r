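test_that("activity vectors indicate seeds and report missing ones", {
  net <- weighted_network(c("g1", "g2", "g3"), matrix(0, 3, 3))
  expect_equal(unname(build_activity_vector(net, "g2")$x), c(0, 1, 0))
  expect_message(av <- build_activity_vector(net, c("g1", "zz", "yy")),
                 "2 of 3 seed genes not present")
  expect_equal(av$missing, c("zz", "yy"))
  expect_equal(sum(av$x), 1)
  expect_equal(sum(build_activity_vector(net, character(0))$x), 0)
})

test_that("direct Katz solve matches closed forms", {
  net <- two_node_network()
  s0 <- katz_score_direct(net, c(1, 0), 0)
  expect_equal(unname(s0$s), c(1, 0))
  s <- katz_score_direct(net, c(1, 0), 0.5)
  expect_equal(unname(s$s), c(4 / 3, 2 / 3), tolerance = 1e-10)
  zero <- weighted_network(c("a", "b", "c"), matrix(0, 3, 3))
  expect_equal(unname(katz_score_direct(zero, c(1, 1, 0), 0.9)$s), c(1, 1, 0))
})

test_that("phi at or beyond the spectral bound raises a divergence error", {
  net <- two_node_network()  # spectral radius 1
  expect_error(katz_score_direct(net, c(1, 0), 1), "spectral_radius")
  expect_error(katz_score_direct(net, c(1, 0), 1.7), "does not converge")
  expect_error(katz_score_direct(net, c(1, 0), -0.1), "nonnegative")
  expect_equal(spectral_radius(net$W), 1, tolerance = 1e-8)
})

test_that("Jacobi iteration agrees with the direct solve", {
  net <- two_node_network()
  j0 <- katz_score_jacobi(net, c(1, 0), 0)
  expect_equal(j0$iterations, 1L)
  expect_equal(unname(j0$s), c(1, 0))
  j <- katz_score_jacobi(net, c(1, 0), 0.5, tol = 1e-12)
  expect_equal(unname(j$s), c(4 / 3, 2 / 3), tolerance = 1e-10)
  set.seed(3)
  for (rep_i in 1:10) {
    n <- sample(20:120, 1)
    net_r <- random_network(n, density = 0.1)
    phi <- 0.5 / spectral_radius(net_r$W)
    x <- as.numeric(stats::runif(n) < 0.1)
    sd_ <- katz_score_direct(net_r, x, phi)
    sj <- katz_score_jacobi(net_r, x, phi, tol = 1e-10)
    expect_lt(max(abs(sd_$s - sj$s)), 1e-8)
  }
  expect_error(katz_score_jacobi(net, c(1, 0), 0.99, max_iter = 3L),
               "did not converge")
})

test_that("scores grow monotonically in phi and dominate the activity vector", {
  set.seed(4)
  net <- random_network(60, density = 0.15)
  x <- as.numeric(stats::runif(60) < 0.2)
  rho <- spectral_radius(net$W)
  phis <- c(0, 0.2, 0.5, 0.9) / rho
  scores <- lapply(phis, function(p) katz_score_direct(net, x, p)$s)
  for (i in seq_along(phis)) expect_true(all(scores[[i]] >= x - 1e-12))
  for (i in seq_len(length(phis) - 1))
    expect_true(all(scores[[i + 1]] - scores[[i]] >= -1e-10))
})

test_that("scoring is equivariant under node relabeling", {
  set.seed(5)
  net <- random_network(40, density = 0.2)
  x <- as.numeric(stats::runif(40) < 0.2)
  phi <- 0.4 / spectral_radius(net$W)
  s1 <- katz_score_direct(net, x, phi)$s
  perm <- sample(40)
  net2 <- weighted_network(net$genes[perm], net$W[perm, perm])
  s2 <- katz_score_direct(net2, x[perm], phi)$s
  expect_equal(unname(s2), unname(s1[perm]), tolerance = 1e-10)
})

test_that("truncated Neumann series approximates the resolvent within its bound", {
  set.seed(6)
  net <- random_network(30, density = 0.2)
  x <- as.numeric(stats::runif(30) < 0.3)
  rho <- spectral_radius(net$W)
  phi <- 0.3 / rho
  s <- katz_score_direct(net, x, phi)$s
  for (T_ in c(3, 6, 10)) {
    approx <- x
    term <- x
    for (t in seq_len(T_)) {
      term <- phi * as.numeric(net$W %*% term)
      approx <- approx + term
    }
    bound <- (phi * rho)^(T_ + 1) / (1 - phi * rho) * sqrt(sum(x^2))
    expect_lte(max(abs(s - approx)), bound + 1e-12)
  }
})

test_that("ranking is descending with deterministic identifier tie-breaks", {
  s <- c(ga = 0.1, gb = 0.9, gc = 0.5)
  expect_equal(unname(rank_genes(s)), c(3, 1, 2))
  tied <- c(gc = 1, ga = 1, gb = 1)
  expect_equal(rank_genes(tied), c(gc = 3L, ga = 1L, gb = 2L))
  expect_equal(unname(rank_genes(s + 7)), unname(rank_genes(s)))
})

test_that("candidate sets take the N nearest genes on the chromosome", {
  loci <- data.frame(chrom = "chr1",
                     start = seq(0, by = 1000, length.out = 250),
                     end = seq(0, by = 1000, length.out = 250) + 100,
                     gene = sprintf("g%03d", 1:250))
  cs <- build_candidate_set(loci, "g125", N = 100L)
  expect_equal(cs$N, 100L)
  expect_true("g125" %in% cs$members)
  small <- loci[1:37, ]
  expect_equal(build_candidate_set(small, "g010", N = 100L)$N, 37L)
  expect_equal(build_candidate_set(loci, "g125", N = 1L)$members, "g125")
  expect_error(build_candidate_set(loci, "absent"), "absent")
})

test_that("r-ratio reflects the disease gene's rank within its candidate set", {
  genes <- sprintf("g%03d", 1:100)
  s_top <- structure(list(s = stats::setNames(c(100, stats::runif(99)), genes)),
                     class = "score_result")
  cs <- structure(list(disease_gene = "g001", members = genes, N = 100L),
                  class = "candidate_set")
  expect_equal(r_ratio(cs, s_top), 0.01)
  s_bot <- structure(list(s = stats::setNames(c(-1, stats::runif(99)), genes)),
                     class = "score_result")
  expect_equal(r_ratio(cs, s_bot), 1.0)
})

test_that("top-fraction selection honors q and the denominator mode", {
  genes <- sprintf("g%02d", 1:20)
  sc <- structure(list(s = stats::setNames(seq(2, 0.1, length.out = 20), genes),
                       ranks = stats::setNames(1:20, genes)),
                  class = "score_result")
  expect_equal(select_top_fraction(sc, 0.10), genes[1:2])
  expect_length(select_top_fraction(sc, 1), 20)
  genes50 <- sprintf("h%02d", 1:50)
  s50 <- stats::setNames(c(rep(1, 7), rep(0, 43)), genes50)
  sc50 <- structure(list(s = s50, ranks = rank_genes(s50)),
                    class = "score_result")
  expect_length(select_top_fraction(sc50, 0.10, "positive_score"), 1)  # ceil(0.7)
  expect_length(select_top_fraction(sc50, 0.10, "all_genes"), 5)
})

test_that("phi calibration returns the grid minimizer with smallest-phi ties", {
  expect_equal(phi_grid(points = 30L)[1], 1e-6)
  expect_lt(max(phi_grid(points = 30L)), 1e-2)
  expect_length(phi_grid(points = 30L), 30)
  sc <- small_scenario()
  net <- generate_network(sc)
  seeds <- union(sc$sources$proteomics, sc$sources$microarray)
  loci <- generate_loci(sc, sc$sources$omim, genes_per_locus = 40L)
  cal <- calibrate_phi(net, seeds, sc$sources$omim, loci,
                       grid = phi_grid(points = 8L), N = 40L)
  expect_true(cal$phi_star %in% cal$grid)
  expect_equal(min(cal$mean_r_ratio),
               cal$mean_r_ratio[match(cal$phi_star, cal$grid)])
  expect_lt(min(cal$mean_r_ratio), 0.25)  # planted module is recoverable
  one <- calibrate_phi(net, seeds, sc$sources$omim, loci,
                       grid = 1e-4, N = 40L)
  expect_equal(one$phi_star, 1e-4)
  expect_error(calibrate_phi(net, seeds, sc$sources$omim, loci,
                             grid = numeric(0)), "empty")
  expect_error(calibrate_phi(net, seeds, character(0), loci), "empty")
  expect_error(calibrate_phi(net, seeds, seeds[1], loci), "disjoint")
})
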