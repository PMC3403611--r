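test_that("scenario construction enforces its invariants and parameter ranges", {
  sc <- small_scenario()
  expect_true(all(unlist(sc$sources) %in% sc$module_genes))
  expect_true(all(sc$module_genes %in% sc$genes))
  expect_length(intersect(sc$sources$omim,
                          union(sc$sources$proteomics, sc$sources$microarray)), 0)
  expect_error(small_scenario(edge_density_in = 1.2), "densities")
  expect_error(small_scenario(edge_density_in = 0.01, edge_density_out = 0.01),
               "must exceed")
  expect_error(synthetic_scenario(n_genes = 10L, n_module = 20L), "module size")
  expect_error(small_scenario(de_effect = 0.5), "de_effect")
  sc2 <- small_scenario(source_overlap = 2L)
  expect_length(intersect(sc2$sources$proteomics, sc2$sources$microarray), 2)
})

test_that("generated network is symmetric, zero-diagonal, with weights in range", {
  sc <- small_scenario()
  net <- generate_network(sc)
  expect_true(Matrix::isSymmetric(net$W))
  expect_true(all(Matrix::diag(net$W) == 0))
  e <- network_edges(net)
  mod <- e$gene1 %in% sc$module_genes & e$gene2 %in% sc$module_genes
  expect_true(all(e$weight[mod] >= 0.6 & e$weight[mod] <= 1))
  expect_true(all(e$weight[!mod] >= 0.1 & e$weight[!mod] <= 0.5))
})

test_that("degenerate densities give a module clique and nothing else", {
  sc <- synthetic_scenario(n_genes = 10L, n_module = 4L, n_causative = 1L,
                           n_proteomics = 1L, n_de_module = 1L,
                           n_de_background = 1L, edge_density_in = 1,
                           edge_density_out = 0, rng_seed = 5L)
  net <- generate_network(sc)
  e <- network_edges(net)
  expect_equal(nrow(e), choose(4, 2))
  expect_true(all(e$gene1 %in% sc$module_genes & e$gene2 %in% sc$module_genes))
})

test_that("generators are bit-for-bit reproducible under a fixed seed", {
  sc <- small_scenario(seed = 42L)
  expect_identical(network_edges(generate_network(sc)),
                   network_edges(generate_network(sc)))
  expect_identical(generate_expression(sc), generate_expression(sc))
  ho <- sc$sources$omim
  expect_identical(generate_loci(sc, ho, 20L), generate_loci(sc, ho, 20L))
  expect_identical(generate_annotations(sc, n_terms = 10L),
                   generate_annotations(sc, n_terms = 10L))
  sc2 <- small_scenario(seed = 43L)
  expect_false(identical(network_edges(generate_network(sc)),
                         network_edges(generate_network(sc2))))
})

test_that("null expression scenario yields identical case and control values", {
  sc <- small_scenario(de_effect = 1, noise_sd = 0)
  ex <- generate_expression(sc)
  d <- ex$datasets[[1]]
  case <- d$values[, d$groups == "case", drop = FALSE]
  ctrl <- d$values[, d$groups == "control", drop = FALSE]
  expect_equal(rowMeans(case), rowMeans(ctrl))
  expect_true(all(apply(d$values, 1, function(r) length(unique(r)) == 1)))
})

test_that("planted DE genes exceed the 1.5-fold ratio at strong effect and low noise", {
  sc <- small_scenario(de_effect = 3, noise_sd = 0.05)
  ex <- generate_expression(sc)
  harmonized <- harmonize_platforms(ex$datasets, ex$probe_maps)
  for (d in harmonized) {
    m_case <- rowMeans(d$values[, d$groups == "case", drop = FALSE])
    m_ctrl <- rowMeans(d$values[, d$groups == "control", drop = FALSE])
    ratio <- (m_case / m_ctrl)[sc$de_gene_ids]
    expect_true(all(ratio > 1.5))
  }
})

test_that("platforms carry 1-3 probes per gene and share the configured subset", {
  sc <- small_scenario()
  ex <- generate_expression(sc)
  for (pm in ex$probe_maps) {
    counts <- table(pm$gene)
    expect_true(all(counts >= 1 & counts <= 3))
  }
  common <- intersect(ex$probe_maps[[1]]$gene, ex$probe_maps[[2]]$gene)
  expect_gte(length(common), round(0.9 * sc$n_genes))
  expect_true(all(sc$module_genes %in% common))
  expect_true(all(sc$de_gene_ids %in% common))
})

test_that("locus tables place held-out genes amid ordered non-overlapping regions", {
  sc <- small_scenario()
  ho <- sc$sources$omim
  loci <- generate_loci(sc, ho, genes_per_locus = 50L)
  expect_true(all(ho %in% loci$gene))
  for (ch in unique(loci$chrom)) {
    reg <- loci[loci$chrom == ch, ]
    expect_equal(nrow(reg), 50L)
    expect_true(all(diff(reg$start) > 0))
    expect_true(all(reg$end > reg$start))
    expect_length(intersect(reg$gene, ho), 1)
  }
  expect_false(anyDuplicated(loci$gene) > 0)
  expect_error(generate_loci(sc, character(0)), "non-empty")
  expect_error(generate_loci(sc, ho, genes_per_locus = 200L), "too small")
})

test_that("annotation generator plants an over-representing term and records it", {
  sc <- small_scenario()
  ann <- generate_annotations(sc, n_terms = 25L)
  planted <- ann$manifest$enriched_term_ids
  members <- ann$collection[[planted]]$genes
  # the planted term draws 80% of its members from the module (capped by it)
  expect_equal(length(intersect(members, sc$module_genes)),
               min(length(sc$module_genes), round(0.8 * length(members))))
  expect_identical(ann$manifest$held_out_disease_genes, sc$sources$omim)
  expect_length(intersect(ann$manifest$held_out_disease_genes,
                          union(sc$sources$proteomics, sc$sources$microarray)), 0)
  expect_error(generate_annotations(sc, n_terms = 0L), "at least 1")
  expect_error(generate_annotations(sc, term_size_range = c(10L, 1000L)),
               "exceed")
})

test_that("abundance and reference generators cover the module as designed", {
  sc <- small_scenario()
  ab <- generate_abundance(sc)
  expect_true(all(ab$level %in% c("negative", "weak", "moderate", "strong")))
  mod_covered <- mean(sc$module_genes %in% ab$gene)
  expect_gte(mod_covered, 0.8)
  ref <- generate_reference_set(sc, n_extra = 50L)
  expect_gte(length(intersect(ref, sc$module_genes)),
             round(0.8 * length(sc$module_genes)))
})
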