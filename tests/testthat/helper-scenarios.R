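# Compact scenario for fast unit tests; the package defaults are the
# full desk-scale study conditions exercised in test-acceptance.R.
small_scenario <- function(seed = 42L, n_case = 6L, n_control = 6L, ...) {
  synthetic_scenario(n_genes = 300L, n_module = 20L, n_causative = 3L,
                     n_proteomics = 5L, n_de_module = 6L, n_de_background = 2L,
                     n_case = n_case, n_control = n_control,
                     rng_seed = seed, ...)
}

# Tiny fixed networks used across prioritize/network tests.
two_node_network <- function() {
  weighted_network(c("a", "b"), matrix(c(0, 1, 1, 0), 2))
}

triangle_pendant_sub <- function() {
  structure(list(
    nodes = c("a", "b", "c", "d"),
    edges = data.frame(gene1 = c("a", "a", "b", "c"),
                       gene2 = c("b", "c", "c", "d"),
                       weight = 1, stringsAsFactors = FALSE),
    weight_floor = 0), class = "subnetwork")
}
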