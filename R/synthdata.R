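#' Synthetic study scenario with a planted disease module
#'
#' Defines every parameter of the synthetic inputs: a gene universe, a
#' planted high-weight disease module, seed genes inside the module split
#' by pseudo-source (causative-list, proteomics, microarray), planted
#' differentially expressed genes, and the noise/effect/sample-size
#' settings of a two-platform case-control expression experiment.  All
#' generators ([generate_network()], [generate_expression()],
#' [generate_loci()], [generate_annotations()], ...) take a scenario and
#' are bit-for-bit reproducible given its `rng_seed`.
#'
#' The defaults are a desk-scale analog of a genome-wide study: 2000 genes,
#' a 50-gene module connected at density 0.6 with weights U(0.6, 1) against
#' a 0.01-density U(0.1, 0.5) background (so a 0.5 weight floor separates
#' module from background edges), a 2-fold expression effect on planted DE
#' genes with log-normal noise (sd 0.25 on the log scale), and 12 cases vs
#' 12 controls per platform.
#'
#' @param n_genes Size of the gene universe.
#' @param n_module Size of the planted disease module.
#' @param n_causative Module genes playing the role of the known causative
#'   list (held out for calibration, then added to the seeds).
#' @param n_proteomics Module genes playing the proteomics-derived seeds.
#' @param n_de_module,n_de_background Planted differentially expressed
#'   genes inside/outside the module; the microarray seed source.
#' @param source_overlap Number of planted DE module genes also placed in
#'   the proteomics list (0 = disjoint sources).
#' @param edge_density_in,edge_density_out Edge probabilities within the
#'   module and elsewhere; `edge_density_in` must exceed
#'   `edge_density_out`, both in \[0, 1\].
#' @param weight_in,weight_out Length-2 uniform weight ranges (within
#'   \[0, 1\]) for module and background edges.
#' @param de_effect Fold-change multiplier (>= 1) applied to planted DE
#'   genes in cases.
#' @param n_case,n_control Samples per group per platform (each >= 2).
#' @param noise_sd Log-scale standard deviation of multiplicative
#'   expression noise.
#' @param probes_per_gene Integer vector of admissible probe counts per
#'   gene (sampled uniformly).
#' @param shared_gene_fraction Fraction of the universe measured by both
#'   platforms (module and DE genes are always shared).
#' @param rng_seed Integer seed driving all generators.
#' @return Object of class `synthetic_scenario`; notable elements: `genes`,
#'   `module_genes`, `sources` (list `omim`, `proteomics`, `microarray`),
#'   `de_gene_ids`, plus all parameters.
#' @export
synthetic_scenario <- function(n_genes = 2000L,
                               n_module = 50L,
                               n_causative = 7L,
                               n_proteomics = 12L,
                               n_de_module = 15L,
                               n_de_background = 5L,
                               source_overlap = 0L,
                               edge_density_in = 0.6,
                               edge_density_out = 0.01,
                               weight_in = c(0.6, 1.0),
                               weight_out = c(0.1, 0.5),
                               de_effect = 2,
                               n_case = 12L,
                               n_control = 12L,
                               noise_sd = 0.25,
                               probes_per_gene = 1:3,
                               shared_gene_fraction = 0.9,
                               rng_seed = 1L) {
  if (any(c(edge_density_in, edge_density_out) < 0) ||
      any(c(edge_density_in, edge_density_out) > 1))
    stop("edge densities must lie in [0, 1]")
  if (edge_density_in <= edge_density_out)
    stop("edge_density_in must exceed edge_density_out")
  if (n_module < 2 || n_module > n_genes)
    stop("module size must satisfy 2 <= n_module <= n_genes")
  if (n_causative + n_proteomics + n_de_module > n_module)
    stop("seed source splits exceed the module size")
  if (de_effect < 1) stop("de_effect must be >= 1")
  if (n_case < 2 || n_control < 2) stop("need at least 2 samples per group")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (any(weight_in < 0) || any(weight_in > 1) ||
      any(weight_out < 0) || any(weight_out > 1))
    stop("weight ranges must lie within [0, 1]")
  if (source_overlap > min(n_proteomics, n_de_module))
    stop("source_overlap exceeds the smaller source split")
  genes <- sprintf("g%05d", seq_len(n_genes))
  sc <- withr::with_seed(rng_seed, {
    module <- sort(sample(genes, n_module), method = "radix")
    shuffled <- sample(module)
    omim <- shuffled[seq_len(n_causative)]
    proteomics <- shuffled[n_causative + seq_len(n_proteomics)]
    de_module <- shuffled[n_causative + n_proteomics + seq_len(n_de_module)]
    if (source_overlap > 0)
      proteomics <- c(proteomics[seq_len(n_proteomics - source_overlap)],
                      de_module[seq_len(source_overlap)])
    de_background <- sample(setdiff(genes, module), n_de_background)
    list(module = module, omim = sort(omim, method = "radix"),
         proteomics = sort(proteomics, method = "radix"),
         de_module = sort(de_module, method = "radix"),
         de_background = sort(de_background, method = "radix"))
  })
  structure(list(
    genes = genes, n_genes = n_genes,
    module_genes = sc$module,
    sources = list(omim = sc$omim, proteomics = sc$proteomics,
                   microarray = sc$de_module),
    de_gene_ids = sort(c(sc$de_module, sc$de_background), method = "radix"),
    edge_density_in = edge_density_in, edge_density_out = edge_density_out,
    weight_in = weight_in, weight_out = weight_out,
    de_effect = de_effect, n_case = n_case, n_control = n_control,
    noise_sd = noise_sd, probes_per_gene = probes_per_gene,
    shared_gene_fraction = shared_gene_fraction,
    rng_seed = as.integer(rng_seed)),
    class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scenario: %d genes, %d-gene module ",
                     "(%d causative / %d proteomics / %d microarray seeds), ",
                     "seed %d\n"),
              x$n_genes, length(x$module_genes), length(x$sources$omim),
              length(x$sources$proteomics), length(x$sources$microarray),
              x$rng_seed))
  invisible(x)
}

# unrank upper-triangle pair index k -> (i, j), i < j, ordered by j then i
unrank_pairs <- function(k, n) {
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  j <- j - (((j - 1) * (j - 2)) %/% 2 >= k)        # float-safety corrections
  j <- j + ((j * (j - 1)) %/% 2 < k)
  i <- k - ((j - 1) * (j - 2)) %/% 2
  cbind(i, j)
}

#' Generate the planted-module weighted network
#'
#' Module gene pairs receive edges at density `edge_density_in` with
#' weights drawn from `weight_in`; all other pairs at `edge_density_out`
#' with weights from `weight_out`.  Weights are quantized to 3 decimals so
#' the STRING-style integer-score file format round-trips exactly.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [weighted_network()] over the scenario's gene universe.
#' @export
generate_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  genes <- scenario$genes
  n <- length(genes)
  mi <- match(scenario$module_genes, genes)
  withr::with_seed(scenario$rng_seed + 1L, {
    in_pairs <- t(utils::combn(sort(mi), 2))
    keep <- stats::runif(nrow(in_pairs)) < scenario$edge_density_in
    in_pairs <- in_pairs[keep, , drop = FALSE]
    w_in <- round(stats::runif(nrow(in_pairs),
                               scenario$weight_in[1], scenario$weight_in[2]), 3)
    M <- n * (n - 1) / 2
    m_bg <- stats::rbinom(1L, M, scenario$edge_density_out)
    bg_idx <- sort(sample.int(M, m_bg))
    bg_pairs <- unrank_pairs(bg_idx, n)
    is_module <- logical(n); is_module[mi] <- TRUE
    keep_bg <- !(is_module[bg_pairs[, 1]] & is_module[bg_pairs[, 2]])
    bg_pairs <- bg_pairs[keep_bg, , drop = FALSE]
    w_out <- round(stats::runif(nrow(bg_pairs),
                                scenario$weight_out[1], scenario$weight_out[2]), 3)
    i <- c(in_pairs[, 1], bg_pairs[, 1])
    j <- c(in_pairs[, 2], bg_pairs[, 2])
    w <- c(w_in, w_out)
    nz <- w > 0
    W <- Matrix::sparseMatrix(i = c(i[nz], j[nz]), j = c(j[nz], i[nz]),
                              x = c(w[nz], w[nz]), dims = c(n, n),
                              dimnames = list(genes, genes))
    weighted_network(genes, W)
  })
}

#' An expression dataset (probe or gene level)
#'
#' @param platform_id Label for the measuring platform.
#' @param values Nonnegative numeric matrix, rows = probes or genes,
#'   columns = samples.
#' @param groups Character vector (`"case"`/`"control"`), one per sample;
#'   both groups must be present.
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(platform_id, values, groups) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("one group label per sample column is required")
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'")
  if (!all(c("case", "control") %in% groups))
    stop("both case and control samples are required")
  if (anyDuplicated(rownames(values)))
    stop("row (gene/probe) identifiers must be unique")
  if (any(values < 0)) stop("expression values must be nonnegative")
  structure(list(platform_id = platform_id, values = values, groups = groups),
            class = "expression_dataset")
}

#' Generate two-platform case-control expression data
#'
#' Emulates two microarray platforms measuring overlapping gene subsets of
#' the universe: each platform carries 1-3 probes per measured gene, values
#' are a per-gene log-normal baseline times multiplicative log-normal noise,
#' and planted DE genes have case-group means `de_effect`-fold the control
#' means before noise.  Module and planted-DE genes are always on both
#' platforms; the shared fraction of the remaining universe is
#' `shared_gene_fraction`.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `datasets` (two [expression_dataset()]s at probe
#'   level) and `probe_maps` (data frames `probe`, `gene` per platform).
#' @export
generate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  genes <- scenario$genes
  forced <- union(scenario$module_genes, scenario$de_gene_ids)
  withr::with_seed(scenario$rng_seed + 2L, {
    n_shared <- max(length(forced),
                    round(scenario$shared_gene_fraction * length(genes)))
    shared <- union(forced,
                    sample(setdiff(genes, forced), n_shared - length(forced)))
    rest <- setdiff(genes, shared)
    n_extra <- min(length(rest) %/% 2, ceiling(0.05 * length(genes)))
    extra1 <- if (n_extra > 0) sample(rest, n_extra) else character(0)
    extra2 <- if (n_extra > 0) sample(setdiff(rest, extra1), n_extra) else character(0)
    baseline <- stats::setNames(exp(stats::rnorm(length(genes), log(100), 0.5)),
                                genes)
    is_de <- genes %in% scenario$de_gene_ids
    names(is_de) <- genes
    make_platform <- function(pid, covered) {
      covered <- sort(covered, method = "radix")
      n_probes <- sample(scenario$probes_per_gene, length(covered), replace = TRUE)
      gene_of_probe <- rep(covered, n_probes)
      probe <- sprintf("%s_%s_p%d", pid, gene_of_probe,
                       unlist(lapply(n_probes, seq_len)))
      samples <- c(sprintf("%s_case%02d", pid, seq_len(scenario$n_case)),
                   sprintf("%s_ctrl%02d", pid, seq_len(scenario$n_control)))
      groups <- rep(c("case", "control"), c(scenario$n_case, scenario$n_control))
      effect <- outer(ifelse(is_de[gene_of_probe], scenario$de_effect, 1),
                      as.numeric(groups == "case"), `^`)
      noise <- if (scenario$noise_sd > 0)
        matrix(exp(stats::rnorm(length(probe) * length(samples),
                                0, scenario$noise_sd)),
               nrow = length(probe))
      else 1
      values <- baseline[gene_of_probe] * effect * noise
      dimnames(values) <- list(probe, samples)
      list(dataset = expression_dataset(pid, values, groups),
           probe_map = data.frame(probe = probe, gene = gene_of_probe,
                                  stringsAsFactors = FALSE))
    }
    p1 <- make_platform("pfA", c(shared, extra1))
    p2 <- make_platform("pfB", c(shared, extra2))
    list(datasets = list(p1$dataset, p2$dataset),
         probe_maps = list(p1$probe_map, p2$probe_map))
  })
}

#' Generate a locus table around held-out disease genes
#'
#' Places each held-out gene on its own chromosome amid
#' `genes_per_locus - 1` neighbor genes at strictly increasing coordinates,
#' so the locus candidate set of each held-out gene has the requested size.
#'
#' @param scenario A [synthetic_scenario()].
#' @param held_out_genes Genes to anchor loci on (non-empty).
#' @param genes_per_locus Genes per locus region (about 100 in typical use).
#' @return BED-like data frame `chrom`, `start`, `end`, `gene` (0-based
#'   half-open coordinates).
#' @export
generate_loci <- function(scenario, held_out_genes, genes_per_locus = 100L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  held_out_genes <- unique(as.character(held_out_genes))
  if (length(held_out_genes) == 0) stop("held_out_genes must be non-empty")
  if (!all(held_out_genes %in% scenario$genes))
    stop("held-out genes must belong to the scenario's gene universe")
  others <- setdiff(scenario$genes, held_out_genes)
  need <- length(held_out_genes) * (genes_per_locus - 1L)
  if (need > length(others))
    stop("gene universe too small to supply locus neighbors")
  withr::with_seed(scenario$rng_seed + 3L, {
    pool <- sample(others, need)
    tabs <- lapply(seq_along(held_out_genes), function(i) {
      nb <- pool[(i - 1L) * (genes_per_locus - 1L) + seq_len(genes_per_locus - 1L)]
      members <- append(nb, held_out_genes[i],
                        after = sample.int(genes_per_locus, 1L) - 1L)
      start <- seq(0L, by = 10000L, length.out = length(members))
      data.frame(chrom = sprintf("chr%d", i), start = start,
                 end = start + 1000L, gene = members,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
}

#' Generate an annotation collection with a planted enriched term
#'
#' The first term draws `planted_fraction` of its members from the planted
#' module (over-representing it by construction); all remaining terms are
#' uniform draws from the universe.  The returned manifest records the
#' planted term and the rest of the ground truth.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_terms Number of terms (>= 1).
#' @param term_size_range Uniform integer range of term sizes.
#' @param planted_fraction Fraction of the planted term's members drawn
#'   from the module.
#' @return List with `collection` (a [gene_set_collection()]) and
#'   `manifest` (class `ground_truth_manifest`: `scenario`,
#'   `held_out_disease_genes`, `enriched_term_ids`, `de_gene_ids`).
#' @export
generate_annotations <- function(scenario, n_terms = 50L,
                                 term_size_range = c(10L, 60L),
                                 planted_fraction = 0.8) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (n_terms < 1) stop("n_terms must be at least 1")
  if (max(term_size_range) > scenario$n_genes)
    stop("term sizes exceed the gene universe")
  withr::with_seed(scenario$rng_seed + 4L, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                    replace = TRUE)
    module <- scenario$module_genes
    k_mod <- min(length(module), round(planted_fraction * sizes[1]))
    planted <- c(sample(module, k_mod),
                 sample(setdiff(scenario$genes, module), sizes[1] - k_mod))
    terms <- vector("list", n_terms)
    terms[[1]] <- list(name = "synthetic process 001 (planted)",
                       genes = sort(planted, method = "radix"))
    for (t in seq_len(n_terms)[-1])
      terms[[t]] <- list(name = sprintf("synthetic process %03d", t),
                         genes = sort(sample(scenario$genes, sizes[t]),
                                      method = "radix"))
    names(terms) <- sprintf("T%04d", seq_len(n_terms))
    manifest <- structure(list(
      scenario = scenario,
      held_out_disease_genes = scenario$sources$omim,
      enriched_term_ids = names(terms)[1],
      de_gene_ids = scenario$de_gene_ids),
      class = "ground_truth_manifest")
    list(collection = gene_set_collection(terms), manifest = manifest)
  })
}

#' Generate a tissue-abundance table
#'
#' Covers a fraction of the universe with four-level abundance calls
#' (negative/weak/moderate/strong); module genes are biased toward being
#' covered and detected, emulating tissue-expressed disease modules.
#'
#' @param scenario A [synthetic_scenario()].
#' @param coverage Fraction of the universe present in the table.
#' @return Data frame `gene`, `level`.
#' @export
generate_abundance <- function(scenario, coverage = 0.75) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$rng_seed + 5L, {
    module <- scenario$module_genes
    covered_mod <- sample(module, round(0.9 * length(module)))
    n_rest <- max(0, round(coverage * scenario$n_genes) - length(covered_mod))
    covered_bg <- sample(setdiff(scenario$genes, module), n_rest)
    lv_mod <- sample(c("weak", "moderate", "strong"), length(covered_mod),
                     replace = TRUE, prob = c(0.3, 0.4, 0.3))
    lv_bg <- sample(c("negative", "weak", "moderate", "strong"),
                    length(covered_bg), replace = TRUE,
                    prob = c(0.3, 0.3, 0.25, 0.15))
    out <- data.frame(gene = c(covered_mod, covered_bg),
                      level = c(lv_mod, lv_bg), stringsAsFactors = FALSE)
    out[order(out$gene, method = "radix"), , drop = FALSE]
  })
}

#' Generate a reference gene set enriched in the planted module
#'
#' Emulates a curated reference network/gene list (innate-immune-like or
#' drug-target-like) that over-represents the planted module.
#'
#' @param scenario A [synthetic_scenario()].
#' @param module_fraction Fraction of the module included.
#' @param n_extra Background genes added.
#' @return Character vector of gene identifiers.
#' @export
generate_reference_set <- function(scenario, module_fraction = 0.8,
                                   n_extra = 150L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$rng_seed + 6L, {
    module <- scenario$module_genes
    sort(c(sample(module, round(module_fraction * length(module))),
           sample(setdiff(scenario$genes, module), n_extra)),
         method = "radix")
  })
}
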