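#' Pipeline configuration
#'
#' Collects every input path and tunable parameter of the end-to-end
#' workflow (seeds -> calibrate -> score -> subnetwork -> k-core ->
#' enrichment).  All numeric parameters are validated against their
#' documented ranges; a config round-trips unchanged through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param network Path to the STRING-style edge list.
#' @param expression List of per-dataset lists with paths `values`,
#'   `probe_map`, `groups`.
#' @param omim Path to the causative gene list (calibration holdout).
#' @param proteomics Path to the proteomics-derived gene list.
#' @param loci Path to the BED-like locus table.
#' @param gene_sets Path to the GMT annotation collection.
#' @param abundance,reference Optional paths (tissue-abundance table,
#'   reference gene set).
#' @param out_dir Output directory.
#' @param fdr_level FDR level of the DE screen (default 0.10).
#' @param fold_low,fold_high Fold-filter bounds (0.67, 1.5).
#' @param phi_grid_min,phi_grid_max,phi_grid_points Propagation-strength
#'   grid specification (see [phi_grid()]).
#' @param candidate_size Locus candidate-set size (default 100).
#' @param top_fraction Fraction of top-ranked genes selected (default 0.10).
#' @param top_denominator `"all_genes"` or `"positive_score"`.
#' @param weight_floor Subnetwork edge-weight floor (default 0.5).
#' @param cut_outer,cut_medium Core-periphery cutpoints (defaults 10, 35).
#' @param alpha Enrichment significance level (default 0.05).
#' @param rng_seed Integer seed recorded in the run log.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(network, expression, omim, proteomics, loci,
                            gene_sets, out_dir,
                            abundance = NULL, reference = NULL,
                            fdr_level = 0.10, fold_low = 0.67, fold_high = 1.5,
                            phi_grid_min = 1e-6, phi_grid_max = 1e-2,
                            phi_grid_points = 30L,
                            candidate_size = 100L,
                            top_fraction = 0.10,
                            top_denominator = "all_genes",
                            weight_floor = 0.5,
                            cut_outer = 10L, cut_medium = 35L,
                            alpha = 0.05, rng_seed = 1L) {
  if (fdr_level <= 0 || fdr_level > 1) stop("fdr_level must lie in (0, 1]")
  if (!(fold_low > 0 && fold_high > fold_low))
    stop("fold bounds must satisfy 0 < fold_low < fold_high")
  if (phi_grid_min <= 0 || phi_grid_max <= phi_grid_min || phi_grid_points < 1)
    stop("invalid phi grid specification")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  if (!top_denominator %in% c("all_genes", "positive_score"))
    stop("top_denominator must be 'all_genes' or 'positive_score'")
  if (weight_floor < 0 || weight_floor > 1)
    stop("weight_floor must lie in [0, 1]")
  if (!(cut_outer > 0 && cut_medium > cut_outer))
    stop("cutpoints must satisfy 0 < cut_outer < cut_medium")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(network = network, expression = expression, omim = omim,
                 proteomics = proteomics, loci = loci, gene_sets = gene_sets,
                 abundance = abundance, reference = reference,
                 out_dir = out_dir,
                 fdr_level = fdr_level, fold_low = fold_low,
                 fold_high = fold_high,
                 phi_grid_min = phi_grid_min, phi_grid_max = phi_grid_max,
                 phi_grid_points = as.integer(phi_grid_points),
                 candidate_size = as.integer(candidate_size),
                 top_fraction = top_fraction,
                 top_denominator = top_denominator,
                 weight_floor = weight_floor,
                 cut_outer = as.integer(cut_outer),
                 cut_medium = as.integer(cut_medium),
                 alpha = alpha, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
config_from_paths <- function(paths, out_dir, ...) {
  pipeline_config(network = paths$network, expression = paths$expression,
                  omim = paths$omim, proteomics = paths$proteomics,
                  loci = paths$loci, gene_sets = paths$gene_sets,
                  abundance = paths$abundance, reference = paths$reference,
                  out_dir = out_dir, ...)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full prioritization workflow
#'
#' Executes, in order: expression harmonization and the DE screen; seed
#' assembly from the three sources; calibration of the propagation
#' strength on the held-out causative genes; scoring of all network genes
#' with the causative genes added to the seeds; top-fraction selection;
#' subnetwork extraction; k-core decomposition and core-periphery
#' partition; annotation enrichment; and, when inputs are provided,
#' tissue-abundance composition and reference-set overlap.  Every stage's
#' output is written under `config$out_dir` together with a run log
#' recording the package version and all parameters.  Reruns with the same
#' config produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `results` (phi_star, calibration table,
#'   seed collection, selected genes, subnetwork summary, enrichment
#'   table, ...) and `paths` to every output file.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(config$network, config$omim, config$proteomics, config$loci,
              config$gene_sets, config$abundance, config$reference,
              unlist(config$expression))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    stop(sprintf("pre-flight validation failed; missing input files: %s",
                 paste(missing, collapse = ", ")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  set.seed(config$rng_seed)

  datasets <- run_stage("expression", {
    ds <- lapply(config$expression, function(e)
      expression_dataset(basename(e$values),
                         read_expression_matrix(e$values),
                         read_tsv_table(e$groups, c("sample", "group"))$group))
    pm <- lapply(config$expression, function(e)
      read_tsv_table(e$probe_map, c("probe", "gene")))
    harmonize_platforms(ds, pm)
  })
  de_genes <- run_stage("de_screen", {
    sel <- select_de_genes(datasets, fdr_level = config$fdr_level,
                           low = config$fold_low, high = config$fold_high)
    tbs <- attr(sel, "tables")
    for (i in seq_along(tbs))
      write_tsv_table(tbs[[i]], out(sprintf("de_dataset%d.tsv", i)))
    sel
  })
  seeds <- run_stage("seeds", {
    sc <- assemble_seeds(read_gene_list(config$omim),
                         read_gene_list(config$proteomics), de_genes)
    write_tsv_table(data.frame(
      gene = c(sc$omim, sc$proteomics, sc$microarray),
      source = rep(c("omim", "proteomics", "microarray"),
                   c(length(sc$omim), length(sc$proteomics),
                     length(sc$microarray))),
      stringsAsFactors = FALSE), out("seeds.tsv"))
    sc
  })
  network <- run_stage("network", read_weighted_network(config$network))
  loci <- run_stage("loci", read_loci(config$loci))
  calib <- run_stage("calibrate", {
    base_seeds <- setdiff(union(seeds$proteomics, seeds$microarray),
                          seeds$omim)
    cal <- calibrate_phi(network, base_seeds, seeds$omim, loci,
                         grid = phi_grid(config$phi_grid_min,
                                         config$phi_grid_max,
                                         config$phi_grid_points),
                         N = config$candidate_size)
    write_tsv_table(cal$table, out("calibration.tsv"))
    cal
  })
  score <- run_stage("score", {
    x <- build_activity_vector(network, seed_union(seeds))
    sc <- katz_score_direct(network, x, calib$phi_star)
    write_tsv_table(data.frame(gene = sc$genes, s = as.numeric(sc$s),
                               rank = as.integer(sc$ranks),
                               stringsAsFactors = FALSE), out("scores.tsv"))
    sc
  })
  selected <- run_stage("select", {
    sel <- select_top_fraction(score, q = config$top_fraction,
                               denominator = config$top_denominator)
    write_gene_list(sel, out("selected.txt"))
    sel
  })
  sub <- run_stage("subnetwork", {
    s <- suppressWarnings(extract_subnetwork(network, selected,
                                             weight_floor = config$weight_floor))
    write_tsv_table(s$edges, out("subnet_edges.tsv"))
    s
  })
  topo <- run_stage("kcore", {
    dec <- k_core_decompose(sub)
    part <- partition_core_periphery(dec, config$cut_outer, config$cut_medium)
    tags <- list(seed = seed_union(seeds))
    reference <- NULL
    if (!is.null(config$reference)) {
      reference <- read_gene_list(config$reference)
      tags$reference <- reference
    }
    write_tsv_table(layer_composition(dec, tags), out("layer_composition.tsv"))
    part_of <- function(g)
      ifelse(g %in% part$inner, "inner",
             ifelse(g %in% part$medium, "medium", "outer"))
    attrs <- data.frame(gene = sub$nodes,
                        core_number = as.integer(dec$core_number[sub$nodes]),
                        partition = part_of(sub$nodes),
                        is_seed = sub$nodes %in% seed_union(seeds),
                        stringsAsFactors = FALSE)
    if (!is.null(reference)) attrs$in_reference <- sub$nodes %in% reference
    write_tsv_table(attrs, out("node_attributes.tsv"))
    write_subnetwork_graphml(sub, out("subnetwork.graphml"), attrs)
    list(decomposition = dec, partition = part, reference = reference,
         node_attributes = attrs)
  })
  enrichment <- run_stage("enrich", {
    tab <- suppressWarnings(
      enrich(selected, read_gmt(config$gene_sets), network$genes,
             alpha = config$alpha))
    write_tsv_table(tab, out("enrichment.tsv"))
    tab
  })
  abundance <- overlap <- NULL
  if (!is.null(config$abundance)) {
    abundance <- run_stage("abundance", {
      ab <- abundance_distribution(sub, read_tsv_table(config$abundance,
                                                       c("gene", "level")))
      write_tsv_table(data.frame(level = names(ab$counts),
                                 count = as.integer(ab$counts),
                                 stringsAsFactors = FALSE),
                      out("abundance.tsv"))
      ab
    })
  }
  if (!is.null(config$reference)) {
    overlap <- run_stage("overlap", {
      ov <- overlap_subnetwork(sub, topo$reference,
                               inner_core = topo$partition$inner,
                               seeds = seed_union(seeds))
      write_tsv_table(ov$tests, out("overlap_tests.tsv"))
      ov
    })
  }
  run_stage("run_log", {
    yaml::write_yaml(list(
      package = "katznet",
      version = as.character(utils::packageVersion("katznet")),
      rng_seed = config$rng_seed,
      parameters = unclass(config)[c("fdr_level", "fold_low", "fold_high",
                                     "phi_grid_min", "phi_grid_max",
                                     "phi_grid_points", "candidate_size",
                                     "top_fraction", "top_denominator",
                                     "weight_floor", "cut_outer", "cut_medium",
                                     "alpha")],
      phi_star = calib$phi_star,
      mean_r_ratio = min(calib$mean_r_ratio),
      n_seeds = length(seed_union(seeds)),
      n_selected = length(selected),
      subnetwork = list(nodes = length(sub$nodes), edges = nrow(sub$edges),
                        kmax = topo$decomposition$kmax)),
      out("run_log.yaml"))
  })
  invisible(list(
    results = list(seeds = seeds, calibration = calib,
                   phi_star = calib$phi_star, score = score,
                   selected = selected, subnetwork = sub, topology = topo,
                   enrichment = enrichment, abundance = abundance,
                   overlap = overlap),
    paths = stats::setNames(
      file.path(config$out_dir,
                c("seeds.tsv", "calibration.tsv", "scores.tsv", "selected.txt",
                  "subnet_edges.tsv", "layer_composition.tsv",
                  "node_attributes.tsv", "subnetwork.graphml",
                  "enrichment.tsv", "run_log.yaml")),
      c("seeds", "calibration", "scores", "selected", "subnet_edges",
        "layer_composition", "node_attributes", "graphml", "enrichment",
        "run_log"))))
}
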