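#' Read a STRING-style weighted edge list
#'
#' Three tab-separated columns per line: gene1, gene2, score.  Integer
#' scores (STRING convention, 0-1000) are divided by `score_scale`;
#' already-normalized real scores are taken as-is.  Duplicate undirected
#' edges are collapsed keeping the maximum weight and self-loops are
#' dropped.
#'
#' @param path Input file path (no header line).
#' @param score_scale Divisor applied to integer-scaled scores.
#' @return A [weighted_network()].
#' @export
read_weighted_network <- function(path, score_scale = 1000) {
  if (!file.exists(path)) stop(sprintf("network file '%s' does not exist", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("network file '%s' is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3))
    stop(sprintf("malformed network row at line %d: expected 3 tab-separated fields",
                 which(nf != 3)[1]))
  g1 <- vapply(fields, `[[`, character(1), 1L)
  g2 <- vapply(fields, `[[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(score))
    stop(sprintf("malformed score at line %d", which(is.na(score))[1]))
  integer_scaled <- all(score == round(score)) && any(score > 1)
  w <- if (integer_scaled) score / score_scale else score
  if (any(w < 0 | w > 1))
    stop("scores do not normalize into [0, 1]")
  weighted_network_from_edges(
    data.frame(gene1 = g1, gene2 = g2, weight = w, stringsAsFactors = FALSE))
}

#' Write a network as a STRING-style integer-score edge list
#'
#' @param network A [weighted_network()].
#' @param path Output path.
#' @param score_scale Multiplier mapping \[0, 1\] weights to integer scores.
#' @return The path, invisibly.
#' @export
write_weighted_network <- function(network, path, score_scale = 1000) {
  e <- network_edges(network)
  writeLines(sprintf("%s\t%s\t%d", e$gene1, e$gene2,
                     as.integer(round(e$weight * score_scale))), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: term id, term name, member genes.  Trailing empty
#' fields are ignored; duplicate term ids and memberless terms are errors.
#'
#' @param path Input path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, function(f) if (length(f) >= 1) f[[1]] else "", character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate term id '%s' in GMT file", ids[duplicated(ids)][1]))
  terms <- lapply(fields, function(f) {
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    list(name = f[[2]], genes = genes)
  })
  names(terms) <- ids
  gene_set_collection(terms)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  writeLines(vapply(names(collection), function(id)
    paste(c(id, collection[[id]]$name, collection[[id]]$genes), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Read an expression matrix (rows x samples TSV)
#'
#' @param path TSV with a header of sample names and row identifiers in
#'   the first column.
#' @return Numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write an expression matrix
#' @param values Numeric matrix with row and column names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(values, path) {
  df <- data.frame(id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write two-column TSV tables (probe maps, group labels, abundance)
#'
#' @param path File path.
#' @param col_names Expected column names (checked on read).
#' @return Data frame with the requested columns.
#' @export
read_tsv_table <- function(path, col_names = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_names) && !all(col_names %in% names(df)))
    stop(sprintf("file '%s' lacks required columns: %s", path,
                 paste(setdiff(col_names, names(df)), collapse = ", ")))
  df
}

#' @rdname read_tsv_table
#' @param df Data frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like locus table
#'
#' Headerless tab-separated columns: chrom, start, end, gene (0-based
#' half-open coordinates).
#'
#' @param path Input path.
#' @return Data frame `chrom`, `start`, `end`, `gene`.
#' @export
read_loci <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "gene"),
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          stringsAsFactors = FALSE)
  df
}

#' @rdname read_loci
#' @param loci Locus data frame to write.
#' @export
write_loci <- function(loci, path) {
  utils::write.table(loci[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write plain gene lists (one identifier per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write every synthetic input the pipeline consumes
#'
#' Runs all generators on a scenario and writes their outputs into a
#' directory: STRING-style network, two platforms of probe-level
#' expression + probe maps + group labels, causative and proteomics gene
#' lists, locus table, GMT annotation collection, abundance table,
#' reference gene set, and a ground-truth manifest (YAML).
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the ground-truth `manifest`, generated
#'   objects, and `paths` to every written file.
#' @export
simulate_inputs <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  network <- generate_network(scenario)
  expr <- generate_expression(scenario)
  loci <- generate_loci(scenario, scenario$sources$omim)
  ann <- generate_annotations(scenario)
  abundance <- generate_abundance(scenario)
  reference <- generate_reference_set(scenario)
  write_weighted_network(network, p("network.tsv"))
  for (i in seq_along(expr$datasets)) {
    d <- expr$datasets[[i]]
    write_expression_matrix(d$values, p(sprintf("expr%d.tsv", i)))
    write_tsv_table(expr$probe_maps[[i]], p(sprintf("probes%d.tsv", i)))
    write_tsv_table(data.frame(sample = colnames(d$values), group = d$groups,
                               stringsAsFactors = FALSE),
                    p(sprintf("groups%d.tsv", i)))
  }
  write_gene_list(scenario$sources$omim, p("omim.txt"))
  write_gene_list(scenario$sources$proteomics, p("proteomics.txt"))
  write_loci(loci, p("loci.bed"))
  write_gmt(ann$collection, p("annotations.gmt"))
  write_tsv_table(abundance, p("abundance.tsv"))
  write_gene_list(reference, p("reference.txt"))
  manifest <- ann$manifest
  yaml::write_yaml(list(
    rng_seed = scenario$rng_seed,
    n_genes = scenario$n_genes,
    module_genes = manifest$scenario$module_genes,
    held_out_disease_genes = manifest$held_out_disease_genes,
    enriched_term_ids = manifest$enriched_term_ids,
    de_gene_ids = manifest$de_gene_ids),
    p("ground_truth.yaml"))
  paths <- list(
    network = p("network.tsv"),
    expression = lapply(seq_along(expr$datasets), function(i)
      list(values = p(sprintf("expr%d.tsv", i)),
           probe_map = p(sprintf("probes%d.tsv", i)),
           groups = p(sprintf("groups%d.tsv", i)))),
    omim = p("omim.txt"), proteomics = p("proteomics.txt"),
    loci = p("loci.bed"), gene_sets = p("annotations.gmt"),
    abundance = p("abundance.tsv"), reference = p("reference.txt"),
    ground_truth = p("ground_truth.yaml"))
  invisible(list(manifest = manifest, network = network, expression = expr,
                 loci = loci, annotations = ann$collection,
                 abundance = abundance, reference = reference, paths = paths))
}
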