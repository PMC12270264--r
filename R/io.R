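#' Read an expression matrix from TSV
#'
#' Expected layout: header row of sample identifiers, first column gene
#' identifiers, tab-separated numeric values.
#'
#' @param path File path.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus samples")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#' @param values Genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(values, path) {
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-phenotype table
#'
#' Two-column TSV (with header): sample identifier, phenotype label.
#'
#' @param path File path.
#' @return Named character vector (names = sample identifiers).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs sample and label columns")
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a sample-to-phenotype table
#' @param phenotype Named character vector (names = sample identifiers).
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotype, path) {
  write.table(data.frame(sample = names(phenotype),
                         phenotype = as.character(phenotype)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member identifiers,
#' tab-separated. Duplicate members within a line are collapsed; a line with
#' fewer than two fields, or a set without members, is a parse error.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(), provenance = path))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop(sprintf("malformed GMT line %d: fewer than 2 tab-separated fields",
                   i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("malformed GMT line %d: set '%s' has no members", i, f[1L]))
    if (f[1L] %in% names(sets))
      stop(sprintf("duplicate set name '%s' at GMT line %d", f[1L], i))
    sets[[f[1L]]] <- members
  }
  gene_set_collection(sets, provenance = path)
}

#' Write gene sets in GMT format
#' @param gene_sets A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  stopifnot(inherits(gene_sets, "gbnea_gene_sets"))
  lines <- vapply(names(gene_sets$sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, gene_sets$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed network from an edge-list TSV
#'
#' Columns `regulator`, `target`, `weight` (a `phenotype` column, written by
#' [write_network_edgelist()], is honored when present). Zero weights,
#' self-edges and duplicate (regulator, target) pairs are parse errors with
#' the offending row number.
#'
#' @param path File path.
#' @param gene_ids Optional gene universe declaring isolated genes; defaults
#'   to the genes appearing in edges.
#' @return A [directed_network()].
#' @export
read_network_edgelist <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("regulator", "target", "weight")
  if (!all(req %in% names(df)))
    stop("edge list must have columns regulator, target, weight")
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- which(!is.finite(w))
  if (length(bad)) stop("non-numeric or non-finite weight at row ", bad[1L])
  bad <- which(w == 0)
  if (length(bad)) stop("zero weight at row ", bad[1L])
  bad <- which(df$regulator == df$target)
  if (length(bad)) stop("self-edge at row ", bad[1L])
  key <- paste0(df$regulator, "\r", df$target)
  bad <- which(duplicated(key))
  if (length(bad)) stop("duplicate (regulator, target) pair at row ", bad[1L])
  if (is.null(gene_ids))
    gene_ids <- sort(unique(c(df$regulator, df$target)), method = "radix")
  label <- if ("phenotype" %in% names(df) &&
               length(unique(df$phenotype)) == 1L)
    unique(df$phenotype) else NA_character_
  directed_network(data.frame(regulator = df$regulator, target = df$target,
                              weight = w, stringsAsFactors = FALSE),
                   gene_ids, phenotype_label = label)
}

#' Write a directed network as an edge-list TSV
#'
#' Edges are written in canonical order (regulator, then target,
#' lexicographic) so that repeated writes diff cleanly; reading the file back
#' recovers the network losslessly.
#'
#' @param network A `"gbnea_network"`.
#' @param path Output path.
#' @export
write_network_edgelist <- function(network, path) {
  ed <- network_edges(network)
  label <- if (is.na(network$phenotype_label)) "NA"
    else network$phenotype_label
  ed$phenotype <- rep(label, nrow(ed))
  out <- data.frame(regulator = ed$regulator, target = ed$target,
                    weight = sprintf("%.17g", ed$weight),
                    phenotype = ed$phenotype, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write behavior scores to TSV
#' @param scores A [behavior_scores()] table.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an enrichment results table to TSV
#' @param results The `$results` data frame of a [gbnea()] fit.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Reads the expression matrix, phenotype table and GMT file named in the
#' configuration, runs [gbnea()], and writes the estimated networks, behavior
#' scores, per-pathway running sums and the results table into `output_dir`.
#'
#' @param config Either a named list or a path to a YAML/JSON file with
#'   fields: `expression_path`, `phenotype_path`, `gmt_path`, `labels`
#'   (length 2), and optionally `stat_name`, `k`, `delta`, `lambda_grid`,
#'   `standardize`, `n_perm`, `alpha`, `seed`, `n_workers`, `output_dir`.
#' @return The fitted [gbnea()] object, invisibly; side effect: files under
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  req <- c("expression_path", "phenotype_path", "gmt_path", "labels")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("missing configuration field(s): ", paste(miss, collapse = ", "))
  labels <- as.character(config$labels)
  if (length(labels) != 2L || labels[1L] == labels[2L])
    stop("labels must be two distinct phenotype levels")
  for (f in c("expression_path", "phenotype_path", "gmt_path"))
    if (!file.exists(config[[f]])) stop("file not found: ", config[[f]])

  grab <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  values <- read_expression(config$expression_path)
  phen <- read_phenotypes(config$phenotype_path)
  miss <- setdiff(colnames(values), names(phen))
  if (length(miss))
    stop("samples without phenotype label: ", paste(head(miss, 5),
                                                    collapse = ", "))
  data <- expression_dataset(values, phen[colnames(values)])
  gene_sets <- read_gmt(config$gmt_path)

  reg <- regression_config(
    delta = grab("delta", 1),
    lambda_grid = grab("lambda_grid", "auto"),
    standardize = grab("standardize", TRUE))
  out_dir <- grab("output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- grab("seed", NULL)

  fit <- gbnea(data, gene_sets, labels = labels,
               stat = grab("stat_name", "Wd1"), k = grab("k", 0),
               n_perm = grab("n_perm", 200L), alpha = grab("alpha", 0.05),
               regression = reg, seed = seed,
               n_workers = grab("n_workers", 1L))

  write_network_edgelist(fit$networks$C,
                         file.path(out_dir, "network_C.tsv"))
  write_network_edgelist(fit$networks$N,
                         file.path(out_dir, "network_N.tsv"))
  write_scores(fit$scores, file.path(out_dir, "behavior_scores.tsv"))
  write_results(fit$results, file.path(out_dir, "enrichment_results.tsv"))
  rs <- do.call(rbind, lapply(names(fit$running_sums), function(nm) {
    data.frame(pathway = nm, position = seq_along(fit$running_sums[[nm]]),
               running_sum = fit$running_sums[[nm]])
  }))
  write.table(rs, file.path(out_dir, "running_sums.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_lines <- c(
    paste0("gbnea version: ", as.character(utils::packageVersion("gbnea"))),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("labels: ", paste(labels, collapse = ",")),
    paste0("stat: ", fit$params$stat, "  k: ", fit$params$k,
           "  n_perm: ", fit$params$n_perm, "  alpha: ", fit$params$alpha,
           "  delta: ", reg$delta))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(fit)
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the jsonlite package")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  }
}
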