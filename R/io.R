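# Readers and writers for the plain-text formats the pipeline touches.
# All matrix writers print 17 significant digits so write -> read round-trips
# to better than 1e-12.

.fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a gene x sample expression matrix as TSV
#'
#' Header row holds the sample ids; the first column (`gene_id`) the gene
#' ids. Values round-trip to full double precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @return `read_expression` returns the matrix; `write_expression` its path,
#'   invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m), .fmt(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("line 1: expected first column 'gene_id'", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- df$gene_id
  m
}

#' Read a probe-to-gene map from a two-column TSV
#'
#' Columns: probe id, gene id (header optional, detected by the literal
#' header `probe`).
#'
#' @param path file path.
#' @return Named character vector, probe -> gene.
#' @export
read_probe_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != 2)
    stop("probe map must have exactly 2 columns (probe, gene)",
         call. = FALSE)
  if (df[1, 1] == "probe") df <- df[-1, , drop = FALSE]
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a per-sample trait table from CSV
#'
#' Expects at least `sample_id` (or `animal`) plus trait/covariate columns.
#'
#' @param path file path.
#' @return data.frame as stored; `group` becomes a factor with the low level
#'   first when its values are exactly low/high.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!any(c("sample_id", "animal") %in% names(df)))
    stop("trait table needs a 'sample_id' or 'animal' column", call. = FALSE)
  if ("group" %in% names(df) && setequal(unique(df$group), c("low", "high")))
    df$group <- factor(df$group, levels = c("low", "high"))
  df
}

#' Write the weighted edge list of an adjacency matrix
#'
#' One row per unordered gene pair with `a_ij >= cutoff` (i < j):
#' `gene_a`, `gene_b`, `weight`.
#'
#' @param adj adjacency matrix.
#' @param path file path.
#' @param cutoff minimum weight written (limits file size).
#' @return Number of edges written, invisibly.
#' @export
write_edgelist <- function(adj, path, cutoff = 0) {
  .check_square_symmetric(adj, "adj")
  ids <- .gene_ids(adj)
  ut <- upper.tri(adj)
  keep <- ut & unclass(adj) >= cutoff
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                   weight = .fmt(unclass(adj)[keep]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(df))
}

#' Write a square matrix (adjacency, TOM) as TSV
#'
#' @param m square matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m))) dimnames(m) <- list(.gene_ids(m), .gene_ids(m))
  write_expression(unclass(m), path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) read_expression(path)

#' Export a network to GraphML for visualization
#'
#' Nodes carry the module color and any topology-profile columns supplied;
#' edges carry the adjacency weight. Only edges with weight >= `cutoff` are
#' exported.
#'
#' @param adj adjacency matrix.
#' @param path output file.
#' @param colors optional named module-color vector over the genes.
#' @param profiles optional data.frame from [node_topology()].
#' @param cutoff minimum edge weight exported.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(adj, path, colors = NULL, profiles = NULL,
                          cutoff = 0) {
  .check_square_symmetric(adj, "adj")
  A <- unclass(adj)
  attr(A, "mode_type") <- NULL; attr(A, "tau") <- NULL; attr(A, "beta") <- NULL
  if (is.null(rownames(A))) dimnames(A) <- list(.gene_ids(A), .gene_ids(A))
  A[A < cutoff] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  if (!is.null(colors))
    igraph::V(g)$module <- unname(colors[igraph::V(g)$name])
  if (!is.null(profiles)) {
    idx <- match(igraph::V(g)$name, profiles$gene_id)
    for (col in setdiff(names(profiles), "gene_id"))
      g <- igraph::set_vertex_attr(g, col, value = profiles[[col]][idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
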