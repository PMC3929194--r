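# Size-ranked module color order: the largest module is always "turquoise".
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue", "darkred",
                   "darkgreen", "darkturquoise", "darkgrey", "orange",
                   "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

#' Average-linkage hierarchical clustering of a TOM dissimilarity
#'
#' UPGMA merge tree over genes using `d_ij = 1 - omega_ij` as the distance.
#'
#' @param d a `tom` object from [topological_overlap()], or a square symmetric
#'   dissimilarity matrix with zero diagonal.
#' @return An [stats::hclust] tree (method "average").
#' @export
hierarchical_cluster <- function(d) {
  if (inherits(d, "tom")) d <- d$dissim
  .check_square_symmetric(d, "d")
  if (any(diag(d) != 0))
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  if (is.null(rownames(d)))
    dimnames(d) <- list(.gene_ids(d), .gene_ids(d))
  hclust(as.dist(d), method = "average")
}

#' Cut a dendrogram into colored gene modules
#'
#' Cuts the merge tree at `height_cutoff`; every resulting branch with at
#' least `min_module_size` genes becomes a module, smaller branches are
#' assigned "grey" (unclustered). Modules are colored in the canonical
#' size-ranked order (turquoise, blue, brown, yellow, green, red, black, ...),
#' ties in size broken by the smallest member gene id, so the largest module
#' is always turquoise.
#'
#' @param dend an [stats::hclust] tree from [hierarchical_cluster()].
#' @param height_cutoff cut height in (0, 1]; the study's default is 0.99.
#' @param min_module_size smallest branch kept as a module.
#' @return An object of class `module_assignment`: list with `colors` (named
#'   character vector, one color per gene), `dendrogram`, `height_cutoff`,
#'   `min_module_size`.
#' @export
cut_modules <- function(dend, height_cutoff = 0.99, min_module_size = 20) {
  if (!inherits(dend, "hclust"))
    stop("dend must be an hclust tree", call. = FALSE)
  if (!is.numeric(height_cutoff) || height_cutoff <= 0 || height_cutoff > 1)
    stop("height_cutoff must lie in (0, 1]", call. = FALSE)
  branch <- cutree(dend, h = height_cutoff)
  genes <- names(branch)
  sizes <- table(branch)
  keep <- names(sizes)[sizes >= min_module_size]
  colors <- setNames(rep("grey", length(genes)), genes)
  if (length(keep) > 0) {
    min_member <- vapply(keep, function(b) min(genes[branch == b]), "")
    ord <- keep[order(-as.integer(sizes[keep]), min_member)]
    if (length(ord) > length(MODULE_COLORS))
      ord_colors <- c(MODULE_COLORS,
                      sprintf("module%03d",
                              seq_len(length(ord) - length(MODULE_COLORS))))
    else ord_colors <- MODULE_COLORS
    for (i in seq_along(ord))
      colors[branch == as.integer(ord[i])] <- ord_colors[i]
  }
  structure(list(colors = colors, dendrogram = dend,
                 height_cutoff = height_cutoff,
                 min_module_size = min_module_size),
            class = "module_assignment")
}

#' Per-module sizes, connectivity and intramodular connectivity
#'
#' For each non-grey module: its size, the mean whole-network connectivity
#' `k_i` of its members, and each member's intramodular connectivity (sum of
#' adjacency to same-module genes). Grey genes appear in the size ledger but
#' get no connectivity summary. Also reports the network-level effective mean
#' degree: the average `k` over non-isolated nodes.
#'
#' @param assign a `module_assignment`.
#' @param adj adjacency matrix over the same genes.
#' @return A list of class `module_summary`: `table` (data.frame color, size,
#'   mean_connectivity), `intramodular` (named vector per gene, NA for grey),
#'   `effective_mean_degree`.
#' @export
module_summaries <- function(assign, adj) {
  if (!inherits(assign, "module_assignment"))
    stop("assign must come from cut_modules()", call. = FALSE)
  .check_square_symmetric(adj, "adj")
  genes <- names(assign$colors)
  if (is.null(rownames(adj))) {
    if (nrow(adj) != length(genes))
      stop("adjacency and assignment cover different gene sets",
           call. = FALSE)
    dimnames(adj) <- list(genes, genes)
  }
  if (!setequal(rownames(adj), genes))
    stop("adjacency and assignment cover different gene sets", call. = FALSE)
  A <- unclass(adj)[genes, genes]
  k <- rowSums(A)
  colors <- assign$colors
  mods <- unique(colors[colors != "grey"])
  # order rows by decreasing size to match the coloring convention
  sz <- vapply(mods, function(m) sum(colors == m), 0L)
  mods <- mods[order(-sz)]
  tab <- data.frame(
    color = c(mods, if (any(colors == "grey")) "grey"),
    size = c(sz[order(-sz)], if (any(colors == "grey")) sum(colors == "grey")),
    mean_connectivity = c(
      vapply(mods, function(m) mean(k[colors == m]), 0),
      if (any(colors == "grey")) NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  intra <- setNames(rep(NA_real_, length(genes)), genes)
  for (m in mods) {
    idx <- which(colors == m)
    intra[idx] <- rowSums(A[idx, idx, drop = FALSE])
  }
  structure(list(table = tab, intramodular = intra,
                 effective_mean_degree =
                   if (any(k > 0)) mean(k[k > 0]) else 0),
            class = "module_summary")
}
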