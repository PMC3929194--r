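#' Read gene sets from a GMT file
#'
#' One set per tab-separated line: set id, description, then member genes.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (the members), with a
#'   `descriptions` attribute. Duplicate set ids are an error.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1],
         ": need id, description and at least one member", call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate gene-set id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2), ids)
  sets
}

#' Fisher's exact over-representation test of a gene module
#'
#' For each gene set, the one-sided (over-representation) Fisher's exact
#' p-value of the 2x2 table (in-module & in-set, in-module & not, out-module &
#' in-set, out & not) over the gene universe — equivalently the
#' hypergeometric tail `P(X >= overlap)`. P-values are adjusted across sets
#' (Benjamini-Hochberg by default) and results are sorted by p-value.
#'
#' Set members outside the universe are dropped before testing; sets left
#' empty are discarded. Module genes outside the universe are an error.
#' `method = "ease"` applies the conservative EASE variant (overlap reduced
#' by one before taking the tail).
#'
#' @param module_genes character vector of module member gene ids.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all analyzable genes (typically every
#'   gene in the network).
#' @param method `"fisher"` (default) or `"ease"`.
#' @param p_adjust multiple-testing method for [stats::p.adjust()].
#' @return data.frame with columns `set_id`, `overlap_count`, `module_size`,
#'   `set_size`, `universe_size`, `p_value`, `adjusted_p`, sorted by
#'   `p_value`.
#' @export
fisher_enrichment <- function(module_genes, sets, universe,
                              method = c("fisher", "ease"),
                              p_adjust = "BH") {
  method <- match.arg(method)
  module_genes <- unique(module_genes)
  universe <- unique(universe)
  outside <- setdiff(module_genes, universe)
  if (length(outside) > 0)
    stop("module gene(s) outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0)
    stop("no gene set overlaps the universe", call. = FALSE)
  U <- length(universe)
  M <- length(module_genes)
  res <- lapply(names(sets), function(id) {
    S <- length(sets[[id]])
    ov <- length(intersect(module_genes, sets[[id]]))
    q <- if (method == "ease") ov - 1 else ov
    # P(X >= q) for X ~ Hypergeom(set in universe, draws = module size)
    p <- phyper(q - 1, S, U - S, M, lower.tail = FALSE)
    data.frame(set_id = id, overlap_count = ov, module_size = M,
               set_size = S, universe_size = U, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- p.adjust(out$p_value, method = p_adjust)
  out <- out[order(out$p_value, out$set_id), ]
  rownames(out) <- NULL
  out
}
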