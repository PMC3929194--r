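#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same distribution: the mean of
#' the sorted columns. Ties within a column receive the mean of the reference
#' values at their rank positions. Delegates to
#' [limma::normalizeQuantiles()], the standard microarray implementation of
#' exactly this convention.
#'
#' @param m numeric genes x samples matrix, all values finite, >= 2 columns.
#' @return A matrix of the same shape and dimnames. Idempotent: applying it
#'   twice equals applying it once (to floating tolerance).
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("m must be a numeric matrix", call. = FALSE)
  if (ncol(m) < 2)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(m)))
    stop("m contains non-finite values; missing data are not supported",
         call. = FALSE)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probe-level rows to one row per gene
#'
#' Groups rows by their mapped gene and replaces each retained gene by the
#' arithmetic mean of its probe rows. Genes represented by fewer than
#' `min_probes` probes are dropped (the pipeline default keeps genes measured
#' by at least two probes).
#'
#' @param m numeric probes x samples matrix with probe ids as rownames.
#' @param probe_map named character vector: names are probe ids, values the
#'   gene each probe measures. Probes absent from the map are dropped.
#' @param min_probes minimum probes a gene needs to be retained.
#' @return A genes x samples matrix, rows ordered by gene id; every row is a
#'   convex combination (the mean) of input rows.
#' @export
collapse_probes <- function(m, probe_map, min_probes = 2) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("m must be a numeric matrix", call. = FALSE)
  if (missing(probe_map) || is.null(probe_map))
    stop("probe_map is required to collapse probes", call. = FALSE)
  if (is.null(names(probe_map)))
    stop("probe_map must be a named vector (probe -> gene)", call. = FALSE)
  if (is.null(rownames(m)))
    stop("m must have probe ids as rownames", call. = FALSE)
  if (min_probes < 1)
    stop("min_probes must be at least 1", call. = FALSE)
  keep <- rownames(m) %in% names(probe_map)
  m <- m[keep, , drop = FALSE]
  gene <- unname(probe_map[rownames(m)])
  counts <- table(gene)
  retained <- sort(names(counts)[counts >= min_probes])
  if (length(retained) == 0)
    return(matrix(numeric(0), 0, ncol(m),
                  dimnames = list(character(0), colnames(m))))
  sums <- rowsum(m[gene %in% retained, , drop = FALSE],
                 group = gene[gene %in% retained])
  out <- sums / as.vector(counts[rownames(sums)])
  out[retained, , drop = FALSE]
}
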