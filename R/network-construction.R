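#' Pairwise Pearson correlation of gene expression profiles
#'
#' @param m numeric genes x samples matrix (log2 expression), >= 3 samples.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#'   A gene with zero variance across samples is an error (its correlation is
#'   undefined), reported by name.
#' @export
correlation_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("m must be a numeric matrix", call. = FALSE)
  if (ncol(m) < 3)
    stop("correlation needs at least 3 samples", call. = FALSE)
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(.gene_ids(m)[v == 0], collapse = ", "), call. = FALSE)
  r <- cor(t(m))
  r <- (r + t(r)) / 2           # force exact symmetry
  diag(r) <- 1
  dimnames(r) <- list(.gene_ids(m), .gene_ids(m))
  r
}

.new_adjacency <- function(a, mode, tau = NULL, beta = NULL) {
  diag(a) <- 0
  structure(a, mode_type = mode, tau = tau, beta = beta,
            class = c("adjacency", "matrix", "array"))
}

#' Hard-threshold (unweighted) adjacency
#'
#' Dichotomizes the correlation matrix: genes i and j are connected
#' (`a_ij = 1`) when `|r_ij| >= tau`. The boundary is inclusive; the diagonal
#' is zero (no self-connections).
#'
#' @param r correlation matrix as from [correlation_matrix()].
#' @param tau threshold in (0, 1]; the study's default is 0.7.
#' @return Binary adjacency matrix of class `adjacency` with attributes
#'   `mode_type = "hard"` and `tau`.
#' @export
hard_adjacency <- function(r, tau = 0.7) {
  .check_square_symmetric(r, "r")
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1)
    stop("tau must lie in (0, 1]", call. = FALSE)
  a <- (abs(r) >= tau) * 1
  .new_adjacency(a, "hard", tau = tau)
}

#' Soft-threshold (weighted) power adjacency
#'
#' The power adjacency function `a_ij = |r_ij|^beta`, a continuous connection
#' strength in \[0, 1\]. Monotone in `|r|`; the diagonal is zero.
#'
#' @param r correlation matrix.
#' @param beta positive soft-thresholding power; the study's default is 7.
#' @return Weighted adjacency matrix of class `adjacency` with attributes
#'   `mode_type = "soft"` and `beta`.
#' @export
soft_adjacency <- function(r, beta = 7) {
  .check_square_symmetric(r, "r")
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("beta must be positive", call. = FALSE)
  a <- abs(r)^beta
  .new_adjacency(a, "soft", beta = beta)
}

#' Topological overlap matrix (TOM) and its dissimilarity
#'
#' For adjacency `a` with connectivity `k_i = sum_u a_iu` and shared-neighbor
#' strength `l_ij = sum_u a_iu a_uj`, the topological overlap is
#' \deqn{\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' for `i != j`, with `omega_ii = 1`. Two genes overlap strongly when they are
#' directly connected and share neighbors. The clustering dissimilarity is
#' `d = 1 - omega`. For binary adjacency, `l_ij` is the number of shared
#' neighbors. Isolated node pairs (k = 0, a = 0) get `omega = 0`.
#'
#' @param adj adjacency matrix (entries in \[0, 1\], zero diagonal).
#' @return A list of class `tom` with elements `omega` and `dissim`
#'   (`dissim = 1 - omega` exactly), both carrying the gene ids.
#' @export
topological_overlap <- function(adj) {
  .check_square_symmetric(adj, "adj")
  A <- unclass(adj)
  attr(A, "mode_type") <- NULL; attr(A, "tau") <- NULL; attr(A, "beta") <- NULL
  if (nrow(A) > 0 && (min(A) < 0 || max(A) > 1))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  if (any(diag(A) != 0))
    stop("adjacency diagonal must be zero", call. = FALSE)
  k <- rowSums(A)
  l <- A %*% A
  min_k <- outer(k, k, pmin)
  omega <- (l + A) / (min_k + 1 - A)
  # guard against floating drift just outside [0, 1]
  omega <- pmin(pmax(omega, 0), 1)
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 1
  dimnames(omega) <- dimnames(A)
  structure(list(omega = omega, dissim = 1 - omega), class = "tom")
}
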