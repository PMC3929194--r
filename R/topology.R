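.adjacency_graph <- function(adj, mode = c("binary", "weighted"),
                             weight_transform = c("reciprocal", "one_minus")) {
  mode <- match.arg(mode)
  weight_transform <- match.arg(weight_transform)
  .check_square_symmetric(adj, "adj")
  A <- unclass(adj)
  attr(A, "mode_type") <- NULL; attr(A, "tau") <- NULL; attr(A, "beta") <- NULL
  if (is.null(rownames(A))) dimnames(A) <- list(.gene_ids(A), .gene_ids(A))
  if (mode == "binary") {
    if (!all(A %in% c(0, 1)))
      stop("binary mode requires a 0/1 adjacency; binarize first ",
           "(e.g. hard_adjacency) or use mode = \"weighted\"", call. = FALSE)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  } else {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    w <- igraph::E(g)$weight
    # shortest paths need edge *lengths*: strong edges must be short
    igraph::E(g)$weight <- if (weight_transform == "reciprocal") 1 / w
                           else 1 - w
  }
  g
}

#' Betweenness centrality of every gene
#'
#' For node k, the sum over pairs (i, j) of the fraction of shortest paths
#' from i to j that pass through k; disconnected pairs contribute 0. By
#' default normalized by the number of ordered pairs `(n-1)(n-2)` (paths are
#' counted in both directions), so values lie in \[0, 1\]. The default
#' operates on the binary (hard-threshold) network — the convention under
#' which the hub tables of this analysis are reported; `mode = "weighted"`
#' uses shortest paths with edge length `1/a_ij` (or `1 - a_ij`).
#'
#' @param adj adjacency matrix.
#' @param normalized divide by `(n-1)(n-2)` ordered pairs (default TRUE).
#' @param mode `"binary"` (default) or `"weighted"`.
#' @param weight_transform how adjacency becomes edge length in weighted mode.
#' @return Named numeric vector over genes. Fewer than 3 nodes: all zeros.
#' @export
betweenness_centrality <- function(adj, normalized = TRUE,
                                   mode = c("binary", "weighted"),
                                   weight_transform = c("reciprocal",
                                                        "one_minus")) {
  g <- .adjacency_graph(adj, mode, weight_transform)
  n <- igraph::vcount(g)
  if (n < 3)
    return(setNames(rep(0, n), igraph::V(g)$name))
  b <- igraph::betweenness(g, directed = FALSE)  # unordered pairs, once each
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Closeness centrality of every gene (component-scaled)
#'
#' Per node i with `m` reachable other nodes and total geodesic distance `D`
#' to them: `CC(i) = (m / (n - 1)) * (m / D)` — the reachable fraction times
#' the inverse mean distance within the component. Lies in \[0, 1\]; isolated
#' nodes get 0. Disconnected graphs are handled without infinities.
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector over genes.
#' @export
closeness_centrality <- function(adj, mode = c("binary", "weighted"),
                                 weight_transform = c("reciprocal",
                                                      "one_minus")) {
  g <- .adjacency_graph(adj, mode, weight_transform)
  n <- igraph::vcount(g)
  if (n <= 1) return(setNames(rep(0, n), igraph::V(g)$name))
  d <- igraph::distances(g)
  cc <- apply(d, 1, function(row) {
    row <- row[is.finite(row)]
    m <- length(row) - 1          # exclude self (distance 0)
    if (m == 0) return(0)
    (m / (n - 1)) * (m / sum(row))
  })
  setNames(as.numeric(cc), igraph::V(g)$name)
}

#' Clustering coefficient of every gene
#'
#' Density of connections among a node's neighbors. One formula covers both
#' network types:
#' \deqn{C_i = \frac{\sum_{j \ne i}\sum_{l \ne i,j} a_{ij} a_{jl} a_{li}}
#'   {(\sum_j a_{ij})^2 - \sum_j a_{ij}^2}}
#' For 0/1 adjacency this reduces exactly to `2 * triangles / (k (k - 1))`.
#' Nodes whose denominator is 0 (degree < 2 in the binary case) get 0.
#'
#' @param adj adjacency matrix, entries in \[0, 1\], zero diagonal.
#' @return Named numeric vector over genes, values in \[0, 1\].
#' @export
clustering_coefficients <- function(adj) {
  .check_square_symmetric(adj, "adj")
  A <- unclass(adj)
  attr(A, "mode_type") <- NULL; attr(A, "tau") <- NULL; attr(A, "beta") <- NULL
  if (any(diag(A) != 0))
    stop("adjacency diagonal must be zero", call. = FALSE)
  num <- diag(A %*% A %*% A)          # = sum_{j,l != i} a_ij a_jl a_li
  den <- rowSums(A)^2 - rowSums(A^2)
  cc <- ifelse(den > 0, num / den, 0)
  setNames(pmin(pmax(cc, 0), 1), .gene_ids(A))
}

#' Fit a (truncated) power law to a degree distribution
#'
#' Builds the empirical degree distribution p(k) and fits, by ordinary least
#' squares on the log scale, either the scale-free model `p(k) ~ k^-r`
#' (regressing `log10 p(k)` on `log10 k`) or the exponentially truncated
#' power law `p(k) ~ k^-r exp(-alpha k)` (regressing on `log10 k` and `k`).
#' The reported `exponent_r` is the fitted slope of `log10 k` (negative for a
#' decaying distribution, e.g. -2 for `p ~ k^-2`); `alpha` is the exponential
#' rate on the natural scale. `r_squared` is the regression R².
#'
#' Binning: integer-valued degrees are binned per integer; continuous
#' (weighted) connectivities into `n_bins` equal-width bins on `log10 k`,
#' each bin represented by the mean connectivity of its members. Zero
#' degrees and empty bins are dropped (log undefined / no mass).
#'
#' @param degrees numeric vector of degrees or connectivities (ignored when
#'   `bins` is supplied).
#' @param model `"power_law"` or `"truncated_power_law"`.
#' @param n_bins bins for continuous connectivities.
#' @param bins optional data.frame with columns `k` and `pk`: a precomputed
#'   distribution, used as-is (e.g. an exact noiseless histogram).
#' @param binning `"auto"` (integer when all degrees are whole), `"integer"`,
#'   or `"log"` to force equal-width log10 bins.
#' @return An object of class `degree_fit`: list with `model`, `exponent_r`,
#'   `alpha` (NA for the pure power law), `r_squared`, `bins`, `fit` (the lm).
#' @export
degree_distribution_fit <- function(degrees = NULL,
                                    model = c("power_law",
                                              "truncated_power_law"),
                                    n_bins = 15,
                                    bins = NULL,
                                    binning = c("auto", "integer", "log")) {
  model <- match.arg(model)
  binning <- match.arg(binning)
  if (is.null(bins)) {
    if (is.null(degrees))
      stop("supply degrees or bins", call. = FALSE)
    degrees <- degrees[degrees > 0]
    integerish <- all(degrees == round(degrees))
    use_integer <- switch(binning, auto = integerish, integer = TRUE,
                          log = FALSE)
    if (use_integer) {
      tab <- table(degrees)
      bins <- data.frame(k = as.numeric(names(tab)),
                         pk = as.numeric(tab) / length(degrees))
    } else {
      lk <- log10(degrees)
      brks <- seq(min(lk), max(lk), length.out = n_bins + 1)
      brks[1] <- brks[1] - 1e-9   # include the minimum
      idx <- cut(lk, brks, labels = FALSE)
      counts <- tabulate(idx, nbins = n_bins)
      kmean <- vapply(seq_len(n_bins), function(b)
        if (counts[b] > 0) mean(degrees[idx == b]) else NA_real_, 0)
      # probability *density* per bin: log-width bins grow linearly in k, so
      # raw per-bin mass would flatten the fitted slope
      width <- 10^brks[-1] - 10^brks[-(n_bins + 1)]
      bins <- data.frame(k = kmean,
                         pk = counts / (length(degrees) * width))
      bins <- bins[counts > 0, ]
    }
  }
  bins <- bins[bins$k > 0 & bins$pk > 0, , drop = FALSE]
  if (nrow(bins) < 3)
    stop("fewer than 3 usable bins; cannot fit a degree distribution",
         call. = FALSE)
  df <- data.frame(lp = log10(bins$pk), lk = log10(bins$k), k = bins$k)
  fit <- if (model == "power_law") lm(lp ~ lk, data = df)
         else lm(lp ~ lk + k, data = df)
  # direct R^2: summary.lm warns on (deliberate) perfect fits
  rss <- sum(fit$residuals^2)
  tss <- sum((df$lp - mean(df$lp))^2)
  r2 <- if (tss == 0) as.numeric(rss < 1e-20) else 1 - rss / tss
  alpha <- if (model == "truncated_power_law")
    -coef(fit)[["k"]] * log(10) else NA_real_
  structure(list(model = model,
                 exponent_r = unname(coef(fit)[["lk"]]),
                 alpha = alpha,
                 r_squared = r2,
                 bins = bins,
                 fit = fit),
            class = "degree_fit")
}

#' Per-gene topology profile
#'
#' Assembles the per-node report used for hub selection: connectivity (degree
#' for a binary network, `k_i = sum_j a_ij` for a weighted one), betweenness
#' centrality, closeness centrality, and clustering coefficient. Betweenness
#' and closeness default to the binary shortest-path convention; pass
#' `mode = "weighted"` to compute them on the weighted network.
#'
#' @param adj adjacency matrix.
#' @inheritParams betweenness_centrality
#' @return data.frame with columns `gene_id`, `degree`, `betweenness`,
#'   `closeness`, `clustering_coefficient`.
#' @export
node_topology <- function(adj, normalized = TRUE,
                          mode = c("binary", "weighted"),
                          weight_transform = c("reciprocal", "one_minus")) {
  .check_square_symmetric(adj, "adj")
  ids <- .gene_ids(adj)
  data.frame(
    gene_id = ids,
    degree = as.numeric(rowSums(adj)),
    betweenness = as.numeric(
      betweenness_centrality(adj, normalized, mode, weight_transform)),
    closeness = as.numeric(closeness_centrality(adj, mode, weight_transform)),
    clustering_coefficient = as.numeric(clustering_coefficients(adj)),
    stringsAsFactors = FALSE)
}

#' Select hub and high-betweenness candidate genes
#'
#' The union of the top `n_top_degree` genes by descending degree and the top
#' `n_top_bc` genes by descending betweenness centrality (the study selects
#' 6 + 5 = 11 candidates). Ties are broken by the other metric, then by gene
#' id. A gene appearing in both lists is reported once, tagged `"both"`.
#'
#' @param profiles data.frame from [node_topology()] (needs `gene_id`,
#'   `degree`, `betweenness`).
#' @param n_top_degree,n_top_bc how many genes each criterion contributes.
#' @return data.frame with columns `gene_id`, `degree`, `betweenness`,
#'   `selected_by` (`"degree"`, `"bc"` or `"both"`), ordered degree picks
#'   first.
#' @export
select_candidates <- function(profiles, n_top_degree = 6, n_top_bc = 5) {
  stopifnot(is.data.frame(profiles),
            all(c("gene_id", "degree", "betweenness") %in% names(profiles)))
  if (nrow(profiles) == 0)
    stop("profiles is empty", call. = FALSE)
  if (n_top_degree > nrow(profiles) || n_top_bc > nrow(profiles))
    stop("requested counts exceed the number of genes", call. = FALSE)
  by_deg <- profiles[order(-profiles$degree, -profiles$betweenness,
                           profiles$gene_id), ]
  by_bc <- profiles[order(-profiles$betweenness, -profiles$degree,
                          profiles$gene_id), ]
  deg_set <- head(by_deg$gene_id, n_top_degree)
  bc_set <- head(by_bc$gene_id, n_top_bc)
  ids <- c(deg_set, setdiff(bc_set, deg_set))
  out <- profiles[match(ids, profiles$gene_id),
                  c("gene_id", "degree", "betweenness")]
  out$selected_by <- ifelse(out$gene_id %in% deg_set & out$gene_id %in% bc_set,
                            "both",
                            ifelse(out$gene_id %in% deg_set, "degree", "bc"))
  rownames(out) <- NULL
  out
}
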