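# Independent brute-force oracles. Deliberately naive (triple loops, explicit
# path counting) so they share no code path with the implementation.

# Eq.-(1) topological overlap by explicit loops.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- sapply(seq_len(n), function(i) sum(a[i, ]))
  omega <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l_ij <- 0
    for (u in seq_len(n)) l_ij <- l_ij + a[i, u] * a[u, j]
    omega[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  omega
}

# All-pairs shortest-path counting on a binary adjacency (BFS layers by
# Floyd-Warshall distances + dynamic-programming path counts).
oracle_geodesics <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  cnt <- matrix(0, n, n); diag(cnt) <- 1
  ord <- order(as.vector(d))  # fill in increasing distance
  for (idx in ord) {
    i <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    if (i == j || !is.finite(d[i, j])) next
    if (d[i, j] == 1) { cnt[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n))
      if (a[u, j] == 1 && is.finite(d[i, u]) && d[i, u] == d[i, j] - 1)
        s <- s + cnt[i, u]
    cnt[i, j] <- s
  }
  list(dist = d, count = cnt)
}

# Normalized betweenness by explicit fraction-of-geodesics summation
# (unordered pairs, divided by (n-1)(n-2)/2).
oracle_betweenness <- function(a) {
  n <- nrow(a)
  geo <- oracle_geodesics(a)
  b <- numeric(n)
  for (k in seq_len(n)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (i == k || j == k || i == j) next
      if (!is.finite(geo$dist[i, j]) || geo$count[i, j] == 0) next
      through <- if (is.finite(geo$dist[i, k]) && is.finite(geo$dist[k, j]) &&
                     geo$dist[i, k] + geo$dist[k, j] == geo$dist[i, j])
        geo$count[i, k] * geo$count[k, j] else 0
      b[k] <- b[k] + through / geo$count[i, j]
    }
  }
  if (n < 3) return(numeric(n))
  b / ((n - 1) * (n - 2) / 2)
}

# Weighted clustering coefficient by triple loop.
oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    num <- 0
    for (j in seq_len(n)) for (l in seq_len(n)) {
      if (j == i || l == i || l == j) next
      num <- num + a[i, j] * a[j, l] * a[l, i]
    }
    den <- sum(a[i, ])^2 - sum(a[i, ]^2)
    if (den > 0) num / den else 0
  })
}

# Naive O(n^3) UPGMA: returns sorted merge heights.
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dm <- d; diag(dm) <- Inf
  heights <- numeric(0)
  dist_between <- function(A, B) {
    s <- 0
    for (i in A) for (j in B) s <- s + d[i, j]
    s / (length(A) * length(B))
  }
  while (sum(active) > 1) {
    best <- Inf; bi <- bj <- 0
    ids <- which(active)
    for (x in seq_along(ids)) for (y in seq_along(ids)) {
      if (y <= x) next
      dd <- dist_between(members[[ids[x]]], members[[ids[y]]])
      if (dd < best) { best <- dd; bi <- ids[x]; bj <- ids[y] }
    }
    heights <- c(heights, best)
    members[[bi]] <- c(members[[bi]], members[[bj]])
    active[bj] <- FALSE
  }
  sort(heights)
}

# Hypergeometric upper-tail by direct summation of the pmf.
oracle_hyper_tail <- function(overlap, set_size, universe, module) {
  xs <- overlap:min(set_size, module)
  if (overlap <= 0) return(1)
  sum(sapply(xs, function(x)
    choose(set_size, x) * choose(universe - set_size, module - x))) /
    choose(universe, module)
}

# Random symmetric weighted adjacency in [0,1], zero diagonal.
random_weighted_adjacency <- function(n, density = 0.6) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  vals <- runif(sum(ut))
  vals[runif(sum(ut)) > density] <- 0
  a[ut] <- vals
  a <- a + t(a)
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

random_binary_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# Small adjacency builders used across test files.
adjacency_from_edges <- function(n, edges, ids = sprintf("g%02d", 1:n)) {
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) { a[e[1], e[2]] <- 1; a[e[2], e[1]] <- 1 }
  a
}
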