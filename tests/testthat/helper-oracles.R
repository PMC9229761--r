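# Brute-force graph oracles, independent of the igraph-backed implementation.
# Distances via Floyd-Warshall; betweenness via explicit enumeration of every
# shortest path; components via reachability closure.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# all shortest paths s -> t as a list of vertex vectors
oracle_shortest_paths <- function(adj, s, t, d) {
  if (!is.finite(d[s, t])) return(list())
  rec <- function(v) {
    if (v == t) return(list(t))
    nxt <- which(adj[v, ] > 0 & d[, t] == d[v, t] - 1)
    out <- list()
    for (w in nxt) {
      for (p in rec(w)) out[[length(out) + 1L]] <- c(v, p)
    }
    out
  }
  rec(s)
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(adj, s, t, d)
      if (!length(paths)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + through / length(paths)
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    cc[v] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  ut <- d[upper.tri(d)]
  fin <- is.finite(ut)
  list(lp = mean(ut[fin]), reachable_fraction = mean(fin))
}

# component membership by closing reachability over boolean products
oracle_largest_component <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  reach <- (adj > 0) | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  max(table(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
}

oracle_attack_curve <- function(adj, ord) {
  n <- nrow(adj)
  rel <- numeric(n + 1)
  for (k in 0:n) {
    remaining <- setdiff(seq_len(n), ord[seq_len(k)])
    rel[k + 1] <- if (length(remaining)) {
      oracle_largest_component(adj[remaining, remaining, drop = FALSE]) / n
    } else 0
  }
  rel
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# all labeled simple graphs on n nodes, as adjacency matrices
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}
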