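#' Degree centrality
#'
#' Number of neighbors of each region in a binary undirected graph.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return named integer vector of per-node degrees.
#' @export
degree_centrality <- function(adj) {
  adj <- check_adjacency(adj)
  d <- as.integer(rowSums(adj))
  names(d) <- rownames(adj)
  d
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node, counting
#' each unordered pair once and normalizing by `(N-1)(N-2)/2` so values are
#' densities in \[0, 1\]. Pairs with no connecting path contribute 0.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(adj) {
  adj <- check_adjacency(adj)
  if (nrow(adj) < 3L) {          # no pair can route through a third node
    return(stats::setNames(rep(0, nrow(adj)), rownames(adj)))
  }
  g <- adj_to_graph(adj)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  names(b) <- rownames(adj)
  b
}

#' Mean clustering coefficient (Cp)
#'
#' Average over nodes of the fraction of a node's neighbor pairs that are
#' themselves connected; nodes of degree < 2 contribute 0.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal.
#' @return scalar Cp in \[0, 1\].
#' @export
clustering_coefficient <- function(adj) {
  adj <- check_adjacency(adj)
  igraph::transitivity(adj_to_graph(adj), type = "localaverage",
                       isolates = "zero")
}

#' Characteristic path length (Lp)
#'
#' Mean shortest-path length (hops) over all mutually reachable unordered
#' node pairs, together with the fraction of pairs that are reachable. Density
#' sweeps routinely produce fragmented graphs, so unreachable pairs are
#' excluded from the mean rather than mapped to an arbitrary large value.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal; must contain
#'   at least one edge.
#' @return list with `lp` and `reachable_fraction`.
#' @export
characteristic_path_length <- function(adj) {
  adj <- check_adjacency(adj)
  if (sum(adj) == 0) stop("graph has no edges; Lp undefined", call. = FALSE)
  d <- igraph::distances(adj_to_graph(adj))
  ut <- d[upper.tri(d)]
  fin <- is.finite(ut)
  list(lp = mean(ut[fin]), reachable_fraction = mean(fin))
}

#' Small-world quantities against degree-preserving null graphs
#'
#' Computes the clustering coefficient Cp and characteristic path length Lp of
#' the graph and of `n_null` degree-preserving randomized graphs
#' (Maslov-Sneppen edge rewiring, 10 x |E| swap attempts each), and the
#' normalized ratios `gamma = Cp/Cp_rand`, `lambda = Lp/Lp_rand` and the
#' small-world index `sigma = gamma/lambda`. `sigma > 1` indicates clustering
#' above, and path length near, that of matched random graphs. When the degree
#' sequence admits no rewiring (complete graphs, stars), density-matched
#' Erdos-Renyi G(n, m) graphs are used instead, with a warning.
#'
#' @param adj symmetric 0/1 adjacency matrix with at least one edge.
#' @param n_null number of null graphs (>= 10).
#' @param null_seed integer seed for the null ensemble; results are
#'   bit-reproducible for a fixed seed.
#' @return object of class `mcn_smallworld`: list with `cp`, `lp`, `cp_rand`,
#'   `lp_rand`, `gamma`, `lambda`, `sigma`, `n_null`, `null_seed`,
#'   `null_model` (`"degree-preserving"` or `"density-matched"`).
#' @export
small_world <- function(adj, n_null = 100L, null_seed = 1L) {
  adj <- check_adjacency(adj)
  if (n_null < 10L) stop("need n_null >= 10", call. = FALSE)
  if (sum(adj) == 0) stop("graph has no edges", call. = FALSE)
  g <- adj_to_graph(adj)
  cp <- clustering_coefficient(adj)
  lp <- characteristic_path_length(adj)$lp
  n_nodes <- nrow(adj)
  n_edges <- igraph::ecount(g)

  null_stats <- with_seed(null_seed, {
    nulls <- lapply(seq_len(n_null), function(i) {
      igraph::rewire(g, igraph::keeping_degseq(niter = 10L * n_edges))
    })
    unchanged <- vapply(nulls, function(h) {
      identical(igraph::as_adjacency_matrix(h, sparse = FALSE),
                unname(adj))
    }, logical(1L))
    model <- "degree-preserving"
    if (all(unchanged)) {
      warning("degree sequence admits no rewiring; ",
              "using density-matched random null graphs", call. = FALSE)
      model <- "density-matched"
      nulls <- lapply(seq_len(n_null), function(i) {
        igraph::sample_gnm(n_nodes, n_edges)
      })
    }
    cps <- vapply(nulls, function(h) {
      igraph::transitivity(h, type = "localaverage", isolates = "zero")
    }, numeric(1L))
    lps <- vapply(nulls, function(h) {
      d <- igraph::distances(h)
      ut <- d[upper.tri(d)]
      mean(ut[is.finite(ut)])
    }, numeric(1L))
    list(cp = mean(cps), lp = mean(lps), model = model)
  })

  gamma <- if (null_stats$cp > 0) cp / null_stats$cp else NA_real_
  lambda <- lp / null_stats$lp
  out <- list(cp = cp, lp = lp,
              cp_rand = null_stats$cp, lp_rand = null_stats$lp,
              gamma = gamma, lambda = lambda, sigma = gamma / lambda,
              n_null = as.integer(n_null), null_seed = as.integer(null_seed),
              null_model = null_stats$model)
  class(out) <- "mcn_smallworld"
  out
}

#' Per-node centrality table
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @param density optional density annotation carried into the output.
#' @return data frame: region, degree, betweenness (and density if given).
#' @export
node_metrics <- function(adj, density = NULL) {
  adj <- check_adjacency(adj)
  out <- data.frame(region = rownames(adj) %||% as.character(seq_len(nrow(adj))),
                    degree = degree_centrality(adj),
                    betweenness = betweenness_centrality(adj),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(density)) out$density <- density
  out
}

#' Identify predominant (hub) nodes
#'
#' Flags regions whose degree centrality AND betweenness centrality both
#' exceed their across-region mean by `threshold_sd` standard deviations.
#' When metrics from several densities are supplied (rows sharing a region),
#' they are averaged across the density grid before thresholding, yielding a
#' single node set rather than a per-density set.
#'
#' @param metrics data frame from [node_metrics()] (possibly row-bound across
#'   densities).
#' @param threshold_sd threshold in standard-deviation units (default 1).
#' @return object of class `mcn_predominant`: list with `regions` (character
#'   vector of flagged regions), `threshold_sd`, and the averaged `metrics`.
#' @export
predominant_nodes <- function(metrics, threshold_sd = 1) {
  stopifnot(is.data.frame(metrics),
            all(c("region", "degree", "betweenness") %in% names(metrics)))
  avg <- stats::aggregate(metrics[, c("degree", "betweenness")],
                          by = list(region = metrics$region), FUN = mean)
  # preserve first-seen region order
  avg <- avg[match(unique(metrics$region), avg$region), ]
  dthr <- mean(avg$degree) + threshold_sd * stats::sd(avg$degree)
  bthr <- mean(avg$betweenness) + threshold_sd * stats::sd(avg$betweenness)
  flagged <- avg$region[!is.na(dthr) & !is.na(bthr) &
                          avg$degree > dthr & avg$betweenness > bthr]
  out <- list(regions = flagged, threshold_sd = threshold_sd, metrics = avg)
  class(out) <- "mcn_predominant"
  out
}
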