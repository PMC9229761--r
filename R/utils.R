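#' Run code with a temporary RNG seed
#'
#' Sets the R random seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so library calls do not disturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Validate a binary undirected adjacency matrix. Returns it with a zeroed
# diagonal; errors on anything that is not square/symmetric/0-1.
check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (!isSymmetric(unname(adj))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  storage.mode(adj) <- "double"
  if (any(is.na(adj)) || !all(adj %in% c(0, 1))) {
    stop("adjacency must contain only 0/1 entries", call. = FALSE)
  }
  diag(adj) <- 0
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
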