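# Interaction networks: unweighted, undirected, simple graphs on the n
# agents. The study design spans the path (linear) network — the connected
# graph with the longest average path length — through randomly densified
# intermediates to the complete graph, plus the edgeless graph as the
# "working as individuals" baseline.

new_network <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1, drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (any(edges[, 1L] == edges[, 2L])) stop_param("self-loops not allowed")
    if (anyDuplicated(edges)) stop_param("duplicate edges not allowed")
    if (min(edges) < 1L || max(edges) > n) stop_param("edge endpoints outside 1..n")
  }
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    ends <- c(edges[, 1L], edges[, 2L])
    other <- c(edges[, 2L], edges[, 1L])
    sp <- split(other, ends)
    adj[as.integer(names(sp))] <- lapply(sp, sort)
  }
  colnames(edges) <- c("i", "j")
  structure(list(n = as.integer(n), edges = edges, adj = adj),
            class = "interaction_network")
}

#' Path (linear) network
#'
#' Agents arranged in a line, each connected only to its immediate
#' neighbor(s): edges `(i, i+1)` for `i = 1..n-1`. This is the minimally
#' connected network, with density `2/n`.
#'
#' @param n Number of agents (>= 2).
#' @return An `interaction_network`.
#' @export
#' @examples
#' network_density(path_network(16))  # 0.125
path_network <- function(n) {
  n <- check_count(n, "n", min = 2L)
  new_network(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

#' Complete (fully connected) network
#'
#' Every pair of agents is directly linked; density 1.
#'
#' @param n Number of agents (>= 2).
#' @return An `interaction_network`.
#' @export
complete_network <- function(n) {
  n <- check_count(n, "n", min = 2L)
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  new_network(n, pairs)
}

#' Edgeless network (individual baseline)
#'
#' No agent has any neighbor, so both copying and collaboration collapse to
#' individual hill climbing; this represents a group whose members share no
#' information.
#'
#' @param n Number of agents (>= 1).
#' @return An `interaction_network` with zero edges.
#' @export
edgeless_network <- function(n) {
  n <- check_count(n, "n", min = 1L)
  new_network(n, matrix(integer(0), ncol = 2L))
}

#' Network density
#'
#' Number of edges divided by the `n (n - 1) / 2` edges of the complete
#' graph on the same nodes.
#'
#' @param net An `interaction_network` with `n >= 2`.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (net$n < 2L) stop_param("density undefined for n < 2")
  nrow(net$edges) / (net$n * (net$n - 1L) / 2)
}

#' Densify a network by adding uniformly random edges
#'
#' Adds edges drawn uniformly at random (without replacement) from the
#' currently absent pairs until the edge count reaches
#' `round(target_density * n (n - 1) / 2)`. The result always contains every
#' edge of `base`, so densifying a connected network preserves connectivity.
#'
#' @param base An `interaction_network`.
#' @param target_density Target density in `(0, 1]`; must be at least the
#'   current density.
#' @param seed Optional integer seed.
#' @return An `interaction_network` whose edges are a superset of `base`'s.
#' @export
#' @examples
#' net <- densify(path_network(16), 0.5, seed = 1)
#' nrow(net$edges)  # 60
densify <- function(base, target_density, seed = NULL) {
  stopifnot(inherits(base, "interaction_network"))
  target_density <- check_prob(target_density, "target_density")
  n <- base$n
  m_full <- (n * (n - 1L)) %/% 2L
  m_target <- as.integer(round(target_density * m_full))
  m_now <- nrow(base$edges)
  if (m_target < m_now) {
    stop_param("`target_density` below the network's current density")
  }
  if (m_target == m_now) return(base)
  local_seed_if(seed)

  present <- matrix(FALSE, n, n)
  present[base$edges] <- TRUE
  cand <- which(upper.tri(present) & !present, arr.ind = TRUE)
  pick <- cand[sample.int(nrow(cand), m_target - m_now), , drop = FALSE]
  new_network(n, rbind(base$edges, unname(pick)))
}

#' Neighbors of a node
#'
#' @param net An `interaction_network`.
#' @param i Node index in `1..n`.
#' @return Sorted integer vector of neighbor indices.
#' @export
network_neighbors <- function(net, i) {
  stopifnot(inherits(net, "interaction_network"))
  i <- check_count(i, "i")
  if (i > net$n) stop_param("node index outside 1..n")
  net$adj[[i]]
}

#' Read / write an edge list
#'
#' Plain-text edge list, one `"i j"` pair of 1-based node indices per line.
#' `read_edgelist` needs `n` because isolated tail nodes leave no trace in
#' the file.
#'
#' @param net An `interaction_network`.
#' @param path File path.
#' @param n Node count for reading.
#' @return `read_edgelist` returns an `interaction_network`;
#'   `write_edgelist` returns `path` invisibly.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  utils::write.table(net$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, n) {
  n <- check_count(n, "n")
  if (file.size(path) == 0) return(new_network(n, matrix(integer(0), ncol = 2L)))
  edges <- as.matrix(utils::read.table(path, col.names = c("i", "j")))
  new_network(n, edges)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> n = %d, %d edges%s\n",
              x$n, nrow(x$edges),
              if (x$n >= 2L) sprintf(", density = %.4g", network_density(x)) else ""))
  invisible(x)
}
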