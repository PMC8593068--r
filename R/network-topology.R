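# Egalitarian (uniform-degree) communication networks: a k-regular ring
# lattice randomized by degree-preserving double-edge swaps, kept connected.
# Nodes are 1-based integers internally; the edge-list serialization is
# 0-based per the file format contract.

# k-regular ring lattice on n nodes. Even k: connect each node to the k/2
# nearest neighbours on each side. Odd k: (k-1)/2 on each side plus the
# diametrically opposite node (requires even n; n*k even guarantees it).
regular_lattice <- function(n, k) {
  edges <- NULL
  if (k %% 2L == 0L) {
    half <- k %/% 2L
    for (d in seq_len(half)) {
      a <- seq_len(n)
      b <- ((a - 1L + d) %% n) + 1L
      edges <- rbind(edges, cbind(a, b))
    }
  } else {
    half <- (k - 1L) %/% 2L
    for (d in seq_len(half)) {
      a <- seq_len(n)
      b <- ((a - 1L + d) %% n) + 1L
      edges <- rbind(edges, cbind(a, b))
    }
    a <- seq_len(n %/% 2L)
    b <- a + n %/% 2L
    edges <- rbind(edges, cbind(a, b))
  }
  t(apply(edges, 1L, sort))
}

edge_keys <- function(edges) paste(edges[, 1L], edges[, 2L])

# Degree-preserving randomization: attempt `n_attempts` double-edge swaps
# (a,b),(c,d) -> (a,c),(b,d), rejecting any swap that would create a
# self-loop or duplicate edge.
double_edge_swap <- function(edges, n_attempts) {
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (k in edge_keys(edges)) assign(k, TRUE, envir = keys)
  m <- nrow(edges)
  for (i in seq_len(n_attempts)) {
    idx <- sample.int(m, 2L)
    e1 <- edges[idx[1L], ]
    e2 <- edges[idx[2L], ]
    if (stats::runif(1) < 0.5) e2 <- rev(e2)
    a <- e1[1L]; b <- e1[2L]; c <- e2[1L]; d <- e2[2L]
    if (a == c || a == d || b == c || b == d) next
    new1 <- sort(c(a, c)); new2 <- sort(c(b, d))
    k1 <- paste(new1[1L], new1[2L]); k2 <- paste(new2[1L], new2[2L])
    if (exists(k1, envir = keys) || exists(k2, envir = keys) || k1 == k2) next
    old1 <- paste(e1[1L], e1[2L])
    e2s <- sort(c(c, d))
    old2 <- paste(e2s[1L], e2s[2L])
    rm(list = c(old1, old2), envir = keys)
    assign(k1, TRUE, envir = keys)
    assign(k2, TRUE, envir = keys)
    edges[idx[1L], ] <- new1
    edges[idx[2L], ] <- new2
  }
  edges
}

adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

bfs_connected <- function(adj) {
  n <- length(adj)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Generate an egalitarian (k-regular) communication network
#'
#' Builds a k-regular ring lattice on `n` nodes and randomizes it with
#' degree-preserving double-edge swaps (10 attempted swaps per edge),
#' resampling until the result is connected (at most 100 attempts). Every
#' node ends with exactly `k` neighbours, so no participant dominates the
#' communication dynamics. The reference design uses `n = 40`, `k = 4`.
#'
#' @param n number of nodes (at least `k + 1`).
#' @param k uniform degree; `n * k` must be even.
#' @param seed integer seed; the same `(n, k, seed)` always yields the same
#'   edge set.
#' @return An object of class `egal_topology`: a list with elements `n`,
#'   `k`, `edges` (two-column matrix of 1-based node ids, each row sorted)
#'   and `adj` (adjacency list).
#' @export
#' @examples
#' topo <- make_egalitarian_network(40, 4, seed = 1)
#' table(lengths(topo$adj))  # all degrees 4
make_egalitarian_network <- function(n, k, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || is.na(k) || k < 1L || n < k + 1L || (n * k) %% 2L != 0L)
    stop("infeasible (n, k): need n >= k + 1 and n * k even", call. = FALSE)
  with_seed(seed, {
    for (try in seq_len(100L)) {
      edges <- regular_lattice(n, k)
      edges <- double_edge_swap(edges, 10L * nrow(edges))
      adj <- adjacency_list(n, edges)
      if (bfs_connected(adj)) {
        ord <- order(edges[, 1L], edges[, 2L])
        topo <- structure(
          list(n = n, k = k, edges = edges[ord, , drop = FALSE], adj = adj),
          class = "egal_topology")
        return(topo)
      }
    }
    stop("failed to generate a connected ", k, "-regular graph on ", n,
         " nodes after 100 attempts", call. = FALSE)
  })
}

#' @export
print.egal_topology <- function(x, ...) {
  cat(sprintf("Egalitarian network: n = %d nodes, degree k = %d, %d edges\n",
              x$n, x$k, nrow(x$edges)))
  invisible(x)
}

#' Neighbours of a node
#'
#' @param topology an `egal_topology`.
#' @param node 1-based node id.
#' @return Sorted integer vector of the node's `k` neighbours.
#' @export
neighbors <- function(topology, node) {
  stopifnot(inherits(topology, "egal_topology"))
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > topology$n)
    stop("unknown node id: ", node, call. = FALSE)
  topology$adj[[node]]
}

#' Mean estimate among a node's neighbours
#'
#' The quantity shown to a clinician in the network condition: the arithmetic
#' mean of the (unrounded) estimates of the clinicians they are connected to.
#' Neighbours with no available estimate (`NA`, e.g. attrited participants)
#' are excluded from the mean.
#'
#' @param topology an `egal_topology`.
#' @param estimates numeric vector of length `topology$n`, indexed by node
#'   id; `NA` marks an unavailable estimate.
#' @param node 1-based node id.
#' @return The mean of the available neighbour estimates.
#' @export
neighbor_mean <- function(topology, estimates, node) {
  stopifnot(inherits(topology, "egal_topology"))
  if (length(estimates) != topology$n)
    stop("`estimates` must have one entry per node", call. = FALSE)
  vals <- estimates[neighbors(topology, node)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("no neighbour of node ", node, " has an available estimate",
         call. = FALSE)
  mean(vals)
}

#' Write a topology as a plain-text edge list
#'
#' One edge per line, two whitespace-separated 0-based node ids.
#'
#' @param topology an `egal_topology`.
#' @param path output file path.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "egal_topology"))
  lines <- sprintf("%d %d", topology$edges[, 1L] - 1L,
                   topology$edges[, 2L] - 1L)
  writeLines(lines, path)
  invisible(path)
}

#' Read a topology from a plain-text edge list
#'
#' @param path file with two 0-based node ids per line. The graph must be
#'   simple and degree-regular.
#' @return An `egal_topology`.
#' @export
read_topology <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("integer", "integer"))
  edges <- unname(t(apply(as.matrix(tab) + 1L, 1L, sort)))
  if (any(edges[, 1L] == edges[, 2L]))
    stop("edge list contains a self-loop", call. = FALSE)
  if (anyDuplicated(edge_keys(edges)))
    stop("edge list contains a duplicate edge", call. = FALSE)
  n <- max(edges)
  adj <- adjacency_list(n, edges)
  degs <- lengths(adj)
  if (length(unique(degs)) != 1L)
    stop("edge list is not degree-regular", call. = FALSE)
  ord <- order(edges[, 1L], edges[, 2L])
  structure(list(n = n, k = degs[1L], edges = edges[ord, , drop = FALSE],
                 adj = adj),
            class = "egal_topology")
}
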