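# Step 1 of CLIMP: for every node v, one maximal clique associated with v,
# found greedily inside the neighborhood subgraph N(v).  Only |V| cliques are
# sought, never the full maximal-clique enumeration (which is NP-hard).

new_clique <- function(seed, members, weight_sum) {
  structure(list(seed = seed,
                 members = sort(members, method = "radix"),
                 weight_sum = weight_sum),
            class = "motif_clique")
}

#' @export
print.motif_clique <- function(x, ...) {
  cat(sprintf("clique[seed=%s, |C|=%d, w=%.4g]: %s\n", x$seed,
              length(x$members), x$weight_sum,
              paste(x$members, collapse = " ")))
  invisible(x)
}

#' Greedy maximal clique associated with a node
#'
#' Finds one maximal clique containing `v`, biased toward the neighbors most
#' similar to `v`, in three sub-steps:
#' (a) start from the full neighborhood `C_v = N(v)`; if it is already a
#' clique, stop; otherwise sort the neighbors of `v` ascending by the weight
#' of their edge to `v` (ties by node id) into an array `U`.
#' (b) Delete the nodes of `U` in order, each deletion removing the node and
#' its incident edges, stopping as soon as `C_v` is complete (equivalently,
#' as soon as `v` and all remaining nodes have identical degree in `C_v`);
#' the deleted nodes are `u_1, ..., u_k`.
#' (c) Re-examine `u_(k-1)` down to `u_1` in reverse order (never `u_k`,
#' whose deletion completed the clique) and re-insert `u_j` iff it is
#' adjacent to every current member of `C_v`.
#'
#' The result is maximal within `N(v)` and its nodes have the closest
#' relationship to `v` among competing cliques; it need not be the maximum
#' clique.  Per-node cost is `O(d_v^2)` set operations.
#'
#' @param g a `similarity_graph`.
#' @param v a node identifier in `g`.  A degree-0 node yields the singleton
#'   clique `{v}`.
#' @return A `motif_clique`: list with `seed`, sorted `members`, and
#'   `weight_sum` (sum of edge weights induced by the members).
#' @export
find_associated_clique <- function(g, v) {
  stopifnot(length(v) == 1L)
  iv <- node_index(g, v)
  nbr <- g$adj[[iv]]
  if (length(nbr) == 0L)
    return(new_clique(v, v, 0))
  n <- length(g$nodes)
  mem <- logical(n)
  mem[c(iv, nbr)] <- TRUE
  size <- length(nbr) + 1L
  # within-C_v degrees, and total internal edge count for an O(1) clique test
  degin <- integer(n)
  for (i in c(iv, nbr)) degin[i] <- sum(mem[g$adj[[i]]])
  m_in <- sum(degin[c(iv, nbr)]) %/% 2L
  is_complete <- function() m_in == size * (size - 1L) / 2L

  if (!is_complete()) {
    ord <- order(g$wts[[iv]], g$nodes[nbr], method = "radix")
    U <- nbr[ord]
    deleted <- integer(0)
    for (u in U) {
      mem[u] <- FALSE
      size <- size - 1L
      m_in <- m_in - degin[u]
      for (x in g$adj[[u]]) if (mem[x]) degin[x] <- degin[x] - 1L
      deleted <- c(deleted, u)
      if (is_complete()) break
    }
    k <- length(deleted)
    if (k >= 2L) {
      for (j in seq(k - 1L, 1L)) {
        uj <- deleted[j]
        # adjacent (in N(v), hence in G) to every current member?
        if (sum(mem[g$adj[[uj]]]) == size) {
          mem[uj] <- TRUE
          size <- size + 1L
        }
      }
    }
  }
  idx <- which(mem)
  new_clique(v, g$nodes[idx], induced_wsum(g, idx))
}

#' Step-1 cliques for every node
#'
#' Runs [find_associated_clique()] for each node of the graph.  The per-node
#' searches are independent, so the loop may be executed in parallel; the
#' result is bit-identical for any `workers` value (cliques are returned in
#' canonical seed order).
#'
#' @inheritParams find_associated_clique
#' @param workers positive integer; number of worker processes (forked via
#'   the parallel package when > 1).  A performance knob only.
#' @return List of `motif_clique`, one per node, ordered by seed id.
#' @export
find_all_cliques <- function(g, workers = 1L) {
  stopifnot(is.numeric(workers), workers >= 1)
  seeds <- g$nodes
  if (length(seeds) == 0L) return(list())
  if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(seeds, function(v) find_associated_clique(g, v),
                              mc.cores = as.integer(workers),
                              mc.preschedule = TRUE)
    # fall back transparently if any fork failed
    bad <- vapply(res, function(x) !inherits(x, "motif_clique"), logical(1))
    if (any(bad)) res[bad] <- lapply(seeds[bad],
                                     function(v) find_associated_clique(g, v))
    res
  } else {
    lapply(seeds, function(v) find_associated_clique(g, v))
  }
}

#' Collapse exactly duplicated cliques
#'
#' Different seeds frequently discover the same member set; redundant copies
#' are merged to unique cliques before ranking.  Only exact duplicates
#' collapse (the seed of the first occurrence is kept); a clique that is a
#' proper subset of another is retained.
#'
#' @param cliques list of `motif_clique`.
#' @return List of unique `motif_clique`, first occurrences in input order.
#' @export
dedupe_cliques <- function(cliques) {
  if (length(cliques) == 0L) return(list())
  key <- vapply(cliques, function(cl) paste(cl$members, collapse = "\r"),
                character(1))
  cliques[!duplicated(key)]
}
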