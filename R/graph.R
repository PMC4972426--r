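# Similarity-graph data model: the substrate every clustering step runs on.
# Undirected, weighted, no self-loops, one stored entry per unordered pair.
# Nodes are opaque strings; all orderings use radix (locale-independent) sort.

#' Construct a motif similarity graph
#'
#' An undirected weighted graph over opaque string node identifiers, stored
#' as a canonical edge table plus adjacency lists.  Edge weights are
#' similarity scores, normally in `(0, 1]`; every stored weight must be
#' `>= gamma`, the similarity cutoff the graph was built at.
#'
#' @param edges data frame (or NULL for an edgeless graph) with columns
#'   `from`, `to`, `weight`.  Self-loops and duplicate unordered pairs are
#'   errors here; use [read_edge_list()] for tolerant file input.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @param gamma similarity cutoff in `[0, 1]` the edges are asserted against.
#' @return An object of class `similarity_graph`.
#' @examples
#' g <- similarity_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                  weight = c(0.8, 0.7)))
#' graph_nodes(g)
#' @export
similarity_graph <- function(edges = NULL, nodes = NULL, gamma = 0) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "weight") %in% names(edges)))
    stop("`edges` must have columns from, to, weight", call. = FALSE)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!is.numeric(edges$weight) || anyNA(edges$weight))
    stop("edge weights must be numeric and non-missing", call. = FALSE)
  if (any(edges$weight < 0))
    stop("negative edge weights are not allowed", call. = FALSE)
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed in a similarity graph", call. = FALSE)
  if (any(edges$weight < gamma))
    stop("all stored edge weights must be >= gamma", call. = FALSE)
  # canonical unordered orientation: from < to in C locale
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate unordered edge(s): ",
         paste(unique(sub("\r", "--", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  ord <- order(edges$from, edges$to, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  node_set <- sort(unique(c(edges$from, edges$to, as.character(nodes))),
                   method = "radix")
  n <- length(node_set)
  ei <- match(edges$from, node_set)
  ej <- match(edges$to, node_set)

  adj <- rep(list(integer(0)), n)
  wts <- rep(list(numeric(0)), n)
  if (nrow(edges) > 0L) {
    end_idx <- c(ei, ej)
    oth_idx <- c(ej, ei)
    w2 <- c(edges$weight, edges$weight)
    sp <- split(seq_along(end_idx), end_idx)
    for (k in names(sp)) {
      i <- as.integer(k)
      sel <- sp[[k]]
      nb <- oth_idx[sel]
      o <- order(nb, method = "radix")
      adj[[i]] <- nb[o]
      wts[[i]] <- w2[sel][o]
    }
  }
  structure(list(nodes = node_set, edges = edges, ei = ei, ej = ej,
                 adj = adj, wts = wts, gamma = gamma),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d edges (gamma = %g)\n",
              length(x$nodes), nrow(x$edges), x$gamma))
  invisible(x)
}

node_index <- function(g, v) {
  i <- match(v, g$nodes)
  if (anyNA(i))
    stop("unknown node(s): ", paste(v[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}

#' Graph accessors
#'
#' `graph_nodes()` returns the sorted node identifiers, `graph_edges()` the
#' canonical edge table, `graph_degree()` per-node degrees and
#' `graph_neighbors()` the neighbors of one node.
#'
#' @param g a `similarity_graph`.
#' @param v a node identifier (for `graph_neighbors`), or for
#'   `graph_degree` an optional vector of nodes (default: all).
#' @return Character vector, data frame, or named integer vector.
#' @export
graph_nodes <- function(g) g$nodes

#' @rdname graph_nodes
#' @export
graph_edges <- function(g) g$edges

#' @rdname graph_nodes
#' @export
graph_degree <- function(g, v = NULL) {
  if (is.null(v)) v <- g$nodes
  stats::setNames(lengths(g$adj)[node_index(g, v)], v)
}

#' @rdname graph_nodes
#' @export
graph_neighbors <- function(g, v) {
  stopifnot(length(v) == 1L)
  g$nodes[g$adj[[node_index(g, v)]]]
}

#' Weight of one edge
#'
#' @inheritParams graph_nodes
#' @param u,v node identifiers.
#' @return The edge weight, or `NA` if `u` and `v` are not adjacent.
#' @export
edge_weight <- function(g, u, v) {
  iu <- node_index(g, u)
  iv <- node_index(g, v)
  k <- match(iv, g$adj[[iu]])
  if (is.na(k)) NA_real_ else g$wts[[iu]][k]
}

#' Read a weighted edge list ("ABC" format)
#'
#' Parses a 3+ column whitespace/tab separated file (`node node weight`, the
#' format MCL consumes); `#`-prefixed and blank lines are ignored.  Edges
#' with weight below `gamma` and self-loops are dropped.  If the same
#' unordered pair occurs more than once the maximum weight is kept and a
#' warning is issued.
#'
#' @param path file path.
#' @param gamma similarity cutoff in `[0, 1]`; only edges with
#'   `weight >= gamma` are kept.  The comparison is exact `>=` on the parsed
#'   decimal value (no epsilon).
#' @param keep_isolated if `TRUE`, nodes whose every incident record fell
#'   below the cutoff (or was a self-loop) are retained as isolated nodes;
#'   by default they are dropped and clustering never sees them.
#' @return A `similarity_graph`.
#' @export
read_edge_list <- function(path, gamma = 0, keep_isolated = FALSE) {
  stopifnot(is.numeric(gamma), gamma >= 0, gamma <= 1)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(similarity_graph(NULL, gamma = gamma))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("malformed edge record at line %d: need 3 columns, got %d",
                 lineno[which(nf < 3L)[1L]], nf[which(nf < 3L)[1L]]),
         call. = FALSE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  wtxt <- vapply(parts, `[[`, character(1), 3L)
  w <- suppressWarnings(as.numeric(wtxt))
  if (anyNA(w))
    stop(sprintf("non-numeric weight %s at line %d",
                 dQuote(wtxt[which(is.na(w))[1L]]), lineno[which(is.na(w))[1L]]),
         call. = FALSE)
  if (any(w < 0))
    stop(sprintf("negative weight at line %d", lineno[which(w < 0)[1L]]),
         call. = FALSE)
  all_nodes <- unique(c(from, to))
  loop <- from == to
  from <- from[!loop]; to <- to[!loop]; w <- w[!loop]
  # canonicalize and resolve duplicates with the max-weight rule
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    warning(sprintf("%d duplicate edge pair(s) resolved by keeping the maximum weight",
                    length(dup)), call. = FALSE)
    agg <- tapply(w, key, max)
    key_u <- names(agg)
    w <- as.numeric(agg)
    lohi <- strsplit(key_u, "\r", fixed = TRUE)
    lo <- vapply(lohi, `[[`, character(1), 1L)
    hi <- vapply(lohi, `[[`, character(1), 2L)
  }
  pass <- w >= gamma
  edges <- data.frame(from = lo[pass], to = hi[pass], weight = w[pass],
                      stringsAsFactors = FALSE)
  nodes <- if (keep_isolated) all_nodes else NULL
  similarity_graph(edges, nodes = nodes, gamma = gamma)
}

#' Write a graph as a 3-column edge list
#'
#' Inverse of [read_edge_list()]: one `from to weight` line per stored
#' unordered edge, in canonical order.
#'
#' @inheritParams graph_nodes
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(g, path) {
  e <- g$edges
  writeLines(sprintf("%s\t%s\t%.12g", e$from, e$to, e$weight), path)
  invisible(path)
}

#' Neighborhood subgraph N(v)
#'
#' The subgraph induced by a node `v` and all of its neighbors.  Every
#' maximal clique containing `v` lies inside `N(v)`, which is why the
#' per-node clique search of [find_associated_clique()] operates there.
#'
#' @inheritParams graph_nodes
#' @param v a node identifier.
#' @return An object of class `neighborhood_subgraph` with elements
#'   `center`, `members` (character, `v` first then sorted neighbors) and
#'   `edges` (the induced edge table).
#' @export
neighborhood <- function(g, v) {
  stopifnot(length(v) == 1L)
  iv <- node_index(g, v)
  mem_idx <- c(iv, g$adj[[iv]])
  mem <- logical(length(g$nodes))
  mem[mem_idx] <- TRUE
  keep <- mem[g$ei] & mem[g$ej]
  structure(list(center = v,
                 members = g$nodes[mem_idx],
                 edges = g$edges[keep, , drop = FALSE]),
            class = "neighborhood_subgraph")
}

#' @export
print.neighborhood_subgraph <- function(x, ...) {
  cat(sprintf("N(%s): %d members, %d induced edges\n",
              x$center, length(x$members), nrow(x$edges)))
  invisible(x)
}

#' Sum of edge weights induced by a node set
#'
#' Sum of the weights of all graph edges with both endpoints in `nodes`.
#' Empty and singleton sets give 0.  This is the quantity cliques and
#' clusters are ranked by.
#'
#' @inheritParams graph_nodes
#' @param nodes character vector of node identifiers (a subset of the graph).
#' @return A single non-negative number.
#' @export
weight_sum <- function(g, nodes) {
  idx <- node_index(g, unique(nodes))
  if (length(idx) < 2L) return(0)
  mem <- logical(length(g$nodes))
  mem[idx] <- TRUE
  sum(g$edges$weight[mem[g$ei] & mem[g$ej]])
}

# induced weight sum via adjacency lists, integer-index fast path
induced_wsum <- function(g, idx) {
  if (length(idx) < 2L) return(0)
  mem <- logical(length(g$nodes))
  mem[idx] <- TRUE
  s <- 0
  for (i in idx) s <- s + sum(g$wts[[i]][mem[g$adj[[i]]]])
  s / 2
}
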