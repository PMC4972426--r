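# Steps 2-4 of CLIMP: rank cliques by edge-weight sum, merge them into
# clusters under the alpha (overlap) / beta (adjacency) rule, resolve nodes
# claimed by several clusters, and rank the final clusters.

#' CLIMP configuration
#'
#' Bundles the tunable parameters of the clustering pipeline.
#'
#' @param alpha overlap threshold in `(0, 1]`: a clique `C_j` may join a
#'   cluster only if at least this fraction of its nodes already lies in the
#'   cluster.
#' @param beta adjacency threshold in `(0, 1]` with `alpha <= beta`: at
#'   least this fraction of `C_j`'s nodes must be in the cluster or share a
#'   graph edge with it.
#' @param gamma similarity cutoff in `[0, 1]` used when building the graph.
#' @param workers positive integer, parallel workers (performance knob only;
#'   never affects output).
#' @param merge_target `"cluster"` (default) tests `C_j` against the
#'   accumulated cluster member set, as the in-place merge of the pseudo-code
#'   implies; `"seed"` tests against the original seed clique only.
#' @return An object of class `climp_config`.
#' @export
climp_config <- function(alpha = 0.5, beta = 0.5, gamma = 0.6, workers = 1L,
                         merge_target = c("cluster", "seed")) {
  merge_target <- match.arg(merge_target)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, beta > 0, beta <= 1,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
            is.numeric(workers), workers >= 1)
  if (alpha > beta)
    stop("alpha must be <= beta", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 workers = as.integer(workers), merge_target = merge_target),
            class = "climp_config")
}

#' @export
print.climp_config <- function(x, ...) {
  cat(sprintf("climp_config: alpha=%g beta=%g gamma=%g workers=%d (merge vs %s)\n",
              x$alpha, x$beta, x$gamma, x$workers, x$merge_target))
  invisible(x)
}

new_cluster <- function(members, source_cliques, weight_sum = NA_real_,
                        rank = NA_integer_) {
  structure(list(rank = rank,
                 members = sort(members, method = "radix"),
                 source_cliques = source_cliques,
                 weight_sum = weight_sum),
            class = "motif_cluster")
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat(sprintf("cluster[rank=%s, |C|=%d, w=%.4g]: %s\n",
              ifelse(is.na(x$rank), "?", x$rank), length(x$members),
              x$weight_sum, paste(x$members, collapse = " ")))
  invisible(x)
}

#' Rank cliques into the merge queue
#'
#' Sorts (deduplicated) cliques descending by their edge-weight sums; ties
#' are broken by larger member count, then by the lexicographically smallest
#' member id, so the queue is deterministic.
#'
#' @param cliques list of `motif_clique` (deduplicated).
#' @return The same cliques in ranked order.
#' @export
sort_cliques <- function(cliques) {
  if (length(cliques) == 0L) return(list())
  w <- vapply(cliques, `[[`, numeric(1), "weight_sum")
  sz <- vapply(cliques, function(cl) length(cl$members), integer(1))
  first <- vapply(cliques, function(cl) cl$members[1L], character(1))
  cliques[order(-w, -sz, first, method = "radix")]
}

#' Clique-into-cluster merge test
#'
#' `C_j` merges into a cluster `C_i` iff (i) the overlap ratio
#' `|C_i intersect C_j| / |C_j|` is at least `alpha`, and (ii) the fraction
#' of `C_j`'s nodes that lie in the cluster or have at least one graph edge
#' to a cluster member is at least `beta`.  A `C_j` node inside the cluster
#' counts toward (ii), so the adjacency ratio never falls below the overlap
#' ratio, consistent with the constraint `alpha <= beta`.
#'
#' @param current a `motif_cluster` (or character vector of member ids).
#' @param cj a `motif_clique` (or character vector of member ids); nonempty.
#' @param g the `similarity_graph`.
#' @param cfg a [climp_config()].
#' @return `TRUE` or `FALSE`.
#' @export
can_merge <- function(current, cj, g, cfg) {
  cur <- if (is.character(current)) current else current$members
  cjm <- if (is.character(cj)) cj else cj$members
  stopifnot(length(cjm) > 0L)
  mem <- logical(length(g$nodes))
  mem[node_index(g, cur)] <- TRUE
  cj_idx <- node_index(g, cjm)
  .can_merge_idx(mem, cj_idx, g, cfg$alpha, cfg$beta)
}

.can_merge_idx <- function(mem, cj_idx, g, alpha, beta) {
  inside <- mem[cj_idx]
  if (sum(inside) / length(cj_idx) < alpha) return(FALSE)
  ok <- inside
  for (k in which(!inside)) {
    if (any(mem[g$adj[[cj_idx[k]]]])) ok[k] <- TRUE
  }
  sum(ok) / length(cj_idx) >= beta
}

#' Merge ranked cliques into clusters (Step 2)
#'
#' Reference semantics are the sequential nested loops of the pseudo-code:
#' scanning the ranked queue, each still-unmerged clique seeds a cluster,
#' and every later unmerged clique is merged into it (and labeled merged)
#' iff [can_merge()] holds against the cluster's current accumulated member
#' set.  Every clique ends up in exactly one cluster.
#'
#' @param queue ranked list of `motif_clique` from [sort_cliques()].
#' @inheritParams can_merge
#' @return List of `motif_cluster` in seeding order (clusters may still
#'   share nodes until [remove_redundant_nodes()]).
#' @export
merge_cliques <- function(queue, g, cfg) {
  n <- length(queue)
  if (n == 0L) return(list())
  idx_list <- lapply(queue, function(cl) node_index(g, cl$members))
  merged <- logical(n)
  out <- vector("list", n)
  n_out <- 0L
  nn <- length(g$nodes)
  for (i in seq_len(n)) {
    if (merged[i]) next
    merged[i] <- TRUE
    mem <- logical(nn)
    mem[idx_list[[i]]] <- TRUE
    test_mem <- if (cfg$merge_target == "seed") mem else NULL
    src <- i
    if (i < n) {
      for (j in (i + 1L):n) {
        if (merged[j]) next
        tm <- if (is.null(test_mem)) mem else test_mem
        if (.can_merge_idx(tm, idx_list[[j]], g, cfg$alpha, cfg$beta)) {
          mem[idx_list[[j]]] <- TRUE
          merged[j] <- TRUE
          src <- c(src, j)
        }
      }
    }
    n_out <- n_out + 1L
    out[[n_out]] <- new_cluster(g$nodes[mem], src)
  }
  out[seq_len(n_out)]
}

#' Delete redundant nodes (Step 3)
#'
#' Clusters produced by [merge_cliques()] may share nodes through
#' overlapping cliques.  For each node present in more than one cluster, its
#' incident edge-weight sum within each cluster's induced subgraph is
#' computed, and the node is kept only in the cluster where that sum is
#' maximal (ties go to the earlier, higher-ranked cluster).  Clusters
#' emptied by the deletions are dropped.  The result is a disjoint family;
#' the operation is idempotent.
#'
#' @param clusters list of `motif_cluster`.
#' @param g the `similarity_graph`.
#' @return List of pairwise-disjoint `motif_cluster`.
#' @export
remove_redundant_nodes <- function(clusters, g) {
  k <- length(clusters)
  if (k == 0L) return(list())
  nn <- length(g$nodes)
  idx_list <- lapply(clusters, function(cl) node_index(g, cl$members))
  count <- tabulate(unlist(idx_list), nbins = nn)
  dup <- which(count > 1L)
  if (length(dup) > 0L) {
    mems <- lapply(idx_list, function(ix) {
      m <- logical(nn); m[ix] <- TRUE; m
    })
    # incident sums are computed against the clusters as given (simultaneous
    # decision), then all deletions are applied
    drop_from <- vector("list", k)
    for (u in dup) {
      holders <- which(vapply(mems, function(m) m[u], logical(1)))
      sums <- vapply(holders, function(ci) {
        sum(g$wts[[u]][mems[[ci]][g$adj[[u]]]])
      }, numeric(1))
      best <- holders[which.max(sums)]   # first max -> earlier cluster
      for (ci in setdiff(holders, best))
        drop_from[[ci]] <- c(drop_from[[ci]], u)
    }
    for (ci in seq_len(k)) {
      if (length(drop_from[[ci]]) > 0L)
        idx_list[[ci]] <- setdiff(idx_list[[ci]], drop_from[[ci]])
    }
  }
  keep <- lengths(idx_list) > 0L
  mapply(function(ix, cl) new_cluster(g$nodes[ix], cl$source_cliques),
         idx_list[keep], clusters[keep], SIMPLIFY = FALSE)
}

#' Rank clusters by edge-weight sum (Step 4)
#'
#' Recomputes each cluster's induced edge-weight sum on the post-deletion
#' member sets and sorts descending; ties are broken by larger size, then by
#' smallest member id.  Ranks 1..m are assigned.
#'
#' @inheritParams remove_redundant_nodes
#' @return List of `motif_cluster` with `rank` and `weight_sum` filled in,
#'   ordered by rank.
#' @export
rank_clusters <- function(clusters, g) {
  if (length(clusters) == 0L) return(list())
  w <- vapply(clusters, function(cl)
    induced_wsum(g, node_index(g, cl$members)), numeric(1))
  sz <- vapply(clusters, function(cl) length(cl$members), integer(1))
  first <- vapply(clusters, function(cl) cl$members[1L], character(1))
  ord <- order(-w, -sz, first, method = "radix")
  out <- clusters[ord]
  for (r in seq_along(out)) {
    out[[r]]$rank <- r
    out[[r]]$weight_sum <- w[ord[r]]
  }
  structure(out, class = "climp_clusters")
}

#' Cluster a similarity graph with CLIMP
#'
#' Full pipeline: per-node greedy maximal cliques (Step 1), deduplication
#' and descending sort by edge-weight sum, merge under the alpha/beta rule
#' (Step 2), redundant-node deletion (Step 3), and cluster ranking (Step 4).
#' Deterministic for fixed input and configuration, independent of
#' `cfg$workers`.
#'
#' @param g a `similarity_graph`.
#' @param cfg a [climp_config()].
#' @return A `climp_clusters` list of disjoint ranked `motif_cluster`s
#'   covering every node of `g` (isolated nodes become singleton clusters).
#' @examples
#' e <- data.frame(from = c("a", "a", "b", "x", "x", "y"),
#'                 to   = c("b", "c", "c", "y", "z", "z"),
#'                 weight = 0.9)
#' climp(similarity_graph(e), climp_config(0.5, 0.5))
#' @export
climp <- function(g, cfg = climp_config()) {
  stopifnot(inherits(g, "similarity_graph"), inherits(cfg, "climp_config"))
  cliques <- find_all_cliques(g, workers = cfg$workers)
  queue <- sort_cliques(dedupe_cliques(cliques))
  clusters <- merge_cliques(queue, g, cfg)
  clusters <- remove_redundant_nodes(clusters, g)
  rank_clusters(clusters, g)
}

#' @export
print.climp_clusters <- function(x, ...) {
  cat(sprintf("climp_clusters: %d clusters over %d nodes\n", length(x),
              sum(vapply(x, function(cl) length(cl$members), integer(1)))))
  for (cl in utils::head(x, 10L)) print(cl)
  if (length(x) > 10L) cat(sprintf("... and %d more\n", length(x) - 10L))
  invisible(x)
}

#' Node-to-cluster assignment vector
#'
#' @param clusters a `climp_clusters` list (or any list of clusters).
#' @param min_size drop clusters smaller than this before assigning
#'   (e.g. `2` to ignore singleton clusters).
#' @return Named character vector mapping node id to cluster rank label.
#' @export
cluster_assignments <- function(clusters, min_size = 1L) {
  keep <- vapply(clusters, function(cl) length(cl$members) >= min_size,
                 logical(1))
  clusters <- clusters[keep]
  if (length(clusters) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- unlist(lapply(clusters, `[[`, "members"))
  lab <- rep(vapply(clusters, function(cl) as.character(cl$rank), character(1)),
             vapply(clusters, function(cl) length(cl$members), integer(1)))
  stats::setNames(lab, ids)
}

#' Read / write cluster files
#'
#' One cluster per line in rank order, members tab-separated
#' (MCL-compatible).
#'
#' @param clusters list of clusters (written in list order = rank order).
#' @param path file path.
#' @return `write_clusters` returns `path` invisibly; `read_clusters`
#'   returns a `climp_clusters` list (ranks from line order, weight sums
#'   unknown).
#' @export
write_clusters <- function(clusters, path) {
  lines <- vapply(clusters, function(cl) paste(cl$members, collapse = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (r in seq_along(lines)) {
    mem <- strsplit(lines[[r]], "\t", fixed = TRUE)[[1]]
    out[[r]] <- new_cluster(mem, integer(0), rank = r)
  }
  structure(out, class = "climp_clusters")
}
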