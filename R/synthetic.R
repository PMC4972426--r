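# Synthetic inputs: the sub-motif splitting procedure used to benchmark
# motif clustering, random motif families standing in for curated profiles,
# and planted-partition weighted graphs with known ground truth.  All
# generators take explicit seeds and leave the global RNG untouched.

#' Split a motif into sub-motif pairs
#'
#' For each `k = 1 .. floor(n/2)` the motif's `n` sites are randomly divided
#' into two disjoint subsets of sizes `k` and `n - k`, yielding exactly
#' `2 * floor(n/2)` sub-motifs.  The full site set is reused across the
#' different `k` (sub-motifs of different splits overlap), and every
#' sub-motif carries its parent's id as the truth label for evaluation.
#'
#' @param m a `motif` with at least 2 sites.
#' @param seed integer RNG seed.
#' @return List of `motif` objects with ids `<parent>|k<k>a` / `<parent>|k<k>b`
#'   and a `parent` field; see [split_truth_labels()].
#' @export
split_motif <- function(m, seed) {
  stopifnot(inherits(m, "motif"))
  if (is.null(m$sites) || m$n_sites < 2L)
    stop("split_motif needs a motif with >= 2 sites", call. = FALSE)
  n <- m$n_sites
  withr::with_seed(seed, {
    out <- list()
    for (k in seq_len(n %/% 2L)) {
      idx <- sort(sample.int(n, k))
      a <- motif(sprintf("%s|k%da", m$id, k), m$sites[idx])
      b <- motif(sprintf("%s|k%db", m$id, k), m$sites[-idx])
      a$parent <- m$id
      b$parent <- m$id
      out[[length(out) + 1L]] <- a
      out[[length(out) + 1L]] <- b
    }
    out
  })
}

#' Truth labels for a list of sub-motifs
#'
#' @param submotifs list of motifs carrying a `parent` field (from
#'   [split_motif()]).
#' @return Named character vector: sub-motif id -> parent motif id.
#' @export
split_truth_labels <- function(submotifs) {
  ids <- vapply(submotifs, `[[`, character(1), "id")
  par <- vapply(submotifs, function(m)
    if (is.null(m$parent)) NA_character_ else m$parent, character(1))
  if (anyNA(par))
    stop("sub-motif(s) without a parent tag", call. = FALSE)
  stats::setNames(par, ids)
}

#' Random motif family generator
#'
#' Each motif gets an independent uniform-random consensus; every site
#' copies the consensus base with probability `conservation` and otherwise
#' a uniformly chosen different base.  Stands in for curated binding-site
#' profiles in desk-scale benchmarks.
#'
#' @param n_motifs,length,sites_per_motif positive integers.
#' @param conservation per-position probability of matching the consensus,
#'   in `(0, 1]`.
#' @param seed integer RNG seed.
#' @param prefix id prefix (ids are `<prefix>001`, ...).
#' @return List of `motif` objects, each with a `consensus` field.
#' @export
random_motif_family <- function(n_motifs, length, sites_per_motif,
                                conservation = 0.9, seed = 1L,
                                prefix = "M") {
  stopifnot(n_motifs >= 1, length >= 1, sites_per_motif >= 1)
  if (!is.numeric(conservation) || conservation <= 0 || conservation > 1)
    stop("conservation must be in (0, 1]", call. = FALSE)
  withr::with_seed(seed, {
    lapply(seq_len(n_motifs), function(i) {
      consensus <- sample(DNA_BASES, length, replace = TRUE)
      sites <- vapply(seq_len(sites_per_motif), function(s) {
        keep <- stats::runif(length) <= conservation
        b <- consensus
        if (any(!keep)) {
          b[!keep] <- vapply(consensus[!keep], function(cb)
            sample(setdiff(DNA_BASES, cb), 1L), character(1))
        }
        paste(b, collapse = "")
      }, character(1))
      m <- motif(sprintf("%s%03d", prefix, i), sites)
      m$consensus <- paste(consensus, collapse = "")
      m
    })
  })
}

#' Planted-partition similarity graph
#'
#' Samples an undirected weighted graph with known blocks: each
#' within-block pair gets an edge with probability `p_within` and weight
#' uniform on `w_within`; each between-block pair with probability
#' `p_between` and weight uniform on `w_between`.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_within,p_between edge probabilities in `[0, 1]`.
#' @param w_within,w_between length-2 weight ranges within `(0, 1]`.
#' @param seed integer RNG seed.
#' @return List with `graph` (a `similarity_graph` over all nodes, isolated
#'   ones included) and `truth` (named vector node id -> block label).
#' @export
planted_partition_graph <- function(block_sizes, p_within = 0.9,
                                    p_between = 0.02,
                                    w_within = c(0.6, 1),
                                    w_between = c(0.4, 0.6), seed = 1L) {
  stopifnot(length(block_sizes) >= 1, all(block_sizes >= 1),
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            length(w_within) == 2L, length(w_between) == 2L,
            all(c(w_within, w_between) > 0), all(c(w_within, w_between) <= 1))
  blocks <- rep(seq_along(block_sizes), block_sizes)
  n <- length(blocks)
  nodes <- sprintf("b%02d_n%03d", blocks, unlist(lapply(block_sizes, seq_len)))
  truth <- stats::setNames(sprintf("b%02d", blocks), nodes)
  if (n >= 2L) {
    pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    same <- blocks[pair_i] == blocks[pair_j]
    withr::with_seed(seed, {
      p <- ifelse(same, p_within, p_between)
      on <- stats::runif(length(p)) < p
      lo <- ifelse(same, w_within[1], w_between[1])[on]
      hi <- ifelse(same, w_within[2], w_between[2])[on]
      w <- stats::runif(sum(on), lo, hi)
    })
    edges <- data.frame(from = nodes[pair_i[on]], to = nodes[pair_j[on]],
                        weight = w, stringsAsFactors = FALSE)
  } else {
    edges <- NULL
  }
  list(graph = similarity_graph(edges, nodes = nodes, gamma = 0),
       truth = truth)
}
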