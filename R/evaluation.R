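# Clustering quality: contingency tables, the Adjusted Rand Index,
# cluster/motif correspondence fractions, and cumulative recovery curves
# over ranked clusters.

#' Contingency table of two partitions
#'
#' `counts[i, j]` is the number of objects carrying truth label `i` and
#' predicted label `j`.
#'
#' @param truth,pred named character vectors mapping node id to label.
#' @param drop if `TRUE`, nodes present in only one of the two partitions
#'   are silently dropped; otherwise a universe mismatch is an error naming
#'   the offending ids.
#' @return An object of class `contingency_table`: list with `counts`
#'   (matrix), `row_sums`, `col_sums`, `N`.
#' @export
contingency <- function(truth, pred, drop = FALSE) {
  stopifnot(!is.null(names(truth)), !is.null(names(pred)))
  only_t <- setdiff(names(truth), names(pred))
  only_p <- setdiff(names(pred), names(truth))
  if ((length(only_t) > 0L || length(only_p) > 0L) && !drop) {
    stop("partition universes differ; offending ids: ",
         paste(utils::head(c(only_t, only_p), 10L), collapse = ", "),
         if (length(c(only_t, only_p)) > 10L) ", ..." else "",
         call. = FALSE)
  }
  ids <- intersect(names(truth), names(pred))
  if (length(ids) == 0L)
    stop("no common objects between the two partitions", call. = FALSE)
  counts <- unclass(table(truth = as.character(truth[ids]),
                          pred = as.character(pred[ids])))
  structure(list(counts = counts,
                 row_sums = rowSums(counts),
                 col_sums = colSums(counts),
                 N = length(ids)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: %d x %d, N = %d\n",
              nrow(x$counts), ncol(x$counts), x$N))
  invisible(x)
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table `n_ij`:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - \sum_i \binom{n_{i.}}{2}
#'   \sum_j \binom{n_{.j}}{2} / \binom{N}{2}}
#'   {\frac{1}{2}\left[\sum_i \binom{n_{i.}}{2} + \sum_j \binom{n_{.j}}{2}\right]
#'   - \sum_i \binom{n_{i.}}{2} \sum_j \binom{n_{.j}}{2} / \binom{N}{2}}}
#' Identical partitions give 1; the all-singletons vs one-cluster pair gives
#' 0.  When the denominator vanishes (both partitions trivial) the value is
#' 1 if the numerator is 0 and 0 otherwise — the formula is undefined there
#' and this convention is ours.
#'
#' @param x a `contingency_table`, a plain counts matrix, or a named truth
#'   vector (then `pred` must be given).
#' @param pred optional named prediction vector when `x` is a truth vector.
#' @param drop passed to [contingency()] when building from two vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(x, pred = NULL, drop = FALSE) {
  if (!is.null(pred)) x <- contingency(x, pred, drop = drop)
  if (inherits(x, "contingency_table")) {
    counts <- x$counts
  } else {
    counts <- as.matrix(x)
  }
  N <- sum(counts)
  if (N < 2) stop("ARI needs at least 2 objects", call. = FALSE)
  sum_ij <- sum(choose(counts, 2))
  a <- sum(choose(rowSums(counts), 2))
  b <- sum(choose(colSums(counts), 2))
  expected <- a * b / choose(N, 2)
  num <- sum_ij - expected
  den <- (a + b) / 2 - expected
  if (den == 0) return(if (num == 0) 1 else 0)
  num / den
}

#' Cluster/motif correspondence fractions
#'
#' In a perfect clustering every cluster contains exactly one true motif
#' and every motif lands in exactly one cluster.  Returns both fractions.
#'
#' @param truth named character vector: node id -> true motif label, covering
#'   every clustered node.
#' @param clusters a `climp_clusters` list (or any list with `$members`).
#' @return List with `frac_single_motif_clusters` (fraction of clusters
#'   whose members carry exactly one truth label) and
#'   `frac_single_cluster_motifs` (fraction of truth labels confined to one
#'   cluster).
#' @export
correspondence_stats <- function(truth, clusters) {
  if (length(clusters) == 0L)
    stop("empty cluster list", call. = FALSE)
  labels_per_cluster <- lapply(clusters, function(cl) {
    lab <- truth[cl$members]
    if (anyNA(lab))
      stop("truth labels missing for: ",
           paste(utils::head(cl$members[is.na(lab)], 5L), collapse = ", "),
           call. = FALSE)
    unique(as.character(lab))
  })
  frac_single <- mean(lengths(labels_per_cluster) == 1L)
  all_labels <- unique(unlist(labels_per_cluster))
  n_clusters_per_label <- vapply(all_labels, function(l)
    sum(vapply(labels_per_cluster, function(ls) l %in% ls, logical(1))),
    integer(1))
  list(frac_single_motif_clusters = frac_single,
       frac_single_cluster_motifs = mean(n_clusters_per_label == 1L))
}

#' Cumulative recovery curve over ranked clusters
#'
#' For each rank `r`, counts the distinct known items appearing anywhere in
#' clusters `1..r` and the cumulative number of member nodes; both curves
#' are non-decreasing.
#'
#' @param clusters ranked cluster list.
#' @param known character vector of node ids flagged as known motifs.
#' @return Data frame with columns `rank`, `known_recovered`,
#'   `cumulative_members`.
#' @export
recovery_curve <- function(clusters, known) {
  known <- unique(as.character(known))
  seen <- character(0)
  nr <- length(clusters)
  rec <- integer(nr)
  cum <- integer(nr)
  total <- 0L
  for (r in seq_len(nr)) {
    mem <- clusters[[r]]$members
    total <- total + length(mem)
    seen <- union(seen, intersect(mem, known))
    rec[r] <- length(seen)
    cum[r] <- total
  }
  data.frame(rank = seq_len(nr), known_recovered = rec,
             cumulative_members = cum)
}

#' Read / write truth-label files
#'
#' Two-column tab-separated text: node id, label.
#'
#' @param path file path.
#' @param labels named character vector (names = node ids).
#' @return `read_truth_labels` returns a named character vector.
#' @export
read_truth_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) < 2L)
    stop("truth file must have 2 tab-separated columns", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_truth_labels
#' @export
write_truth_labels <- function(labels, path) {
  writeLines(paste(names(labels), as.character(labels), sep = "\t"), path)
  invisible(path)
}
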