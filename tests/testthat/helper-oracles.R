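# Independent oracles and fixture generators.  Everything here is written
# from the definitions with plain loops, deliberately not sharing code with
# the package internals it checks.

DNA <- c("A", "C", "G", "T")

# seeded Erdos-Renyi weighted graph as a similarity_graph
rand_graph <- function(n, p, wrange = c(0.4, 1), seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%03d", seq_len(n))
    from <- character(0); to <- character(0); w <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j])
          w <- c(w, runif(1, wrange[1], wrange[2]))
        }
      }
    }
    similarity_graph(data.frame(from = from, to = to, weight = w),
                     nodes = nodes, gamma = 0)
  })
}

adjacent_oracle <- function(g, u, v) {
  e <- graph_edges(g)
  any((e$from == u & e$to == v) | (e$from == v & e$to == u))
}

is_clique_oracle <- function(g, members) {
  if (length(members) <= 1) return(TRUE)
  for (i in seq_len(length(members) - 1))
    for (j in (i + 1):length(members))
      if (!adjacent_oracle(g, members[i], members[j])) return(FALSE)
  TRUE
}

# maximal within N(v): no node of N(v) outside the set is adjacent to all
# of its members
is_maximal_in_neighborhood_oracle <- function(g, v, members) {
  nv <- c(v, graph_neighbors(g, v))
  outside <- setdiff(nv, members)
  for (u in outside) {
    if (all(vapply(members, function(m) adjacent_oracle(g, u, m), logical(1))))
      return(FALSE)
  }
  TRUE
}

# brute-force induced-subgraph edge table
induced_edges_oracle <- function(g, members) {
  e <- graph_edges(g)
  e[e$from %in% members & e$to %in% members, , drop = FALSE]
}

# ARI by direct pair counting over all object pairs (no contingency table)
ari_pairs_oracle <- function(truth, pred) {
  ids <- names(truth)
  stopifnot(setequal(ids, names(pred)))
  N <- length(ids)
  a <- 0; ab <- 0; ac <- 0  # together-in-both, together-in-truth, -in-pred
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      st <- truth[[ids[i]]] == truth[[ids[j]]]
      sp <- pred[[ids[i]]] == pred[[ids[j]]]
      if (st) ab <- ab + 1
      if (sp) ac <- ac + 1
      if (st && sp) a <- a + 1
    }
  }
  total <- N * (N - 1) / 2
  expected <- ab * ac / total
  den <- (ab + ac) / 2 - expected
  if (den == 0) return(if (a - expected == 0) 1 else 0)
  (a - expected) / den
}

random_partition <- function(N, k, seed, prefix = "c") {
  withr::with_seed(seed, {
    stats::setNames(sprintf("%s%d", prefix, sample.int(k, N, replace = TRUE)),
                    sprintf("o%02d", seq_len(N)))
  })
}

random_test_motif <- function(id, L, n_sites, seed) {
  withr::with_seed(seed, {
    motif(id, vapply(seq_len(n_sites), function(i)
      paste(sample(DNA, L, replace = TRUE), collapse = ""), character(1)))
  })
}

# Brute-force implementation of the documented similarity contract,
# written with explicit loops: smoothed frequencies, log-odds, per-column
# IC; raw(alignment) = sum of column-pair scores / min(L1, L2); max over
# ungapped offsets and both orientations of m2; self-normalized, clipped
# to [-1, 1], floored at 0.
spic_oracle <- function(m1, m2, min_overlap = 4, background = rep(0.25, 4),
                        pseudocount = 0.25) {
  prof <- function(m) {
    counts <- matrix(0, 4, m$length, dimnames = list(DNA, NULL))
    for (s in m$sites) {
      ch <- strsplit(s, "")[[1]]
      for (i in seq_along(ch)) counts[ch[i], i] <- counts[ch[i], i] + 1
    }
    f <- matrix(0, 4, m$length)
    for (i in seq_len(m$length))
      f[, i] <- (counts[, i] + pseudocount) / (sum(counts[, i]) + 4 * pseudocount)
    pwm <- log2(f / background)
    ic <- numeric(m$length)
    for (i in seq_len(m$length)) ic[i] <- 2 + sum(f[, i] * log2(f[, i]))
    list(f = f, pwm = pwm, ic = ic, L = m$length)
  }
  raw_max <- function(p1, p2) {
    best <- -Inf
    for (o in seq(-(p2$L - min_overlap), p1$L - min_overlap)) {
      lo <- max(1, 1 + o); hi <- min(p1$L, p2$L + o)
      if (hi - lo + 1 < min_overlap) next
      s <- 0
      for (i in lo:hi) {
        j <- i - o
        s <- s + 0.5 * (p1$ic[i] * sum(p2$f[, j] * p1$pwm[, i]) +
                        p2$ic[j] * sum(p1$f[, i] * p2$pwm[, j]))
      }
      s <- s / min(p1$L, p2$L)
      if (s > best) best <- s
    }
    best
  }
  rc <- function(m) {
    motif(paste0(m$id, "rc"), vapply(m$sites, function(s)
      paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = ""),
      character(1), USE.NAMES = FALSE))
  }
  p1 <- prof(m1); p2 <- prof(m2)
  raw12 <- max(raw_max(p1, p2), raw_max(p1, prof(rc(m2))))
  self <- function(m, p) max(raw_max(p, p), raw_max(p, prof(rc(m))))
  s1 <- self(m1, p1); s2 <- self(m2, p2)
  if (!(s1 > 0) || !(s2 > 0)) return(0)
  min(max(raw12 / sqrt(s1 * s2), 0), 1)
}

# connected-components partition of a similarity_graph (baseline clusterer)
components_oracle <- function(g) {
  nodes <- graph_nodes(g)
  lab <- stats::setNames(seq_along(nodes), nodes)
  e <- graph_edges(g)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      a <- e$from[k]; b <- e$to[k]
      m <- min(lab[[a]], lab[[b]])
      if (lab[[a]] != m || lab[[b]] != m) {
        lab[[a]] <- m; lab[[b]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(as.character(lab), names(lab))
}
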