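# Steps 2-4: clique ranking, merging, redundancy removal, cluster ranking

mk_clique <- function(members, w = 0) climpr:::new_clique(members[1], members, w)

test_that("climp_config validates its fields", {
  cfg <- climp_config(0.5, 0.5, 0.6)
  expect_s3_class(cfg, "climp_config")
  expect_error(climp_config(alpha = 0.9, beta = 0.1), "alpha must be <= beta")
  expect_error(climp_config(alpha = 0), "alpha")
  expect_error(climp_config(gamma = 1.5), "gamma")
})

test_that("sort_cliques orders by weight sum, then size, then member id", {
  cl <- list(mk_clique(c("a", "b"), 2.1), mk_clique(c("c", "d", "e"), 3.0),
             mk_clique("f", 0))
  expect_equal(vapply(sort_cliques(cl), `[[`, numeric(1), "weight_sum"),
               c(3.0, 2.1, 0))
  # equal sums: the size-3 clique first
  cl <- list(mk_clique(c("x", "y"), 1.0), mk_clique(c("a", "b", "c"), 1.0))
  expect_equal(lengths(lapply(sort_cliques(cl), `[[`, "members")), c(3L, 2L))
  # equal sums and sizes: smallest member id first
  cl <- list(mk_clique(c("m", "n"), 1.0), mk_clique(c("a", "z"), 1.0))
  expect_equal(sort_cliques(cl)[[1]]$members[1], "a")
  expect_equal(sort_cliques(list()), list())
})

test_that("can_merge evaluates the alpha and beta ratios", {
  # cluster {1,2,3,4}, clique {3,4,5}; 5 has an edge to 1
  e <- data.frame(from = c("1", "1", "2", "3", "1"),
                  to = c("2", "3", "4", "4", "5"),
                  weight = 0.9)
  g <- similarity_graph(e)
  cfg <- climp_config(0.5, 0.5)
  cur <- climpr:::new_cluster(c("1", "2", "3", "4"), 1L)
  cj <- mk_clique(c("3", "4", "5"))
  expect_true(can_merge(cur, cj, g, cfg))          # overlap 2/3, adjacency 3/3
  expect_false(can_merge(cur, cj, g, climp_config(0.7, 0.7)))  # 2/3 < 0.7
  # subset clique: both ratios 1
  expect_true(can_merge(cur, mk_clique(c("3", "4")), g, climp_config(1, 1)))
  # disjoint with no edges: both ratios 0
  g2 <- similarity_graph(e, nodes = c("8", "9"))
  expect_false(can_merge(cur, mk_clique(c("8", "9")), g2, cfg))
})

test_that("merge_cliques follows the sequential queue semantics", {
  # hand-executed trace: queue [{1,2,3,4}, {3,4,5}, {5,6}], alpha=beta=0.5.
  # {3,4,5} merges into the seed cluster (overlap 2/3); then {5,6} is
  # tested against the ACCUMULATED cluster {1..5}: overlap 1/2 >= 0.5,
  # adjacency 2/2 -> one cluster {1..6}.
  e <- data.frame(from = c("1", "1", "1", "2", "2", "3", "3", "4", "5"),
                  to = c("2", "3", "4", "3", "4", "4", "5", "5", "6"),
                  weight = 0.9)
  g <- similarity_graph(e)
  queue <- list(mk_clique(c("1", "2", "3", "4"), 5.4),
                mk_clique(c("3", "4", "5"), 2.7),
                mk_clique(c("5", "6"), 0.9))
  out <- merge_cliques(queue, g, climp_config(0.5, 0.5))
  expect_equal(length(out), 1L)
  expect_setequal(out[[1]]$members, as.character(1:6))
  expect_equal(out[[1]]$source_cliques, 1:3)

  # against the seed clique only, {5,6} fails the overlap test (0/3... 1/3)
  out_seed <- merge_cliques(queue, g, climp_config(0.5, 0.5,
                                                   merge_target = "seed"))
  expect_equal(length(out_seed), 2L)
  expect_setequal(out_seed[[1]]$members, as.character(1:5))
  expect_setequal(out_seed[[2]]$members, c("5", "6"))
})

test_that("mutually non-mergeable cliques become one cluster each, in order", {
  g <- similarity_graph(data.frame(from = c("a", "x"), to = c("b", "y"),
                                   weight = c(0.9, 0.8)))
  queue <- sort_cliques(list(mk_clique(c("a", "b"), 0.9),
                             mk_clique(c("x", "y"), 0.8)))
  out <- merge_cliques(queue, g, climp_config(0.5, 0.5))
  expect_equal(length(out), 2L)
  expect_setequal(out[[1]]$members, c("a", "b"))
  expect_setequal(out[[2]]$members, c("x", "y"))
})

test_that("remove_redundant_nodes keeps each node where its incident sum is maximal", {
  # x belongs to A = {a1, a2, x} and B = {b1, x}; incident sums 1.5 vs 0.9
  e <- data.frame(from = c("a1", "a1", "a2", "b1"),
                  to = c("a2", "x", "x", "x"),
                  weight = c(0.9, 0.7, 0.8, 0.9))
  g <- similarity_graph(e)
  A <- climpr:::new_cluster(c("a1", "a2", "x"), 1L)
  B <- climpr:::new_cluster(c("b1", "x"), 2L)
  out <- remove_redundant_nodes(list(A, B), g)
  expect_setequal(out[[1]]$members, c("a1", "a2", "x"))
  expect_setequal(out[[2]]$members, "b1")

  # equal sums: kept in the higher-ranked (earlier) cluster
  e2 <- data.frame(from = c("a1", "b1"), to = c("x", "x"),
                   weight = c(0.8, 0.8))
  g2 <- similarity_graph(e2)
  out2 <- remove_redundant_nodes(list(climpr:::new_cluster(c("a1", "x"), 1L),
                                      climpr:::new_cluster(c("b1", "x"), 2L)),
                                 g2)
  expect_setequal(out2[[1]]$members, c("a1", "x"))
  expect_setequal(out2[[2]]$members, "b1")

  # already-disjoint clusters unchanged; idempotence
  expect_equal(lapply(remove_redundant_nodes(out, g), `[[`, "members"),
               lapply(out, `[[`, "members"))

  # a cluster emptied by deletions is dropped
  out3 <- remove_redundant_nodes(list(climpr:::new_cluster(c("a1", "x"), 1L),
                                      climpr:::new_cluster("x", 2L)), g2)
  expect_equal(length(out3), 1L)
})

test_that("rank_clusters recomputes sums and orders deterministically", {
  e <- data.frame(from = c("a", "c", "c", "d", "f"),
                  to = c("b", "d", "e", "e", "g"),
                  weight = c(0.5, 0.9, 0.9, 0.9, 1.0))
  g <- similarity_graph(e)
  cl <- list(climpr:::new_cluster(c("a", "b"), 1L),
             climpr:::new_cluster(c("c", "d", "e"), 2L),
             climpr:::new_cluster(c("f", "g"), 3L))
  out <- rank_clusters(cl, g)
  expect_equal(vapply(out, `[[`, numeric(1), "weight_sum"), c(2.7, 1.0, 0.5))
  expect_equal(vapply(out, `[[`, integer(1), "rank"), 1:3)
  # single cluster -> rank 1
  expect_equal(rank_clusters(list(cl[[1]]), g)[[1]]$rank, 1L)
  # equal sums, different sizes: larger first
  e2 <- data.frame(from = c("a", "c", "d"), to = c("b", "d", "e"),
                   weight = c(1.0, 0.5, 0.5))
  g2 <- similarity_graph(e2)
  out2 <- rank_clusters(list(climpr:::new_cluster(c("a", "b"), 1L),
                             climpr:::new_cluster(c("c", "d", "e"), 2L)), g2)
  expect_equal(length(out2[[1]]$members), 3L)
})

test_that("climp clusters two disjoint triangles exactly, and empty graphs", {
  e <- data.frame(from = c("a", "a", "b", "x", "x", "y"),
                  to = c("b", "c", "c", "y", "z", "z"),
                  weight = c(0.9, 0.9, 0.9, 0.8, 0.8, 0.8))
  out <- climp(similarity_graph(e), climp_config(0.5, 0.5))
  expect_equal(length(out), 2L)
  expect_setequal(out[[1]]$members, c("a", "b", "c"))
  expect_setequal(out[[2]]$members, c("x", "y", "z"))
  expect_equal(climp(similarity_graph(NULL), climp_config()), list())
})

test_that("pipeline properties on random graphs: disjoint, conservative, monotone, deterministic", {
  for (seed in 1:10) {
    g <- rand_graph(30, 0.25, seed = seed * 13)
    out <- climp(g, climp_config(0.5, 0.5, workers = 1))
    members <- unlist(lapply(out, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0L)          # pairwise disjoint
    expect_setequal(members, graph_nodes(g))          # node conservation
    w <- vapply(out, `[[`, numeric(1), "weight_sum")
    expect_true(all(diff(w) <= 1e-12))                # monotone ranking
    expect_equal(vapply(out, `[[`, integer(1), "rank"), seq_along(out))
    for (wk in c(2, 4))
      expect_identical(climp(g, climp_config(0.5, 0.5, workers = wk)), out)
  }
})

test_that("alpha = beta = 1 merges only fully contained, fully adjacent cliques", {
  # triangle abc plus pendant clique {c, d}: overlap 1/2 < 1 -> no merge;
  # redundancy removal then keeps c in the triangle (incident sum 1.8 vs
  # 0.9), leaving {a, b, c} and the residue {d}
  e <- data.frame(from = c("a", "a", "b", "c"), to = c("b", "c", "c", "d"),
                  weight = 0.9)
  out <- climp(similarity_graph(e), climp_config(1, 1))
  expect_equal(length(out), 2L)
  sizes <- sort(lengths(lapply(out, `[[`, "members")))
  expect_equal(sizes, c(1L, 3L))
})

test_that("cluster file round-trip and assignments", {
  e <- data.frame(from = c("a", "x"), to = c("b", "y"), weight = c(0.9, 0.8))
  out <- climp(similarity_graph(e), climp_config())
  path <- withr::local_tempfile()
  write_clusters(out, path)
  back <- read_clusters(path)
  expect_equal(lapply(back, `[[`, "members"), lapply(out, `[[`, "members"))
  asg <- cluster_assignments(out)
  expect_equal(unname(asg[c("a", "b")]), c("1", "1"))
  expect_equal(unname(asg[c("x", "y")]), c("2", "2"))
  expect_equal(length(cluster_assignments(out, min_size = 3L)), 0L)
})
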