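# Minimal cost paths: Dijkstra optimality against exhaustive search,
# iterative edge removal, Menger bound, and clustering semantics.

test_that("edge costs are the thickness ratio in (0, 1]", {
  expect_equal(edge_cost(6, 6), 1)
  expect_equal(edge_cost(6, 12), 0.5)
  expect_equal(edge_cost(3, 12), 0.25)
  expect_error(edge_cost(7, 6))
})

test_that("the cheaper branch of a diamond is selected", {
  # EXT -> 1 -> 3 costs 0.5 + 0.5 = 1.0; EXT -> 2 -> 3 costs 0.4 + 0.9 = 1.3
  cv <- 2
  e <- data.frame(from = c(0, 1, 0, 2), to = c(1, 3, 2, 3),
                  cvmax = cv / c(0.5, 0.5, 0.4, 0.9))
  g <- toy_graph(e, target = 3)
  m <- minimal_cost_path(g, cv)
  expect_equal(m$cells, c(1, 3))
  expect_equal(m$total_cost, 1.0)
})

test_that("a single-path graph returns that path; none when cut", {
  g <- chain_graph(c(8, 6, 9))
  m <- minimal_cost_path(g, 5)
  expect_equal(m$cells, 1:3)
  expect_equal(m$total_cost, sum(5 / c(8, 6, 9)))
  expect_null(minimal_cost_path(g, 6.5))
})

test_that("Dijkstra cost equals exhaustive enumeration on random graphs", {
  set.seed(99)
  for (k in 1:50) {
    g <- random_graph(sample(5:12, 1))
    cv <- runif(1, 1, 6)
    m <- minimal_cost_path(g, cv)
    ref <- brute_force_mcp_cost(g, cv)
    if (is.null(m)) expect_equal(ref, Inf)
    else expect_equal(m$total_cost, ref, tolerance = 1e-9)
  }
})

test_that("reported paths respect their contract", {
  set.seed(12)
  for (k in 1:10) {
    g <- random_graph(8)
    cv <- runif(1, 1, 5)
    for (m in enumerate_mcps(g, cv)) {
      ed <- g$edges[match(m$edges, g$edges$face_id), ]
      expect_true(all(ed$cvmax >= cv))
      expect_equal(m$total_cost, sum(cv / ed$cvmax), tolerance = 1e-12)
      expect_equal(ed$from[1] == 0 || ed$to[1] == 0, TRUE)  # starts outside
      expect_true(m$cells[length(m$cells)] %in% g$target_cells)
    }
  }
})

test_that("iterative removal finds edge-disjoint paths and terminates", {
  # two fully disjoint corridors
  e <- data.frame(from = c(0, 1, 0, 3), to = c(1, 2, 3, 4),
                  cvmax = c(6, 8, 4, 9))
  g <- toy_graph(e, target = c(2, 4), n_cells = 4)
  ms <- enumerate_mcps(g, 3)
  expect_equal(length(ms), 2)
  expect_equal(length(intersect(ms[[1]]$edges, ms[[2]]$edges)), 0)
  expect_equal(vapply(ms, function(m) m$rank, integer(1)), 1:2)
  # single path: second extraction finds nothing
  g1 <- chain_graph(c(8, 6, 9))
  expect_equal(length(enumerate_mcps(g1, 5)), 1)
})

test_that("path count never exceeds the Menger/max-flow bound", {
  set.seed(55)
  for (k in 1:15) {
    g <- random_graph(sample(5:10, 1), p_edge = 0.5, n_hull = 3)
    cv <- runif(1, 1, 5)
    ms <- enumerate_mcps(g, cv)
    e <- g$edges[g$edges$cvmax >= cv, , drop = FALSE]
    if (!nrow(e)) { expect_equal(length(ms), 0); next }
    n <- g$n_cells + 2L  # n-1 = EXTERIOR, n = virtual sink
    from <- ifelse(e$from == 0, n - 1L, e$from)
    to <- ifelse(e$to == 0, n - 1L, e$to)
    gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
    caps <- rep(1, igraph::ecount(gr))
    for (tcell in g$target_cells) {
      gr <- igraph::add_edges(gr, c(tcell, n))
      caps <- c(caps, Inf)
    }
    bound <- igraph::max_flow(gr, source = n - 1L, target = n,
                              capacity = caps)$value
    expect_lte(length(ms), bound)
  }
})

test_that("extraction is invariant to edge input order", {
  set.seed(64)
  g <- random_graph(9, p_edge = 0.5, n_hull = 3)
  cv <- 2.5
  ref <- enumerate_mcps(g, cv)
  for (k in 1:5) {
    gp <- g
    gp$edges <- gp$edges[sample(nrow(gp$edges)), ]
    got <- enumerate_mcps(gp, cv)
    expect_equal(length(got), length(ref))
    expect_equal(lapply(got, function(m) m$cells),
                 lapply(ref, function(m) m$cells))
    expect_equal(lapply(got, function(m) sort(m$edges)),
                 lapply(ref, function(m) sort(m$edges)))
  }
})

fake_mcp <- function(cells, cv = 2) {
  structure(list(cv = cv, cells = cells, edges = integer(0),
                 total_cost = 0, rank = 1L), class = "mcp")
}

test_that("clustering follows Jaccard similarity with single linkage", {
  # ~90% shared cells -> one trajectory
  tr <- cluster_mcps(list(fake_mcp(1:10), fake_mcp(2:10)), metric = "cells")
  expect_equal(length(tr), 1)
  expect_setequal(tr[[1]]$cells, 1:10)
  # disjoint -> two
  tr2 <- cluster_mcps(list(fake_mcp(1:5), fake_mcp(6:10)), metric = "cells")
  expect_equal(length(tr2), 2)
  # chain A~B, B~C, A!~C merges through single linkage
  A <- fake_mcp(1:6); B <- fake_mcp(4:9); C <- fake_mcp(7:12)
  sim <- function(a, b) length(intersect(a$cells, b$cells)) /
    length(union(a$cells, b$cells))
  expect_gte(sim(A, B), 0.3); expect_gte(sim(B, C), 0.3)
  expect_lt(sim(A, C), 0.3)
  tr3 <- cluster_mcps(list(A, B, C), metric = "cells")
  expect_equal(length(tr3), 1)
})
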