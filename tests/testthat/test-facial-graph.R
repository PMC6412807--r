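# Facial graph construction, thresholding, channels, and the two
# independent CVlim computations.

test_that("two-cell tessellation yields the expected graph counts", {
  tess <- two_tetra_tess(radii = 0.1)
  g <- build_facial_graph(tess, target = 2L)  # shared vertex
  expect_equal(g$n_cells, 2)
  expect_equal(sum(g$edges$to != 0), 1)   # one internal edge
  expect_equal(sum(g$edges$to == 0), 6)   # six hull edges
  # vertex 2 is shared by both cells -> both are target cells
  expect_setequal(g$target_cells, 1:2)
  # a vertex of only one cell targets that cell alone
  g1 <- build_facial_graph(tess, target = 1L)
  expect_equal(length(g1$target_cells), 1)
})

test_that("a target point outside the hull is rejected", {
  tess <- two_tetra_tess()
  expect_error(
    build_facial_graph(tess, structure(c(10, 10, 10), point = TRUE)),
    "outside")
  # and a point inside resolves to its containing cell
  g <- build_facial_graph(tess, structure(c(0.1, 0.1, 0.1), point = TRUE))
  expect_equal(length(g$target_cells), 1)
})

test_that("thresholding keeps exactly the passable edges, nested in cv", {
  g <- chain_graph(c(8, 6, 9))
  expect_equal(nrow(graph_at(g, 1e-9)$edges), 3)
  expect_equal(nrow(graph_at(g, 7)$edges), 2)
  expect_equal(nrow(graph_at(g, 10)$edges), 0)
  set.seed(31)
  rg <- random_graph(10)
  for (cv in c(2, 5, 8)) {
    e_lo <- graph_at(rg, cv)$edges$face_id
    e_hi <- graph_at(rg, cv + 1)$edges$face_id
    expect_true(all(e_hi %in% e_lo))
  }
})

test_that("single-path bottleneck and parallel-path maximum", {
  expect_equal(as.numeric(compute_cvlim(chain_graph(c(8, 6, 9)))), 6)
  # two parallel chains with bottlenecks 5 and 7
  e <- data.frame(from = c(0, 1, 0, 2), to = c(1, 3, 2, 3),
                  cvmax = c(5, 9, 7, 8))
  g <- toy_graph(e, target = 3)
  expect_equal(as.numeric(compute_cvlim(g)), 7)
  expect_equal(as.numeric(cvlim_widest(g)), 7)
})

test_that("unreachable targets give CVlim 0 with a flag", {
  e <- data.frame(from = c(0, 2), to = c(1, 3), cvmax = c(5, 5))
  g <- toy_graph(e, target = 3, n_cells = 3)
  v <- compute_cvlim(g)
  expect_equal(as.numeric(v), 0)
  expect_false(attr(v, "reachable"))
  w <- cvlim_widest(g)
  expect_equal(as.numeric(w), 0)
  expect_false(attr(w, "reachable"))
})

test_that("bisection CVlim equals max-min Dijkstra and brute force", {
  set.seed(77)
  for (k in 1:30) {
    g <- random_graph(sample(4:10, 1))
    a <- as.numeric(compute_cvlim(g))
    b <- as.numeric(cvlim_widest(g))
    expect_equal(a, b)
    expect_equal(a, brute_force_widest(g))
  }
})

test_that("channels carry reach flags and deterministic ordering", {
  # one component reaching both ends, one dead-end pocket
  e <- data.frame(from = c(0, 1, 2, 4), to = c(1, 2, 3, 5),
                  cvmax = c(6, 6, 6, 6))
  g <- toy_graph(e, target = 3, n_cells = 5)
  ch <- channels_at(g, 5, channels_only = FALSE)
  expect_equal(length(ch), 2)  # {1,2,3} and {4,5}; the channel first
  expect_true(ch[[1]]$reaches_exterior && ch[[1]]$reaches_target)
  expect_setequal(ch[[1]]$cells, 1:3)
  only <- channels_at(g, 5)
  expect_equal(length(only), 1)
  # above every door: nothing
  expect_equal(length(channels_at(g, 7)), 0)
})

test_that("channel cells are nested across thresholds", {
  m <- make_shell_pore(n_atoms = 200, aperture_width = 7, seed = 9)
  an <- suppressWarnings(detect_channels(m, cv = 3))
  g <- an$graph
  for (cvs in list(c(2, 3.5), c(2.5, 4))) {
    hi <- channels_at(g, cvs[2])
    lo <- channels_at(g, cvs[1])
    for (ch in hi) {
      container <- vapply(lo, function(cl) all(ch$cells %in% cl$cells),
                          logical(1))
      expect_true(any(container))
    }
  }
})

test_that("profile records ordered appearance of disjoint channels", {
  # two parallel corridors to two different target cells, widths 6 and 4
  e <- data.frame(from = c(0, 1, 0, 3), to = c(1, 2, 3, 4),
                  cvmax = c(6, 8, 4, 9))
  g <- toy_graph(e, target = c(2, 4), n_cells = 4)
  pr <- cv_profile(g, seq(7, 1, by = -1))
  ev <- attr(pr, "events")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$cv, c(6, 4))
})
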