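# Shared helpers: rigid motions, synthetic graphs, tiny tessellations and
# brute-force oracles used across the suite.

random_rotation <- function() {
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# a facial graph given as an edge table; node 0 is EXTERIOR
toy_graph <- function(edges, target, n_cells = max(c(edges$from, edges$to))) {
  facial_graph(edges, n_cells = n_cells, target_cells = target)
}

# chain EXT - 1 - 2 - ... - k with given door widths
chain_graph <- function(cvmaxes) {
  k <- length(cvmaxes)
  toy_graph(data.frame(from = seq_len(k) - 1L, to = seq_len(k),
                       cvmax = cvmaxes), target = k)
}

# random connected-ish facial graph for property tests
random_graph <- function(n_nodes, p_edge = 0.4, n_hull = 2) {
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  e <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
  hull <- sample.int(n_nodes, min(n_hull, n_nodes))
  e <- rbind(e, data.frame(from = 0L, to = hull))
  e$cvmax <- round(runif(nrow(e), 1, 10), 2)
  toy_graph(e, target = n_nodes, n_cells = n_nodes)
}

# exhaustive minimal-cost-path search (simple paths, DFS)
brute_force_mcp_cost <- function(g, cv) {
  e <- g$edges[g$edges$cvmax >= cv, , drop = FALSE]
  if (!nrow(e)) return(Inf)
  n <- g$n_cells + 1L
  from <- ifelse(e$from == 0, n, e$from)
  to <- ifelse(e$to == 0, n, e$to)
  w <- cv / e$cvmax
  best <- Inf
  visit <- rep(FALSE, n)
  dfs <- function(u, cost) {
    if (cost >= best) return()
    if (u != n && u %in% g$target_cells) { best <<- cost; return() }
    visit[u] <<- TRUE
    inc <- which(from == u | to == u)
    for (j in inc) {
      v <- if (from[j] == u) to[j] else from[j]
      if (!visit[v]) dfs(v, cost + w[j])
    }
    visit[u] <<- FALSE
  }
  dfs(n, 0)
  best
}

# exhaustive bottleneck (widest path) value over all simple paths
brute_force_widest <- function(g) {
  e <- g$edges
  n <- g$n_cells + 1L
  from <- ifelse(e$from == 0, n, e$from)
  to <- ifelse(e$to == 0, n, e$to)
  best <- 0
  visit <- rep(FALSE, n)
  dfs <- function(u, width) {
    if (width <= best) return()
    if (u != n && u %in% g$target_cells) { best <<- max(best, width); return() }
    visit[u] <<- TRUE
    inc <- which(from == u | to == u)
    for (j in inc) {
      v <- if (from[j] == u) to[j] else from[j]
      if (!visit[v]) dfs(v, min(width, e$cvmax[j]))
    }
    visit[u] <<- FALSE
  }
  dfs(n, Inf)
  best
}

# two unit-corner tetrahedra sharing the (1,0,0),(0,1,0),(0,0,1) face
two_tetra_points <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(2 / 3 + 0.35, 2 / 3 + 0.35, 2 / 3 + 0.35))
}

two_tetra_tess <- function(radii = 0.1) {
  pts <- two_tetra_points()
  at <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   vdw_radius = radii)
  annotate_cvmax(triangulate(at))
}

# double shell: outer hull shell, buried inner shell around a target atom;
# the cells between the inner shell and the target have no hull vertex
double_shell_model <- function(seed = 11) {
  outer <- make_shell_pore(shell_radius = 12, n_atoms = 250,
                           aperture_width = 0, seed = seed)
  inner <- make_shell_pore(shell_radius = 5.5, n_atoms = 120,
                           aperture_width = 0, seed = seed + 1)
  at <- rbind(outer$atoms[-nrow(outer$atoms), ],
              inner$atoms)  # keep the single central FE from `inner`
  at$serial <- seq_len(nrow(at))
  at$resno[at$resname != "HEM"] <- seq_len(sum(at$resname != "HEM"))
  structure(list(id = "double_shell", atoms = at,
                 elements = outer$elements), class = "structure_model")
}

# approximate 3D minimum enclosing ball of balls (Badoiu-Clarkson);
# its radius is an upper bound certificate: R_hat >= R_opt
enclosing_ball_radius <- function(xyz, r, iters = 2000L) {
  c0 <- colMeans(xyz)
  for (k in seq_len(iters)) {
    d <- sqrt(rowSums((xyz - rep(c0, each = nrow(xyz)))^2)) + r
    i <- which.max(d)
    dir <- xyz[i, ] - c0
    nd <- sqrt(sum(dir^2))
    far <- if (nd > 0) xyz[i, ] + dir / nd * r[i] else xyz[i, ]
    c0 <- c0 + (far - c0) / (k + 1)
  }
  max(sqrt(rowSums((xyz - rep(c0, each = nrow(xyz)))^2)) + r)
}

minimal_pdb <- function() {
  c("HELIX    1  H1 ALA A   10  ALA A   12  1                                   3",
    "ATOM      1  N   ALA A  10      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB  ALA A  10      12.919   6.841  -4.950  1.00  0.00           C",
    "ATOM      4  H   ALA A  10      10.500   5.500  -7.000  1.00  0.00           H",
    "HETATM    5 FE   HEM A 508      11.000   7.000  -5.000  1.00  0.00          FE",
    "HETATM    6  O   HOH A 600      12.000   8.000  -5.000  1.00  0.00           O",
    "HETATM    7  C1  LIG A 700      13.000   8.000  -5.000  1.00  0.00           C",
    "END")
}
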