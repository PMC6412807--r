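## Minimal cost paths (MCPs): exterior -> active site paths minimizing the
## summed door cost CV/CVmax, extracted with Dijkstra's algorithm and
## removed edge-by-edge to expose alternative routes.

#' Cost of passing one door
#'
#' The cost assigned to an edge of the facial graph at ligand thickness
#' `cv` is `cv / cvmax`, in `(0, 1]`: the wider the door relative to the
#' ligand, the cheaper the passage. Only doors with `cvmax >= cv` are in
#' the thresholded graph, so the cost never exceeds 1.
#'
#' @param cv ligand thickness (Angstrom), > 0.
#' @param cvmax door width (Angstrom), `>= cv`.
#' @return dimensionless cost in `(0, 1]`.
#' @export
edge_cost <- function(cv, cvmax) {
  stopifnot(all(cv > 0), all(cv <= cvmax))
  cv / cvmax
}

# Deterministic Dijkstra on the thresholded facial graph from EXTERIOR to
# the set of target cells. Ties on cost are broken by fewer edges, then by
# smallest predecessor id, giving an input-order independent path.
.dijkstra_mcp <- function(edges, n_cells, target_cells, cv) {
  if (!nrow(edges)) return(NULL)
  n <- n_cells + 1L  # node n = EXTERIOR
  from <- ifelse(edges$from == 0, n, edges$from)
  to <- ifelse(edges$to == 0, n, edges$to)
  w <- cv / edges$cvmax
  m <- nrow(edges)
  sp <- split(seq_len(2L * m), c(from, to))
  adj <- vector("list", n)
  adj[as.integer(names(sp))] <- sp
  endpoint <- c(to, from)  # endpoint[j]: the far node of half-edge j
  wts <- c(w, w)
  eid <- c(seq_len(m), seq_len(m))
  eps <- 1e-9
  dist <- rep(Inf, n); hops <- rep(Inf, n); pred <- rep(NA_integer_, n)
  pred_edge <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[n] <- 0; hops[n] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    d0 <- min(dist[cand])
    sel <- cand[dist[cand] <= d0 + eps]
    if (length(sel) > 1) {
      h0 <- min(hops[sel]); sel <- sel[hops[sel] == h0]
    }
    u <- min(sel)
    done[u] <- TRUE
    for (j in adj[[u]]) {
      v <- endpoint[j]
      if (done[v]) next
      nd <- dist[u] + wts[j]
      better <- nd < dist[v] - eps ||
        (nd <= dist[v] + eps &&
           (hops[u] + 1 < hops[v] ||
              (hops[u] + 1 == hops[v] && !is.na(pred[v]) && u < pred[v])))
      if (better) {
        dist[v] <- min(nd, dist[v]); hops[v] <- hops[u] + 1
        pred[v] <- u; pred_edge[v] <- eid[j]
      }
    }
  }
  reach <- target_cells[is.finite(dist[target_cells])]
  if (!length(reach)) return(NULL)
  dt <- dist[reach]
  sel <- reach[dt <= min(dt) + eps]
  if (length(sel) > 1) {
    h0 <- min(hops[sel]); sel <- sel[hops[sel] == h0]
  }
  tgt <- min(sel)
  cells <- integer(0); face_ids <- integer(0)
  u <- tgt
  while (u != n) {
    cells <- c(u, cells)
    face_ids <- c(pred_edge[u], face_ids)
    u <- pred[u]
  }
  list(cells = cells, face_ids = face_ids, cost = dist[tgt])
}

#' Minimal cost path from the exterior to the active site
#'
#' Runs Dijkstra's algorithm on the facial graph thresholded at `cv`, with
#' edge cost `cv/cvmax`, from the EXTERIOR super-node to the nearest target
#' cell. Ties are broken deterministically (fewer edges, then smallest cell
#' ids), so the result does not depend on input ordering.
#'
#' @param g a [facial_graph()].
#' @param cv ligand thickness (Angstrom).
#' @return an object of class `mcp` — list with `cv`, `cells` (ordered cell
#'   ids, exterior side first), `edges` (ordered face ids), `total_cost`,
#'   `rank` — or `NULL` when no path exists.
#' @export
minimal_cost_path <- function(g, cv) {
  stopifnot(inherits(g, "facial_graph"), cv > 0)
  e <- g$edges[g$edges$cvmax >= cv, , drop = FALSE]
  res <- .dijkstra_mcp(e, g$n_cells, g$target_cells, cv)
  if (is.null(res)) return(NULL)
  fid <- e$face_id[res$face_ids]
  structure(list(cv = cv, cells = res$cells, edges = fid,
                 total_cost = res$cost, rank = 1L),
            class = "mcp")
}

#' @export
print.mcp <- function(x, ...) {
  cat(sprintf("<mcp rank %d at CV = %.3g A> %d doors, %d cells, cost %.3f\n",
              x$rank, x$cv, length(x$edges), length(x$cells), x$total_cost))
  invisible(x)
}

#' Enumerate minimal cost paths by iterative edge removal
#'
#' Extracts the MCP, removes all of its edges from the working graph,
#' reapplies Dijkstra's algorithm, and repeats until no path to the active
#' site remains. The returned MCPs are pairwise edge-disjoint and ranked in
#' extraction order.
#'
#' @inheritParams minimal_cost_path
#' @param max_paths stop after this many paths (default unlimited).
#' @return list of `mcp` objects (possibly empty).
#' @export
enumerate_mcps <- function(g, cv, max_paths = Inf) {
  stopifnot(inherits(g, "facial_graph"), cv > 0)
  e <- g$edges[g$edges$cvmax >= cv, , drop = FALSE]
  out <- list()
  while (length(out) < max_paths) {
    res <- .dijkstra_mcp(e, g$n_cells, g$target_cells, cv)
    if (is.null(res)) break
    fid <- e$face_id[res$face_ids]
    out[[length(out) + 1]] <- structure(
      list(cv = cv, cells = res$cells, edges = fid,
           total_cost = res$cost, rank = length(out) + 1L),
      class = "mcp")
    e <- e[!(e$face_id %in% fid), , drop = FALSE]
  }
  out
}

#' Cluster minimal cost paths into trajectories
#'
#' Single-linkage agglomeration of MCPs with similarity the Jaccard index;
#' MCPs joining at similarity `>= overlap_threshold` form one cluster. Each
#' cluster defines a trajectory — one channel in the usual access-channel
#' nomenclature — whose cells are the union of its members'. When the
#' originating tessellation is supplied, each trajectory carries volume,
#' boundary surface and lining information.
#'
#' The similarity is computed on the MCPs' lining-atom sets by default:
#' parallel routes through the same mouth can be cell-disjoint (cells are
#' maximally fine-grained) while threading between the same atoms, and the
#' atom sets are what the method ultimately reports. `metric = "cells"`
#' clusters on the raw cell sets instead.
#'
#' @param mcps list of `mcp` objects (see [enumerate_mcps()]).
#' @param overlap_threshold Jaccard similarity in `(0, 1]` required to join
#'   a cluster (default 0.3).
#' @param tess optional annotated tessellation for measures.
#' @param model optional `structure_model` for egress annotation.
#' @param metric `"atoms"` (default; falls back to `"cells"` when no
#'   tessellation is supplied) or `"cells"`.
#' @return list of `trajectory` objects sorted by volume (cell count when no
#'   tessellation) descending: `member_mcps`, `cells`, `volume`,
#'   `boundary_surface`, `lining`, `egress`.
#' @export
cluster_mcps <- function(mcps, overlap_threshold = 0.3, tess = NULL,
                         model = NULL, metric = c("atoms", "cells")) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  metric <- match.arg(metric)
  k <- length(mcps)
  if (k == 0) return(list())
  sets <- if (metric == "atoms" && !is.null(tess))
    lapply(mcps, function(m) lining_atoms(m$cells, tess))
  else lapply(mcps, function(m) unique(m$cells))
  if (k == 1) memb <- 1L
  else {
    D <- matrix(0, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      D[i, j] <- D[j, i] <- 1 - if (uni) inter / uni else 0
    }
    hc <- hclust(as.dist(D), method = "single")
    memb <- cutree(hc, h = 1 - overlap_threshold)
  }
  out <- lapply(unique(memb), function(cl) {
    members <- mcps[memb == cl]
    cells <- sort(unique(unlist(lapply(members, function(m) m$cells))))
    traj <- list(member_mcps = members, cells = cells,
                 volume = length(cells), boundary_surface = NA_real_,
                 lining = NULL, egress = NULL)
    if (!is.null(tess)) {
      cv <- members[[1]]$cv
      traj$volume <- region_volume(cells, tess)
      traj$boundary_surface <- region_boundary_surface(cells, tess, cv)
      traj$lining <- lining_residues(cells, tess)
      if (!is.null(model))
        traj$egress <- egress_elements(cells, tess, model, cv = cv)
    }
    structure(traj, class = "trajectory")
  })
  vol <- vapply(out, function(t) t$volume, numeric(1))
  out[order(-vol, vapply(out, function(t) min(t$cells), numeric(1)))]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d MCPs, %d cells, volume %.1f A^3",
              length(x$member_mcps), length(x$cells), x$volume))
  if (!is.na(x$boundary_surface))
    cat(sprintf(", boundary %.1f A^2", x$boundary_surface))
  cat("\n")
  if (!is.null(x$lining) && nrow(x$lining))
    cat("  lining:", nrow(x$lining), "residues\n")
  if (!is.null(x$egress) && nrow(x$egress))
    cat("  egress:", paste(x$egress$label, collapse = ", "), "\n")
  invisible(x)
}
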