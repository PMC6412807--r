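## The facial graph: tetrahedral cells are nodes, passable triangular faces
## are edges. A single EXTERIOR super-node (coded 0) is attached through
## every hull face with that face's own CVmax: a ligand may enter wherever a
## hull door is wide enough.

#' Construct a facial graph
#'
#' Usually obtained from [build_facial_graph()]; this constructor also lets
#' tests and scripts assemble synthetic graphs directly.
#'
#' @param edges data frame with integer columns `from`, `to` (cell ids,
#'   `0` = EXTERIOR), numeric `cvmax`, and optionally `face_id`.
#' @param n_cells number of tetrahedral cells (nodes besides EXTERIOR).
#' @param target_cells integer vector of active-site cell ids (nonempty).
#' @param cell_volumes optional per-cell volumes used for channel ordering.
#' @param tess optional originating [triangulate()] result.
#' @return object of class `facial_graph`.
#' @export
facial_graph <- function(edges, n_cells, target_cells, cell_volumes = NULL,
                         tess = NULL) {
  stopifnot(all(c("from", "to", "cvmax") %in% names(edges)),
            length(target_cells) >= 1,
            all(target_cells >= 1 & target_cells <= n_cells))
  if (is.null(edges$face_id)) edges$face_id <- seq_len(nrow(edges))
  swap <- edges$from == 0  # canonical orientation: EXTERIOR sits in `to`
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  stopifnot(all(edges$from >= 1 & edges$from <= n_cells),
            all(edges$to >= 0 & edges$to <= n_cells))
  if (is.null(cell_volumes)) cell_volumes <- rep(1, n_cells)
  structure(list(edges = edges, n_cells = as.integer(n_cells),
                 target_cells = as.integer(sort(unique(target_cells))),
                 cell_volumes = cell_volumes, tess = tess),
            class = "facial_graph")
}

# locate the tetrahedral cell containing a literal point (barycentric test)
.locate_cell <- function(tess, pt) {
  for (i in seq_len(nrow(tess$tetra))) {
    v <- tess$xyz[tess$tetra[i, ], , drop = FALSE]
    M <- t(v[2:4, , drop = FALSE]) - v[1, ]
    b <- tryCatch(solve(M, pt - v[1, ]), error = function(e) NULL)
    if (is.null(b)) next
    if (all(b >= -1e-9) && sum(b) <= 1 + 1e-9) return(i)
  }
  NA_integer_
}

#' Build the facial graph of an annotated tessellation
#'
#' Nodes are the tetrahedra plus one EXTERIOR super-node (id 0); every face
#' becomes an edge weighted by its CVmax, hull faces linking their cell to
#' EXTERIOR. The target cells are the tetrahedra incident to the target atom
#' (the active-site atom is itself a tessellation vertex, so its star of
#' cells is the arrival region) or, for a literal point, the single cell
#' containing it.
#'
#' @param tess an [annotate_cvmax()]-annotated tessellation.
#' @param target atom row index into the tessellated atom set, or a length-3
#'   point with attribute `point` (see [resolve_target()]).
#' @return a [facial_graph()].
#' @export
build_facial_graph <- function(tess, target) {
  stopifnot(inherits(tess, "tessellation"))
  if (anyNA(tess$faces$cvmax)) stop("faces are not CVmax-annotated; run annotate_cvmax()")
  if (!is.null(attr(target, "point"))) {
    cell <- .locate_cell(tess, as.numeric(target))
    if (is.na(cell)) stop("target point lies outside the convex hull")
    target_cells <- cell
  } else {
    target <- as.integer(target)
    hit <- rowSums(tess$tetra == target) > 0
    if (!any(hit)) stop("target atom ", target, " is not a tessellation vertex")
    target_cells <- which(hit)
  }
  f <- tess$faces
  edges <- data.frame(from = f$cell1,
                      to = ifelse(is.na(f$cell2), 0L, f$cell2),
                      cvmax = f$cvmax,
                      face_id = seq_len(nrow(f)))
  facial_graph(edges, nrow(tess$tetra), target_cells,
               cell_volumes = tess$vol, tess = tess)
}

#' @export
print.facial_graph <- function(x, ...) {
  nh <- sum(x$edges$to == 0)
  cat("<facial_graph>", x$n_cells, "cells + EXTERIOR,",
      nrow(x$edges), "edges (", nh, "hull ),",
      length(x$target_cells), "target cells\n")
  invisible(x)
}

#' Threshold a facial graph at a ligand thickness
#'
#' Keeps exactly the edges whose door admits the ligand (`cvmax >= cv`);
#' nodes are unchanged. Thresholded edge sets are nested in `cv`.
#'
#' @param g a [facial_graph()].
#' @param cv ligand thickness in Angstrom (> 0).
#' @return the thresholded `facial_graph`, with element `cv` recording the
#'   threshold.
#' @export
graph_at <- function(g, cv) {
  stopifnot(inherits(g, "facial_graph"), cv > 0)
  g$edges <- g$edges[g$edges$cvmax >= cv, , drop = FALSE]
  g$cv <- cv
  g
}

.cell_components <- function(g, cv) {
  e <- g$edges[g$edges$cvmax >= cv, , drop = FALSE]
  internal <- e[e$to != 0, , drop = FALSE]
  gr <- igraph::make_empty_graph(n = g$n_cells, directed = FALSE)
  if (nrow(internal))
    gr <- igraph::add_edges(gr, rbind(internal$from, internal$to))
  comp <- igraph::components(gr)$membership
  hull_open <- unique(e$from[e$to == 0])
  list(membership = comp, hull_open = hull_open)
}

#' Connected components of the thresholded facial graph
#'
#' Restricts the graph at `cv` to tetrahedral nodes, finds its connected
#' components, and flags each with whether it touches the EXTERIOR (through
#' an open hull door) and whether it contains a target cell. Components with
#' both flags are channels in the strict sense and are returned first,
#' sorted by volume descending (ties by smallest cell id).
#'
#' @inheritParams graph_at
#' @param channels_only drop components that are not exterior-to-target
#'   channels (default `TRUE`).
#' @return list of `channel` objects: `cv`, `cells`, `reaches_exterior`,
#'   `reaches_target`, `volume`.
#' @export
channels_at <- function(g, cv, channels_only = TRUE) {
  stopifnot(inherits(g, "facial_graph"))
  cc <- .cell_components(g, cv)
  comp <- cc$membership
  ids <- unique(comp)
  out <- list()
  for (k in ids) {
    cells <- which(comp == k)
    re <- any(cells %in% cc$hull_open)
    rt <- any(cells %in% g$target_cells)
    if (channels_only && !(re && rt)) next
    out[[length(out) + 1]] <- structure(
      list(cv = cv, cells = cells, reaches_exterior = re, reaches_target = rt,
           volume = sum(g$cell_volumes[cells])),
      class = "channel")
  }
  if (!length(out)) return(out)
  is_chan <- vapply(out, function(ch) ch$reaches_exterior && ch$reaches_target,
                    logical(1))
  vol <- vapply(out, function(ch) ch$volume, numeric(1))
  mincell <- vapply(out, function(ch) min(ch$cells), numeric(1))
  out[order(!is_chan, -vol, mincell)]
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel at CV = %.3g A> %d cells, volume %.1f A^3%s%s\n",
              x$cv, length(x$cells), x$volume,
              if (x$reaches_exterior) ", exterior" else "",
              if (x$reaches_target) ", target" else ""))
  invisible(x)
}

.connected_at <- function(g, cv) {
  cc <- .cell_components(g, cv)
  tcomp <- unique(cc$membership[g$target_cells])
  any(cc$membership[cc$hull_open] %in% tcomp)
}

#' Limiting ligand thickness CVlim
#'
#' The largest CV at which at least one exterior-to-active-site channel
#' exists; equivalently the bottleneck (maximum over exterior-to-target
#' paths of the minimum door CVmax along the path). Computed exactly by
#' binary search over the sorted distinct CVmax values with connectivity
#' tests; [cvlim_widest()] recomputes it with a max-min variant of
#' Dijkstra's algorithm as an independent cross-check.
#'
#' @param g a [facial_graph()].
#' @return CVlim in Angstrom; 0 with attribute `reachable = FALSE` when the
#'   target is unreachable at every positive CV.
#' @export
compute_cvlim <- function(g) {
  stopifnot(inherits(g, "facial_graph"))
  vals <- sort(unique(g$edges$cvmax[g$edges$cvmax > 0]))
  if (!length(vals) || !.connected_at(g, vals[1]))
    return(structure(0, reachable = FALSE))
  lo <- 1L; hi <- length(vals)  # connected at vals[lo]
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (.connected_at(g, vals[mid])) lo <- mid else hi <- mid - 1L
  }
  structure(vals[lo], reachable = TRUE)
}

#' Widest-path CVlim by max-min Dijkstra
#'
#' Bottleneck shortest path from EXTERIOR to the target cells: grows a set
#' of finalized nodes, always expanding the node whose best path has the
#' largest minimum door width. Agrees with [compute_cvlim()] on every input;
#' kept as an independent oracle.
#'
#' @inheritParams compute_cvlim
#' @return CVlim in Angstrom (0, `reachable = FALSE` attribute, if no path).
#' @export
cvlim_widest <- function(g) {
  stopifnot(inherits(g, "facial_graph"))
  n <- g$n_cells + 1L  # node n is EXTERIOR
  e <- g$edges
  from <- ifelse(e$from == 0, n, e$from)
  to <- ifelse(e$to == 0, n, e$to)
  idx <- seq_len(nrow(e))
  sp <- split(c(idx, idx), c(from, to))
  adj <- vector("list", n)
  adj[as.integer(names(sp))] <- sp
  other <- cbind(from, to)
  width <- rep(-Inf, n); width[n] <- Inf
  done <- rep(FALSE, n)
  repeat {
    u <- which.max(ifelse(done, -Inf, width))
    if (width[u] == -Inf || done[u]) break
    done[u] <- TRUE
    if (u != n && u %in% g$target_cells)
      return(structure(width[u], reachable = TRUE))
    for (j in adj[[u]]) {
      v <- if (other[j, 1] == u) other[j, 2] else other[j, 1]
      w <- min(width[u], e$cvmax[j])
      if (w > width[v]) width[v] <- w
    }
    if (all(done | !is.finite(width))) break
  }
  best <- suppressWarnings(max(width[g$target_cells][done[g$target_cells]],
                               -Inf))
  if (is.finite(best) && best > 0) structure(best, reachable = TRUE)
  else structure(0, reachable = FALSE)
}

#' Channel appearance profile over a CV grid
#'
#' Evaluates [channels_at()] on a descending grid of CV values and records,
#' for every channel present at each CV, its size and whether it is new: a
#' channel is a "new channel" event when its cell set is disjoint from every
#' channel already seen at a higher CV (the first channel appears at CVlim,
#' later disjoint ones at smaller CV).
#'
#' @param g a [facial_graph()].
#' @param cv_grid numeric vector of CV values (Angstrom), sorted descending
#'   (it is re-sorted if not).
#' @return data frame with one row per (cv, channel): `cv`, `channel` (rank
#'   at that cv), `n_cells`, `volume`, `new`. The attribute `events` holds
#'   the (cv, volume) rows where a new channel appeared.
#' @export
cv_profile <- function(g, cv_grid) {
  stopifnot(inherits(g, "facial_graph"), all(cv_grid > 0))
  cv_grid <- sort(unique(cv_grid), decreasing = TRUE)
  seen <- list()
  rows <- list()
  for (cv in cv_grid) {
    chans <- channels_at(g, cv)
    for (i in seq_along(chans)) {
      ch <- chans[[i]]
      is_new <- !any(vapply(seen, function(s) any(ch$cells %in% s), logical(1)))
      if (is_new) seen[[length(seen) + 1]] <- ch$cells
      rows[[length(rows) + 1]] <- data.frame(
        cv = cv, channel = i, n_cells = length(ch$cells),
        volume = ch$volume, new = is_new)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cv = numeric(0), channel = integer(0), n_cells = integer(0),
               volume = numeric(0), new = logical(0))
  attr(out, "events") <- out[out$new, c("cv", "channel", "n_cells", "volume"),
                             drop = FALSE]
  out
}
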