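#' Detect access channels to a buried active site
#'
#' End-to-end analysis: reads (or takes) a structure, selects the heavy
#' atoms to tessellate, assigns vdW radii, builds the Delaunay tessellation
#' and its CVmax-annotated facial graph, computes the limiting ligand
#' thickness CVlim, the channels at the working thickness `cv`, the minimal
#' cost paths and their clustering into trajectories, and the
#' surface-pocket vs active-site partition of the main channel's void.
#'
#' The working thickness comes from `cv` (Angstrom) or, alternatively, from
#' the cylindrical thickness of a named ligand present in the structure
#' (`ligand`); exactly one of the two must be supplied.
#'
#' @param structure path to a PDB file, PDB text, or a `structure_model`.
#' @param cv working ligand thickness in Angstrom.
#' @param ligand residue name of a co-crystallized ligand whose
#'   [structure_ligand_thickness()] is used as `cv`.
#' @param target a [target_spec()]; default the heme iron.
#' @param include atom categories to tessellate (see [select_atoms()]).
#' @param chain chain to analyze; default the structure's first chain.
#' @param radii radii table (see [vdw_radii()]); radii already present on
#'   the atoms (e.g. fixture models) are kept.
#' @param cv_grid optional descending CV grid for the channel-appearance
#'   profile (default: from just above CVlim down to `cv_grid_min` in steps
#'   of 0.25 Angstrom, matching the usual reporting resolution).
#' @param cv_grid_min lower end of the default profile grid.
#' @param cluster_threshold Jaccard threshold for [cluster_mcps()].
#' @param max_paths cap on extracted MCPs.
#' @param jitter_seed seed of the degeneracy jitter (see [triangulate()]).
#' @return object of class `channel_analysis` with elements `model`,
#'   `atoms` (tessellated selection), `tess`, `graph`, `cv`, `cvlim`,
#'   `channels`, `mcps`, `trajectories`, `profile`, `void_fractions` and
#'   `params`.
#' @examples
#' \donttest{
#' m <- make_shell_pore(n_atoms = 220, aperture_width = 8, seed = 3)
#' an <- detect_channels(m, cv = 4)
#' an$cvlim            # about 5 = 8 - 2 * 1.5
#' length(an$channels) # 1
#' }
#' @export
detect_channels <- function(structure, cv = NULL, ligand = NULL,
                            target = target_spec(),
                            include = c("protein", "cofactor"),
                            chain = NULL, radii = vdw_radii(),
                            cv_grid = NULL, cv_grid_min = 2,
                            cluster_threshold = 0.3, max_paths = 20L,
                            jitter_seed = 20987L) {
  model <- if (inherits(structure, "structure_model")) structure
  else read_structure(structure)
  if (is.null(cv) && is.null(ligand))
    stop("supply a working thickness: either cv= (Angstrom) or ligand= ",
         "(residue name)")
  model <- assign_radii(model, radii, overwrite = FALSE)
  if (is.null(chain)) chain <- model$atoms$chain[1]
  atoms <- select_atoms(model, include = include, chain = chain)
  tgt <- resolve_target(atoms, target)
  if (is.null(cv)) cv <- as.numeric(structure_ligand_thickness(model, ligand,
                                                               table = radii))
  stopifnot(cv > 0)

  tess <- triangulate(atoms, seed = jitter_seed)
  tess <- annotate_cvmax(tess)
  g <- build_facial_graph(tess, tgt)
  cvlim <- compute_cvlim(g)

  channels <- channels_at(g, cv)
  mcps <- enumerate_mcps(g, cv, max_paths = max_paths)
  trajectories <- cluster_mcps(mcps, overlap_threshold = cluster_threshold,
                               tess = tess, model = model)
  if (is.null(cv_grid)) {
    top <- max(cv, as.numeric(cvlim)) + 0.25
    cv_grid <- seq(top, min(cv_grid_min, top), by = -0.25)
  }
  profile <- cv_profile(g, cv_grid)
  void <- if (length(channels)) classify_void(channels[[1]], tess) else NULL

  structure(list(model = model, atoms = atoms, tess = tess, graph = g,
                 cv = cv, cvlim = cvlim, channels = channels, mcps = mcps,
                 trajectories = trajectories, profile = profile,
                 void_fractions = void,
                 params = list(include = include, chain = chain,
                               cluster_threshold = cluster_threshold,
                               max_paths = max_paths,
                               jitter_seed = jitter_seed,
                               target = target)),
            class = "channel_analysis")
}

#' @export
print.channel_analysis <- function(x, ...) {
  cat("<channel_analysis>", x$model$id, "\n")
  cat(sprintf("  %d atoms tessellated into %d cells (chain %s)\n",
              nrow(x$atoms), nrow(x$tess$tetra), x$params$chain))
  cat(sprintf("  CVlim = %.3f A%s; working CV = %.3f A\n",
              as.numeric(x$cvlim),
              if (isFALSE(attr(x$cvlim, "reachable"))) " (target unreachable)"
              else "", x$cv))
  cat(sprintf("  %d channel(s) at CV; %d MCPs in %d trajectorie(s)\n",
              length(x$channels), length(x$mcps), length(x$trajectories)))
  if (length(x$channels))
    cat(sprintf("  main channel: %d cells, volume %.0f A^3\n",
                length(x$channels[[1]]$cells), x$channels[[1]]$volume))
  if (!is.null(x$void_fractions))
    cat(sprintf("  void partition: %.0f%% surface pockets, %.0f%% active site\n",
                100 * x$void_fractions[["surface_fraction"]],
                100 * x$void_fractions[["active_site_fraction"]]))
  invisible(x)
}

#' Per-channel and per-trajectory summary tables
#'
#' @param object a `channel_analysis`.
#' @param ... unused.
#' @return a `summary.channel_analysis`: list of data frames `channels`
#'   (rank, n_cells, volume, boundary_surface), `mcps` (rank, cost,
#'   n_doors, n_cells, volume, boundary_surface) and `trajectories`.
#' @export
summary.channel_analysis <- function(object, ...) {
  x <- object
  chan <- if (length(x$channels)) data.frame(
    rank = seq_along(x$channels),
    n_cells = vapply(x$channels, function(c) length(c$cells), integer(1)),
    volume = vapply(x$channels, function(c) c$volume, numeric(1)),
    boundary_surface = vapply(x$channels, function(c)
      region_boundary_surface(c$cells, x$tess, x$cv), numeric(1)))
  else data.frame(rank = integer(0), n_cells = integer(0),
                  volume = numeric(0), boundary_surface = numeric(0))
  mc <- if (length(x$mcps)) data.frame(
    rank = vapply(x$mcps, function(m) m$rank, integer(1)),
    cost = vapply(x$mcps, function(m) m$total_cost, numeric(1)),
    n_doors = vapply(x$mcps, function(m) length(m$edges), integer(1)),
    n_cells = vapply(x$mcps, function(m) length(m$cells), integer(1)),
    volume = vapply(x$mcps, function(m) region_volume(m$cells, x$tess),
                    numeric(1)),
    boundary_surface = vapply(x$mcps, function(m)
      region_boundary_surface(m$cells, x$tess, x$cv), numeric(1)))
  else data.frame(rank = integer(0), cost = numeric(0), n_doors = integer(0),
                  n_cells = integer(0), volume = numeric(0),
                  boundary_surface = numeric(0))
  traj <- if (length(x$trajectories)) data.frame(
    rank = seq_along(x$trajectories),
    n_mcps = vapply(x$trajectories, function(t) length(t$member_mcps),
                    integer(1)),
    n_cells = vapply(x$trajectories, function(t) length(t$cells), integer(1)),
    volume = vapply(x$trajectories, function(t) t$volume, numeric(1)),
    boundary_surface = vapply(x$trajectories, function(t) t$boundary_surface,
                              numeric(1)))
  else data.frame(rank = integer(0), n_mcps = integer(0), n_cells = integer(0),
                  volume = numeric(0), boundary_surface = numeric(0))
  structure(list(id = x$model$id, cv = x$cv, cvlim = x$cvlim,
                 channels = chan, mcps = mc, trajectories = traj,
                 void_fractions = x$void_fractions, profile = x$profile),
            class = "summary.channel_analysis")
}

#' @export
print.summary.channel_analysis <- function(x, ...) {
  cat("Channel analysis of", x$id, "\n")
  cat(sprintf("CVlim = %.3f A, working CV = %.3f A\n\n", as.numeric(x$cvlim),
              x$cv))
  cat("Channels:\n"); print(x$channels, row.names = FALSE)
  cat("\nMinimal cost paths:\n"); print(x$mcps, row.names = FALSE)
  cat("\nTrajectories:\n"); print(x$trajectories, row.names = FALSE)
  if (!is.null(x$void_fractions)) {
    cat("\nMain channel void partition:\n")
    print(round(x$void_fractions, 3))
  }
  ev <- attr(x$profile, "events")
  if (!is.null(ev) && nrow(ev)) {
    cat("\nChannel appearance events (descending CV):\n")
    print(ev, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a channel analysis
#'
#' Projects atoms and channel cells on two coordinates (default x, y):
#' atoms in grey, the cells of each channel colored by rank (barycenters),
#' the target atom marked red. A quick sanity view, not a renderer — use
#' [export_facial_graph()]/[export_boundary()] for molecular viewers.
#'
#' @param x a `channel_analysis`.
#' @param dims length-2 integer choice of coordinates.
#' @param ... passed to [graphics::plot()].
#' @export
plot.channel_analysis <- function(x, dims = c(1, 2), ...) {
  xyz <- x$tess$xyz
  plot(xyz[, dims[1]], xyz[, dims[2]], pch = 16, cex = 0.4, col = "grey70",
       asp = 1, xlab = c("x", "y", "z")[dims[1]],
       ylab = c("x", "y", "z")[dims[2]],
       main = sprintf("%s: CV = %.2f A, CVlim = %.2f A", x$model$id, x$cv,
                      as.numeric(x$cvlim)), ...)
  if (length(x$channels)) {
    cols <- hcl.colors(max(3, length(x$channels)), "Dark 3")
    for (i in seq_along(x$channels)) {
      b <- x$tess$bary[x$channels[[i]]$cells, , drop = FALSE]
      points(b[, dims[1]], b[, dims[2]], pch = 1, cex = 0.6, col = cols[i])
    }
    legend("topright", bty = "n", pch = 1, col = cols[seq_along(x$channels)],
           legend = sprintf("channel %d", seq_along(x$channels)))
  }
  tv <- unique(unlist(lapply(x$graph$target_cells, function(i) x$tess$tetra[i, ])))
  ti <- tv[which.max(tabulate(match(unlist(
    lapply(x$graph$target_cells, function(i) x$tess$tetra[i, ])), tv)))]
  points(xyz[ti, dims[1]], xyz[ti, dims[2]], pch = 8, col = "red", cex = 1.5)
  invisible(x)
}
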