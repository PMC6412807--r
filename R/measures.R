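## Quantifying tetrahedron sets: volume, boundary surface, and the
## surface-pocket vs active-site partition of a channel's void.

#' Volume of a set of tetrahedral cells
#'
#' The sum of the member tetrahedra volumes; additive over disjoint sets and
#' monotone under inclusion.
#'
#' @param cells integer vector of cell ids.
#' @param tess a [triangulate()] result.
#' @return volume in cubic Angstrom.
#' @export
region_volume <- function(cells, tess) {
  stopifnot(inherits(tess, "tessellation"),
            all(cells >= 1 & cells <= nrow(tess$tetra)))
  sum(tess$vol[unique(cells)])
}

#' Boundary surface of a set of cells at a ligand thickness
#'
#' The boundary of a region is the set of its triangular faces through
#' which the ligand cannot pass (`cvmax < cv`); passable faces are openings
#' and are excluded even at the rim of the region, so a fully open path has
#' surface 0. A closed internal face is one wall: it is counted once even
#' when both incident cells belong to the region.
#'
#' @inheritParams region_volume
#' @param cv ligand thickness in Angstrom.
#' @return summed face area in square Angstrom.
#' @export
region_boundary_surface <- function(cells, tess, cv) {
  stopifnot(inherits(tess, "tessellation"))
  if (anyNA(tess$faces$cvmax)) stop("faces are not CVmax-annotated")
  cells <- unique(cells)
  f <- tess$faces
  touch <- f$cell1 %in% cells | (!is.na(f$cell2) & f$cell2 %in% cells)
  closed <- f$cvmax < cv
  sum(f$area[touch & closed])
}

#' Partition a channel's void into surface pockets, active site and transit
#'
#' A cell is a surface-pocket cell iff it carries a hull face, or is
#' connected to such a cell through cells that all keep at least one vertex
#' atom on the convex hull (concavities draped over the protein surface).
#' Interior cells whose vertex set touches the target residue's atoms (by
#' default the heme) form the active-site region; remaining interior cells
#' are transit. Fractions are volume-weighted and sum to at most 1.
#'
#' @param channel a `channel` from [channels_at()], or an integer cell set.
#' @param tess an annotated tessellation whose `atoms` table carries the
#'   `category` column (cofactor atoms delimit the active site).
#' @param site_atoms optional explicit atom row indices defining the active
#'   site; defaults to the cofactor atoms of `tess$atoms`.
#' @return named numeric: `surface_fraction`, `active_site_fraction`,
#'   `transit_fraction`.
#' @export
classify_void <- function(channel, tess, site_atoms = NULL) {
  cells <- if (inherits(channel, "channel")) channel$cells else
    as.integer(channel)
  stopifnot(length(cells) > 0, inherits(tess, "tessellation"))
  f <- tess$faces
  hull_cells <- unique(f$cell1[is.na(f$cell2)])
  hull_atoms <- unique(unlist(f[is.na(f$cell2), c("v1", "v2", "v3")]))
  has_hull_vertex <- rowSums(matrix(tess$tetra %in% hull_atoms,
                                    nrow(tess$tetra))) > 0

  inset <- logical(nrow(tess$tetra)); inset[cells] <- TRUE
  surface <- logical(nrow(tess$tetra))
  frontier <- intersect(cells, hull_cells)
  surface[frontier] <- TRUE
  # spread through hull-touching cells of the set (internal faces only)
  internal <- f[!is.na(f$cell2), c("cell1", "cell2")]
  repeat {
    nb <- c(internal$cell2[surface[internal$cell1]],
            internal$cell1[surface[internal$cell2]])
    nb <- unique(nb[inset[nb] & !surface[nb] & has_hull_vertex[nb]])
    if (!length(nb)) break
    surface[nb] <- TRUE
  }

  if (is.null(site_atoms)) {
    cat_col <- tess$atoms$category
    site_atoms <- if (!is.null(cat_col)) which(cat_col == "cofactor") else
      integer(0)
  }
  touches_site <- rowSums(matrix(tess$tetra %in% site_atoms,
                                 nrow(tess$tetra))) > 0

  vol <- tess$vol
  vtot <- sum(vol[cells])
  s <- sum(vol[cells][surface[cells]])
  a <- sum(vol[cells][!surface[cells] & touches_site[cells]])
  c(surface_fraction = s / vtot,
    active_site_fraction = a / vtot,
    transit_fraction = max(0, vtot - s - a) / vtot)
}
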