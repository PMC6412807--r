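## Two visualization modes, both emitted as plain PDB for any viewer:
## mode 1 draws the facial graph (virtual atoms at tetrahedron barycenters,
## passable shared faces as bonds); mode 2 draws a region's boundary (the
## tessellation edges of its closed faces as pseudo-bonds between the
## original protein atoms).

#' Export the facial graph as virtual atoms and bonds (mode 1)
#'
#' One HETATM pseudo-atom per tetrahedron, placed at the barycenter of its
#' four vertex atoms, with CONECT records between pseudo-atoms whose shared
#' face is passable at `cv`. Pseudo-atoms are carbon, residue `TET`, chain
#' `Z`, numbered by cell id, so output is deterministic. If more than 99999
#' pseudo-atoms are requested the file is split into MODEL blocks with
#' renumbered serials (with a warning).
#'
#' @param tess an annotated tessellation.
#' @param cv ligand thickness defining passable faces.
#' @param cells optional subset of cell ids (default all).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
export_facial_graph <- function(tess, cv, path, cells = NULL) {
  stopifnot(inherits(tess, "tessellation"))
  if (anyNA(tess$faces$cvmax)) stop("faces are not CVmax-annotated")
  if (is.null(cells)) cells <- seq_len(nrow(tess$tetra))
  cells <- sort(unique(cells))
  f <- tess$faces
  keep <- !is.na(f$cell2) & f$cvmax >= cv &
    f$cell1 %in% cells & f$cell2 %in% cells
  serial_of <- integer(nrow(tess$tetra))
  serial_of[cells] <- seq_along(cells)
  if (length(cells) > 99999) {
    warning("more than 99999 pseudo-atoms; writing multi-model output")
    return(.export_multimodel(tess, cells, f[keep, , drop = FALSE], path))
  }
  if (!length(cells)) {
    writeLines(c("REMARK   3 facial graph (empty cell set)", "END"), path)
    return(invisible(path))
  }
  at <- data.frame(
    serial = serial_of[cells], name = "C", element = "C", alt_loc = "",
    resname = "TET", chain = "Z", resno = serial_of[cells] %% 10000L,
    icode = "", x = tess$bary[cells, 1], y = tess$bary[cells, 2],
    z = tess$bary[cells, 3], occ = 1, category = "pseudo")
  conect <- cbind(serial_of[f$cell1[keep]], serial_of[f$cell2[keep]])
  write_structure(at, path, conect = conect,
                  remarks = sprintf("facial graph at CV=%.3f A", cv))
  invisible(path)
}

.export_multimodel <- function(tess, cells, faces, path) {
  chunks <- split(cells, (seq_along(cells) - 1) %/% 99999L)
  lines <- character(0)
  for (ci in seq_along(chunks)) {
    cl <- chunks[[ci]]
    serial <- seq_along(cl)
    lines <- c(lines, sprintf("MODEL     %4d", ci), sprintf(
      "HETATM%5d  C   TET Z%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, serial %% 10000L, tess$bary[cl, 1], tess$bary[cl, 2],
      tess$bary[cl, 3]), "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Export a region's boundary as pseudo-bonds between protein atoms (mode 2)
#'
#' Writes the region's vertex atoms with their original coordinates and
#' serial numbers, plus CONECT records for every edge of every boundary
#' face (a face incident to the region with `cvmax < cv`); each undirected
#' edge is written once. The bonds come from the tessellation, not from
#' chemistry.
#'
#' @param cells integer cell ids of the region (an MCP's or channel's cells).
#' @param tess an annotated tessellation.
#' @param cv ligand thickness defining closed faces.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
export_boundary <- function(cells, tess, cv, path) {
  stopifnot(inherits(tess, "tessellation"))
  if (anyNA(tess$faces$cvmax)) stop("faces are not CVmax-annotated")
  cells <- unique(cells)
  ai <- lining_atoms(cells, tess)
  f <- tess$faces
  touch <- f$cell1 %in% cells | (!is.na(f$cell2) & f$cell2 %in% cells)
  bf <- f[touch & f$cvmax < cv, , drop = FALSE]
  edges <- rbind(cbind(bf$v1, bf$v2), cbind(bf$v1, bf$v3),
                 cbind(bf$v2, bf$v3))
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort.int))
    edges <- unique(edges)
  }
  at <- tess$atoms[ai, , drop = FALSE]
  if (is.null(at$serial)) at$serial <- ai
  need <- c("name", "element", "alt_loc", "resname", "chain", "resno",
            "icode", "occ", "category")
  defaults <- list(name = "CA", element = "C", alt_loc = "", resname = "UNK",
                   chain = "A", resno = 1L, icode = "", occ = 1,
                   category = "protein")
  for (col in need) if (is.null(at[[col]])) at[[col]] <- defaults[[col]]
  conect <- if (nrow(edges))
    cbind(at$serial[match(edges[, 1], ai)], at$serial[match(edges[, 2], ai)])
  else NULL
  write_structure(at, path, conect = conect,
                  remarks = sprintf("region boundary at CV=%.3f A", cv))
  invisible(path)
}
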