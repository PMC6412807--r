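## Lining report: the atoms and residues a tetrahedron set is built from,
## and the secondary-structure elements at a trajectory's egress.

#' Atoms lining a set of cells
#'
#' Union of the vertex atoms of the member tetrahedra. Satisfies
#' `lining_atoms(union(A, B)) == union(lining_atoms(A), lining_atoms(B))`.
#'
#' @inheritParams region_volume
#' @return sorted integer vector of atom row indices into the tessellated
#'   atom set.
#' @export
lining_atoms <- function(cells, tess) {
  stopifnot(inherits(tess, "tessellation"))
  if (!length(cells)) return(integer(0))
  sort(unique(as.vector(tess$tetra[unique(cells), , drop = FALSE])))
}

#' Residues lining a set of cells
#'
#' Unique residues of the lining atoms, sorted by chain then residue
#' number; cofactor (heme) entries are listed after protein residues.
#'
#' @inheritParams region_volume
#' @param atoms atom table matching the tessellated set; defaults to
#'   `tess$atoms`.
#' @return data frame with columns `chain`, `resno`, `resname`, `category`,
#'   `n_atoms` (lining atoms contributed by the residue).
#' @export
lining_residues <- function(cells, tess, atoms = NULL) {
  if (is.null(atoms)) atoms <- tess$atoms
  ai <- lining_atoms(cells, tess)
  if (!length(ai) || is.null(atoms$resno)) {
    return(data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), category = character(0),
                      n_atoms = integer(0)))
  }
  at <- atoms[ai, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$resname)
  agg <- aggregate(list(n_atoms = key), by = list(
    chain = at$chain, resno = at$resno, resname = at$resname,
    category = at$category), FUN = length)
  agg <- agg[order(agg$category != "protein", agg$chain, agg$resno), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Secondary-structure elements at a trajectory's egress
#'
#' Finds the cells of the set that carry an open hull face (the mouths),
#' takes their lining residues, and reports the HELIX/SHEET elements
#' containing them; mouth residues matched by no record are reported as a
#' loop element. An optional annotation table (label, chain, first, last)
#' can override the PDB element labels with curated names.
#'
#' @param x a `trajectory`, `channel`, or integer cell set.
#' @param tess annotated tessellation.
#' @param model `structure_model` providing HELIX/SHEET records.
#' @param cv ligand thickness defining which hull doors are open; defaults
#'   to the trajectory/channel's own `cv`.
#' @param annotations optional data frame with columns `label`, `chain`,
#'   `first`, `last` replacing the model's element table.
#' @return data frame of elements (`kind`, `label`, `chain`, `first`,
#'   `last`); zero rows with attribute `reaches_exterior = FALSE` when the
#'   set has no open hull door.
#' @export
egress_elements <- function(x, tess, model, cv = NULL, annotations = NULL) {
  cells <- if (is.list(x)) x$cells else as.integer(x)
  if (is.null(cv) && is.list(x)) {
    cv <- if (!is.null(x$cv)) x$cv else x$member_mcps[[1]]$cv
  }
  stopifnot(!is.null(cv))
  f <- tess$faces
  open_hull <- is.na(f$cell2) & f$cvmax >= cv
  mouth_cells <- intersect(unique(f$cell1[open_hull]), cells)
  if (!length(mouth_cells)) {
    out <- data.frame(kind = character(0), label = character(0),
                      chain = character(0), first = integer(0),
                      last = integer(0))
    attr(out, "reaches_exterior") <- FALSE
    return(out)
  }
  res <- lining_residues(mouth_cells, tess)
  res <- res[res$category == "protein", , drop = FALSE]
  el <- if (!is.null(annotations)) {
    data.frame(kind = if (is.null(annotations$kind)) "annotated" else
                 annotations$kind,
               label = annotations$label, chain = annotations$chain,
               first = annotations$first, last = annotations$last,
               stringsAsFactors = FALSE)
  } else model$elements
  hits <- list()
  unmatched <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    m <- which(el$chain == res$chain[i] & el$first <= res$resno[i] &
                 el$last >= res$resno[i])
    if (length(m)) hits[[length(hits) + 1]] <- el[m, , drop = FALSE]
    else unmatched[i] <- TRUE
  }
  out <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(kind = character(0), label = character(0),
               chain = character(0), first = integer(0), last = integer(0))
  if (any(unmatched)) {
    lo <- res[unmatched, , drop = FALSE]
    for (ch in unique(lo$chain)) {
      rr <- range(lo$resno[lo$chain == ch])
      out <- rbind(out, data.frame(kind = "loop",
                                   label = sprintf("loop %d-%d", rr[1], rr[2]),
                                   chain = ch, first = rr[1], last = rr[2]))
    }
  }
  rownames(out) <- NULL
  attr(out, "reaches_exterior") <- TRUE
  out
}
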