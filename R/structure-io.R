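#' Van der Waals radii table
#'
#' Bondi-style van der Waals radii in Angstrom for the elements commonly met
#' in protein crystal structures, plus a fallback for anything else. The
#' table is a named numeric vector keyed by upper-case element symbol. A
#' user-supplied key-value file (`element: radius` per line, `#` comments)
#' can replace or extend it.
#'
#' @param file optional path to a key-value radii file overriding defaults.
#' @param default radius (Angstrom) used for elements absent from the table.
#' @return named numeric vector of radii with attribute `default`.
#' @examples
#' vdw_radii()[["C"]]
#' @export
vdw_radii <- function(file = NULL, default = 2.0) {
  tab <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 2.05,
    CU = 1.40, "NA" = 2.27, K = 2.75, CO = 2.00, NI = 1.63
  )
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "[:=[:space:]]+")[[1]]
      if (length(kv) >= 2) tab[toupper(kv[1])] <- as.numeric(kv[2])
    }
  }
  attr(tab, "default") <- default
  tab
}

## fixed-width column layout of PDB ATOM/HETATM records
.pdb_atom_fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"

.format_atom_name <- function(name, element) {
  # one/two-letter elements are right-justified into columns 13-14
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 2 || nchar(name) == 4) sprintf("%-4s", name)
  else sprintf(" %-3s", name)
}

.infer_element <- function(name) {
  nm <- gsub("[0-9' ]", "", toupper(name))
  two <- substr(nm, 1, 2)
  if (two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA", "CU", "NI", "CO")) two
  else substr(nm, 1, 1)
}

#' Parse a PDB structure
#'
#' Reads ATOM/HETATM/HELIX/SHEET records from a PDB file or from PDB text.
#' Hydrogens (and deuteriums) are dropped; alternate locations are resolved
#' by keeping the highest-occupancy conformer (ties broken in favour of
#' altLoc `"A"`, then lowest serial). Each atom is assigned a category:
#' `ATOM` records are `protein`, `HETATM` heme (`HEM`/`HEC`) is `cofactor`,
#' water (`HOH`/`WAT`/`DOD`) is `water`, and any other `HETATM` is `ligand`.
#'
#' @param pdb path to a PDB file, or a character vector / single string of
#'   PDB-format text.
#' @param id structure label; defaults to the file basename or `"structure"`.
#' @return an object of class `structure_model`: a list with elements
#'   `id`, `atoms` (data frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`,
#'   `category`, `vdw_radius`) and `elements` (data frame of secondary
#'   structure: `kind`, `label`, `chain`, `first`, `last`).
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "HETATM    2 FE   HEM A  99       1.000   1.000   1.000  1.00  0.00          FE")
#' m <- read_structure(pdb)
#' m$atoms$category
#' @export
read_structure <- function(pdb, id = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  } else {
    txt <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(txt, path)
    if (is.null(id)) id <- "structure"
  }
  p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                        verbose = FALSE))
  at <- p$atom
  if (nrow(at) == 0) stop("no parsable ATOM/HETATM records in input")

  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "", NA, at$elesy)))
  miss <- is.na(elem)
  if (any(miss)) {
    warning("element column missing for ", sum(miss), " atoms; inferring from atom name")
    elem[miss] <- vapply(at$elety[miss], .infer_element, character(1))
  }

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    alt_loc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    record = at$type,
    stringsAsFactors = FALSE
  )

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms in input")

  # alternate-location resolution: highest occupancy, tie -> altLoc 'A'
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname, atoms$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occ,
                 atoms$alt_loc != "A", atoms$alt_loc, atoms$serial)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }

  atoms$category <- ifelse(atoms$record == "ATOM", "protein",
                    ifelse(atoms$resname %in% c("HEM", "HEC"), "cofactor",
                    ifelse(atoms$resname %in% c("HOH", "WAT", "DOD"), "water",
                           "ligand")))
  atoms$record <- NULL
  atoms$vdw_radius <- NA_real_
  rownames(atoms) <- NULL

  elements <- .parse_secondary(p)

  structure(list(id = id, atoms = atoms, elements = elements),
            class = "structure_model")
}

.parse_secondary <- function(p) {
  out <- data.frame(kind = character(), label = character(),
                    chain = character(), first = integer(), last = integer(),
                    stringsAsFactors = FALSE)
  if (!is.null(p$helix) && length(p$helix$start)) {
    out <- rbind(out, data.frame(
      kind = "helix",
      label = paste0("H", seq_along(p$helix$start)),
      chain = p$helix$chain,
      first = as.integer(p$helix$start),
      last = as.integer(p$helix$end), stringsAsFactors = FALSE))
  }
  if (!is.null(p$sheet) && length(p$sheet$start)) {
    out <- rbind(out, data.frame(
      kind = "sheet",
      label = paste0("S", seq_along(p$sheet$start)),
      chain = p$sheet$chain,
      first = as.integer(p$sheet$start),
      last = as.integer(p$sheet$end), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$id, "\n")
  cat("  atoms:", nrow(x$atoms), "heavy atoms (",
      paste(names(table(x$atoms$category)), table(x$atoms$category),
            collapse = ", "), ")\n")
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  cat("  secondary elements:", nrow(x$elements), "\n")
  invisible(x)
}

#' Assign van der Waals radii to a structure
#'
#' Fills the `vdw_radius` column of a structure's atom table from an
#' element-to-radius map. Elements absent from the table fall back to the
#' table's default radius, with a warning naming them.
#'
#' @param model a `structure_model`.
#' @param table named radii vector as returned by [vdw_radii()].
#' @param overwrite replace radii that are already set (default `TRUE`).
#' @return the model with `vdw_radius` populated.
#' @export
assign_radii <- function(model, table = vdw_radii(), overwrite = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$atoms) == 0) return(model)
  idx <- match(toupper(model$atoms$element), names(table))
  r <- unname(table[idx])
  if (anyNA(idx)) {
    unk <- unique(model$atoms$element[is.na(idx)])
    warning("no vdW radius for element(s) ", paste(unk, collapse = ", "),
            "; using default ", attr(table, "default"), " Angstrom")
    r[is.na(idx)] <- attr(table, "default")
  }
  if (overwrite) model$atoms$vdw_radius <- r
  else {
    keep <- is.na(model$atoms$vdw_radius)
    model$atoms$vdw_radius[keep] <- r[keep]
  }
  model
}

#' Select atoms by category (and optionally chain)
#'
#' Returns the atom records whose category is in `include`, preserving input
#' order. Channels are computed for the ligand to travel through, so
#' co-crystallized ligands and waters are excluded by default while the heme
#' cofactor — whose iron is the usual target — is kept in the tessellated set.
#'
#' @param model a `structure_model`.
#' @param include character vector of categories to keep; default
#'   `c("protein", "cofactor")`.
#' @param chain optional chain id; `NULL` keeps all chains.
#' @return data frame of selected atoms.
#' @export
select_atoms <- function(model, include = c("protein", "cofactor"),
                         chain = NULL) {
  stopifnot(inherits(model, "structure_model"), length(include) > 0)
  at <- model$atoms
  keep <- at$category %in% include
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  out <- at[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("atom selection is empty (include = ",
         paste(include, collapse = ","), ")")
  rownames(out) <- NULL
  out
}

#' Target specification
#'
#' Describes the buried active-site target: an atom matched by name and
#' residue name (default the heme iron, atom `"FE"` in residue `"HEM"`), an
#' atom serial number, or a literal point in Angstrom coordinates.
#'
#' @param mode one of `"atom_name"`, `"serial"`, `"coords"`.
#' @param name,resname atom and residue name for `mode = "atom_name"`.
#' @param serial atom serial for `mode = "serial"`.
#' @param coords length-3 numeric for `mode = "coords"`.
#' @return object of class `target_spec`.
#' @export
target_spec <- function(mode = c("atom_name", "serial", "coords"),
                        name = "FE", resname = "HEM",
                        serial = NULL, coords = NULL) {
  mode <- match.arg(mode)
  spec <- switch(mode,
    atom_name = list(mode = mode, name = toupper(name),
                     resname = toupper(resname)),
    serial = {
      stopifnot(length(serial) == 1)
      list(mode = mode, serial = as.integer(serial))
    },
    coords = {
      stopifnot(length(coords) == 3, all(is.finite(coords)))
      list(mode = mode, coords = as.numeric(coords))
    })
  structure(spec, class = "target_spec")
}

#' Resolve a target specification against a set of atoms
#'
#' @param atoms atom data frame (e.g. from [select_atoms()]) or a
#'   `structure_model`.
#' @param spec a [target_spec()].
#' @return for atom modes, the unique row index of the target atom within
#'   `atoms`; for `mode = "coords"`, the literal point (with attribute
#'   `point = TRUE`).
#' @export
resolve_target <- function(atoms, spec = target_spec()) {
  stopifnot(inherits(spec, "target_spec"))
  if (inherits(atoms, "structure_model")) atoms <- atoms$atoms
  if (spec$mode == "coords")
    return(structure(spec$coords, point = TRUE))
  hit <- switch(spec$mode,
    atom_name = which(toupper(atoms$name) == spec$name &
                      toupper(atoms$resname) == spec$resname),
    serial = which(atoms$serial == spec$serial))
  if (length(hit) == 0)
    stop("target not found: ", .describe_target(spec))
  if (length(hit) > 1)
    stop("ambiguous target ", .describe_target(spec), "; candidates: ",
         paste(sprintf("serial %d (%s %s%d chain %s)", atoms$serial[hit],
                       atoms$name[hit], atoms$resname[hit], atoms$resno[hit],
                       atoms$chain[hit]), collapse = "; "))
  hit
}

.describe_target <- function(spec) {
  switch(spec$mode,
    atom_name = sprintf("atom %s of residue %s", spec$name, spec$resname),
    serial = sprintf("serial %d", spec$serial),
    coords = sprintf("point (%.2f, %.2f, %.2f)", spec$coords[1],
                     spec$coords[2], spec$coords[3]))
}

#' Write atoms as PDB records
#'
#' Writes a PDB file for an atom table or a `structure_model` (including
#' HELIX/SHEET records when present). Coordinates are written at the PDB
#' precision of 1e-3 Angstrom.
#'
#' @param x atom data frame or `structure_model`.
#' @param path output file path.
#' @param conect optional two-column integer matrix of atom serial pairs
#'   written as CONECT records.
#' @param remarks optional character vector written as REMARK lines.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, conect = NULL, remarks = NULL) {
  model <- NULL
  if (inherits(x, "structure_model")) { model <- x; x <- x$atoms }
  lines <- character(0)
  if (!is.null(remarks)) lines <- c(lines, sprintf("REMARK   3 %s", remarks))
  if (!is.null(model) && nrow(model$elements)) {
    el <- model$elements
    h <- el[el$kind == "helix", , drop = FALSE]
    if (nrow(h)) lines <- c(lines, sprintf(
      "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d  1                               %5d",
      seq_len(nrow(h)), substr(h$label, 1, 3), "ALA", h$chain, h$first,
      "ALA", h$chain, h$last, h$last - h$first + 1))
    s <- el[el$kind == "sheet", , drop = FALSE]
    if (nrow(s)) lines <- c(lines, sprintf(
      "SHEET  %3d %3s 1 %3s %1s%4d  %3s %1s%4d  0",
      seq_len(nrow(s)), substr(s$label, 1, 3), "ALA", s$chain, s$first,
      "ALA", s$chain, s$last))
  }
  if (nrow(x)) {
    rec <- ifelse(x$category %in% c("protein"), "ATOM", "HETATM")
    names4 <- vapply(seq_len(nrow(x)),
                     function(i) .format_atom_name(x$name[i], x$element[i]),
                     character(1))
    lines <- c(lines, sprintf(
      "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, x$serial %% 100000L, names4,
      substr(paste0(x$alt_loc, " "), 1, 1), substr(x$resname, 1, 3),
      substr(paste0(x$chain, " "), 1, 1), x$resno %% 10000L,
      substr(paste0(x$icode, " "), 1, 1),
      x$x, x$y, x$z, ifelse(is.na(x$occ), 1, x$occ), 0, x$element))
  }
  if (!is.null(conect) && nrow(conect)) {
    lines <- c(lines, sprintf("CONECT%5d%5d", conect[, 1], conect[, 2]))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
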