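#' Volume of a tetrahedron
#'
#' `|det(p2-p1, p3-p1, p4-p1)| / 6`; degenerate (coplanar) input gives 0.
#'
#' @param p1,p2,p3,p4 length-3 numeric coordinates (Angstrom).
#' @return volume in cubic Angstrom.
#' @examples
#' tetra_volume(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))  # 1/6
#' @export
tetra_volume <- function(p1, p2, p3, p4) {
  abs(det(cbind(p2 - p1, p3 - p1, p4 - p1))) / 6
}

#' Area of a triangle
#'
#' `||(p2-p1) x (p3-p1)|| / 2`; collinear input gives 0.
#'
#' @param p1,p2,p3 length-3 numeric coordinates (Angstrom).
#' @return area in square Angstrom.
#' @export
face_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cr^2)) / 2
}

.find_python <- function() {
  for (cand in c(Sys.getenv("TUNNELTESS_PYTHON"), "python3", "python")) {
    if (nzchar(cand) && nzchar(Sys.which(cand))) return(cand)
  }
  stop("no python interpreter found on PATH (required for the Qhull ",
       "Delaunay backend); set TUNNELTESS_PYTHON to override")
}

.delaunay_backend <- function(xyz) {
  script <- system.file("python", "delaunay3d.py", package = "tunneltess",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write.table(format(xyz, digits = 17, scientific = TRUE, trim = TRUE),
              fin, row.names = FALSE, col.names = FALSE, quote = FALSE)
  out <- suppressWarnings(system2(.find_python(), c(script, fin, fout),
                                  stdout = TRUE, stderr = TRUE))
  if (!file.exists(fout) || length(readLines(fout, n = 1)) == 0)
    stop("Delaunay backend failed: ", paste(out, collapse = " "))
  hdr <- scan(fout, n = 3, quiet = TRUE)
  simp <- matrix(scan(fout, skip = 1, quiet = TRUE), ncol = 4, byrow = TRUE)
  list(simplices = simp + 1L, hull_volume = hdr[2], n_coplanar = hdr[3])
}

#' Delaunay tessellation of a heavy-atom set
#'
#' Partitions the convex hull of the atoms into non-overlapping tetrahedral
#' cells with atoms at their vertices (Delaunay), and builds the triangular
#' face topology: every face is either internal (shared by exactly two
#' cells) or a hull face (one cell, exterior on the other side). Faces are
#' identified by their sorted vertex triple and numbered in that order, so
#' ids are deterministic. Degenerate (co-spherical/coplanar) input is
#' retried after a deterministic jitter of `jitter` Angstrom drawn with the
#' given seed.
#'
#' @param atoms atom data frame with columns `x`, `y`, `z`, `vdw_radius`
#'   (e.g. from [select_atoms()] after [assign_radii()]), or a plain
#'   3-column coordinate matrix (then radii default to 0).
#' @param jitter magnitude (Angstrom) of the symbolic perturbation applied
#'   only when the backend reports degeneracy.
#' @param seed seed for the jitter, recorded in the result.
#' @return object of class `tessellation`: list with `atoms` (the input
#'   table), `xyz` (n x 3 matrix), `radii`, `tetra` (m x 4 vertex indices),
#'   `vol` (m volumes), `bary` (m x 3 barycenters), `faces` (data frame
#'   `v1,v2,v3,cell1,cell2,area,cvmax`; `cell2 = NA` marks hull faces),
#'   `hull_faces` (face ids), `hull_volume` (Qhull's convex hull volume) and
#'   `jittered` flag.
#' @export
triangulate <- function(atoms, jitter = 1e-6, seed = 20987L) {
  if (is.matrix(atoms)) {
    xyz <- atoms
    atoms <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        vdw_radius = 0)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 4) stop("need at least 4 atoms to tessellate")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  radii <- if ("vdw_radius" %in% names(atoms)) atoms$vdw_radius else
    rep(0, nrow(xyz))

  res <- tryCatch(.delaunay_backend(xyz), error = function(e) e)
  jittered <- FALSE
  if (inherits(res, "error") || res$n_coplanar > 0) {
    set.seed(seed)
    xyz_j <- xyz + matrix(runif(length(xyz), -jitter, jitter), ncol = 3)
    res <- .delaunay_backend(xyz_j)
    jittered <- TRUE
    if (res$n_coplanar > 0)
      stop("degenerate point set: triangulation incomplete even after jitter")
    xyz_used <- xyz_j
  } else xyz_used <- xyz

  tetra <- res$simplices
  m <- nrow(tetra)

  # volumes and barycenters (vectorized over cells)
  a <- xyz_used[tetra[, 1], , drop = FALSE]
  b <- xyz_used[tetra[, 2], , drop = FALSE] - a
  c3 <- xyz_used[tetra[, 3], , drop = FALSE] - a
  d <- xyz_used[tetra[, 4], , drop = FALSE] - a
  vol <- abs(b[, 1] * (c3[, 2] * d[, 3] - c3[, 3] * d[, 2]) -
             b[, 2] * (c3[, 1] * d[, 3] - c3[, 3] * d[, 1]) +
             b[, 3] * (c3[, 1] * d[, 2] - c3[, 2] * d[, 1])) / 6
  bary <- (xyz_used[tetra[, 1], ] + xyz_used[tetra[, 2], ] +
           xyz_used[tetra[, 3], ] + xyz_used[tetra[, 4], ]) / 4

  # four faces per cell; canonical sorted triples
  comb <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  tri <- matrix(0L, 4L * m, 3L)
  cell_of <- rep(seq_len(m), each = 4L)
  for (k in 1:4) {
    f <- tetra[, comb[k, ], drop = FALSE]
    f <- t(apply(f, 1, sort.int))
    tri[seq(k, by = 4L, length.out = m), ] <- f
  }
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  ord <- order(tri[, 1], tri[, 2], tri[, 3])
  key_s <- key[ord]
  first <- !duplicated(key_s)
  fid_sorted <- cumsum(first)
  fid <- integer(length(key)); fid[ord] <- fid_sorted
  nf <- fid_sorted[length(fid_sorted)]

  v_first <- tri[ord[first], , drop = FALSE]
  cell1 <- rep(NA_integer_, nf); cell2 <- rep(NA_integer_, nf)
  for (i in seq_along(fid)) {
    f <- fid[i]
    if (is.na(cell1[f])) cell1[f] <- cell_of[i]
    else if (is.na(cell2[f])) cell2[f] <- cell_of[i]
    else stop("face shared by more than two cells; inconsistent tessellation")
  }

  p1 <- xyz_used[v_first[, 1], , drop = FALSE]
  u <- xyz_used[v_first[, 2], , drop = FALSE] - p1
  v <- xyz_used[v_first[, 3], , drop = FALSE] - p1
  cr1 <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cr2 <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cr3 <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  area <- sqrt(cr1^2 + cr2^2 + cr3^2) / 2

  faces <- data.frame(v1 = v_first[, 1], v2 = v_first[, 2], v3 = v_first[, 3],
                      cell1 = cell1, cell2 = cell2, area = area,
                      cvmax = NA_real_)

  structure(list(atoms = atoms, xyz = xyz_used, radii = radii, tetra = tetra,
                 vol = vol, bary = bary, faces = faces,
                 hull_faces = which(is.na(cell2)),
                 hull_volume = res$hull_volume,
                 jittered = jittered, jitter_seed = seed),
            class = "tessellation")
}

#' @export
print.tessellation <- function(x, ...) {
  cat("<tessellation>", nrow(x$xyz), "atoms,", nrow(x$tetra), "cells,",
      nrow(x$faces), "faces (", length(x$hull_faces), "on hull )\n")
  cat(sprintf("  total volume %.1f A^3 (hull %.1f A^3)%s\n", sum(x$vol),
              x$hull_volume, if (x$jittered) ", jittered" else ""))
  if (!all(is.na(x$faces$cvmax)))
    cat(sprintf("  door widths CVmax: %.2f-%.2f A\n",
                min(x$faces$cvmax), max(x$faces$cvmax)))
  invisible(x)
}

#' Dump a tessellation as text (one cell per line: id + vertex indices)
#'
#' @param tess a `tessellation`.
#' @param path output path or `""` for stdout.
#' @export
dump_tessellation <- function(tess, path = "") {
  writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(tess$tetra)),
                     tess$tetra[, 1], tess$tetra[, 2], tess$tetra[, 3],
                     tess$tetra[, 4]), path)
  invisible(path)
}
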