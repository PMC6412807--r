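## Cylindrical ligand model: the ligand thickness CV is the diameter of the
## smallest enclosing cylinder of the ligand's vdW spheres, minimized over
## the axis direction. For a fixed direction the section reduces to the
## minimum enclosing circle of the projected centers with additive radii.

# --- minimum enclosing circle of disks (2D, additively weighted) ---------

.circle_basis <- function(q, r) {
  b <- nrow(q)
  if (b == 0) return(list(c = c(0, 0), R = -Inf))
  if (b == 1) return(list(c = q[1, ], R = r[1]))
  if (b == 2) {
    d <- sqrt(sum((q[2, ] - q[1, ])^2))
    if (d + r[2] <= r[1]) return(list(c = q[1, ], R = r[1]))
    if (d + r[1] <= r[2]) return(list(c = q[2, ], R = r[2]))
    R <- (d + r[1] + r[2]) / 2
    u <- if (d > 0) (q[2, ] - q[1, ]) / d else c(1, 0)
    return(list(c = q[1, ] + (R - r[1]) * u, R = R))
  }
  # three boundary disks: |c - qi| = R - ri (tangent internally);
  # same algebra as the equal-clearance point with negated radii
  cand <- .apollonius_points(q, -r)
  best <- NULL
  if (!is.null(cand)) for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    R <- max(sqrt((cc[1] - q[, 1])^2 + (cc[2] - q[, 2])^2) + r)
    if (is.null(best) || R < best$R) best <- list(c = cc, R = R)
  }
  if (is.null(best)) {  # degenerate triple: fall back to best pair circle
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      cb <- .circle_basis(q[pr, , drop = FALSE], r[pr])
      R <- max(sqrt((cb$c[1] - q[, 1])^2 + (cb$c[2] - q[, 2])^2) + r)
      if (is.null(best) || R < best$R) best <- list(c = cb$c, R = R)
    }
  }
  best
}

.mec_disks <- function(q, r) {
  tol <- 1e-10 * max(1, abs(q), r)
  welzl <- function(np, B) {
    if (np == 0 || nrow(B$q) == 3) return(.circle_basis(B$q, B$r))
    D <- welzl(np - 1, B)
    i <- np
    if (sqrt(sum((q[i, ] - D$c)^2)) + r[i] <= D$R + tol) return(D)
    welzl(np - 1, list(q = rbind(B$q, q[i, ]), r = c(B$r, r[i])))
  }
  welzl(nrow(q), list(q = q[0, , drop = FALSE], r = numeric(0)))
}

# fast approximate section diameter used to rank candidate directions
.section_diam_approx <- function(xyz, r, u, iters = 40L) {
  e <- .orthobasis(u)
  px <- xyz %*% e$e1; py <- xyz %*% e$e2
  cx <- mean(px); cy <- mean(py)
  for (k in seq_len(iters)) {
    d <- sqrt((px - cx)^2 + (py - cy)^2) + r
    i <- which.max(d)
    dd <- sqrt((px[i] - cx)^2 + (py[i] - cy)^2)
    ux <- if (dd > 0) (px[i] - cx) / dd else 1
    uy <- if (dd > 0) (py[i] - cy) / dd else 0
    fx <- px[i] + r[i] * ux; fy <- py[i] + r[i] * uy
    cx <- cx + (fx - cx) / (k + 1); cy <- cy + (fy - cy) / (k + 1)
  }
  2 * max(sqrt((px - cx)^2 + (py - cy)^2) + r)
}

.section_diam_exact <- function(xyz, r, u) {
  e <- .orthobasis(u)
  q <- cbind(as.vector(xyz %*% e$e1), as.vector(xyz %*% e$e2))
  2 * .mec_disks(q, r)$R
}

.orthobasis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Ligand critical thickness under the cylindrical model
#'
#' The critical value CV of a ligand is the diameter of its smallest
#' enclosing cylinder: over all axis directions, the minimum of the
#' diameter of the smallest circle enclosing the atom spheres projected on
#' the plane normal to the axis (projected centers with additive vdW
#' radii). Directions are scanned on a Fibonacci sphere grid and the best
#' candidates are refined by local optimization over the axis angles; the
#' per-direction section problem is solved exactly (Welzl-type minimum
#' enclosing circle of disks).
#'
#' @param atoms atom data frame with `x`, `y`, `z` and `vdw_radius`
#'   columns (e.g. a ligand selection), or an n x 3 coordinate matrix.
#' @param radii optional radii overriding `atoms$vdw_radius`.
#' @param radii_mode `"vdw"` (default) measures the cylinder around the vdW
#'   spheres; `"centers"` measures around the atom centers only.
#' @param n_directions coarse direction-grid size (half-sphere equivalent;
#'   default 500).
#' @param refine number of best coarse directions polished by local
#'   optimization (default 3).
#' @return CV in Angstrom, with attribute `axis` (the optimal direction).
#' @examples
#' ligand_thickness(matrix(c(0,0,0, 0,0,3), 2, byrow = TRUE), radii = c(1, 1))
#' @export
ligand_thickness <- function(atoms, radii = NULL,
                             radii_mode = c("vdw", "centers"),
                             n_directions = 500L, refine = 3L) {
  radii_mode <- match.arg(radii_mode)
  if (is.matrix(atoms)) xyz <- atoms
  else xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) == 0) stop("empty ligand")
  if (is.null(radii)) {
    radii <- if (!is.matrix(atoms) && !is.null(atoms$vdw_radius))
      atoms$vdw_radius else rep(0, nrow(xyz))
  }
  if (anyNA(radii)) stop("ligand atoms lack vdW radii")
  if (radii_mode == "centers") radii <- rep(0, nrow(xyz))
  xyz <- sweep(xyz, 2, colMeans(xyz))

  if (nrow(xyz) == 1) {
    return(structure(2 * radii[1], axis = c(0, 0, 1)))
  }
  dirs <- .fibonacci_sphere(max(50L, n_directions))
  coarse <- apply(dirs, 1, function(u) .section_diam_approx(xyz, radii, u))
  # principal axes are natural candidates (elongated molecules)
  pca <- tryCatch(svd(xyz)$v, error = function(e) NULL)
  extra <- if (!is.null(pca)) t(pca) else NULL
  cand <- dirs[order(coarse)[seq_len(min(refine, nrow(dirs)))], ,
               drop = FALSE]
  if (!is.null(extra)) cand <- rbind(cand, extra)

  best <- Inf; best_axis <- c(0, 0, 1)
  for (i in seq_len(nrow(cand))) {
    u0 <- cand[i, ]
    ang0 <- c(acos(max(-1, min(1, u0[3]))), atan2(u0[2], u0[1]))
    obj <- function(a) {
      u <- c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
      .section_diam_exact(xyz, radii, u)
    }
    op <- optim(ang0, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 400))
    if (op$value < best) {
      best <- op$value
      a <- op$par
      best_axis <- c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
    }
  }
  structure(best, axis = best_axis)
}

#' Extract a ligand from a structure and measure its thickness
#'
#' Convenience wrapper: selects the HETATM atoms of the given residue name
#' (first residue occurrence by default), assigns radii, and calls
#' [ligand_thickness()].
#'
#' @param model a `structure_model` (radii need not be assigned yet).
#' @param resname ligand residue name (e.g. `"KTN"`).
#' @param which index of the conformer/copy when several residues match
#'   (ordered by chain then residue number), default 1.
#' @param table radii table for [assign_radii()].
#' @param ... passed to [ligand_thickness()].
#' @return CV in Angstrom.
#' @export
structure_ligand_thickness <- function(model, resname, which = 1,
                                       table = vdw_radii(), ...) {
  model <- assign_radii(model, table, overwrite = FALSE)
  at <- model$atoms
  lig <- at[toupper(at$resname) == toupper(resname) &
              at$category %in% c("ligand", "cofactor"), , drop = FALSE]
  if (!nrow(lig)) stop("no ligand residue ", resname, " in structure")
  key <- paste(lig$chain, lig$resno, lig$icode)
  copies <- unique(key)
  if (which > length(copies)) stop("only ", length(copies), " copies of ",
                                   resname, " present")
  lig <- lig[key == copies[which], , drop = FALSE]
  ligand_thickness(lig, ...)
}
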