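## Synthetic toy structures with analytic ground truth. A quasi-uniform
## atom shell encloses a single buried target atom; a pore is carved at a
## pole and framed by three atoms placed on a circle of radius
## aperture/2, so the pore door is an equilateral triangle whose widest
## clear disc has diameter exactly aperture - 2 * atom_radius (the frame
## atoms are not jittered; the rest of the shell is).

.fixture_shell_points <- function(shell_radius, n_atoms, seed, jitter) {
  pts <- .fibonacci_sphere(n_atoms) * shell_radius
  set.seed(seed)
  pts + matrix(runif(3 * n_atoms, -jitter, jitter), ncol = 3)
}

.pore_frame <- function(shell_radius, aperture, pole = c(0, 0, 1)) {
  # three atoms on the sphere, on a circle of in-plane radius aperture/2
  # centered on the pole axis
  rho <- aperture / 2
  if (rho >= shell_radius) stop("aperture too wide for the shell")
  zc <- sqrt(shell_radius^2 - rho^2) * sign(pole[3])
  az <- c(0, 2 * pi / 3, 4 * pi / 3)
  cbind(rho * cos(az), rho * sin(az), zc)
}

.fixture_model <- function(xyz, radii, id, remarks, elements = NULL,
                           resname = "ALA") {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n),
    name = c(rep("CA", n - 1), "FE"),
    element = c(rep("C", n - 1), "FE"),
    alt_loc = "", resname = c(rep(resname, n - 1), "HEM"),
    chain = "A",
    resno = c(seq_len(n - 1), 9999L),
    icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1,
    category = c(rep("protein", n - 1), "cofactor"),
    vdw_radius = radii,
    stringsAsFactors = FALSE)
  if (is.null(elements))
    elements <- data.frame(kind = character(0), label = character(0),
                           chain = character(0), first = integer(0),
                           last = integer(0))
  structure(list(id = id, atoms = atoms, elements = elements,
                 remarks = remarks), class = "structure_model")
}

#' Toy shell structure with a single pore of analytic width
#'
#' Builds a quasi-uniform spherical shell of pseudo-atoms (Fibonacci
#' placement plus seeded jitter) with a buried target atom (`FE` of residue
#' `HEM`) at the center and, unless `aperture_width` is 0, one pore at the
#' north pole framed by three unjittered atoms so that the pore door admits
#' ligands up to exactly `aperture_width - 2 * atom_radius`. The three
#' frame residues are annotated as a one-turn helix, so egress reporting
#' can be tested against a known element. Deterministic for a fixed seed.
#'
#' @param shell_radius shell radius in Angstrom.
#' @param atom_radius vdW radius given to every shell atom.
#' @param n_atoms number of shell atoms (>= 100) before carving.
#' @param aperture_width pore width in Angstrom (0 = closed shell).
#' @param seed jitter seed.
#' @param jitter jitter magnitude in Angstrom (recorded in a REMARK).
#' @return a `structure_model` with radii pre-assigned.
#' @export
make_shell_pore <- function(shell_radius = 15, atom_radius = 1.5,
                            n_atoms = 500, aperture_width = 8,
                            seed = 1L, jitter = 0.1) {
  stopifnot(n_atoms >= 100, shell_radius > 0, atom_radius > 0,
            aperture_width >= 0)
  spacing <- sqrt(4 * pi * shell_radius^2 / n_atoms)
  if (aperture_width / 2 + spacing >= shell_radius * sqrt(2))
    stop("aperture leaves no shell: reduce aperture_width or enlarge shell")
  pts <- .fixture_shell_points(shell_radius, n_atoms, seed, jitter)
  elements <- NULL
  if (aperture_width > 0) {
    frame <- .pore_frame(shell_radius, aperture_width)
    # clear the cap so the frame triangle is an unobstructed hull door
    keep <- sqrt(rowSums((pts - rep(c(0, 0, shell_radius),
                                    each = nrow(pts)))^2)) >
      aperture_width / 2 + 0.6 * spacing
    pts <- pts[keep, , drop = FALSE]
    pts <- rbind(pts, frame)
    nfr <- nrow(pts)
    elements <- data.frame(kind = "helix", label = "H1", chain = "A",
                           first = nfr - 2L, last = nfr,
                           stringsAsFactors = FALSE)
  }
  xyz <- rbind(pts, c(0, 0, 0))
  radii <- c(rep(atom_radius, nrow(pts)), 2.0)
  .fixture_model(xyz, radii, id = sprintf("shell_pore_a%g_s%d",
                                          aperture_width, seed),
                 remarks = sprintf("shell pore fixture seed=%d jitter=%.3f aperture=%.3f",
                                   seed, jitter, aperture_width),
                 elements = elements)
}

#' Toy two-chamber structure with two pores of different widths
#'
#' A shell as in [make_shell_pore()] with pores at the two poles
#' (`aperture1` north, `aperture2` south) and an equatorial wall of atoms
#' separating the two hemispherical chambers. The wall keeps a clearing of
#' radius `clearing` around the central target atom: doors crossing the
#' wall near the target are narrow (closed at the pore widths of interest)
#' while each chamber keeps wide doors onto the target atom's own cell
#' star, so the two pore systems are cell-disjoint components that both
#' reach the active site. Ground truth: the first channel appears at
#' `aperture1 - 2 * atom_radius`, the second at `aperture2 - 2 *
#' atom_radius`.
#'
#' @inheritParams make_shell_pore
#' @param aperture1,aperture2 pore widths (north/south), `aperture1 >=
#'   aperture2`.
#' @param clearing radius of the atom-free disc kept around the target in
#'   the wall plane.
#' @return a `structure_model` with radii pre-assigned.
#' @export
make_two_pore <- function(shell_radius = 15, atom_radius = 1.5,
                          n_atoms = 500, aperture1 = 8, aperture2 = 5,
                          seed = 1L, jitter = 0.1, clearing = 4) {
  stopifnot(n_atoms >= 100, aperture1 >= aperture2, aperture2 > 0,
            clearing < shell_radius)
  spacing <- sqrt(4 * pi * shell_radius^2 / n_atoms)
  pts <- .fixture_shell_points(shell_radius, n_atoms, seed, jitter)
  pole_n <- c(0, 0, shell_radius); pole_s <- c(0, 0, -shell_radius)
  keep <- sqrt(rowSums((pts - rep(pole_n, each = nrow(pts)))^2)) >
    aperture1 / 2 + 0.6 * spacing &
    sqrt(rowSums((pts - rep(pole_s, each = nrow(pts)))^2)) >
    aperture2 / 2 + 0.6 * spacing
  pts <- pts[keep, , drop = FALSE]

  # equatorial wall: Vogel spiral annulus from the clearing to the shell
  k <- ceiling(pi * (shell_radius^2 - clearing^2) / spacing^2 * 1.8)
  i <- seq_len(k)
  rr <- shell_radius * sqrt(i / k)
  th <- pi * (1 + sqrt(5)) * i
  wall <- cbind(rr * cos(th), rr * sin(th), 0)
  wall <- wall[rr >= clearing & rr <= shell_radius - 0.1 * spacing, ,
               drop = FALSE]
  set.seed(seed + 1L)
  wall <- wall + matrix(runif(length(wall), -jitter, jitter),
                        ncol = 3)

  frame1 <- .pore_frame(shell_radius, aperture1, c(0, 0, 1))
  frame2 <- .pore_frame(shell_radius, aperture2, c(0, 0, -1))
  pts <- rbind(pts, wall, frame1, frame2)
  nfr <- nrow(pts)
  elements <- data.frame(kind = "helix", label = c("H1", "H2"), chain = "A",
                         first = c(nfr - 5L, nfr - 2L),
                         last = c(nfr - 3L, nfr), stringsAsFactors = FALSE)
  xyz <- rbind(pts, c(0, 0, 0))
  radii <- c(rep(atom_radius, nrow(pts)), 2.0)
  .fixture_model(xyz, radii,
                 id = sprintf("two_pore_a%g_%g_s%d", aperture1, aperture2,
                              seed),
                 remarks = sprintf("two pore fixture seed=%d jitter=%.3f apertures=%.3f,%.3f clearing=%.2f",
                                   seed, jitter, aperture1, aperture2,
                                   clearing),
                 elements = elements)
}
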