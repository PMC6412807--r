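# Cylindrical ligand model: closed forms, invariances, bounds, convergence.

test_that("degenerate ligands have closed-form thickness", {
  expect_equal(as.numeric(ligand_thickness(matrix(c(0, 0, 0), 1),
                                           radii = 1.6)), 3.2)
  line <- cbind(0, 0, seq(0, 8, by = 2))
  expect_equal(as.numeric(ligand_thickness(line, radii = rep(1.2, 5))), 2.4,
               tolerance = 1e-6)
})

test_that("a flat square of spheres measures across its side", {
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  v <- ligand_thickness(sq, radii = rep(1, 4))
  expect_equal(as.numeric(v), 4, tolerance = 1e-6)
})

test_that("thickness is invariant under rigid motions", {
  set.seed(21)
  xyz <- matrix(rnorm(36, sd = 2), ncol = 3)
  r <- runif(12, 1.2, 1.9)
  v0 <- as.numeric(ligand_thickness(xyz, radii = r))
  for (k in 1:4) {
    R <- random_rotation(); t0 <- rnorm(3, sd = 8)
    v <- as.numeric(ligand_thickness(xyz %*% t(R) + rep(t0, each = 12),
                                     radii = r))
    expect_equal(v, v0, tolerance = 1e-6)
  }
})

test_that("thickness never exceeds the enclosing-sphere diameter", {
  set.seed(22)
  for (k in 1:5) {
    n <- sample(5:20, 1)
    xyz <- matrix(rnorm(3 * n, sd = 2.5), ncol = 3)
    r <- runif(n, 1, 2)
    cvv <- as.numeric(ligand_thickness(xyz, radii = r))
    expect_lte(cvv, 2 * enclosing_ball_radius(xyz, r) + 1e-6)
    # and is at least the largest single sphere
    expect_gte(cvv, 2 * max(r) - 1e-9)
  }
})

test_that("doubling the direction grid moves the result by < 0.05 A", {
  set.seed(23)
  xyz <- matrix(rnorm(30, sd = 2.5), ncol = 3)
  r <- runif(10, 1.2, 1.8)
  a <- as.numeric(ligand_thickness(xyz, radii = r, n_directions = 250))
  b <- as.numeric(ligand_thickness(xyz, radii = r, n_directions = 500))
  expect_lt(abs(a - b), 0.05)
})

test_that("center-only mode drops the vdW augmentation", {
  line <- cbind(0, 0, seq(0, 6, by = 2))
  v <- ligand_thickness(line, radii = rep(1.5, 4), radii_mode = "centers")
  expect_equal(as.numeric(v), 0, tolerance = 1e-6)
})

test_that("ligands are extracted from structures by residue name", {
  # a fake two-copy ligand structure
  pdb <- c(
    "HETATM    1  C1  KTN A 700       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  KTN A 700       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  KTN A 701       0.000   0.000  10.000  1.00  0.00           C",
    "END")
  m <- read_structure(pdb)
  v1 <- structure_ligand_thickness(m, "KTN", which = 1)
  expect_equal(as.numeric(v1), 2 * 1.7, tolerance = 1e-6)
  v2 <- structure_ligand_thickness(m, "KTN", which = 2)
  expect_equal(as.numeric(v2), 2 * 1.7)
  expect_error(structure_ligand_thickness(m, "KTN", which = 3), "copies")
  expect_error(structure_ligand_thickness(m, "XYZ"), "no ligand")
})
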