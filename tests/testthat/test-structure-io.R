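test_that("PDB parsing assigns categories and drops hydrogens", {
  m <- read_structure(minimal_pdb())
  expect_s3_class(m, "structure_model")
  # 3 protein heavy atoms (H dropped), 1 cofactor, 1 water, 1 ligand
  expect_equal(sum(m$atoms$category == "protein"), 3)
  expect_equal(sum(m$atoms$category == "cofactor"), 1)
  expect_equal(sum(m$atoms$category == "water"), 1)
  expect_equal(sum(m$atoms$category == "ligand"), 1)
  expect_false(any(m$atoms$element %in% c("H", "D")))
  expect_equal(m$atoms$resname[m$atoms$category == "cofactor"], "HEM")
  # HELIX parsed
  expect_equal(nrow(m$elements), 1)
  expect_equal(m$elements$kind, "helix")
  expect_equal(c(m$elements$first, m$elements$last), c(10, 12))
})

test_that("two plain ATOM records give two protein atoms", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C")
  m <- read_structure(pdb)
  expect_equal(nrow(m$atoms), 2)
  expect_true(all(m$atoms$category == "protein"))
})

test_that("alternate locations keep the highest occupancy, ties go to A", {
  pdb <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB BALA A   1       0.000   9.000   0.000  0.70  0.00           C",
    "ATOM      4  CB AALA A   1       0.000   1.000   0.000  0.30  0.00           C",
    "ATOM      5  N  BALA A   1       5.000   0.000   0.000  0.50  0.00           N",
    "ATOM      6  N  AALA A   1       0.000   5.000   0.000  0.50  0.00           N")
  m <- read_structure(pdb)
  expect_equal(nrow(m$atoms), 3)
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(ca$alt_loc, "A")        # higher occupancy
  cb <- m$atoms[m$atoms$name == "CB", ]
  expect_equal(cb$alt_loc, "B")        # higher occupancy wins over A
  nn <- m$atoms[m$atoms$name == "N", ]
  expect_equal(nn$alt_loc, "A")        # tie -> A
})

test_that("unparsable input is a hard error", {
  expect_error(read_structure("REMARK nothing here"), "parsable|PDB|records")
})

test_that("radius assignment uses the table with warned fallback", {
  m <- read_structure(minimal_pdb())
  m <- assign_radii(m)
  expect_equal(m$atoms$vdw_radius[m$atoms$element == "C"][1], 1.70)
  expect_equal(m$atoms$vdw_radius[m$atoms$element == "FE"][1], 2.00)
  # unknown element falls back with a warning
  tab <- vdw_radii(default = 1.9)
  tab <- tab[names(tab) != "FE"]
  attr(tab, "default") <- 1.9
  expect_warning(m2 <- assign_radii(m, tab), "FE")
  expect_equal(m2$atoms$vdw_radius[m2$atoms$element == "FE"][1], 1.9)
})

test_that("radii config files override defaults", {
  f <- tempfile()
  writeLines(c("# custom", "C: 1.60", "XX: 2.50"), f)
  tab <- vdw_radii(f)
  expect_equal(unname(tab[["C"]]), 1.60)
  expect_equal(unname(tab[["XX"]]), 2.50)
  expect_equal(unname(tab[["N"]]), 1.55)
})

test_that("atom selection filters categories and rejects empty results", {
  m <- read_structure(minimal_pdb())
  sel <- select_atoms(m)   # default protein + cofactor
  expect_equal(nrow(sel), 4)
  expect_true(all(sel$category %in% c("protein", "cofactor")))
  all3 <- select_atoms(m, c("protein", "cofactor", "ligand"))
  expect_equal(nrow(all3), 5)
  expect_false(any(all3$category == "water"))
  # no ATOM-record-free category present -> error
  apo <- m
  apo$atoms <- apo$atoms[apo$atoms$category != "ligand", ]
  expect_error(select_atoms(apo, "ligand"), "empty")
})

test_that("target resolution finds the heme iron and reports ambiguity", {
  m <- read_structure(minimal_pdb())
  i <- resolve_target(m$atoms)
  expect_equal(m$atoms$name[i], "FE")
  expect_equal(m$atoms$resname[i], "HEM")
  expect_error(resolve_target(m$atoms, target_spec("serial", serial = 1234)),
               "not found")
  # duplicated heme iron on two chains -> error listing candidates
  dup <- m$atoms
  extra <- dup[dup$name == "FE", ]
  extra$chain <- "B"; extra$serial <- 99
  dup <- rbind(dup, extra)
  expect_error(resolve_target(dup), "ambiguous.*99|99.*ambiguous")
  # literal point passes through
  pt <- resolve_target(m$atoms, target_spec("coords", coords = c(1, 2, 3)))
  expect_true(isTRUE(attr(pt, "point")))
  expect_equal(as.numeric(pt), c(1, 2, 3))
})

test_that("writing and re-reading preserves coordinates to PDB precision", {
  m <- make_shell_pore(n_atoms = 120, aperture_width = 6, seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f, remarks = m$remarks)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                    as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  expect_equal(m2$atoms$category, m$atoms$category)
  # helix annotation survives the round trip
  expect_equal(m2$elements$first, m$elements$first)
  expect_equal(m2$elements$last, m$elements$last)
})

test_that("the shipped radii config loads and matches the defaults", {
  f <- system.file("extdata", "vdw_radii.txt", package = "tunneltess")
  expect_true(nzchar(f))
  tab <- vdw_radii(f)
  expect_equal(unname(tab[["C"]]), 1.70)
  expect_equal(unname(tab[["FE"]]), 2.00)
})
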