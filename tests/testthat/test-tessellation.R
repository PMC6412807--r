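test_that("tetrahedron volume and triangle area closed forms", {
  expect_equal(tetra_volume(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               1 / 6)
  expect_equal(tetra_volume(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  # homogeneity: scaling by 2 multiplies volume by 8
  p <- list(c(0.3, 1, 2), c(2, 0.5, 1), c(1, 2, 0.1), c(0.2, 0.4, 3))
  expect_equal(do.call(tetra_volume, lapply(p, function(v) 2 * v)),
               8 * do.call(tetra_volume, p))
  expect_equal(face_area(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), 6)
  expect_equal(face_area(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
  expect_equal(face_area(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)), sqrt(3))
})

test_that("a single simplex tessellates into one cell with four hull faces", {
  tess <- triangulate(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(nrow(tess$tetra), 1)
  expect_equal(nrow(tess$faces), 4)
  expect_equal(length(tess$hull_faces), 4)
  expect_equal(sum(tess$vol), 1 / 6)
})

test_that("cube corners partition into tetrahedra of total volume 1", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(cube) <- NULL
  tess <- triangulate(cube)  # degenerate (co-spherical): exercises jitter
  expect_equal(sum(tess$vol), 1, tolerance = 1e-5)
  expect_equal(sum(tess$vol), tess$hull_volume, tolerance = 1e-6)
})

test_that("two reflected corner tetrahedra share one internal face", {
  tess <- triangulate(two_tetra_points())
  expect_equal(nrow(tess$tetra), 2)
  internal <- tess$faces[!is.na(tess$faces$cell2), ]
  expect_equal(nrow(internal), 1)
  expect_equal(length(tess$hull_faces), 6)
  # the shared face is the (1,0,0),(0,1,0),(0,0,1) triangle
  expect_setequal(unlist(internal[, c("v1", "v2", "v3")]), 2:4)
})

test_that("tessellation volumes are conserved on random clouds", {
  set.seed(101)
  for (n in c(30, 80, 150)) {
    xyz <- matrix(runif(3 * n, 0, 20), ncol = 3)
    tess <- triangulate(xyz)
    expect_equal(sum(tess$vol), tess$hull_volume, tolerance = 1e-6)
  }
})

test_that("face topology is mutually consistent", {
  set.seed(7)
  tess <- triangulate(matrix(rnorm(3 * 60, sd = 8), ncol = 3))
  f <- tess$faces
  # every cell owns exactly 4 faces
  counts <- table(c(f$cell1, f$cell2[!is.na(f$cell2)]))
  expect_true(all(counts == 4))
  expect_equal(length(counts), nrow(tess$tetra))
  # hull faces have exactly one incident cell, internal exactly two
  expect_true(all(is.na(f$cell2[tess$hull_faces])))
  expect_true(all(!is.na(f$cell1)))
  # barycenters are vertex means
  i <- nrow(tess$tetra)
  expect_equal(tess$bary[i, ], colMeans(tess$xyz[tess$tetra[i, ], ]))
  # all volumes positive
  expect_true(all(tess$vol > 0))
})

test_that("under-determined point sets are rejected", {
  expect_error(triangulate(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "at least 4")
})

test_that("tessellation dump lists one cell per line", {
  tess <- triangulate(two_tetra_points())
  f <- tempfile()
  dump_tessellation(tess, f)
  ln <- readLines(f)
  expect_equal(length(ln), 2)
  expect_equal(scan(text = ln[1], quiet = TRUE)[1], 1)
})
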