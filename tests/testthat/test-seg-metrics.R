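cube_mask <- function(shape, lo, hi, spacing = c(2, 2, 2), name = "cube") {
  m <- array(FALSE, shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  struct_mask(m, spacing, name = name)
}

test_that("surface voxels follow the 6-neighbour definition", {
  single <- cube_mask(c(3, 3, 3), c(2, 2, 2), c(2, 2, 2), c(1, 1, 1))
  expect_equal(nrow(surface_points(single)), 1)
  expect_equal(surface_points(single)[1, ], c(1, 1, 1), ignore_attr = TRUE)

  solid <- cube_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4), c(1, 1, 1))
  expect_equal(nrow(surface_points(solid)), 26)  # all but the centre

  # array-edge members count as surface
  full <- struct_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(nrow(surface_points(full)), 27 - 1)

  set.seed(51)
  for (rep in 1:8) {
    m <- rand_blob_mask(c(8, 9, 7), spacing = c(1.5, 2, 1))
    got <- surface_points(m)
    want <- voxel_idx_to_mm(oracle_surface_idx(m$membership), m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
                 want[order(want[, 1], want[, 2], want[, 3]), ],
                 ignore_attr = TRUE)
  }
})

test_that("volumetric Dice counts voxel overlap", {
  a <- cube_mask(c(6, 4, 4), c(1, 2, 2), c(2, 2, 2))
  b <- cube_mask(c(6, 4, 4), c(2, 2, 2), c(2, 2, 2))
  expect_equal(vdsc(a, a), 1)
  expect_equal(vdsc(a, b), 2 / 3)  # 2 and 1 voxels overlapping in 1
  c2 <- cube_mask(c(6, 4, 4), c(5, 2, 2), c(6, 2, 2))
  expect_equal(vdsc(a, c2), 0)
  e1 <- struct_mask(array(FALSE, c(3, 3, 3)), c(2, 2, 2), allow_empty = TRUE)
  expect_warning(v <- vdsc(e1, e1), "empty")
  expect_equal(v, 1)
})

test_that("surface Dice respects the distance tolerance", {
  a <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(5, 5, 5))
  expect_equal(sdsc(a, a, 0), 1)
  expect_equal(sdsc(a, a, 3), 1)
  # shift by one voxel = 2 mm: tau = 3 covers every surface distance
  b <- cube_mask(c(8, 8, 8), c(4, 3, 3), c(6, 5, 5))
  expect_equal(sdsc(a, b, 3), 1)
  # tau = 0 keeps exactly the coincident surface points
  o <- oracle_seg_metrics(a, b, tau = 0)
  expect_equal(sdsc(a, b, 0), o$sdsc)
  # monotone in tau, saturating at 1
  taus <- c(0, 1, 2, 4, 8, 100)
  vals <- vapply(taus, function(t) sdsc(a, b, t), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[length(vals)], 1)
})

test_that("HD95 is bounded by rigid shifts and zero on identity", {
  a <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(5, 5, 5), spacing = c(1, 1, 1))
  expect_equal(hd95(a, a), 0)
  b <- cube_mask(c(8, 8, 8), c(4, 3, 3), c(6, 5, 5), spacing = c(1, 1, 1))
  expect_lte(hd95(a, b), 1)
})

test_that("all three metrics equal the pairwise brute-force oracle", {
  set.seed(52)
  for (rep in 1:12) {
    shape <- rep(sample(8:16, 1), 3)
    sp <- stats::runif(3, 0.8, 2.5)
    a <- rand_blob_mask(shape, spacing = sp, name = "a")
    b <- rand_blob_mask(shape, spacing = sp, name = "b")
    o <- oracle_seg_metrics(a, b, tau = 3)
    expect_equal(vdsc(a, b), o$vdsc, tolerance = 1e-12)
    expect_equal(sdsc(a, b, 3), o$sdsc, tolerance = 1e-12)
    expect_equal(hd95(a, b), o$hd95, tolerance = 1e-9)
    # symmetry
    expect_equal(vdsc(b, a), vdsc(a, b))
    expect_equal(sdsc(b, a, 3), sdsc(a, b, 3))
    expect_equal(hd95(b, a), hd95(a, b))
  }
})

test_that("metric preconditions are enforced", {
  a <- cube_mask(c(4, 4, 4), c(2, 2, 2), c(3, 3, 3))
  off <- cube_mask(c(4, 4, 4), c(2, 2, 2), c(3, 3, 3), spacing = c(1, 2, 2))
  expect_error(vdsc(a, off), "aligned")
  expect_error(sdsc(a, off), "aligned")
  e <- struct_mask(array(FALSE, c(4, 4, 4)), c(2, 2, 2), allow_empty = TRUE)
  expect_error(surface_points(e), "empty")
  expect_error(sdsc(a, a, -1), ">= 0")
})
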