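test_that("surface extraction follows the 26-neighborhood rule", {
  # solid 3x3x3 cube: all voxels but the centre touch background
  s <- extractSurface(mask(cubeArray(c(7, 7, 7), c(3, 3, 3), c(5, 5, 5))))
  expect_equal(nrow(s@indices), 26)
  expect_false(any(s@indices[, 1] == 4 & s@indices[, 2] == 4 &
                   s@indices[, 3] == 4))
  # a single voxel is its own surface; a 1x1x3 line is all surface
  expect_equal(nrow(extractSurface(singleVoxelMask(c(5, 5, 5),
                                                   c(3, 3, 3)))@indices), 1)
  line <- mask(cubeArray(c(1, 1, 3), c(1, 1, 1), c(1, 1, 3)))
  expect_equal(nrow(extractSurface(line)@indices), 3)
  # voxels on the grid border are surface voxels (outside counts background)
  full <- mask(array(TRUE, c(4, 4, 4)))
  expect_equal(nrow(extractSurface(full)@indices), 4^3 - 2^3)
  expect_error(extractSurface(mask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("Dice coefficient handles identity, disjoint and partial overlap", {
  a <- mask(cubeArray(c(10, 6, 6), c(1, 1, 1), c(2, 2, 2)))
  expect_equal(dice(a, a), 1)
  b <- mask(cubeArray(c(10, 6, 6), c(8, 4, 4), c(9, 5, 5)))
  expect_equal(dice(a, b), 0)
  # two 8-voxel cubes sharing a 4-voxel face-slab: 2*4/(8+8)
  c1 <- mask(cubeArray(c(10, 6, 6), c(2, 2, 2), c(3, 3, 3)))
  c2 <- mask(cubeArray(c(10, 6, 6), c(3, 2, 2), c(4, 3, 3)))
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(mask(array(FALSE, c(3, 3, 3))),
                    mask(array(FALSE, c(3, 3, 3)))), 1)
  expect_error(dice(a, mask(cubeArray(c(9, 6, 6), c(1, 1, 1), c(2, 2, 2)))),
               "grids")
})

test_that("surface distances are exact in physical millimetres", {
  a <- singleVoxelMask(c(9, 5, 5), c(2, 3, 3))
  b <- singleVoxelMask(c(9, 5, 5), c(5, 3, 3))
  expect_equal(assd(a, b), 3)
  expect_equal(mssd(a, b), 3)
  a2 <- singleVoxelMask(c(9, 5, 5), c(2, 3, 3), spacing = c(2, 1, 1))
  b2 <- singleVoxelMask(c(9, 5, 5), c(5, 3, 3), spacing = c(2, 1, 1))
  expect_equal(assd(a2, b2), 6)
  expect_equal(mssd(a2, b2), 6)
  expect_equal(assd(a, a), 0)
  expect_equal(mssd(a, a), 0)
  # cube extended by 5 layers on one face: maximal surface gap 5 voxels
  inner <- mask(cubeArray(c(16, 8, 8), c(2, 2, 2), c(6, 6, 6)))
  outer <- mask(cubeArray(c(16, 8, 8), c(2, 2, 2), c(11, 6, 6)))
  expect_equal(mssd(inner, outer), 5)
  expect_error(assd(a, mask(array(FALSE, c(9, 5, 5)))), "non-empty")
})

test_that("fast metrics match the brute-force oracle on random mask pairs", {
  set.seed(42)
  for (i in 1:30) {
    p <- randomMaskPair(maxDim = 12, density = 0.2,
                        spacing = runif(3, 0.5, 2))
    o <- oracleDistances(p$a, p$b)
    expect_equal(assd(p$a, p$b), o$assd, tolerance = 1e-12)
    expect_equal(mssd(p$a, p$b), o$mssd, tolerance = 1e-12)
    # the unpooled directional-mean variant matches its oracle counterpart
    expect_equal(assd(p$a, p$b, pooled = FALSE),
                 oracleDistances(p$a, p$b, pooled = FALSE)$assd,
                 tolerance = 1e-12)
  }
})

test_that("metrics are symmetric, translation invariant and scale with spacing", {
  set.seed(43)
  for (i in 1:8) {
    p <- randomMaskPair(maxDim = 10, density = 0.25)
    expect_equal(dice(p$a, p$b), dice(p$b, p$a))
    expect_equal(assd(p$a, p$b), assd(p$b, p$a))
    expect_equal(mssd(p$a, p$b), mssd(p$b, p$a))
    expect_lte(assd(p$a, p$b), mssd(p$a, p$b))
    # joint translation by one voxel along z
    shift <- function(m) {
      v <- voxelData(m); d <- dim(v)
      s <- array(FALSE, d + c(0, 0, 1)); s[, , 2:(d[3] + 1)] <- v
      mask(s, voxelSpacing(m))
    }
    pad <- function(m) {
      v <- voxelData(m); d <- dim(v)
      s <- array(FALSE, d + c(0, 0, 1)); s[, , 1:d[3]] <- v
      mask(s, voxelSpacing(m))
    }
    expect_equal(assd(shift(p$a), shift(p$b)), assd(pad(p$a), pad(p$b)),
                 tolerance = 1e-12)
    # doubling the spacing doubles distances, leaves Dice unchanged
    a2 <- mask(voxelData(p$a), 2); b2 <- mask(voxelData(p$b), 2)
    expect_equal(assd(a2, b2), 2 * assd(p$a, p$b), tolerance = 1e-12)
    expect_equal(mssd(a2, b2), 2 * mssd(p$a, p$b), tolerance = 1e-12)
    expect_equal(dice(a2, b2), dice(p$a, p$b))
  }
})
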