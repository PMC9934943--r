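# fixtures are built in code: small masks, cubes and random grids

cubeArray <- function(dim, from, to) {
  m <- array(FALSE, dim)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

sphereArray <- function(dim, center, radius) {
  idx <- lapply(1:3, function(ax) seq_len(dim[ax]) - 1)
  r2 <- outer(outer((idx[[1]] - center[1])^2, (idx[[2]] - center[2])^2, "+"),
              (idx[[3]] - center[3])^2, "+")
  r2 <= radius^2
}

mask <- function(values, spacing = 1, ...) {
  SegmentationMask(values, spacing = spacing, ...)
}

singleVoxelMask <- function(dim, at, spacing = 1) {
  m <- array(FALSE, dim)
  m[at[1], at[2], at[3]] <- TRUE
  mask(m, spacing)
}

# a non-empty random mask pair on a shared small grid
randomMaskPair <- function(maxDim = 16, density = 0.2, spacing = c(1, 1, 1)) {
  repeat {
    d <- sample(6:maxDim, 3, replace = TRUE)
    a <- array(runif(prod(d)) < density, d)
    b <- array(runif(prod(d)) < density, d)
    if (any(a) && any(b))
      return(list(a = mask(a, spacing), b = mask(b, spacing)))
  }
}
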