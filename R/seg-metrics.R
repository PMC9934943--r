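## Overlap and surface-distance agreement between two lung masks.
##
## Surface voxels are lung voxels with at least one non-lung voxel among
## their 26 neighbours (6 faces, 12 edges, 8 corners); voxels on the grid
## border count the outside as background. Distances are Euclidean between
## voxel centres in physical mm (centre of voxel i at i * spacing), computed
## exactly through a separable Euclidean distance transform; a brute-force
## all-pairs oracle is provided for verification on small masks.

#' SurfaceVoxelSet: boundary voxels of a segmentation mask
#'
#' @slot indices integer matrix (n x 3) of 1-based voxel indices.
#' @slot coordinatesMm numeric matrix (n x 3) of voxel-centre positions in mm
#'   (\code{(index - 1) * spacing}).
#' @slot spacing numeric(3) mm.
#' @export
setClass("SurfaceVoxelSet", representation(
  indices = "matrix", coordinatesMm = "matrix", spacing = "numeric"))

setMethod("show", "SurfaceVoxelSet", function(object) {
  cat(sprintf("SurfaceVoxelSet: %d surface voxels, spacing %s mm\n",
              nrow(object@indices),
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

# logical array marking the surface voxels of a mask array
surfaceArray <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  allNb <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    allNb <- allNb & pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy,
                         (2:(d[3] + 1)) + dz]
  }
  m & !allNb
}

#' Extract the surface voxels of a mask
#'
#' A lung voxel is a surface voxel when at least one of its 26 neighbours is
#' background; neighbours outside the grid count as background, so a lung
#' region touching the grid border is still bounded there.
#'
#' @param mask a non-empty [SegmentationMask-class].
#' @return A [SurfaceVoxelSet-class].
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
#' extractSurface(SegmentationMask(m))  # 26 of the 27 cube voxels
#' @export
extractSurface <- function(mask) {
  m <- voxelData(mask)
  if (!any(m))
    stop("degenerate input: empty segmentation mask has no surface")
  surf <- surfaceArray(m)
  idx <- which(surf, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  sp <- voxelSpacing(mask)
  new("SurfaceVoxelSet", indices = idx,
      coordinatesMm = sweep(idx - 1, 2, sp, "*"),
      spacing = sp)
}

checkMaskPair <- function(maskA, maskB) {
  if (!all(dim(voxelData(maskA)) == dim(voxelData(maskB))))
    stop("masks are on different grids (shape mismatch)")
  sa <- voxelSpacing(maskA); sb <- voxelSpacing(maskB)
  if (any(abs(sa - sb) > 1e-6 * pmax(abs(sa), abs(sb))))
    stop("masks are on different grids (spacing mismatch)")
  invisible(TRUE)
}

#' Dice similarity coefficient of two masks
#'
#' \code{DSC = 2 |X intersect Y| / (|X| + |Y|)}: 0 for disjoint masks, 1 for
#' identical ones. Two empty masks agree vacuously (DSC = 1).
#'
#' @param maskA,maskB aligned [SegmentationMask-class]s.
#' @return DSC in \code{[0, 1]}.
#' @export
dice <- function(maskA, maskB) {
  checkMaskPair(maskA, maskB)
  a <- voxelData(maskA); b <- voxelData(maskB)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# physical-mm distance from every voxel to the nearest site voxel (exact)
distanceToSites <- function(sites, spacing) {
  sqrt(.edt3d_cpp(sites, dim(sites), spacing))
}

# the two directional nearest-surface distance lists (A->B, B->A), in mm
surfaceDistanceLists <- function(maskA, maskB) {
  checkMaskPair(maskA, maskB)
  a <- voxelData(maskA); b <- voxelData(maskB)
  if (!any(a) || !any(b))
    stop("degenerate input: surface distances need two non-empty masks")
  sp <- voxelSpacing(maskA)
  sa <- surfaceArray(a); sb <- surfaceArray(b)
  dToB <- distanceToSites(sb, sp)
  dToA <- distanceToSites(sa, sp)
  list(aToB = dToB[sa], bToA = dToA[sb])
}

#' Average symmetric surface distance (ASSD)
#'
#' For every surface voxel of each mask, the Euclidean distance (mm) to the
#' nearest surface voxel of the other mask is recorded; the ASSD is the mean
#' of all recorded distances. The default pools the two directional lists
#' (weighted by surface-voxel counts); \code{pooled = FALSE} averages the two
#' directional means instead.
#'
#' @param maskA,maskB aligned, non-empty [SegmentationMask-class]s.
#' @param pooled pool both directional lists before averaging (default).
#' @return ASSD in mm; 0 for a perfect match.
#' @export
assd <- function(maskA, maskB, pooled = TRUE) {
  dl <- surfaceDistanceLists(maskA, maskB)
  if (pooled) mean(c(dl$aToB, dl$bToA))
  else (mean(dl$aToB) + mean(dl$bToA)) / 2
}

#' Maximum symmetric surface distance (MSSD)
#'
#' The maximum over both directions of the nearest-surface distances: the
#' symmetric Hausdorff distance between the two surface voxel sets, sensitive
#' to outliers and equal to the true maximum boundary error.
#'
#' @inheritParams assd
#' @return MSSD in mm.
#' @export
mssd <- function(maskA, maskB) {
  dl <- surfaceDistanceLists(maskA, maskB)
  max(dl$aToB, dl$bToA)
}

#' Brute-force oracle for the surface distances
#'
#' Computes ASSD and MSSD by exhaustive all-pairs distance enumeration
#' between the two surface voxel sets, with no spatial index or transform.
#' Intended for verification on small masks (at most a few thousand surface
#' voxels per mask).
#'
#' @inheritParams assd
#' @return A list with elements \code{assd} and \code{mssd} (mm).
#' @export
oracleDistances <- function(maskA, maskB, pooled = TRUE) {
  checkMaskPair(maskA, maskB)
  ca <- extractSurface(maskA)@coordinatesMm
  cb <- extractSurface(maskB)@coordinatesMm
  # direct squared differences per axis (no |a|^2+|b|^2-2ab expansion, which
  # loses precision); row blocks keep memory bounded
  aToB <- rep(Inf, nrow(ca))
  bToA <- rep(Inf, nrow(cb))
  for (blk in split(seq_len(nrow(ca)), ceiling(seq_len(nrow(ca)) / 512))) {
    d2 <- outer(ca[blk, 1], cb[, 1], "-")^2 +
          outer(ca[blk, 2], cb[, 2], "-")^2 +
          outer(ca[blk, 3], cb[, 3], "-")^2
    aToB[blk] <- sqrt(apply(d2, 1, min))
    bToA <- pmin(bToA, sqrt(apply(d2, 2, min)))
  }
  list(assd = if (pooled) mean(c(aToB, bToA))
              else (mean(aToB) + mean(bToA)) / 2,
       mssd = max(aToB, bToA))
}

#' Agreement metrics for one mask pair
#'
#' Convenience wrapper returning DSC, ASSD and MSSD together.
#'
#' @inheritParams assd
#' @param comparison label from \code{comparisonTypes}.
#' @return A one-row \code{data.frame}: \code{comparison}, \code{dsc},
#'   \code{assd_mm}, \code{mssd_mm}.
#' @export
agreementMetrics <- function(maskA, maskB, comparison = "intra_observer") {
  dl <- surfaceDistanceLists(maskA, maskB)
  data.frame(comparison = comparison,
             dsc = dice(maskA, maskB),
             assd_mm = mean(c(dl$aToB, dl$bToA)),
             mssd_mm = max(dl$aToB, dl$bToA),
             stringsAsFactors = FALSE)
}
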