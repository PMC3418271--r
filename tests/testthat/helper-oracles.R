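# Independent, brute-force oracles used to cross-check the compiled
# morphology kernels, plus small fixture builders.  These deliberately
# use different algorithms (iterative dilation, chamfer passes, graph
# components) from the implementations they verify.

# 2D flood fill of `air` from the slice border, 8-connectivity, by
# iterated dilation-and-intersect until a fixed point.
floodBorderAirOracle2D <- function(air) {
  ny <- nrow(air); nx <- ncol(air)
  cur <- matrix(FALSE, ny, nx)
  cur[1, ] <- air[1, ]; cur[ny, ] <- air[ny, ]
  cur[, 1] <- air[, 1]; cur[, nx] <- air[, nx]
  repeat {
    grown <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      shifted <- matrix(FALSE, ny, nx)
      shifted[ys, xs] <- cur[ys - dy, xs - dx]
      grown <- grown | shifted
    }
    grown <- grown & air
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# Chebyshev distance to background (outside the slice counts as
# background) by two chamfer passes over the 8-neighborhood.
chebyshevDistOracle2D <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  big <- ny + nx
  d <- matrix(big, ny + 2, nx + 2)   # pad with background
  d[2:(ny + 1), 2:(nx + 1)] <- ifelse(mask, big, 0)
  d[1, ] <- 0; d[ny + 2, ] <- 0; d[, 1] <- 0; d[, nx + 2] <- 0
  for (y in 2:(ny + 1)) for (x in 2:(nx + 1))
    d[y, x] <- min(d[y, x],
                   d[y - 1, x - 1] + 1, d[y - 1, x] + 1,
                   d[y - 1, x + 1] + 1, d[y, x - 1] + 1)
  for (y in (ny + 1):2) for (x in (nx + 1):2)
    d[y, x] <- min(d[y, x],
                   d[y + 1, x + 1] + 1, d[y + 1, x] + 1,
                   d[y + 1, x - 1] + 1, d[y, x + 1] + 1)
  d[2:(ny + 1), 2:(nx + 1)]
}

# Exhaustive 26-connectivity component labeling through igraph.
componentsOracle3D <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  key <- function(z, y, x) paste(z, y, x)
  lookup <- stats::setNames(seq_len(n), key(idx[, 1], idx[, 2], idx[, 3]))
  edges <- integer(0)
  for (i in seq_len(n)) {
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      k <- key(idx[i, 1] + dz, idx[i, 2] + dy, idx[i, 3] + dx)
      j <- lookup[k]
      if (!is.na(j) && j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # return membership per voxel alongside voxel coordinates
  list(coords = idx, membership = memb)
}

# Minimal SegmentationResult carrying a prescribed volume, for
# bookkeeping tests that do not need real masks.
fakeSegResult <- function(mm3) {
  m <- BinaryMask(array(TRUE, c(1, 1, 1)))
  new("SegmentationResult", lungMask = m, bodyROI = m, erodedROI = m,
      voxelCount = 1, volumeMm3 = mm3,
      histogram = stackHistogram(CTVolume(array(0, c(1, 1, 1)),
                                          calibrated = TRUE)),
      params = SegmentationParams())
}

# Small calibrated volume from an array of HU values.
huVolume <- function(a, voxelSizeUm = 35) {
  CTVolume(a, voxelSizeUm = voxelSizeUm, calibrated = TRUE)
}
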