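# Internal voxel-array helpers shared by the geometry modules.

# Shift a 3D array by an integer offset, padding with `fill`.
shift3 <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- src[[ax]] + d[ax]
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Euclidean distance (voxels) from every voxel to the nearest TRUE voxel.
dist_to_mask <- function(target) {
  stopifnot(length(dim(target)) == 3)
  cpp_dist_to_mask(target)
}

# Logical mask of foreground voxels with at least one 6-neighbour outside the
# mask (array borders count as background).
surface_voxels <- function(mask) {
  inner <- mask
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    inner <- inner & shift3(mask, d)
  }
  mask & !inner
}

# In-slice 4-neighbour boundary, computed for all slices perpendicular to
# `axis` at once.  A vessel pixel is boundary if any in-plane 4-neighbour is
# background.
boundary_in_slice <- function(mask, axis) {
  inplane <- setdiff(1:3, axis)
  inner <- mask
  for (ax in inplane) {
    for (s in c(-1, 1)) {
      d <- c(0, 0, 0); d[ax] <- s
      inner <- inner & shift3(mask, d)
    }
  }
  mask & !inner
}

# Separable Gaussian smoothing with zero padding (kernel radius 3*sigma).
gaussian_smooth3 <- function(vol, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- vol
  for (ax in 1:3) {
    acc <- array(0, dim(vol))
    for (i in seq_along(off)) {
      d <- c(0, 0, 0); d[ax] <- off[i]
      acc <- acc + w[i] * shift3(out, d, fill = 0)
    }
    out <- acc
  }
  out
}

# n x 3 matrix of (i, j, k) indices of TRUE voxels, in column-major order.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}
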