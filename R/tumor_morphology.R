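#' Tumor surface area and volume
#'
#' Volume is voxel count times voxel volume.  Surface area is measured on the
#' 0.5 isosurface of the mask after sub-voxel Gaussian smoothing
#' (sigma = 0.7 voxel), extracted by marching tetrahedra; the smoothing
#' suppresses the voxelization staircase, which would otherwise inflate the
#' area of a digital sphere by roughly 9%.
#'
#' @param tumor logical 3D mask, non-empty.
#' @param spacing isotropic voxel size in mm (default 1).
#' @return named vector `T_surface` (mm^2), `T_volume` (mm^3).
#' @export
mesh_surface_volume <- function(tumor, spacing = 1) {
  stopifnot(length(dim(tumor)) == 3)
  if (!any(tumor)) stop("empty tumor mask")
  vol <- sum(tumor) * spacing^3
  # pad so the isosurface closes at the array border
  dm <- dim(tumor)
  padded <- array(0, dm + 8L)
  padded[5:(4 + dm[1]), 5:(4 + dm[2]), 5:(4 + dm[3])] <- as.numeric(tumor)
  sm <- gaussian_smooth3(padded, sigma = 0.7)
  area <- cpp_mesh_area(sm, 0.5) * spacing^2
  c(T_surface = area, T_volume = vol)
}

#' Sphericity and compactness from surface and volume
#'
#' Sphericity `pi^(1/3) * (6 V)^(2/3) / A` is 1 for a perfect sphere and
#' decreases as the shape departs from sphericity; compactness is the
#' surface-to-volume ratio `A / V` (1/mm), larger for less compact shapes of
#' a given volume.
#'
#' @param Tsurface surface area (mm^2), positive.
#' @param Tvolume volume (mm^3), positive.
#' @return named vector `T_sphere`, `T_compact`.
#' @export
shape_scores <- function(Tsurface, Tvolume) {
  if (!is.finite(Tsurface) || !is.finite(Tvolume) ||
      Tsurface <= 0 || Tvolume <= 0)
    stop("surface and volume must be positive")
  c(T_sphere = pi^(1 / 3) * (6 * Tvolume)^(2 / 3) / Tsurface,
    T_compact = Tsurface / Tvolume)
}

#' Principal axis lengths, flatness and maximum 3D diameter
#'
#' Axis lengths are `4 * sqrt(eigenvalue)` of the covariance of the physical
#' voxel coordinates (the axes of the fitted ellipsoid), sorted descending.
#' Flatness here is `major / medium` (>= 1; larger values indicate a flatter,
#' more elongated cross-section).  The maximum 3D diameter is the exact
#' largest pairwise distance between surface voxels.
#'
#' @param tumor logical 3D mask with at least 4 non-coplanar voxels.
#' @param spacing isotropic voxel size in mm (default 1).
#' @return named vector `T_maxD`, `T_majorAxis`, `T_mediumAxis`,
#'   `T_minorAxis` (mm) and `T_flat` (dimensionless).
#' @export
principal_axes_diameters <- function(tumor, spacing = 1) {
  stopifnot(length(dim(tumor)) == 3)
  pts <- mask_coords(tumor)
  if (nrow(pts) < 4) stop("tumor has fewer than 4 voxels")
  xyz <- pts * spacing
  ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  if (ev[3] < 1e-12 * ev[1] || ev[2] < 1e-12)
    stop("degenerate (coplanar) tumor shape")
  axes <- 4 * sqrt(ev)
  surf <- mask_coords(surface_voxels(tumor)) * spacing
  maxd <- cpp_max_pairwise(matrix(as.numeric(surf), ncol = 3))
  c(T_maxD = maxd, T_majorAxis = axes[1], T_mediumAxis = axes[2],
    T_minorAxis = axes[3], T_flat = axes[1] / axes[2])
}

#' First-order intensity statistics within the tumor
#'
#' Representative first-order subset of the high-throughput texture catalog:
#' mean, median, min, max, range, population variance, skewness, kurtosis,
#' energy, histogram entropy (log base 2) and uniformity over tumor voxels.
#'
#' @param intensity numeric 3D volume.
#' @param tumor logical mask on the same grid, non-empty.
#' @param n_bins number of histogram bins for entropy/uniformity (default 32).
#' @return named vector of statistics, names prefixed `fo_`.
#' @export
first_order_intensity <- function(intensity, tumor, n_bins = 32) {
  if (!identical(dim(intensity), dim(tumor))) stop("grid mismatch")
  if (!any(tumor)) stop("empty tumor mask")
  x <- as.numeric(intensity[tumor])
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  skew <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((x - m)^4) / v^2 else 0
  rng <- range(x)
  if (rng[1] == rng[2]) {
    p <- 1
  } else {
    h <- cut(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
             include.lowest = TRUE)
    p <- tabulate(h, n_bins) / n
    p <- p[p > 0]
  }
  c(fo_mean = m, fo_median = stats::median(x), fo_min = rng[1],
    fo_max = rng[2], fo_range = diff(rng), fo_variance = v,
    fo_skewness = skew, fo_kurtosis = kurt, fo_energy = sum(x^2),
    fo_entropy = -sum(p * log2(p)), fo_uniformity = sum(p^2))
}

#' Tumor morphology record of a case
#'
#' Computes the surface/volume, shape scores, principal axes and (when an
#' intensity volume is present) first-order intensity statistics of the tumor
#' in a structure set.
#'
#' @param s an isotropic [structure_set()].
#' @param n_bins histogram bins passed to [first_order_intensity()].
#' @return one-row data.frame of morphology (and optional `fo_`) columns.
#' @export
tumor_morphology <- function(s, n_bins = 32) {
  stopifnot(inherits(s, "structure_set"))
  if (!is_isotropic(s))
    stop("structure set must be resampled to an isotropic grid first")
  sp <- s$spacing[1]
  sv <- mesh_surface_volume(s$tumor, sp)
  sc <- shape_scores(sv[["T_surface"]], sv[["T_volume"]])
  ax <- principal_axes_diameters(s$tumor, sp)
  out <- as.data.frame(as.list(c(sv, sc, ax)))
  if (!is.null(s$intensity)) {
    out <- cbind(out, as.data.frame(as.list(
      first_order_intensity(s$intensity, s$tumor, n_bins))))
  }
  out
}
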