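#' Summary statistics of a branch radius profile
#'
#' Minimum, maximum, mean, range and population standard deviation (divisor
#' n) of the per-voxel radius sequence of a skeleton edge.
#'
#' @param radius_seq positive numeric vector.
#' @return named vector `R_min`, `R_max`, `R_mean`, `R_range`, `R_std`.
#' @export
radius_stats <- function(radius_seq) {
  if (!length(radius_seq)) stop("empty radius sequence")
  m <- mean(radius_seq)
  c(R_min = min(radius_seq), R_max = max(radius_seq), R_mean = m,
    R_range = max(radius_seq) - min(radius_seq),
    R_std = sqrt(mean((radius_seq - m)^2)))
}

#' Tumor encasement angle of a vessel
#'
#' For every 2D cross-section of the vessel perpendicular to each of the
#' three grid axes, the fraction of the vessel's in-slice boundary pixels
#' lying within `contact_tau` voxels (3D Euclidean distance) of the tumor is
#' computed; the feature is the maximum such fraction over all slices and
#' axes.  Mirrors the clinical circumferential-contact criterion (180 degrees
#' separating abutment from encasement).  Cross-sections with fewer than
#' `min_perimeter` boundary pixels are skipped as unstable at grid
#' resolution.
#'
#' @param vessel logical 3D vessel mask, non-empty.
#' @param tumor logical 3D tumor mask (empty tumor gives 0).
#' @param contact_tau contact distance threshold in voxels (default 3).
#' @param min_perimeter minimum boundary pixel count per slice (default 8).
#' @return list with `frac` in [0, 1] and `deg` = 360 * frac.
#' @export
encasement_angle <- function(vessel, tumor, contact_tau = 3,
                             min_perimeter = 8) {
  if (!any(vessel)) stop("empty vessel mask")
  stopifnot(contact_tau > 0, identical(dim(vessel), dim(tumor)))
  if (!any(tumor)) return(list(frac = 0, deg = 0))
  contact <- dist_to_mask(tumor) <= contact_tau
  best <- 0
  for (axis in 1:3) {
    bd <- boundary_in_slice(vessel, axis)
    C <- apply(bd, axis, sum)
    L <- apply(bd & contact, axis, sum)
    ok <- C >= min_perimeter
    if (any(ok)) best <- max(best, max(L[ok] / C[ok]))
  }
  list(frac = best, deg = 360 * best)
}

#' Radius-distance product features along a branch
#'
#' Forms the sequence `Dn[i] = radius_seq[i] * tumor_dist_seq[i]` (inscribed
#' radius times shortest tumor distance, voxel^2), its summary statistics
#' (population divisor), and the ratio of the mean product outside versus
#' inside the tumor-proximal region (path voxels with tumor distance <=
#' `roi_rho`).  Tumor-proximal narrowing raises the ratio.  The ratio is `NA`
#' when either group is empty or the inside mean is zero.
#'
#' @param radius_seq positive numeric vector.
#' @param tumor_dist_seq non-negative numeric vector, same length.
#' @param roi_rho tumor-distance threshold (voxels) defining the proximal
#'   region (default 10).
#' @return named vector `D_min`, `D_max`, `D_mean`, `D_range`, `D_std`,
#'   `D_ratio` (`D_ratio` possibly `NA`).
#' @export
radius_distance_features <- function(radius_seq, tumor_dist_seq,
                                     roi_rho = 10) {
  if (length(radius_seq) != length(tumor_dist_seq))
    stop("radius and distance sequences differ in length")
  if (!length(radius_seq)) stop("empty sequences")
  dn <- radius_seq * tumor_dist_seq
  m <- mean(dn)
  inside <- tumor_dist_seq <= roi_rho
  dratio <- NA_real_
  if (any(inside) && any(!inside)) {
    mi <- mean(dn[inside])
    if (mi > 0) dratio <- mean(dn[!inside]) / mi
  }
  c(D_min = min(dn), D_max = max(dn), D_mean = m,
    D_range = max(dn) - min(dn), D_std = sqrt(mean((dn - m)^2)),
    D_ratio = dratio)
}

#' Tumor contact area and contact length of a vessel
#'
#' `C_area` counts vessel surface voxels within `contact_tau` voxels of the
#' tumor; `C_length` counts the distinct skeleton voxels that those contact
#' surface voxels map to (via the surface-to-skeleton nearest map), i.e. the
#' skeleton span of the contact region.
#'
#' @param vessel logical vessel mask (used for grid checking).
#' @param tumor logical tumor mask.
#' @param sk [skeletonize_graph()] result built from `vessel`.
#' @param contact_tau contact distance threshold in voxels (default 3).
#' @return named integer vector `C_area`, `C_length`.
#' @export
contact_features <- function(vessel, tumor, sk, contact_tau = 3) {
  stopifnot(inherits(sk, "skeleton"),
            identical(dim(vessel), dim(tumor)),
            identical(dim(vessel), sk$mask_dim))
  if (!any(tumor) || nrow(sk$surface) == 0)
    return(c(C_area = 0L, C_length = 0L))
  tdist <- dist_to_mask(tumor)
  in_contact <- tdist[sk$surface] <= contact_tau
  c(C_area = sum(in_contact),
    C_length = length(unique(sk$surface_map[in_contact])))
}

#' Extract the per-vessel anatomical feature records of a case
#'
#' For each of the five named vessels, computes the 14 anatomically designed
#' tumor-vessel features ([ANATOMICAL_FEATURES]): five radius statistics, the
#' encasement angle, six radius-distance product features, and the contact
#' area/length.  Profile features are computed on the branch closest to the
#' tumor (smallest minimum tumor distance; ties toward the longer branch);
#' the encasement angle and contact features use the whole vessel mask.
#' Vessels absent from the structure set yield a flagged record with missing
#' features.
#'
#' @param s an isotropic [structure_set()].
#' @param branches optional named list (by vessel) of precomputed
#'   [split_branches()] results; computed internally when `NULL`.
#' @param config a [pancvas_config()].
#' @param case_id identifier written into the `case` column.
#' @return data.frame with one row per vessel in [VESSEL_NAMES]: identifier
#'   columns, the 14 features, the auxiliary `theta_encase_frac` rendering,
#'   and a logical `missing` flag.
#' @export
extract_case <- function(s, branches = NULL, config = pancvas_config(),
                         case_id = "case") {
  stopifnot(inherits(s, "structure_set"))
  if (!is_isotropic(s))
    stop("structure set must be resampled to an isotropic grid first")
  rows <- lapply(VESSEL_NAMES, function(vn) {
    base <- data.frame(case = case_id, vessel = vn,
                       vessel_class = unname(VESSEL_CLASS[vn]),
                       stringsAsFactors = FALSE)
    empty <- as.list(setNames(rep(NA_real_, length(ANATOMICAL_FEATURES)),
                              ANATOMICAL_FEATURES))
    if (!vn %in% names(s$vessels)) {
      return(cbind(base, as.data.frame(empty),
                   theta_encase_frac = NA_real_, missing = TRUE))
    }
    vessel <- s$vessels[[vn]]
    sk <- skeletonize_graph(vessel, prune_min = config$prune_min)
    br <- if (!is.null(branches) && vn %in% names(branches)) {
      branches[[vn]]
    } else {
      split_branches(vessel, sk, tumor = s$tumor, vessel_name = vn)
    }
    b <- select_tumor_branch(br)
    rs <- radius_stats(b$radius_seq)
    td <- if (!is.null(b$tumor_dist_seq)) b$tumor_dist_seq else
      tumor_distance_profile(b, s$tumor)
    df <- radius_distance_features(b$radius_seq, td, roi_rho = config$roi_rho)
    ang <- encasement_angle(vessel, s$tumor,
                            contact_tau = config$contact_tau,
                            min_perimeter = config$min_perimeter)
    cf <- contact_features(vessel, s$tumor, sk,
                           contact_tau = config$contact_tau)
    feats <- c(rs, theta_encase_deg = ang$deg, df, cf)
    cbind(base, as.data.frame(as.list(feats[ANATOMICAL_FEATURES])),
          theta_encase_frac = ang$frac, missing = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Branch nearest the tumor; ties broken toward the longer branch, then the
# lower branch index.
select_tumor_branch <- function(branches) {
  stopifnot(length(branches) >= 1)
  if (length(branches) == 1) return(branches[[1]])
  dmin <- vapply(branches, function(b) {
    if (is.null(b$tumor_dist_seq)) Inf else min(b$tumor_dist_seq)
  }, numeric(1))
  len <- vapply(branches, function(b) nrow(b$path), numeric(1))
  branches[[order(dmin, -len)[1]]]
}
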