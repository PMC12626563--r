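#' Skeletonize a vessel mask into a centerline graph
#'
#' Reduces a binary tubular mask to a one-voxel-wide medial curve by
#' topology-preserving sequential thinning (voxels are eroded in order of
#' increasing distance to the background, deleting only simple points and
#' preserving curve endpoints; 26-connectivity for the skeleton,
#' 6-connectivity for the background).  The skeleton is decomposed into a
#' graph of edges between endpoints (degree 1) and junctions (degree >= 3);
#' terminal spurs shorter than `max(prune_min, 0.5 * local radius)` are
#' removed.  Each vessel surface voxel is mapped to its nearest skeleton voxel
#' (Euclidean distance, ties toward the lowest lexicographic index).
#'
#' @param mask logical 3D array, non-empty, assumed isotropic.
#' @param prune_min minimum retained spur length in voxels (default 5).
#' @return an object of class `skeleton` with elements:
#'   \describe{
#'     \item{voxels}{n x 3 matrix of skeleton voxel indices}
#'     \item{edges}{list of integer vectors, each an ordered path of row
#'       indices into `voxels`}
#'     \item{degree}{integer degree of each skeleton voxel}
#'     \item{endpoints, junctions}{row indices of degree-1 / degree>=3 voxels}
#'     \item{surface}{m x 3 matrix of vessel surface voxel indices}
#'     \item{surface_map}{integer vector: row in `voxels` nearest to each
#'       surface voxel (the mapping f(v))}
#'   }
#' @export
skeletonize_graph <- function(mask, prune_min = 5) {
  stopifnot(length(dim(mask)) == 3, is.logical(mask))
  if (!any(mask)) stop("empty mask")
  sk_mask <- cpp_thin(mask)
  radius_map <- dist_to_mask(!mask)

  g <- build_skeleton_graph(sk_mask, dim(mask))
  # iterative spur pruning
  repeat {
    drop <- integer()
    for (e in seq_along(g$edges)) {
      path <- g$edges[[e]]
      ends <- c(path[1], path[length(path)])
      is_term <- g$degree[ends] == 1
      if (!any(is_term)) next
      if (all(is_term) && length(g$edges) == 1) next  # lone edge: keep
      anchor <- if (all(is_term)) ends[1] else ends[!is_term][1]
      r_local <- radius_map[matrix(g$voxels[anchor, ], 1)]
      if (length(path) < max(prune_min, 0.5 * r_local)) drop <- c(drop, e)
    }
    if (!length(drop)) break
    keep_vox <- rep(FALSE, nrow(g$voxels))
    for (e in setdiff(seq_along(g$edges), drop)) keep_vox[g$edges[[e]]] <- TRUE
    # junction voxels stay if still used; dropped spur interiors vanish
    for (e in drop) {
      path <- g$edges[[e]]
      ends <- c(path[1], path[length(path)])
      keep_vox[ends[g$degree[ends] >= 3]] <- TRUE
    }
    if (!any(keep_vox)) break
    new_mask <- array(FALSE, dim(mask))
    new_mask[g$voxels[keep_vox, , drop = FALSE]] <- TRUE
    g2 <- build_skeleton_graph(new_mask, dim(mask))
    if (length(g2$edges) == length(g$edges)) { g <- g2; break }
    g <- g2
  }

  # the exact medial curve of a capped tube stops about one radius short of
  # each flat end; extend long terminal edges along their tangent so the
  # centerline spans the full structure (matches the behaviour expected of
  # curve skeletons of vessels)
  g <- extend_terminal_edges(g, mask, radius_map)

  surf <- mask_coords(surface_voxels(mask))
  smap <- if (nrow(g$voxels)) {
    cpp_nearest_ref(matrix(as.numeric(surf), ncol = 3),
                    matrix(as.numeric(g$voxels), ncol = 3))
  } else integer()
  out <- list(voxels = g$voxels, edges = g$edges, degree = g$degree,
              endpoints = which(g$degree == 1),
              junctions = which(g$degree >= 3),
              n_junctions = g$n_junctions %||% 0L,
              surface = surf, surface_map = smap,
              mask_dim = dim(mask))
  class(out) <- "skeleton"
  out
}

#' @export
print.skeleton <- function(x, ...) {
  cat("skeleton:", nrow(x$voxels), "voxels,", length(x$edges), "edges,",
      length(x$endpoints), "endpoints,", x$n_junctions, "junctions\n")
  invisible(x)
}

# Build voxel adjacency (26-connectivity) and trace edges between nodes.
build_skeleton_graph <- function(sk_mask, dm) {
  vox <- mask_coords(sk_mask)
  n <- nrow(vox)
  if (n == 0) return(list(voxels = vox, edges = list(), degree = integer()))
  key <- function(m) (m[, 3] - 1) * (dm[1] * dm[2]) + (m[, 2] - 1) * dm[1] + m[, 1]
  keys <- key(vox)
  nbr <- vector("list", n)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    shifted <- sweep(vox, 2, offs[r, ], "+")
    ok <- shifted[, 1] >= 1 & shifted[, 1] <= dm[1] &
          shifted[, 2] >= 1 & shifted[, 2] <= dm[2] &
          shifted[, 3] >= 1 & shifted[, 3] <= dm[3]
    m <- match(key(shifted[ok, , drop = FALSE]), keys)
    src <- which(ok)[!is.na(m)]
    tgt <- m[!is.na(m)]
    for (a in seq_along(src)) nbr[[src[a]]] <- c(nbr[[src[a]]], tgt[a])
  }
  nbr <- lapply(nbr, function(v) sort(unique(v)))
  degree <- lengths(nbr)

  nodes <- which(degree != 2)
  visited <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  edges <- list()
  trace_from <- function(start, nxt) {
    path <- c(start, nxt)
    prev <- start; cur <- nxt
    while (degree[cur] == 2) {
      nx <- setdiff(nbr[[cur]], prev)
      if (!length(nx)) break
      prev <- cur; cur <- nx[1]
      path <- c(path, cur)
    }
    path
  }
  for (nd in nodes) {
    for (nx in nbr[[nd]]) {
      if (!is.null(visited[[ekey(nd, nx)]])) next
      path <- trace_from(nd, nx)
      for (a in seq_len(length(path) - 1))
        visited[[ekey(path[a], path[a + 1])]] <- TRUE
      edges[[length(edges) + 1]] <- path
    }
  }
  # components made only of degree-2 voxels (cycles): one edge each
  used <- rep(FALSE, n)
  for (e in edges) used[e] <- TRUE
  for (start in which(!used & degree > 0)) {
    if (used[start]) next
    path <- trace_from(start, nbr[[start]][1])
    used[path] <- TRUE
    edges[[length(edges) + 1]] <- path
  }
  # merge 26-adjacent junction voxels into junction clusters and drop the
  # micro-edges internal to a cluster (a thick junction region otherwise
  # splinters into spurious one/two-voxel edges)
  jvox <- which(degree >= 3)
  cluster_id <- rep(NA_integer_, n)
  ncl <- 0L
  for (jv in jvox) {
    if (!is.na(cluster_id[jv])) next
    ncl <- ncl + 1L
    stack <- jv
    cluster_id[jv] <- ncl
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      for (nb in intersect(nbr[[cur]], jvox)) {
        if (is.na(cluster_id[nb])) {
          cluster_id[nb] <- ncl
          stack <- c(stack, nb)
        }
      }
    }
  }
  if (length(edges)) {
    internal <- vapply(edges, function(p) {
      cl <- cluster_id[p]
      !anyNA(cl) && length(unique(cl)) == 1
    }, logical(1))
    edges <- edges[!internal]
  }
  # deterministic orientation: start from the end with lower linear key
  edges <- lapply(edges, function(p) {
    if (keys[p[length(p)]] < keys[p[1]]) rev(p) else p
  })
  edges <- edges[order(vapply(edges, function(p) keys[p[1]], numeric(1)))]
  list(voxels = vox, edges = edges, degree = degree,
       n_junctions = ncl, cluster_id = cluster_id)
}

# Straighten and complete the terminal ends of long edges.  Sequential
# thinning leaves two artefacts at the flat end of a tube: the curve stops
# about one radius short of the cap, and the surviving tail can drift off
# the medial line toward the cap rim (its distance values decay toward the
# tip).  For each degree-1 end of an edge much longer than the local radius:
# (1) trim the strictly-decaying tail, then (2) walk outward from the new
# tip along the local tangent through the mask.  Short edges (blobs, stubs)
# are left untouched.
extend_terminal_edges <- function(g, mask, radius_map) {
  if (!length(g$edges)) return(g)
  dm <- dim(mask)
  sk_mask <- array(FALSE, dm)
  if (nrow(g$voxels)) sk_mask[g$voxels] <- TRUE
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs_unit <- offs / sqrt(rowSums(offs^2))
  changed <- FALSE
  for (e in seq_along(g$edges)) {
    p <- g$edges[[e]]
    rmax <- max(radius_map[g$voxels[p, , drop = FALSE]])
    if (length(p) < 3 * rmax || length(p) < 3) next
    for (side in c("head", "tail")) {
      if (side == "tail") p <- rev(p)
      if (g$degree[p[1]] != 1) next
      # (1) trim the decaying off-axis tail
      ev <- radius_map[g$voxels[p, , drop = FALSE]]
      t <- 0L
      while (t + 1L < length(p) && t < ceiling(rmax) &&
             ev[t + 1L] < ev[t + 2L] - 0.2) t <- t + 1L
      if (t > 0L) {
        sk_mask[g$voxels[p[seq_len(t)], , drop = FALSE]] <- FALSE
        p <- p[-seq_len(t)]
        changed <- TRUE
      }
      if (length(p) < 3) next
      # (2) extend along the local tangent to the mask boundary
      m <- min(5L, length(p) - 1L)
      tip <- g$voxels[p[1], ]
      d <- tip - g$voxels[p[1L + m], ]
      nd <- sqrt(sum(d^2))
      if (nd < 1e-9) next
      d <- d / nd
      x <- tip
      for (step in seq_len(ceiling(3 * rmax) + 2L)) {
        cand <- sweep(offs, 2, x, "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
              cand[, 2] >= 1 & cand[, 2] <= dm[2] &
              cand[, 3] >= 1 & cand[, 3] <= dm[3]
        ok[ok] <- mask[cand[ok, , drop = FALSE]] &
                  !sk_mask[cand[ok, , drop = FALSE]]
        if (!any(ok)) break
        dots <- as.vector(offs_unit %*% d)
        dots[!ok] <- -Inf
        best <- which.max(dots)
        if (dots[best] < 0.6) break
        x <- cand[best, ]
        sk_mask[matrix(x, 1)] <- TRUE
        changed <- TRUE
      }
    }
  }
  if (!changed) return(g)
  build_skeleton_graph(sk_mask, dm)
}

#' Split a vessel mask into branches
#'
#' Assigns every vessel voxel to exactly one skeleton edge (the edge owning
#' the nearest skeleton path voxel; ties go to the voxel with the lowest
#' lexicographic index), so the branch masks partition the vessel mask.  A
#' manual branch-label volume overrides the automatic assignment.
#'
#' @param mask logical vessel mask the skeleton was built from.
#' @param sk a [skeletonize_graph()] result.
#' @param tumor optional logical tumor mask; when given, each branch carries
#'   its tumor-distance profile.
#' @param manual_labels optional integer array on the same grid; positive
#'   labels define the branches directly.
#' @param vessel_name name tag stored on each branch.
#' @return list of `vessel_branch` objects (fields `vessel_name`, `path`,
#'   `radius_seq`, `tumor_dist_seq`, `branch_mask`).
#' @export
split_branches <- function(mask, sk, tumor = NULL, manual_labels = NULL,
                           vessel_name = "vessel") {
  stopifnot(inherits(sk, "skeleton"))
  if (!identical(dim(mask), sk$mask_dim)) stop("skeleton/mask grid mismatch")
  radius_map <- dist_to_mask(!mask)
  tdist_map <- if (!is.null(tumor)) {
    if (!identical(dim(tumor), dim(mask))) stop("tumor grid mismatch")
    dist_to_mask(tumor)
  } else NULL

  make_branch <- function(path_rows, bmask) {
    path <- sk$voxels[path_rows, , drop = FALSE]
    b <- list(vessel_name = vessel_name, path = path,
              radius_seq = radius_map[path],
              tumor_dist_seq = if (!is.null(tdist_map)) tdist_map[path] else NULL,
              branch_mask = bmask)
    class(b) <- "vessel_branch"
    b
  }

  if (!is.null(manual_labels)) {
    if (!identical(dim(manual_labels), dim(mask)))
      stop("manual_labels grid mismatch")
    labs <- sort(setdiff(unique(manual_labels[mask]), 0))
    return(lapply(labs, function(lab) {
      bmask <- mask & (manual_labels == lab)
      inside <- bmask[sk$voxels]
      make_branch(which(inside), bmask)
    }))
  }

  if (!length(sk$edges)) {
    # degenerate skeleton: single branch covering the mask
    return(list(make_branch(seq_len(nrow(sk$voxels)), mask)))
  }

  # flatten edge paths; shared node voxels go to the first edge listing them
  flat_rows <- integer(); flat_edge <- integer()
  seen <- rep(FALSE, nrow(sk$voxels))
  for (e in seq_along(sk$edges)) {
    p <- sk$edges[[e]]
    new <- p[!seen[p]]
    seen[new] <- TRUE
    flat_rows <- c(flat_rows, new)
    flat_edge <- c(flat_edge, rep(e, length(new)))
  }
  vcoords <- mask_coords(mask)
  nearest <- cpp_nearest_ref(matrix(as.numeric(vcoords), ncol = 3),
                             matrix(as.numeric(sk$voxels[flat_rows, ,
                                                         drop = FALSE]),
                                    ncol = 3))
  assign_edge <- flat_edge[nearest]
  lapply(seq_along(sk$edges), function(e) {
    bmask <- array(FALSE, dim(mask))
    bmask[vcoords[assign_edge == e, , drop = FALSE]] <- TRUE
    make_branch(sk$edges[[e]], bmask)
  })
}

#' @export
print.vessel_branch <- function(x, ...) {
  cat("vessel_branch", x$vessel_name, ":", nrow(x$path), "skeleton voxels,",
      sum(x$branch_mask), "mask voxels\n")
  invisible(x)
}

#' Radius profile along a branch
#'
#' The inscribed radius at each skeleton path voxel: the Euclidean distance
#' transform of the vessel mask evaluated along the path.
#'
#' @param branch a `vessel_branch`.
#' @param mask logical vessel mask containing the branch path.
#' @return numeric vector of radii (voxels), one per path voxel.
#' @export
radius_profile <- function(branch, mask) {
  stopifnot(inherits(branch, "vessel_branch"))
  if (!all(mask[branch$path])) stop("branch path leaves the vessel mask")
  dist_to_mask(!mask)[branch$path]
}

#' Tumor distance profile along a branch
#'
#' Euclidean distance (voxels) from each skeleton path voxel to the nearest
#' tumor voxel; zero where the path enters the tumor.
#'
#' @param branch a `vessel_branch`.
#' @param tumor logical tumor mask, non-empty.
#' @return numeric vector, one distance per path voxel.
#' @export
tumor_distance_profile <- function(branch, tumor) {
  stopifnot(inherits(branch, "vessel_branch"))
  if (!any(tumor)) stop("empty tumor mask")
  dist_to_mask(tumor)[branch$path]
}

#' Export a skeleton as a voxel table
#' @param sk a [skeletonize_graph()] result.
#' @return data.frame with columns `edge`, `pos`, `i`, `j`, `k`.
#' @export
skeleton_to_df <- function(sk) {
  stopifnot(inherits(sk, "skeleton"))
  do.call(rbind, lapply(seq_along(sk$edges), function(e) {
    p <- sk$voxels[sk$edges[[e]], , drop = FALSE]
    data.frame(edge = e, pos = seq_len(nrow(p)),
               i = p[, 1], j = p[, 2], k = p[, 3])
  }))
}
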