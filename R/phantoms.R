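# Synthetic vessel/tumor scenes with known geometric ground truth.  Every
# phantom's truth record is sufficient to re-render its mask exactly, so
# seeded scenes are bitwise reproducible.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stamp a tube: union of thin disks (radius r(s), axial half-width 0.35 for
# sample step 0.5) perpendicular to the local tangent, giving flat end caps.
# `centerline` is an m x 3 matrix of samples, `radii` length m.
rasterize_tube <- function(centerline, radii, grid) {
  mask <- array(FALSE, grid)
  m <- nrow(centerline)
  # tangents by central differences
  tang <- rbind(centerline[2, ] - centerline[1, ],
                if (m > 2) centerline[3:m, , drop = FALSE] -
                  centerline[1:(m - 2), , drop = FALSE],
                centerline[m, ] - centerline[m - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  half <- 0.35
  for (a in seq_len(m)) {
    p <- centerline[a, ]
    r <- radii[a]
    d <- tang[a, ]
    # per-axis extent of the tilted disk: r*sqrt(1-d_e^2) + half*|d_e|
    ext <- r * sqrt(pmax(0, 1 - d^2)) + half * abs(d)
    if (any(p - ext < 0.5) || any(p + ext > grid + 0.5))
      stop("tube exceeds the grid")
    lo <- pmax(1, floor(p - ext)); hi <- pmin(grid, ceiling(p + ext))
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx <- outer(outer(ii - p[1], rep(0, length(jj)), "+"),
                rep(0, length(kk)), "+")
    dy <- outer(outer(rep(0, length(ii)), jj - p[2], "+"),
                rep(0, length(kk)), "+")
    dz <- outer(outer(rep(0, length(ii)), rep(0, length(jj)), "+"),
                kk - p[3], "+")
    ax <- dx * d[1] + dy * d[2] + dz * d[3]
    perp2 <- dx^2 + dy^2 + dz^2 - ax^2
    sel <- abs(ax) <= half & perp2 <= r^2
    mask[ii, jj, kk] <- mask[ii, jj, kk] | sel
  }
  mask
}

# Per-sample radius with an optional smooth (Gaussian) stenotic dip.
stenosis_radii <- function(s, radius, stenosis = NULL) {
  r <- rep(radius, length(s))
  if (!is.null(stenosis)) {
    f <- stenosis$factor %||% 0.5
    sc <- stenosis$center %||% mean(range(s))
    w <- stenosis$width %||% 12
    r <- radius * (1 - (1 - f) * exp(-((s - sc) / (w / 2))^2))
  }
  r
}

#' Generate a tubular vessel phantom
#'
#' Builds a straight, curved (sinusoidal) or Y-shaped tube of known
#' centerline and radius on an isotropic grid.  The truth record (exact
#' centerline samples and per-arclength radii) re-renders the mask exactly.
#'
#' @param shape `"straight"`, `"curved"` or `"Y"`.
#' @param length tube length in voxels along the main (third) axis.
#' @param radius tube radius in voxels (>= 2).
#' @param grid grid dimensions (default 96^3).
#' @param center in-plane centre `c(i, j)`; defaults to the grid centre.
#' @param curve_amp lateral amplitude of the curved shape (voxels).
#' @param stenosis optional list(`factor`, `center`, `width`): the radius is
#'   multiplied by a smooth dip reaching `factor` at axial position `center`.
#' @param seed optional; present for interface symmetry (geometry is
#'   deterministic given the parameters).
#' @return list with `mask` (logical array) and `truth` (parameters plus
#'   `centerline` samples and `radii`).
#' @export
make_vessel_phantom <- function(shape = c("straight", "curved", "Y"),
                                length = 60, radius = 4, grid = c(96, 96, 96),
                                center = NULL, curve_amp = 8,
                                stenosis = NULL, seed = NULL) {
  shape <- match.arg(shape)
  if (radius < 2) stop("radius must be >= 2 voxels")
  if (is.null(center)) center <- c(grid[1] / 2, grid[2] / 2)
  k0 <- (grid[3] - length) / 2
  if (k0 < 1 || 2 * radius + 2 > min(grid[1:2]))
    stop("tube exceeds the grid")
  step <- 0.5
  if (shape == "Y") {
    s_tr <- seq(0, length / 2, by = step)
    trunk <- cbind(center[1], center[2], k0 + s_tr)
    ang <- 35 * pi / 180
    s_li <- seq(step, length / 2, by = step)
    limb1 <- cbind(center[1] + sin(ang) * s_li, center[2],
                   k0 + length / 2 + cos(ang) * s_li)
    limb2 <- cbind(center[1] - sin(ang) * s_li, center[2],
                   k0 + length / 2 + cos(ang) * s_li)
    cl <- rbind(trunk, limb1, limb2)
    s <- c(s_tr, length / 2 + s_li, length / 2 + s_li)
  } else {
    s <- seq(0, length, by = step)
    off <- if (shape == "curved") curve_amp * sin(2 * pi * s / length) else 0
    cl <- cbind(center[1] + off, center[2], k0 + s)
  }
  radii <- stenosis_radii(s, radius, stenosis)
  truth <- list(kind = "vessel", shape = shape, length = length,
                radius = radius, grid = grid, center = center,
                curve_amp = curve_amp, stenosis = stenosis,
                centerline = cl, arclength = s, radii = radii)
  list(mask = rasterize_tube(cl, radii, grid), truth = truth)
}

#' Generate a tumor phantom
#'
#' `"ellipsoid"`: axis-aligned solid ellipsoid.  `"wrap"`: a shell sector of
#' angular width `psi_deg` around a straight vessel's centerline, at radial
#' gap `gap` outside the vessel surface, `thickness` voxels thick, spanning
#' `span` axial voxels -- the ground-truth encasement fraction is
#' `psi_deg / 360`.
#'
#' @param kind `"ellipsoid"` or `"wrap"`.
#' @param params for `"ellipsoid"`: list(`center`, `semi_axes`); for
#'   `"wrap"`: list(`psi_deg` in (0, 360], `gap`, `thickness`, `span`,
#'   optional `phi0_deg` sector centre).
#' @param vessel_truth truth record of a straight [make_vessel_phantom()]
#'   (required for `"wrap"`).
#' @param grid grid dimensions (defaults to the vessel grid, else 96^3).
#' @param seed unused; geometry is deterministic.
#' @return list with `mask` and `truth`.
#' @export
make_tumor_phantom <- function(kind = c("ellipsoid", "wrap"), params = list(),
                               vessel_truth = NULL, grid = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "ellipsoid") {
    grid <- grid %||% c(96, 96, 96)
    ctr <- params$center %||% (grid / 2)
    ax <- params$semi_axes %||% c(10, 8, 8)
    ii <- seq_len(grid[1]); jj <- seq_len(grid[2]); kk <- seq_len(grid[3])
    d2 <- outer(outer(((ii - ctr[1]) / ax[1])^2, ((jj - ctr[2]) / ax[2])^2,
                      "+"), ((kk - ctr[3]) / ax[3])^2, "+")
    mask <- d2 <= 1
    truth <- list(kind = "tumor", tumor_kind = "ellipsoid", center = ctr,
                  semi_axes = ax, grid = grid)
  } else {
    if (is.null(vessel_truth) || !identical(vessel_truth$shape, "straight"))
      stop("wrap phantom requires a straight vessel truth")
    psi <- params$psi_deg %||% 180
    if (psi <= 0 || psi > 360) stop("wrap angle must lie in (0, 360]")
    gap <- params$gap %||% 1
    thick <- params$thickness %||% 2
    span <- params$span %||% 10
    phi0 <- params$phi0_deg %||% 0
    grid <- grid %||% vessel_truth$grid
    ctr <- vessel_truth$center
    r <- vessel_truth$radius
    kmid <- mean(range(vessel_truth$centerline[, 3]))
    ii <- seq_len(grid[1]); jj <- seq_len(grid[2]); kk <- seq_len(grid[3])
    rho <- sqrt(outer((ii - ctr[1])^2, (jj - ctr[2])^2, "+"))
    phi <- (atan2(outer(rep(1, length(ii)), jj - ctr[2]),
                  outer(ii - ctr[1], rep(1, length(jj)))) * 180 / pi -
              phi0 + 180) %% 360 - 180
    ring <- rho >= r + gap & rho <= r + gap + thick & abs(phi) <= psi / 2
    mask <- array(FALSE, grid)
    kin <- kk[abs(kk - kmid) <= span / 2]
    for (k in kin) mask[, , k] <- ring
    truth <- list(kind = "tumor", tumor_kind = "wrap", psi_deg = psi,
                  gap = gap, thickness = thick, span = span,
                  phi0_deg = phi0, grid = grid,
                  vessel_center = ctr, vessel_radius = r, kmid = kmid)
  }
  list(mask = mask, truth = truth)
}

#' Compose a synthetic scene of vessels and one tumor
#'
#' Places up to five parallel straight vessels (named from [VESSEL_NAMES])
#' and an ellipsoidal tumor adjacent to the first vessel.  An optional
#' stenosis factor narrows the first vessel within its tumor-proximal
#' segment.  A single scene seed fans out to per-structure substreams (used
#' for placement jitter), so adding a vessel never perturbs the tumor draw.
#'
#' @param n_vessels number of vessels (1 to 5).
#' @param stenosis optional radius multiplier in (0, 1] applied to the first
#'   vessel near the tumor.
#' @param seed scene seed.
#' @param grid grid dimensions (default 96^3).
#' @param vessel_radius tube radius in voxels (default 4).
#' @param vessel_length tube length in voxels (default 60).
#' @param tumor_gap gap (voxels) between tumor surface and first vessel
#'   surface (default 1, i.e. in contact range).
#' @param tumor_semi_axes tumor ellipsoid semi-axes (default c(12, 9, 9)).
#' @return object of class `phantom_scene`: `structures` (a
#'   [structure_set()]) and `truth`.
#' @export
make_scene <- function(n_vessels = 1, stenosis = NULL, seed = 1,
                       grid = c(96, 96, 96), vessel_radius = 4,
                       vessel_length = 60, tumor_gap = 1,
                       tumor_semi_axes = c(12, 9, 9)) {
  if (n_vessels < 1 || n_vessels > 5) stop("n_vessels must be 1..5")
  truth <- list(kind = "scene", n_vessels = n_vessels, stenosis = stenosis,
                seed = seed, grid = grid, vessel_radius = vessel_radius,
                vessel_length = vessel_length, tumor_gap = tumor_gap,
                tumor_semi_axes = tumor_semi_axes)
  render_scene(truth)
}

#' Re-render a phantom scene from its truth record
#' @param truth the `truth` element of a [make_scene()] result.
#' @return the reconstructed `phantom_scene`.
#' @export
render_scene <- function(truth) {
  stopifnot(identical(truth$kind, "scene"))
  grid <- truth$grid
  n_vessels <- truth$n_vessels
  # base in-plane positions: spaced columns across the grid
  base_i <- grid[1] * (0.30 + 0.12 * (seq_len(n_vessels) - 1))
  base_j <- grid[2] * 0.40
  vessels <- list()
  vtruths <- list()
  for (v in seq_len(n_vessels)) {
    jit <- with_seed(truth$seed * 1000 + v,
                     runif(2, -3, 3))
    sten <- NULL
    if (v == 1 && !is.null(truth$stenosis) && truth$stenosis < 1) {
      sten <- list(factor = truth$stenosis,
                   center = truth$vessel_length / 2, width = 16)
    }
    vp <- make_vessel_phantom("straight", length = truth$vessel_length,
                              radius = truth$vessel_radius, grid = grid,
                              center = c(base_i[v] + jit[1],
                                         base_j + jit[2]),
                              stenosis = sten)
    nm <- VESSEL_NAMES[v]
    vessels[[nm]] <- vp$mask
    vtruths[[nm]] <- vp$truth
  }
  # tumor beside vessel 1, surface-to-surface gap ~ tumor_gap
  v1 <- vtruths[[1]]
  tjit <- with_seed(truth$seed * 1000 + 777, runif(1, -2, 2))
  ctr <- c(v1$center[1],
           v1$center[2] + truth$vessel_radius + truth$tumor_gap +
             truth$tumor_semi_axes[2],
           grid[3] / 2 + tjit)
  tp <- make_tumor_phantom("ellipsoid",
                           list(center = ctr,
                                semi_axes = truth$tumor_semi_axes),
                           grid = grid)
  scene <- list(
    structures = structure_set(tumor = tp$mask, vessels = vessels,
                               spacing = c(1, 1, 1)),
    truth = c(truth, list(vessels = vtruths, tumor = tp$truth)))
  class(scene) <- "phantom_scene"
  scene
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("phantom_scene (seed", x$truth$seed, "):\n")
  print(x$structures)
  invisible(x)
}

#' Simulate a tabular feature/outcome dataset from a logistic model
#'
#' Draws features i.i.d. from the stated distributions and outcomes from
#' Bernoulli(logistic(linear predictor)) under `model`.  Defaults: standard
#' normal for standardized features, `T_flat ~ U(1, 1.6)`,
#' `T_sphere ~ U(0.4, 1)`, standard normal otherwise.
#'
#' @param model a [risk_score_model()].
#' @param n number of rows (>= 1).
#' @param feature_distributions optional named list of functions `f(n)`
#'   drawing each feature; must cover any feature lacking a default.
#' @param seed RNG seed.
#' @return list: `X` (data.frame), `p` (generating probabilities), `y`
#'   (binary outcomes).
#' @export
simulate_feature_table <- function(model, n, feature_distributions = NULL,
                                   seed = 1) {
  stopifnot(inherits(model, "risk_score_model"), n >= 1)
  draw_default <- function(f) {
    if (f == "T_flat") return(function(n) runif(n, 1.0, 1.6))
    if (f == "T_sphere") return(function(n) runif(n, 0.4, 1.0))
    function(n) rnorm(n)
  }
  with_seed(seed, {
    X <- as.data.frame(lapply(setNames(model$feature_names,
                                       model$feature_names), function(f) {
      d <- feature_distributions[[f]]
      if (is.null(d)) d <- draw_default(f)
      if (!is.function(d)) stop("distribution for ", f, " must be a function")
      d(n)
    }))
    p <- predict_risk(model, X)
    y <- rbinom(n, 1, p)
    list(X = X, p = as.numeric(p), y = y)
  })
}
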