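# Shared fixture builders (all generated in code; nothing on disk).

digital_ball <- function(r, grid = rep(2 * r + 11, 3), center = (grid + 1) / 2) {
  ii <- seq_len(grid[1]); jj <- seq_len(grid[2]); kk <- seq_len(grid[3])
  d2 <- outer(outer((ii - center[1])^2, (jj - center[2])^2, "+"),
              (kk - center[3])^2, "+")
  d2 <= r^2
}

digital_ellipsoid <- function(semi, grid = 2 * ceiling(semi) + 11) {
  if (length(grid) == 1) grid <- rep(grid, 3)
  ctr <- (grid + 1) / 2
  ii <- seq_len(grid[1]); jj <- seq_len(grid[2]); kk <- seq_len(grid[3])
  d2 <- outer(outer(((ii - ctr[1]) / semi[1])^2, ((jj - ctr[2]) / semi[2])^2,
                    "+"), ((kk - ctr[3]) / semi[3])^2, "+")
  d2 <= 1
}

# blob = union of a few random balls, always non-empty and connected
random_blob <- function(seed, grid = c(24, 24, 24), n_balls = 3, rmax = 5) {
  set.seed(seed)
  mask <- array(FALSE, grid)
  prev <- grid / 2
  for (b in seq_len(n_balls)) {
    ctr <- pmin(grid - 6, pmax(7, prev + round(runif(3, -4, 4))))
    r <- runif(1, 3, rmax)
    mask <- mask | digital_ball(r, grid, ctr)
    prev <- ctr
  }
  mask
}

# straight digital cylinder along the third axis with flat caps
digital_cylinder <- function(radius, length, grid = NULL) {
  if (is.null(grid)) grid <- c(2 * radius + 9, 2 * radius + 9, length + 10)
  ctr <- c((grid[1] + 1) / 2, (grid[2] + 1) / 2)
  k0 <- floor((grid[3] - length) / 2)
  ii <- seq_len(grid[1]); jj <- seq_len(grid[2]); kk <- seq_len(grid[3])
  inplane <- outer((ii - ctr[1])^2, (jj - ctr[2])^2, "+") <= radius^2
  mask <- array(FALSE, grid)
  for (k in k0:(k0 + length - 1)) mask[, , k] <- inplane
  mask
}

# wrap-phantom scene used by encasement tests: big tube + shell sector
wrap_pair <- function(psi_deg, radius = 24, length = 50,
                      grid = c(64, 64, 60)) {
  vp <- make_vessel_phantom("straight", length = length, radius = radius,
                            grid = grid)
  tp <- make_tumor_phantom("wrap", list(psi_deg = psi_deg),
                           vessel_truth = vp$truth)
  list(vessel = vp$mask, tumor = tp$mask, truth = tp$truth)
}

expect_partition <- function(branches, mask) {
  acc <- array(0L, dim(mask))
  for (b in branches) acc <- acc + b$branch_mask
  expect_true(all(acc[mask] == 1L))
  expect_true(all(acc[!mask] == 0L))
}
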