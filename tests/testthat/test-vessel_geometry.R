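test_that("a straight tube skeletonizes to a single centerline edge", {
  vp <- make_vessel_phantom("straight", length = 60, radius = 4,
                            grid = c(40, 40, 80))
  sk <- skeletonize_graph(vp$mask)
  expect_length(sk$endpoints, 2)
  expect_length(sk$edges, 1)
  expect_true(abs(length(sk$edges[[1]]) - 60) <= 4)
  # deterministic ordering: path starts at the lexicographically lower end
  p <- sk$voxels[sk$edges[[1]], ]
  expect_lt(p[1, 3], p[nrow(p), 3])
})

test_that("a Y-shaped union yields one junction and three edges", {
  yp <- make_vessel_phantom("Y", length = 60, radius = 4,
                            grid = c(96, 48, 96))
  sk <- skeletonize_graph(yp$mask)
  expect_identical(sk$n_junctions, 1L)
  expect_length(sk$edges, 3)
  expect_length(sk$endpoints, 3)
})

test_that("degenerate non-tubular input collapses without spurious branches", {
  ball <- digital_ball(8, c(40, 40, 40))
  sk <- skeletonize_graph(ball)
  expect_lte(nrow(sk$voxels), 15)
  expect_lte(length(sk$edges), 1)
  expect_error(skeletonize_graph(array(FALSE, c(8, 8, 8))), "empty")
})

test_that("skeletonization is invariant to axis-aligned rotations", {
  for (shape in c("straight", "Y")) {
    vp <- make_vessel_phantom(shape, length = 50, radius = 4,
                              grid = c(80, 40, 80))
    sk <- skeletonize_graph(vp$mask)
    for (perm in list(c(3, 2, 1), c(2, 1, 3), c(1, 3, 2))) {
      skp <- skeletonize_graph(aperm(vp$mask, perm))
      expect_length(skp$edges, length(sk$edges))
      expect_length(skp$endpoints, length(sk$endpoints))
      expect_identical(skp$n_junctions, sk$n_junctions)
    }
  }
})

test_that("branch masks partition the vessel mask", {
  # single edge: one branch equal to the vessel mask
  vp <- make_vessel_phantom("straight", length = 40, radius = 4,
                            grid = c(32, 32, 56))
  sk <- skeletonize_graph(vp$mask)
  br <- split_branches(vp$mask, sk)
  expect_length(br, 1)
  expect_identical(br[[1]]$branch_mask, vp$mask)

  # Y phantom: three pairwise-disjoint branches covering the mask
  yp <- make_vessel_phantom("Y", length = 60, radius = 4,
                            grid = c(96, 48, 96))
  sky <- skeletonize_graph(yp$mask)
  bry <- split_branches(yp$mask, sky)
  expect_length(bry, 3)
  expect_partition(bry, yp$mask)

  # random blobs across seeds
  for (seed in 1:20) {
    blob <- random_blob(seed)
    skb <- skeletonize_graph(blob)
    brb <- split_branches(blob, skb)
    expect_partition(brb, blob)
  }
})

test_that("a manual branch-label volume overrides automatic assignment", {
  yp <- make_vessel_phantom("Y", length = 60, radius = 4,
                            grid = c(96, 48, 96))
  sk <- skeletonize_graph(yp$mask)
  auto <- split_branches(yp$mask, sk)
  manual <- array(0L, dim(yp$mask))
  manual[auto[[1]]$branch_mask | auto[[2]]$branch_mask] <- 1L
  manual[auto[[3]]$branch_mask] <- 2L
  over <- split_branches(yp$mask, sk, manual_labels = manual)
  expect_length(over, 2)
  expect_identical(over[[1]]$branch_mask,
                   auto[[1]]$branch_mask | auto[[2]]$branch_mask)
  expect_identical(over[[2]]$branch_mask, auto[[3]]$branch_mask)
  bad <- array(0L, c(4, 4, 4))
  expect_error(split_branches(yp$mask, sk, manual_labels = bad), "mismatch")
})

test_that("radius profiles recover cylinder and cone radii", {
  for (r in c(3, 4, 6)) {
    vp <- make_vessel_phantom("straight", length = 60, radius = r,
                              grid = c(2 * r + 10, 2 * r + 10, 80))
    sk <- skeletonize_graph(vp$mask)
    b <- split_branches(vp$mask, sk)[[1]]
    prof <- radius_profile(b, vp$mask)
    n <- length(prof)
    central <- prof[ceiling(0.1 * n):floor(0.9 * n)]
    expect_true(all(abs(central - r) <= 0.5))
  }
  # cone: radius 2 -> 6 along the axis, profile monotone up to 0.5 ripple
  s <- seq(0, 60, by = 0.5)
  cl <- cbind(20, 20, 8 + s)
  radii <- 2 + 4 * s / 60
  cone <- pancvas:::rasterize_tube(cl, radii, c(40, 40, 80))
  skc <- skeletonize_graph(cone)
  bc <- split_branches(cone, skc)[[1]]
  pr <- radius_profile(bc, cone)
  n <- length(pr)
  core <- pr[ceiling(0.1 * n):floor(0.9 * n)]
  expect_true(all(diff(cummax(core)) >= 0))
  expect_true(all(cummax(core) - core <= 0.5 + 1e-9))

  # one-voxel line: all radii in (0, 1]
  line <- array(FALSE, c(9, 9, 30)); line[5, 5, 5:25] <- TRUE
  skl <- skeletonize_graph(line)
  bl <- split_branches(line, skl)[[1]]
  pl <- radius_profile(bl, line)
  expect_true(all(pl > 0 & pl <= 1))

  # path outside the mask is a consistency error
  expect_error(radius_profile(bl, array(FALSE, c(9, 9, 30)) | FALSE),
               "path")
})

test_that("tumor distance profiles respect phantom geometry", {
  vp <- make_vessel_phantom("straight", length = 50, radius = 4,
                            grid = c(70, 40, 70))
  sk <- skeletonize_graph(vp$mask)
  b <- split_branches(vp$mask, sk)[[1]]
  # ball centre 20 voxels off the centerline, radius 6 -> min distance ~14
  ctr <- c(35 + 20, 20, 35)
  tum <- digital_ball(6, c(70, 40, 70), ctr)
  d <- tumor_distance_profile(b, tum)
  expect_lt(abs(min(d) - 14), 0.75)
  # translating the tumor 5 voxels farther raises the minimum by 5
  tum2 <- digital_ball(6, c(70, 40, 70), ctr + c(5, 0, 0))
  d2 <- tumor_distance_profile(b, tum2)
  expect_lt(abs((min(d2) - min(d)) - 5), 0.75)
  # a path voxel inside the tumor has distance zero
  tum3 <- digital_ball(6, c(70, 40, 70), c(35, 20, 35))
  d3 <- tumor_distance_profile(b, tum3)
  expect_true(any(d3 == 0))
  expect_error(tumor_distance_profile(b, array(FALSE, c(70, 40, 70)) | FALSE),
               "empty")
})

test_that("the surface map is total and stays within the local radius", {
  for (r in c(3, 4, 6)) {
    vp <- make_vessel_phantom("straight", length = 40, radius = r,
                              grid = c(2 * r + 10, 2 * r + 10, 60))
    sk <- skeletonize_graph(vp$mask)
    expect_identical(length(sk$surface_map), nrow(sk$surface))
    expect_true(all(sk$surface_map >= 1 & sk$surface_map <= nrow(sk$voxels)))
    d <- sqrt(rowSums((sk$surface -
                         sk$voxels[sk$surface_map, , drop = FALSE])^2))
    expect_true(all(d <= r + 1))
  }
})
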