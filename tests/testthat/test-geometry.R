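rotationAbout <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

test_that("Kabsch superposition recovers exact rigid motions", {
  X <- positions(randomFrame(25, 1))
  R <- rotationAbout(c(1, 1, 0), 40)
  Y <- sweep(X %*% t(R), 2, c(1, -2, 0.5), "+")
  fit <- kabschSuperpose(X, Y)
  expect_lt(fit$rmsd, 1e-10)
  expect_lt(max(abs(fit$Yfit - X)), 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("reflections are rejected by the determinant constraint", {
  X <- positions(randomFrame(12, 2))
  Y <- X
  Y[, 1] <- -Y[, 1]
  fit <- kabschSuperpose(X, Y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("fitted RMSD of noisy copies matches direct evaluation", {
  set.seed(30)
  X <- positions(randomFrame(200, 3, scale = 3))
  sigma <- 0.05
  Y <- X + matrix(rnorm(600, sd = sigma), 200, 3)
  fit <- kabschSuperpose(X, Y)
  direct <- sqrt(mean(rowSums((fit$Yfit - X)^2)))
  expect_equal(fit$rmsd, direct, tolerance = 1e-9)
  ## close to the raw noise scale for many points
  expect_equal(fit$rmsd, sigma * sqrt(3), tolerance = 0.1)
  expect_error(kabschSuperpose(X[1:2, ], Y[1:2, ]), "3 points")
})

test_that("core separation follows mass-weighted centres", {
  topo <- Topology(data.frame(
    name = "C", element = "C", resname = "BEA", resid = 1:4, unit = 1L,
    charge = 0, sigma = 0, epsilon = 0, mass = 12,
    stringsAsFactors = FALSE))
  fr <- Frame(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3), c(0, 0, 4)))
  d <- comDistance(fr, topo, GroupSelection("a", 1:2),
                   GroupSelection("b", 3:4))
  expect_equal(d, 3.0, tolerance = 1e-12)
  ## translation invariance
  fr2 <- Frame(positions(fr) + c(7))
  expect_equal(comDistance(fr2, topo, GroupSelection("a", 1:2),
                           GroupSelection("b", 3:4)), 3.0,
               tolerance = 1e-12)
  ## zero-mass selections are rejected
  topo0 <- Topology(data.frame(
    name = "X", element = "C", resname = "BEA", resid = 1:4, unit = 1L,
    charge = 0, sigma = 0, epsilon = 0, mass = 0,
    stringsAsFactors = FALSE))
  expect_error(comDistance(fr, topo0, GroupSelection("a", 1:2),
                           GroupSelection("b", 3:4)), "zero total mass")
})

test_that("orientation angle distinguishes facing and rotated tetrads", {
  traj <- buildToyDimer(ToyDimerSpec(mode = "5-5", separation = 1.2),
                        nFrames = 1)
  sel <- toyDimerSelections(traj)
  f <- traj@frames[[1]]
  ## coaxial stack with outward normals: facing tetrads at 180 degrees
  ang <- orientationAngle(f, traj@topology, sel$facing1, sel$facing2,
                          sel$core1, sel$core2)
  expect_equal(ang, 180, tolerance = 1e-6)
  ## rotate unit 2's facing tetrad by 90 degrees about an in-plane axis
  p <- positions(f)
  idx <- indices(sel$facing2)
  ctr <- colMeans(p[idx, ])
  p[idx, ] <- sweep(sweep(p[idx, ], 2, ctr) %*%
                      t(rotationAbout(c(1, 0, 0), 90)), 2, ctr, "+")
  ang90 <- orientationAngle(Frame(p), traj@topology, sel$facing1,
                            sel$facing2, sel$core1, sel$core2)
  expect_equal(ang90, 90, tolerance = 1e-6)
})

test_that("orientation angle is symmetric and noise-stable", {
  traj <- buildToyDimer(ToyDimerSpec(mode = "3-5", separation = 1.4),
                        nFrames = 1)
  sel <- toyDimerSelections(traj)
  f <- traj@frames[[1]]
  a1 <- orientationAngle(f, traj@topology, sel$facing1, sel$facing2,
                         sel$core1, sel$core2)
  a2 <- orientationAngle(f, traj@topology, sel$facing2, sel$facing1,
                         sel$core2, sel$core1)
  expect_equal(a1, a2, tolerance = 1e-9)
  set.seed(8)
  p <- positions(f)
  idx <- c(indices(sel$facing1), indices(sel$facing2))
  p[idx, ] <- p[idx, ] + matrix(rnorm(length(idx) * 3, sd = 0.01),
                                length(idx), 3)
  aN <- orientationAngle(Frame(p), traj@topology, sel$facing1,
                         sel$facing2, sel$core1, sel$core2)
  expect_lt(abs(aN - a1), 2)
})

test_that("collinear tetrads are rejected", {
  topo <- Topology(data.frame(
    name = "C", element = "C", resname = "BEA", resid = 1:6, unit = 1L,
    charge = 0, sigma = 0, epsilon = 0, mass = 12,
    stringsAsFactors = FALSE))
  fr <- Frame(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                    c(1, 0, 0), c(1, 1, 0), c(1, 2, 0)))
  expect_error(orientationAngle(fr, topo, GroupSelection("a", 1:3),
                                GroupSelection("b", 4:6)), "collinear")
})

test_that("interface shift is zero coaxially and exact under lateral offsets", {
  traj <- buildToyDimer(ToyDimerSpec(mode = "5-5", separation = 1.2),
                        nFrames = 1)
  sel <- toyDimerSelections(traj)
  f <- traj@frames[[1]]
  expect_lt(shiftCoordinate(f, traj@topology, sel$external1,
                            sel$external2), 1e-9)
  ## translate unit 2 laterally by 0.45 nm
  p <- positions(f)
  u2 <- which(atoms(traj@topology)$unit == 2)
  p[u2, 1] <- p[u2, 1] + 0.45
  s <- shiftCoordinate(Frame(p), traj@topology, sel$external1,
                       sel$external2)
  expect_equal(s, 0.45, tolerance = 1e-6)
  ## invariant under a rotation of the whole system
  R <- rotationAbout(c(2, 1, 1), 65)
  s2 <- shiftCoordinate(Frame(p %*% t(R)), traj@topology, sel$external1,
                        sel$external2)
  expect_equal(s2, s, tolerance = 1e-9)
})

test_that("twist offset reduces modulo the 4-fold symmetry period", {
  for (tw in c(0, 45, 100)) {
    traj <- buildToyDimer(ToyDimerSpec(mode = "5-5", separation = 1.3,
                                       twist = tw), nFrames = 1)
    sel <- toyDimerSelections(traj)
    got <- twistOffset(traj@frames[[1]], sel$ring1, sel$ring2)
    expect_equal(got, tw %% 90, tolerance = 1)
  }
})

test_that("contact area matches the analytic union of facing disks", {
  ## at separation 0.7 = 2 x rise the facing plates coincide, so supply
  ## the stacking axis as the interface normal explicitly
  traj <- buildToyDimer(ToyDimerSpec(mode = "5-5", separation = 0.7,
                                     twist = 0), nFrames = 1)
  sel <- toyDimerSelections(traj)
  f <- traj@frames[[1]]
  ca <- contactArea(f, traj@topology, sel$facing1, sel$facing2,
                    normal = c(0, 0, 1))
  ## coaxial identical plates: the overlap is one plate's footprint
  expect_equal(ca$area, ca$footprintA, tolerance = 0.02 * ca$footprintA)
  ## analytic union of 4 disks (radius 0.17 nm carbon beads at ring
  ## radius 0.55 nm: disjoint disks)
  expect_equal(ca$footprintA, 4 * pi * 0.17^2, tolerance = 0.01)
  ## halving the raster spacing changes the area by < 0.5%
  ca2 <- contactArea(f, traj@topology, sel$facing1, sel$facing2,
                     gridSpacing = 0.005, normal = c(0, 0, 1))
  expect_lt(abs(ca2$area - ca$area) / ca$area, 0.005)
  ## area is bounded by the individual footprints
  expect_lte(ca$area, min(ca$footprintA, ca$footprintB) + 1e-9)
})

test_that("widely separated selections have zero contact area", {
  traj <- buildToyDimer(ToyDimerSpec(mode = "5-5", separation = 1.2),
                        nFrames = 1)
  sel <- toyDimerSelections(traj)
  p <- positions(traj, 1)
  u2 <- which(atoms(traj@topology)$unit == 2)
  p[u2, 1] <- p[u2, 1] + 3
  ca <- contactArea(Frame(p), traj@topology, sel$facing1, sel$facing2,
                    normal = c(0, 0, 1))
  expect_equal(ca$area, 0)
})

test_that("cylindrical projection maps azimuth and height faithfully", {
  topo <- Topology(data.frame(
    name = "C", element = "C", resname = "BEA", resid = 1, unit = 1L,
    charge = 0, sigma = 0, epsilon = 0, mass = 12,
    stringsAsFactors = FALSE))
  traj <- Trajectory(topo, list(Frame(matrix(c(0.5, 0, 1), 1))))
  m <- cylindricalProjection(traj, GroupSelection("a", 1),
                             axisOrigin = c(0, 0, 0), axisDir = c(0, 0, 1),
                             nAzimuth = 36,
                             heightBreaks = seq(0, 2, by = 0.5))
  hit <- which(m$occupancy > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 1)
  expect_equal(m$azimuth[hit[1, 1]], 5)       # first 10-degree sector
  expect_equal(m$height[hit[1, 2]], 1.25)     # bin (1.0, 1.5]
  ## a 4-fold ring gives 4 equal peaks 90 degrees apart
  ringT <- buildToyDimer(ToyDimerSpec(twist = 0), nFrames = 1)
  rsel <- toyDimerSelections(ringT)
  mr <- cylindricalProjection(ringT, rsel$ring1, axisOrigin = c(0, 0, 0),
                              axisDir = c(0, 0, 1), nAzimuth = 8,
                              heightBreaks = c(-1, 1))
  peaks <- which(mr$occupancy[, 1] > 0)
  expect_length(peaks, 4)
  expect_equal(diff(peaks), c(2, 2, 2))
  expect_equal(length(unique(mr$occupancy[peaks, 1])), 1)
})
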