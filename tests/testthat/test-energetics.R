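test_that("the Coulomb kernel reproduces the MD unit convention", {
  topo <- chargeTopology(c(1, 1))
  fr <- Frame(rbind(c(0, 0, 0), c(1, 0, 0)))
  e <- groupPairEnergy(fr, topo, GroupSelection("a", 1),
                       GroupSelection("b", 2))
  expect_equal(e[["elec"]], 33.20636, tolerance = 1e-7)
  expect_equal(e[["vdw"]], 0)
})

test_that("empty groups contribute zero energy", {
  topo <- chargeTopology(c(1, 1))
  fr <- Frame(rbind(c(0, 0, 0), c(1, 0, 0)))
  e <- groupPairEnergy(fr, topo, GroupSelection("a", integer(0)),
                       GroupSelection("b", 2))
  expect_equal(unname(e), c(0, 0))
})

test_that("group energies match an independent brute-force double loop", {
  topo <- randomTopology(40, seed = 8)
  fr <- randomFrame(40, seed = 9)
  A <- GroupSelection("A", 1:20)
  B <- GroupSelection("B", 21:40)
  got <- groupPairEnergy(fr, topo, A, B)
  a <- atoms(topo)
  want <- bruteForceEnergy(positions(fr), a$charge, a$sigma, a$epsilon,
                           1:20, 21:40)
  expect_equal(got[["elec"]], want[["elec"]], tolerance = 1e-10)
  expect_equal(got[["vdw"]], want[["vdw"]], tolerance = 1e-10)
})

test_that("the energy kernel is symmetric, superposable and rigid-motion invariant", {
  topo <- randomTopology(30, seed = 3)
  fr <- randomFrame(30, seed = 4)
  A <- GroupSelection("A", 1:10)
  B <- GroupSelection("B", 11:20)
  C <- GroupSelection("C", 21:30)
  BC <- GroupSelection("BC", 11:30)
  eAB <- groupPairEnergy(fr, topo, A, B)
  expect_identical(eAB, groupPairEnergy(fr, topo, B, A))
  eSum <- groupPairEnergy(fr, topo, A, BC)
  expect_equal(eSum, eAB + groupPairEnergy(fr, topo, A, C),
               tolerance = 1e-12)
  ## global rotation + translation
  ax <- c(1, 2, 3)
  R <- {
    th <- 0.7
    a <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  fr2 <- Frame(sweep(positions(fr) %*% t(R), 2, c(0.3, -1, 2), "+"))
  e2 <- groupPairEnergy(fr2, topo, A, B)
  expect_equal(e2, eAB, tolerance = 1e-9 * max(abs(eAB)))
})

test_that("overlapping groups and zero distances are rejected", {
  topo <- chargeTopology(c(1, 1, 1))
  fr <- Frame(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(groupPairEnergy(fr, topo, GroupSelection("a", 1:2),
                               GroupSelection("b", 2:3)), "overlap")
  expect_error(groupPairEnergy(fr, topo, GroupSelection("a", 1),
                               GroupSelection("b", 2)), "zero distance")
})

test_that("minimum-image distances are used when a box is present", {
  topo <- chargeTopology(c(1, 1))
  fr <- Frame(rbind(c(0.1, 0, 0), c(4.9, 0, 0)), box = c(5, 5, 5))
  e <- groupPairEnergy(fr, topo, GroupSelection("a", 1),
                       GroupSelection("b", 2))
  ## image distance 0.2 nm, not 4.8
  expect_equal(e[["elec"]], 33.20636 / 0.2, tolerance = 1e-7)
})

test_that("an identical bound and unbound ensemble gives a zero matrix", {
  traj <- buildToyDimer(ToyDimerSpec(nIons = 2), nFrames = 2, seed = 3)
  sel <- toyDimerSelections(traj)
  groups <- list(sel$core1, sel$core2, sel$ring1, sel$ring2, sel$ions)
  m <- enthalpyMatrix(traj, traj, groups)
  expect_equal(max(abs(values(m, "total"))), 0)
})

test_that("approaching like-charged phosphate rings raises the backbone term", {
  bound <- buildToyDimer(ToyDimerSpec(separation = 1.1), nFrames = 1)
  unbound <- buildToyDimer(ToyDimerSpec(separation = 3.0), nFrames = 1)
  sel <- toyDimerSelections(bound)
  m <- enthalpyMatrix(bound, unbound,
                      list(sel$core1, sel$core2, sel$ring1, sel$ring2))
  expect_gt(values(m, "elec")["ring1", "ring2"], 0)
})

test_that("the decomposition conserves the total energy change", {
  n <- 60
  topo <- randomTopology(n, seed = 12)
  bound <- Trajectory(topo, list(randomFrame(n, 13), randomFrame(n, 14)),
                      weights = c(0.7, 0.3))
  unbound <- Trajectory(topo, list(randomFrame(n, 15), randomFrame(n, 16)))
  groups <- list(GroupSelection("g1", 1:15), GroupSelection("g2", 16:35),
                 GroupSelection("g3", 36:60))
  m <- enthalpyMatrix(bound, unbound, groups)
  a <- atoms(topo)
  tot <- function(traj, w) {
    e <- vapply(seq_along(traj@frames), function(i)
      sum(bruteForceTotal(positions(traj, i), a$charge, a$sigma, a$epsilon,
                          1:n)), 0)
    sum(e * w)
  }
  want <- tot(bound, c(0.7, 0.3)) - tot(unbound, c(0.5, 0.5))
  expect_equal(interactionTotal(m), want,
               tolerance = 1e-6 * max(1, abs(want)))
  expect_equal(sum(groupContributions(m)), interactionTotal(m),
               tolerance = 1e-9)
})

test_that("a single phosphate pair lands in the right energy-density bin", {
  topo <- Topology(data.frame(
    name = c("P", "P"), element = "P", resname = "PHO", resid = c(1, 1),
    unit = c(1L, 2L), charge = -1, sigma = 0, epsilon = 0, mass = 95,
    stringsAsFactors = FALSE))
  fr <- Frame(rbind(c(0, 0, 0), c(0.8, 0, 0)))
  traj <- Trajectory(topo, list(fr))
  pA <- selectAtoms(topo, "unit 1", "pA")
  pB <- selectAtoms(topo, "unit 2", "pB")
  prof <- phosphateEnergyDensity(traj, pA, pB, binWidth = 0.1)
  tab <- values(prof)
  occupied <- tab[tab$density != 0, ]
  expect_equal(nrow(occupied), 1)
  expect_equal(occupied$r, 0.75)  # bin (0.7, 0.8] has centre 0.75
  expect_equal(occupied$density * 0.1, 33.20636 / 0.8, tolerance = 1e-7)
})

test_that("the cumulative phosphate curve conserves the total electrostatics", {
  traj <- buildToyDimer(ToyDimerSpec(separation = 1.1, twist = 45),
                        nFrames = 1)
  sel <- toyDimerSelections(traj)
  prof <- phosphateEnergyDensity(traj, sel$ring1, sel$ring2)
  total <- groupPairEnergy(traj@frames[[1]], traj@topology, sel$ring1,
                           sel$ring2)[["elec"]]
  cum <- prof@cumulative[length(prof@cumulative)]
  expect_equal(cum, total, tolerance = 1e-8 * abs(total))
  ## rigid translation leaves the profile unchanged
  shifted <- Trajectory(traj@topology,
                        list(Frame(positions(traj, 1) + 5)))
  prof2 <- phosphateEnergyDensity(shifted, sel$ring1, sel$ring2)
  expect_equal(values(prof2), values(prof), tolerance = 1e-9)
})

test_that("close-contact phosphate pairs track the stacking geometry", {
  ## an aligned (twist 0) dimer has closer cross-strand phosphates than the
  ## half-period twisted one at the same separation
  aligned <- buildToyDimer(ToyDimerSpec(mode = "3-3", separation = 0.8,
                                        twist = 0), nFrames = 1)
  twisted <- buildToyDimer(ToyDimerSpec(mode = "5-5", separation = 0.8,
                                        twist = 45), nFrames = 1)
  sa <- toyDimerSelections(aligned)
  st <- toyDimerSelections(twisted)
  dA <- minPPDistances(aligned@frames[[1]], aligned@topology, sa$ring1,
                       sa$ring2)
  dT <- minPPDistances(twisted@frames[[1]], twisted@topology, st$ring1,
                       st$ring2)
  expect_length(dA, 12)
  expect_gt(sum(dA < 0.6), sum(dT < 0.6))
  ## symmetry: swapping the rings preserves the distance multiset
  dRev <- minPPDistances(aligned@frames[[1]], aligned@topology, sa$ring2,
                         sa$ring1)
  expect_equal(sort(dA), sort(dRev), tolerance = 1e-12)
})

test_that("single-pair minimal distance is the pair distance", {
  topo <- Topology(data.frame(
    name = "P", element = "P", resname = "PHO", resid = 1,
    unit = c(1L, 2L), charge = -1, sigma = 0, epsilon = 0, mass = 95,
    stringsAsFactors = FALSE))
  fr <- Frame(rbind(c(0, 0, 0), c(0.7, 0, 0)))
  d <- minPPDistances(fr, topo, selectAtoms(topo, "unit 1"),
                      selectAtoms(topo, "unit 2"))
  expect_equal(d, 0.7, ignore_attr = TRUE)
})

test_that("group dipoles follow the point-charge definition", {
  topo <- chargeTopology(c(1, -1))
  fr <- Frame(rbind(c(0.1, 0, 0), c(0, 0, 0)))
  mu <- groupDipole(fr, topo, GroupSelection("d", 1:2))
  expect_equal(as.numeric(mu), c(0.1, 0, 0) * 1 - c(0.05, 0, 0) * 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(mu, "totalCharge"), 0)
  ## neutral group: origin-independent
  fr2 <- Frame(positions(fr) + 3)
  mu2 <- groupDipole(fr2, topo, GroupSelection("d", 1:2))
  expect_equal(as.numeric(mu2), as.numeric(mu), tolerance = 1e-12)
  ## perpendicular dipoles
  topo4 <- chargeTopology(c(1, -1, 1, -1))
  fr4 <- Frame(rbind(c(0.1, 0, 0), c(0, 0, 0),
                     c(1, 0.1, 0), c(1, 0, 0)))
  m1 <- groupDipole(fr4, topo4, GroupSelection("a", 1:2))
  m2 <- groupDipole(fr4, topo4, GroupSelection("b", 3:4))
  cosang <- sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2))
  expect_equal(acos(cosang) * 180 / pi, 90, tolerance = 1e-6)
})
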