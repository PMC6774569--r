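test_that("a single unbiased uniform window gives a flat profile", {
  set.seed(21)
  vals <- runif(20000, 1, 3)
  w <- list(UmbrellaWindow(2.0, 0, ColvarSeries(seq_along(vals), vals)))
  sol <- suppressWarnings(whamSolve(w, binWidth = 0.1,
                                    plateau = c(2.5, 3.0)))
  G <- sol$profile@G
  ok <- is.finite(G)
  ## multinomial noise on -kBT log(counts): 3 sigma on G
  nPerBin <- length(vals) / sum(ok)
  sigma <- kBT300 / sqrt(nPerBin)
  expect_lt(max(abs(G[ok])), 3.5 * sigma)
})

test_that("two-window discrete WHAM matches a hand fixed-point iteration", {
  v1 <- rep(c(1.05, 1.15, 1.25), times = c(30, 20, 10))
  v2 <- rep(c(1.05, 1.15, 1.25), times = c(5, 15, 40))
  k <- 50; centers <- c(1.1, 1.2)
  w <- list(UmbrellaWindow(centers[1], k, ColvarSeries(seq_along(v1), v1)),
            UmbrellaWindow(centers[2], k, ColvarSeries(seq_along(v2), v2)))
  sol <- suppressWarnings(whamSolve(w, binWidth = 0.1, tol = 1e-12,
                                    plateau = c(0.9, 1.4)))
  ## independent scalar fixed-point iteration on the same 3-bin histograms
  bins <- c(1.05, 1.15, 1.25)
  n <- rbind(c(30, 20, 10), c(5, 15, 40))
  C <- exp(-0.5 * k * outer(centers, bins, "-")^2 / kBT300)
  N <- rowSums(n)
  z <- c(1, 1)
  for (it in 1:20000) {
    p <- colSums(n) / (N[1] * C[1, ] / z[1] + N[2] * C[2, ] / z[2])
    p <- p / sum(p)
    z <- c(sum(C[1, ] * p), sum(C[2, ] * p))
  }
  f2 <- -kBT300 * (log(z[2]) - log(z[1]))
  expect_equal(sol$f[2], f2, tolerance = 1e-8)
})

test_that("WHAM recovers a planted double-well landscape", {
  ls <- defaultLandscape()
  w <- sampleWindows(ls, nPerWindow = 20000, seed = 42)
  sol <- whamSolve(w)
  prof <- sol$profile
  ok <- is.finite(prof@G)
  plat <- prof@bins >= 3.0 & prof@bins <= 3.4
  Ut <- landscapeEnergy(ls, prof@bins)
  Ut <- Ut - mean(Ut[plat & ok])
  expect_lt(sqrt(mean((prof@G[ok] - Ut[ok])^2)), 0.3)
})

test_that("WHAM is invariant under window reordering and a global shift", {
  ls <- defaultLandscape()
  w <- sampleWindows(ls, centers = seq(1.2, 2.0, by = 0.1),
                     nPerWindow = 3000, seed = 13)
  sol <- suppressWarnings(whamSolve(w, plateau = c(1.8, 2.0)))
  perm <- rev(seq_along(w))
  sol2 <- suppressWarnings(whamSolve(w[perm], plateau = c(1.8, 2.0)))
  expect_equal(sol2$profile@G, sol$profile@G, tolerance = 1e-5)
  ## shift all samples and centers by a constant (a bin-width multiple, so
  ## the histogram grid lines up and the identity is exact to tol)
  shift <- 0.40
  wS <- lapply(w, function(x)
    UmbrellaWindow(x@center + shift, x@k,
                   ColvarSeries(x@samples@times, x@samples@values + shift)))
  sol3 <- suppressWarnings(whamSolve(wS, plateau = c(1.8, 2.0) + shift))
  expect_equal(sol3$profile@G, sol$profile@G, tolerance = 1e-5)
})

test_that("non-overlapping window groups are rejected with the gap named", {
  mk <- function(ctr, vals)
    UmbrellaWindow(ctr, 286.1, ColvarSeries(seq_along(vals), vals))
  set.seed(31)
  w <- list(mk(1.2, rnorm(200, 1.2, 0.04)), mk(2.8, rnorm(200, 2.8, 0.04)))
  expect_error(suppressWarnings(whamSolve(w)), "non-overlapping")
})

test_that("unbiased frame weights reproduce the WHAM profile", {
  ls <- defaultLandscape()
  w <- sampleWindows(ls, nPerWindow = 3000, seed = 7)
  sol <- whamSolve(w)
  fw <- whamWeights(w, sol)
  expect_equal(sum(fw@weights), 1, tolerance = 1e-12)
  allr <- unlist(lapply(w, function(x) x@samples@values))
  bins <- sol$profile@bins
  bwd <- bins[2] - bins[1]
  idx <- pmin(length(bins),
              pmax(1, floor((allr - (bins[1] - bwd / 2)) / bwd) + 1))
  P <- tapply(fw@weights, idx, sum)
  Grec <- -kBT300 * log(as.numeric(P))
  ib <- as.integer(names(P))
  plat <- bins[ib] >= 3.0 & bins[ib] <= 3.4
  Grec <- Grec - mean(Grec[plat])
  ok <- is.finite(sol$profile@G[ib])
  expect_lt(max(abs(Grec[ok] - sol$profile@G[ib][ok])), 0.3)
})

test_that("a single unbiased window gets uniform weights", {
  set.seed(17)
  vals <- runif(500, 1, 2)
  w <- list(UmbrellaWindow(1.5, 0, ColvarSeries(seq_along(vals), vals)))
  sol <- suppressWarnings(whamSolve(w, plateau = c(1.5, 2)))
  fw <- whamWeights(w, sol)
  expect_equal(fw@weights, rep(1 / 500, 500), tolerance = 1e-12)
})

test_that("identical windows give equal weight to samples at equal r", {
  vals <- seq(1.2, 1.8, length.out = 100)
  mk <- function() UmbrellaWindow(1.5, 100, ColvarSeries(seq_along(vals),
                                                         vals))
  w <- list(mk(), mk())
  sol <- suppressWarnings(whamSolve(w, plateau = c(1.7, 1.8)))
  fw <- whamWeights(w, sol)
  w1 <- fw@weights[fw@window == 1]
  w2 <- fw@weights[fw@window == 2]
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("autocorrelation-aware blocks behave in the iid and duplicated limits", {
  set.seed(10)
  x <- rnorm(2000, sd = 0.1) + 2
  expect_equal(integratedAutocorrelationTime(x), 1)
  tauDup <- integratedAutocorrelationTime(rep(x, each = 2))
  expect_equal(tauDup, 2, tolerance = 0.2)

  mkw <- function(vals)
    list(UmbrellaWindow(2, 0, ColvarSeries(seq_along(vals), vals)))
  b1 <- suppressWarnings(bootstrapProfile(mkw(x), nBoot = 30,
                                          binWidth = 0.05,
                                          plateau = c(1.9, 2.1), seed = 4))
  b2 <- suppressWarnings(bootstrapProfile(mkw(rep(x, each = 2)), nBoot = 30,
                                          binWidth = 0.05,
                                          plateau = c(1.9, 2.1), seed = 4))
  expect_equal(b1$blockLengths, 1L)
  expect_equal(b2$blockLengths, 2L)
  ok <- is.finite(b1$profile@se) & is.finite(b2$profile@se) &
    b1$profile@se > 0
  ## duplicating every sample should not shrink errors: block doubling
  ## compensates the doubled sample count (within 25%)
  expect_equal(median(b2$profile@se[ok] / b1$profile@se[ok]), 1,
               tolerance = 0.25)
})

test_that("bootstrap rejects too few replicates", {
  w <- sampleWindows(flatLandscape(), centers = 2, nPerWindow = 100,
                     seed = 1)
  expect_error(bootstrapProfile(w, nBoot = 0), "nBoot")
  expect_error(bootstrapProfile(w, nBoot = 5), "nBoot")
})

test_that("the standard-state identity dG = 0 holds for G = 0 over V0", {
  ## G = 0 over exactly 1661 A = 166.1 nm: integral/V0 = 1
  bins <- seq(0, 166.1, by = 0.1)
  prof <- FreeEnergyProfile(bins, rep(0, length(bins)),
                            anchor = "plateau:test")
  st <- StateDefinition("I", 1e-9, 166.1, 166.1)
  expect_equal(standardStateDG(prof, st)@dG, 0, tolerance = 1e-9)
})

test_that("the square-well closed form is reproduced", {
  bins <- seq(0, 0.1, by = 0.001)
  prof <- FreeEnergyProfile(bins, rep(-10, length(bins)),
                            anchor = "plateau:test")
  st <- StateDefinition("I", 1e-9, 0.1, 0.1)
  got <- standardStateDG(prof, st, temperature = 300, V0 = 1661)@dG
  expect_equal(got, -10 + kBT300 * log(1661), tolerance = 1e-3)
  expect_equal(round(got, 2), -5.58)
})

test_that("the quadrature converges under bin refinement", {
  G <- function(r) -15 * exp(-(r - 1.1)^2 / (2 * 0.1^2))
  mk <- function(bw) {
    bins <- seq(0.9 + bw / 2, 2.0, by = bw)
    FreeEnergyProfile(bins, G(bins), anchor = "plateau:test")
  }
  st <- StateDefinition("I", 0.9, 2.0, 2.0)
  d1 <- standardStateDG(mk(0.02), st)@dG
  d2 <- standardStateDG(mk(0.01), st)@dG
  expect_lt(abs(d1 - d2), 1e-3)
})

test_that("jacobian-weighted variant differs by the expected volume factor", {
  ## flat G over a thin shell at radius r0: literal integral = L, jacobian
  ## integral = 4 pi r0^2 L
  bins <- seq(1.0, 1.1, by = 0.001)
  prof <- FreeEnergyProfile(bins, rep(0, length(bins)),
                            anchor = "plateau:test")
  st <- StateDefinition("I", 1.0, 1.1, 1.1)
  lit <- standardStateDG(prof, st)@dG
  jac <- standardStateDG(prof, st, jacobian = TRUE)@dG
  r0A <- 10.5
  expect_equal(jac - lit, -kBT300 * log(4 * pi * r0A^2), tolerance = 0.01)
})

test_that("printed free energies give the published populations and gaps", {
  dg <- c(`3-3 G` = 6.4, `3-5 G` = -13.5, `3-5 A` = -11.7,
          `5-5 G` = -17.5, `5-5 A` = -8.6)
  p <- statePopulations(dg, temperature = 300)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(round(100 * p[["5-5 G"]], 1), 99.9)
  expect_equal(round(100 * p[["3-5 G"]], 1), 0.1)
  expect_equal(round(100 * p[["3-3 G"]], 1), 0)
  expect_equal(round(100 * p[["5-5 A"]], 1), 0)
  ## free-energy gaps between the G-mediated modes
  expect_equal(round(dg[["3-5 G"]] - dg[["5-5 G"]]), 4)
  expect_equal(round(dg[["3-3 G"]] - dg[["5-5 G"]]), 24)
})

test_that("populations obey the analytic symmetry and ratio cases", {
  expect_equal(unname(statePopulations(c(-5, -5))), c(0.5, 0.5))
  ## three states spaced by kBT ln 2: populations 4/7, 2/7, 1/7
  dg <- c(0, kBT300 * log(2), 2 * kBT300 * log(2))
  expect_equal(unname(statePopulations(dg)), c(4, 2, 1) / 7,
               tolerance = 1e-9)
  ## invariance under a uniform shift
  expect_equal(statePopulations(dg + 100), statePopulations(dg),
               tolerance = 1e-9)
  expect_error(statePopulations(numeric(0)), "empty")
})

test_that("state assignment finds basins, merges, and handles edge cases", {
  ## single parabola: one state at the vertex
  bins <- seq(1, 2, by = 0.02)
  G <- 40 * (bins - 1.5)^2 - 6
  prof <- FreeEnergyProfile(bins, G, anchor = "plateau:test")
  st <- assignStates(prof)
  expect_length(st, 1)
  expect_lt(abs((st[[1]]@rLo + st[[1]]@rHi) / 2 - 1.5), 0.1)

  ## monotone increasing: no bound state
  prof2 <- FreeEnergyProfile(bins, 10 * (bins - 1), anchor = "plateau:test")
  expect_length(assignStates(prof2), 0)

  ## the default planted landscape: two basins near 1.1 and 1.5 nm
  fine <- seq(1.0, 3.4, by = 0.02)
  ls <- defaultLandscape()
  G3 <- landscapeEnergy(ls, fine)
  prof3 <- FreeEnergyProfile(fine, G3, anchor = "plateau:test")
  st3 <- assignStates(prof3)
  expect_length(st3, 2)
  mids <- vapply(st3, function(s) (s@rLo + s@rHi) / 2, 0)
  expect_lt(abs(mids[1] - 1.15), 0.15)
  expect_lt(abs(mids[2] - 1.55), 0.25)

  ## two dips separated by a barrier below the default threshold merge
  Gm <- -5 * exp(-(bins - 1.4)^2 / (2 * 0.085^2)) -
    5.2 * exp(-(bins - 1.6)^2 / (2 * 0.085^2))
  profM <- FreeEnergyProfile(bins, Gm, anchor = "plateau:test")
  expect_length(assignStates(profM), 1)
})

test_that("convergence series behaves like a stationary estimator", {
  ls <- defaultLandscape()
  w <- sampleWindows(ls, nPerWindow = 6000, seed = 19)
  expect_error(convergenceSeries(w, chunkCount = 1), "chunkCount")
  profs <- convergenceSeries(w, chunkCount = 3)
  expect_length(profs, 3)
  last <- profs[[3]]@G
  prev <- profs[[2]]@G
  ok <- is.finite(last) & is.finite(prev)
  ## stationary data: consecutive cumulative profiles agree closely
  expect_lt(sqrt(mean((last[ok] - prev[ok])^2)), 0.3)
  ## first chunk is noisier than the full profile against the truth
  plat <- profs[[1]]@bins >= 3.0 & profs[[1]]@bins <= 3.4
  Ut <- landscapeEnergy(ls, profs[[1]]@bins)
  rmsTo <- function(p) {
    ok <- is.finite(p@G)
    U <- Ut - mean(Ut[plat & ok])
    sqrt(mean((p@G[ok] - U[ok])^2))
  }
  expect_gt(rmsTo(profs[[1]]), rmsTo(profs[[3]]) * 0.8)
})
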