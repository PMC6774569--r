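## Synthetic-data generators: every input class the pipeline consumes, with
## known ground truth. All generators are seed-deterministic.

#' Evaluate a planted landscape
#'
#' @param spec a [LandscapeSpec-class].
#' @param r coordinate values, nm.
#' @return U(r) in kcal/mol.
#' @export
landscapeEnergy <- function(spec, r) {
  U <- ifelse(r < spec@rWall, spec@kWall * (spec@rWall - r)^2, 0)
  for (i in seq_along(spec@centers))
    U <- U - spec@depths[i] *
      exp(-(r - spec@centers[i])^2 / (2 * spec@widths[i]^2))
  U
}

#' The default planted free-energy landscape
#'
#' Two Gaussian wells at 1.1 nm (depth 20 kcal/mol) and 1.5 nm (depth
#' 14 kcal/mol) on a harmonic repulsive wall below 1.0 nm, flat beyond
#' 2.9 nm — a dimerization-like topography with a deep direct-stacking
#' basin, a shallower mediated basin and an unbound plateau.
#'
#' @return a [LandscapeSpec-class].
#' @export
defaultLandscape <- function() {
  LandscapeSpec(centers = c(1.1, 1.5), depths = c(20, 14),
                widths = c(0.12, 0.18), rWall = 1.0, kWall = 500,
                domain = c(0.9, 3.6))
}

#' Metropolis sampling of harmonic umbrella windows
#'
#' Draws samples from the biased stationary density
#' p(r) proportional to exp(-(U(r) + k/2 (r - r_c)^2) / kBT) in every
#' window, by Metropolis Monte Carlo with a step size auto-tuned to
#' 30-50 percent acceptance during a discarded burn-in. Only the stationary
#' density matters for WHAM, so no dynamics is simulated; replica exchange
#' is not emulated because WHAM pools samples per bias.
#'
#' @param landscape a [LandscapeSpec-class].
#' @param centers window centres, nm (default 25 windows 1.1-3.5 nm).
#' @param k force constant, kcal/(mol nm^2) (default 286.1).
#' @param nPerWindow samples recorded per window.
#' @param seed integer seed; fixed seed gives identical output.
#' @param temperature K.
#' @param thin record every `thin`-th Metropolis step (default 1; increase
#'   for nearly independent samples).
#' @param step initial proposal half-width, nm (auto-tuned).
#' @param burnin discarded tuning/equilibration steps.
#' @return list of [UmbrellaWindow-class] objects, with per-window
#'   acceptance rates in `attr(, "acceptance")`.
#' @export
sampleWindows <- function(landscape, centers = seq(1.1, 3.5, by = 0.1),
                          k = 286.1, nPerWindow = 1000, seed = 1,
                          temperature = 300, thin = 1, step = 0.05,
                          burnin = 2000) {
  stopifnot(nPerWindow >= 1, k >= 0)
  dom <- landscape@domain
  if (any(centers < dom[1] - 1e-9) || any(centers > dom[2] + 1e-9))
    stop("window centers outside landscape domain")
  set.seed(seed)
  W <- length(centers)
  kBT <- .kB * temperature
  logp <- function(r) {
    out <- rep(-Inf, length(r))
    ok <- r >= dom[1] & r <= dom[2]
    out[ok] <- -(landscapeEnergy(landscape, r[ok]) +
                   0.5 * k * (r[ok] - centers[ok])^2) / kBT
    out
  }
  ## start at the biased minimum estimate: the window centre clipped to the
  ## domain (for k = 0, the domain midpoint)
  r <- if (k > 0) pmin(pmax(centers, dom[1]), dom[2])
       else rep(mean(dom), W)
  steps <- rep(step, W)
  lp <- logp(r)
  ## burn-in with step tuning in batches of 100
  nBatch <- max(1L, burnin %/% 100L)
  for (b in seq_len(nBatch)) {
    accBatch <- rep(0, W)
    for (s in 1:100) {
      prop <- r + (stats::runif(W) * 2 - 1) * steps
      lpp <- logp(prop)
      acc <- log(stats::runif(W)) < (lpp - lp)
      r[acc] <- prop[acc]; lp[acc] <- lpp[acc]
      accBatch <- accBatch + acc
    }
    rate <- accBatch / 100
    steps <- ifelse(rate > 0.5, steps * 1.3,
                    ifelse(rate < 0.3, steps / 1.3, steps))
  }
  ## production
  total <- nPerWindow * thin
  samples <- matrix(0, nPerWindow, W)
  accepted <- rep(0, W)
  rec <- 0
  for (s in seq_len(total)) {
    prop <- r + (stats::runif(W) * 2 - 1) * steps
    lpp <- logp(prop)
    acc <- log(stats::runif(W)) < (lpp - lp)
    r[acc] <- prop[acc]; lp[acc] <- lpp[acc]
    accepted <- accepted + acc
    if (s %% thin == 0) {
      rec <- rec + 1
      samples[rec, ] <- r
    }
  }
  rate <- accepted / total
  if (any(rate == 0))
    stop("zero acceptance in window(s) ",
         paste(which(rate == 0), collapse = ", "),
         "; try a smaller initial step")
  out <- lapply(seq_len(W), function(i)
    UmbrellaWindow(centers[i], k,
                   ColvarSeries(seq_len(nPerWindow) - 1, samples[, i]),
                   temperature))
  attr(out, "acceptance") <- rate
  attr(out, "seed") <- seed
  out
}

## local coordinates of one toy unit (axis z, core COM at origin):
## 3 tetrad planes (4 beads each), 12-bead phosphate ring, 3 adenine beads
## stacked just beyond the 5' plane (at +z)
.toyUnitLocal <- function(spec) {
  zs <- c(-spec@rise, 0, spec@rise)   # 3' plane, middle, 5' plane
  ang <- .radians(c(0, 90, 180, 270))
  bead <- function(radius, phi, z)
    cbind(radius * cos(phi), radius * sin(phi), rep(z, length(phi)))
  tet <- do.call(rbind, lapply(zs, function(z) bead(spec@tetradRadius, ang, z)))
  phos <- do.call(rbind, lapply(seq_along(zs), function(l)
    bead(spec@ringRadius, ang + .radians(spec@helicalStep) * (l - 1), zs[l])))
  ade <- bead(spec@tetradRadius + 0.25, .radians(c(15, 135, 255)),
              zs[3] + 0.2)
  list(tet = tet, phos = phos, ade = ade)
}

#' Build a toy quadruplex dimer trajectory
#'
#' Two rigid coarse-grained units per [ToyDimerSpec-class]: three stacked
#' 4-bead tetrad planes, a 12-bead phosphate ring with exact 4-fold
#' symmetry, and three terminal adenine beads near the 5' tetrad. Unit 2
#' is flipped/translated/twisted according to the stacking mode, separation
#' and twist offset. Counterions, when requested, are equilibrated by
#' Metropolis against the fixed charges using the same Coulomb + LJ energy
#' as the decomposition module; each recorded frame is a decorrelated ion
#' configuration (the DNA beads are rigid).
#'
#' @param spec a [ToyDimerSpec-class].
#' @param nFrames number of frames.
#' @param seed integer seed.
#' @param sweepsPerFrame ion Monte Carlo sweeps between recorded frames.
#' @return a [Trajectory-class] whose topology carries charges/LJ from the
#'   spec (phosphates `spec@phosphateCharge`, ions +1, other beads neutral).
#' @export
buildToyDimer <- function(spec, nFrames = 1, seed = 1, sweepsPerFrame = 50) {
  set.seed(seed)
  loc <- .toyUnitLocal(spec)
  flip <- .rotationMatrix(c(1, 0, 0), pi)
  place <- function(xyz, flipped, twistDeg, zShift) {
    p <- xyz
    if (flipped) p <- p %*% t(flip)
    if (twistDeg != 0) p <- p %*% t(.rotationMatrix(c(0, 0, 1),
                                                    .radians(twistDeg)))
    sweep(p, 2, c(0, 0, zShift), "+")
  }
  ## which unit is flipped so the requested ends face across the interface
  ## (unit 1 below, its +z side faces unit 2; local 5' plane is at +z)
  flip1 <- spec@mode %in% c("3-3", "3-5")
  flip2 <- spec@mode %in% c("5-5", "3-5")
  unitXyz <- function(uflip, twist, z)
    rbind(place(loc$tet, uflip, twist, z), place(loc$ade, uflip, twist, z),
          place(loc$phos, uflip, twist, z))
  u1 <- unitXyz(flip1, 0, 0)
  u2 <- unitXyz(flip2, spec@twist, spec@separation)
  unitAtoms <- function(unit) data.frame(
    name = c(rep("GB", 12), rep("AB", 3), rep("P", 12)),
    element = c(rep("C", 12), rep("N", 3), rep("P", 12)),
    resname = c(rep("GUA", 12), rep("ADE", 3), rep("PHO", 12)),
    resid = c(1:12, 13:15, 16:27),
    unit = unit,
    charge = c(rep(0, 15), rep(spec@phosphateCharge, 12)),
    sigma = c(rep(0.35, 15), rep(0.40, 12)),
    epsilon = c(rep(0.10, 15), rep(0.15, 12)),
    mass = c(rep(150, 12), rep(134, 3), rep(95, 12)),
    stringsAsFactors = FALSE)
  at <- rbind(unitAtoms(1L), unitAtoms(2L))
  fixedXyz <- rbind(u1, u2)
  nIon <- spec@nIons
  if (nIon > 0) {
    halfL <- spec@ringRadius + 1.0
    zlo <- -3 * spec@rise - 1.0
    zhi <- spec@separation + 3 * spec@rise + 1.0
    vol <- (2 * halfL)^2 * (zhi - zlo)
    packing <- floor(vol / 0.3^3)
    if (nIon > packing)
      stop("counterion count ", nIon, " exceeds the packing bound ", packing)
    at <- rbind(at, data.frame(
      name = "K", element = "K", resname = "K", resid = seq_len(nIon),
      unit = 0L, charge = 1, sigma = 0.30, epsilon = 0.10, mass = 39.098,
      stringsAsFactors = FALSE))
  }
  topo <- Topology(at)
  a <- topo@atoms
  nFixed <- nrow(fixedXyz)
  if (nIon == 0) {
    frames <- lapply(seq_len(nFrames), function(i) Frame(fixedXyz, time = i - 1))
    return(Trajectory(topo, frames))
  }
  ## ion Metropolis in a fixed rectangular region (non-periodic)
  kBT <- .kB * 300
  ionPos <- cbind(stats::runif(nIon, -halfL, halfL),
                  stats::runif(nIon, -halfL, halfL),
                  stats::runif(nIon, zlo, zhi))
  ## single-ion energy (Coulomb + LJ against everything else), vectorized
  oneIonE <- function(pos, i, xi) {
    other <- rbind(fixedXyz, pos[-i, , drop = FALSE])
    qi <- a$charge[nFixed + i]
    qs <- c(a$charge[seq_len(nFixed)], a$charge[nFixed + seq_len(nIon)][-i])
    sg <- (c(a$sigma[seq_len(nFixed)],
             a$sigma[nFixed + seq_len(nIon)][-i]) + a$sigma[nFixed + i]) / 2
    ep <- sqrt(c(a$epsilon[seq_len(nFixed)],
                 a$epsilon[nFixed + seq_len(nIon)][-i]) *
                 a$epsilon[nFixed + i])
    d <- sqrt(rowSums(sweep(other, 2, xi)^2))
    sr6 <- (sg / d)^6
    .kCoulomb * qi * sum(qs / d) + 4 * sum(ep * (sr6 * sr6 - sr6))
  }
  stepIon <- 0.1
  curE <- vapply(seq_len(nIon), function(i) oneIonE(ionPos, i, ionPos[i, ]),
                 0)
  frames <- vector("list", nFrames)
  totalSweeps <- nFrames * sweepsPerFrame + 200   # 200 equilibration sweeps
  f <- 0
  for (s in seq_len(totalSweeps)) {
    for (i in seq_len(nIon)) {
      cand <- ionPos[i, ] + (stats::runif(3) * 2 - 1) * stepIon
      if (abs(cand[1]) > halfL || abs(cand[2]) > halfL ||
          cand[3] < zlo || cand[3] > zhi) next
      eNew <- oneIonE(ionPos, i, cand)
      if (log(stats::runif(1)) < -(eNew - curE[i]) / kBT) {
        ionPos[i, ] <- cand
        ## energies of other ions change too; recompute lazily below
        curE[i] <- eNew
      }
    }
    ## refresh cached energies each sweep (ion-ion coupling)
    curE <- vapply(seq_len(nIon), function(i) oneIonE(ionPos, i, ionPos[i, ]),
                   0)
    if (s > 200 && (s - 200) %% sweepsPerFrame == 0) {
      f <- f + 1
      frames[[f]] <- Frame(rbind(fixedXyz, ionPos), time = f - 1)
    }
  }
  Trajectory(topo, frames[seq_len(nFrames)])
}

#' Standard selections on a toy-dimer topology
#'
#' Convenience groups for a [buildToyDimer()] trajectory: guanine cores,
#' phosphate rings, adenines and ions, plus the per-plane tetrad selections
#' and (from frame geometry) the facing tetrads of the two units.
#'
#' @param traj a toy-dimer [Trajectory-class].
#' @return named list of [GroupSelection-class] objects / lists:
#'   `core1`, `core2`, `ring1`, `ring2`, `ade1`, `ade2`, `ions`,
#'   `facing1`, `facing2` (facing tetrad planes), `external1`, `external2`
#'   (lists of the two external tetrads, ordered bottom/top in z).
#' @export
toyDimerSelections <- function(traj) {
  topo <- traj@topology
  fr <- traj@frames[[1]]
  planes <- list(`1` = 1:4, `2` = 5:8, `3` = 9:12)  # local resid blocks
  planeSel <- function(unit, resids)
    selectAtoms(topo, sprintf("resname GUA and unit %d and resid %s", unit,
                              paste(resids, collapse = " ")),
                label = sprintf("tetrad_u%d_%s", unit, resids[1]))
  planeZ <- function(sel) mean(fr@positions[sel@indices, 3])
  out <- list(
    core1 = selectAtoms(topo, "resname GUA and unit 1", "core1"),
    core2 = selectAtoms(topo, "resname GUA and unit 2", "core2"),
    ring1 = selectAtoms(topo, "resname PHO and unit 1", "ring1"),
    ring2 = selectAtoms(topo, "resname PHO and unit 2", "ring2"),
    ade1 = selectAtoms(topo, "resname ADE and unit 1", "ade1"),
    ade2 = selectAtoms(topo, "resname ADE and unit 2", "ade2"),
    ions = selectAtoms(topo, "unit 0", "ions"))
  for (u in 1:2) {
    sels <- lapply(planes, function(p) planeSel(u, p))
    zs <- vapply(sels, planeZ, 0)
    ord <- order(zs)
    out[[paste0("external", u)]] <- list(sels[[ord[1]]], sels[[ord[3]]])
    ## facing plane: the external tetrad nearest the other unit's core
    otherZ <- mean(fr@positions[out[[paste0("core", 3 - u)]]@indices, 3])
    ext <- c(ord[1], ord[3])
    facing <- ext[which.min(abs(zs[ext] - otherZ))]
    out[[paste0("facing", u)]] <- sels[[facing]]
  }
  out
}

#' Plant a clustered conformational ensemble
#'
#' Each output frame is one medoid plus isotropic Gaussian coordinate noise
#' of scale `spread`, followed by a random rigid-body motion (uniform random
#' rotation, Gaussian translation). True labels are returned for recovery
#' scoring.
#'
#' @param medoidFrames non-empty list of [Frame-class] objects sharing an
#'   atom count.
#' @param counts frames to generate per medoid.
#' @param spread Gaussian displacement scale, nm (>= 0).
#' @param seed integer seed.
#' @param topology optional [Topology-class]; a generic carbon-bead
#'   topology is built when omitted.
#' @return list with `trajectory` ([Trajectory-class]) and `labels`
#'   (integer vector of true medoid indices).
#' @export
plantClusters <- function(medoidFrames, counts, spread, seed = 1,
                          topology = NULL) {
  if (!length(medoidFrames)) stop("empty medoid list")
  if (spread < 0) stop("spread must be >= 0")
  n <- nrow(medoidFrames[[1]]@positions)
  if (!all(vapply(medoidFrames, function(f) nrow(f@positions), 0L) == n))
    stop("medoids must share atom count")
  if (length(counts) != length(medoidFrames))
    stop("one count per medoid")
  set.seed(seed)
  if (is.null(topology))
    topology <- Topology(data.frame(name = "C", element = "C",
                                    resname = "BEA", resid = seq_len(n),
                                    unit = 1L, stringsAsFactors = FALSE))
  randomRotation <- function() {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  frames <- list(); labels <- integer(0); t <- 0
  for (m in seq_along(medoidFrames)) {
    base <- medoidFrames[[m]]@positions
    for (k in seq_len(counts[m])) {
      p <- base + matrix(stats::rnorm(n * 3, sd = spread), n, 3)
      ctr <- colMeans(p)
      p <- sweep(sweep(p, 2, ctr) %*% t(randomRotation()), 2,
                 ctr + stats::rnorm(3, sd = 0.5), "+")
      t <- t + 1
      frames[[t]] <- Frame(p, time = t - 1)
      labels <- c(labels, m)
    }
  }
  list(trajectory = Trajectory(topology, frames), labels = labels)
}

#' A coarse two-monomer telomeric topology
#'
#' One bead per nucleotide for two units of the human telomeric sequence
#' d[AGGG(TTAGGG)3] (22 residues each, resnames DA/DG/DT), with simple
#' helical bead coordinates. Mainly a fixture for selection and I/O tests:
#' each unit carries 12 guanine residues (four G-runs of three).
#'
#' @return list with `topology` ([Topology-class]) and `frame`
#'   ([Frame-class]).
#' @export
telomericTopology <- function() {
  seq1 <- strsplit("AGGGTTAGGGTTAGGGTTAGGG", "")[[1]]
  resname <- paste0("D", seq1)
  unitDf <- function(unit) data.frame(
    name = "C1'", element = "C", resname = resname,
    resid = seq_along(resname), unit = unit, stringsAsFactors = FALSE)
  at <- rbind(unitDf(1L), unitDf(2L))
  nres <- length(resname)
  helix <- function(zoff) {
    phi <- .radians(34) * (seq_len(nres) - 1)
    cbind(cos(phi), sin(phi), zoff + 0.34 * (seq_len(nres) - 1) * 0.1)
  }
  pos <- rbind(helix(0), helix(2.5))
  list(topology = Topology(at), frame = Frame(pos))
}
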