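## Nonbonded energy kernel and the enthalpy-decomposition machinery.
##
## A single direct-sum Coulomb + Lennard-Jones implementation is used
## everywhere (decomposition, phosphate profiles, counterion equilibration):
## E_coul = 33.20636 q_i q_j / r_ij  [kcal/mol, q in e, r in nm]
## E_lj   = 4 eps_ij [(sig_ij/r)^12 - (sig_ij/r)^6], Lorentz-Berthelot
## combination (arithmetic sigma, geometric epsilon); minimum image when a
## box is present; no cutoff and no reciprocal-space term, so group energies
## are exactly decomposable.

## energy between index sets ia, ib of one frame (ia, ib disjoint), or
## within one set when ib is NULL
.pairEnergy <- function(pos, charge, sigma, epsilon, ia, ib = NULL,
                        box = numeric(0)) {
  if (is.null(ib)) {
    n <- length(ia)
    if (n < 2) return(c(elec = 0, vdw = 0))
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ia[pr[, 1]]; j <- ia[pr[, 2]]
  } else {
    if (!length(ia) || !length(ib)) return(c(elec = 0, vdw = 0))
    i <- rep(ia, times = length(ib)); j <- rep(ib, each = length(ia))
  }
  d <- .displacement(pos[i, , drop = FALSE], pos[j, , drop = FALSE], box)
  r <- sqrt(rowSums(d * d))
  if (any(r == 0)) {
    k <- which(r == 0)[1]
    stop(sprintf("zero distance between atoms %d and %d", i[k], j[k]))
  }
  elec <- .kCoulomb * sum(charge[i] * charge[j] / r)
  eps <- sqrt(epsilon[i] * epsilon[j])
  act <- eps > 0
  vdw <- 0
  if (any(act)) {
    sig <- (sigma[i[act]] + sigma[j[act]]) / 2
    sr6 <- (sig / r[act])^6
    vdw <- 4 * sum(eps[act] * (sr6 * sr6 - sr6))
  }
  c(elec = elec, vdw = vdw)
}

#' Nonbonded interaction energy between two atom groups
#'
#' Direct double-sum Coulomb and 12-6 Lennard-Jones energy between two
#' disjoint groups, using the attached charges and LJ parameters. The
#' kernel is symmetric, superposable over disjoint groups and invariant
#' under rigid motion.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class] with parameters attached.
#' @param A,B disjoint [GroupSelection-class] objects.
#' @return named numeric: `elec` and `vdw`, kcal/mol.
#' @export
#' @examples
#' # two +1e charges 1 nm apart: elec = +33.21 kcal/mol
#' topo <- Topology(data.frame(name = c("Q1","Q2"), element = "K",
#'                             resname = "ION", resid = 1:2, unit = 0,
#'                             charge = 1, sigma = 0, epsilon = 0, mass = 39))
#' fr <- Frame(rbind(c(0,0,0), c(1,0,0)))
#' groupPairEnergy(fr, topo, GroupSelection("a", 1), GroupSelection("b", 2))
groupPairEnergy <- function(frame, topology, A, B) {
  if (length(intersect(A@indices, B@indices)))
    stop("groups '", A@label, "' and '", B@label, "' overlap")
  a <- topology@atoms
  .pairEnergy(frame@positions, a$charge, a$sigma, a$epsilon,
              A@indices, B@indices, frame@box)
}

## weighted ensemble average of all group-pair energies over a trajectory;
## returns list(elec, vdw) of nGroups x nGroups symmetric matrices where the
## diagonal holds intra-group energies
.ensemblePairMatrix <- function(traj, groups) {
  a <- traj@topology@atoms
  w <- frameWeights(traj)
  n <- length(groups)
  elec <- matrix(0, n, n); vdw <- matrix(0, n, n)
  for (f in seq_along(traj@frames)) {
    fr <- traj@frames[[f]]
    for (i in seq_len(n)) {
      for (j in i:n) {
        e <- if (i == j)
          .pairEnergy(fr@positions, a$charge, a$sigma, a$epsilon,
                      groups[[i]]@indices, NULL, fr@box)
        else
          .pairEnergy(fr@positions, a$charge, a$sigma, a$epsilon,
                      groups[[i]]@indices, groups[[j]]@indices, fr@box)
        elec[i, j] <- elec[i, j] + w[f] * e[["elec"]]
        vdw[i, j] <- vdw[i, j] + w[f] * e[["vdw"]]
      }
    }
  }
  elec[lower.tri(elec)] <- t(elec)[lower.tri(elec)]
  vdw[lower.tri(vdw)] <- t(vdw)[lower.tri(vdw)]
  list(elec = elec, vdw = vdw)
}

#' Interaction-enthalpy decomposition matrix
#'
#' For every (unordered) pair of named groups, the change in the weighted
#' ensemble-averaged nonbonded interaction energy between the bound and the
#' unbound ensemble; diagonal entries hold intra-group changes. The sum of
#' all entries equals the total nonbonded energy change of the group
#' partition (conservation identity, verified by the class validity tests).
#'
#' @param bound,unbound [Trajectory-class] objects sharing one topology;
#'   per-frame weights (e.g. from WHAM unbiasing) are honoured.
#' @param groups list of pairwise disjoint [GroupSelection-class] objects.
#' @return an [InteractionMatrix-class].
#' @export
enthalpyMatrix <- function(bound, unbound, groups) {
  if (!identical(bound@topology@atoms, unbound@topology@atoms))
    stop("bound and unbound trajectories must share a topology")
  labs <- vapply(groups, function(g) g@label, "")
  all_idx <- unlist(lapply(groups, function(g) g@indices))
  if (anyDuplicated(all_idx)) stop("groups overlap")
  if (!length(bound@frames) || !length(unbound@frames))
    stop("empty ensemble")
  mb <- .ensemblePairMatrix(bound, groups)
  mu <- .ensemblePairMatrix(unbound, groups)
  new("InteractionMatrix", labels = labs, elec = mb$elec - mu$elec,
      vdw = mb$vdw - mu$vdw, boundLabel = "bound", unboundLabel = "unbound")
}

#' Total enthalpy change of an interaction matrix
#'
#' Sum over all unordered group pairs plus intra-group (diagonal) terms —
#' the total nonbonded energy change of the partition.
#'
#' @param x an [InteractionMatrix-class].
#' @param component `"total"`, `"elec"` or `"vdw"`.
#' @return kcal/mol.
#' @export
interactionTotal <- function(x, component = "total") {
  m <- values(x, component)
  sum(m[upper.tri(m, diag = TRUE)])
}

#' Per-group overall contributions
#'
#' Row sums of the decomposition, counting each pair once: the overall
#' contribution of each structural element to the dimerization enthalpy.
#'
#' @param x an [InteractionMatrix-class].
#' @param component `"total"`, `"elec"` or `"vdw"`.
#' @return named numeric vector, kcal/mol; its sum equals
#'   [interactionTotal()].
#' @export
groupContributions <- function(x, component = "total") {
  m <- values(x, component)
  ## split each off-diagonal pair evenly; keep diagonal whole
  contrib <- rowSums(m) / 2 + diag(m) / 2
  stats::setNames(contrib, x@labels)
}

## split a phosphate selection into per-residue PO4 units; returns a list of
## index vectors and the index of the phosphorus atom within each
.po4Units <- function(topology, sel) {
  a <- topology@atoms
  idx <- sel@indices
  key <- paste(a$unit[idx], a$resid[idx])
  parts <- split(idx, key)
  units <- lapply(parts, function(ii) {
    p <- ii[toupper(a$element[ii]) == "P"]
    if (!length(p)) stop("PO4 unit without a phosphorus atom (resid ",
                         a$resid[ii[1]], ")")
    list(atoms = ii, p = p[1])
  })
  units[order(vapply(units, function(u) u$p, 1L))]
}

#' Electrostatic energy density of cross-strand phosphate interactions
#'
#' For each cross-strand PO4 pair in each frame, accumulates the Coulomb
#' energy between the two PO4 charge sets into bins of the P-P distance.
#' The density is normalized per frame and per bin width; the attached
#' cumulative curve runs up to the total cross-strand phosphate
#' electrostatic energy per frame.
#'
#' @param traj a [Trajectory-class]; frame weights are honoured.
#' @param phosA,phosB phosphate selections of the two units, resolvable
#'   into per-residue PO4 units each containing a phosphorus atom.
#' @param binWidth P-P distance bin width, nm (default 0.02).
#' @param distance `"P"` measures the P-P atom distance (default),
#'   `"com"` the distance between PO4 charge-set centres of mass.
#' @return an [EnergyDensityProfile-class].
#' @export
phosphateEnergyDensity <- function(traj, phosA, phosB, binWidth = 0.02,
                                   distance = c("P", "com")) {
  distance <- match.arg(distance)
  topo <- traj@topology
  a <- topo@atoms
  uA <- .po4Units(topo, phosA)
  uB <- .po4Units(topo, phosB)
  w <- frameWeights(traj)
  dists <- list(); energies <- list(); wts <- list()
  for (f in seq_along(traj@frames)) {
    fr <- traj@frames[[f]]
    for (ua in uA) {
      for (ub in uB) {
        rpp <- if (distance == "P") {
          d <- .displacement(fr@positions[ua$p, , drop = FALSE],
                             fr@positions[ub$p, , drop = FALSE], fr@box)
          sqrt(sum(d^2))
        } else {
          ca <- .centerOfMass(fr@positions[ua$atoms, , drop = FALSE],
                              a$mass[ua$atoms])
          cb <- .centerOfMass(fr@positions[ub$atoms, , drop = FALSE],
                              a$mass[ub$atoms])
          sqrt(sum(.displacement(matrix(ca, 1), matrix(cb, 1), fr@box)^2))
        }
        e <- .pairEnergy(fr@positions, a$charge, a$sigma, a$epsilon,
                         ua$atoms, ub$atoms, fr@box)[["elec"]]
        dists[[length(dists) + 1]] <- rpp
        energies[[length(energies) + 1]] <- e
        wts[[length(wts) + 1]] <- w[f]
      }
    }
  }
  dd <- unlist(dists); ee <- unlist(energies); ww <- unlist(wts)
  nb <- max(1L, ceiling(max(dd) / binWidth))
  bin <- pmin(nb, pmax(1L, ceiling(dd / binWidth)))
  acc <- rep(0, nb)
  for (k in seq_along(bin)) acc[bin[k]] <- acc[bin[k]] + ww[k] * ee[k]
  centers <- (seq_len(nb) - 0.5) * binWidth
  new("EnergyDensityProfile", bins = centers, density = acc / binWidth,
      cumulative = cumsum(acc), binWidth = binWidth)
}

#' Minimal cross-strand P-P distances
#'
#' For each PO4 unit of the first selection, the minimum P-P distance to
#' any PO4 unit of the second selection.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class].
#' @param phosA,phosB phosphate selections.
#' @return numeric vector of minimal distances, nm (empty for an empty
#'   first selection).
#' @export
minPPDistances <- function(frame, topology, phosA, phosB) {
  if (!length(phosA@indices)) return(numeric(0))
  pa <- vapply(.po4Units(topology, phosA), function(u) u$p, 1L)
  pb <- vapply(.po4Units(topology, phosB), function(u) u$p, 1L)
  dm <- .distMatrix(frame@positions[pa, , drop = FALSE],
                    frame@positions[pb, , drop = FALSE], frame@box)
  apply(dm, 1, min)
}

#' Dipole moment of an atom group
#'
#' Sum of q_i (r_i - r_COM) about the mass-weighted centre; for neutral
#' groups the result is origin-independent, for charged groups the
#' COM-origin convention applies and is recorded in the result.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class].
#' @param sel a non-empty [GroupSelection-class].
#' @return numeric length-3 dipole vector, e nm, with attributes
#'   `totalCharge` (e) and `origin` (`"com"`).
#' @export
groupDipole <- function(frame, topology, sel) {
  idx <- sel@indices
  if (!length(idx)) stop("empty selection '", sel@label, "'")
  a <- topology@atoms
  pos <- frame@positions[idx, , drop = FALSE]
  com <- .centerOfMass(pos, a$mass[idx])
  q <- a$charge[idx]
  mu <- colSums(sweep(pos, 2, com) * q)
  attr(mu, "totalCharge") <- sum(q)
  attr(mu, "origin") <- "com"
  mu
}
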