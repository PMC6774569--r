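## Ion/water statistics and weighted conformational clustering.

#' Mean counterion contact counts
#'
#' Classifies each ion per frame by minimum atom-atom distance: "all" if
#' within `cutoff` of either backbone, "interface" if within `cutoff` of
#' both backbones at the same time, "interface_po4" if within `cutoff` of
#' the PO4 sets of both units at the same time. Counts are averaged with
#' the trajectory's frame weights. By construction
#' interface_po4 <= interface <= all.
#'
#' @param traj a [Trajectory-class].
#' @param ions ion selection.
#' @param bbA,bbB backbone selections of the two units.
#' @param po4A,po4B PO4 selections of the two units.
#' @param cutoff contact cutoff, nm (default 0.7).
#' @return named numeric: `all`, `interface`, `interface_po4`.
#' @export
ionContactCounts <- function(traj, ions, bbA, bbB, po4A, po4B, cutoff = 0.7) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!length(ions@indices)) {
    warning("empty ion selection")
    return(c(all = 0, interface = 0, interface_po4 = 0))
  }
  w <- frameWeights(traj)
  acc <- c(all = 0, interface = 0, interface_po4 = 0)
  for (fi in seq_along(traj@frames)) {
    f <- traj@frames[[fi]]
    p <- f@positions
    di <- function(sel) {
      dm <- .distMatrix(p[ions@indices, , drop = FALSE],
                        p[sel@indices, , drop = FALSE], f@box)
      apply(dm, 1, min)
    }
    dA <- di(bbA); dB <- di(bbB); dpA <- di(po4A); dpB <- di(po4B)
    acc <- acc + w[fi] * c(
      all = sum(dA <= cutoff | dB <= cutoff),
      interface = sum(dA <= cutoff & dB <= cutoff),
      interface_po4 = sum(dpA <= cutoff & dpB <= cutoff))
  }
  acc
}

#' 3-D number-density grid of selected atoms
#'
#' Superposes every frame onto the first by the alignment selection
#' (Kabsch), bins the selected atoms on a regular grid, and normalizes so
#' the density integral equals the mean selected-atom count per frame.
#' Frame weights are honoured; `stride` emulates widely spaced snapshots.
#'
#' @param traj a [Trajectory-class].
#' @param sel atoms to accumulate.
#' @param spacing voxel edge, nm (default 0.05).
#' @param alignSel alignment selection (default: `sel`).
#' @param stride use every `stride`-th frame.
#' @param pad margin added around the data extent, nm.
#' @return a [DensityGrid-class].
#' @export
densityGrid <- function(traj, sel, spacing = 0.05, alignSel = sel,
                        stride = 1, pad = 0.1) {
  if (spacing <= 0) stop("spacing must be > 0")
  use <- seq(1, length(traj@frames), by = stride)
  w <- frameWeights(traj)[use]
  w <- w / sum(w)
  ref <- traj@frames[[use[1]]]@positions[alignSel@indices, , drop = FALSE]
  coords <- vector("list", length(use))
  for (j in seq_along(use)) {
    f <- traj@frames[[use[j]]]
    fit <- kabschSuperpose(ref, f@positions[alignSel@indices, , drop = FALSE])
    coords[[j]] <- sweep(f@positions[sel@indices, , drop = FALSE] %*%
                           t(fit$rotation), 2, fit$translation, "+")
  }
  allc <- do.call(rbind, coords)
  lo <- apply(allc, 2, min) - pad
  hi <- apply(allc, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  arr <- array(0, dim = dims)
  vox <- spacing^3
  for (j in seq_along(use)) {
    p <- coords[[j]]
    ii <- pmin(dims[1], pmax(1L, as.integer(floor((p[, 1] - lo[1]) / spacing)) + 1L))
    jj <- pmin(dims[2], pmax(1L, as.integer(floor((p[, 2] - lo[2]) / spacing)) + 1L))
    kk <- pmin(dims[3], pmax(1L, as.integer(floor((p[, 3] - lo[3]) / spacing)) + 1L))
    for (t in seq_along(ii))
      arr[ii[t], jj[t], kk[t]] <- arr[ii[t], jj[t], kk[t]] + w[j]
  }
  DensityGrid(lo, spacing, arr / vox, nFrames = length(use),
              alignLabel = alignSel@label)
}

#' Integral of a density grid
#'
#' Sum of density times voxel volume: the mean number of selected atoms
#' per frame for a grid built by [densityGrid()].
#'
#' @param grid a [DensityGrid-class].
#' @return the particle-count integral.
#' @export
gridIntegral <- function(grid) sum(grid@values) * grid@spacing^3

#' High-density site detection and occupancy
#'
#' Finds connected voxel components (26-connectivity) above
#' `thresholdMultiple` times the bulk density and integrates the density
#' over each component: the mean number of particles occupying the site.
#' Sites are returned sorted by decreasing occupancy.
#'
#' @param grid a density-normalized [DensityGrid-class].
#' @param bulkDensity bulk number density, nm^-3 (> 0).
#' @param thresholdMultiple density threshold in bulk units (default 10).
#' @return data.frame with columns `x`, `y`, `z` (site centre of density,
#'   nm), `occupancy` (particles) and `voxels`.
#' @export
siteOccupancy <- function(grid, bulkDensity, thresholdMultiple = 10) {
  if (bulkDensity <= 0) stop("bulk density must be > 0")
  thr <- thresholdMultiple * bulkDensity
  v <- grid@values
  d <- dim(v)
  above <- v > thr
  if (!any(above))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0), voxels = integer(0)))
  comp <- array(0L, dim = d)
  cid <- 0L
  idxAbove <- which(above)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (start in idxAbove) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      nb <- sweep(offsets, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      new <- lin[above[lin] & comp[lin] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  vox <- grid@spacing^3
  sites <- lapply(seq_len(cid), function(cc) {
    lin <- which(comp == cc)
    ci <- arrayInd(lin, d)
    dens <- v[lin]
    ctr <- grid@origin + (colSums(ci * dens) / sum(dens) - 0.5) * grid@spacing
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               occupancy = sum(dens) * vox, voxels = length(lin))
  })
  out <- do.call(rbind, sites)
  out[order(-out$occupancy), , drop = FALSE]
}

#' Radial distribution function
#'
#' Pair-distance histogram between a reference and a target selection,
#' normalized by the spherical shell volume 4 pi r^2 dr and by the
#' ideal-gas density of the target species, with frame weights honoured.
#' For periodic frames the density comes from the box volume (and `rMax`
#' must fit within half the smallest edge); for non-periodic systems pass
#' the sampling `volume` explicitly.
#'
#' @param traj a [Trajectory-class].
#' @param refSel,targetSel non-empty selections.
#' @param dr bin width, nm.
#' @param rMax maximum distance, nm.
#' @param volume sampling volume for non-periodic systems, nm^3.
#' @return data.frame with `r` (bin centres, nm) and `g`.
#' @export
rdf <- function(traj, refSel, targetSel, dr = 0.01, rMax = 1.5,
                volume = NULL) {
  if (!length(refSel@indices) || !length(targetSel@indices))
    stop("empty selection")
  w <- frameWeights(traj)
  nb <- as.integer(ceiling(rMax / dr))
  acc <- rep(0, nb)
  nTarget <- length(targetSel@indices)
  vols <- numeric(length(traj@frames))
  for (fi in seq_along(traj@frames)) {
    f <- traj@frames[[fi]]
    if (length(f@box)) {
      if (rMax > min(f@box) / 2 + 1e-9)
        stop("rMax exceeds half the smallest box edge")
      vols[fi] <- prod(f@box)
    } else {
      if (is.null(volume))
        stop("non-periodic frames need an explicit sampling volume")
      vols[fi] <- volume
    }
    dm <- .distMatrix(f@positions[refSel@indices, , drop = FALSE],
                      f@positions[targetSel@indices, , drop = FALSE], f@box)
    shared <- intersect(refSel@indices, targetSel@indices)
    if (length(shared))
      dm[cbind(match(shared, refSel@indices),
               match(shared, targetSel@indices))] <- Inf
    dd <- dm[dm < rMax]
    if (length(dd)) {
      bin <- pmax(1L, as.integer(ceiling(dd / dr)))
      for (b in unique(bin)) acc[b] <- acc[b] + w[fi] * sum(bin == b)
    }
  }
  centers <- (seq_len(nb) - 0.5) * dr
  shell <- 4 * pi * centers^2 * dr
  rho <- nTarget / stats::weighted.mean(vols, w)
  g <- acc / (length(refSel@indices) * shell * rho)
  data.frame(r = centers, g = g)
}

#' Hybrid k-centers / k-medoids conformational clustering
#'
#' Stage 1 (k-centers): seeds with the first frame and repeatedly adds the
#' frame farthest (superposed RMSD on the fit selection) from its nearest
#' centre until that distance is at most `cutoff`, guaranteeing every frame
#' lies within `cutoff` of a centre. Stage 2 (k-medoids): alternates
#' assignment to the nearest medoid and medoid update to the member
#' minimizing the weighted within-cluster RMSD sum, until labels stabilize
#' (at most 100 iterations); empty clusters are deleted. Cluster
#' populations are the sums of frame weights. Ties break toward the lowest
#' frame index, so the procedure is deterministic.
#'
#' @param traj a [Trajectory-class].
#' @param fitSel non-empty fit selection (e.g. all heavy atoms of the two
#'   guanine cores).
#' @param cutoff RMSD cutoff, nm (default 0.3).
#' @param weights per-frame weights (default: the trajectory's).
#' @return a [ClusterModel-class].
#' @export
clusterEnsemble <- function(traj, fitSel, cutoff = 0.3, weights = NULL) {
  if (!length(fitSel@indices)) stop("empty fit selection")
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- length(traj@frames)
  w <- if (is.null(weights)) frameWeights(traj) else weights / sum(weights)
  coords <- lapply(traj@frames, function(f)
    f@positions[fitSel@indices, , drop = FALSE])
  rmsdIJ <- function(i, j) kabschSuperpose(coords[[i]], coords[[j]])$rmsd
  ## stage 1: k-centers
  centers <- 1L
  dNearest <- vapply(seq_len(n), function(j) rmsdIJ(1L, j), 0)
  assign1 <- rep(1L, n)
  while (max(dNearest) > cutoff) {
    newC <- which.max(dNearest)  # which.max returns the first (lowest index)
    centers <- c(centers, newC)
    dNew <- vapply(seq_len(n), function(j) rmsdIJ(newC, j), 0)
    upd <- dNew < dNearest
    dNearest[upd] <- dNew[upd]
    assign1[upd] <- length(centers)
  }
  maxRadius1 <- max(dNearest)
  ## stage 2: k-medoids refinement
  medoids <- centers
  labels <- assign1
  distToMedoid <- matrix(NA_real_, n, length(medoids))
  for (m in seq_along(medoids))
    distToMedoid[, m] <- vapply(seq_len(n), function(j)
      rmsdIJ(medoids[m], j), 0)
  pairCache <- new.env(parent = emptyenv())
  cachedRmsd <- function(i, j) {
    if (i == j) return(0)
    key <- paste(min(i, j), max(i, j))
    v <- pairCache[[key]]
    if (is.null(v)) {
      v <- rmsdIJ(i, j)
      pairCache[[key]] <- v
    }
    v
  }
  for (it in seq_len(100)) {
    newLabels <- apply(distToMedoid, 1, which.min)
    keep <- sort(unique(newLabels))
    if (length(keep) < length(medoids)) {
      medoids <- medoids[keep]
      distToMedoid <- distToMedoid[, keep, drop = FALSE]
      newLabels <- match(newLabels, keep)
    }
    changed <- FALSE
    for (m in seq_along(medoids)) {
      members <- which(newLabels == m)
      if (length(members) < 2) next
      costs <- vapply(members, function(c1)
        sum(w[members] * vapply(members, function(j) cachedRmsd(c1, j), 0)),
        0)
      best <- members[which.min(costs)]
      if (best != medoids[m]) {
        medoids[m] <- best
        distToMedoid[, m] <- vapply(seq_len(n), function(j)
          rmsdIJ(best, j), 0)
        changed <- TRUE
      }
    }
    if (identical(newLabels, labels) && !changed) { labels <- newLabels; break }
    labels <- newLabels
  }
  pops <- vapply(seq_along(medoids), function(m) sum(w[labels == m]), 0)
  maxRadius2 <- max(distToMedoid[cbind(seq_len(n), labels)])
  new("ClusterModel", medoids = as.integer(medoids),
      labels = as.integer(labels), labelsInitial = as.integer(assign1),
      populations = pops / sum(pops), cutoff = cutoff,
      fitLabel = fitSel@label,
      maxRadius = c(kcenters = maxRadius1, refined = maxRadius2))
}
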