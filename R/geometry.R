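## Geometric order parameters of the dimer and superposition machinery.
## All observables are invariant under global rigid motion; angles are
## reported in degrees.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping Y onto X,
#' with optional per-point weights. Improper rotations (reflections) are
#' rejected by enforcing determinant +1.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3), nm.
#' @param weights optional per-point weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3, so that
#'   `Y %*% t(rotation) + translation` approximates X), `rmsd` (nm) and
#'   `Yfit` (the transformed Y).
#' @export
kabschSuperpose <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point counts differ")
  if (nrow(X) < 3) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- t(Yc * w) %*% Xc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Yfit <- Yc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((Yfit - Xc)^2)))
  Yfit <- sweep(Yfit, 2, cx, "+")
  list(rotation = R, translation = cx - as.vector(R %*% cy), rmsd = rmsd,
       Yfit = Yfit)
}

#' RMSD between two frames after optimal superposition
#'
#' @param frameA,frameB [Frame-class] objects sharing atom count.
#' @param sel optional [GroupSelection-class] restricting the fit.
#' @param weights optional per-atom weights on the selection.
#' @return RMSD in nm.
#' @export
frameRmsd <- function(frameA, frameB, sel = NULL, weights = NULL) {
  ia <- if (is.null(sel)) seq_len(nrow(frameA@positions)) else sel@indices
  kabschSuperpose(frameA@positions[ia, , drop = FALSE],
                  frameB@positions[ia, , drop = FALSE], weights)$rmsd
}

.selCOM <- function(frame, topology, sel) {
  idx <- sel@indices
  if (!length(idx)) stop("empty selection '", sel@label, "'")
  .centerOfMass(frame@positions[idx, , drop = FALSE],
                topology@atoms$mass[idx])
}

#' Centre-of-mass separation of two cores
#'
#' The reaction coordinate r of the dimerization analysis: the Euclidean
#' distance between the mass-weighted centres of the two guanine-core
#' selections, with minimum-image treatment when a box is present.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class].
#' @param coreA,coreB [GroupSelection-class] objects (non-empty, positive
#'   total mass).
#' @return separation in nm.
#' @export
comDistance <- function(frame, topology, coreA, coreB) {
  ca <- .selCOM(frame, topology, coreA)
  cb <- .selCOM(frame, topology, coreB)
  d <- .displacement(matrix(ca, 1), matrix(cb, 1), frame@box)
  sqrt(sum(d^2))
}

## best-fit plane normal of a point set (total least squares): the singular
## direction of smallest singular value of the centred coordinates
.planeNormal <- function(pos) {
  c0 <- colMeans(pos)
  sv <- svd(sweep(pos, 2, c0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("collinear atoms: tetrad plane undefined")
  list(normal = sv$v[, 3], center = c0)
}

#' Orientation angle between two tetrad planes
#'
#' Fits each tetrad's plane by total least squares, orients each normal
#' outward from its own unit's core centre, and returns the angle between
#' the two normals. Facing tetrads of coaxially stacked units give about
#' 180 degrees under this convention.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class].
#' @param tetradA,tetradB tetrad selections (>= 3 non-collinear atoms each).
#' @param coreA,coreB core selections used to fix the outward sign of each
#'   normal; when omitted the raw normals are used with the angle folded
#'   into `[0, 90]`.
#' @return angle in degrees, in `[0, 180]`.
#' @export
orientationAngle <- function(frame, topology, tetradA, tetradB,
                             coreA = NULL, coreB = NULL) {
  pa <- .planeNormal(frame@positions[tetradA@indices, , drop = FALSE])
  pb <- .planeNormal(frame@positions[tetradB@indices, , drop = FALSE])
  na <- pa$normal; nb <- pb$normal
  if (!is.null(coreA)) {
    out <- pa$center - .selCOM(frame, topology, coreA)
    if (sum(na * out) < 0) na <- -na
  }
  if (!is.null(coreB)) {
    out <- pb$center - .selCOM(frame, topology, coreB)
    if (sum(nb * out) < 0) nb <- -nb
  }
  ang <- .degrees(acos(pmin(1, pmax(-1, sum(na * nb)))))
  if (is.null(coreA) || is.null(coreB)) ang <- min(ang, 180 - ang)
  ang
}

#' Interface shift between the axes of two stacked units
#'
#' Each unit's axis is the vector joining the centres of mass of its two
#' external tetrads. The interface plane is normal to the mean axis and
#' passes through the midpoint between the facing tetrad centres; the shift
#' is the in-plane distance between the two axis-plane intersections. A
#' coaxial dimer has shift 0.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class].
#' @param unitATetrads,unitBTetrads lists of two [GroupSelection-class]
#'   objects: the external tetrads of each unit.
#' @return shift in nm.
#' @export
shiftCoordinate <- function(frame, topology, unitATetrads, unitBTetrads) {
  comsA <- lapply(unitATetrads, function(s) .selCOM(frame, topology, s))
  comsB <- lapply(unitBTetrads, function(s) .selCOM(frame, topology, s))
  axisA <- comsA[[2]] - comsA[[1]]
  axisB <- comsB[[2]] - comsB[[1]]
  if (sqrt(sum(axisA^2)) < 1e-9 || sqrt(sum(axisB^2)) < 1e-9)
    stop("degenerate (zero-length) unit axis")
  if (sum(axisA * axisB) < 0) axisB <- -axisB
  n <- .normalize(.normalize(axisA) + .normalize(axisB))
  ## facing tetrads: the closest COM pair across units
  dd <- outer(seq_along(comsA), seq_along(comsB), Vectorize(function(i, j)
    sqrt(sum((comsA[[i]] - comsB[[j]])^2))))
  ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
  mid <- (comsA[[ij[1]]] + comsB[[ij[2]]]) / 2
  intersect1 <- function(p0, a) {
    denom <- sum(n * a)
    if (abs(denom) < 1e-12) stop("unit axis parallel to interface plane")
    p0 + a * sum(n * (mid - p0)) / denom
  }
  qa <- intersect1(comsA[[1]], axisA)
  qb <- intersect1(comsB[[1]], axisB)
  d <- qa - qb
  d <- d - sum(d * n) * n  # numerical safety: keep strictly in-plane
  sqrt(sum(d^2))
}

## azimuthal 4-fold phase of a ring about an axis, degrees in [0, 90)
.ringPhase <- function(pos, origin, basis) {
  rel <- sweep(pos, 2, origin)
  x <- rel %*% basis$u
  y <- rel %*% basis$v
  phi <- atan2(y, x)
  ## circular mean in 4*phi space folds out the 4-fold symmetry
  ph <- atan2(mean(sin(4 * phi)), mean(cos(4 * phi))) / 4
  (.degrees(ph)) %% 90
}

#' Backbone twist offset between two 4-fold symmetric rings
#'
#' Computes the azimuthal phase of each phosphate ring about their common
#' axis via the circular mean of bead azimuths (in 4-fold symmetry space)
#' and returns the phase difference reduced modulo the 90-degree symmetry
#' period. Alternating backbones half a period apart give ~45 degrees.
#'
#' @param frame a [Frame-class].
#' @param ringA,ringB ring selections (4-fold symmetric bead placement).
#' @return twist offset in degrees, in `[0, 90)`.
#' @export
twistOffset <- function(frame, ringA, ringB) {
  pa <- frame@positions[ringA@indices, , drop = FALSE]
  pb <- frame@positions[ringB@indices, , drop = FALSE]
  ca <- colMeans(pa); cb <- colMeans(pb)
  axis <- cb - ca
  if (sqrt(sum(axis^2)) < 1e-9) {
    ## concentric rings: fall back to the normal of ring A's best plane
    axis <- .planeNormal(pa)$normal
  }
  basis <- .orthonormalBasis(axis)
  phA <- .ringPhase(pa, ca, basis)
  phB <- .ringPhase(pb, cb, basis)
  (phB - phA) %% 90
}

#' Stacking contact area between two selections
#'
#' Projects the atoms of both selections as van der Waals disks onto the
#' interface plane (normal to the line joining the two selections' centres
#' of mass, through its midpoint), rasterizes each union footprint on a
#' regular grid, and returns the overlap area of the two footprints.
#'
#' @param frame a [Frame-class].
#' @param topology the matching [Topology-class] (supplies elements/radii).
#' @param selA,selB non-empty selections.
#' @param gridSpacing raster spacing, nm (default 0.01).
#' @param normal optional plane normal overriding the COM-line default.
#' @return list with `area` (overlap, nm^2), `footprintA`, `footprintB`
#'   (individual footprint areas, nm^2).
#' @export
contactArea <- function(frame, topology, selA, selB, gridSpacing = 0.01,
                        normal = NULL) {
  if (!length(selA@indices) || !length(selB@indices))
    stop("empty selection")
  a <- topology@atoms
  radius <- if (!is.null(a$radius)) a$radius else .elementRadius(a$element)
  pA <- frame@positions[selA@indices, , drop = FALSE]
  pB <- frame@positions[selB@indices, , drop = FALSE]
  rA <- radius[selA@indices]; rB <- radius[selB@indices]
  cA <- colMeans(pA); cB <- colMeans(pB)
  if (is.null(normal)) {
    normal <- cB - cA
    if (sqrt(sum(normal^2)) < 1e-9)
      stop("interface plane undefined: coincident selection centres")
  }
  basis <- .orthonormalBasis(normal)
  proj <- function(p) cbind(p %*% basis$u, p %*% basis$v)
  qA <- proj(pA); qB <- proj(pB)
  lo <- pmin(apply(qA, 2, min) - max(rA), apply(qB, 2, min) - max(rB))
  hi <- pmax(apply(qA, 2, max) + max(rA), apply(qB, 2, max) + max(rB))
  ## offset the raster by an irrational fraction of a cell so atom centres
  ## never align with grid lines (alignment biases the midpoint rule)
  off <- gridSpacing * (sqrt(5) - 1) / 2
  gx <- seq(lo[1] + off, hi[1], by = gridSpacing)
  gy <- seq(lo[2] + off, hi[2], by = gridSpacing)
  inUnion <- function(q, r) {
    mask <- matrix(FALSE, length(gx), length(gy))
    for (k in seq_len(nrow(q))) {
      ix <- which(abs(gx - q[k, 1]) <= r[k])
      iy <- which(abs(gy - q[k, 2]) <= r[k])
      if (!length(ix) || !length(iy)) next
      dd <- outer((gx[ix] - q[k, 1])^2, (gy[iy] - q[k, 2])^2, "+")
      mask[ix, iy] <- mask[ix, iy] | (dd <= r[k]^2)
    }
    mask
  }
  mA <- inUnion(qA, rA); mB <- inUnion(qB, rB)
  cell <- gridSpacing^2
  list(area = sum(mA & mB) * cell, footprintA = sum(mA) * cell,
       footprintB = sum(mB) * cell)
}

#' Cylindrical projection of atom positions
#'
#' Maps selected atoms of every frame to (azimuth, height) about a given
#' axis and accumulates a 2-D occupancy histogram, emulating the projection
#' of backbone atoms onto the curved surface of a cylinder enclosing the
#' dimer.
#'
#' @param traj a [Trajectory-class].
#' @param sel atom selection.
#' @param axisOrigin point on the axis, nm.
#' @param axisDir axis direction.
#' @param nAzimuth number of azimuthal bins (default 72, i.e. 5 degrees).
#' @param heightBreaks bin breaks for the height coordinate, nm; derived
#'   from the data when NULL.
#' @return list with `azimuth` (bin centres, degrees), `height` (bin
#'   centres, nm) and `occupancy` (matrix, weighted counts).
#' @export
cylindricalProjection <- function(traj, sel, axisOrigin, axisDir,
                                  nAzimuth = 72, heightBreaks = NULL) {
  basis <- .orthonormalBasis(axisDir)
  w <- frameWeights(traj)
  az <- numeric(0); hh <- numeric(0); ww <- numeric(0)
  for (i in seq_along(traj@frames)) {
    p <- sweep(traj@frames[[i]]@positions[sel@indices, , drop = FALSE],
               2, axisOrigin)
    if (!nrow(p)) next
    az <- c(az, (.degrees(atan2(p %*% basis$v, p %*% basis$u))) %% 360)
    hh <- c(hh, as.vector(p %*% basis$n))
    ww <- c(ww, rep(w[i], nrow(p)))
  }
  if (is.null(heightBreaks)) {
    rng <- range(hh)
    heightBreaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 21)
  }
  azBreaks <- seq(0, 360, length.out = nAzimuth + 1)
  ia <- findInterval(az, azBreaks, rightmost.closed = TRUE)
  ih <- findInterval(hh, heightBreaks, rightmost.closed = TRUE)
  keep <- ih >= 1 & ih <= length(heightBreaks) - 1
  occ <- matrix(0, nAzimuth, length(heightBreaks) - 1)
  for (k in which(keep)) occ[ia[k], ih[k]] <- occ[ia[k], ih[k]] + ww[k]
  list(azimuth = (azBreaks[-1] + azBreaks[-length(azBreaks)]) / 2,
       height = (heightBreaks[-1] + heightBreaks[-length(heightBreaks)]) / 2,
       occupancy = occ)
}

#' Per-frame geometric observables of a dimer trajectory
#'
#' Convenience wrapper computing, for every frame: the core separation r,
#' the orientation angle between the facing tetrads, the interface shift
#' and the backbone twist offset.
#'
#' @param traj a [Trajectory-class] of a two-unit dimer.
#' @param coreA,coreB guanine-core selections.
#' @param tetradA,tetradB facing-tetrad selections.
#' @param externalA,externalB lists of the two external tetrads per unit.
#' @param ringA,ringB phosphate-ring selections.
#' @return data.frame with one row per frame: `r`, `angle`, `shift`,
#'   `twist`.
#' @export
geometryRecord <- function(traj, coreA, coreB, tetradA, tetradB,
                           externalA, externalB, ringA, ringB) {
  topo <- traj@topology
  out <- lapply(traj@frames, function(f) {
    c(r = comDistance(f, topo, coreA, coreB),
      angle = orientationAngle(f, topo, tetradA, tetradB, coreA, coreB),
      shift = shiftCoordinate(f, topo, externalA, externalB),
      twist = twistOffset(f, ringA, ringB))
  })
  as.data.frame(do.call(rbind, out))
}
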