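#' Number of atoms
#' @param x a Topology, Frame or Trajectory.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#' @param x a Trajectory.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom table accessor
#' @param x a Topology or Trajectory.
#' @return data.frame of atom records.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Coordinate accessor
#' @param x a Frame, or a Trajectory (with frame index `i`).
#' @param ... frame index for trajectories.
#' @return N x 3 coordinate matrix, nm.
#' @export
setGeneric("positions", function(x, ...) standardGeneric("positions"))

#' Per-frame weight accessor
#' @param x a Trajectory.
#' @return numeric weights summing to 1 (uniform when unset).
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))

#' Replace per-frame weights
#' @param x a Trajectory.
#' @param value new weights (normalized to sum 1).
#' @return the modified Trajectory.
#' @export
setGeneric("frameWeights<-", function(x, value) standardGeneric("frameWeights<-"))

#' Selection indices accessor
#' @param x a GroupSelection.
#' @return integer 1-based atom indices.
#' @export
setGeneric("indices", function(x) standardGeneric("indices"))

#' Profile / grid value table accessor
#' @param x a FreeEnergyProfile, EnergyDensityProfile or InteractionMatrix.
#' @param ... unused.
#' @return a data.frame (profiles) or matrix (interaction matrices).
#' @export
setGeneric("values", function(x, ...) standardGeneric("values"))

## methods -------------------------------------------------------------------

#' @describeIn nAtoms atom count of a topology.
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @describeIn nAtoms atom count of a frame.
#' @export
setMethod("nAtoms", "Frame", function(x) nrow(x@positions))

#' @describeIn nAtoms atom count of a trajectory's topology.
#' @export
setMethod("nAtoms", "Trajectory", function(x) nAtoms(x@topology))

#' @describeIn nFrames frame count.
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' @describeIn atoms atom table of a topology.
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @describeIn atoms atom table of a trajectory's topology.
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @describeIn positions coordinates of a frame.
#' @export
setMethod("positions", "Frame", function(x, ...) x@positions)

#' @describeIn positions coordinates of trajectory frame `i` (default 1).
#' @param i frame index.
#' @export
setMethod("positions", "Trajectory", function(x, i = 1, ...)
  x@frames[[i]]@positions)

#' @describeIn frameWeights weights of a trajectory (uniform when unset).
#' @export
setMethod("frameWeights", "Trajectory", function(x) {
  if (length(x@weights)) x@weights
  else rep(1 / length(x@frames), length(x@frames))
})

#' @describeIn frameWeights-set replace trajectory weights.
#' @export
setMethod("frameWeights<-", "Trajectory", function(x, value) {
  x@weights <- as.numeric(value) / sum(value)
  validObject(x)
  x
})

#' @describeIn indices indices of a selection.
#' @export
setMethod("indices", "GroupSelection", function(x) x@indices)

#' @describeIn values profile table (bins, G, se).
#' @export
setMethod("values", "FreeEnergyProfile", function(x, ...)
  data.frame(r = x@bins, G = x@G, se = x@se))

#' @describeIn values density table (bins, density, cumulative).
#' @export
setMethod("values", "EnergyDensityProfile", function(x, ...)
  data.frame(r = x@bins, density = x@density, cumulative = x@cumulative))

#' @describeIn values total (elec + vdW) matrix; use `component` to pick
#'   `"total"`, `"elec"` or `"vdw"`.
#' @param component which component matrix to return.
#' @export
setMethod("values", "InteractionMatrix", function(x, component = "total", ...) {
  m <- switch(component, total = x@elec + x@vdw, elec = x@elec, vdw = x@vdw,
              stop("component must be total, elec or vdw"))
  dimnames(m) <- list(x@labels, x@labels)
  m
})

## show methods --------------------------------------------------------------

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, units: %s\n",
              nrow(a), length(unique(paste(a$unit, a$resid))),
              paste(sort(unique(a$unit)), collapse = ",")))
  cat(sprintf("  parameters attached: %s\n",
              if (any(a$charge != 0) || any(a$epsilon != 0)) "yes" else "no"))
})

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame: %d atoms, t = %g ps, %s\n", nrow(object@positions),
              object@time,
              if (length(object@box)) sprintf("box %.3g x %.3g x %.3g nm",
                                              object@box[1], object@box[2],
                                              object@box[3])
              else "non-periodic"))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms, weights: %s\n",
              length(object@frames), nAtoms(object@topology),
              if (length(object@weights)) "set" else "uniform"))
})

setMethod("show", "GroupSelection", function(object) {
  cat(sprintf("GroupSelection '%s': %d atoms\n", object@label,
              length(object@indices)))
})

setMethod("show", "ColvarSeries", function(object) {
  cat(sprintf("ColvarSeries: %d samples, r in [%.3f, %.3f] nm\n",
              length(object@values), min(object@values), max(object@values)))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow: center %.3f nm, k = %.1f kcal/(mol nm^2), %d samples, T = %g K\n",
              object@center, object@k, length(object@samples@values),
              object@temperature))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  ok <- is.finite(object@G)
  cat(sprintf("FreeEnergyProfile: %d bins (%.3f-%.3f nm), min G = %.2f kcal/mol, anchor: %s\n",
              length(object@bins), min(object@bins), max(object@bins),
              if (any(ok)) min(object@G[ok]) else NA, object@anchor))
})

setMethod("show", "StateDefinition", function(object) {
  cat(sprintf("State '%s': r in [%.2f, %.2f) nm, R = %.2f nm\n",
              object@label, object@rLo, object@rHi, object@R))
})

setMethod("show", "StandardStateResult", function(object) {
  cat(sprintf("Standard-state dG(dim) [%s]: %.2f +/- %s kcal/mol (T = %g K, V0 = %.0f A^3)",
              object@label, object@dG,
              if (is.na(object@error)) "NA" else sprintf("%.2f", object@error),
              object@temperature, object@V0))
  if (!is.na(object@population))
    cat(sprintf(", population %.1f%%", 100 * object@population))
  cat("\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf("InteractionMatrix: %d groups (%s), bound '%s' vs unbound '%s'\n",
              length(object@labels), paste(object@labels, collapse = ","),
              object@boundLabel, object@unboundLabel))
  cat(sprintf("  total dH = %.3g kcal/mol\n", interactionTotal(object)))
})

setMethod("show", "EnergyDensityProfile", function(object) {
  cat(sprintf("EnergyDensityProfile: %d bins, total cross-strand energy %.3g kcal/mol per frame\n",
              length(object@bins), object@cumulative[length(object@cumulative)]))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d x %d x %d voxels, spacing %.3f nm, integral %.4g atoms\n",
              d[1], d[2], d[3], object@spacing, gridIntegral(object)))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d clusters (cutoff %.2f nm), populations: %s\n",
              length(object@medoids), object@cutoff,
              paste(sprintf("%.1f%%", 100 * object@populations), collapse = ", ")))
})

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf("LandscapeSpec: %d Gaussian wells at {%s} nm, wall at %.2f nm, domain [%.2f, %.2f] nm\n",
              length(object@centers),
              paste(format(object@centers), collapse = ", "),
              object@rWall, object@domain[1], object@domain[2]))
})

setMethod("show", "ToyDimerSpec", function(object) {
  cat(sprintf("ToyDimerSpec: mode %s, separation %.2f nm, twist %g deg, %d counterions\n",
              object@mode, object@separation, object@twist, object@nIons))
})
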