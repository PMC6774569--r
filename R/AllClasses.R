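#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core structural containers
## ---------------------------------------------------------------------------

#' Topology: per-atom metadata for a structure
#'
#' Holds the ordered atom records all analyses operate on: names, elements,
#' residue bookkeeping, the unit each atom belongs to (monomer 1, monomer 2,
#' or solvent/ions coded as 0), partial charges (e), Lennard-Jones parameters
#' (sigma nm, epsilon kcal/mol), and masses (amu). Charges and LJ parameters
#' are zero until a sidecar parameter table is attached with
#' [attachParameters()].
#'
#' @slot atoms data.frame with columns `name`, `element`, `resname`, `resid`,
#'   `unit`, `charge`, `sigma`, `epsilon`, `mass`, and optionally `radius`
#'   (vdW radius nm for coarse beads).
#' @seealso [Topology()], [attachParameters()], [selectAtoms()]
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("name", "element", "resname", "resid", "unit",
            "charge", "sigma", "epsilon", "mass")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) < 1) return("topology must contain at least one atom")
  if (!all(is.finite(a$charge))) return("non-finite charge")
  if (!all(is.finite(a$mass))) return("non-finite mass")
  if (!all(a$unit %in% c(0L, 1L, 2L)))
    return("unit must be 1, 2 (monomers) or 0 (solvent/ions)")
  for (u in unique(a$unit)) {
    r <- a$resid[a$unit == u]
    if (is.unsorted(r)) return(sprintf("resid not non-decreasing in unit %d", u))
  }
  TRUE
})

#' Construct a Topology
#'
#' @param atoms data.frame of atom records; missing `charge`, `sigma`,
#'   `epsilon` columns are filled with 0, missing `mass` is derived from the
#'   element (unknown elements get mass 0 with a warning).
#' @return A [Topology-class] object.
#' @export
#' @examples
#' topo <- Topology(data.frame(name = "P", element = "P", resname = "PHO",
#'                             resid = 1, unit = 1))
#' nAtoms(topo)
Topology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("charge", "sigma", "epsilon"))
    if (is.null(atoms[[col]])) atoms[[col]] <- 0
  if (is.null(atoms[["mass"]])) {
    atoms$mass <- .elementMass(atoms$element)
    if (any(atoms$mass == 0))
      warning("unknown element(s) assigned mass 0 (excluded from COM): ",
              paste(unique(atoms$element[atoms$mass == 0]), collapse = ", "))
  }
  atoms$resid <- as.integer(atoms$resid)
  atoms$unit <- as.integer(atoms$unit)
  new("Topology", atoms = atoms)
}

#' Frame: one set of coordinates
#'
#' @slot positions N x 3 matrix of coordinates in nm.
#' @slot box orthorhombic box edge lengths (nm), or `numeric(0)` for a
#'   non-periodic system.
#' @slot time time stamp in ps.
#' @export
setClass("Frame", representation(positions = "matrix", box = "numeric",
                                 time = "numeric"))

setValidity("Frame", function(object) {
  p <- object@positions
  if (ncol(p) != 3) return("positions must have 3 columns")
  if (!all(is.finite(p))) return("non-finite positions")
  if (length(object@box) != 0) {
    if (length(object@box) != 3) return("box must have 3 edge lengths")
    if (!all(object@box > 0)) return("box edges must be strictly positive")
  }
  TRUE
})

#' Construct a Frame
#' @param positions N x 3 matrix, nm.
#' @param box optional 3 orthorhombic edge lengths, nm.
#' @param time time stamp, ps.
#' @return A [Frame-class] object.
#' @export
Frame <- function(positions, box = numeric(0), time = 0) {
  new("Frame", positions = as.matrix(positions), box = as.numeric(box),
      time = as.numeric(time))
}

#' Trajectory: an ordered series of frames over one topology
#'
#' Optional per-frame weights carry unbiased ensemble weights (for example
#' from [whamWeights()]) into every downstream weighted statistic.
#'
#' @slot topology the shared [Topology-class].
#' @slot frames list of [Frame-class] objects with a common atom count.
#' @slot weights per-frame weights summing to 1, or `numeric(0)` when unset
#'   (interpreted as uniform).
#' @export
setClass("Trajectory", representation(topology = "Topology", frames = "list",
                                      weights = "numeric"))

setValidity("Trajectory", function(object) {
  n <- nAtoms(object@topology)
  if (length(object@frames) < 1) return("trajectory needs at least one frame")
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is(f, "Frame")) return(sprintf("frame %d is not a Frame", i))
    if (nrow(f@positions) != n)
      return(sprintf("frame %d has %d atoms, topology has %d",
                     i, nrow(f@positions), n))
  }
  if (length(object@weights)) {
    if (length(object@weights) != length(object@frames))
      return("weights length must equal frame count")
    if (any(object@weights < 0)) return("negative frame weight")
    if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  }
  TRUE
})

#' Construct a Trajectory
#' @param topology a [Topology-class].
#' @param frames list of [Frame-class] objects.
#' @param weights optional per-frame weights (normalized to sum 1).
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(topology, frames, weights = numeric(0)) {
  if (length(weights)) weights <- weights / sum(weights)
  new("Trajectory", topology = topology, frames = frames,
      weights = as.numeric(weights))
}

#' GroupSelection: a labelled set of atom indices
#'
#' Realizes the named structural elements of the enthalpy decomposition
#' (guanines, adenines, thymines, backbones, ions, water, per monomer).
#'
#' @slot label selection label.
#' @slot indices sorted unique 1-based atom indices.
#' @export
setClass("GroupSelection", representation(label = "character",
                                          indices = "integer"))

setValidity("GroupSelection", function(object) {
  if (length(object@label) != 1) return("label must be a single string")
  if (any(object@indices < 1)) return("indices must be >= 1")
  if (anyDuplicated(object@indices)) return("duplicate indices")
  TRUE
})

#' Construct a GroupSelection
#' @param label selection label.
#' @param indices 1-based atom indices (sorted and uniqued).
#' @return A [GroupSelection-class] object.
#' @export
GroupSelection <- function(label, indices) {
  new("GroupSelection", label = as.character(label),
      indices = sort(unique(as.integer(indices))))
}

#' ColvarSeries: a reaction-coordinate time series
#'
#' Samples of the collective coordinate r, the centre-of-mass separation of
#' the two guanine cores, as produced by biased sampling.
#'
#' @slot times times in ps.
#' @slot values coordinate values in nm, finite and positive.
#' @export
setClass("ColvarSeries", representation(times = "numeric", values = "numeric"))

setValidity("ColvarSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (!all(is.finite(object@values)) || any(object@values <= 0))
    return("values must be finite and > 0")
  TRUE
})

#' Construct a ColvarSeries
#' @param times times, ps.
#' @param values reaction-coordinate samples, nm.
#' @return A [ColvarSeries-class] object.
#' @export
ColvarSeries <- function(times, values) {
  new("ColvarSeries", times = as.numeric(times), values = as.numeric(values))
}

## ---------------------------------------------------------------------------
## Free-energy containers
## ---------------------------------------------------------------------------

#' UmbrellaWindow: biased samples from one harmonic window
#'
#' @slot center restraint centre r_c, nm.
#' @slot k harmonic force constant, kcal/(mol nm^2).
#' @slot samples a [ColvarSeries-class].
#' @slot temperature K.
#' @export
setClass("UmbrellaWindow", representation(center = "numeric", k = "numeric",
                                          samples = "ColvarSeries",
                                          temperature = "numeric"))

setValidity("UmbrellaWindow", function(object) {
  if (object@k < 0) return("force constant must be >= 0")
  if (length(object@samples@values) < 2) return("need at least 2 samples")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

#' Construct an UmbrellaWindow
#' @param center restraint centre, nm.
#' @param k force constant, kcal/(mol nm^2).
#' @param samples a [ColvarSeries-class] (or numeric vector of values).
#' @param temperature K.
#' @return An [UmbrellaWindow-class] object.
#' @export
UmbrellaWindow <- function(center, k, samples, temperature = 300) {
  if (is.numeric(samples))
    samples <- ColvarSeries(seq_along(samples) - 1, samples)
  new("UmbrellaWindow", center = as.numeric(center), k = as.numeric(k),
      samples = samples, temperature = as.numeric(temperature))
}

#' FreeEnergyProfile: G(r) with standard errors
#'
#' @slot bins bin centres, nm, strictly increasing with uniform width.
#' @slot G free energy, kcal/mol (NA where unsampled).
#' @slot se standard errors, kcal/mol (NA where unknown).
#' @slot anchor text tag describing the zero convention, e.g.
#'   `"plateau:3-3.4"` for profiles anchored to a zero-mean unbound plateau.
#' @export
setClass("FreeEnergyProfile", representation(bins = "numeric", G = "numeric",
                                             se = "numeric",
                                             anchor = "character"))

setValidity("FreeEnergyProfile", function(object) {
  b <- object@bins
  if (length(b) < 2) return("need at least 2 bins")
  d <- diff(b)
  if (any(d <= 0)) return("bins must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * d[1]) return("bins must be uniform width")
  if (length(object@G) != length(b)) return("G length must match bins")
  if (length(object@se) != length(b)) return("se length must match bins")
  TRUE
})

#' Construct a FreeEnergyProfile
#' @param bins bin centres, nm.
#' @param G free energies, kcal/mol.
#' @param se standard errors (default NA).
#' @param anchor anchoring-convention tag.
#' @return A [FreeEnergyProfile-class] object.
#' @export
FreeEnergyProfile <- function(bins, G, se = rep(NA_real_, length(bins)),
                              anchor = "unanchored") {
  new("FreeEnergyProfile", bins = as.numeric(bins), G = as.numeric(G),
      se = as.numeric(se), anchor = as.character(anchor))
}

#' StateDefinition: an r-range defining a (meta)stable state
#'
#' @slot label state label (e.g. "I" for the deepest, G-mediated basin).
#' @slot rLo,rHi basin range `[rLo, rHi)`, nm.
#' @slot R upper integration limit of the bound-state volume integral, nm.
#' @export
setClass("StateDefinition", representation(label = "character",
                                           rLo = "numeric", rHi = "numeric",
                                           R = "numeric"))

setValidity("StateDefinition", function(object) {
  if (!(object@rLo > 0 && object@rLo < object@rHi))
    return("need 0 < rLo < rHi")
  if (object@R > object@rHi + 1e-12) return("R must be <= rHi")
  TRUE
})

#' Construct a StateDefinition
#' @param label state label.
#' @param rLo,rHi basin range, nm.
#' @param R integration upper limit, nm (default `rHi`).
#' @return A [StateDefinition-class] object.
#' @export
StateDefinition <- function(label, rLo, rHi, R = rHi) {
  new("StateDefinition", label = as.character(label), rLo = as.numeric(rLo),
      rHi = as.numeric(rHi), R = as.numeric(R))
}

#' StandardStateResult: a standard-state dimerization free energy
#'
#' @slot dG standard-state dimerization free energy, kcal/mol.
#' @slot error bootstrap error, kcal/mol (NA when not estimated).
#' @slot V0 standard volume, A^3.
#' @slot temperature K.
#' @slot population equilibrium population fraction in `[0,1]` (NA until
#'   assigned by [statePopulations()]).
#' @slot label state label.
#' @export
setClass("StandardStateResult",
         representation(dG = "numeric", error = "numeric", V0 = "numeric",
                        temperature = "numeric", population = "numeric",
                        label = "character"))

setValidity("StandardStateResult", function(object) {
  p <- object@population
  if (!is.na(p) && (p < 0 || p > 1)) return("population must be in [0,1]")
  if (object@V0 <= 0) return("V0 must be positive")
  TRUE
})

#' Construct a StandardStateResult
#' @param dG free energy, kcal/mol.
#' @param error bootstrap error, kcal/mol.
#' @param V0 standard volume, A^3.
#' @param temperature K.
#' @param population population fraction.
#' @param label state label.
#' @return A [StandardStateResult-class] object.
#' @export
StandardStateResult <- function(dG, error = NA_real_, V0 = standardVolume(),
                                temperature = 300, population = NA_real_,
                                label = "") {
  new("StandardStateResult", dG = as.numeric(dG), error = as.numeric(error),
      V0 = as.numeric(V0), temperature = as.numeric(temperature),
      population = as.numeric(population), label = as.character(label))
}

#' FrameWeights: unbiased per-sample weights from WHAM
#'
#' @slot weights per-sample weights, non-negative, summing to 1.
#' @slot window source window index per sample.
#' @export
setClass("FrameWeights", representation(weights = "numeric",
                                        window = "integer"))

setValidity("FrameWeights", function(object) {
  if (length(object@weights) != length(object@window))
    return("weights and window must have equal length")
  if (any(object@weights < 0)) return("negative weight")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Energetics containers
## ---------------------------------------------------------------------------

#' InteractionMatrix: group-pair interaction-enthalpy decomposition
#'
#' Entry (A,B) holds the change in ensemble-averaged nonbonded interaction
#' energy between groups A and B on going from the unbound to the bound
#' ensemble; diagonal entries hold intra-group changes. Electrostatic and
#' van der Waals components are stored separately.
#'
#' @slot labels group labels.
#' @slot elec,vdw symmetric matrices of components, kcal/mol.
#' @slot boundLabel,unboundLabel ensemble tags.
#' @export
setClass("InteractionMatrix",
         representation(labels = "character", elec = "matrix", vdw = "matrix",
                        boundLabel = "character", unboundLabel = "character"))

setValidity("InteractionMatrix", function(object) {
  n <- length(object@labels)
  for (m in list(object@elec, object@vdw)) {
    if (!all(dim(m) == c(n, n))) return("matrix dims must match labels")
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9 * (max(abs(m), na.rm = TRUE) + 1))
      return("matrices must be symmetric")
  }
  TRUE
})

#' EnergyDensityProfile: electrostatic energy vs P-P distance
#'
#' @slot bins P-P distance bin centres, nm.
#' @slot density electrostatic energy per frame per nm, kcal/mol/nm.
#' @slot cumulative running integral of the density, kcal/mol per frame.
#' @slot binWidth nm.
#' @export
setClass("EnergyDensityProfile",
         representation(bins = "numeric", density = "numeric",
                        cumulative = "numeric", binWidth = "numeric"))

setValidity("EnergyDensityProfile", function(object) {
  n <- length(object@bins)
  if (length(object@density) != n || length(object@cumulative) != n)
    return("density and cumulative must match bins")
  expect <- cumsum(object@density * object@binWidth)
  if (max(abs(expect - object@cumulative)) >
      1e-6 * (max(abs(expect)) + 1e-12))
    return("cumulative must be the running integral of the density")
  TRUE
})

## ---------------------------------------------------------------------------
## Ensemble-analysis containers
## ---------------------------------------------------------------------------

#' DensityGrid: 3-D number density on a regular grid
#'
#' Density is normalized so that its integral (sum times voxel volume)
#' equals the mean number of selected atoms per frame.
#'
#' @slot origin grid origin (corner of first voxel), nm.
#' @slot spacing voxel edge, nm.
#' @slot values 3-D array of number densities, nm^-3.
#' @slot nFrames number of frames accumulated.
#' @slot alignLabel label of the alignment selection.
#' @export
setClass("DensityGrid",
         representation(origin = "numeric", spacing = "numeric",
                        values = "array", nFrames = "numeric",
                        alignLabel = "character"))

setValidity("DensityGrid", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(dim(object@values)) != 3) return("values must be a 3-D array")
  if (length(object@origin) != 3) return("origin must have 3 components")
  TRUE
})

#' Construct a DensityGrid
#' @param origin corner of the grid, nm.
#' @param spacing voxel edge, nm.
#' @param values 3-D density array, nm^-3.
#' @param nFrames frames accumulated.
#' @param alignLabel alignment selection label.
#' @return A [DensityGrid-class] object.
#' @export
DensityGrid <- function(origin, spacing, values, nFrames = 1,
                        alignLabel = "") {
  new("DensityGrid", origin = as.numeric(origin), spacing = as.numeric(spacing),
      values = values, nFrames = as.numeric(nFrames),
      alignLabel = as.character(alignLabel))
}

#' ClusterModel: weighted conformational clusters
#'
#' Result of the hybrid k-centers/k-medoids clustering under an RMSD metric
#' after optimal superposition. The k-centers stage guarantees every frame
#' lies within `cutoff` of its centre; the model records both the stage-1
#' assignment and the refined one.
#'
#' @slot medoids frame indices of the cluster medoids.
#' @slot labels refined per-frame cluster labels.
#' @slot labelsInitial stage-1 (k-centers) labels.
#' @slot populations weighted cluster populations, summing to 1.
#' @slot cutoff RMSD cutoff, nm.
#' @slot fitLabel label of the fit selection.
#' @slot maxRadius named vector: max frame-to-centre RMSD after stage 1 and
#'   after refinement, nm.
#' @export
setClass("ClusterModel",
         representation(medoids = "integer", labels = "integer",
                        labelsInitial = "integer", populations = "numeric",
                        cutoff = "numeric", fitLabel = "character",
                        maxRadius = "numeric"))

setValidity("ClusterModel", function(object) {
  if (abs(sum(object@populations) - 1) > 1e-8)
    return("populations must sum to 1")
  if (length(object@populations) != length(object@medoids))
    return("one population per medoid")
  if (any(object@labels < 1 | object@labels > length(object@medoids)))
    return("labels out of range")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-data specs
## ---------------------------------------------------------------------------

#' LandscapeSpec: an analytic planted free-energy landscape U(r)
#'
#' Sum of Gaussian wells on a harmonic repulsive wall, flat at large r:
#' U(r) = kWall (rWall - r)^2 for r < rWall, minus
#' sum_i depth_i exp(-(r - center_i)^2 / (2 width_i^2)).
#'
#' @slot centers well centres, nm.
#' @slot depths well depths, kcal/mol (positive = attractive well).
#' @slot widths Gaussian widths, nm.
#' @slot rWall onset of the repulsive wall, nm.
#' @slot kWall wall stiffness, kcal/(mol nm^2).
#' @slot domain sampling domain `c(rMin, rMax)`, nm.
#' @export
setClass("LandscapeSpec",
         representation(centers = "numeric", depths = "numeric",
                        widths = "numeric", rWall = "numeric",
                        kWall = "numeric", domain = "numeric"))

setValidity("LandscapeSpec", function(object) {
  if (length(object@centers) != length(object@depths) ||
      length(object@centers) != length(object@widths))
    return("centers, depths, widths must have equal length")
  if (any(object@widths <= 0)) return("widths must be > 0")
  if (length(object@domain) != 2 || object@domain[1] <= 0 ||
      object@domain[2] <= object@domain[1])
    return("domain must be positive and increasing")
  TRUE
})

#' Construct a LandscapeSpec
#'
#' @param centers,depths,widths Gaussian well parameters (nm, kcal/mol, nm).
#' @param rWall,kWall repulsive wall onset (nm) and stiffness
#'   (kcal/(mol nm^2)).
#' @param domain sampling domain, nm.
#' @return A [LandscapeSpec-class] object.
#' @seealso [defaultLandscape()], [landscapeEnergy()]
#' @export
LandscapeSpec <- function(centers, depths, widths, rWall = 1.0, kWall = 500,
                          domain = c(0.9, 3.6)) {
  new("LandscapeSpec", centers = as.numeric(centers),
      depths = as.numeric(depths), widths = as.numeric(widths),
      rWall = as.numeric(rWall), kWall = as.numeric(kWall),
      domain = as.numeric(domain))
}

#' ToyDimerSpec: geometric parameters for a toy quadruplex dimer
#'
#' Each toy unit is a rigid stack of three 4-bead tetrad planes, wrapped by a
#' 12-bead phosphate ring with 4-fold symmetry, plus three terminal adenine
#' beads; mode chooses which ends face across the interface.
#'
#' @slot mode stacking mode, one of "3-3", "3-5", "5-5".
#' @slot separation core centre-of-mass separation, nm.
#' @slot twist backbone twist offset of unit 2 about the stacking axis,
#'   degrees.
#' @slot phosphateCharge charge per phosphate bead, e (default -1).
#' @slot nIons number of monovalent (+1 e) counterions.
#' @slot ringRadius phosphate-ring radius, nm.
#' @slot tetradRadius tetrad bead ring radius, nm.
#' @slot rise inter-tetrad rise, nm.
#' @slot helicalStep per-level azimuthal advance of the phosphate ring,
#'   degrees (default 0 so the ring has a single well-defined 4-fold phase).
#' @export
setClass("ToyDimerSpec",
         representation(mode = "character", separation = "numeric",
                        twist = "numeric", phosphateCharge = "numeric",
                        nIons = "integer", ringRadius = "numeric",
                        tetradRadius = "numeric", rise = "numeric",
                        helicalStep = "numeric"))

setValidity("ToyDimerSpec", function(object) {
  if (!object@mode %in% c("3-3", "3-5", "5-5"))
    return("mode must be one of 3-3, 3-5, 5-5")
  if (object@separation <= 0) return("separation must be > 0")
  if (object@nIons < 0) return("nIons must be >= 0")
  TRUE
})

#' Construct a ToyDimerSpec
#' @param mode stacking mode ("3-3", "3-5", "5-5").
#' @param separation core COM separation, nm.
#' @param twist backbone twist offset, degrees.
#' @param phosphateCharge charge per phosphate bead, e.
#' @param nIons counterion count.
#' @param ringRadius phosphate ring radius, nm.
#' @param tetradRadius tetrad ring radius, nm.
#' @param rise inter-tetrad rise, nm.
#' @param helicalStep per-level phosphate azimuth advance, degrees.
#' @return A [ToyDimerSpec-class] object.
#' @export
ToyDimerSpec <- function(mode = "5-5", separation = 1.1, twist = 45,
                         phosphateCharge = -1, nIons = 0, ringRadius = 1.0,
                         tetradRadius = 0.55, rise = 0.35, helicalStep = 0) {
  new("ToyDimerSpec", mode = mode, separation = as.numeric(separation),
      twist = as.numeric(twist), phosphateCharge = as.numeric(phosphateCharge),
      nIons = as.integer(nIons), ringRadius = as.numeric(ringRadius),
      tetradRadius = as.numeric(tetradRadius), rise = as.numeric(rise),
      helicalStep = as.numeric(helicalStep))
}
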