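## Readers and writers for the standard formats the pipeline touches.
## Internal lengths are nm; PDB (A) and OpenDX (A) are converted at the
## boundary by the exact factor 0.1.

.solventResnames <- c("HOH", "WAT", "SOL", "TIP3", "K", "CL", "NA", "POT",
                      "CLA", "MG", "ION")

## map PDB chain letters / solvent residues to unit ids
.unitsFromChains <- function(chain, resname) {
  unit <- rep(1L, length(chain))
  solvent <- toupper(resname) %in% .solventResnames
  chain[is.na(chain)] <- ""
  nonsolv <- unique(chain[!solvent])
  if (length(nonsolv) >= 2) unit[chain == nonsolv[2]] <- 2L
  if (length(nonsolv) > 2)
    unit[chain %in% nonsolv[-(1:2)]] <- 2L  # extra chains folded into unit 2
  unit[solvent] <- 0L
  unit
}

.guessElement <- function(name, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- trimws(elesy)
    if (all(nzchar(e))) return(e)
  }
  e <- gsub("[0-9']", "", trimws(name))
  ifelse(toupper(e) %in% c("K", "CL", "NA", "MG", "BR", "P"), toupper(e),
         substr(e, 1, 1))
}

#' Read a structure file
#'
#' Reads a PDB or GRO file into a topology plus a single coordinate frame.
#' PDB coordinates (A) are converted to nm; GRO is already nm. Monomer units
#' are assigned from PDB chains (first chain = unit 1, second = unit 2);
#' solvent and ion residues become unit 0. Charges and LJ parameters are
#' zero until [attachParameters()] is called.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; guessed from the extension by default.
#' @return list with elements `topology` ([Topology-class]) and `frame`
#'   ([Frame-class]).
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .readPdbStructure(path) else .readGroStructure(path)
}

.readPdbStructure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  element <- .guessElement(a$elety, a$elesy)
  topo <- Topology(data.frame(
    name = a$elety, element = element, resname = a$resid,
    resid = a$resno, unit = .unitsFromChains(a$chain, a$resid),
    stringsAsFactors = FALSE))
  pos <- cbind(a$x, a$y, a$z) * 0.1
  list(topology = topo, frame = Frame(pos))
}

.readGroStructure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO parse error: bad atom count on line 2")
  if (length(lines) < 2 + n) stop("GRO file truncated: expected ", n, " atoms")
  rec <- lines[3:(2 + n)]
  num <- function(s, i) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("GRO parse error on line ", 2 + which(is.na(v))[1])
    v
  }
  resid <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- num(substr(rec, 21, 28))
  y <- num(substr(rec, 29, 36))
  z <- num(substr(rec, 37, 44))
  boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                                  "\\s+")[[1]]))
  box <- if (length(boxline) >= 3 && all(is.finite(boxline[1:3])) &&
             all(boxline[1:3] > 0)) boxline[1:3] else numeric(0)
  unit <- ifelse(toupper(resname) %in% .solventResnames, 0L, 1L)
  topo <- Topology(data.frame(name = name, element = .guessElement(name),
                              resname = resname, resid = resid, unit = unit,
                              stringsAsFactors = FALSE))
  list(topology = topo, frame = Frame(cbind(x, y, z), box = box))
}

#' Write a structure (or trajectory) as PDB
#'
#' Writes one frame, or all frames of a trajectory as a multi-model PDB.
#' Units are encoded as chains (1 = A, 2 = B, solvent = S) so a round trip
#' preserves them; coordinates are written in A.
#'
#' @param x a [Trajectory-class], or a [Topology-class] (then supply `frame`).
#' @param path output file.
#' @param frame a [Frame-class] when `x` is a topology.
#' @return the path, invisibly.
#' @export
writeStructure <- function(x, path, frame = NULL) {
  if (is(x, "Trajectory")) {
    topo <- x@topology
    xyz <- do.call(rbind, lapply(x@frames, function(f) as.vector(t(f@positions)) * 10))
  } else {
    topo <- x
    if (is.null(frame)) stop("supply a frame when writing a Topology")
    xyz <- matrix(as.vector(t(frame@positions)) * 10, nrow = 1)
  }
  a <- topo@atoms
  chain <- c("S", "A", "B")[a$unit + 1L]
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resid, resid = a$resname,
                   elety = a$name, chain = chain,
                   elesy = substr(a$element, 1, 2))
  invisible(path)
}

#' Read a trajectory file
#'
#' Multi-model PDB or XYZ. XYZ coordinates are interpreted as A (the
#' conventional unit of that format) and converted to nm; frames without
#' time stamps get sequential times 0, 1, 2, ... ps.
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model) or `"xyz"`; guessed by default.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .readPdbTrajectory(path) else .readXyzTrajectory(path)
}

.readPdbTrajectory <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  topo <- Topology(data.frame(
    name = a$elety, element = .guessElement(a$elety, a$elesy),
    resname = a$resid, resid = a$resno,
    unit = .unitsFromChains(a$chain, a$resid), stringsAsFactors = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    Frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE) * 0.1, time = i - 1))
  Trajectory(topo, frames)
}

.readXyzTrajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); elements <- NULL; i <- 1; fidx <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error: bad atom count at line ", i)
    fidx <- fidx + 1
    comment <- if (i + 1 <= length(lines)) lines[i + 1] else ""
    tm <- regmatches(comment, regexec("t\\s*=\\s*([-0-9.eE+]+)", comment))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else fidx - 1
    if (i + 1 + n > length(lines))
      stop("XYZ truncated in frame ", fidx)
    rec <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    if (any(lengths(rec) < 4)) stop("XYZ parse error in frame ", fidx)
    el <- vapply(rec, `[`, "", 1)
    pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3))) * 0.1
    if (any(is.na(pos))) stop("XYZ parse error: non-numeric coordinate in frame ", fidx)
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("inconsistent atom count at frame ", fidx)
    frames[[fidx]] <- Frame(pos, time = time)
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames in ", path)
  topo <- Topology(data.frame(name = elements, element = elements,
                              resname = "XYZ", resid = 1L, unit = 1L,
                              stringsAsFactors = FALSE))
  Trajectory(topo, frames)
}

#' Write a trajectory as XYZ
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrajectoryXyz <- function(traj, path) {
  el <- traj@topology@atoms$element
  con <- file(path, "w"); on.exit(close(con))
  for (f in traj@frames) {
    writeLines(as.character(length(el)), con)
    writeLines(sprintf("t= %g", f@time), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", el,
                       f@positions[, 1] * 10, f@positions[, 2] * 10,
                       f@positions[, 3] * 10), con)
  }
  invisible(path)
}

#' Read a reaction-coordinate time series (COLVAR-style)
#'
#' Whitespace-delimited columns; lines starting with `#` are headers and are
#' skipped. The first column is time (ps) and `valueColumn` the coordinate
#' (nm).
#'
#' @param path file path.
#' @param valueColumn 1-based column index of the coordinate (default 2).
#' @return a [ColvarSeries-class].
#' @export
readTimeseries <- function(path, valueColumn = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) stop("no data lines in ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  parse1 <- function(j) {
    tk <- toks[[j]]
    if (length(tk) < valueColumn)
      stop("too few columns on line ", keep[j], " of ", path)
    v <- suppressWarnings(as.numeric(tk[c(1, valueColumn)]))
    if (any(is.na(v)))
      stop("non-numeric value on line ", keep[j], " of ", path)
    v
  }
  m <- t(vapply(seq_along(toks), parse1, numeric(2)))
  ColvarSeries(m[, 1], m[, 2])
}

#' Write a reaction-coordinate time series
#'
#' @param series a [ColvarSeries-class].
#' @param path output file.
#' @param header optional comment written as a `#` line.
#' @return the path, invisibly.
#' @export
writeTimeseries <- function(series, path, header = "time_ps r_nm") {
  con <- file(path, "w"); on.exit(close(con))
  if (nzchar(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("%.6f %.10g", series@times, series@values), con)
  invisible(path)
}

#' Write a density grid as an OpenDX scalar field
#'
#' Origin and spacing are written in A per the OpenDX convention used by
#' molecular-visualization tools; densities are written as stored (nm^-3).
#'
#' @param grid a [DensityGrid-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGrid <- function(grid, path) {
  d <- dim(grid@values)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by g4stack",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1] * 10, grid@origin[2] * 10,
            grid@origin[3] * 10),
    sprintf("delta %.6f 0 0", grid@spacing * 10),
    sprintf("delta 0 %.6f 0", grid@spacing * 10),
    sprintf("delta 0 0 %.6f", grid@spacing * 10),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## DX data order: x slowest, z fastest
  idx <- expand.grid(z = seq_len(d[3]), y = seq_len(d[2]), x = seq_len(d[1]))
  flat <- grid@values[cbind(idx$x, idx$y, idx$z)]
  n3 <- (length(flat) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(flat[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(flat) > n3)
    writeLines(paste(sprintf("%.8g", flat[(n3 + 1):length(flat)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field'), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' @param path file path.
#' @return a [DensityGrid-class] (origin/spacing converted back to nm).
#' @export
readGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  cl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(strsplit(trimws(sub(".*counts", "", cl)), "\\s+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("origin", "",
                                        grep("^origin", lines, value = TRUE)[1])),
                             "\\s+")[[1]]) * 0.1
  deltas <- grep("^delta", lines, value = TRUE)
  sp <- as.numeric(strsplit(trimws(sub("delta", "", deltas[1])), "\\s+")[[1]])
  spacing <- max(sp) * 0.1
  start <- grep("data follows", lines)[1] + 1
  end <- start - 1 + ceiling(prod(d) / 3)
  dataLines <- lines[start:length(lines)]
  dataLines <- dataLines[!grepl("attribute|object", dataLines)]
  vals <- as.numeric(unlist(strsplit(trimws(dataLines), "\\s+")))
  vals <- vals[seq_len(prod(d))]
  arr <- array(0, dim = d)
  idx <- expand.grid(z = seq_len(d[3]), y = seq_len(d[2]), x = seq_len(d[1]))
  arr[cbind(idx$x, idx$y, idx$z)] <- vals
  DensityGrid(org, spacing, arr)
}

#' Read a sidecar nonbonded parameter table
#'
#' Whitespace-delimited table with header columns `resname`, `atomname`,
#' `charge_e`, `sigma_nm`, `epsilon_kcal`, `mass_amu` and optionally
#' `radius_nm`; `#` lines are comments.
#'
#' @param path file path.
#' @return a data.frame of parameters.
#' @export
readParameterTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("resname", "atomname", "charge_e", "sigma_nm", "epsilon_kcal",
            "mass_amu")
  if (!all(need %in% names(tab)))
    stop("parameter table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}

#' Attach nonbonded parameters to a topology
#'
#' Assigns partial charges, LJ parameters, masses (and optionally vdW radii)
#' keyed by (residue name, atom name) from a sidecar table. Atoms with no
#' matching row keep their current values and trigger a warning.
#'
#' @param topology a [Topology-class].
#' @param params a data.frame from [readParameterTable()] or a file path.
#' @return the updated [Topology-class].
#' @export
attachParameters <- function(topology, params) {
  if (is.character(params)) params <- readParameterTable(params)
  a <- topology@atoms
  key <- paste(a$resname, a$name, sep = "/")
  pkey <- paste(params$resname, params$atomname, sep = "/")
  hit <- match(key, pkey)
  miss <- is.na(hit)
  if (any(miss))
    warning(sum(miss), " atom(s) without parameters, e.g. ",
            paste(utils::head(unique(key[miss]), 3), collapse = ", "))
  ok <- !miss
  a$charge[ok] <- params$charge_e[hit[ok]]
  a$sigma[ok] <- params$sigma_nm[hit[ok]]
  a$epsilon[ok] <- params$epsilon_kcal[hit[ok]]
  a$mass[ok] <- params$mass_amu[hit[ok]]
  if (!is.null(params$radius_nm)) {
    if (is.null(a$radius)) a$radius <- .elementRadius(a$element)
    a$radius[ok] <- params$radius_nm[hit[ok]]
  }
  new("Topology", atoms = a)
}
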