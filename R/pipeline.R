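## Config-driven orchestration: synthetic generation -> WHAM -> states /
## standard-state free energies / populations -> enthalpy decomposition ->
## geometry -> ion statistics -> clustering, with a machine-readable report.

.defaultConfig <- function() {
  list(
    temperature = 300,
    V0 = 1661,
    forceConstant = 286.1,
    windowCenters = list(from = 1.1, to = 3.5, by = 0.1),
    nPerWindow = 2000,
    binWidth = 0.02,
    plateau = c(3.0, 3.4),
    equilibration = 0.1,
    cutoffs = list(ionContact = 0.7, clusterRmsd = 0.3),
    bootstrap = list(replicates = 0),
    seed = 1,
    landscape = list(centers = c(1.1, 1.5), depths = c(20, 14),
                     widths = c(0.12, 0.18), rWall = 1.0, kWall = 500,
                     domain = c(0.9, 3.6)),
    dimer = list(mode = "5-5", separation = 1.1, twist = 45, nIons = 6,
                 nFrames = 5, unboundSeparation = 3.2),
    dgValues = NULL,
    stages = c("synth", "wham", "states", "dg", "populations", "decompose",
               "geometry", "ions", "cluster")
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key(s): ",
         paste(paste0(path, extra), collapse = ", "))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                      paste0(path, key, "."))
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Validate and complete a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), rejects unknown keys, fills
#' defaults (T = 300 K, V0 = 1661 A^3, k = 286.1 kcal/(mol nm^2), ion
#' contact cutoff 0.7 nm, cluster RMSD cutoff 0.3 nm, plateau 3.0-3.4 nm)
#' and type-checks the physical parameters.
#'
#' @param x path to a YAML file, a list, or NULL for pure defaults.
#' @return a validated config list of class `g4Config`.
#' @export
validateConfig <- function(x = NULL) {
  user <- if (is.null(x)) list()
          else if (is.character(x)) {
            if (!file.exists(x)) stop("config file not found: ", x)
            y <- yaml::read_yaml(x)
            if (is.null(y)) list() else y
          } else if (is.list(x)) x
          else stop("config must be a path, a list, or NULL")
  cfg <- .mergeConfig(.defaultConfig(), user)
  checkPos <- function(v, key) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("config key '", key, "' must be positive and finite")
  }
  checkPos(cfg$temperature, "temperature")
  checkPos(cfg$V0, "V0")
  if (cfg$forceConstant < 0) stop("forceConstant must be >= 0")
  checkPos(cfg$binWidth, "binWidth")
  checkPos(cfg$cutoffs$ionContact, "cutoffs.ionContact")
  checkPos(cfg$cutoffs$clusterRmsd, "cutoffs.clusterRmsd")
  if (length(cfg$plateau) != 2 || cfg$plateau[2] <= cfg$plateau[1])
    stop("plateau must be an increasing range")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("g4Config", "list")
  cfg
}

## small deterministic polynomial hash for config provenance
.configHash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.windowCentersOf <- function(cfg)
  seq(cfg$windowCenters$from, cfg$windowCenters$to, by = cfg$windowCenters$by)

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on synthetic inputs
#' with known ground truth: umbrella-window generation and WHAM unbiasing,
#' state detection, standard-state free energies and populations, enthalpy
#' decomposition on a toy dimer, geometric order parameters, ion statistics
#' and conformational clustering. All randomness derives from the config
#' seed; a failed stage stops execution and the partial report (with the
#' error recorded) is returned.
#'
#' @param config a `g4Config` from [validateConfig()] (or anything it
#'   accepts).
#' @return a report list: one entry per executed stage plus a `provenance`
#'   block (config echo, config hash, seeds, package version, timestamps,
#'   stage log).
#' @export
runPipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "g4Config")) config else validateConfig(config)
  report <- list(provenance = list(
    package = "g4stack",
    version = as.character(utils::packageVersion("g4stack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    configHash = .configHash(cfg),
    config = unclass(cfg),
    stageLog = list()))
  state <- new.env(parent = emptyenv())
  logStage <- function(name, status, dt) {
    report$provenance$stageLog[[name]] <<- list(status = status,
                                                wallTime = dt)
  }
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' requires upstream artifact '", what,
           "' (enable its producing stage)")
    state[[what]]
  }

  stageFuns <- list(
    synth = function() {
      spec <- do.call(LandscapeSpec, cfg$landscape)
      state$landscape <- spec
      state$windows <- sampleWindows(
        spec, centers = .windowCentersOf(cfg), k = cfg$forceConstant,
        nPerWindow = cfg$nPerWindow, seed = cfg$seed,
        temperature = cfg$temperature)
      dspec <- ToyDimerSpec(mode = cfg$dimer$mode,
                            separation = cfg$dimer$separation,
                            twist = cfg$dimer$twist, nIons = cfg$dimer$nIons)
      uspec <- ToyDimerSpec(mode = cfg$dimer$mode,
                            separation = cfg$dimer$unboundSeparation,
                            twist = cfg$dimer$twist, nIons = cfg$dimer$nIons)
      state$bound <- buildToyDimer(dspec, nFrames = cfg$dimer$nFrames,
                                   seed = cfg$seed)
      state$unbound <- buildToyDimer(uspec, nFrames = cfg$dimer$nFrames,
                                     seed = cfg$seed + 1L)
      list(windows = length(state$windows),
           samplesPerWindow = cfg$nPerWindow,
           dimerFrames = cfg$dimer$nFrames)
    },
    wham = function() {
      wn <- need("windows", "wham")
      sol <- whamSolve(wn, binWidth = cfg$binWidth, plateau = cfg$plateau)
      state$wham <- sol
      if (cfg$bootstrap$replicates >= 20) {
        bp <- bootstrapProfile(wn, nBoot = cfg$bootstrap$replicates,
                               binWidth = cfg$binWidth,
                               plateau = cfg$plateau, seed = cfg$seed)
        sol$profile <- bp$profile
        state$wham <- sol
      }
      list(profile = values(sol$profile), f = sol$f,
           converged = sol$converged)
    },
    states = function() {
      sol <- need("wham", "states")
      st <- assignStates(sol$profile)
      state$states <- st
      lapply(st, function(s) list(label = s@label, rLo = s@rLo, rHi = s@rHi,
                                  R = s@R))
    },
    dg = function() {
      sol <- need("wham", "dg")
      st <- need("states", "dg")
      res <- lapply(st, function(s)
        standardStateDG(sol$profile, s, temperature = cfg$temperature,
                        V0 = cfg$V0))
      state$dg <- res
      lapply(res, function(r) list(label = r@label, dG = r@dG, V0 = r@V0,
                                   temperature = r@temperature))
    },
    populations = function() {
      dgv <- if (!is.null(cfg$dgValues)) unlist(cfg$dgValues)
             else stats::setNames(
               vapply(need("dg", "populations"), function(r) r@dG, 0),
               vapply(need("dg", "populations"), function(r) r@label, ""))
      p <- statePopulations(dgv, temperature = cfg$temperature)
      state$populations <- p
      as.list(p)
    },
    decompose = function() {
      bnd <- need("bound", "decompose")
      unb <- need("unbound", "decompose")
      sb <- toyDimerSelections(bnd)
      groups <- list(sb$core1, sb$core2, sb$ade1, sb$ade2, sb$ring1,
                     sb$ring2)
      if (length(sb$ions@indices)) groups <- c(groups, list(sb$ions))
      m <- enthalpyMatrix(bnd, unb, groups)
      state$enthalpy <- m
      list(labels = m@labels, total = values(m, "total"),
           elec = values(m, "elec"), vdw = values(m, "vdw"),
           overall = as.list(groupContributions(m)))
    },
    geometry = function() {
      bnd <- need("bound", "geometry")
      sb <- toyDimerSelections(bnd)
      rec <- geometryRecord(bnd, sb$core1, sb$core2, sb$facing1, sb$facing2,
                            sb$external1, sb$external2, sb$ring1, sb$ring2)
      state$geometry <- rec
      lapply(rec, function(col) list(mean = mean(col), sd = stats::sd(col)))
    },
    ions = function() {
      bnd <- need("bound", "ions")
      sb <- toyDimerSelections(bnd)
      if (!length(sb$ions@indices)) return(list(note = "no ions in system"))
      counts <- ionContactCounts(bnd, sb$ions, sb$ring1, sb$ring2,
                                 sb$ring1, sb$ring2,
                                 cutoff = cfg$cutoffs$ionContact)
      grid <- densityGrid(bnd, sb$ions, spacing = 0.05,
                          alignSel = sb$core1)
      nIons <- length(sb$ions@indices)
      vol <- prod(apply(positions(bnd, 1), 2, function(v) diff(range(v)) + 1))
      bulk <- nIons / vol
      sites <- siteOccupancy(grid, bulkDensity = bulk)
      state$ionGrid <- grid
      list(contacts = as.list(counts), gridIntegral = gridIntegral(grid),
           nSites = nrow(sites),
           topOccupancy = if (nrow(sites)) sites$occupancy[1] else 0)
    },
    cluster = function() {
      bnd <- need("bound", "cluster")
      unb <- need("unbound", "cluster")
      planted <- plantClusters(
        list(bnd@frames[[1]], unb@frames[[1]]),
        counts = c(10, 10), spread = 0.05, seed = cfg$seed,
        topology = bnd@topology)
      fit <- selectAtoms(bnd@topology, "resname GUA", "cores")
      model <- clusterEnsemble(planted$trajectory, fit,
                               cutoff = cfg$cutoffs$clusterRmsd)
      state$clusters <- model
      list(nClusters = length(model@medoids),
           populations = as.numeric(model@populations),
           maxRadius = as.list(model@maxRadius),
           recoveryARI = adjustedRand(model@labels, planted$labels))
    })

  for (stage in cfg$stages) {
    if (is.null(stageFuns[[stage]])) stop("unknown stage: ", stage)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stageFuns[[stage]](), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      logStage(stage, "failed", dt)
      report$error <- list(stage = stage, message = conditionMessage(res))
      warning("stage '", stage, "' failed: ", conditionMessage(res),
              "; returning partial report")
      return(report)
    }
    logStage(stage, "ok", dt)
    report[[stage]] <- res
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a [runPipeline()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Validate a report against the packaged JSON schema
#'
#' Structural validation (a pragmatic subset of JSON Schema: `type`,
#' `required`, `properties`) against `inst/schema/report-schema.json`.
#'
#' @param report a report list or path to a report JSON file.
#' @param schemaPath schema file (default: the packaged schema).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validateReport <- function(report,
                           schemaPath = system.file("schema",
                                                    "report-schema.json",
                                                    package = "g4stack")) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(schemaPath)
  checkNode <- function(node, sch, path) {
    ty <- sch$type
    okType <- switch(ty,
      object = is.list(node) && (is.null(names(node)) == (length(node) == 0) ||
                                   !is.null(names(node))),
      array = is.list(node) || (is.vector(node) && length(node) != 1),
      number = is.numeric(node) && length(node) == 1,
      string = is.character(node) && length(node) == 1,
      integer = is.numeric(node) && length(node) == 1,
      TRUE)
    if (!okType) stop("schema violation at ", path, ": expected ", ty)
    if (ty == "object") {
      for (req in unlist(sch$required))
        if (is.null(node[[req]]))
          stop("schema violation at ", path, ": missing required '", req, "'")
      for (pn in names(sch$properties))
        if (!is.null(node[[pn]]))
          checkNode(node[[pn]], sch$properties[[pn]], paste0(path, ".", pn))
    }
    invisible(TRUE)
  }
  checkNode(report, schema, "$")
  invisible(TRUE)
}
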