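## Umbrella-sampling unbiasing (WHAM), correlation-aware bootstrap errors,
## standard-state dimerization free energies and equilibrium populations.

## bias energy of window w at coordinates r (kcal/mol)
.biasEnergy <- function(r, center, k) 0.5 * k * (r - center)^2

## shared WHAM fixed-point iteration on a fixed bin grid.
## samples: list of numeric vectors; returns P (bin probabilities), f
## (per-window free energies, f[1] = 0), G, convergence info.
.whamCore <- function(samples, centers, k, temperature, bins, tol = 1e-6,
                      maxIter = 1e5) {
  kBT <- .kB * temperature
  W <- length(samples)
  B <- length(bins)
  half <- (bins[2] - bins[1]) / 2
  breaks <- c(bins - half, bins[B] + half)
  counts <- t(vapply(samples, function(s) {
    h <- graphics::hist(s, breaks = breaks, plot = FALSE)
    h$counts
  }, numeric(B)))
  N <- rowSums(counts)
  Ctot <- colSums(counts)
  ## bias Boltzmann factors at bin centres, W x B
  C <- exp(-outer(seq_len(W), seq_len(B), function(i, b)
    .biasEnergy(bins[b], centers[i], k[i])) / kBT)
  z <- rep(1, W)
  f <- rep(0, W)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- colSums(C * (N / z))
    P <- ifelse(denom > 0, Ctot / denom, 0)
    P <- P / sum(P)
    z <- as.vector(C %*% P)
    fNew <- -kBT * log(z)
    fNew <- fNew - fNew[1]
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
  }
  G <- ifelse(P > 0, -kBT * log(P), NA_real_)
  list(P = P, f = f, G = G, bins = bins, counts = counts,
       converged = converged, iterations = iter,
       residual = if (converged) tol else NA_real_)
}

.binGrid <- function(values, binWidth) {
  lo <- floor(min(values) / binWidth) * binWidth
  hi <- ceiling(max(values) / binWidth) * binWidth
  seq(lo + binWidth / 2, hi - binWidth / 2 + 1e-12, by = binWidth)
}

.anchorProfile <- function(bins, G, plateau) {
  inPlat <- bins >= plateau[1] & bins <= plateau[2] & is.finite(G)
  if (any(inPlat)) {
    list(G = G - mean(G[inPlat]),
         anchor = sprintf("plateau:%g-%g", plateau[1], plateau[2]))
  } else {
    warning("no sampled bins in the plateau range; anchoring min G = 0")
    list(G = G - min(G, na.rm = TRUE), anchor = "min")
  }
}

.checkOverlap <- function(windows, core) {
  counts <- core$counts
  W <- nrow(counts)
  if (W == 1) return(invisible(TRUE))
  sampled <- counts > 0
  adj <- matrix(FALSE, W, W)
  for (i in 1:(W - 1)) for (j in (i + 1):W)
    adj[i, j] <- adj[j, i] <- any(sampled[i, ] & sampled[j, ])
  comp <- rep(0L, W); cid <- 0L
  for (s in seq_len(W)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  if (max(comp) > 1) {
    hi <- max(vapply(which(comp == 1), function(i)
      max(core$bins[sampled[i, ]]), 0))
    lo <- min(vapply(which(comp != 1), function(i)
      min(core$bins[sampled[i, ]]), Inf))
    stop(sprintf(
      "windows form %d non-overlapping groups (sampling gap near %.3f-%.3f nm)",
      max(comp), min(hi, lo), max(hi, lo)))
  }
  ## warn on weakly overlapping adjacent pairs
  ord <- order(vapply(windows, function(w) w@center, 0))
  for (a in seq_len(W - 1)) {
    i <- ord[a]; j <- ord[a + 1]
    shared <- sampled[i, ] & sampled[j, ]
    nShared <- min(sum(counts[i, shared]), sum(counts[j, shared]))
    if (nShared < 10)
      warning(sprintf("windows %d and %d share only %d samples in overlapping bins",
                      i, j, nShared))
  }
  invisible(TRUE)
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Combines the biased histograms of all windows into one unbiased free
#' energy profile G(r) by iterating the standard self-consistent WHAM
#' equations until the per-window free energies change by less than `tol`.
#' The profile is anchored so the mean over the declared unbound plateau
#' range is zero.
#'
#' @param windows list of [UmbrellaWindow-class] objects at one temperature.
#' @param binWidth histogram bin width, nm (default 0.02, about 5 bins per
#'   0.1 nm window spacing).
#' @param tol convergence tolerance on the window free energies, kcal/mol.
#' @param maxIter iteration cap (warning with residual when hit).
#' @param plateau anchoring range `c(lo, hi)` in nm (default 3.0-3.4).
#' @return list with `profile` (a [FreeEnergyProfile-class]), `f`
#'   (per-window free energies, `f[1] = 0`), `converged`, `iterations`.
#' @export
whamSolve <- function(windows, binWidth = 0.02, tol = 1e-6, maxIter = 1e5,
                      plateau = c(3.0, 3.4)) {
  if (!length(windows)) stop("need at least one window")
  Ts <- vapply(windows, function(w) w@temperature, 0)
  if (max(Ts) - min(Ts) > 1e-9) stop("all windows must share a temperature")
  samples <- lapply(windows, function(w) w@samples@values)
  centers <- vapply(windows, function(w) w@center, 0)
  k <- vapply(windows, function(w) w@k, 0)
  bins <- .binGrid(unlist(samples), binWidth)
  core <- .whamCore(samples, centers, k, Ts[1], bins, tol, maxIter)
  .checkOverlap(windows, core)
  if (!core$converged)
    warning(sprintf("WHAM hit maxIter = %d without converging to %g",
                    maxIter, tol))
  anc <- .anchorProfile(bins, core$G, plateau)
  prof <- FreeEnergyProfile(bins, anc$G, anchor = anc$anchor)
  list(profile = prof, f = core$f, converged = core$converged,
       iterations = core$iterations, P = core$P)
}

#' Unbiased per-sample weights from a converged WHAM solution
#'
#' Weight of sample t from window j is proportional to
#' 1 / sum_l N_l exp((f_l - w_l(r_t)) / kBT), normalized over all samples;
#' these weights turn the pooled biased samples into the unbiased ensemble
#' used for cluster populations and weighted averages.
#'
#' @param windows the windows passed to [whamSolve()].
#' @param wham the [whamSolve()] result (must be converged).
#' @return a [FrameWeights-class].
#' @export
whamWeights <- function(windows, wham) {
  if (!isTRUE(wham$converged)) stop("WHAM solution is not converged")
  f <- wham$f
  kBT <- .kB * windows[[1]]@temperature
  centers <- vapply(windows, function(w) w@center, 0)
  k <- vapply(windows, function(w) w@k, 0)
  N <- vapply(windows, function(w) length(w@samples@values), 0)
  wts <- lapply(seq_along(windows), function(j) {
    r <- windows[[j]]@samples@values
    denom <- rowSums(vapply(seq_along(windows), function(l)
      N[l] * exp((f[l] - .biasEnergy(r, centers[l], k[l])) / kBT),
      numeric(length(r))))
    1 / denom
  })
  src <- rep(seq_along(windows), vapply(wts, length, 0L))
  w <- unlist(wts)
  new("FrameWeights", weights = w / sum(w), window = as.integer(src))
}

#' Integrated autocorrelation time (initial positive sequence estimator)
#'
#' @param x numeric series.
#' @param maxLag largest lag examined.
#' @return the integrated autocorrelation time in samples (>= 1).
#' @export
integratedAutocorrelationTime <- function(x, maxLag = min(length(x) - 2, 1000)) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1]
  ## suppress pure estimator noise so an uncorrelated series gives tau = 1
  rho[abs(rho) < 2 / sqrt(n)] <- 0
  tau <- 1
  m <- 1
  while (m + 1 <= length(rho)) {
    pair <- rho[m] + rho[m + 1]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 2
  }
  max(1, tau)
}

#' Bootstrap errors for a WHAM profile (and optional state free energies)
#'
#' Moving-block bootstrap within each window with block length equal to the
#' integrated autocorrelation time (rounded up), so correlated samples are
#' resampled in blocks and the errors account for the correlation in the
#' series. Standard errors are standard deviations across replicates.
#'
#' @param windows list of [UmbrellaWindow-class] objects.
#' @param nBoot bootstrap replicates (>= 20).
#' @param binWidth,tol,maxIter,plateau as in [whamSolve()].
#' @param seed integer seed (recorded in the result).
#' @param states optional list of [StateDefinition-class]; when given, the
#'   bootstrap also returns errors of the standard-state free energies.
#' @param temperature,V0 forwarded to [standardStateDG()] when `states`
#'   are given.
#' @return list with `profile` (the full-data profile with `se` filled),
#'   `f`, `blockLengths`, `seed`, and `dgErrors` (named, when `states`).
#' @export
bootstrapProfile <- function(windows, nBoot = 50, binWidth = 0.02,
                             tol = 1e-6, maxIter = 1e5,
                             plateau = c(3.0, 3.4), seed = 1, states = NULL,
                             temperature = 300, V0 = 1661) {
  if (nBoot < 20) stop("nBoot must be >= 20")
  base <- whamSolve(windows, binWidth, tol, maxIter, plateau)
  bins <- base$profile@bins
  centers <- vapply(windows, function(w) w@center, 0)
  k <- vapply(windows, function(w) w@k, 0)
  Tw <- windows[[1]]@temperature
  samples <- lapply(windows, function(w) w@samples@values)
  L <- vapply(samples, function(s)
    as.integer(ceiling(integratedAutocorrelationTime(s))), 0L)
  N <- vapply(samples, length, 0L)
  if (any(L > N)) stop("window shorter than one bootstrap block")
  set.seed(seed)
  resample1 <- function(s, blk) {
    n <- length(s)
    nb <- ceiling(n / blk)
    starts <- sample.int(n - blk + 1, nb, replace = TRUE)
    idx <- as.vector(outer(0:(blk - 1), starts, "+"))[seq_len(n)]
    s[idx]
  }
  Gmat <- matrix(NA_real_, nBoot, length(bins))
  dgMat <- if (!is.null(states))
    matrix(NA_real_, nBoot, length(states)) else NULL
  for (b in seq_len(nBoot)) {
    res <- lapply(seq_along(samples), function(i)
      resample1(samples[[i]], L[i]))
    core <- .whamCore(res, centers, k, Tw, bins, tol, maxIter)
    anc <- .anchorProfile(bins, core$G, plateau)
    Gmat[b, ] <- anc$G
    if (!is.null(states)) {
      prof <- FreeEnergyProfile(bins, anc$G, anchor = anc$anchor)
      dgMat[b, ] <- vapply(states, function(st)
        standardStateDG(prof, st, temperature = temperature, V0 = V0)@dG, 0)
    }
  }
  se <- apply(Gmat, 2, stats::sd, na.rm = TRUE)
  prof <- base$profile
  prof@se <- se
  out <- list(profile = prof, f = base$f, blockLengths = L, seed = seed)
  if (!is.null(states)) {
    out$dgErrors <- stats::setNames(apply(dgMat, 2, stats::sd, na.rm = TRUE),
                                    vapply(states, function(s) s@label, ""))
  }
  out
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Standard-state dimerization free energy from a profile
#'
#' Evaluates the standard-state expression literally: the angular integrals
#' cancel the radial correction, leaving
#' \deqn{\Delta G^\circ = -k_B T \ln\left[\frac{1}{V_0}\int_0^R
#'   e^{-G(r)/k_BT}\, dr\right]}
#' with r expressed in Angstrom and V0 in cubic Angstrom (trapezoid rule on
#' the profile bins; bins below the first sampled r contribute 0). The
#' integral runs over the state's own range `[rLo, R]`, so that separate
#' basins of one profile yield separate state free energies; for the
#' deepest state this coincides with the integral from 0 because nothing is
#' sampled below its lower boundary. The
#' dimensional tension of the literal form (a length over a volume) is kept
#' as printed; `jacobian = TRUE` switches to the 4 pi r^2-weighted variant
#' for sensitivity analysis.
#'
#' @param profile an anchored [FreeEnergyProfile-class].
#' @param state a [StateDefinition-class]; its `R` is the upper limit, nm.
#' @param temperature K.
#' @param V0 standard volume, A^3 (default 1661).
#' @param jacobian include the 4 pi r^2 volume element (default FALSE,
#'   the literal form).
#' @return a [StandardStateResult-class].
#' @export
standardStateDG <- function(profile, state, temperature = 300, V0 = 1661,
                            jacobian = FALSE) {
  if (identical(profile@anchor, "unanchored"))
    stop("profile must be anchored before computing a standard-state dG")
  bins <- profile@bins
  half <- (bins[2] - bins[1]) / 2
  if (state@R > bins[length(bins)] + half + 1e-9)
    stop(sprintf("R = %.3f nm lies beyond the profile (max %.3f nm)",
                 state@R, bins[length(bins)] + half))
  kBT <- .kB * temperature
  use <- bins <= state@R + 1e-12 & bins > state@rLo - half - 1e-12
  rA <- bins[use] * 10                     # Angstrom
  G <- profile@G[use]
  y <- ifelse(is.finite(G), exp(-G / kBT), 0)
  if (jacobian) y <- 4 * pi * rA^2 * y
  if (sum(y > 0) < 2) stop("state range is not sampled")
  integral <- .trapz(rA, y)
  dG <- -kBT * log(integral / V0)
  StandardStateResult(dG, V0 = V0, temperature = temperature,
                      label = state@label)
}

#' Equilibrium populations from standard-state free energies
#'
#' Boltzmann weights p_i = exp(-dG_i/kBT) / sum_j exp(-dG_j/kBT), computed
#' with max-subtraction for overflow safety. Populations sum to 1 and are
#' invariant under a uniform shift of all free energies.
#'
#' @param x numeric vector of standard-state free energies (kcal/mol), or a
#'   list of [StandardStateResult-class] objects sharing a temperature.
#' @param temperature K (taken from the results when `x` is a list).
#' @return named numeric vector of population fractions.
#' @export
#' @examples
#' # the five printed dimerization free energies at 300 K
#' round(100 * statePopulations(c(`3-3 G` = 6.4, `3-5 G` = -13.5,
#'   `3-5 A` = -11.7, `5-5 G` = -17.5, `5-5 A` = -8.6)), 1)
statePopulations <- function(x, temperature = 300) {
  if (is.list(x) && all(vapply(x, is, TRUE, "StandardStateResult"))) {
    Ts <- vapply(x, function(r) r@temperature, 0)
    if (max(Ts) - min(Ts) > 1e-9) stop("results must share a temperature")
    temperature <- Ts[1]
    labs <- vapply(x, function(r) r@label, "")
    x <- stats::setNames(vapply(x, function(r) r@dG, 0), labs)
  }
  if (!length(x)) stop("empty free-energy list")
  kBT <- .kB * temperature
  e <- -x / kBT
  e <- e - max(e)
  p <- exp(e) / sum(exp(e))
  p
}

#' Detect (meta)stable states from a free-energy profile
#'
#' Smooths the profile with a 3-bin moving average, finds local minima,
#' merges minima separated by barriers smaller than `minBarrier`, and sets
#' basin boundaries (and the integration limit R) at the flanking maxima.
#' The unbound plateau is the trailing region within 0.5 kcal/mol of the
#' profile's end level; minima not deeper than `minBarrier` below that
#' level are discarded. States are labelled I, II, ... in order of
#' increasing r.
#'
#' @param profile a [FreeEnergyProfile-class] with at least 5 bins.
#' @param minBarrier minimum separating barrier, kcal/mol (default 0.5).
#' @return list of [StateDefinition-class] (possibly empty).
#' @export
assignStates <- function(profile, minBarrier = 0.5) {
  bins <- profile@bins
  if (length(bins) < 5) stop("profile needs at least 5 bins")
  ok <- which(is.finite(profile@G))
  if (length(ok) < 5) return(list())
  ## longest contiguous sampled run
  runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  r <- bins[run]
  Gs <- .movingAverage3(profile@G[run])
  n <- length(Gs)
  plateauLevel <- Gs[n]
  inPlateau <- rep(FALSE, n)
  i <- n
  while (i >= 1 && abs(Gs[i] - plateauLevel) <= 0.5) {
    inPlateau[i] <- TRUE; i <- i - 1
  }
  ## interior local minima only: a monotone profile has no bound state
  isMin <- c(FALSE, diff(sign(diff(Gs))) > 0, FALSE)
  minima <- which(isMin & !inPlateau)
  minima <- minima[Gs[minima] < plateauLevel - minBarrier]
  if (!length(minima)) return(list())
  ## merge minima separated by sub-threshold barriers (keep the deeper)
  minima <- minima[order(r[minima])]
  merged <- TRUE
  while (merged && length(minima) > 1) {
    merged <- FALSE
    for (a in seq_len(length(minima) - 1)) {
      m1 <- minima[a]; m2 <- minima[a + 1]
      barrier <- max(Gs[m1:m2]) - max(Gs[m1], Gs[m2])
      if (barrier < minBarrier) {
        drop <- if (Gs[m1] <= Gs[m2]) a + 1 else a
        minima <- minima[-drop]
        merged <- TRUE
        break
      }
    }
  }
  ## basin boundaries at flanking maxima (or the run/plateau edges)
  plateauStart <- if (any(inPlateau)) min(which(inPlateau)) else n
  isMax <- c(FALSE, diff(sign(diff(Gs))) < 0, FALSE)
  maxPos <- which(isMax)
  states <- vector("list", length(minima))
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  halfBin <- (bins[2] - bins[1]) / 2
  for (s in seq_along(minima)) {
    m <- minima[s]
    left <- maxPos[maxPos < m]
    right <- maxPos[maxPos > m & maxPos <= plateauStart]
    lo <- if (length(left)) max(left) else 1
    hi <- if (length(right)) min(right) else plateauStart
    states[[s]] <- StateDefinition(
      label = roman[min(s, length(roman))],
      rLo = r[lo] - halfBin, rHi = r[hi] + halfBin, R = r[hi] + halfBin)
  }
  states
}

#' Free-energy profiles on cumulative time slices
#'
#' Recomputes the profile on cumulative fractions (1/n, 2/n, ..., 1) of
#' each window's samples after discarding an initial equilibration
#' fraction, to monitor convergence with sampling time.
#'
#' @param windows list of [UmbrellaWindow-class] objects.
#' @param chunkCount number of cumulative slices (>= 2).
#' @param equilibration initial fraction discarded (default 0.1).
#' @param binWidth,tol,maxIter,plateau as in [whamSolve()].
#' @return list of [FreeEnergyProfile-class], one per cumulative slice,
#'   all on the full-data bin grid.
#' @export
convergenceSeries <- function(windows, chunkCount, equilibration = 0.1,
                              binWidth = 0.02, tol = 1e-6, maxIter = 1e5,
                              plateau = c(3.0, 3.4)) {
  if (chunkCount < 2) stop("chunkCount must be >= 2")
  samples <- lapply(windows, function(w) {
    v <- w@samples@values
    v[(floor(length(v) * equilibration) + 1):length(v)]
  })
  nMin <- min(lengths(samples))
  if (nMin < chunkCount * 10)
    stop("too few samples per chunk (need >= 10 per window per chunk)")
  centers <- vapply(windows, function(w) w@center, 0)
  k <- vapply(windows, function(w) w@k, 0)
  Tw <- windows[[1]]@temperature
  bins <- .binGrid(unlist(samples), binWidth)
  lapply(seq_len(chunkCount), function(ch) {
    sub <- lapply(samples, function(s)
      s[seq_len(floor(length(s) * ch / chunkCount))])
    core <- .whamCore(sub, centers, k, Tw, bins, tol, maxIter)
    anc <- .anchorProfile(bins, core$G, plateau)
    FreeEnergyProfile(bins, anc$G, anchor = anc$anchor)
  })
}
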