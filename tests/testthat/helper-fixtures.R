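## Shared fixtures, built in code.

kB <- 0.0019872041
kBT300 <- kB * 300

## a flat landscape (no wells, no wall inside the domain)
flatLandscape <- function(domain = c(1.0, 3.0))
  LandscapeSpec(centers = numeric(0), depths = numeric(0),
                widths = numeric(0), rWall = 0.5, kWall = 0, domain = domain)

## a tiny charged topology: n point beads with given charges (no LJ)
chargeTopology <- function(charges, sigma = 0, epsilon = 0,
                           element = "K", resname = "ION") {
  n <- length(charges)
  Topology(data.frame(name = paste0("Q", seq_len(n)), element = element,
                      resname = resname, resid = seq_len(n), unit = 0L,
                      charge = charges, sigma = sigma, epsilon = epsilon,
                      mass = 10, stringsAsFactors = FALSE))
}

## a random parameterized topology for energy oracles
randomTopology <- function(n, seed) {
  set.seed(seed)
  Topology(data.frame(name = paste0("A", seq_len(n)), element = "C",
                      resname = "RND", resid = seq_len(n), unit = 1L,
                      charge = runif(n, -1, 1), sigma = runif(n, 0.2, 0.4),
                      epsilon = runif(n, 0.05, 0.3), mass = 12,
                      stringsAsFactors = FALSE))
}

randomFrame <- function(n, seed, scale = 2) {
  set.seed(seed)
  Frame(matrix(runif(n * 3, 0, scale), n, 3))
}

## independent brute-force nonbonded energy (plain double loop, Angstrom
## Coulomb constant) used as the oracle for the vectorized kernel
bruteForceEnergy <- function(pos, charge, sigma, epsilon, ia, ib) {
  elec <- 0; vdw <- 0
  for (i in ia) {
    for (j in ib) {
      rA <- sqrt(sum((pos[i, ] - pos[j, ])^2)) * 10  # Angstrom
      elec <- elec + 332.0636 * charge[i] * charge[j] / rA
      eps <- sqrt(epsilon[i] * epsilon[j])
      if (eps > 0) {
        sig <- (sigma[i] + sigma[j]) / 2 * 10
        vdw <- vdw + 4 * eps * ((sig / rA)^12 - (sig / rA)^6)
      }
    }
  }
  c(elec = elec, vdw = vdw)
}

## total nonbonded energy over all pairs within an index set (single pass)
bruteForceTotal <- function(pos, charge, sigma, epsilon, idx) {
  tot <- c(elec = 0, vdw = 0)
  for (a in seq_along(idx)) {
    for (b in seq_len(a - 1)) {
      tot <- tot + bruteForceEnergy(pos, charge, sigma, epsilon,
                                    idx[a], idx[b])
    }
  }
  tot
}

## k shape-distinct medoid conformations (independent random clouds, so
## their pairwise superposed RMSD is well above typical cluster cutoffs)
shapeMedoids <- function(n, k, seed, scale = 2) {
  set.seed(seed)
  lapply(seq_len(k), function(i) Frame(matrix(runif(n * 3, 0, scale), n, 3)))
}

## quadrature standard-state dG from an analytic landscape (fine grid),
## anchored to a zero-mean plateau like the WHAM profiles
landscapeTrueDG <- function(landscape, rLo, R, plateau = c(3.0, 3.4),
                            temperature = 300, V0 = 1661, dr = 0.001) {
  fine <- seq(max(landscape@domain[1], 0.9) + dr / 2, R, by = dr)
  plat <- landscapeEnergy(landscape, seq(plateau[1], plateau[2], by = dr))
  G <- landscapeEnergy(landscape, fine) - mean(plat)
  prof <- FreeEnergyProfile(fine, G, anchor = "plateau:analytic")
  standardStateDG(prof, StateDefinition("true", rLo, R, R),
                  temperature = temperature, V0 = V0)@dG
}
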