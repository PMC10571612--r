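#' @include AllClasses.R AllGenerics.R
NULL

#' Construct the reduced-unit simulation parameter set
#'
#' Defaults follow the coarse-grained chromatin model conventions: bead
#' diameter sigma is the length unit (30 nm, ~5 kbp per bead), thermal energy
#' kBT the energy unit, bond constant ks = 100 kBT/sigma^2 (rigid bonds),
#' attractive LJ cutoff 2.5 sigma and WCA cutoff 2^(1/6) sigma, confinement
#' radius 45 sigma, and a bending stiffness of 2 kBT giving a persistence
#' length of 2 beads (60 nm).
#'
#' @param sigma bead diameter (length unit; 1 in reduced units)
#' @param kBT thermal energy (energy unit; 1 in reduced units)
#' @param ks harmonic bond constant (kBT/sigma^2)
#' @param rcAttr attractive LJ cutoff (sigma)
#' @param rcRep repulsive-only cutoff; must be 2^(1/6) sigma
#' @param Rc confinement radius (sigma)
#' @param dt integration timestep (reduced time, <= 0.01)
#' @param gamma Langevin friction coefficient (reduced)
#' @param mass bead mass (reduced)
#' @param kBend angle stiffness (kBT); persistence length = kBend beads
#' @param nSteps default step count for runs driven by this parameter set
#' @param seed RNG seed
#' @return a \linkS4class{SimulationParameters} object
#' @examples
#' p <- SimulationParameters(Rc = 22.5)
#' @export
SimulationParameters <- function(sigma = 1, kBT = 1, ks = 100, rcAttr = 2.5,
                                 rcRep = 2^(1 / 6), Rc = 45, dt = 0.005,
                                 gamma = 1, mass = 1, kBend = 2,
                                 nSteps = 500000L, seed = 1L) {
  new("SimulationParameters",
    sigma = sigma, kBT = kBT, ks = ks, rcAttr = rcAttr, rcRep = rcRep,
    Rc = Rc, dt = dt, gamma = gamma, mass = mass, kBend = kBend,
    nSteps = as.integer(nSteps), seed = as.integer(seed)
  )
}

#' Construct a symmetric species-pair interaction map
#'
#' Pairs are given as named epsilon values like \code{"F-F" = 2}; every pair
#' not listed defaults to excluded-volume (WCA, epsilon = 1 kBT). Order within
#' a pair name does not matter; symmetry is enforced on construction.
#'
#' @param epsilon named numeric vector of attraction strengths in kBT, names
#'   of the form "A-B" with A, B in H, rD, F, X
#' @param excludedVolume character vector of pair names forced to
#'   excluded-volume mode (any epsilon given for them is ignored)
#' @return an \linkS4class{InteractionMatrix}
#' @examples
#' im <- InteractionMatrix(c("F-F" = 2, "H-H" = 0.35))
#' epsilonOf(im, "F", "F")
#' @export
InteractionMatrix <- function(epsilon = numeric(), excludedVolume = character()) {
  eps <- matrix(0, 4, 4, dimnames = list(SPECIES, SPECIES))
  mode <- matrix("excluded_volume", 4, 4)
  parsePair <- function(nm) {
    parts <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% SPECIES)) {
      stop("bad pair name '", nm, "'; expected e.g. 'F-F' or 'rD-F'")
    }
    parts
  }
  for (nm in names(epsilon)) {
    p <- parsePair(nm)
    eps[p[1], p[2]] <- eps[p[2], p[1]] <- epsilon[[nm]]
    mode[match(p[1], SPECIES), match(p[2], SPECIES)] <- "attractive"
    mode[match(p[2], SPECIES), match(p[1], SPECIES)] <- "attractive"
  }
  for (nm in excludedVolume) {
    p <- match(parsePair(nm), SPECIES)
    mode[p[1], p[2]] <- mode[p[2], p[1]] <- "excluded_volume"
    eps[p[1], p[2]] <- eps[p[2], p[1]] <- 0
  }
  new("InteractionMatrix", species = SPECIES, epsilon = eps, mode = as.character(mode))
}

#' Genome model for confinement sizing
#'
#' @param genomeLength genome size in base pairs (default: 360 Mbp, the
#'   diploid Drosophila genome)
#' @param bpPerBead base pairs per bead (default 5 kbp)
#' @param phi chromatin volume fraction (default 0.1)
#' @return a \linkS4class{GenomeModel}
#' @examples
#' nGenomeBeads(GenomeModel()) # 72000
#' @export
GenomeModel <- function(genomeLength = 360e6, bpPerBead = 5000, phi = 0.1) {
  new("GenomeModel", genomeLength = genomeLength, bpPerBead = bpPerBead,
      phi = phi)
}

#' Harmonic bond energy and force
#'
#' V(r) = ks (r - sigma)^2 between consecutive polymer beads; the returned
#' scalar force is -dV/dr (positive = repulsive, pushing the beads apart).
#'
#' @param r inter-bead distance (sigma)
#' @param ks spring constant (kBT/sigma^2)
#' @param sigma equilibrium bond length
#' @return list with \code{energy} (kBT) and \code{force} (kBT/sigma)
#' @examples
#' harmonicBond(1.1)$energy # 1 kBT at ks = 100
#' @export
harmonicBond <- function(r, ks = 100, sigma = 1) {
  if (any(r <= 0)) stop("invalid geometry: non-positive bond length")
  list(energy = ks * (r - sigma)^2, force = -2 * ks * (r - sigma))
}

#' Lennard-Jones pair energy and force
#'
#' The 12-6 LJ potential, cut and shifted so the energy is continuous at the
#' cutoff (the shift does not alter forces). Attractive pairs use the given
#' epsilon and cutoff \code{rcAttr}; excluded-volume pairs use epsilon = 1 kBT
#' and the WCA cutoff 2^(1/6) sigma, at which both the shifted energy and the
#' force vanish continuously.
#'
#' Distances below 0.3 sigma are evaluated at 0.3 sigma (force capping for
#' overlapping initial configurations) and reported via a warning.
#'
#' @param r pair distance (sigma)
#' @param epsilon attraction strength (kBT); ignored for excluded-volume mode
#' @param mode "attractive" or "excluded_volume"
#' @param rcAttr attractive cutoff (sigma)
#' @param shifted if FALSE, return the bare truncated potential without the
#'   cut-and-shift
#' @return list with \code{energy} (kBT) and \code{force} (kBT/sigma, -dV/dr)
#' @examples
#' ljPair(2^(1 / 6), 1, shifted = FALSE)$energy # -1 kBT, the LJ minimum
#' ljPair(2.6, 1)$energy # 0 beyond the cutoff
#' @export
ljPair <- function(r, epsilon = 1,
                   mode = c("attractive", "excluded_volume"),
                   rcAttr = 2.5, shifted = TRUE) {
  mode <- match.arg(mode)
  if (any(r <= 0)) stop("invalid geometry: non-positive pair distance")
  if (mode == "excluded_volume") {
    epsilon <- 1
    rc <- 2^(1 / 6)
  } else {
    rc <- rcAttr
  }
  capped <- r < 0.3
  if (any(capped)) {
    warning("unstable configuration: pair distance below 0.3 sigma; force capped")
    r <- pmax(r, 0.3)
  }
  lj <- function(rr) 4 * epsilon * ((1 / rr)^12 - (1 / rr)^6)
  shift <- if (shifted) lj(rc) else 0
  e <- ifelse(r <= rc, lj(r) - shift, 0)
  f <- ifelse(r <= rc, 24 * epsilon * (2 * (1 / r)^13 - (1 / r)^7), 0)
  list(energy = e, force = f)
}

#' Bending energy of a consecutive bead triple
#'
#' V(theta) = kBend (1 + cos theta), zero for a straight triple (theta = pi).
#' With kBend = lp/sigma the tangent-correlation persistence length of a free
#' chain is approximately kBend beads.
#'
#' @param theta bond angle at the central bead, radians in [0, pi]
#' @param kBend stiffness (kBT)
#' @return energy in kBT
#' @examples
#' bendingEnergy(pi) # 0 at the minimum
#' bendingEnergy(pi / 2, kBend = 2) # kBend
#' @export
bendingEnergy <- function(theta, kBend = 2) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  kBend * (1 + cos(theta))
}

#' Confinement radius from the chromatin volume fraction
#'
#' phi = NG * (4/3) pi (sigma/2)^3 / ((4/3) pi Rc^3), with bead volume taken
#' at radius sigma/2, so Rc = (NG / (8 phi))^(1/3) sigma. For the default
#' genome (72,000 beads, phi = 0.1) this gives 44.8 sigma, conventionally rounded
#' as 45 sigma.
#'
#' @param genome a \linkS4class{GenomeModel}
#' @param sigma bead diameter (sigma; 1 in reduced units)
#' @return confinement radius Rc in units of sigma
#' @examples
#' confinementRadiusFromPhi(GenomeModel()) # ~44.8
#' @export
confinementRadiusFromPhi <- function(genome, sigma = 1) {
  stopifnot(is(genome, "GenomeModel"))
  if (genome@phi <= 0) stop("phi must be > 0")
  ng <- genome@genomeLength / genome@bpPerBead
  (ng / (8 * genome@phi))^(1 / 3) * sigma
}

#' Bead count from a number concentration
#'
#' N = round(c * (4/3) pi Rc^3): the number of beads of a species present at
#' number density \code{conc} (sigma^-3) inside the confinement sphere.
#'
#' @param conc number density in sigma^-3
#' @param Rc confinement radius (sigma)
#' @return integer bead count
#' @examples
#' countFromConcentration(0.013, 45) # 4962
#' @export
countFromConcentration <- function(conc, Rc) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  as.integer(round(conc * (4 / 3) * pi * Rc^3))
}

#' @rdname countFromConcentration
#' @param n bead count
#' @export
concentrationFromCount <- function(n, Rc) {
  n / ((4 / 3) * pi * Rc^3)
}
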