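#' @include AllClasses.R AllGenerics.R model-core.R
NULL

#' Full system composition: counts, rDNA fraction and confinement radius
#'
#' A lightweight container describing a complete simulation system before any
#' positions exist. \code{scaleSystem} shrinks it to a desk-scale replica at
#' identical number densities.
#'
#' @slot nPch polymer length (H + rD beads)
#' @slot rdnaFraction fraction of the polymer designated rDNA
#' @slot nF number of free Fibrillarin beads
#' @slot nX number of free amphiphile beads
#' @slot Rc confinement radius (sigma)
#' @export
setClass("SystemSpec",
  slots = c(nPch = "integer", rdnaFraction = "numeric", nF = "integer",
            nX = "integer", Rc = "numeric")
)

setValidity("SystemSpec", function(object) {
  msg <- character()
  if (object@rdnaFraction < 0 || object@rdnaFraction >= 1) {
    msg <- c(msg, "rdnaFraction must lie in [0, 1)")
  }
  if (any(c(object@nPch, object@nF, object@nX) < 0)) {
    msg <- c(msg, "counts must be >= 0")
  }
  if (object@Rc <= 0) msg <- c(msg, "Rc must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SystemSpec", function(object) {
  cat(sprintf(
    "SystemSpec: polymer %d (rDNA fraction %.3g), F=%d, X=%d, Rc=%g sigma\n",
    object@nPch, object@rdnaFraction, object@nF, object@nX, object@Rc
  ))
})

#' @rdname SystemSpec-class
#' @param nPch polymer length
#' @param rdnaFraction fraction of the polymer labeled rD (default 0.2)
#' @param nF,nX free bead counts
#' @param Rc confinement radius (sigma)
#' @export
SystemSpec <- function(nPch = 10000L, rdnaFraction = 0.2, nF = 4962L,
                       nX = 4962L, Rc = 45) {
  new("SystemSpec",
    nPch = as.integer(nPch), rdnaFraction = rdnaFraction,
    nF = as.integer(nF), nX = as.integer(nX), Rc = Rc
  )
}

#' Build the PCH-rDNA block copolymer plus free protein beads
#'
#' Constructs a linear polymer of \code{nPch} beads whose central contiguous
#' block of \code{round(rdnaFraction * nPch)} beads is labeled rD and the
#' flanks H (the rDNA block embedded between two PCH blocks), followed by
#' \code{nF} Fibrillarin and \code{nX} amphiphile beads with no bonds.
#' Consecutive polymer pairs are bonded; consecutive triples carry a bending
#' term.
#'
#' @param nPch polymer bead count
#' @param rdnaFraction fraction of the polymer labeled rD, in [0, 1)
#' @param nF number of free F beads
#' @param nX number of free X beads
#' @return a \linkS4class{Topology}
#' @examples
#' top <- buildTopology(10, 0.2, 3, 3)
#' speciesLabels(top)[5:6] # the centred rD block
#' @export
buildTopology <- function(nPch, rdnaFraction = 0.2, nF = 0, nX = 0) {
  if (rdnaFraction < 0 || rdnaFraction >= 1) {
    stop("rdnaFraction must lie in [0, 1)")
  }
  if (any(c(nPch, nF, nX) < 0)) stop("counts must be >= 0")
  nPch <- as.integer(nPch)
  species <- rep("H", nPch)
  nRd <- as.integer(round(rdnaFraction * nPch))
  rdRange <- c(0L, 0L)
  if (nRd > 0) {
    start <- as.integer(floor((nPch - nRd) / 2)) + 1L
    rdRange <- c(start, start + nRd - 1L)
    species[rdRange[1]:rdRange[2]] <- "rD"
  }
  species <- c(species, rep("F", nF), rep("X", nX))
  bonds <- if (nPch >= 2) {
    cbind(seq_len(nPch - 1L), seq_len(nPch - 1L) + 1L)
  } else {
    matrix(integer(), 0, 2)
  }
  angles <- if (nPch >= 3) {
    cbind(seq_len(nPch - 2L), seq_len(nPch - 2L) + 1L, seq_len(nPch - 2L) + 2L)
  } else {
    matrix(integer(), 0, 3)
  }
  storage.mode(bonds) <- "integer"
  storage.mode(angles) <- "integer"
  new("Topology",
    species = species, bonds = bonds, angles = angles,
    nPolymer = nPch, rdRange = rdRange
  )
}

#' @rdname buildTopology
#' @param spec a \linkS4class{SystemSpec}
#' @export
buildTopologyFromSpec <- function(spec) {
  buildTopology(spec@nPch, spec@rdnaFraction, spec@nF, spec@nX)
}

#' Shrink a system specification at constant densities
#'
#' Scales all bead counts by \code{scaleFactor} and the confinement radius by
#' \code{scaleFactor^(1/3)}, so every number density (polymer and proteins)
#' and all interaction strengths are unchanged; the rDNA fraction is
#' preserved. Used to produce desk-scale replicas of the full-size system.
#'
#' @param spec a \linkS4class{SystemSpec}
#' @param scaleFactor in (0, 1]
#' @return the scaled \linkS4class{SystemSpec}
#' @examples
#' scaleSystem(SystemSpec(), 1 / 8) # Rc = 22.5 sigma, 1250 polymer beads
#' @export
scaleSystem <- function(spec, scaleFactor) {
  stopifnot(is(spec, "SystemSpec"))
  if (scaleFactor <= 0 || scaleFactor > 1) {
    stop("scaleFactor must lie in (0, 1]")
  }
  out <- new("SystemSpec",
    nPch = as.integer(round(spec@nPch * scaleFactor)),
    rdnaFraction = spec@rdnaFraction,
    nF = as.integer(round(spec@nF * scaleFactor)),
    nX = as.integer(round(spec@nX * scaleFactor)),
    Rc = spec@Rc * scaleFactor^(1 / 3)
  )
  counts <- c(out@nPch, out@nF, out@nX)
  present <- counts[c(spec@nPch, spec@nF, spec@nX) > 0]
  if (any(present < 10)) {
    stop("scaled system too small: fewer than 10 beads in a species")
  }
  out
}

#' Initial configuration inside the confinement sphere
#'
#' Lays the polymer down as a confined self-avoiding random walk with bond
#' length sigma, places free beads uniformly in the sphere, then applies a
#' deterministic pairwise push-off so no two beads are closer than 0.8 sigma.
#' The result is fully determined by \code{seed}.
#'
#' @param topology a \linkS4class{Topology}
#' @param params a \linkS4class{SimulationParameters} (supplies Rc)
#' @param seed integer RNG seed
#' @return a \linkS4class{SystemState} at time 0
#' @examples
#' top <- buildTopology(20, 0.2, 10, 10)
#' st <- initializePositions(top, SimulationParameters(Rc = 8), seed = 1)
#' @export
initializePositions <- function(topology, params, seed = 1L) {
  stopifnot(is(topology, "Topology"), is(params, "SimulationParameters"))
  n <- length(topology@species)
  nFree <- n - topology@nPolymer
  # feasibility: packing fraction of beads (radius sigma/2) below 0.5
  packing <- n * (4 / 3) * pi * 0.5^3 / ((4 / 3) * pi * params@Rc^3)
  if (packing >= 0.5) {
    stop("packing infeasible: ", n, " beads exceed half the confinement volume")
  }
  pos <- init_positions_cpp(topology@nPolymer, nFree, params@Rc,
                            as.integer(seed), 0.8)
  new("SystemState",
    positions = pos, species = topology@species, Rc = params@Rc, time = 0
  )
}
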