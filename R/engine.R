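#' @include AllClasses.R AllGenerics.R model-core.R topology.R
NULL

speciesCodes <- function(species) {
  match(species, SPECIES) - 1L
}

matrixArgs <- function(im) {
  list(
    eps = im@epsilon,
    attractive = matrix(as.integer(matrix(im@mode, 4, 4) == "attractive"), 4, 4)
  )
}

#' Total forces on every bead
#'
#' Sums bond, bending, pair (LJ / WCA) and confining-wall forces. The default
#' cell-list/neighbor evaluation and the brute-force all-pairs evaluation
#' agree for every pair within the cutoff; the brute-force path exists as the
#' reference implementation for testing.
#'
#' @param state a \linkS4class{SystemState}
#' @param topology the matching \linkS4class{Topology}
#' @param matrix an \linkS4class{InteractionMatrix}
#' @param params a \linkS4class{SimulationParameters}
#' @param method "neighbor" (cell-list accelerated) or "brute" (all pairs)
#' @return list: \code{forces} (n x 3, kBT/sigma), \code{potential} (kBT),
#'   \code{capped} (count of capped pair evaluations)
#' @export
computeForces <- function(state, topology, matrix, params,
                          method = c("neighbor", "brute")) {
  method <- match.arg(method)
  ma <- matrixArgs(matrix)
  compute_forces_cpp(
    state@positions, speciesCodes(state@species), topology@bonds,
    topology@angles, ma$eps, ma$attractive, state@Rc, params@ks,
    params@kBend, params@rcAttr,
    brute = (method == "brute")
  )
}

#' Integrate the system with an underdamped Langevin thermostat
#'
#' BAOAB velocity-Verlet integration at constant temperature \code{kBT}
#' inside the confinement sphere (purely repulsive shifted-LJ wall). The
#' Gaussian noise satisfies fluctuation-dissipation, so a free bead diffuses
#' with D = kBT/(gamma * mass). Identical seeds give identical trajectories.
#'
#' @param state starting \linkS4class{SystemState}
#' @param topology the matching \linkS4class{Topology}
#' @param params a \linkS4class{SimulationParameters}
#' @param matrix an \linkS4class{InteractionMatrix}
#' @param nSteps number of timesteps
#' @param seed RNG seed for this run segment
#' @param frameInterval steps between saved frames (default: save 50 frames)
#' @param forceCap cap on per-bead force magnitude (kBT/sigma); <= 0 disables.
#'   Used during push-off to survive residual overlaps.
#' @return a \linkS4class{Trajectory} whose first frame is the input state
#' @export
integrateDynamics <- function(state, topology, params, matrix, nSteps,
                              seed = params@seed, frameInterval = NULL,
                              forceCap = -1) {
  stopifnot(is(state, "SystemState"), is(topology, "Topology"))
  if (params@dt > 0.01) stop("dt too large; refusing to start")
  nSteps <- as.integer(nSteps)
  if (is.null(frameInterval)) {
    frameInterval <- max(1L, as.integer(nSteps %/% 50L))
  }
  ma <- matrixArgs(matrix)
  res <- integrate_cpp(
    state@positions, speciesCodes(state@species), topology@bonds,
    topology@angles, ma$eps, ma$attractive, state@Rc, params@ks,
    params@kBend, params@rcAttr, params@dt, params@gamma, params@mass,
    params@kBT, nSteps, as.integer(frameInterval), as.integer(seed),
    forceCap, 0.4, state@time
  )
  new("Trajectory",
    frames = res$frames, times = as.numeric(res$times),
    species = state@species, Rc = state@Rc,
    frameInterval = as.integer(frameInterval),
    kineticTemp = as.numeric(res$kineticTemp),
    potential = as.numeric(res$potential),
    provenance = list(
      params = paramsAsList(params), seed = as.integer(seed),
      nSteps = nSteps, forceCap = forceCap,
      interactionMatrix = interactionAsList(matrix),
      nBeads = length(state@species),
      speciesCounts = as.list(table(state@species)),
      capped = res$capped, neighborRebuilds = res$rebuilds,
      package = "nucleopch",
      version = as.character(utils::packageVersion("nucleopch"))
    )
  )
}

paramsAsList <- function(p) {
  list(
    sigma = p@sigma, kBT = p@kBT, ks = p@ks, rcAttr = p@rcAttr,
    rcRep = p@rcRep, Rc = p@Rc, dt = p@dt, gamma = p@gamma, mass = p@mass,
    kBend = p@kBend, nSteps = p@nSteps, seed = p@seed
  )
}

interactionAsList <- function(im) {
  m <- matrix(im@mode, 4, 4)
  out <- list()
  for (i in 1:4) {
    for (j in i:4) {
      nm <- paste(SPECIES[i], SPECIES[j], sep = "-")
      out[[nm]] <- list(epsilon = unname(im@epsilon[i, j]), mode = m[i, j])
    }
  }
  out
}

#' Staged simulation protocol: push-off, equilibration, production
#'
#' Runs the standard three-stage protocol from a fresh random configuration:
#' a short capped-force push-off to remove residual overlaps, an
#' equilibration segment, and a production segment with frame saving. The
#' returned trajectory covers the production segment (its first frame is the
#' equilibrated configuration). The summary records final-frame observables:
#' largest-cluster fraction per species, radius of gyration of the polymer,
#' and the mean production kinetic temperature.
#'
#' @param config list with elements \code{spec} (\linkS4class{SystemSpec}),
#'   \code{matrix} (\linkS4class{InteractionMatrix}), \code{params}
#'   (\linkS4class{SimulationParameters}), \code{seed}, and step counts
#'   \code{pushoffSteps}, \code{equilSteps}, \code{prodSteps} (production may
#'   be 0: the trajectory then holds only the equilibrated frame),
#'   \code{frameInterval}, optional \code{clusterCutoff} (default 1.5), and
#'   optional \code{initialState} (a \linkS4class{SystemState} that replaces
#'   the random start, e.g. a condensed droplet for stability assays)
#' @return list: \code{trajectory} (\linkS4class{Trajectory}),
#'   \code{summary} (named list of final-frame observables)
#' @export
runProtocol <- function(config) {
  spec <- config$spec
  params <- config$params
  if (is.null(params)) params <- SimulationParameters(Rc = spec@Rc)
  if (!isTRUE(all.equal(params@Rc, spec@Rc))) {
    params@Rc <- spec@Rc
  }
  matrix <- config$matrix
  seed <- as.integer(config$seed %||% params@seed)
  pushoffSteps <- as.integer(config$pushoffSteps %||% 2000L)
  equilSteps <- as.integer(config$equilSteps %||% 20000L)
  prodSteps <- as.integer(config$prodSteps %||% params@nSteps)
  frameInterval <- config$frameInterval %||% max(1L, prodSteps %/% 25L)
  cutoff <- config$clusterCutoff %||% 1.5

  topology <- buildTopologyFromSpec(spec)
  state <- config$initialState %||%
    initializePositions(topology, params, seed = seed)

  if (pushoffSteps > 0) {
    tr <- integrateDynamics(state, topology, params, matrix, pushoffSteps,
                            seed = seed, frameInterval = pushoffSteps,
                            forceCap = 50)
    state <- getFrame(tr, -1L)
  }
  if (equilSteps > 0) {
    tr <- integrateDynamics(state, topology, params, matrix, equilSteps,
                            seed = seed + 1L,
                            frameInterval = max(1L, equilSteps))
    state <- getFrame(tr, -1L)
  }
  if (prodSteps > 0) {
    traj <- integrateDynamics(state, topology, params, matrix, prodSteps,
                              seed = seed + 2L,
                              frameInterval = as.integer(frameInterval))
  } else {
    traj <- new("Trajectory",
      frames = list(state@positions), times = state@time,
      species = state@species, Rc = state@Rc, frameInterval = 1L,
      kineticTemp = NA_real_, potential = NA_real_,
      provenance = list(seed = seed, params = paramsAsList(params),
                        interactionMatrix = interactionAsList(matrix),
                        note = "equilibrated frame only (prodSteps = 0)")
    )
  }
  traj@provenance$protocol <- list(
    seed = seed, pushoffSteps = pushoffSteps, equilSteps = equilSteps,
    prodSteps = prodSteps,
    spec = list(nPch = spec@nPch, rdnaFraction = spec@rdnaFraction,
                nF = spec@nF, nX = spec@nX, Rc = spec@Rc)
  )

  final <- getFrame(traj, -1L)
  pos <- positions(final)
  sp <- speciesLabels(final)
  lcf <- vapply(SPECIES, function(s) {
    idx <- sp == s
    if (!any(idx)) return(NA_real_)
    largestClusterFraction(findClusters(pos[idx, , drop = FALSE], cutoff))
  }, numeric(1))
  poly <- sp %in% c("H", "rD")
  summary <- list(
    largestClusterFraction = lcf,
    polymerRg = if (any(poly)) {
      radiusOfGyration(pos[poly, , drop = FALSE])
    } else {
      NA_real_
    },
    meanKineticTemp = if (prodSteps > 0) mean(traj@kineticTemp[-1]) else NA_real_,
    finalPotential = traj@potential[length(traj@potential)],
    seed = seed
  )
  list(trajectory = traj, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
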