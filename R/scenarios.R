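#' @include AllClasses.R AllGenerics.R model-core.R topology.R engine.R observables.R
NULL

#' The +rDNA interaction hierarchy
#'
#' Default attraction strengths implementing the affinity hierarchy
#' rD-F = F-F > X-X > F-X > X-H > H-H (kBT):
#' F-F = rD-F = 2.0, X-X = 1.75, F-X = 1.5, X-H = 1.0, H-H = 0.35.
#' All other pairs (H-F, H-rD, rD-rD, rD-X) are excluded-volume only. The
#' strict hierarchy is asserted at construction; overrides that violate it
#' are rejected with the violated inequality named.
#'
#' @param overrides named numeric vector of epsilon overrides, e.g.
#'   \code{c("X-X" = 1.6)}
#' @return an \linkS4class{InteractionMatrix}
#' @examples
#' plusRdnaMatrix()
#' @export
plusRdnaMatrix <- function(overrides = numeric()) {
  eps <- c("F-F" = 2.0, "rD-F" = 2.0, "X-X" = 1.75, "F-X" = 1.5,
           "X-H" = 1.0, "H-H" = 0.35)
  for (nm in names(overrides)) {
    key <- normalizePairName(nm)
    if (!key %in% names(eps)) {
      stop("pair '", nm, "' is not attractive in the +rDNA matrix")
    }
    eps[key] <- overrides[[nm]]
  }
  checkHierarchy(eps)
  InteractionMatrix(eps)
}

normalizePairName <- function(nm) {
  parts <- strsplit(nm, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% SPECIES)) {
    stop("bad pair name '", nm, "'")
  }
  cands <- c(paste(parts[1], parts[2], sep = "-"),
             paste(parts[2], parts[1], sep = "-"))
  known <- c("F-F", "rD-F", "X-X", "F-X", "X-H", "H-H")
  hit <- cands[cands %in% known]
  if (length(hit)) hit[1] else cands[1]
}

checkHierarchy <- function(eps) {
  # rD-F = F-F > X-X > F-X > X-H > H-H
  if (eps[["rD-F"]] != eps[["F-F"]]) {
    stop("hierarchy violated: rD-F must equal F-F")
  }
  chain <- c("F-F", "X-X", "F-X", "X-H", "H-H")
  for (i in seq_len(length(chain) - 1)) {
    if (eps[[chain[i]]] <= eps[[chain[i + 1]]]) {
      stop("hierarchy violated: ", chain[i], " > ", chain[i + 1],
           " does not hold (", eps[[chain[i]]], " <= ", eps[[chain[i + 1]]],
           ")")
    }
  }
  invisible(TRUE)
}

#' The -rDNA interaction matrix
#'
#' The +rDNA matrix with the rDNA-Fibrillarin attraction removed (the pair
#' reverts to excluded volume), modeling the deletion of the rDNA repeats.
#' The amphiphile-PCH attraction defaults to X-H = 1.5 kBT = F-X, satisfying
#' the X-H >= F-X condition under which the amphiphile neocondensate forms
#' inside the PCH void. A weaker X-H is accepted with a warning since it
#' leaves the neocondensate regime.
#'
#' @param xH the X-H attraction strength (kBT)
#' @return an \linkS4class{InteractionMatrix}
#' @examples
#' minusRdnaMatrix()
#' @export
minusRdnaMatrix <- function(xH = 1.5) {
  eps <- c("F-F" = 2.0, "X-X" = 1.75, "F-X" = 1.5, "X-H" = xH, "H-H" = 0.35)
  if (xH < eps[["F-X"]]) {
    warning("X-H (", xH, ") < F-X (", eps[["F-X"]],
            "): outside the neocondensate regime (requires X-H >= F-X)")
  }
  InteractionMatrix(eps)
}

#' Reference full-size system for the four-component model
#'
#' 10,000 polymer beads (20 percent rDNA, centred), Fibrillarin at
#' concentration 0.013 sigma^-3 and the amphiphile at \code{cX}, inside the
#' Rc = 45 sigma confinement.
#'
#' @param cX amphiphile concentration (sigma^-3), default 0.013
#' @param cF Fibrillarin concentration (sigma^-3), default 0.013
#' @param Rc confinement radius (sigma)
#' @return a \linkS4class{SystemSpec}
#' @export
referenceSystem <- function(cX = 0.013, cF = 0.013, Rc = 45) {
  SystemSpec(
    nPch = 10000L, rdnaFraction = 0.2,
    nF = countFromConcentration(cF, Rc),
    nX = countFromConcentration(cX, Rc), Rc = Rc
  )
}

#' Run a named scenario at desk scale
#'
#' Runs the +rDNA or -rDNA scenario: the reference system scaled down by
#' \code{scale} (densities and interaction strengths unchanged), the staged
#' push-off/equilibration/production protocol, and the organization
#' classification of the final frame.
#'
#' @param name "plus-rdna" or "minus-rdna"
#' @param scale system scale factor in (0, 1]; default 1/27 (Rc = 15 sigma)
#' @param seed RNG seed
#' @param prodSteps production steps (default 250000)
#' @param equilSteps equilibration steps (default 20000)
#' @param cX amphiphile concentration (sigma^-3)
#' @param start "dispersed" (default) starts from a random gas and measures
#'   assembly, the protocol behind the reported phenotypes; "assembled"
#'   places the system in the canonical layered organization (condensed F
#'   droplet coated by an X shell, polymer around it) and measures whether
#'   the interaction matrix sustains or disassembles it.
#' @param params optional \linkS4class{SimulationParameters} override
#' @return list: \code{trajectory}, \code{report}
#'   (\linkS4class{OrganizationReport} of the final frame), \code{summary}
#' @export
runScenario <- function(name = c("plus-rdna", "minus-rdna"), scale = 1 / 27,
                        seed = 1L, prodSteps = 250000L, equilSteps = 20000L,
                        cX = 0.013, start = c("dispersed", "assembled"),
                        params = NULL) {
  name <- match.arg(name)
  start <- match.arg(start)
  spec <- scaleSystem(referenceSystem(cX = cX), scale)
  im <- if (name == "plus-rdna") plusRdnaMatrix() else minusRdnaMatrix()
  # dt = 0.01 (validated against bond/persistence statistics) doubles the
  # physical time sampled per step relative to the conservative default
  if (is.null(params)) {
    params <- SimulationParameters(Rc = spec@Rc, seed = seed, dt = 0.01)
  }
  cfg <- list(
    spec = spec, matrix = im, params = params, seed = seed,
    equilSteps = equilSteps, prodSteps = prodSteps
  )
  if (start == "assembled") {
    cfg$initialState <- assembledState(spec, seed = seed)
    cfg$pushoffSteps <- 4000L
  }
  res <- runProtocol(cfg)
  report <- layeringVerdict(getFrame(res$trajectory, -1L))
  list(trajectory = res$trajectory, report = report, summary = res$summary)
}

#' Canonical layered starting configuration
#'
#' Builds the layered organization directly: a dense Fibrillarin droplet at
#' the centre, the amphiphile as a shell hugging its surface, and the
#' polymer laid down as a self-avoiding walk in the remaining volume
#' (residual overlaps are resolved by the capped push-off stage).
#' Deterministic given the seed.
#'
#' @param spec a \linkS4class{SystemSpec}
#' @param seed RNG seed
#' @return a \linkS4class{SystemState}
#' @export
assembledState <- function(spec, seed = 1L) {
  topology <- buildTopologyFromSpec(spec)
  n <- nBeads(topology)
  pos <- matrix(0, n, 3)
  rF <- 0
  if (spec@nF > 0) {
    fb <- denseBall(spec@nF, 0.95)
    rF <- max(sqrt(rowSums(fb^2)))
    pos[speciesLabels(topology) == "F", ] <- fb
  }
  if (spec@nX > 0) {
    seedState <- withSeed(seed + 7L, {
      v <- matrix(stats::rnorm(3 * spec@nX), spec@nX, 3)
      v <- v / sqrt(rowSums(v^2))
      v * stats::runif(spec@nX, rF + 0.4, rF + 1.5)
    })
    pos[speciesLabels(topology) == "X", ] <- seedState
  }
  if (topology@nPolymer > 0) {
    # grow the polymer outside the droplet + shell core
    chain <- init_positions_cpp(topology@nPolymer, 0L, spec@Rc,
                                as.integer(seed), 0.8,
                                rExcl = if (spec@nF > 0) rF + 2.2 else 0)
    pos[seq_len(topology@nPolymer), ] <- chain
  }
  new("SystemState", positions = pos, species = speciesLabels(topology),
      Rc = spec@Rc, time = 0)
}
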