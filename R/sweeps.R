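#' @include AllClasses.R AllGenerics.R model-core.R topology.R engine.R observables.R scenarios.R
NULL

## shared single-cell runner: staged protocol, returns trajectory + final state
runCell <- function(spec, im, seed, prodSteps, equilSteps, params = NULL) {
  runCell2(list(
    spec = spec, matrix = im, params = params, seed = seed,
    equilSteps = equilSteps, prodSteps = prodSteps,
    frameInterval = max(1L, as.integer(prodSteps) %/% 10L)
  ))
}

runCell2 <- function(cfg) {
  if (is.null(cfg$params)) {
    cfg$params <- SimulationParameters(Rc = cfg$spec@Rc,
                                       seed = cfg$seed %||% 1L, dt = 0.01)
  }
  runProtocol(cfg)
}

## deterministic compact droplet: cubic-lattice ball, spacing 1.1 sigma
denseBall <- function(n, spacing = 1.1) {
  k <- ceiling((n * spacing^3 / (4 / 3 * pi))^(1 / 3)) + 2
  g <- as.matrix(expand.grid(x = -k:k, y = -k:k, z = -k:k)) * spacing
  g[order(rowSums(g^2)), ][seq_len(n), , drop = FALSE]
}

#' Fibrillarin condensation phase diagram
#'
#' Single-component Fibrillarin systems over a concentration x attraction
#' grid. Each cell is called condensed when the largest-cluster fraction is
#' at least 0.5 sustained over the final three saved frames. The
#' per-concentration threshold is the smallest epsilon condensed in at least
#' half of the seeds; a threshold column that is not non-increasing in
#' concentration is flagged as undersampled, never smoothed.
#'
#' By default each cell starts from a condensed droplet containing all F
#' beads and measures whether it survives or evaporates (a droplet-stability
#' assay). Dispersed starts are nucleation-limited at low concentration —
#' the critical nucleus there is large and the barrier tens of kBT — so a
#' gas start measures run length rather than the phase boundary; see the
#' methods vignette. \code{start = "dispersed"} restores the gas start.
#'
#' @param cGrid Fibrillarin concentrations (sigma^-3)
#' @param epsGrid F-F attraction strengths (kBT)
#' @param seeds replicate seeds
#' @param Rc confinement radius per concentration (recycled over
#'   \code{cGrid}); the default uses 15 sigma cells and widens to 30 sigma
#'   below c = 0.005 so dilute cells keep enough beads
#' @param start "condensed" (droplet-stability assay) or "dispersed"
#' @param prodSteps,equilSteps protocol step counts per cell
#' @return a \linkS4class{SweepResult}; thresholds has one row per
#'   concentration
#' @export
fibrillarinPhaseDiagram <- function(cGrid, epsGrid, seeds = 1:2, Rc = NULL,
                                    start = c("condensed", "dispersed"),
                                    prodSteps = 250000L, equilSteps = 10000L) {
  stopifnot(length(cGrid) > 0, length(epsGrid) > 0)
  start <- match.arg(start)
  if (is.null(Rc)) Rc <- ifelse(cGrid < 0.005, 30, 15)
  Rc <- rep_len(Rc, length(cGrid))
  rows <- list()
  for (ci in seq_along(cGrid)) {
    cF <- cGrid[ci]
    nF <- countFromConcentration(cF, Rc[ci])
    for (eps in epsGrid) {
      im <- if (eps > 0) InteractionMatrix(c("F-F" = eps)) else InteractionMatrix()
      for (seed in seeds) {
        spec <- new("SystemSpec", nPch = 0L, rdnaFraction = 0,
                    nF = nF, nX = 0L, Rc = Rc[ci])
        cfg <- list(spec = spec, matrix = im, seed = seed,
                    prodSteps = prodSteps, equilSteps = equilSteps,
                    frameInterval = max(1L, as.integer(prodSteps) %/% 10L))
        if (start == "condensed") {
          cfg$initialState <- new("SystemState",
            positions = denseBall(nF), species = rep("F", nF),
            Rc = Rc[ci], time = 0
          )
          cfg$pushoffSteps <- 0L
        }
        res <- runCell2(cfg)
        call <- condensationCall(res$trajectory, "F")
        rows[[length(rows) + 1L]] <- data.frame(
          cF = cF, eps = eps, seed = seed, nF = nF,
          condensed = call$condensed,
          fraction = mean(call$fractions)
        )
      }
    }
  }
  cells <- do.call(rbind, rows)
  thr <- do.call(rbind, lapply(cGrid, function(cc) {
    sub <- cells[cells$cF == cc, ]
    byEps <- vapply(sort(unique(sub$eps)), function(e) {
      mean(sub$condensed[sub$eps == e]) >= 0.5
    }, logical(1))
    epsSorted <- sort(unique(sub$eps))
    hit <- which(byEps)
    data.frame(
      cF = cc,
      threshold = if (length(hit)) epsSorted[min(hit)] else NA_real_,
      monotoneColumn = all(diff(byEps) >= 0)
    )
  }))
  flagged <- FALSE
  okThr <- thr$threshold[!is.na(thr$threshold)]
  if (length(okThr) > 1) {
    ord <- order(thr$cF[!is.na(thr$threshold)])
    flagged <- any(diff(okThr[ord]) > 0) || any(!thr$monotoneColumn)
  }
  new("SweepResult",
    axes = list(cF = cGrid, eps = epsGrid), cells = cells, thresholds = thr,
    meta = list(Rc = Rc, seeds = seeds, prodSteps = prodSteps,
                equilSteps = equilSteps,
                undersampled = flagged)
  )
}

#' PCH chain collapse sweep over the self-attraction
#'
#' An isolated all-H chain at varying epsilon_HH. A chain is called collapsed
#' when its mean radius of gyration over the final three frames drops below
#' 0.6 of the athermal (epsilon_HH = 0) reference for the same chain length.
#' The reported onset is the smallest epsilon called collapsed in at least
#' half of the seeds.
#'
#' @param epsGrid epsilon_HH values (kBT); 0 is added if absent (reference)
#' @param chainN chain length in beads
#' @param seeds replicate seeds
#' @param prodSteps,equilSteps protocol step counts per cell
#' @param Rc confinement radius; defaults to a generous bound so the
#'   athermal coil is unconstrained
#' @return a \linkS4class{SweepResult} with \code{meta$onset}
#' @export
pchCollapseSweep <- function(epsGrid, chainN = 300L, seeds = 1:2,
                             prodSteps = 200000L, equilSteps = 20000L,
                             Rc = NULL) {
  if (!0 %in% epsGrid) epsGrid <- c(0, epsGrid)
  epsGrid <- sort(unique(epsGrid))
  if (is.null(Rc)) Rc <- max(15, ceiling(chainN^0.62))
  rows <- list()
  for (eps in epsGrid) {
    im <- if (eps > 0) InteractionMatrix(c("H-H" = eps)) else InteractionMatrix()
    for (seed in seeds) {
      spec <- new("SystemSpec", nPch = as.integer(chainN), rdnaFraction = 0,
                  nF = 0L, nX = 0L, Rc = Rc)
      res <- runCell(spec, im, seed, prodSteps, equilSteps)
      traj <- res$trajectory
      n <- nFrames(traj)
      rg <- mean(vapply(seq.int(max(1, n - 2), n), function(i) {
        radiusOfGyration(positions(getFrame(traj, i)))
      }, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(eps = eps, seed = seed, rg = rg)
    }
  }
  cells <- do.call(rbind, rows)
  rg0 <- mean(cells$rg[cells$eps == 0])
  cells$collapsed <- cells$rg < 0.6 * rg0
  collapsedByEps <- vapply(epsGrid, function(e) {
    mean(cells$collapsed[cells$eps == e]) >= 0.5
  }, logical(1))
  hit <- which(collapsedByEps)
  onset <- if (length(hit)) epsGrid[min(hit)] else NA_real_
  thr <- data.frame(eps = epsGrid, collapsed = collapsedByEps)
  new("SweepResult",
    axes = list(eps = epsGrid), cells = cells, thresholds = thr,
    meta = list(chainN = chainN, Rc = Rc, rgAthermal = rg0, onset = onset,
                seeds = seeds, prodSteps = prodSteps)
  )
}

#' rDNA engulfment sweep over the rDNA-Fibrillarin attraction
#'
#' Three-component H/rD/F systems (epsilon_HH = 0.35, epsilon_FF = 2, H-F
#' excluded volume) at varying epsilon_rD-F. Each cell is classified as
#' "interior" (rDNA condensed within the Fibrillarin complex) or "wrapping"
#' (rDNA coats the condensate surface) via the rD interior fraction; a cell
#' whose Fibrillarin did not condense is marked invalid.
#'
#' @param epsRdF rD-F attraction strengths (kBT); 0 gives an excluded-volume
#'   pair (rDNA unlinked from F beyond the polymer tether)
#' @param seeds replicate seeds
#' @param scale system scale factor (default 1/27)
#' @param prodSteps,equilSteps protocol step counts per cell
#' @return a \linkS4class{SweepResult}
#' @export
rdnaEngulfmentSweep <- function(epsRdF = c(0.75, 2), seeds = 1:2,
                                scale = 1 / 27, prodSteps = 200000L,
                                equilSteps = 20000L) {
  base <- referenceSystem()
  spec <- scaleSystem(new("SystemSpec", nPch = base@nPch,
                          rdnaFraction = base@rdnaFraction, nF = base@nF,
                          nX = 0L, Rc = base@Rc), scale)
  rows <- list()
  for (eps in epsRdF) {
    epsSet <- c("H-H" = 0.35, "F-F" = 2)
    if (eps > 0) epsSet <- c(epsSet, "rD-F" = eps)
    im <- InteractionMatrix(epsSet)
    for (seed in seeds) {
      res <- runCell(spec, im, seed, prodSteps, equilSteps)
      st <- getFrame(res$trajectory, -1L)
      pos <- positions(st)
      sp <- speciesLabels(st)
      fCall <- condensationCall(res$trajectory, "F")
      row <- data.frame(epsRdF = eps, seed = seed,
                        fCondensed = fCall$condensed,
                        interiorFraction = NA_real_, call = NA_character_,
                        valid = fCall$condensed)
      if (fCall$condensed) {
        fLc <- largestClusterPositions(pos, sp, "F")
        ifr <- interiorFraction(pos[sp == "rD", , drop = FALSE], fLc$pos)
        row$interiorFraction <- ifr$fraction
        row$call <- ifr$call
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  cells <- do.call(rbind, rows)
  calls <- do.call(rbind, lapply(epsRdF, function(e) {
    sub <- cells[cells$epsRdF == e & cells$valid, ]
    data.frame(
      epsRdF = e,
      call = if (nrow(sub)) {
        names(sort(table(sub$call), decreasing = TRUE))[1]
      } else {
        NA_character_
      }
    )
  }))
  new("SweepResult",
    axes = list(epsRdF = epsRdF), cells = cells, thresholds = calls,
    meta = list(scale = scale, seeds = seeds, prodSteps = prodSteps)
  )
}

#' Wetting sweep over the Fibrillarin-amphiphile attraction
#'
#' Four-component systems with the +rDNA matrix except epsilon_FX swept.
#' Each cell reports the amphiphile coverage verdict on the Fibrillarin
#' surface and the F-X centre distance d_FX; d_FX decreases as epsilon_FX
#' grows across the dissociated-to-wetting transition.
#'
#' Sweep values outside the +rDNA hierarchy (epsilon_FX outside
#' (X-H, X-X)) relax the hierarchy assertion: the sweep intentionally leaves
#' the wild-type regime.
#'
#' @param epsFX F-X attraction strengths (kBT)
#' @param seeds replicate seeds
#' @param scale system scale factor
#' @param prodSteps,equilSteps protocol step counts per cell
#' @return a \linkS4class{SweepResult}
#' @export
wettingSweep <- function(epsFX = c(0.75, 1.5), seeds = 1:2, scale = 1 / 27,
                         prodSteps = 200000L, equilSteps = 20000L) {
  spec <- scaleSystem(referenceSystem(), scale)
  rows <- list()
  for (eps in epsFX) {
    epsSet <- c("F-F" = 2.0, "rD-F" = 2.0, "X-X" = 1.75, "X-H" = 1.0,
                "H-H" = 0.35)
    if (eps > 0) epsSet <- c(epsSet, "F-X" = eps)
    im <- InteractionMatrix(epsSet)
    for (seed in seeds) {
      res <- runCell(spec, im, seed, prodSteps, equilSteps)
      st <- getFrame(res$trajectory, -1L)
      pos <- positions(st)
      sp <- speciesLabels(st)
      fLc <- largestClusterPositions(pos, sp, "F")
      xLc <- largestClusterPositions(pos, sp, "X")
      cov <- surfaceCoverage(fLc$pos, pos[sp == "X", , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        epsFX = eps, seed = seed, coverage = cov$coverage,
        verdict = cov$verdict,
        dFX = comDistance(fLc$pos, xLc$pos),
        fCondensed = fLc$condensed, xCondensed = xLc$condensed
      )
    }
  }
  cells <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(epsFX, function(e) {
    sub <- cells[cells$epsFX == e, ]
    data.frame(
      epsFX = e,
      verdict = names(sort(table(sub$verdict), decreasing = TRUE))[1],
      meanDFX = mean(sub$dFX), meanCoverage = mean(sub$coverage)
    )
  }))
  new("SweepResult",
    axes = list(epsFX = epsFX), cells = cells, thresholds = agg,
    meta = list(scale = scale, seeds = seeds, prodSteps = prodSteps)
  )
}

#' Amphiphile depletion series
#'
#' The +rDNA scenario at decreasing amphiphile concentration cX, all other
#' parameters fixed. Each cell reports the layering verdict, d_HF and the
#' nucleolar-edge occupancy analogue: the fraction of Fibrillarin-cluster
#' surface beads with an H bead within the contact cutoff. d_HF is expected
#' to be non-decreasing as cX decreases; violations are flagged, not
#' smoothed.
#'
#' @param cXValues amphiphile concentrations (sigma^-3); 0 removes X
#' @param seeds replicate seeds
#' @param scale system scale factor
#' @param prodSteps,equilSteps protocol step counts per cell
#' @return a \linkS4class{SweepResult}
#' @export
amphiphileDepletionSeries <- function(cXValues = c(0.013, 0.005, 0),
                                      seeds = 1:2, scale = 1 / 27,
                                      prodSteps = 250000L,
                                      equilSteps = 20000L) {
  rows <- list()
  for (cX in cXValues) {
    # scale the fixed components, then set the amphiphile count from cX
    # directly (it may legitimately be small or zero in a depletion series)
    spec <- scaleSystem(referenceSystem(cX = 0.013), scale)
    spec@nX <- as.integer(countFromConcentration(cX, spec@Rc))
    im <- plusRdnaMatrix()
    for (seed in seeds) {
      res <- runCell(spec, im, seed, prodSteps, equilSteps)
      st <- getFrame(res$trajectory, -1L)
      pos <- positions(st)
      sp <- speciesLabels(st)
      report <- layeringVerdict(st)
      fLc <- largestClusterPositions(pos, sp, "F")
      hOcc <- surfaceCoverage(fLc$pos, pos[sp == "H", , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        cX = cX, seed = seed, verdict = verdict(report),
        dHF = report@dHF, xCoverage = report@xCoverage,
        hEdgeOccupancy = hOcc$coverage
      )
    }
  }
  cells <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(cXValues, function(cc) {
    sub <- cells[cells$cX == cc, ]
    data.frame(
      cX = cc,
      verdict = names(sort(table(sub$verdict), decreasing = TRUE))[1],
      meanDHF = mean(sub$dHF), meanHEdge = mean(sub$hEdgeOccupancy)
    )
  }))
  ord <- order(agg$cX, decreasing = TRUE) # decreasing cX
  dhfMonotone <- all(diff(agg$meanDHF[ord]) >= -1e-9)
  new("SweepResult",
    axes = list(cX = cXValues), cells = cells, thresholds = agg,
    meta = list(scale = scale, seeds = seeds, prodSteps = prodSteps,
                dHFNonDecreasing = dhfMonotone)
  )
}
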