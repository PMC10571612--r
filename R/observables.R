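#' @include AllClasses.R AllGenerics.R
NULL

#' Connected clusters of beads within a distance cutoff
#'
#' Computes the connected components of the graph linking beads closer than
#' \code{cutoff} (default 1.5 sigma, the first-coordination-shell scale).
#' Labels are deterministic: clusters are numbered by their lowest member
#' index.
#'
#' @param positions (n x 3) coordinates of one species subset
#' @param cutoff linking distance (sigma)
#' @return a \linkS4class{ClusterSet}
#' @examples
#' chain <- cbind(seq(0, 6, by = 1.2), 0, 0)
#' largestClusterFraction(findClusters(chain, 1.5)) # one cluster
#' @export
findClusters <- function(positions, cutoff = 1.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(positions) || nrow(positions) == 0) {
    return(new("ClusterSet", labels = integer(), sizes = integer(),
               largest = integer()))
  }
  labels <- cluster_labels_cpp(positions, cutoff)
  sizes <- tabulate(labels)
  new("ClusterSet",
    labels = as.integer(labels), sizes = as.integer(sizes),
    largest = as.integer(which.max(sizes))
  )
}

#' Condensation call from largest-cluster fraction
#'
#' A species counts as condensed when at least half of its beads belong to
#' one connected cluster (boundary inclusive). \code{isCondensed} evaluates a
#' single configuration; \code{condensationCall} applies the sustained
#' criterion over the final three saved frames of a trajectory (fewer frames
#' are used as available and flagged).
#'
#' @param clusters a \linkS4class{ClusterSet}
#' @param nSpecies number of beads of the species (defaults to the subset
#'   size inside \code{clusters})
#' @return list: \code{condensed} logical, \code{fraction} largest-cluster
#'   fraction
#' @examples
#' cs <- findClusters(cbind(runif(20, 0, 0.5), 0, 0), 1.5)
#' isCondensed(cs)$condensed
#' @export
isCondensed <- function(clusters, nSpecies = length(clusters@labels)) {
  if (nSpecies <= 0) stop("nSpecies must be > 0")
  fraction <- if (length(clusters@sizes)) max(clusters@sizes) / nSpecies else 0
  list(condensed = fraction >= 0.5, fraction = fraction)
}

#' @rdname isCondensed
#' @param trajectory a \linkS4class{Trajectory}
#' @param species which species to assess
#' @param cutoff cluster linking distance (sigma)
#' @return \code{condensationCall}: list with \code{condensed} (sustained over
#'   the final three frames), \code{fractions} per assessed frame, and
#'   \code{flagged} (TRUE when fewer than three frames were available)
#' @export
condensationCall <- function(trajectory, species, cutoff = 1.5) {
  n <- nFrames(trajectory)
  use <- seq.int(max(1L, n - 2L), n)
  fr <- vapply(use, function(i) {
    st <- getFrame(trajectory, i)
    idx <- speciesLabels(st) == species
    isCondensed(findClusters(positions(st)[idx, , drop = FALSE], cutoff),
                sum(idx))$fraction
  }, numeric(1))
  list(condensed = all(fr >= 0.5), fractions = fr, flagged = length(use) < 3L)
}

#' Radius of gyration of a bead subset
#'
#' Root-mean-square distance of the beads from their centroid.
#'
#' @param positions (n x 3) coordinates
#' @return Rg in sigma
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))) # 1
#' @export
radiusOfGyration <- function(positions) {
  if (is.null(positions) || nrow(positions) == 0) {
    stop("empty subset")
  }
  centred <- sweep(positions, 2, colMeans(positions))
  sqrt(mean(rowSums(centred^2)))
}

#' Distance between the centres of mass of two bead sets
#'
#' Used for the inter-condensate distances d_HF (PCH vs Fibrillarin largest
#' clusters) and d_FX (Fibrillarin vs amphiphile).
#'
#' @param posA,posB (n x 3) coordinates of the two sets (typically the
#'   largest cluster of each species)
#' @return Euclidean distance in sigma
#' @export
comDistance <- function(posA, posB) {
  if (nrow(posA) == 0 || nrow(posB) == 0) stop("empty cluster")
  sqrt(sum((colMeans(posA) - colMeans(posB))^2))
}

largestClusterPositions <- function(positions, species, which, cutoff = 1.5) {
  idx <- which(species == which)
  if (!length(idx)) return(list(pos = NULL, flagged = TRUE, condensed = FALSE))
  sub <- positions[idx, , drop = FALSE]
  cs <- findClusters(sub, cutoff)
  cond <- isCondensed(cs)
  if (!cond$condensed) {
    # species entirely (or mostly) uncondensed: fall back to all its beads
    return(list(pos = sub, flagged = TRUE, condensed = FALSE))
  }
  list(pos = sub[clusterMembers(cs), , drop = FALSE], flagged = FALSE,
       condensed = TRUE)
}

#' Amphiphile coverage of the Fibrillarin condensate surface
#'
#' Surface beads of the F cluster are those with fewer than 8 F neighbours
#' within 1.5 sigma (a coordination-number criterion, rotation invariant).
#' Coverage is the fraction of surface beads with at least one X bead within
#' \code{contactCutoff}. Verdict thresholds: below 0.1 "none", at or above
#' 0.75 "complete", otherwise "partial".
#'
#' @param fPositions (n x 3) coordinates of the F cluster
#' @param xPositions (m x 3) coordinates of the X beads (may be empty)
#' @param contactCutoff contact distance (sigma)
#' @return list: \code{coverage} fraction in [0, 1], \code{verdict} one of
#'   "none", "partial", "complete", \code{nSurface} surface bead count
#' @export
surfaceCoverage <- function(fPositions, xPositions, contactCutoff = 1.5) {
  if (nrow(fPositions) == 0) stop("empty F cluster")
  nF <- nrow(fPositions)
  d2f <- as.matrix(stats::dist(fPositions))^2
  coordination <- rowSums(d2f <= 1.5^2) - 1L
  surface <- which(coordination < 8)
  if (!length(surface)) surface <- seq_len(nF) # tiny cluster: all surface
  if (is.null(xPositions) || nrow(xPositions) == 0) {
    return(list(coverage = 0, verdict = "none", nSurface = length(surface)))
  }
  cc2 <- contactCutoff^2
  covered <- vapply(surface, function(i) {
    d2 <- (xPositions[, 1] - fPositions[i, 1])^2 +
      (xPositions[, 2] - fPositions[i, 2])^2 +
      (xPositions[, 3] - fPositions[i, 3])^2
    any(d2 <= cc2)
  }, logical(1))
  coverage <- mean(covered)
  verdict <- if (coverage < 0.1) "none" else if (coverage >= 0.75) "complete" else "partial"
  list(coverage = coverage, verdict = verdict, nSurface = length(surface))
}

#' Fraction of rDNA inside the Fibrillarin condensate
#'
#' The interior region is the ball around the F-cluster centre of mass with
#' radius equal to the 80th percentile of the F beads' radial distances
#' (robust to stragglers). Interior condensation is called at fraction >=
#' 0.5; smaller values indicate wrapping around the condensate surface.
#'
#' @param rdPositions (n x 3) rD bead coordinates
#' @param fPositions (m x 3) F cluster coordinates
#' @return list: \code{fraction} in [0, 1], \code{call} "interior" or
#'   "wrapping", \code{fRadius} the 80th-percentile F radius used
#' @export
interiorFraction <- function(rdPositions, fPositions) {
  if (nrow(fPositions) == 0) stop("empty F cluster")
  centre <- colMeans(fPositions)
  rF <- sqrt(rowSums(sweep(fPositions, 2, centre)^2))
  extent <- stats::quantile(rF, 0.8, names = FALSE)
  rRd <- sqrt(rowSums(sweep(rdPositions, 2, centre)^2))
  fraction <- mean(rRd < extent)
  list(fraction = fraction,
       call = if (fraction >= 0.5) "interior" else "wrapping",
       fRadius = extent)
}

#' Classify the organization of a full four-component configuration
#'
#' Computes radial medians of the F, X and H beads about the Fibrillarin
#' cluster centre (or the X cluster centre when F is dissociated) and applies
#' the classification rules:
#' \itemize{
#'   \item \strong{layered}: median_F < median_X < median_H and the X
#'     coverage of the F surface is complete (the canonical H > X > F
#'     engulfment);
#'   \item \strong{neocondensate_in_H}: the X cluster centre lies inside the
#'     H condensate (within its 80th-percentile radial extent) while the F
#'     cluster sits farther from the H centre than X does;
#'   \item \strong{dissociated}: the F-X centre distance exceeds the sum of
#'     the two clusters' radial extents;
#'   \item \strong{partial_wetting}: F and X associate (not dissociated) with
#'     partial surface coverage;
#'   \item \strong{none}: anything else (e.g. a uniform mixture).
#' }
#'
#' @param state a \linkS4class{SystemState} containing all species
#' @param cutoff cluster linking distance (sigma)
#' @return an \linkS4class{OrganizationReport}
#' @export
layeringVerdict <- function(state, cutoff = 1.5) {
  pos <- positions(state)
  sp <- speciesLabels(state)
  flags <- character()

  parts <- list()
  for (s in SPECIES) {
    lc <- largestClusterPositions(pos, sp, s, cutoff)
    parts[[s]] <- lc
    if (is.null(lc$pos)) {
      flags <- c(flags, paste0("species ", s, " absent"))
    } else if (lc$flagged) {
      flags <- c(flags, paste0("species ", s, " uncondensed; using all beads"))
    }
  }
  condensed <- vapply(SPECIES, function(s) isTRUE(parts[[s]]$condensed),
                      logical(1))
  names(condensed) <- SPECIES

  hPos <- parts[["H"]]$pos
  fPos <- parts[["F"]]$pos
  xPos <- parts[["X"]]$pos
  rdIdx <- sp == "rD"
  rdPos <- pos[rdIdx, , drop = FALSE]

  dHF <- if (!is.null(hPos) && !is.null(fPos)) comDistance(hPos, fPos) else NA_real_
  dFX <- if (!is.null(fPos) && !is.null(xPos)) comDistance(fPos, xPos) else NA_real_

  rdInt <- if (nrow(rdPos) > 0 && !is.null(fPos)) {
    interiorFraction(rdPos, fPos)$fraction
  } else {
    NA_real_
  }

  cover <- if (!is.null(fPos)) {
    surfaceCoverage(fPos, xPos, contactCutoff = cutoff)
  } else {
    list(coverage = NA_real_, verdict = "none")
  }

  radialExtent <- function(p) {
    centre <- colMeans(p)
    stats::quantile(sqrt(rowSums(sweep(p, 2, centre)^2)), 0.8, names = FALSE)
  }

  dissociated <- FALSE
  if (!is.null(fPos) && !is.null(xPos) && is.finite(dFX)) {
    dissociated <- dFX > (radialExtent(fPos) + radialExtent(xPos))
  }

  # radial medians about the reference centre
  centre <- if (!is.null(fPos) && !dissociated) {
    colMeans(fPos)
  } else if (!is.null(xPos)) {
    colMeans(xPos)
  } else if (!is.null(fPos)) {
    colMeans(fPos)
  } else {
    colMeans(pos)
  }
  medRad <- function(p) {
    if (is.null(p) || nrow(p) == 0) return(NA_real_)
    stats::median(sqrt(rowSums(sweep(p, 2, centre)^2)))
  }
  radialMedians <- c(
    F = medRad(fPos), X = medRad(xPos),
    H = medRad(pos[sp == "H", , drop = FALSE])
  )

  verdict <- "none"
  layered <- condensed[["F"]] && condensed[["X"]] &&
    all(is.finite(radialMedians)) &&
    radialMedians["F"] < radialMedians["X"] &&
    radialMedians["X"] < radialMedians["H"] &&
    identical(cover$verdict, "complete")
  neo <- FALSE
  if (condensed[["X"]] && !is.null(hPos) && !is.null(xPos) &&
      !is.null(fPos) && nrow(hPos) > 3) {
    hCentre <- colMeans(hPos)
    hExtent <- radialExtent(hPos)
    xInH <- sqrt(sum((colMeans(xPos) - hCentre)^2)) < hExtent
    fFarther <- sqrt(sum((colMeans(fPos) - hCentre)^2)) >
      sqrt(sum((colMeans(xPos) - hCentre)^2))
    neo <- xInH && fFarther
  }
  if (layered) {
    verdict <- "layered"
  } else if (neo) {
    verdict <- "neocondensate_in_H"
  } else if (dissociated && condensed[["F"]] && condensed[["X"]]) {
    verdict <- "dissociated"
  } else if (condensed[["F"]] && condensed[["X"]] &&
             identical(cover$verdict, "partial")) {
    verdict <- "partial_wetting"
  }

  new("OrganizationReport",
    condensed = condensed, dHF = dHF, dFX = dFX,
    rdInteriorFraction = if (is.na(rdInt)) NA_real_ else rdInt,
    xCoverage = if (is.na(cover$coverage)) NA_real_ else cover$coverage,
    xCoverageVerdict = cover$verdict, verdict = verdict,
    radialMedians = radialMedians, flags = flags
  )
}
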