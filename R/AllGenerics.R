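#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param object,x an object of the documented class
#' @param ... passed on to methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(object, ...) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(object) standardGeneric("speciesLabels"))

#' @rdname accessors
#' @export
setGeneric("confinementRadius",
           function(object) standardGeneric("confinementRadius"))

#' @rdname accessors
#' @export
setGeneric("nBeads", function(object) standardGeneric("nBeads"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("epsilonOf", function(object, a, b) standardGeneric("epsilonOf"))

#' @rdname accessors
#' @export
setGeneric("modeOf", function(object, a, b) standardGeneric("modeOf"))

#' @rdname accessors
#' @export
setGeneric("nGenomeBeads", function(object) standardGeneric("nGenomeBeads"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("largestClusterFraction",
           function(object) standardGeneric("largestClusterFraction"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers",
           function(object, label) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(object, channel) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("objectTable", function(object) standardGeneric("objectTable"))

## ---- methods --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("positions", "SystemState", function(object, ...) object@positions)

#' @rdname accessors
#' @export
setMethod("speciesLabels", "SystemState", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("speciesLabels", "Topology", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("speciesLabels", "Trajectory", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("confinementRadius", "SystemState", function(object) object@Rc)

#' @rdname accessors
#' @export
setMethod("confinementRadius", "Trajectory", function(object) object@Rc)

#' @rdname accessors
#' @export
setMethod("nBeads", "SystemState", function(object) nrow(object@positions))

#' @rdname accessors
#' @export
setMethod("nBeads", "Topology", function(object) length(object@species))

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(object) length(object@frames))

#' @rdname accessors
#' @param i frame index (negative counts from the end, -1 = final frame)
#' @export
setMethod("getFrame", "Trajectory", function(object, i) {
  n <- length(object@frames)
  if (i < 0) i <- n + i + 1
  stopifnot(i >= 1, i <= n)
  new("SystemState",
    positions = object@frames[[i]], species = object@species,
    Rc = object@Rc, time = object@times[i]
  )
})

#' @rdname accessors
#' @export
setMethod("provenance", "Trajectory", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("epsilonOf", "InteractionMatrix", function(object, a, b) {
  object@epsilon[a, b]
})

#' @rdname accessors
#' @export
setMethod("modeOf", "InteractionMatrix", function(object, a, b) {
  matrix(object@mode, 4, 4, dimnames = list(SPECIES, SPECIES))[a, b]
})

#' @rdname accessors
#' @export
setMethod("nGenomeBeads", "GenomeModel", function(object) {
  as.integer(object@genomeLength / object@bpPerBead)
})

#' @rdname accessors
#' @export
setMethod("clusterSizes", "ClusterSet", function(object) object@sizes)

#' @rdname accessors
#' @export
setMethod("largestClusterFraction", "ClusterSet", function(object) {
  if (length(object@labels) == 0) return(NA_real_)
  max(object@sizes) / length(object@labels)
})

#' @rdname accessors
#' @param label cluster label; defaults to the largest cluster
#' @export
setMethod("clusterMembers", "ClusterSet", function(object, label) {
  if (missing(label)) label <- object@largest
  which(object@labels == label)
})

#' @rdname accessors
#' @export
setMethod("verdict", "OrganizationReport", function(object) object@verdict)

#' @rdname accessors
#' @export
setMethod("channelNames", "VoxelImage", function(object) names(object@channels))

#' @rdname accessors
#' @export
setMethod("getChannel", "VoxelImage", function(object, channel) {
  if (!channel %in% names(object@channels)) {
    stop("no channel named '", channel, "'")
  }
  object@channels[[channel]]
})

#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelImage", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "SegmentedObjects", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("labelArray", "SegmentedObjects", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("objectTable", "SegmentedObjects", function(object) object@objects)

## ---- show methods ----------------------------------------------------------

setMethod("show", "SimulationParameters", function(object) {
  cat("SimulationParameters (reduced units)\n")
  cat(sprintf("  sigma=%g kBT=%g ks=%g kBend=%g\n", object@sigma, object@kBT,
              object@ks, object@kBend))
  cat(sprintf("  cutoffs: attractive %.3g sigma, repulsive %.6g sigma\n",
              object@rcAttr, object@rcRep))
  cat(sprintf("  Rc=%g sigma, dt=%g, gamma=%g, mass=%g, nSteps=%d, seed=%d\n",
              object@Rc, object@dt, object@gamma, object@mass, object@nSteps,
              object@seed))
})

setMethod("show", "InteractionMatrix", function(object) {
  cat("InteractionMatrix (kBT); '.' marks excluded-volume pairs\n")
  e <- object@epsilon
  m <- matrix(object@mode, 4, 4)
  disp <- matrix(sprintf("%.3g", e), 4, 4)
  disp[m == "excluded_volume"] <- "."
  dimnames(disp) <- list(object@species, object@species)
  print(disp, quote = FALSE)
})

setMethod("show", "Topology", function(object) {
  tab <- table(factor(object@species, levels = SPECIES))
  cat(sprintf("Topology: %d beads (H=%d rD=%d F=%d X=%d), %d bonds, %d angles\n",
              length(object@species), tab["H"], tab["rD"], tab["F"], tab["X"],
              nrow(object@bonds), nrow(object@angles)))
  if (object@rdRange[1] > 0) {
    cat(sprintf("  rD block: beads %d-%d\n", object@rdRange[1],
                object@rdRange[2]))
  }
})

setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d beads in sphere Rc=%g sigma, t=%g\n",
              nrow(object@positions), object@Rc, object@time))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d beads, t in [%g, %g], Rc=%g sigma\n",
              length(object@frames), length(object@species),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA, object@Rc))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d beads in %d clusters; largest %d/%d (%.2f)\n",
              length(object@labels), length(object@sizes),
              if (length(object@sizes)) max(object@sizes) else 0L,
              length(object@labels),
              largestClusterFraction(object)))
})

setMethod("show", "OrganizationReport", function(object) {
  cat("OrganizationReport\n")
  cat("  verdict:", object@verdict, "\n")
  cat(sprintf("  d_HF=%.3g sigma, d_FX=%.3g sigma\n", object@dHF, object@dFX))
  cat(sprintf("  rD interior fraction=%.3g, X coverage of F=%.3g (%s)\n",
              object@rdInteriorFraction, object@xCoverage,
              object@xCoverageVerdict))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "),
                                "\n")
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over:", paste(names(object@axes), collapse = ", "), "\n")
  cat(sprintf("  %d replicate cells\n", nrow(object@cells)))
  if (nrow(object@thresholds)) {
    print(object@thresholds)
  }
})

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("VoxelImage: %s voxels, %d channel(s): %s; voxel %s um\n",
              paste(d, collapse = "x"), length(object@channels),
              paste(names(object@channels), collapse = ", "),
              paste(signif(object@voxelSize, 3), collapse = "x")))
})

setMethod("show", "SegmentedObjects", function(object) {
  cat(sprintf("SegmentedObjects[%s]: %d object(s), threshold %.4g\n",
              object@channel, nrow(object@objects), object@threshold))
})
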