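#' @import methods
NULL

## Species order used everywhere: H (PCH polymer), rD (rDNA block),
## F (Fibrillarin), X (amphiphilic protein).
SPECIES <- c("H", "rD", "F", "X")

#' Physical constants and integrator settings in reduced units
#'
#' All lengths are expressed in units of the bead diameter \code{sigma}
#' (nominally 30 nm, ~5 kbp of chromatin) and all energies in units of the
#' thermal energy \code{kBT}. The attractive Lennard-Jones cutoff is
#' \code{rcAttr} (2.5 sigma); pairs restricted to excluded volume use a
#' WCA cutoff \code{rcRep} = 2^(1/6) sigma. \code{Rc} is the radius of the
#' spherical nuclear confinement, \code{ks} the harmonic bond constant
#' (kBT/sigma^2), and \code{kBend} the angle stiffness giving the chain its
#' persistence length (kBend = lp/sigma).
#'
#' @slot sigma bead diameter, the length unit (dimensionless 1 in reduced units)
#' @slot kBT thermal energy, the energy unit
#' @slot ks bond spring constant (kBT/sigma^2)
#' @slot rcAttr attractive LJ cutoff (sigma)
#' @slot rcRep repulsive-only (WCA) cutoff, 2^(1/6) sigma
#' @slot Rc confinement radius (sigma)
#' @slot dt integration timestep (reduced time)
#' @slot gamma Langevin friction coefficient (reduced)
#' @slot mass bead mass (reduced)
#' @slot kBend angle stiffness (kBT)
#' @slot nSteps default number of integration steps
#' @slot seed RNG seed
#' @export
setClass("SimulationParameters",
  slots = c(
    sigma = "numeric", kBT = "numeric", ks = "numeric", rcAttr = "numeric",
    rcRep = "numeric", Rc = "numeric", dt = "numeric", gamma = "numeric",
    mass = "numeric", kBend = "numeric", nSteps = "integer", seed = "integer"
  )
)

setValidity("SimulationParameters", function(object) {
  msg <- character()
  num <- c(
    sigma = object@sigma, kBT = object@kBT, ks = object@ks,
    rcAttr = object@rcAttr, rcRep = object@rcRep, Rc = object@Rc,
    dt = object@dt, gamma = object@gamma, mass = object@mass
  )
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad)) {
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  }
  if (object@kBend < 0) msg <- c(msg, "kBend must be >= 0")
  if (object@rcRep >= object@rcAttr) msg <- c(msg, "rcRep must be < rcAttr")
  if (abs(object@rcRep - 2^(1 / 6)) > 1e-12) {
    msg <- c(msg, "rcRep must equal 2^(1/6) (the WCA minimum)")
  }
  if (object@dt > 0.01) {
    msg <- c(msg, "dt exceeds the stability bound (dt <= 0.01 reduced units)")
  }
  if (length(msg)) msg else TRUE
})

#' Symmetric species-pair interaction map
#'
#' Holds the pairwise attraction strength epsilon (kBT) and the pair mode for
#' every unordered pair of the four species H, rD, F, X. Pairs in mode
#' \code{"attractive"} interact through the full 12-6 LJ potential truncated
#' at 2.5 sigma; pairs in mode \code{"excluded_volume"} interact through a
#' purely repulsive WCA potential with epsilon = 1 kBT.
#'
#' @slot species the species labels (always H, rD, F, X)
#' @slot epsilon symmetric 4x4 numeric matrix of attraction strengths (kBT)
#' @slot mode symmetric 4x4 character matrix, "attractive" or "excluded_volume"
#' @export
setClass("InteractionMatrix",
  slots = c(species = "character", epsilon = "matrix", mode = "character")
)

setValidity("InteractionMatrix", function(object) {
  msg <- character()
  ns <- length(object@species)
  if (!identical(object@species, SPECIES)) {
    msg <- c(msg, "species must be H, rD, F, X")
  }
  e <- object@epsilon
  if (!is.numeric(e) || !identical(dim(e), c(ns, ns))) {
    msg <- c(msg, "epsilon must be a numeric 4x4 matrix")
  } else {
    if (any(e < 0)) msg <- c(msg, "epsilon values must be >= 0")
    if (!isTRUE(all.equal(e, t(e), tolerance = 0))) {
      msg <- c(msg, "epsilon must be symmetric")
    }
  }
  m <- object@mode
  if (length(m) != ns * ns ||
      !all(m %in% c("attractive", "excluded_volume"))) {
    msg <- c(msg, "mode must be 'attractive' or 'excluded_volume' per pair")
  } else {
    mm <- matrix(m, ns, ns)
    if (!identical(mm, t(mm))) msg <- c(msg, "mode must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Genome-scale bookkeeping for the confinement calculation
#'
#' Converts a genome size into a bead count (one bead per \code{bpPerBead}
#' base pairs) and stores the chromatin volume fraction \code{phi} used to
#' size the spherical confinement.
#'
#' @slot genomeLength genome size in base pairs (diploid)
#' @slot bpPerBead base pairs represented by one bead
#' @slot phi chromatin volume fraction inside the nucleus
#' @export
setClass("GenomeModel",
  slots = c(genomeLength = "numeric", bpPerBead = "numeric", phi = "numeric")
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  if (object@genomeLength <= 0) msg <- c(msg, "genomeLength must be > 0")
  if (object@bpPerBead <= 0) msg <- c(msg, "bpPerBead must be > 0")
  if (object@genomeLength %% object@bpPerBead != 0) {
    msg <- c(msg, "genomeLength must be an exact multiple of bpPerBead")
  }
  if (object@phi <= 0 || object@phi >= 0.64) {
    msg <- c(msg, "phi must lie in (0, 0.64) (random close packing bound)")
  }
  if (length(msg)) msg else TRUE
})

#' Bead topology: species labels, bonds, angles, block annotation
#'
#' The polymer occupies bead indices 1..nPolymer with consecutive harmonic
#' bonds and bending triples; the rDNA block is a single contiguous centred
#' run within the polymer. Free F and X beads follow and carry no bonds.
#'
#' @slot species species label per bead ("H", "rD", "F" or "X")
#' @slot bonds integer matrix (m x 2) of bonded bead index pairs (1-based)
#' @slot angles integer matrix (k x 3) of consecutive bead triples
#' @slot nPolymer number of polymer beads (H + rD)
#' @slot rdRange integer(2): first and last rD bead index, or c(0L, 0L)
#' @export
setClass("Topology",
  slots = c(
    species = "character", bonds = "matrix", angles = "matrix",
    nPolymer = "integer", rdRange = "integer"
  )
)

setValidity("Topology", function(object) {
  msg <- character()
  n <- length(object@species)
  if (!all(object@species %in% SPECIES)) msg <- c(msg, "unknown species label")
  b <- object@bonds
  if (nrow(b) > 0) {
    if (any(b < 1 | b > object@nPolymer)) {
      msg <- c(msg, "bonds must connect polymer beads only")
    }
    if (any(abs(b[, 1] - b[, 2]) != 1)) {
      msg <- c(msg, "bonds must connect consecutive polymer indices")
    }
  }
  if (object@nPolymer > n) msg <- c(msg, "nPolymer exceeds bead count")
  if (any(object@species[seq_len(object@nPolymer)] %in% c("F", "X"))) {
    msg <- c(msg, "polymer beads must be H or rD")
  }
  if (object@rdRange[1] > 0) {
    idx <- object@rdRange[1]:object@rdRange[2]
    if (!all(object@species[idx] == "rD")) {
      msg <- c(msg, "rdRange does not match rD labels")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A bead configuration inside the confinement sphere
#'
#' @slot positions numeric matrix (n x 3) of bead coordinates (sigma)
#' @slot species species label per bead
#' @slot Rc confinement radius (sigma)
#' @slot time simulation time of this configuration (reduced units)
#' @export
setClass("SystemState",
  slots = c(positions = "matrix", species = "character", Rc = "numeric",
            time = "numeric")
)

setValidity("SystemState", function(object) {
  msg <- character()
  if (nrow(object@positions) != length(object@species)) {
    msg <- c(msg, "positions and species lengths differ")
  }
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be n x 3")
  if (nrow(object@positions) > 0) {
    r <- sqrt(rowSums(object@positions^2))
    if (any(r > object@Rc - 0.5 + 1e-9)) {
      msg <- c(msg, "beads must satisfy |r| <= Rc - sigma/2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Time-ordered simulation frames with full provenance
#'
#' @slot frames list of (n x 3) position matrices
#' @slot times simulation time per frame (reduced units)
#' @slot species species label per bead (shared by all frames)
#' @slot Rc confinement radius (sigma)
#' @slot frameInterval steps between saved frames
#' @slot kineticTemp instantaneous kinetic temperature per frame
#' @slot potential potential energy per frame (kBT)
#' @slot provenance list: parameter set, seed, topology summary, code version
#' @export
setClass("Trajectory",
  slots = c(
    frames = "list", times = "numeric", species = "character", Rc = "numeric",
    frameInterval = "integer", kineticTemp = "numeric", potential = "numeric",
    provenance = "list"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@times)) {
    msg <- c(msg, "frames and times lengths differ")
  }
  if (is.unsorted(object@times)) msg <- c(msg, "frames must be time-ordered")
  if (length(msg)) msg else TRUE
})

#' Connected clusters of a bead subset
#'
#' @slot labels integer cluster label per bead (1-based, ordered by lowest
#'   member index)
#' @slot sizes integer vector of cluster sizes, indexed by label
#' @slot largest label of the largest cluster
#' @export
setClass("ClusterSet",
  slots = c(labels = "integer", sizes = "integer", largest = "integer")
)

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (length(object@labels) > 0) {
    if (sum(object@sizes) != length(object@labels)) {
      msg <- c(msg, "sizes must partition the bead subset")
    }
    if (length(object@largest) != 1 ||
        object@sizes[object@largest] < max(object@sizes)) {
      msg <- c(msg, "largest must index a maximal cluster")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-configuration organization classification
#'
#' Captures the quantities used to classify a final configuration:
#' condensation per species, the distance between the PCH and Fibrillarin
#' cluster centres of mass (d_HF), the Fibrillarin/amphiphile distance
#' (d_FX), the fraction of rDNA inside the Fibrillarin condensate, the
#' amphiphile coverage of the Fibrillarin surface, and the layering verdict.
#'
#' @slot condensed named logical: condensation call per species
#' @slot dHF distance between H and F cluster centres of mass (sigma)
#' @slot dFX distance between F and X cluster centres of mass (sigma)
#' @slot rdInteriorFraction fraction of rD beads inside the F condensate
#' @slot xCoverage fraction of F surface beads contacted by X
#' @slot xCoverageVerdict "none", "partial" or "complete"
#' @slot verdict overall organization: "layered", "partial_wetting",
#'   "dissociated", "neocondensate_in_H" or "none"
#' @slot radialMedians named numeric: median radial distance of F, X, H beads
#'   about the reference condensate centre
#' @slot flags character vector of caveats (e.g. species uncondensed)
#' @export
setClass("OrganizationReport",
  slots = c(
    condensed = "logical", dHF = "numeric", dFX = "numeric",
    rdInteriorFraction = "numeric", xCoverage = "numeric",
    xCoverageVerdict = "character", verdict = "character",
    radialMedians = "numeric", flags = "character"
  )
)

setValidity("OrganizationReport", function(object) {
  msg <- character()
  fr <- c(object@rdInteriorFraction, object@xCoverage)
  fr <- fr[is.finite(fr)]
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  dd <- c(object@dHF, object@dFX)
  if (any(is.finite(dd) & dd < 0)) msg <- c(msg, "distances must be >= 0")
  ok <- c("layered", "partial_wetting", "dissociated", "neocondensate_in_H",
          "none")
  if (!object@verdict %in% ok) msg <- c(msg, "unknown verdict")
  if (length(msg)) msg else TRUE
})

#' Parameter-sweep result grid
#'
#' @slot axes named list of swept parameter values
#' @slot cells data.frame with one row per (cell, seed) replicate and the
#'   per-cell classification columns
#' @slot thresholds data.frame of derived per-axis thresholds (may be empty)
#' @slot meta list: scale, step counts, seeds, timing
#' @export
setClass("SweepResult",
  slots = c(axes = "list", cells = "data.frame", thresholds = "data.frame",
            meta = "list")
)

#' Multi-channel 3D intensity volume
#'
#' @slot channels named list of 3D (or 2D) numeric arrays, all same shape
#' @slot voxelSize physical voxel size per axis (micrometres)
#' @export
setClass("VoxelImage",
  slots = c(channels = "list", voxelSize = "numeric")
)

setValidity("VoxelImage", function(object) {
  msg <- character()
  if (length(object@channels) == 0) msg <- c(msg, "at least one channel")
  dims <- lapply(object@channels, dim)
  if (length(unique(lapply(dims, as.integer))) > 1) {
    msg <- c(msg, "all channels must share the same shape")
  }
  if (is.null(names(object@channels)) || any(names(object@channels) == "")) {
    msg <- c(msg, "channels must be named")
  }
  if (any(object@voxelSize <= 0)) msg <- c(msg, "voxel sizes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Labeled segmentation of one channel
#'
#' @slot labels integer array of object labels (0 = background, labels dense
#'   from 1)
#' @slot objects data.frame: label, voxels, centroid (voxel coordinates),
#'   bounding box
#' @slot voxelSize physical voxel size per axis (micrometres)
#' @slot channel name of the segmented channel
#' @slot threshold the intensity threshold that produced the masks
#' @export
setClass("SegmentedObjects",
  slots = c(labels = "array", objects = "data.frame", voxelSize = "numeric",
            channel = "character", threshold = "numeric")
)

setValidity("SegmentedObjects", function(object) {
  msg <- character()
  labs <- object@objects$label
  if (length(labs) && !all(sort(labs) == seq_along(labs))) {
    msg <- c(msg, "labels must be dense from 1")
  }
  if (length(msg)) msg else TRUE
})
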