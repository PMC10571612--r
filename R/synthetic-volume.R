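#' @include AllClasses.R AllGenerics.R imaging.R
NULL

## seed scoping helper: set the RNG for the call, restore afterwards
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic nucleus volume with known ground truth
#'
#' Renders a two- or three-channel 3D volume emulating the observed
#' PCH-nucleolus organizations, alongside the exact ground-truth masks:
#' \describe{
#'   \item{surrounded}{a central nucleolus sphere tightly enclosed by a PCH
#'     shell (the canonical wild-type configuration);}
#'   \item{extended}{PCH as an elongated ellipsoid at the nuclear edge
#'     (controllable in-plane aspect ratio), nucleolus apart from it;}
#'   \item{compact}{PCH as a compact ball, nucleolus a separate sphere;}
#'   \item{void}{a hollow PCH shell whose core is devoid of PCH but filled by
#'     a distinct protein channel (the amphiphile neocondensate in the PCH
#'     void).}
#' }
#' Intensities are rendered on a dim nuclear background and degraded with
#' additive Gaussian noise of standard deviation \code{noise} times the
#' foreground amplitude.
#'
#' @param organization one of "surrounded", "extended", "compact", "void"
#' @param dim voxel grid dimensions (default 64 x 64 x 64)
#' @param voxelSize micrometres per voxel, per axis
#' @param nucleusRadius nuclear radius (voxels)
#' @param nucleolusRadius nucleolus radius (voxels)
#' @param shellThickness PCH shell thickness (voxels; surrounded/void)
#' @param aspectRatio in-plane major/minor axis ratio of the extended PCH
#' @param noise relative noise level (0 = noise free)
#' @param intensity foreground amplitude (arbitrary units)
#' @param background background amplitude inside the nucleus
#' @param seed RNG seed (noise reproducibility)
#' @return list: \code{image} (\linkS4class{VoxelImage} with channels "fib",
#'   "hp1a" and, for "void", "protein"), \code{truth} (list of logical
#'   ground-truth arrays: nucleolus, pch, and core for "void"),
#'   \code{params} (the geometry actually used)
#' @examples
#' g <- generateNucleusVolume("surrounded", dim = c(32, 32, 32), noise = 0)
#' channelNames(g$image)
#' @export
generateNucleusVolume <- function(organization = c("surrounded", "extended",
                                                   "compact", "void"),
                                  dim = c(64, 64, 64),
                                  voxelSize = c(0.1, 0.1, 0.1),
                                  nucleusRadius = min(dim) * 0.45,
                                  nucleolusRadius = min(dim) * 0.14,
                                  shellThickness = max(2, round(min(dim) * 0.06)),
                                  aspectRatio = 2,
                                  noise = 0.05, intensity = 200,
                                  background = 10, seed = 1L) {
  organization <- match.arg(organization)
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  ctr <- (dim + 1) / 2

  xs <- (seq_len(nx) - ctr[1])
  ys <- (seq_len(ny) - ctr[2])
  zs <- (seq_len(nz) - ctr[3])
  X <- array(rep(xs, times = ny * nz), dim)
  Y <- array(rep(rep(ys, each = nx), times = nz), dim)
  Z <- array(rep(zs, each = nx * ny), dim)

  sphere <- function(centre, radius) {
    (X - centre[1])^2 + (Y - centre[2])^2 + (Z - centre[3])^2 <= radius^2
  }
  ellipsoid <- function(centre, ax, ay, az) {
    ((X - centre[1]) / ax)^2 + ((Y - centre[2]) / ay)^2 +
      ((Z - centre[3]) / az)^2 <= 1
  }

  nucleus <- sphere(c(0, 0, 0), nucleusRadius)

  truth <- list()
  if (organization == "surrounded") {
    if (nucleolusRadius + shellThickness >= nucleusRadius) {
      stop("impossible geometry: shell does not fit inside the nucleus")
    }
    truth$nucleolus <- sphere(c(0, 0, 0), nucleolusRadius)
    truth$pch <- sphere(c(0, 0, 0), nucleolusRadius + shellThickness) &
      !truth$nucleolus
  } else if (organization == "extended") {
    minor <- nucleolusRadius
    major <- aspectRatio * minor
    off <- nucleusRadius - minor - 1
    if (major >= nucleusRadius || off <= 0) {
      stop("impossible geometry: extended PCH does not fit")
    }
    # elongated in x, flattened in y, hugging the nuclear edge along +y
    truth$pch <- ellipsoid(c(0, off, 0), major, minor, minor) & nucleus
    truth$nucleolus <- sphere(c(0, -nucleusRadius / 2, 0), nucleolusRadius)
  } else if (organization == "compact") {
    gapCentre <- nucleusRadius / 2
    if (nucleolusRadius >= gapCentre) {
      stop("impossible geometry: compact ball overlaps the nucleolus")
    }
    truth$pch <- sphere(c(0, gapCentre, 0), nucleolusRadius * 1.3)
    truth$nucleolus <- sphere(c(0, -gapCentre, 0), nucleolusRadius)
  } else { # void
    inner <- nucleolusRadius
    outer <- inner + shellThickness
    if (outer >= nucleusRadius) {
      stop("impossible geometry: PCH shell does not fit inside the nucleus")
    }
    truth$core <- sphere(c(0, 0, 0), inner)
    truth$pch <- sphere(c(0, 0, 0), outer) & !truth$core
    truth$nucleolus <- sphere(c(nucleusRadius / 2 + inner / 2, 0, 0),
                              nucleolusRadius * 0.8) & nucleus
  }

  render <- function(mask, amp) {
    img <- array(0, dim)
    img[nucleus] <- background
    img[mask] <- amp
    img
  }
  channels <- list(
    fib = render(truth$nucleolus, intensity),
    hp1a = render(truth$pch, intensity * 0.9)
  )
  if (organization == "void") {
    channels$protein <- render(truth$core, intensity * 0.8)
  }

  if (noise > 0) {
    channels <- withSeed(seed, lapply(channels, function(img) {
      pmax(img + stats::rnorm(length(img), sd = noise * intensity), 0)
    }))
    channels <- lapply(channels, function(v) array(v, dim))
  }

  list(
    image = VoxelImage(channels, voxelSize = voxelSize),
    truth = truth,
    params = list(
      organization = organization, dim = dim, voxelSize = voxelSize,
      nucleusRadius = nucleusRadius, nucleolusRadius = nucleolusRadius,
      shellThickness = shellThickness, aspectRatio = aspectRatio,
      noise = noise, intensity = intensity, background = background,
      seed = seed
    )
  )
}

#' Synthetic time series with photobleaching decay
#'
#' Repeats a synthetic nucleus volume over \code{nTime} timepoints with the
#' foreground intensity decaying as exp(-bleachRate * t) (t = 0, 1, ...) and
#' fresh noise per frame, emulating a photobleaching live-imaging series.
#'
#' @param nTime number of timepoints
#' @param bleachRate exponential decay rate per frame
#' @param ... passed to \code{\link{generateNucleusVolume}}
#' @param seed base RNG seed (frame t uses seed + t)
#' @return list of \linkS4class{VoxelImage}; the first frame's ground truth
#'   is attached as attribute \code{truth}
#' @export
generateNucleusTimeseries <- function(nTime = 5L, bleachRate = 0.1, ...,
                                      seed = 1L) {
  args <- list(...)
  frames <- lapply(seq_len(nTime) - 1L, function(t) {
    a <- args
    a$intensity <- (a$intensity %||% 200) * exp(-bleachRate * t)
    a$seed <- seed + t
    do.call(generateNucleusVolume, a)
  })
  out <- lapply(frames, `[[`, "image")
  attr(out, "truth") <- frames[[1]]$truth
  out
}
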