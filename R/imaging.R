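#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a multi-channel voxel image
#'
#' @param channels named list of 2D or 3D numeric arrays (equal shapes)
#' @param voxelSize physical voxel size per axis in micrometres (recycled to
#'   the array dimensionality)
#' @return a \linkS4class{VoxelImage}
#' @export
VoxelImage <- function(channels, voxelSize = c(0.1, 0.1, 0.1)) {
  ndim <- length(dim(channels[[1]]))
  voxelSize <- rep_len(voxelSize, ndim)
  new("VoxelImage", channels = channels, voxelSize = voxelSize)
}

#' Otsu threshold from the between-class-variance criterion
#'
#' Builds a histogram over \code{levels} bins spanning the intensity range
#' and returns the threshold maximizing the between-class variance
#' omega0 * omega1 * (mu0 - mu1)^2 over all candidate cuts.
#'
#' @param x numeric vector or array of intensities
#' @param levels number of histogram bins (default 256)
#' @return the threshold on the intensity scale (voxels strictly above it are
#'   foreground)
#' @export
otsuThreshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) stop("degenerate histogram: constant image")
  h <- tabulate(
    pmin(levels, 1L + as.integer((x - rng[1]) / diff(rng) * levels)),
    nbins = levels
  )
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[levels]
  # between-class variance for a cut after bin k
  bcv <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-levels])
  rng[1] + k / levels * diff(rng)
}

#' Yen threshold from the maximum-correlation criterion
#'
#' Yen's automatic threshold maximizes the criterion
#' -log(P0 * P1) - 2 log(G0 * G1) where P and G are the cumulative sums of
#' the histogram probabilities and squared probabilities below/above the cut.
#'
#' @inheritParams otsuThreshold
#' @return the threshold on the intensity scale
#' @export
yenThreshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) stop("degenerate histogram: constant image")
  h <- tabulate(
    pmin(levels, 1L + as.integer((x - rng[1]) / diff(rng) * levels)),
    nbins = levels
  )
  p <- h / sum(h)
  P0 <- cumsum(p)
  G0 <- cumsum(p^2)
  GT <- G0[levels]
  crit <- vapply(seq_len(levels - 1L), function(k) {
    p0 <- P0[k]
    p1 <- 1 - p0
    g0 <- G0[k]
    g1 <- GT - g0
    if (p0 <= 0 || p1 <= 0 || g0 <= 0 || g1 <= 0) return(-Inf)
    -log(g0 * g1) + 2 * log(p0 * p1)
  }, numeric(1))
  k <- which.max(crit)
  rng[1] + k / levels * diff(rng)
}

## background subtraction: grayscale opening with a cube structuring element
## of half-width `radius` (a rolling-ball-style background estimate), clamped
## at zero after subtraction.
subtractBackground <- function(img, radius) {
  if (is.null(radius) || radius <= 0) return(img)
  d <- dim(img)
  bg <- box_max_cpp(box_min_cpp(as.numeric(img), d, as.integer(radius)),
                    d, as.integer(radius))
  out <- pmax(img - array(bg, d), 0)
  array(out, d)
}

#' Segment one channel by histogram thresholding
#'
#' Preprocessing (background subtraction with a cube opening of half-width
#' \code{backgroundRadius}, then Gaussian smoothing with \code{gaussianSigma})
#' followed by Otsu, Yen or fixed thresholding and connected-component
#' labeling (26-connectivity in 3D, 8 in 2D).
#'
#' @param image a \linkS4class{VoxelImage}
#' @param channel channel name
#' @param method "otsu", "yen" or "fixed"
#' @param backgroundRadius half-width (voxels) of the background opening;
#'   0 disables
#' @param gaussianSigma Gaussian smoothing sigma (voxels); 0 disables
#' @param fixedThreshold threshold for \code{method = "fixed"}
#' @param minVoxels discard objects smaller than this (default 1 = keep all)
#' @return a \linkS4class{SegmentedObjects}
#' @export
segmentChannel <- function(image, channel, method = c("otsu", "yen", "fixed"),
                           backgroundRadius = 0, gaussianSigma = 0,
                           fixedThreshold = NULL, minVoxels = 1L) {
  method <- match.arg(method)
  img <- getChannel(image, channel)
  img <- subtractBackground(img, backgroundRadius)
  if (gaussianSigma > 0) {
    img <- array(gaussian_blur_cpp(as.numeric(img), dim(img), gaussianSigma),
                 dim(img))
  }
  thr <- switch(method,
    otsu = otsuThreshold(img),
    yen = yenThreshold(img),
    fixed = {
      if (is.null(fixedThreshold)) stop("fixedThreshold required")
      fixedThreshold
    }
  )
  mask <- img > thr
  segmentMask(mask, voxelSize = voxelSize(image), channel = channel,
              threshold = thr, minVoxels = minVoxels)
}

#' @rdname segmentChannel
#' @param mask logical/0-1 array to label directly (bypasses thresholding;
#'   used for ground-truth masks)
#' @param voxelSize physical voxel size per axis (micrometres)
#' @param threshold recorded threshold value
#' @export
segmentMask <- function(mask, voxelSize = c(0.1, 0.1, 0.1),
                        channel = "mask", threshold = NA_real_,
                        minVoxels = 1L) {
  d <- dim(mask)
  voxelSize <- rep_len(voxelSize, length(d))
  labels <- label_components_cpp(as.integer(mask != 0), d)
  tab <- objectStats(labels, d, minVoxels)
  labels <- tab$labels
  new("SegmentedObjects",
    labels = array(labels, d), objects = tab$objects, voxelSize = voxelSize,
    channel = channel, threshold = as.numeric(threshold)
  )
}

## per-object voxel count, centroid (centre of geometry, voxel coordinates)
## and bounding box; small objects dropped and labels renumbered densely
objectStats <- function(labels, d, minVoxels = 1L) {
  n <- max(labels, 0L)
  if (n == 0) {
    return(list(labels = labels, objects = data.frame(
      label = integer(), voxels = integer(), cx = numeric(), cy = numeric(),
      cz = numeric()
    )))
  }
  sizes <- tabulate(labels[labels > 0], nbins = n)
  keep <- which(sizes >= minVoxels)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  labels <- ifelse(labels > 0, remap[labels], 0L)
  idx <- which(labels > 0)
  lab <- labels[idx]
  coords <- arrayInd(idx, d)
  if (ncol(coords) == 2) coords <- cbind(coords, 1L)
  objects <- data.frame(
    label = seq_along(keep),
    voxels = as.integer(sizes[keep]),
    cx = as.numeric(tapply(coords[, 1], lab, mean)),
    cy = as.numeric(tapply(coords[, 2], lab, mean)),
    cz = as.numeric(tapply(coords[, 3], lab, mean))
  )
  list(labels = as.integer(labels), objects = objects)
}

#' Shell occupancy around a segmented object
#'
#' Dilates the nucleolus mask by \code{dilationPx} (discrete ball structuring
#' element), subtracts the original to obtain a shell, and returns the
#' fraction of shell voxels overlapped by the target segmentation: the
#' fraction of the nucleolar edge occupied by the target channel.
#'
#' @param nucleolus a \linkS4class{SegmentedObjects} (the dilated object)
#' @param target a \linkS4class{SegmentedObjects} sharing the same grid
#' @param dilationPx shell thickness in voxels (>= 1)
#' @return occupancy fraction in [0, 1]
#' @export
shellOccupancy <- function(nucleolus, target, dilationPx = 1L) {
  stopifnot(dilationPx >= 1)
  nMask <- labelArray(nucleolus) > 0
  if (!any(nMask)) stop("undefined occupancy: empty nucleolus mask")
  d <- dim(nMask)
  if (!identical(d, dim(labelArray(target)))) stop("masks must share geometry")
  dil <- array(dilate_ball_cpp(as.integer(nMask), d, as.integer(dilationPx)),
               d) > 0
  shell <- dil & !nMask
  tMask <- labelArray(target) > 0
  sum(shell & tMask) / sum(shell)
}

#' Nearest-object distances between two segmentations
#'
#' For every object in A, the Euclidean distance from its centre of geometry
#' to the nearest B-object centre, in physical units (anisotropic voxel sizes
#' applied).
#'
#' @param objectsA,objectsB \linkS4class{SegmentedObjects}
#' @return data.frame: label, nearest B label, distance (micrometres); an
#'   empty-B input yields an empty result with a \code{flag} attribute
#' @export
nearestObjectDistance <- function(objectsA, objectsB) {
  a <- objectTable(objectsA)
  b <- objectTable(objectsB)
  if (nrow(a) == 0) stop("no objects in A")
  vs <- rep_len(voxelSize(objectsA), 3)
  if (nrow(b) == 0) {
    out <- data.frame(label = integer(), nearest = integer(),
                      distance = numeric())
    attr(out, "flag") <- "no objects in B"
    return(out)
  }
  am <- cbind(a$cx * vs[1], a$cy * vs[2], a$cz * vs[3])
  bm <- cbind(b$cx * vs[1], b$cy * vs[2], b$cz * vs[3])
  res <- t(vapply(seq_len(nrow(am)), function(i) {
    d2 <- (bm[, 1] - am[i, 1])^2 + (bm[, 2] - am[i, 2])^2 +
      (bm[, 3] - am[i, 3])^2
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, numeric(2)))
  data.frame(label = a$label, nearest = b$label[res[, 1]],
             distance = res[, 2])
}

#' Aspect ratio of a 2D mask
#'
#' Ratio of the major to minor axis of the moment-equivalent ellipse of the
#' mask (central second moments, 0.5-pixel floor on the minor axis to handle
#' degenerate collinear masks, flagged).
#'
#' @param mask 2D logical/0-1 matrix (apply a max projection upstream for
#'   volumes)
#' @return list: \code{ratio} (>= 1), \code{major}, \code{minor} (pixels),
#'   \code{flagged}
#' @export
aspectRatio2D <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  ctr <- colMeans(idx)
  xc <- idx[, 1] - ctr[1]
  yc <- idx[, 2] - ctr[2]
  # second moments of the pixel set (+1/12 per-pixel term for unit squares)
  mxx <- mean(xc^2) + 1 / 12
  myy <- mean(yc^2) + 1 / 12
  mxy <- mean(xc * yc)
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
  # ellipse with matching moments: semi-axis = 2 sqrt(lambda)
  major <- 2 * sqrt(max(ev[1], 0))
  minor <- 2 * sqrt(max(ev[2], 0))
  # a collinear mask reduces to the single-pixel width 2 sqrt(1/12) = 0.577;
  # floor there and flag
  onePx <- 2 * sqrt(1 / 12)
  flagged <- minor <= onePx + 1e-9
  minor <- max(minor, onePx)
  list(ratio = major / minor, major = major, minor = minor, flagged = flagged)
}

#' Crofton-style perimeter of a 2D mask
#'
#' Multi-direction Crofton estimator: intercept counts along the horizontal,
#' vertical and two diagonal directions, combined with the standard 4-direction
#' weights. Circularity values depend on the perimeter estimator, so the
#' estimator is fixed and documented here.
#'
#' @param mask 2D logical/0-1 matrix
#' @return perimeter estimate in pixel units
#' @export
croftonPerimeter <- function(mask) {
  m <- (mask != 0) * 1L
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  # intercepts (0-1 transitions) along each direction
  nH <- sum(abs(pad[, -1] - pad[, -(nc + 2L)]))
  nV <- sum(abs(pad[-1, ] - pad[-(nr + 2L), ]))
  d1 <- sum(abs(pad[-1, -1] - pad[-(nr + 2L), -(nc + 2L)]))
  d2 <- sum(abs(pad[-1, -(nc + 2L)] - pad[-(nr + 2L), -1]))
  # Crofton with 4 directions: P = pi/4 * sum_d (intercepts_d * spacing_d) / 2
  (pi / 4) * (nH + nV + (d1 + d2) / sqrt(2)) / 2
}

#' Area, circularity and normalized intensity over time
#'
#' For a time series of images: per timepoint, the channel is max-projected
#' (if 3D), preprocessed, thresholded (Yen by default) and the largest
#' segment measured: area (pixels scaled by pixel area), circularity
#' 4 pi area / perimeter^2 (Crofton perimeter), and mean intensity within the
#' segment. The intensity trace is divided by its value at the first
#' timepoint (first value exactly 1). Timepoints where the segment vanishes
#' are recorded as gaps (NA), never interpolated.
#'
#' @param images list of \linkS4class{VoxelImage} over time (consistent
#'   geometry)
#' @param channel channel name
#' @param method threshold method (default "yen")
#' @param backgroundRadius,gaussianSigma preprocessing, as in
#'   \code{\link{segmentChannel}}
#' @return data.frame: time index, area (square micrometres), circularity,
#'   meanIntensity (raw), normIntensity (relative to T = 0)
#' @export
objectTimeseries <- function(images, channel, method = "yen",
                             backgroundRadius = 0, gaussianSigma = 0) {
  stopifnot(length(images) >= 1)
  rows <- lapply(seq_along(images), function(t) {
    im <- images[[t]]
    img <- getChannel(im, channel)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
    proc <- subtractBackground(img, backgroundRadius)
    if (gaussianSigma > 0) {
      proc <- array(gaussian_blur_cpp(as.numeric(proc), dim(proc),
                                      gaussianSigma), dim(proc))
    }
    thr <- tryCatch(
      switch(method, otsu = otsuThreshold(proc), yen = yenThreshold(proc),
             stop("unknown method")),
      error = function(e) NA_real_
    )
    if (is.na(thr)) {
      return(data.frame(time = t, area = NA_real_, circularity = NA_real_,
                        meanIntensity = NA_real_))
    }
    mask <- proc > thr
    labs <- array(label_components_cpp(as.integer(mask), dim(mask)),
                  dim(mask))
    if (max(labs) == 0) {
      return(data.frame(time = t, area = NA_real_, circularity = NA_real_,
                        meanIntensity = NA_real_))
    }
    sizes <- tabulate(labs[labs > 0])
    big <- which.max(sizes)
    seg <- labs == big
    vs <- rep_len(voxelSize(im), 2)
    perim <- croftonPerimeter(seg)
    data.frame(
      time = t,
      area = sum(seg) * vs[1] * vs[2],
      circularity = 4 * pi * sum(seg) / perim^2,
      meanIntensity = mean(img[seg])
    )
  })
  out <- do.call(rbind, rows)
  ref <- out$meanIntensity[1]
  out$normIntensity <- if (is.finite(ref) && ref > 0) {
    out$meanIntensity / ref
  } else {
    NA_real_
  }
  out
}

#' Normalized intensity line profile
#'
#' Samples each requested channel along the segment between two endpoints
#' (bilinear interpolation in-plane; for 3D images a z slice is selected by
#' the endpoints' third coordinate) and scales each channel's trace
#' independently so its maximum is exactly 1. A zero-intensity profile is
#' returned unscaled with a flag.
#'
#' @param image a \linkS4class{VoxelImage}
#' @param from,to endpoints in voxel coordinates (length 2 or 3)
#' @param channels channel names (default: all)
#' @param n number of samples along the line
#' @return data.frame with \code{position} (micrometres along the line) and
#'   one normalized column per channel; attribute \code{flag} lists channels
#'   returned unscaled
#' @export
lineProfile <- function(image, from, to, channels = channelNames(image),
                        n = 100L) {
  d <- dim(getChannel(image, channels[1]))
  ndim <- length(d)
  if (length(from) < 2 || length(to) < 2) stop("endpoints need >= 2 coords")
  checkInside <- function(p) {
    all(p[1:2] >= 1) && p[1] <= d[1] && p[2] <= d[2]
  }
  if (!checkInside(from) || !checkInside(to)) {
    stop("endpoints must lie inside the image")
  }
  t <- seq(0, 1, length.out = n)
  xs <- from[1] + t * (to[1] - from[1])
  ys <- from[2] + t * (to[2] - from[2])
  z <- if (ndim == 3) as.integer(round(if (length(from) >= 3) from[3] else 1)) else NULL
  bilinear <- function(img, x, y) {
    x0 <- pmax(1L, pmin(dim(img)[1] - 1L, floor(x)))
    y0 <- pmax(1L, pmin(dim(img)[2] - 1L, floor(y)))
    fx <- x - x0
    fy <- y - y0
    i00 <- img[cbind(x0, y0)]
    i10 <- img[cbind(x0 + 1L, y0)]
    i01 <- img[cbind(x0, y0 + 1L)]
    i11 <- img[cbind(x0 + 1L, y0 + 1L)]
    i00 * (1 - fx) * (1 - fy) + i10 * fx * (1 - fy) +
      i01 * (1 - fx) * fy + i11 * fx * fy
  }
  vs <- voxelSize(image)
  pos <- sqrt(((xs - xs[1]) * vs[1])^2 + ((ys - ys[1]) * vs[2])^2)
  out <- data.frame(position = pos)
  flagged <- character()
  for (ch in channels) {
    img <- getChannel(image, ch)
    if (ndim == 3) img <- img[, , z]
    tr <- bilinear(img, xs, ys)
    mx <- max(tr)
    if (mx > 0) {
      tr <- tr / mx
    } else {
      flagged <- c(flagged, ch)
    }
    out[[ch]] <- tr
  }
  attr(out, "flag") <- flagged
  out
}

#' Object volumes in physical units
#'
#' Voxel count times voxel volume, per labeled object.
#'
#' @param objects a \linkS4class{SegmentedObjects}
#' @return named numeric vector of volumes (cubic micrometres), one entry per
#'   object label
#' @export
objectVolume <- function(objects) {
  tab <- objectTable(objects)
  vs <- rep_len(voxelSize(objects), 3)
  out <- tab$voxels * prod(vs)
  names(out) <- tab$label
  out
}
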