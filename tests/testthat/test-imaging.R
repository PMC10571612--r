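rasterDisk <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xx <- matrix(seq_len(n), n, n)
  yy <- t(xx)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

test_that("Otsu threshold maximizes between-class variance (exhaustive oracle)", {
  # two-level image: threshold falls strictly between the levels
  img <- array(10, c(12, 12, 4))
  img[3:5, 3:5, 2] <- 200
  img[8:10, 8:10, 3] <- 200
  thr <- otsuThreshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # exhaustive maximization over all 256 histogram cuts, independent code
  set.seed(1)
  x <- c(rnorm(4000, 40, 12), rnorm(1500, 160, 25))
  got <- otsuThreshold(x, levels = 256L)
  rng <- range(x)
  h <- tabulate(pmin(256L, 1L + as.integer((x - rng[1]) / diff(rng) * 256)),
                nbins = 256L)
  mids <- rng[1] + (seq_len(256) - 0.5) / 256 * diff(rng)
  best <- -Inf
  bestK <- NA
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      bestK <- k
    }
  }
  oracle <- rng[1] + bestK / 256 * diff(rng)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("Yen threshold maximizes its criterion and separates modes", {
  set.seed(2)
  x <- c(rnorm(5000, 30, 8), rnorm(800, 180, 20))
  thr <- yenThreshold(x)
  # classifies both modes almost perfectly
  expect_gt(mean(x[1:5000] <= thr), 0.95)
  expect_gt(mean(x[5001:5800] > thr), 0.95)
  # exhaustive maximization of the Yen criterion, independent code
  rng <- range(x)
  h <- tabulate(pmin(256L, 1L + as.integer((x - rng[1]) / diff(rng) * 256)),
                nbins = 256L)
  p <- h / sum(h)
  best <- -Inf
  bestK <- NA
  for (k in 1:255) {
    p0 <- sum(p[1:k]); p1 <- 1 - p0
    g0 <- sum(p[1:k]^2); g1 <- sum(p[(k + 1):256]^2)
    if (p0 <= 0 || p1 <= 0 || g0 <= 0 || g1 <= 0) next
    crit <- -log(g0 * g1) + 2 * log(p0 * p1)
    if (crit > best) {
      best <- crit
      bestK <- k
    }
  }
  expect_equal(thr, rng[1] + bestK / 256 * diff(rng), tolerance = 1e-12)
  expect_error(yenThreshold(rep(5, 100)), "degenerate")
  expect_error(otsuThreshold(rep(5, 100)), "degenerate")
})

test_that("segmentation labels connected components in 3D", {
  img <- array(5, c(24, 24, 24))
  sph <- function(c0, r) {
    idx <- as.matrix(expand.grid(x = 1:24, y = 1:24, z = 1:24))
    m <- rowSums(sweep(idx, 2, c0)^2) <= r^2
    array(m, c(24, 24, 24))
  }
  img[sph(c(7, 7, 7), 3)] <- 200
  img[sph(c(17, 17, 17), 3)] <- 200
  vi <- VoxelImage(list(fib = img), voxelSize = c(0.1, 0.1, 0.1))
  seg <- segmentChannel(vi, "fib", method = "otsu")
  expect_equal(nrow(objectTable(seg)), 2)
  expect_gt(seg@threshold, 5)
  expect_lt(seg@threshold, 200)
  # 26-connectivity agrees with an R breadth-first oracle on random masks
  set.seed(3)
  m <- array(runif(8 * 8 * 8) < 0.3, c(8, 8, 8))
  labs <- nucleopch:::label_components_cpp(as.integer(m), dim(m))
  # oracle: flood fill over 26-neighborhoods
  oracleLabs <- array(0L, dim(m))
  nxt <- 0L
  coords <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(coords))) {
    p <- coords[i, ]
    if (oracleLabs[p[1], p[2], p[3]] > 0) next
    nxt <- nxt + 1L
    queue <- list(p)
    oracleLabs[p[1], p[2], p[3]] <- nxt
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        v <- q + c(dx, dy, dz)
        if (any(v < 1) || any(v > 8)) next
        if (m[v[1], v[2], v[3]] && oracleLabs[v[1], v[2], v[3]] == 0) {
          oracleLabs[v[1], v[2], v[3]] <- nxt
          queue <- c(queue, list(v))
        }
      }
    }
  }
  # same partition (label names may differ)
  got <- array(labs, dim(m))
  expect_equal(length(unique(got[m])), length(unique(oracleLabs[m])))
  tab <- table(got[m], oracleLabs[m])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("shell occupancy measures coverage of the nucleolar edge", {
  d <- c(28, 28, 28)
  idx <- as.matrix(expand.grid(x = 1:28, y = 1:28, z = 1:28))
  ctr <- c(14, 14, 14)
  r2 <- rowSums(sweep(idx, 2, ctr)^2)
  nucMask <- array(r2 <= 6^2, d)
  nuc <- segmentMask(nucMask)
  # target covering everything outside the nucleolus: occupancy 1
  everywhere <- segmentMask(array(!nucMask, d))
  expect_equal(shellOccupancy(nuc, everywhere, 1), 1)
  # disjoint target: occupancy 0
  corner <- array(FALSE, d)
  corner[1:3, 1:3, 1:3] <- TRUE
  expect_equal(shellOccupancy(nuc, segmentMask(corner), 1), 0)
  # hemispherical target (x above centre): occupancy ~ 0.5 by symmetry,
  # cross-checked by direct voxel counting of the dilated shell
  hemi <- array(idx[, 1] > ctr[1], d)
  occ <- shellOccupancy(nuc, segmentMask(hemi), 1)
  dil <- array(nucleopch:::dilate_ball_cpp(as.integer(nucMask), d, 1L), d) > 0
  shell <- dil & !nucMask
  direct <- sum(shell & hemi) / sum(shell)
  expect_equal(occ, direct, tolerance = 1e-12)
  expect_equal(occ, 0.5, tolerance = 0.12) # discretized half-space cut
  # monotone non-decreasing when the target is dilated
  hemiGrow <- array(
    nucleopch:::dilate_ball_cpp(as.integer(hemi), d, 2L), d) > 0
  expect_gte(shellOccupancy(nuc, segmentMask(hemiGrow), 1), occ)
  expect_error(shellOccupancy(segmentMask(array(FALSE, d)), nuc, 1),
               "empty nucleolus")
})

test_that("nearest-object distances use physical units and match brute force", {
  d <- c(30, 30, 8)
  mk <- function(centres) {
    m <- array(FALSE, d)
    for (c0 in centres) m[c0[1] + (-1:1), c0[2] + (-1:1), c0[3]] <- TRUE
    segmentMask(m, voxelSize = c(0.1, 0.1, 0.4))
  }
  a <- mk(list(c(5, 5, 4)))
  expect_equal(nearestObjectDistance(a, a)$distance, 0)
  # 10 voxels apart in x at 0.1 um/voxel = 1 um
  b <- mk(list(c(15, 5, 4)))
  expect_equal(nearestObjectDistance(a, b)$distance, 1.0)
  # anisotropic z spacing is honoured
  cz <- mk(list(c(5, 5, 6)))
  expect_equal(nearestObjectDistance(a, cz)$distance, 2 * 0.4)
  # random many-object case equals the brute-force all-pairs minimum
  set.seed(4)
  centresA <- lapply(1:5, function(i) c(sample(3:27, 2), sample(2:7, 1)))
  centresB <- lapply(1:6, function(i) c(sample(3:27, 2), sample(2:7, 1)))
  A <- mk(centresA)
  B <- mk(centresB)
  got <- nearestObjectDistance(A, B)
  ta <- objectTable(A)
  tb <- objectTable(B)
  vs <- c(0.1, 0.1, 0.4)
  for (i in seq_len(nrow(ta))) {
    dd <- sqrt(((tb$cx - ta$cx[i]) * vs[1])^2 +
               ((tb$cy - ta$cy[i]) * vs[2])^2 +
               ((tb$cz - ta$cz[i]) * vs[3])^2)
    expect_equal(got$distance[i], min(dd), tolerance = 1e-12)
  }
  # empty B: flagged empty result
  emptyB <- segmentMask(array(FALSE, d))
  res <- nearestObjectDistance(a, emptyB)
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "flag"), "no objects")
})

test_that("aspect ratio from the moment-equivalent ellipse", {
  disk <- rasterDisk(101, 35)
  expect_equal(aspectRatio2D(disk)$ratio, 1, tolerance = 0.02)
  # 2:1 ellipse (second-moment oracle: exact ratio 2)
  n <- 121
  xx <- matrix(seq_len(n), n, n)
  yy <- t(xx)
  ell <- ((xx - 61) / 40)^2 + ((yy - 61) / 20)^2 <= 1
  expect_equal(aspectRatio2D(ell)$ratio, 2, tolerance = 0.05 * 2)
  # rotation invariance
  th <- 37 * pi / 180
  xr <- (xx - 61) * cos(th) + (yy - 61) * sin(th)
  yr <- -(xx - 61) * sin(th) + (yy - 61) * cos(th)
  ellR <- (xr / 40)^2 + (yr / 20)^2 <= 1
  expect_equal(aspectRatio2D(ellR)$ratio, aspectRatio2D(ell)$ratio,
               tolerance = 0.02 * 2)
  # degenerate collinear mask: minor axis floored at the one-pixel width
  line <- matrix(FALSE, 20, 20)
  line[5, 3:18] <- TRUE
  deg <- aspectRatio2D(line)
  expect_true(deg$flagged)
  expect_equal(deg$minor, 2 * sqrt(1 / 12), tolerance = 1e-9)
  expect_gt(deg$ratio, 10) # a 16-px line is strongly anisotropic
})

test_that("circularity uses the documented Crofton perimeter estimator", {
  disk <- rasterDisk(101, 35)
  p <- croftonPerimeter(disk)
  expect_equal(p, 2 * pi * 35, tolerance = 0.05 * 2 * pi * 35)
  circDisk <- 4 * pi * sum(disk) / p^2
  expect_equal(circDisk, 1, tolerance = 0.05)
  # axis-aligned square: the estimator gives P = (pi/8)(4 + 8/sqrt(2)) L
  L <- 60
  sq <- matrix(FALSE, 80, 80)
  sq[11:(10 + L), 11:(10 + L)] <- TRUE
  pSq <- croftonPerimeter(sq)
  analytic <- (pi / 8) * (4 * L + 8 * L / sqrt(2))
  expect_equal(pSq, analytic, tolerance = 0.03 * analytic)
  circSq <- 4 * pi * sum(sq) / pSq^2
  expect_equal(circSq, 4 * pi * L^2 / analytic^2, tolerance = 0.05)
})

test_that("object time series: area, circularity and normalized intensity", {
  mkFrame <- function(amp) {
    img <- matrix(8, 60, 60)
    img[rasterDisk(60, 14, 30, 30)] <- amp
    VoxelImage(list(pit = img), voxelSize = c(0.1, 0.1))
  }
  # constant series: normalized intensity all 1
  const <- replicate(4, mkFrame(150), simplify = FALSE)
  ts1 <- objectTimeseries(const, "pit")
  expect_equal(ts1$normIntensity, rep(1, 4), tolerance = 1e-9)
  expect_equal(ts1$circularity, rep(1, 4), tolerance = 0.05)
  expect_equal(ts1$area, rep(sum(rasterDisk(60, 14, 30, 30)) * 0.01, 4),
               tolerance = 0.05)
  # decaying series: first value exactly 1, later values below
  decay <- lapply(c(150, 120, 90), mkFrame)
  ts2 <- objectTimeseries(decay, "pit")
  expect_identical(ts2$normIntensity[1], 1)
  expect_true(all(diff(ts2$normIntensity) < 0))
})

test_that("line profiles are normalized per channel with peaks located", {
  n <- 64
  xx <- matrix(seq_len(n), n, n)
  yy <- t(xx)
  spot <- exp(-((xx - 40)^2 + (yy - 32)^2) / (2 * 4^2))
  flat <- matrix(7, n, n)
  vi <- VoxelImage(list(g = spot, m = flat), voxelSize = c(0.1, 0.1))
  prof <- lineProfile(vi, from = c(10, 32), to = c(60, 32), n = 101)
  expect_equal(max(prof$g), 1)
  expect_equal(max(prof$m), 1)
  expect_true(all(abs(prof$m - 1) < 1e-9)) # constant channel: flat trace
  # Gaussian peak located within one voxel of the analytic centre
  peakX <- 10 + (60 - 10) * (which.max(prof$g) - 1) / 100
  expect_lt(abs(peakX - 40), 1)
  # zero-intensity profile flagged, unscaled
  zero <- VoxelImage(list(z = matrix(0, n, n)), voxelSize = c(0.1, 0.1))
  pz <- lineProfile(zero, c(5, 5), c(20, 20))
  expect_equal(attr(pz, "flag"), "z")
  expect_true(all(pz$z == 0))
  expect_error(lineProfile(vi, c(0, 5), c(20, 20)), "inside")
})

test_that("object volumes are voxel counts times voxel volume", {
  d <- c(30, 30, 30)
  m <- array(FALSE, d)
  m[1:10, 1:10, 1:10] <- TRUE # exactly 1000 voxels
  seg <- segmentMask(m, voxelSize = c(0.1, 0.1, 0.1))
  expect_equal(unname(objectVolume(seg)), 1.0)
  # digitized sphere of radius 10 voxels: (4/3) pi 10^3 voxels within 3%
  idx <- as.matrix(expand.grid(1:30, 1:30, 1:30))
  sph <- array(rowSums(sweep(idx, 2, c(15, 15, 15))^2) <= 10^2, d)
  segS <- segmentMask(sph, voxelSize = c(0.1, 0.1, 0.1))
  expect_equal(unname(objectVolume(segS)), (4 / 3) * pi * 10^3 * 0.001,
               tolerance = 0.03)
})
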