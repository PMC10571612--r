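test_that("cluster finding matches a brute-force connectivity oracle", {
  # all pairs beyond the cutoff: every bead a singleton
  far <- cbind(seq(0, 30, by = 3), 0, 0)
  cs <- findClusters(far, 1.5)
  expect_equal(length(clusterSizes(cs)), nrow(far))
  expect_true(all(clusterSizes(cs) == 1))
  # a chain of beads spaced 1.2 sigma forms one cluster
  chain <- cbind(seq(0, 12, by = 1.2), 0, 0)
  expect_equal(largestClusterFraction(findClusters(chain, 1.5)), 1)
  # randomized oracle comparison (union-find over the full distance matrix)
  for (seed in 1:4) {
    pts <- randomInSphere(300, 6, seed = seed)
    got <- findClusters(pts, 1.5)@labels
    want <- bruteClusters(pts, 1.5)
    expect_identical(as.integer(got), as.integer(want))
  }
  # empty subset
  empty <- findClusters(matrix(numeric(), 0, 3), 1.5)
  expect_equal(length(empty@labels), 0)
})

test_that("condensation calls use the largest-cluster fraction, boundary inclusive", {
  one <- findClusters(ballPositions(30), 1.5)
  expect_true(isCondensed(one)$condensed)
  expect_equal(isCondensed(one)$fraction, 1)
  sing <- findClusters(cbind(seq(0, 57, 3), 0, 0), 1.5)
  expect_false(isCondensed(sing)$condensed)
  expect_equal(isCondensed(sing)$fraction, 1 / 20)
  # fraction exactly 0.5 counts as condensed
  half <- rbind(ballPositions(5), ballPositions(5) + 50)
  cs <- findClusters(half, 1.5)
  expect_equal(isCondensed(cs)$fraction, 0.5)
  expect_true(isCondensed(cs)$condensed)
  expect_error(isCondensed(cs, 0), "nSpecies")
})

test_that("radius of gyration matches the direct formula", {
  expect_equal(radiusOfGyration(matrix(c(3, 4, 5), 1, 3)), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  pts <- randomInSphere(100, 5, seed = 2)
  centred <- sweep(pts, 2, colMeans(pts))
  direct <- sqrt(sum(centred^2) / nrow(pts))
  expect_equal(radiusOfGyration(pts), direct, tolerance = 1e-12)
  expect_error(radiusOfGyration(matrix(numeric(), 0, 3)), "empty")
})

test_that("centre-of-mass distances behave on constructed geometries", {
  pts <- randomInSphere(50, 4, seed = 3)
  expect_equal(comDistance(pts, pts), 0)
  expect_equal(comDistance(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3)), 1)
  # concentric shells share a centre
  sphPoints <- function(n, r, seed) {
    set.seed(seed)
    v <- matrix(rnorm(3 * n), n, 3)
    r * v / sqrt(rowSums(v^2))
  }
  inner <- sphPoints(4000, 2, 4)
  outer <- sphPoints(4000, 5, 5)
  expect_lt(comDistance(inner, outer), 0.2)
  expect_error(comDistance(matrix(numeric(), 0, 3), pts), "empty")
})

test_that("surface coverage classifies wetting of a condensate", {
  # a single F bead surrounded by 12 X beads is completely wetted
  ico <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
    c(1, 1, 0) / sqrt(2), c(-1, 1, 0) / sqrt(2), c(1, -1, 0) / sqrt(2),
    c(-1, -1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2), c(0, -1, 1) / sqrt(2)
  ) * 1.1
  cov <- surfaceCoverage(matrix(0, 1, 3), ico)
  expect_equal(cov$coverage, 1)
  expect_equal(cov$verdict, "complete")
  # no X near any F
  none <- surfaceCoverage(ballPositions(20), ballPositions(10) + 40)
  expect_equal(none$coverage, 0)
  expect_equal(none$verdict, "none")
  expect_equal(surfaceCoverage(ballPositions(5), NULL)$verdict, "none")
  # hemispherical X coat over an F ball: X sits 1 sigma radially outside
  # every upper-half surface bead, so roughly half the surface is covered
  fball <- ballPositions(120)
  d2 <- as.matrix(stats::dist(fball))^2
  surfaceIdx <- which(rowSums(d2 <= 1.5^2) - 1L < 8)
  upper <- surfaceIdx[fball[surfaceIdx, 3] > 0]
  radial <- fball[upper, , drop = FALSE]
  xcap <- radial * (1 + 1 / sqrt(rowSums(radial^2)))
  hemi <- surfaceCoverage(fball, xcap)
  expect_equal(hemi$verdict, "partial")
  expect_gt(hemi$coverage, 0.3)
  expect_lt(hemi$coverage, 0.75)
})

test_that("rDNA interior fraction separates engulfment from wrapping", {
  fball <- ballPositions(150)
  atCentre <- matrix(0, 20, 3)
  expect_equal(interiorFraction(atCentre, fball)$fraction, 1)
  expect_equal(interiorFraction(atCentre, fball)$call, "interior")
  rext <- max(sqrt(rowSums(fball^2)))
  set.seed(7)
  v <- matrix(rnorm(60), 20, 3)
  farOut <- 3 * rext * v / sqrt(rowSums(v^2))
  expect_equal(interiorFraction(farOut, fball)$fraction, 0)
  expect_equal(interiorFraction(farOut, fball)$call, "wrapping")
  # constructed half-in/half-out split
  half <- rbind(matrix(0, 50, 3), 3 * rext * v[rep(1:20, 3)[1:50], ])
  fr <- interiorFraction(half, fball)$fraction
  expect_equal(fr, 0.5, tolerance = 0.15)
})

test_that("layering verdicts recognize constructed organizations", {
  sphPoints <- function(n, rmin, rmax, seed) {
    set.seed(seed)
    v <- matrix(rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    r <- runif(n, rmin, rmax)
    v * r
  }
  # concentric dense F ball (liquid-like spacing so interior beads reach
  # coordination >= 8) / X shell hugging its surface / H outside: layered
  fpos <- ballPositions(300, spacing = 0.95)
  rF <- max(sqrt(rowSums(fpos^2)))
  xpos <- sphPoints(500, rF + 0.2, rF + 2, 2)
  hpos <- sphPoints(500, rF + 2, rF + 5.5, 3)
  st <- new("SystemState",
    positions = rbind(fpos, xpos, hpos),
    species = c(rep("F", nrow(fpos)), rep("X", nrow(xpos)),
                rep("H", nrow(hpos))),
    Rc = 12, time = 0
  )
  rep1 <- layeringVerdict(st)
  expect_equal(verdict(rep1), "layered")
  # F ball and X ball 30 sigma apart, H around X: amphiphile neocondensate
  fball <- ballPositions(150)
  xball <- sweep(ballPositions(150), 2, c(30, 0, 0), `+`)
  hshell <- sweep(sphPoints(400, 4, 7, 4), 2, c(30, 0, 0), `+`)
  st2 <- new("SystemState",
    positions = rbind(fball, xball, hshell),
    species = c(rep("F", 150), rep("X", 150), rep("H", 400)),
    Rc = 40, time = 0
  )
  rep2 <- layeringVerdict(st2)
  expect_equal(verdict(rep2), "neocondensate_in_H")
  expect_gt(rep2@dHF, rep1@dHF)
  # a uniform random mixture has no organization
  set.seed(8)
  mix <- randomInSphere(600, 9, seed = 8)
  st3 <- new("SystemState",
    positions = mix,
    species = sample(c(rep("F", 200), rep("X", 200), rep("H", 200))),
    Rc = 10, time = 0
  )
  expect_equal(verdict(layeringVerdict(st3)), "none")
})

test_that("verdicts and distances are invariant under rigid motions", {
  sphPoints <- function(n, rmin, rmax, seed) {
    set.seed(seed)
    v <- matrix(rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    v * runif(n, rmin, rmax)
  }
  pos <- rbind(sphPoints(200, 0, 5, 1), sphPoints(200, 5, 7, 2),
               sphPoints(300, 7, 10, 3))
  species <- c(rep("F", 200), rep("X", 200), rep("H", 300))
  st <- new("SystemState", positions = pos, species = species, Rc = 30,
            time = 0)
  base <- layeringVerdict(st)
  Rm <- rotationMatrix(c(1, 2, 3), 0.7)
  shifted <- sweep(pos %*% t(Rm), 2, c(3, -2, 1), `+`)
  st2 <- new("SystemState", positions = shifted, species = species, Rc = 30,
             time = 0)
  moved <- layeringVerdict(st2)
  expect_equal(verdict(moved), verdict(base))
  expect_equal(moved@dHF, base@dHF, tolerance = 1e-9)
  expect_equal(moved@xCoverage, base@xCoverage, tolerance = 1e-9)
})
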