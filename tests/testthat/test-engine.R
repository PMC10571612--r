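test_that("neighbor-list forces equal brute-force all-pairs evaluation", {
  # 150+ beads including a bonded polymer, random positions
  pts <- randomInSphere(180, 7.2, seed = 4)
  top <- buildTopology(30, 0.2, 90, 60)
  st <- new("SystemState", positions = pts, species = speciesLabels(top),
            Rc = 8, time = 0)
  p <- SimulationParameters(Rc = 8)
  im <- plusRdnaMatrix()
  fn <- computeForces(st, top, im, p, method = "neighbor")
  fb <- computeForces(st, top, im, p, method = "brute")
  scale <- max(1, max(abs(fb$forces)))
  expect_lt(max(abs(fn$forces - fb$forces)) / scale, 1e-12)
  expect_equal(fn$potential, fb$potential, tolerance = 1e-12)
})

test_that("total force equals the negative potential gradient", {
  # finite-difference oracle on a small mixed system; the initializer
  # guarantees separations above the force-capping floor
  top <- buildTopology(12, 0.25, 16, 12)
  p <- SimulationParameters(Rc = 6)
  st <- initializePositions(top, p, seed = 9)
  im <- plusRdnaMatrix()
  f <- computeForces(st, top, im, p, method = "brute")
  h <- 1e-6
  peAt <- function(pos) {
    s <- new("SystemState", positions = pos, species = speciesLabels(top),
             Rc = 6, time = 0)
    computeForces(s, top, im, p, method = "brute")$potential
  }
  for (bead in c(1, 5, 13, 30)) {
    for (axis in 1:3) {
      up <- positions(st); up[bead, axis] <- up[bead, axis] + h
      dn <- positions(st); dn[bead, axis] <- dn[bead, axis] - h
      fd <- -(peAt(up) - peAt(dn)) / (2 * h)
      expect_equal(f$forces[bead, axis], fd,
                   tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("pair forces respect the 2.5 sigma cutoff", {
  top <- buildTopology(0, 0, 2, 0)
  p <- SimulationParameters(Rc = 20)
  im <- InteractionMatrix(c("F-F" = 2))
  atSep <- function(d) {
    st <- new("SystemState", positions = rbind(c(0, 0, 0), c(d, 0, 0)),
              species = c("F", "F"), Rc = 20, time = 0)
    computeForces(st, top, im, p, method = "brute")$forces
  }
  f24 <- atSep(2.4)
  expect_gt(f24[1, 1], 0) # bead 1 pulled toward bead 2 (+x direction)
  expect_lt(abs(f24[1, 2]), 1e-12)
  f26 <- atSep(2.6)
  expect_equal(max(abs(f26)), 0)
  # empty system
  etop <- buildTopology(0, 0, 0, 0)
  est <- new("SystemState", positions = matrix(numeric(), 0, 3),
             species = character(), Rc = 20, time = 0)
  ef <- computeForces(est, etop, im, p, method = "brute")
  expect_equal(nrow(ef$forces), 0)
})

test_that("integration is deterministic and inert at zero temperature", {
  top <- buildTopology(0, 0, 3, 0)
  p0 <- SimulationParameters(Rc = 10, kBT = 1)
  pos <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))
  st <- new("SystemState", positions = pos, species = rep("F", 3), Rc = 10,
            time = 0)
  im <- InteractionMatrix() # all excluded volume, beads far apart: no forces
  # kBT = 0 with zero forces: positions unchanged over any number of steps
  pz <- new("SimulationParameters", sigma = 1, kBT = 1e-300, ks = 100,
            rcAttr = 2.5, rcRep = 2^(1 / 6), Rc = 10, dt = 0.005, gamma = 1,
            mass = 1, kBend = 2, nSteps = 0L, seed = 1L)
  trz <- integrateDynamics(st, top, pz, im, nSteps = 500, seed = 1,
                           frameInterval = 100)
  expect_equal(getFrame(trz, -1L)@positions, pos, tolerance = 1e-100)
  # identical seeds give bit-identical trajectories
  tr1 <- integrateDynamics(st, top, p0, im, nSteps = 2000, seed = 5,
                           frameInterval = 500)
  tr2 <- integrateDynamics(st, top, p0, im, nSteps = 2000, seed = 5,
                           frameInterval = 500)
  expect_identical(tr1@frames, tr2@frames)
  expect_false(identical(
    tr1@frames,
    integrateDynamics(st, top, p0, im, 2000, seed = 6,
                      frameInterval = 500)@frames
  ))
})

test_that("a free bead diffuses with D = kBT/(gamma mass)", {
  # time-origin-averaged MSD over a long single-bead run; slope 6 D t
  top <- buildTopology(0, 0, 1, 0)
  p <- SimulationParameters(Rc = 1000, dt = 0.005)
  st <- new("SystemState", positions = matrix(0, 1, 3), species = "F",
            Rc = 1000, time = 0)
  tr <- integrateDynamics(st, top, p, InteractionMatrix(), nSteps = 200000,
                          seed = 7, frameInterval = 200)
  pos <- t(vapply(tr@frames, function(f) f[1, ], numeric(3)))
  nf <- nrow(pos)
  dtFrame <- diff(tr@times)[1]
  lags <- 1:40
  msd <- vapply(lags, function(L) {
    d <- pos[(1 + L):nf, , drop = FALSE] - pos[1:(nf - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  slope <- coef(lm(msd ~ I(lags * dtFrame)))[2]
  expect_equal(unname(slope), 6, tolerance = 0.1)
})

test_that("the thermostat holds the kinetic temperature and bond statistics", {
  # interacting 60-bead system: kinetic temperature within 5% of kBT
  spec <- new("SystemSpec", nPch = 20L, rdnaFraction = 0, nF = 40L, nX = 0L,
              Rc = 7)
  res <- runProtocol(list(spec = spec, matrix = InteractionMatrix(c("F-F" = 1)),
                          seed = 2, pushoffSteps = 500L, equilSteps = 2000L,
                          prodSteps = 30000L, frameInterval = 1000L))
  expect_equal(res$summary$meanKineticTemp, 1, tolerance = 0.05)
  # bond-length distribution: sd ~ (2 ks)^(-1/2) = 0.0707 sigma at ks = 100
  top <- buildTopology(2, 0, 0, 0)
  p <- SimulationParameters(Rc = 10)
  st <- new("SystemState", positions = rbind(c(0, 0, 0), c(1, 0, 0)),
            species = c("H", "H"), Rc = 10, time = 0)
  tr <- integrateDynamics(st, top, p, InteractionMatrix(), nSteps = 150000,
                          seed = 11, frameInterval = 100)
  r <- vapply(tr@frames[-(1:100)], function(f) {
    sqrt(sum((f[1, ] - f[2, ])^2))
  }, numeric(1))
  expect_equal(mean(r), 1.0, tolerance = 0.05)
  expect_equal(sd(r), sqrt(1 / 200), tolerance = 0.2)
})

test_that("no bead leaves the confinement sphere in any saved frame", {
  spec <- new("SystemSpec", nPch = 30L, rdnaFraction = 0.2, nF = 30L,
              nX = 30L, Rc = 6)
  res <- runProtocol(list(spec = spec, matrix = plusRdnaMatrix(), seed = 3,
                          pushoffSteps = 500L, equilSteps = 1000L,
                          prodSteps = 20000L, frameInterval = 1000L))
  for (i in seq_len(nFrames(res$trajectory))) {
    r <- sqrt(rowSums(positions(getFrame(res$trajectory, i))^2))
    expect_true(all(r <= 6))
  }
})

test_that("the staged protocol is reproducible and handles zero production", {
  spec <- new("SystemSpec", nPch = 12L, rdnaFraction = 0.25, nF = 12L,
              nX = 12L, Rc = 6)
  cfg <- list(spec = spec, matrix = plusRdnaMatrix(), seed = 8,
              pushoffSteps = 200L, equilSteps = 500L, prodSteps = 0L)
  res <- runProtocol(cfg)
  expect_equal(nFrames(res$trajectory), 1L) # equilibrated frame only
  # provenance replays to an identical summary
  res2 <- runProtocol(cfg)
  expect_identical(res$summary, res2$summary)
  expect_identical(positions(getFrame(res$trajectory, 1)),
                   positions(getFrame(res2$trajectory, 1)))
})

test_that("free chains are swollen relative to collapsed chains", {
  # epsilon_HH = 0 vs 0.5 for the same N: Rg ratio > 1.5
  runChain <- function(eps) {
    spec <- new("SystemSpec", nPch = 100L, rdnaFraction = 0, nF = 0L,
                nX = 0L, Rc = 18)
    im <- if (eps > 0) InteractionMatrix(c("H-H" = eps)) else InteractionMatrix()
    res <- runProtocol(list(spec = spec, matrix = im, seed = 5,
                            equilSteps = 10000L, prodSteps = 250000L,
                            frameInterval = 25000L))
    tr <- res$trajectory
    mean(vapply(seq.int(nFrames(tr) - 2, nFrames(tr)), function(i) {
      radiusOfGyration(positions(getFrame(tr, i)))
    }, numeric(1)))
  }
  expect_gt(runChain(0) / runChain(0.5), 1.5)
})
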