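test_that("harmonic bond energy and force follow V = ks (r - sigma)^2", {
  # minimum of the potential
  b <- harmonicBond(1.0, ks = 100)
  expect_equal(b$energy, 0)
  expect_equal(b$force, 0)
  # direct evaluation at r = 1.1 sigma
  expect_equal(harmonicBond(1.1, ks = 100)$energy, 1.0)
  # symmetry of the quadratic
  expect_equal(harmonicBond(0.9, ks = 100)$energy,
               harmonicBond(1.1, ks = 100)$energy)
  # force is -dV/dr (finite difference)
  h <- 1e-7
  for (r in c(0.85, 1.0, 1.2)) {
    fd <- -(harmonicBond(r + h)$energy - harmonicBond(r - h)$energy) / (2 * h)
    expect_equal(harmonicBond(r)$force, fd, tolerance = 1e-6)
  }
  expect_error(harmonicBond(0), "invalid geometry")
  expect_error(harmonicBond(-1), "invalid geometry")
})

test_that("LJ pair potential: minimum, cutoff, shift and force consistency", {
  # unshifted minimum at 2^(1/6) sigma is exactly -epsilon with zero force
  m <- ljPair(2^(1 / 6), epsilon = 1.7, shifted = FALSE)
  expect_equal(m$energy, -1.7)
  expect_equal(m$force, 0, tolerance = 1e-12)
  # zero beyond the attractive cutoff
  z <- ljPair(2.6, epsilon = 2)
  expect_equal(z$energy, 0)
  expect_equal(z$force, 0)
  # shifted energy is continuous at the cutoff
  eps <- 1.5
  below <- ljPair(2.5 - 1e-9, eps)$energy
  expect_lt(abs(below), 1e-6)
  # excluded-volume mode vanishes continuously at 2^(1/6)
  wca <- ljPair(2^(1 / 6) - 1e-9, mode = "excluded_volume")
  expect_lt(abs(wca$energy), 1e-6)
  expect_lt(abs(wca$force), 1e-3)
  expect_equal(ljPair(1.2, mode = "excluded_volume")$energy, 0)
  # force equals -dV/dr over the working range (finite-difference oracle);
  # the truncation points themselves are excluded (the derivative has its
  # documented jump at the cutoff of the cut-and-shifted form)
  h <- 1e-6
  rGrid <- seq(0.8, 3.0, by = 0.1)
  rGrid <- rGrid[abs(rGrid - 2.5) > 0.01 & abs(rGrid - 2^(1 / 6)) > 0.01]
  for (r in rGrid) {
    for (mode in c("attractive", "excluded_volume")) {
      e1 <- ljPair(r - h, 1.3, mode = mode)$energy
      e2 <- ljPair(r + h, 1.3, mode = mode)$energy
      f <- ljPair(r, 1.3, mode = mode)$force
      fd <- -(e2 - e1) / (2 * h)
      expect_equal(f, fd, tolerance = 1e-5)
    }
  }
  # overlap capping is reported
  expect_warning(ljPair(0.1, 1), "unstable configuration")
  expect_error(ljPair(0, 1), "invalid geometry")
})

test_that("bending energy is harmonic-cosine with minimum at the straight triple", {
  expect_equal(bendingEnergy(pi), 0, tolerance = 1e-12)
  expect_equal(bendingEnergy(pi / 2, kBend = 2), 2)
  expect_equal(bendingEnergy(0, kBend = 2), 4) # fully folded costs 2 kBend
  expect_error(bendingEnergy(-0.1), "theta")
  expect_error(bendingEnergy(3.2), "theta")
})

test_that("confinement radius from the chromatin volume fraction", {
  # default genome: 360 Mbp / 5 kbp = 72,000 beads at phi = 0.1 gives the
  # nominal 45 sigma (44.81 before rounding)
  g <- GenomeModel()
  expect_equal(nGenomeBeads(g), 72000L)
  rc <- confinementRadiusFromPhi(g)
  expect_equal(round(rc), 45)
  expect_equal(rc, (72000 / 0.8)^(1 / 3), tolerance = 1e-12)
  # closed-form case: 4096 beads at phi = 0.512 give exactly Rc = 10
  expect_equal(confinementRadiusFromPhi(GenomeModel(4096 * 5e3, 5e3, 0.512)),
               10, tolerance = 1e-12)
  # direct evaluation at phi = 0.8 (phi upper validity bound is 0.64, so
  # construct the value directly)
  expect_equal((72000 / (8 * 0.8))^(1 / 3), 22.4, tolerance = 0.01)
  # monotone decreasing in phi, increasing in NG
  phis <- c(0.05, 0.1, 0.2, 0.4)
  rcs <- vapply(phis, function(p) {
    confinementRadiusFromPhi(GenomeModel(phi = p))
  }, numeric(1))
  expect_true(all(diff(rcs) < 0))
  ngs <- c(100e6, 200e6, 400e6)
  rcs2 <- vapply(ngs, function(n) {
    confinementRadiusFromPhi(GenomeModel(genomeLength = n))
  }, numeric(1))
  expect_true(all(diff(rcs2) > 0))
  expect_error(GenomeModel(phi = 0), "phi")
})

test_that("bead counts from number concentration and back", {
  expect_equal(countFromConcentration(0, 45), 0L)
  # reference composition: cF = 0.013 inside Rc = 45 sigma
  expect_equal(countFromConcentration(0.013, 45), 4962L)
  # the reported nucleolar particle density is a valid input
  expect_gt(countFromConcentration(0.015, 45), 0)
  # inverse agrees within rounding
  for (conc in c(0.0013, 0.005, 0.013)) {
    n <- countFromConcentration(conc, 22.5)
    expect_equal(concentrationFromCount(n, 22.5), conc, tolerance = 0.02)
  }
  expect_error(countFromConcentration(-1, 45), "concentration")
})

test_that("simulation parameter invariants are enforced", {
  p <- SimulationParameters()
  expect_equal(p@rcRep, 2^(1 / 6))
  expect_error(SimulationParameters(rcRep = 1.13), "2\\^\\(1/6\\)")
  expect_error(SimulationParameters(dt = 0.02), "stability")
  expect_error(SimulationParameters(Rc = -1), "strictly positive")
  expect_error(SimulationParameters(rcAttr = 1.0), "rcRep")
})

test_that("interaction matrix is symmetric, validated and round-trips", {
  im <- plusRdnaMatrix()
  expect_equal(epsilonOf(im, "F", "X"), epsilonOf(im, "X", "F"))
  expect_equal(epsilonOf(im, "F", "F"), 2.0)
  expect_equal(modeOf(im, "H", "F"), "excluded_volume")
  expect_error(InteractionMatrix(c("F-Q" = 1)), "bad pair name")
  # serialization round-trip is bit-exact
  p <- SimulationParameters(Rc = 22.5)
  path <- withr::local_tempfile()
  writeParameterConfig(p, im, path)
  back <- readParameterConfig(path)
  expect_identical(back$matrix@epsilon, im@epsilon)
  expect_identical(back$matrix@mode, im@mode)
  expect_identical(back$params@Rc, p@Rc)
  expect_identical(back$params@dt, p@dt)
})
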