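test_that("block copolymer topology: centred rDNA block, bonds, free beads", {
  # small exhaustive case: 10 beads at 20% rDNA puts beads 5-6 in the block
  top <- buildTopology(10, 0.2, 0, 0)
  expect_identical(which(speciesLabels(top) == "rD"), 5:6)
  expect_equal(nrow(top@bonds), 9)
  expect_equal(nrow(top@angles), 8)
  # full-size chain: 2,000 rD beads centred in 10,000
  big <- buildTopology(10000, 0.2, 0, 0)
  expect_equal(sum(speciesLabels(big) == "rD"), 2000)
  expect_identical(big@rdRange, c(4001L, 6000L))
  # fraction 0 gives an all-H chain
  none <- buildTopology(10, 0, 0, 0)
  expect_true(all(speciesLabels(none) == "H"))
  # free beads are appended unbonded
  mixed <- buildTopology(10, 0.2, 3, 4)
  expect_equal(sum(speciesLabels(mixed) == "F"), 3)
  expect_equal(sum(speciesLabels(mixed) == "X"), 4)
  expect_true(all(mixed@bonds <= 10))
  expect_error(buildTopology(10, 1.0, 0, 0), "rdnaFraction")
  expect_error(buildTopology(10, -0.1, 0, 0), "rdnaFraction")
})

test_that("initial configurations are deterministic, separated and confined", {
  top <- buildTopology(40, 0.2, 20, 20)
  p <- SimulationParameters(Rc = 10)
  s1 <- initializePositions(top, p, seed = 11)
  s2 <- initializePositions(top, p, seed = 11)
  expect_identical(positions(s1), positions(s2))
  s3 <- initializePositions(top, p, seed = 12)
  expect_false(identical(positions(s1), positions(s3)))
  # no pair closer than 0.8 sigma (brute-force check)
  expect_gte(nucleopch:::min_pair_distance_cpp(positions(s1)), 0.8 - 1e-6)
  # all beads inside Rc - sigma/2
  expect_true(all(sqrt(rowSums(positions(s1)^2)) <= 10 - 0.5))
  # bond lengths near sigma after growth
  bl <- sqrt(rowSums((positions(s1)[2:40, ] - positions(s1)[1:39, ])^2))
  expect_true(all(bl < 1.6))
  # packing infeasibility is reported
  expect_error(
    initializePositions(buildTopology(0, 0, 5000, 0),
                        SimulationParameters(Rc = 5)),
    "packing infeasible"
  )
})

test_that("system scaling preserves densities and the rDNA fraction", {
  full <- SystemSpec() # 10,000 polymer, 4,962 F, 4,962 X, Rc 45
  expect_identical(scaleSystem(full, 1), full)
  eighth <- scaleSystem(full, 1 / 8)
  expect_equal(eighth@Rc, 22.5)
  expect_equal(eighth@nPch, 1250L)
  expect_equal(eighth@nF, 620L)
  expect_equal(eighth@rdnaFraction, 0.2)
  # densities before/after equal within rounding
  for (s in c(1 / 2, 1 / 8, 1 / 27)) {
    sc <- scaleSystem(full, s)
    expect_equal(concentrationFromCount(sc@nF, sc@Rc),
                 concentrationFromCount(full@nF, full@Rc), tolerance = 0.02)
    expect_equal(concentrationFromCount(sc@nPch, sc@Rc),
                 concentrationFromCount(full@nPch, full@Rc), tolerance = 0.02)
  }
  expect_error(scaleSystem(full, 0), "scaleFactor")
  expect_error(scaleSystem(full, 1 / 2000), "too small")
})

test_that("athermal chains reproduce self-avoiding-walk Rg scaling", {
  # Rg ~ N^nu with nu = 0.59 +/- 0.06 across N = 50..400 at epsilon = 0
  im <- InteractionMatrix()
  ns <- c(50, 100, 200, 400)
  rg <- vapply(ns, function(n) {
    p <- SimulationParameters(Rc = max(20, ceiling(n^0.62)))
    vals <- vapply(1:4, function(seed) {
      top <- buildTopology(n, 0, 0, 0)
      st <- initializePositions(top, p, seed = seed)
      tr <- integrateDynamics(st, top, p, im, nSteps = 10000, seed = seed + 100,
                              frameInterval = 2500)
      mean(vapply(2:5, function(i) {
        radiusOfGyration(positions(getFrame(tr, i)))
      }, numeric(1)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  nu <- coef(lm(log(rg) ~ log(ns)))[2]
  expect_gt(nu, 0.53)
  expect_lt(nu, 0.65)
})

test_that("states and topologies round-trip through extended XYZ", {
  top <- buildTopology(12, 0.25, 5, 5)
  p <- SimulationParameters(Rc = 8)
  st <- initializePositions(top, p, seed = 3)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(st, path)
  back <- readXYZ(path)
  expect_equal(speciesLabels(back), speciesLabels(st))
  expect_equal(getFrame(back, 1)@positions, positions(st), tolerance = 1e-12)
  expect_equal(back@Rc, 8)
})
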