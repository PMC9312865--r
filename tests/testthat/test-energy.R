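test_that("the GB smoothing function has its limits and closed values", {
  expect_equal(fGB(0, 2, 2), 2)
  expect_equal(fGB(100, 1, 1), 100, tolerance = 1e-9)
  expect_equal(fGB(4, 2, 3), sqrt(16 + 6 * exp(-16 / 24)))
  expect_equal(fGB(1.3, 1.7, 2.2), fGB(1.3, 2.2, 1.7))
  expect_error(fGB(1, -1, 2), "positive")
})

test_that("R6 effective radii match the Monte-Carlo descreening oracle", {
  iso <- bornIonFixture(0.5, 1.7)
  expect_equal(as.numeric(effectiveBornRadii(iso)), 1.7)

  two <- mkStruct(c("C", "C"), c(0, 4, 0, 0, 0, 0), radius = 1.5)
  R <- effectiveBornRadii(two)
  expect_equal(as.numeric(R[1]), mcBornRadius(two, 1), tolerance = 0.01)

  # overlapping spheres exercise the partial-cap branch
  near <- mkStruct(c("C", "O"), c(0, 2.0, 0, 0, 0, 0), radius = c(1.4, 1.8))
  Rn <- effectiveBornRadii(near)
  expect_equal(as.numeric(Rn[1]), mcBornRadius(near, 1), tolerance = 0.01)
  expect_equal(as.numeric(Rn[2]), mcBornRadius(near, 2), tolerance = 0.01)

  # a third descreening neighbor can only grow the effective radius
  three <- mkStruct(c("C", "C", "C"), c(0, 4, -4, 0, 0, 0, 0, 0, 0),
                    radius = 1.5)
  expect_gt(effectiveBornRadii(three)[1], R[1])
  expect_true(all(effectiveBornRadii(three) >= 1.5))

  # buried atom: shell of 12 neighbors
  shell <- PGBind:::.fibonacciSphere(12) * 3.4
  buried <- mkStruct(rep("C", 13), rbind(c(0, 0, 0), shell), radius = 1.6)
  expect_gt(effectiveBornRadii(buried)[1], 1.6)

  dup <- mkStruct(c("C", "C"), c(0, 0, 0, 0, 0, 0))
  expect_error(effectiveBornRadii(dup), "coincident")
})

test_that("electrostatic size is sqrt(5/3) Rg with single-atom fallback", {
  expect_equal(electrostaticSize(bornIonFixture(1, 2)), 2)

  withr::with_seed(31, {
    u <- matrix(stats::rnorm(3e5), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- u * 10 * stats::runif(1e5)^(1 / 3)
  })
  ball <- mkStruct(rep("C", 1e5), pts)
  expect_equal(electrostaticSize(ball), 10, tolerance = 0.01)

  st <- makeHostGuest(fixtureSpec(seed = 2), 1)@complexStructure
  expect_equal(electrostaticSize(rigidMotion(st)), electrostaticSize(st),
               tolerance = 1e-9)
})

test_that("the ALPB Born-ion energy matches the hand-evaluated closed form", {
  p <- gbParameters(epsIn = 1, epsOut = 80)
  ion <- bornIonFixture(1, 2)
  alpha <- 0.571412; beta <- 1 / 80
  closed <- -0.5 * 332.0637 * (1 - 1 / 80) * (1 / (1 + beta * alpha)) *
    (1 / 2 + alpha * beta / 2)
  expect_equal(polarSolvationEnergy(ion, params = p), closed,
               tolerance = 1e-6)

  # epsOut -> Inf limit: the classic Born energy
  pInf <- gbParameters(epsIn = 1, epsOut = 1e9)
  expect_equal(polarSolvationEnergy(ion, params = pInf),
               -0.5 * 332.0637 / 2, tolerance = 1e-4)

  # q -> -q symmetry and zero-charge annihilation
  expect_equal(polarSolvationEnergy(bornIonFixture(-1, 2), params = p),
               polarSolvationEnergy(ion, params = p))
  expect_identical(polarSolvationEnergy(bornIonFixture(0, 2), params = p), 0)
})

test_that("vectorized energies equal naive double-loop oracles", {
  withr::with_seed(17, {
    xyz <- matrix(stats::rnorm(15, sd = 3), ncol = 3)
    while (min(dist(xyz)) < 1.2) xyz <- matrix(stats::rnorm(15, sd = 3),
                                               ncol = 3)
    st <- mkStruct(c("C", "N", "O", "C", "H"), xyz,
                   charge = stats::runif(5, -0.5, 0.5),
                   radius = stats::runif(5, 1.2, 2),
                   rminHalf = stats::runif(5, 1.2, 2),
                   ljEps = stats::runif(5, 0.05, 0.3),
                   bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  })
  p <- gbParameters()
  R <- effectiveBornRadii(st)
  expect_equal(polarSolvationEnergy(st, R, p), bfPolar(st, R, p),
               tolerance = 1e-9)
  cou <- coulombEnergies(st, p)
  ref <- bfCoulomb(st)
  expect_equal(cou$eelec, ref$eelec, tolerance = 1e-9)
  expect_equal(cou$eel14, ref$eel14, tolerance = 1e-9)
  expect_equal(ljEnergy(st, p), bfLJ(st), tolerance = 1e-9)
})

test_that("Coulomb terms respect bond-separation classes", {
  p <- gbParameters()
  # two unit charges at 3.320637 A: 332.0637/3.320637 = 100 kcal/mol
  pairSt <- mkStruct(c("N", "N"), c(0, 3.320637, 0, 0, 0, 0), charge = 1)
  cou <- coulombEnergies(pairSt, p)
  expect_equal(cou$eelec, 100, tolerance = 1e-6)
  expect_equal(cou$eel14, 0)

  bonded <- pairSt; bonded@bonds <- matrix(c(1L, 2L), ncol = 2)
  couB <- coulombEnergies(bonded, p)
  expect_equal(couB$eelec, 0)
  expect_equal(couB$eel14, 0)

  # linear 4-chain: the (1,4) pair is three bonds apart -> eel14 / 1.2
  chain <- mkStruct(rep("C", 4), cbind(0:3 * 1.5, 0, 0), charge = 1,
                    bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  couC <- coulombEnergies(chain, p)
  expect_equal(couC$eel14, 332.0637 / 4.5 / 1.2, tolerance = 1e-9)
  expect_equal(couC$eelec, 0)
})

test_that("Lennard-Jones well depth and zero crossing are exact", {
  p <- gbParameters()
  rmin <- 1.7 + 1.9
  st <- mkStruct(c("C", "N"), c(0, rmin, 0, 0, 0, 0),
                 rminHalf = c(1.7, 1.9), ljEps = c(0.09, 0.16))
  expect_equal(ljEnergy(st, p), -sqrt(0.09 * 0.16), tolerance = 1e-12)
  st0 <- st; st0@atoms$x[2] <- rmin * 2^(-1 / 6)
  expect_equal(ljEnergy(st0, p), 0, tolerance = 1e-12)
})

test_that("SASA sampling reproduces sphere areas, additivity, occlusion", {
  p <- gbParameters()
  one <- mkStruct("C", c(0, 0, 0), radius = 1.5)
  np1 <- nonpolarEnergy(one, p)
  expect_equal(np1$sasa, 4 * pi * 2.9^2, tolerance = 0.005)
  expect_equal(np1$esurf, 0.0072 * np1$sasa)

  far <- mkStruct(c("C", "C"), c(0, 50, 0, 0, 0, 0), radius = 1.5)
  expect_equal(nonpolarEnergy(far, p)$sasa, 2 * np1$sasa, tolerance = 0.005)

  close <- mkStruct(c("C", "C"), c(0, 2, 0, 0, 0, 0), radius = 1.5)
  expect_lt(nonpolarEnergy(close, p)$sasa, 2 * np1$sasa * 0.99)
})

test_that("energy terms are invariant under rigid motion and scale as q^2", {
  st <- makeHostGuest(fixtureSpec(seed = 4, atomsPerHost = c(12L, 14L),
                                  atomsPerGuest = c(3L, 4L)), 1)@complexStructure
  ebA <- energyBreakdown(st)
  ebB <- energyBreakdown(rigidMotion(st))
  analytic <- c("eel14", "vdwaals", "eelec", "egb", "esize")
  expect_equal(ebA[analytic], ebB[analytic], tolerance = 1e-6)
  # sampled SASA: exact under translation, sampling-resolution exact under
  # rotation (principal axes of this ring-like fixture are near-degenerate)
  expect_equal(ebA[["esurf"]], ebB[["esurf"]], tolerance = 2e-3)

  scaled <- st; scaled@atoms$charge <- 2 * st@atoms$charge
  expect_equal(polarSolvationEnergy(scaled),
               4 * polarSolvationEnergy(st), tolerance = 1e-9)
  expect_equal(coulombEnergies(scaled)$eelec,
               4 * coulombEnergies(st)$eelec, tolerance = 1e-9)

  neutral <- mkStruct(c("C", "C"), c(0, 8, 0, 0, 0, 0), charge = 0)
  ebN <- energyBreakdown(neutral)
  expect_identical(unname(ebN[c("egb", "eelec", "eel14")]), c(0, 0, 0))
})

test_that("enthalpy isolates intermolecular terms at infinite separation", {
  # receptor and ligand far apart: intramolecular contributions cancel
  rec <- mkStruct(rep("C", 3), cbind(0:2 * 1.5, 0, 0),
                  charge = c(0.2, -0.1, 0.1),
                  bonds = rbind(c(1, 2), c(2, 3)), role = "receptor")
  lig <- mkStruct(rep("O", 2), cbind(c(500, 501.5), 0, 0),
                  charge = c(0.3, -0.3), bonds = rbind(c(1, 2)),
                  role = "ligand")
  cx <- methods::new("ParameterizedStructure",
                     atoms = rbind(rec@atoms, lig@atoms),
                     bonds = rbind(rec@bonds, lig@bonds + 3L),
                     role = "complex", name = "far")
  ebC <- energyBreakdown(cx)
  ent <- enthalpy(ebC, energyBreakdown(rec), energyBreakdown(lig))
  expect_equal(ent$dh, sum(ent$perTermDeltas), tolerance = 1e-9)
  # at 500 A separation every coupling term is negligible but nonzero;
  # bonded-network terms cancel exactly
  expect_equal(unname(ent$perTermDeltas["eel14"]), 0, tolerance = 1e-12)
  expect_lt(abs(ent$dh), 0.05)
  # brute-force recomputation of dh as a single sum
  expect_equal(ent$dh,
               sum(ebC[PGBind:::.ENERGY_TERMS]) -
                 sum(energyBreakdown(rec)[PGBind:::.ENERGY_TERMS]) -
                 sum(energyBreakdown(lig)[PGBind:::.ENERGY_TERMS]),
               tolerance = 1e-9)
})

test_that("the entropy residual obeys its defining identity", {
  expect_equal(entropyFeature(-8, -20), -12)
  expect_equal(entropyFeature(-5, -5), 0)
  dh <- -13.7; ddg <- -6.2
  expect_equal(dh - entropyFeature(ddg, dh), ddg)
  expect_warning(z <- entropyFeature(NA, -4), "inference")
  expect_identical(z, 0)
})

test_that("the physics vector has 16 ordered entries and reconstructs ddG", {
  lc <- makeHostGuest(fixtureSpec(seed = 6, atomsPerHost = c(12L, 16L),
                                  atomsPerGuest = c(3L, 4L)), 2)
  lc@ddgExp <- -4.25
  P <- physicsFeatures(lc)
  expect_length(P, 16L)
  expect_identical(names(P), physicsFeatureNames())
  expect_equal(sum(physicsInitPattern() * P), -4.25, tolerance = 1e-6)
  # determinism
  expect_identical(as.numeric(P), as.numeric(physicsFeatures(lc)))
})
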