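test_that("viscosity map is linear between the medium and packed-cell limits", {
  expect_equal(viscosityFromCellFraction(0), 1e-3)
  expect_equal(viscosityFromCellFraction(1), 1.0)
  expect_equal(viscosityFromCellFraction(0.5), 0.5005)
  expect_error(viscosityFromCellFraction(1.2), "\\[0, 1\\]")
  expect_error(viscosityFromCellFraction(-0.1), "\\[0, 1\\]")
})

test_that("plane-channel reduction reproduces the analytic wall shear", {
  ch <- solveChannelFlow(32, mu = 1e-3, meanVelocity = 3e-3, gap = 200e-6)
  expect_equal(ch$wallShear, 6 * 1e-3 * 3e-3 / 200e-6, tolerance = 0.02)
  # profile symmetric and parabolic-shaped
  expect_equal(ch$u, rev(ch$u), tolerance = 1e-10)
  expect_equal(max(ch$u) / mean(ch$u), 1.5, tolerance = 0.01)
})

test_that("duct reduction matches the series solution", {
  du <- solveDuctFlow(32, 32, mu = 1e-3, meanVelocity = 3e-3,
                      widthY = 200e-6, widthZ = 200e-6)
  ex <- outer(du$y, du$z, function(y, z)
    ductSeriesProfile(y, z, 200e-6, 200e-6))
  ex <- ex * mean(du$u) / mean(ex)
  expect_lt(max(abs(du$u - ex)) / max(ex), 0.02)
})

test_that("3-D solver conserves flux plane-by-plane on the empty duct", {
  dom <- voxelize(unitDesign(0, 0), 16)
  fl <- solveFlow(dom, 1e-3, inletVelocity = 3e-3)
  expect_true(fl@converged)
  flux <- sapply(seq_len(17), function(i) sum(fl@u[i, , ]) * dom@spacing^2)
  expect_lt((max(flux) - min(flux)) / flux[1], 1e-6)
  expect_equal(flux[1], fl@inletFlux)
  # no-slip: velocities vanish on faces adjacent to walls by construction
  expect_true(all(abs(fl@v[, 1, ]) == 0))
  expect_true(all(abs(fl@w[, , 1]) == 0))
})

test_that("3-D outflow profile approaches the developed duct solution", {
  dom <- voxelize(unitDesign(0, 0), 20)
  fl <- solveFlow(dom, 1e-3, inletVelocity = 3e-3)
  y <- (seq_len(20) - 0.5) * dom@spacing
  ex <- outer(y, y, function(yy, zz)
    ductSeriesProfile(yy, zz, 200e-6, 200e-6))
  uout <- fl@u[20, , ]
  ex <- ex * mean(uout) / mean(ex)
  expect_lt(max(abs(uout - ex)) / max(ex), 0.02)
})

test_that("Stokes flow is linear in the inlet velocity", {
  dom <- voxelize(unitDesign(40, 60), 12)
  f1 <- solveFlow(dom, 1e-3, inletVelocity = 1e-3)
  f2 <- solveFlow(dom, 1e-3, inletVelocity = 2e-3)
  expect_lt(max(abs(f2@u - 2 * f1@u)) / max(abs(f2@u)), 1e-5)
  s1 <- shearMagnitude(f1, 1e-3, dom)
  s2 <- shearMagnitude(f2, 1e-3, dom)
  expect_equal(s2$meanBiomass, 2 * s1$meanBiomass, tolerance = 1e-5)
})

test_that("grid refinement decreases the empty-duct velocity error", {
  # compare mid-duct outlet profiles to the series solution at increasing
  # resolution: the L2 error must decrease monotonically
  errs <- sapply(c(8, 16, 24), function(n) {
    dom <- voxelize(unitDesign(0, 0), n)
    fl <- solveFlow(dom, 1e-3, inletVelocity = 3e-3)
    y <- (seq_len(n) - 0.5) * dom@spacing
    ex <- outer(y, y, function(yy, zz)
      ductSeriesProfile(yy, zz, 200e-6, 200e-6))
    uo <- fl@u[n, , ]
    ex <- ex * mean(uo) / mean(ex)
    sqrt(mean((uo - ex)^2)) / max(ex)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("biomass penalization suppresses velocity inside dense biomass", {
  dims <- c(16, 16, 16)
  dom <- makeDuct(dims, biomassLayers = 4L)
  slab <- dom@labels == 2L
  fLow <- solveFlow(dom, 1e-3, inletVelocity = 3e-3)   # uniform viscosity
  epsC <- array(0, dims); epsC[slab] <- 1
  fHigh <- solveFlow(dom, viscosityFromCellFraction(epsC), 3e-3)
  uc <- function(f) 0.5 * (f@u[1:16, , ] + f@u[2:17, , ])
  vLow <- mean(abs(uc(fLow)[slab]))
  vHigh <- mean(abs(uc(fHigh)[slab]))
  expect_lt(vHigh, 0.05 * vLow)   # > 95% reduction
})

test_that("shear magnitude reductions behave as expected", {
  dom <- voxelize(unitDesign(30, 30, culturedSurfaces = "bottom"), 12)
  fl <- solveFlow(dom, 1e-3, inletVelocity = 3e-3)
  sh <- shearMagnitude(fl, 1e-3, dom)
  expect_true(all(sh$tau >= 0))
  expect_lte(sh$meanBiomass, sh$maxBiomass)
  # zero velocity gives zero shear
  f0 <- fl
  f0@u[] <- 0; f0@v[] <- 0; f0@w[] <- 0
  expect_true(all(shearMagnitude(f0, 1e-3, dom)$tau == 0))
})

test_that("default operating point is in the creeping-flow regime", {
  Re <- 1000 * 3e-3 * 200e-6 / 1e-3
  expect_lt(Re, 1)
})
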