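p <- kineticParams()

test_that("closed-domain scalar mass is conserved without reaction", {
  dom <- voxelize(unitDesign(50, 50, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  p0 <- kineticParams(vm = 0)              # switch the sink off
  tot0 <- glucoseContent(st, dom, p0)
  s <- st
  for (k in 1:5)
    s <- stepGlucose(s, dom, flow = NULL, p0, dt = 3600,
                     boundary = "closed")$state
  expect_lt(abs(glucoseContent(s, dom, p0) - tot0) / tot0, 5 * 1e-10)
})

test_that("uniform field with no reaction and no flow stays unchanged", {
  dom <- makeDuct(c(8, 8, 8))
  st <- blankState(dom, cgf = 2.5)
  g <- stepGlucose(st, dom, flow = NULL, kineticParams(vm = 0), dt = 3600,
                   boundary = "closed")
  expect_equal(g$state@cgf, st@cgf, tolerance = 1e-10)
  l <- stepLactate(st, dom, flow = NULL, p, dt = 3600,
                   uptakeField = array(0, dom@dims), boundary = "closed")
  expect_equal(l$state@cl, st@cl, tolerance = 1e-10)
})

test_that("two-sided Dirichlet relaxes to the linear steady profile", {
  dom <- makeDuct(c(16, 4, 4))
  st <- blankState(dom)
  g <- stepGlucose(st, dom, flow = NULL, kineticParams(vm = 0), dt = 1e9,
                   glin = 1, boundary = "fixed", cRight = 0)
  prof <- g$state@cgf[, 2, 2]
  xc <- (seq_len(16) - 0.5) / 16
  expect_equal(prof, 1 - xc, tolerance = 1e-6)
  # steady diffusive flux D * dc/L through any interior face
  D <- p@dgf; h <- dom@spacing; L <- 16 * h
  flux <- D * (prof[8] - prof[9]) / h * h^2
  expect_equal(flux, D * 1 / L * h^2, tolerance = 1e-6)
})

test_that("closed-box uptake budget matches the content drop", {
  dom <- voxelize(unitDesign(50, 50, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  tot0 <- glucoseContent(st, dom, p)
  consumed <- 0
  s <- st
  for (k in 1:6) {
    g <- stepGlucose(s, dom, flow = NULL, p, dt = 3600, boundary = "closed")
    s <- g$state
    consumed <- consumed + g$diagnostics$consumed
  }
  drop <- tot0 - glucoseContent(s, dom, p)
  expect_lt(abs(consumed - drop) / drop, 0.01)
  expect_gt(drop, 0)
})

test_that("cumulative lactate equals twice the glucose consumed", {
  dom <- voxelize(unitDesign(50, 50, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  tot0 <- glucoseContent(st, dom, p)
  s <- st
  for (k in 1:6) {
    g <- stepGlucose(s, dom, flow = NULL, p, dt = 3600, boundary = "closed")
    s <- stepLactate(g$state, dom, flow = NULL, p, dt = 3600,
                     uptakeField = g$diagnostics$uptakeField,
                     boundary = "closed")$state
  }
  gluc <- tot0 - glucoseContent(s, dom, p)
  lact <- lactateContent(s, dom)
  expect_equal(lact / gluc, 2, tolerance = 0.01)
})

test_that("advective steady state balances outlet lactate flux and production", {
  dom <- voxelize(unitDesign(40, 40, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  mu <- viscosityFromCellFraction(st@epsC)
  fl <- solveFlow(dom, mu, 3e-3)
  s <- st
  for (k in 1:4) {   # residence time << dt: steady after the first steps
    g <- stepGlucose(s, dom, fl, p, dt = 3600, glin = 4.5)
    s <- stepLactate(g$state, dom, fl, p, dt = 3600,
                     uptakeField = g$diagnostics$uptakeField)$state
    rl <- lactateRate(g$diagnostics$uptakeField)
  }
  h <- dom@spacing
  outFlux <- sum(fl@u[13, , ] * s@cl[12, , ]) * h^2   # upwind outlet flux
  prod <- sum(rl) * h^3
  expect_equal(outFlux, prod, tolerance = 0.02)
})

test_that("upwind advection stays positive at coarse-grid Peclet numbers", {
  dom <- makeDuct(c(12, 12, 12), biomassLayers = 2L)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  fl <- solveFlow(dom, viscosityFromCellFraction(st@epsC), 3e-3)
  s <- st
  for (k in 1:5) {
    g <- stepGlucose(s, dom, fl, p, dt = 3600, glin = 4.5)
    s <- stepLactate(g$state, dom, fl, p, dt = 3600,
                     uptakeField = g$diagnostics$uptakeField)$state
  }
  expect_true(all(s@cgf >= 0))
  expect_true(all(s@cl >= 0))
  # no over/undershoot beyond iterative-solver noise (oscillatory schemes
  # would violate the inlet bound at the percent level)
  expect_true(all(s@cgf[dom@labels != 1L] <= 4.5 + 1e-6))
  expect_equal(s@budgets$clippedMass, 0)
})

test_that("biomass is unchanged without growth, death or migration", {
  dom <- voxelize(unitDesign(50, 50, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 0, initialCellDensity = 5e13, p)
  st@cgf[] <- 0                                  # no substrate: rg = 0
  b <- stepBiomass(st, dom, array(0, dom@dims), p, dt = 3600)
  expect_equal(b$state@epsC, st@epsC)
})

test_that("well-mixed growth matches the exponential solution over 10 steps", {
  # kc = 0 makes rg independent of epsC; saturated glucose keeps it constant
  pK <- kineticParams(kc = 0)
  dom <- voxelize(unitDesign(50, 50, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, pK)
  rg <- growthRate(pK@keq * 4.5, 0.5, 0, pK)
  s <- st
  for (k in 1:10) s <- stepBiomass(s, dom, array(0, dom@dims), pK,
                                   dt = 3600)$state
  e0 <- st@epsC[dom@labels == 2L][1]
  expect_equal(s@epsC[dom@labels == 2L][1], e0 * exp(rg * 36000),
               tolerance = 0.005)
})

test_that("acidic medium kills the culture in the instant-removal gate", {
  dom <- voxelize(unitDesign(50, 50, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  st@cl[] <- 20                      # pH = 7.4 - 0.0406*20 = 6.59 < 6.8
  b <- stepBiomass(st, dom, array(0, dom@dims), p, dt = 3600,
                   viabilityMode = "remove")
  expect_true(all(b$state@epsC == 0))
  # freeze mode retains the biomass but stops growth
  b2 <- stepBiomass(st, dom, array(0, dom@dims), p, dt = 3600,
                    viabilityMode = "freeze")
  expect_equal(b2$state@epsC, st@epsC)
})

test_that("monolayer caps bound the cell fraction per voxel and per column", {
  dom <- voxelize(unitDesign(0, 0, culturedSurfaces = "bottom"), 12)
  st <- initCultureState(dom, glin = 4.5, initialCellDensity = 5e13, p)
  st@epsC[dom@labels == 2L] <- 0.999
  pf <- kineticParams(kc = 0)        # fast growth
  expect_warning(
    b <- stepBiomass(st, dom, array(0.3, dom@dims), pf, dt = 3600 * 5),
    "capped")
  expect_true(all(b$state@epsC <= 1))
  # per-column bound: total epsC * h along each column never exceeds dc
  h <- dom@spacing
  bio <- dom@labels == 2L
  colSums <- rowsum(b$state@epsC[bio] * h,
                    paste(which(bio, arr.ind = TRUE)[, 1],
                          which(bio, arr.ind = TRUE)[, 2]))
  expect_true(all(colSums <= p@dc * (1 + 1e-9)))
})

test_that("time-step halving changes the outcome by less than one percent", {
  d <- unitDesign(40, 60, culturedSurfaces = "bottom")
  oc1 <- operatingConditions(durationH = 12, dtH = 1)
  oc2 <- operatingConditions(durationH = 12, dtH = 0.5)
  r1 <- runCulture(d, oc1, resolution = 12L)
  r2 <- runCulture(d, oc2, resolution = 12L)
  expect_equal(r1@finalMeanDensity, r2@finalMeanDensity, tolerance = 0.01)
})

test_that("BDF2 scheme agrees with implicit Euler at small dt", {
  d <- unitDesign(40, 60, culturedSurfaces = "bottom")
  oc <- operatingConditions(durationH = 6, dtH = 0.5)
  r1 <- runCulture(d, oc, resolution = 10L, control = list(scheme = "be"))
  r2 <- runCulture(d, oc, resolution = 10L, control = list(scheme = "bdf2"))
  expect_equal(r1@finalMeanDensity, r2@finalMeanDensity, tolerance = 0.02)
})
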