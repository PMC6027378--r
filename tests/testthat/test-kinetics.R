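p <- kineticParams()

test_that("glucose uptake follows Michaelis-Menten with the published Vm", {
  expect_equal(glucoseUptakeRate(1e6, 1, p), p@vm, tolerance = 1e-5)
  expect_equal(glucoseUptakeRate(0, 1, p), 0)
  # half-saturation identity at c = Km, full cell fraction
  expect_equal(glucoseUptakeRate(6.3e-3, 1, p), p@vm / 2)
  # monotone in both arguments, bounded by Vm
  cs <- seq(0, 10, length.out = 50)
  expect_true(all(diff(glucoseUptakeRate(cs, 0.5, p)) >= 0))
  ebs <- seq(0, 1, length.out = 50)
  expect_true(all(diff(glucoseUptakeRate(1, ebs, p)) >= 0))
  expect_true(all(glucoseUptakeRate(cs, 1, p) <= p@vm))
  expect_error(glucoseUptakeRate(-1, 0.5, p), "nonnegative")
  expect_error(glucoseUptakeRate(1, 1.5, p), "\\[0, 1\\]")
})

test_that("lactate is produced at twice the glucose uptake rate", {
  expect_equal(lactateRate(0), 0)
  expect_equal(lactateRate(1.95e-5), 3.9e-5)
  rg <- runif(20)
  expect_equal(lactateRate(rg) / rg, rep(2, 20))
  expect_error(lactateRate(-1), "nonnegative")
})

test_that("pH is affine and strictly decreasing in lactate", {
  expect_equal(phFromLactate(0), 7.4)
  expect_equal(phFromLactate(10), 6.994)
  # two-point slope recovers -0.0406
  expect_equal((phFromLactate(5) - phFromLactate(0)) / 5, -0.0406)
  # the viability threshold is crossed at cl = (7.4 - 6.8)/0.0406
  clStar <- (7.4 - 6.8) / 0.0406
  expect_equal(phFromLactate(clStar), 6.8)
  expect_error(phFromLactate(-0.1), "nonnegative")
})

test_that("viability gate is inclusive at the threshold", {
  expect_equal(viabilityStep(7.4), 1)
  expect_equal(viabilityStep(6.5, 6.8), 0)
  expect_equal(viabilityStep(6.8, 6.8), 1)   # alive at exactly 6.8
  expect_equal(viabilityStep(c(7, 6.7), 6.8), c(1, 0))
})

test_that("shear growth law reproduces the published branches", {
  expect_equal(shearGrowthFactor(0, p), p@kg0 * 0.8761)
  expect_equal(shearGrowthFactor(0.3, p), p@kg0 * 11.326)
  expect_equal(shearGrowthFactor(0.8, p), p@kg0 * 2.5 * 0.2 * 11.326)
  expect_equal(shearGrowthFactor(1.5, p), 0)
  expect_error(shearGrowthFactor(-0.1, p), "nonnegative")
})

test_that("shear growth factor is continuous across its branch points", {
  # linear branch meets the plateau at 0.1 Pa within 1e-3 (printed constants)
  expect_equal(p@alphaC + p@betaC * 0.1, 11.326, tolerance = 1e-3 / 11.326)
  expect_equal(2.5 * (1 - 0.6) * 11.326, 11.326)
  eps <- 1e-9
  expect_lt(abs(shearGrowthFactor(0.6 - eps, p) -
                  shearGrowthFactor(0.6 + eps, p)) / p@kg0, 1e-6)
  expect_lt(shearGrowthFactor(1 - eps, p) / p@kg0, 1e-6)
  expect_equal(shearGrowthFactor(1, p), 0)
  # stimulation / inhibition / lethality ordering
  expect_gt(shearGrowthFactor(0.3, p), shearGrowthFactor(0, p))
  expect_lt(shearGrowthFactor(0.9, p), shearGrowthFactor(0.3, p))
})

test_that("growth rate saturates in glucose and self-limits in cell fraction", {
  expect_equal(growthRate(1e9, 0.5, 0.3, p), shearGrowthFactor(0.3, p),
               tolerance = 1e-6)
  expect_equal(growthRate(0, 0.5, 0.3, p), 0)
  expect_equal(growthRate(0, 0, 0, p), 0)    # vanishing denominator
  # half-saturation identity: cgc = kc * rhoCell * epsC
  cgc <- p@kc * p@rhoCell * 0.4
  expect_equal(growthRate(cgc, 0.4, 0.2, p), shearGrowthFactor(0.2, p) / 2)
  expect_true(all(growthRate(seq(0, 5, 0.5), 0.3, 0.05, p) <=
                    shearGrowthFactor(0.05, p)))
})

test_that("cell volume converts densities to sensible fractions", {
  expect_equal(cellVolume(p), pi / 6 * (13e-6)^3)
  eps0 <- 5e7 * 1e6 * cellVolume(p)     # 5e7 cells/cm^3 in SI
  expect_gt(eps0, 0.05)
  expect_lt(eps0, 0.07)
})
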