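test_that("sagitta relation reproduces the published worked diameters", {
  # printed dimensions truncate sub-micrometre fractions:
  # (100^2 + 7^2)/7 = 1435.57 is printed as 1435
  expect_equal(trunc(diameterFromDelta(7, 100)), 1435)
  expect_equal(diameterFromDelta(7, 100), 10049 / 7)
  expect_equal(trunc(diameterFromDelta(17, 100)), 605)
  expect_equal(diameterFromDelta(100, 100), 200)   # tangent minimum D = 2r
  expect_equal(diameterFromDelta(50, 100), 250)    # (10000 + 2500)/50
  expect_identical(diameterFromDelta(0, 100), Inf) # flat-wall sentinel
  expect_error(diameterFromDelta(-1, 100), "\\[0, r\\]")
  expect_error(diameterFromDelta(101, 100), "\\[0, r\\]")
})

test_that("inverse sagitta relation and round trip", {
  expect_equal(deltaFromDiameter(200, 100), 100)
  expect_equal(deltaFromDiameter((1e4 + 49) / 7, 100), 7)
  expect_equal(deltaFromDiameter(520, 100), (520 - sqrt(520^2 - 4e4)) / 2)
  expect_equal(deltaFromDiameter(520, 100), 20)
  expect_error(deltaFromDiameter(150, 100), ">= 2 r")
  deltas <- seq(0.5, 100, length.out = 40)
  expect_equal(deltaFromDiameter(diameterFromDelta(deltas), 100), deltas,
               tolerance = 1e-9)
  # D(delta) strictly decreasing on (0, r], minimum 2r at delta = r
  D <- diameterFromDelta(deltas)
  expect_true(all(diff(D) < 0))
  expect_true(all(D >= 200))
})

test_that("attachment area matches the cap-arc formula and its limits", {
  expect_equal(attachmentArea(1435, 200, 200), 4.01e-8, tolerance = 5e-3)
  expect_equal(attachmentArea(200, 200, 200), pi * 100 * 200 * 1e-12)
  expect_equal(attachmentArea(Inf, 200, 200), 4.0e-8)  # flat-face limit
  expect_error(attachmentArea(150, 200, 200), ">= chord")
  # decreases toward the flat limit as D grows, maximal at the half-cylinder
  Ds <- c(200, 300, 500, 1000, 5000, 1e6)
  areas <- attachmentArea(Ds, 200, 200)
  expect_true(all(diff(areas) < 0))
  expect_gt(min(areas), 4.0e-8 - 1e-12)
})

test_that("attachment angle is a bounded descriptive output", {
  expect_equal(attachmentAngle(unitDesign(100, 100)), 90)
  expect_equal(attachmentAngle(unitDesign(17, 40)), asin(200 / ((1e4 + 289) / 17)) * 180 / pi)
  expect_lt(attachmentAngle(unitDesign(7, 90)), 10)   # nearly flat
  expect_equal(attachmentAngle(unitDesign(0, 50)), 0) # flat wall
})

test_that("voxelized solid volume converges first-order to the segment volume", {
  d <- unitDesign(100, 0, culturedSurfaces = "bottom")
  exact <- 2 * segmentArea(100) / 200^2       # top + bottom half-cylinders
  errs <- sapply(c(16, 32, 64), function(n)
    abs(solidVolumeFraction(voxelize(d, n)) - exact))
  expect_true(all(diff(errs) < 0))
  # first order: error ratio about 2 under mesh halving
  expect_gt(errs[1] / errs[2], 1.6)
  expect_gt(errs[2] / errs[3], 1.6)
  expect_lt(errs[3], 0.05)
})

test_that("voxel labels satisfy the domain invariants", {
  d <- unitDesign(50, 80, culturedSurfaces = c("bottom", "front"))
  dom <- voxelize(d, 16)
  expect_true(all(dom@labels %in% 0:2))
  expect_identical(dim(dom@labels), dom@dims)
  # biomass voxels exactly marked by shellFace
  expect_identical(dom@shellFace > 0L, dom@labels == 2L)
  expect_setequal(unique(as.integer(dom@shellFace[dom@labels == 2L])),
                  c(1L, 3L))
  # flat walls: no solid, all-fluid duct
  duct <- voxelize(unitDesign(0, 0), 12)
  expect_equal(sum(duct@labels == 1L), 0)
  # flat cultured wall still gets a shell
  duct2 <- voxelize(unitDesign(0, 0, culturedSurfaces = "bottom"), 12)
  expect_gt(sum(duct2@labels == 2L), 0)
  expect_true(all(which(duct2@labels == 2L, arr.ind = TRUE)[, 3] == 1L))
})

test_that("biomass shell hugs the cultured cap only", {
  d <- unitDesign(60, 60, culturedSurfaces = "bottom")
  dom <- voxelize(d, 16)
  bio <- which(dom@labels == 2L, arr.ind = TRUE)
  # all biomass voxels in the lower half (bottom cap region)
  expect_true(all(bio[, 3] <= 9))
})

test_that("fully blocked cross-sections raise an occlusion error", {
  d <- unitDesign(100, 100)
  labels <- array(0L, c(8, 8, 8))
  labels[4, , ] <- 1L                      # a solid wall across the duct
  expect_error(ductDomain(c(8, 8, 8), 1e-5, labels = labels), "occluded")
  # the tangent reference design remains open through the cusp channels
  expect_s4_class(voxelize(d, 16), "VoxelDomain")
})

test_that("minimum cross-section matches closed forms and is monotone", {
  duct <- voxelize(unitDesign(0, 0), 16)
  expect_equal(minCrossSection(duct), 4.0e-8)
  # one half-cylinder cap built directly: free area = (2r)^2 - pi r^2 / 2
  n <- 64
  h <- 200 / n
  ctr <- -100 + (seq_len(n) - 0.5) * h
  cor0 <- ctr - h / 2; cor1 <- ctr + h / 2
  xm <- pmax(abs(cor0), abs(cor1))
  tm <- pmax(abs(cor0 + 100), abs(cor1 + 100))     # axis at z = -100
  solid2d <- outer(xm^2, tm^2, "+") < 100^2
  labels <- array(0L, c(n, n, n))
  for (k in seq_len(n)) labels[, , k] <- matrix(solid2d[, k], n, n)
  labels <- aperm(labels, c(1, 3, 2))              # cap invariant along y
  dom <- ductDomain(c(n, n, n), h * 1e-6, labels = labels)
  exact <- (200^2 - segmentArea(100)) * 1e-12
  expect_equal(minCrossSection(dom), exact, tolerance = 0.06)
  expect_equal(exact, 2.43e-8, tolerance = 5e-3)
  # growing any fiber never increases the free cross-section
  mcs <- sapply(c(20, 40, 60, 80, 100), function(dz)
    minCrossSection(voxelize(unitDesign(50, dz), 16)))
  expect_true(all(diff(mcs) <= 0))
})

test_that("geometry metrics are assembled consistently", {
  d <- unitDesign(7, 90, culturedSurfaces = "bottom")
  m <- geometryMetrics(voxelize(d, 16))
  expect_equal(m$attachmentArea, attachmentArea(diameterFromDelta(7), 200, 200))
  expect_equal(m$effectiveCurvature, 1 / diameterFromDelta(7))
  expect_true(m$minCrossSection > 0 &&
                m$minCrossSection <= 4.0e-8 + 1e-12)
  expect_true(all(unlist(m) >= 0))
})

test_that("design validity enforces the displacement range", {
  expect_error(unitDesign(150, 50), "\\[0, r\\]")
  expect_error(unitDesign(-2, 50), "\\[0, r\\]")
  expect_error(unitDesign(10, 10, culturedSurfaces = "left"), "unknown")
})
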