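test_that("candidate sampling is uniform, in-range and seed-reproducible", {
  c1 <- sampleCandidates(50, seed = 11)
  c2 <- sampleCandidates(50, seed = 11)
  expect_identical(sapply(c1, slot, "deltaY"), sapply(c2, slot, "deltaY"))
  expect_identical(sapply(c1, slot, "deltaZ"), sapply(c2, slot, "deltaZ"))
  dys <- sapply(c1, slot, "deltaY")
  expect_true(all(dys >= 0 & dys <= 100))
  # Monte-Carlo check of the uniform mean on (0, 100)
  big <- sampleCandidates(1e4, seed = 3)
  expect_equal(mean(sapply(big, slot, "deltaY")), 50, tolerance = 1 / 50)
  expect_error(sampleCandidates(5, 1, rangeUm = c(50, 10)), "increasing")
  expect_error(sampleCandidates(5, 1, rangeUm = c(0, 150)), "within")
  # sampling must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sampleCandidates(10, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("campaign with a known separable objective recovers its argmax", {
  mock <- function(d) -(d@deltaY - 7)^2 - (d@deltaZ - 90)^2
  grid <- c(list(unitDesign(7, 90)),
            sampleCandidates(30, seed = 5))
  camp <- runCampaign(candidates = grid, evaluator = mock)
  best <- bestDesign(camp)
  expect_equal(best@deltaY, 7)
  expect_equal(best@deltaZ, 90)
  # ranking correctness: the reported best dominates every completed CE
  expect_true(all(camp@results$ce <= camp@results$ce[camp@best]))
  # coverage: with more samples the sampled optimum approaches the truth
  d10 <- runCampaign(candidates = sampleCandidates(10, seed = 2),
                     evaluator = mock)
  d200 <- runCampaign(candidates = sampleCandidates(200, seed = 2),
                      evaluator = mock)
  expect_lte(-d200@results$ce[d200@best], -d10@results$ce[d10@best])
})

test_that("single-candidate campaigns work and ties break by area then index",
{
  one <- runCampaign(candidates = list(unitDesign(20, 20)),
                     evaluator = function(d) 0.5)
  expect_equal(one@best, 1L)
  # equal CE: larger attachment area wins (larger delta, smaller D, longer
  # arc), then the lower candidate index
  tie <- runCampaign(candidates = list(unitDesign(10, 50),
                                       unitDesign(50, 50),
                                       unitDesign(50, 50)),
                     evaluator = function(d) 1)
  expect_equal(tie@best, 2L)
})

test_that("failed candidates are excluded but the campaign continues", {
  ev <- function(d) if (d@deltaY < 50) stop("synthetic failure") else 0.1
  camp <- runCampaign(candidates = list(unitDesign(10, 50),
                                        unitDesign(80, 50)),
                      evaluator = ev)
  expect_equal(sum(camp@results$status == "ok"), 1)
  expect_equal(camp@best, 2L)
  expect_error(runCampaign(candidates = list(unitDesign(10, 50)),
                           evaluator = function(d) stop("boom")),
               "no candidate completed")
})

test_that("seeded coarse campaigns are bit-reproducible end-to-end", {
  oc <- operatingConditions(durationH = 2, dtH = 1)
  c1 <- runCampaign(n = 3, seed = 7, oc = oc, resolution = 10L)
  c2 <- runCampaign(n = 3, seed = 7, oc = oc, resolution = 10L)
  expect_identical(c1@results, c2@results)
  expect_identical(c1@best, c2@best)
})

test_that("ratio report bins CE against |deltaY/deltaZ| with special bands", {
  mock <- function(d) 1 / (1 + abs(d@deltaY / max(d@deltaZ, 1e-9)))
  camp <- runCampaign(candidates = sampleCandidates(100, seed = 4),
                      evaluator = mock)
  rep1 <- ratioReport(camp)
  expect_true(all(c("bin", "n", "meanCE", "band") %in% names(rep1)))
  expect_equal(sum(rep1$n), 100)
  # synthetic CE decreasing in ratio: bin means must decrease
  expect_true(all(diff(rep1$meanCE) < 0))
  expect_true("favourable" %in% rep1$band)
  # flat secondary wall goes to the infinite band, not an error
  campInf <- runCampaign(candidates = list(unitDesign(50, 0)),
                         evaluator = function(d) 0.2)
  repInf <- ratioReport(campInf)
  expect_match(repInf$bin[1], "infinite")
  # one candidate, one bin
  expect_equal(nrow(ratioReport(campInf)), 1)
})
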