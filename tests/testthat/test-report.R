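# synthetic full-model samples with controllable draws
reportSamples <- function(subjectsIds = "E", nSessions = 2L,
                          Vdraws = NULL, nd = 1000L, nc = 1L) {
  vm <- fullVarMap(subjectsIds, rep(nSessions, length(subjectsIds)))
  K <- nrow(vm$VMap); G <- length(subjectsIds)
  draws <- list()
  for (k in seq_len(K)) {
    draws[[sprintf("V[%d]", k)]] <-
      if (is.null(Vdraws)) matrix(rnorm(nd * nc, 0, 0.02), nd, nc)
      else matrix(Vdraws, nd, nc)
  }
  for (g in seq_len(G))
    draws[[sprintf("sigma[%d]", g)]] <- matrix(runif(nd * nc, 0.01, 0.03), nd, nc)
  if (G == 1L) {
    draws[["sigma"]] <- draws[["sigma[1]"]]; draws[["sigma[1]"]] <- NULL
  }
  makeSamples(draws, spec = modelSpec(6), varMap = vm)
}

test_that("value summaries pin the quantile convention", {
  # draws = sorted 1..1000 ms: type-7 central 95% interval is
  # (25.975, 975.025) and the median 500.5
  set.seed(1)
  samp <- reportSamples(Vdraws = (1:1000) / 1000)  # seconds
  vs <- valueSummaries(samp)
  expect_identical(nrow(vs), 4L)
  expect_equal(vs$lo[1], 25.975)
  expect_equal(vs$hi[1], 975.025)
  expect_equal(vs$median[1], 500.5)

  # constant draws collapse to a point interval
  sampC <- reportSamples(Vdraws = -0.0125)  # negative values reported as-is
  vsC <- valueSummaries(sampC)
  expect_equal(vsC$median[2], -12.5)
  expect_equal(vsC$lo[2], -12.5)
  expect_equal(vsC$hi[2], -12.5)
})

test_that("summaries cover every subject-category pair and ignore chain order", {
  set.seed(2)
  subj <- sprintf("m%d", 1:8)
  vm <- fullVarMap(subj, rep(3L, 8))
  nd <- 200; nc <- 3
  draws <- list()
  for (k in 1:32) draws[[sprintf("V[%d]", k)]] <- matrix(rnorm(nd * nc, 0, 0.02), nd, nc)
  for (g in 1:8) draws[[sprintf("sigma[%d]", g)]] <- matrix(runif(nd * nc, 0.01, 0.03), nd, nc)
  for (k in 1:32) draws[[sprintf("alpha[%d]", k)]] <- matrix(rnorm(nd * nc, 0, 0.005), nd, nc)
  samp <- makeSamples(draws, spec = modelSpec(7), varMap = vm)

  vs <- valueSummaries(samp)
  expect_identical(nrow(vs), 32L)
  expect_true(all(vs$lo <= vs$median & vs$median <= vs$hi))

  # the time-trend model carries 32 slope parameters over 8 subjects
  ts <- trendSummaries(samp)
  expect_identical(nrow(ts), 32L)
  expect_true(all(ts$slopeLo <= ts$slopeMedian & ts$slopeMedian <= ts$slopeHi))

  # permuting chains leaves the summaries untouched
  samp2 <- samp
  samp2@draws <- samp@draws[, c(3, 1, 2), ]
  expect_equal(valueSummaries(samp2), vs)

  # trend summaries refuse a model without a time trend
  samp6 <- makeSamples(draws[!grepl("alpha", names(draws))],
                       spec = modelSpec(6), varMap = vm)
  expect_error(trendSummaries(samp6), "time trend")
})

test_that("credible intervals shrink with more sessions", {
  des <- studyDesign(c(big = 16L, small = 4L), dvGrid = c(-0.06, 0, 0.06),
                     nPerBlock = 60L)
  sim <- simulateDataset(realisticTruth(des, seed = 13), des, seed = 14)
  fit <- runMCMC(modelSpec(6), sim$dataset, smallConfig(seed = 15))
  vs <- valueSummaries(fit)
  widths <- tapply(vs$hi - vs$lo, vs$subject, mean)
  expect_gt(widths[["small"]], widths[["big"]])
})

test_that("joint category samples preserve within-draw correlation", {
  # a strong shared time trend induces correlated session values across
  # categories; joint sampling must keep it, per-column shuffling kills it
  des <- studyDesign(c(A = 24L), dvGrid = c(-0.06, 0, 0.06), nPerBlock = 80L)
  gt <- drawParameters(des, timeTrend = TRUE, fixed = list(
    V = 0, sigma = 0.006, omega = 0.25, tau = 0.05, alpha = 0.03))
  sim <- simulateDataset(gt, des, seed = 25)
  trueCor <- cor(matrix(sim$truth@sessionValues$value, ncol = 4,
                        byrow = TRUE))
  expect_gt(min(trueCor), 0.8)  # generator-level correlation is strong

  fit <- runMCMC(modelSpec(6), sim$dataset, smallConfig(seed = 26))
  pts <- categoryCorrelationSamples(fit, "A", nPoints = 1000, seed = 27)
  expect_identical(nrow(pts), 1000L)
  expect_identical(colnames(pts), imageCategories())
  rJoint <- cor(pts[, "female"], pts[, "control"])
  expect_gt(rJoint, 0.5)

  # negative control: shuffling categories independently destroys it
  set.seed(28)
  shuffled <- apply(pts, 2, sample)
  rShuf <- cor(shuffled[, "female"], shuffled[, "control"])
  expect_lt(abs(rShuf), 0.1)

  expect_error(categoryCorrelationSamples(fit, "nobody"), "not present")
})

test_that("time-trend slopes are calibrated and detect real drift", {
  # calibration: alpha = 0 -> slope CIs cover 0 at ~95%
  cover <- 0L; total <- 0L
  for (r in 1:3) {
    des <- studyDesign(c(A = 8L, B = 8L), dvGrid = c(-0.06, 0, 0.06),
                       nPerBlock = 60L)
    gt <- drawParameters(des, timeTrend = TRUE, fixed = list(
      V = rnorm(8, 0, 0.02), sigma = 0.02, omega = 0.3,
      tau = runif(16, 0.04, 0.06), alpha = 0))
    sim <- simulateDataset(gt, des, seed = 300 + r)
    fit <- runMCMC(modelSpec(7), sim$dataset,
                   chainConfig(nChains = 2, nAdapt = 300, nBurn = 600,
                               nIter = 1600, thin = 4, seed = 400 + r))
    ts <- trendSummaries(fit)
    cover <- cover + sum(ts$slopeLo <= 0 & ts$slopeHi >= 0)
    total <- total + nrow(ts)
  }
  expect_gte(cover / total, 0.85)

  # power: a -5 ms/rank-unit drift at 60 well-measured sessions excludes 0
  des60 <- studyDesign(c(E = 60L), dvGrid = c(-0.08, -0.04, 0, 0.04, 0.08),
                       nPerBlock = 100L)
  gt60 <- drawParameters(des60, timeTrend = TRUE, fixed = list(
    V = 0.01, sigma = 0.010, omega = 0.3, tau = 0.05, alpha = -0.005))
  sim60 <- simulateDataset(gt60, des60, seed = 61)
  fit60 <- runMCMC(modelSpec(7), sim60$dataset,
                   chainConfig(nChains = 2, nAdapt = 300, nBurn = 800,
                               nIter = 2400, thin = 6, seed = 62))
  ts60 <- trendSummaries(fit60)
  expect_gte(sum(ts60$slopeHi < 0), 3)  # drift detected across categories
  expect_equal(mean(ts60$slopeMedian), -5, tolerance = 0.5)
})
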