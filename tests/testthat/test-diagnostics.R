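test_that("pooling fractions match hand-computed oracles", {
  # 2 units x 2 draws, residuals (1,-1) in each unit: within-unit means are
  # (0, 0), so the between-unit variance vanishes and lambda = 1
  eps <- rbind(c(1, -1), c(1, -1))
  x <- rbind(c(2, 0), c(0, 2))
  out <- poolingFractions(x, eps)
  expect_identical(unname(out["lambda"]), 1)

  # residuals identically zero: R^2 = 1
  expect_identical(unname(poolingFractions(x, 0 * eps)["R2"]), 1)

  # opposite extreme: unit means as spread as the draws -> lambda = 0
  eps0 <- rbind(c(1, 1), c(-1, -1))
  expect_identical(unname(poolingFractions(x, eps0)["lambda"]), 0)

  # plain arithmetic case, worked by hand:
  # eps = [(1, 3), (-1, -3)]: pooled entries {1, 3, -1, -3} -> var(eps) = 5;
  # unit means (2, -2) -> var(E_u[eps]) = 4; lambda = 1 - 4/5
  epsH <- rbind(c(1, 3), c(-1, -3))
  expect_equal(unname(poolingFractions(x, epsH)["lambda"]), 1 - 4 / 5)
  # R^2 against x = [(2,0),(0,2)]: var(x) per draw = 1 -> R2 = 1 - 5/1
  expect_equal(unname(poolingFractions(x, epsH)["R2"]), 1 - 5)

  # property: lambda stays in [0, 1] for arbitrary residual sets
  set.seed(14)
  for (i in 1:25) {
    e <- matrix(rnorm(12 * 7, sd = runif(1, 0.1, 10)), 12, 7)
    lam <- unname(poolingFractions(matrix(rnorm(12), 12, 1), e)["lambda"])
    expect_gte(lam, 0)
    expect_lte(lam, 1)
  }
})

test_that("DIC arithmetic: identity, degenerate pD, Gaussian effective parameters", {
  # degenerate posterior: constant parameter draws -> pD = 0, DIC = Dbar
  rep0 <- dicFromDeviance(matrix(42.5, 50, 2), 42.5)
  expect_identical(rep0@pD, 0)
  expect_identical(rep0@DIC, rep0@Dbar)

  # conjugate Normal-Normal: closed-form posterior; for a Gaussian
  # likelihood pD equals n * Var_post(theta) / sigma^2 (the shrinkage sum)
  set.seed(6)
  n <- 25; y <- rnorm(n, 1, 1)
  postVar <- 1 / (n + 1 / 100)  # sigma = 1, prior sd 10
  postMean <- postVar * sum(y)
  theta <- matrix(rnorm(8000, postMean, sqrt(postVar)), 2000, 4)
  devOf <- function(th) -2 * vapply(th, function(t)
    sum(dnorm(y, t, 1, log = TRUE)), 0)
  devDraws <- matrix(devOf(as.vector(theta)), 2000, 4)
  repG <- dicFromDeviance(devDraws, devOf(mean(theta)))
  pDExp <- n * postVar
  expect_lt(abs(repG@pD - pDExp), 0.06)  # ~3.5 MC s.e. of the pD estimate
  expect_equal(repG@DIC, repG@Dbar + repG@pD)

  # >1% non-finite deviance draws is an error
  bad <- matrix(42.5, 50, 2); bad[1:3] <- Inf
  expect_error(dicFromDeviance(bad, 42.5), "non-finite")
})

test_that("model DIC is built from the package's own deviance", {
  fit <- smallFit()
  sim <- smallSim()
  rep6 <- dic(fit, sim$dataset)
  expect_equal(rep6@DIC, rep6@Dbar + rep6@pD)
  expect_gt(rep6@pD, 0)
  expect_identical(rep6@nNonFinite, 0L)

  # cross-check one retained draw against choiceDeviance()
  idx <- socialval:::.modelIndex(fit@spec, sim$dataset)
  lvars <- sprintf("logitp[%d]", seq_len(idx$B))
  oneDraw <- fit@draws[7, 2, lvars]
  par <- list(logitp = unname(oneDraw))
  dev1 <- choiceDeviance(par, fit@spec, sim$dataset)
  b <- idx$blocks
  expect_equal(dev1, -2 * sum(dbinom(b$n, b$N, plogis(unname(oneDraw)),
                                     log = TRUE)), tolerance = 1e-10)

  # deviance (and so DIC) ignores the prior: same draws, different priors
  specWide <- modelSpec(6, priors = priorConfig(VVariance = 100))
  repW <- dic(fit, sim$dataset, spec = specWide)
  expect_equal(repW@Dbar, rep6@Dbar)
  expect_equal(repW@DIC, rep6@DIC)
})

test_that("pooling metrics on a fitted model stay in range and flag levels", {
  fit <- smallFit()
  pool <- poolingMetrics(fit, smallSim()$dataset)
  lv <- pool@levels
  expect_identical(lv$level, c("session", "utility", "counts"))
  expect_true(all(lv$lambda >= 0 & lv$lambda <= 1))
  expect_true(all(lv$R2 <= 1))
  expect_equal(names(pool@residuals), c("session", "utility", "counts"))
  # partial pooling only
  fitComplete <- runMCMC(modelSpec(2), smallSim()$dataset,
                         chainConfig(nChains = 2, nAdapt = 150, nBurn = 150,
                                     nIter = 300, thin = 2, seed = 5))
  expect_error(poolingMetrics(fitComplete, smallSim()$dataset), "partial")
})

test_that("choice-curve fits recover the generating parameters", {
  # symmetry: counts symmetric about dv = 0 give beta0 = 0, pse = 0
  sym <- data.frame(dv = c(-0.04, 0, 0.04), n = c(4L, 10L, 16L), N = 20L)
  fit <- fitChoiceCurve(sym)
  expect_lt(abs(fit$beta0), 1e-8)
  expect_lt(abs(fit$pse), 1e-8)
  expect_false(fit$separable)
  expect_equal(fit$width, 1 / fit$beta1)

  # 3-point toy against a brute-force likelihood grid
  toy <- data.frame(dv = c(-0.04, 0, 0.04), n = c(2L, 10L, 18L), N = 20L)
  gfit <- fitChoiceCurve(toy)
  nll <- function(b0, b1) {
    p <- plogis(b0 + b1 * toy$dv)
    -sum(dbinom(toy$n, toy$N, p, log = TRUE))
  }
  b0g <- gfit$beta0; b1g <- gfit$beta1
  grid0 <- seq(b0g - 0.5, b0g + 0.5, length.out = 41)
  grid1 <- seq(b1g - 20, b1g + 20, length.out = 41)
  for (pass in 1:4) {
    vals <- outer(grid0, grid1, Vectorize(nll))
    hit <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best0 <- grid0[hit[1]]; best1 <- grid1[hit[2]]
    span0 <- diff(range(grid0)) / 8; span1 <- diff(range(grid1)) / 8
    grid0 <- seq(best0 - span0, best0 + span0, length.out = 41)
    grid1 <- seq(best1 - span1, best1 + span1, length.out = 41)
  }
  expect_equal(gfit$beta0, best0, tolerance = 1e-4)
  expect_equal(gfit$beta1, best1, tolerance = 1e-3)

  # generative recovery: omega -> 0, v = 20 ms, tau = 40 ms, large N
  des <- studyDesign(c(X = 1L), dvGrid = seq(-0.08, 0.08, by = 0.02),
                     nPerBlock = 8000L)
  gt <- drawParameters(des, fixed = list(V = 0.02, sigma = 1e-9, omega = 0,
                                         tau = 0.04))
  sim <- simulateDataset(gt, des, seed = 41)
  b <- choiceBlocks(sim$dataset)
  rec <- fitChoiceCurve(b[b$category == "female", ])
  expect_lt(abs(rec$pse - (-0.02)), 0.002)
  expect_lt(abs(rec$width - 0.04), 0.004)

  # separation is flagged, not papered over
  sep <- data.frame(dv = c(-0.02, 0.02), n = c(0L, 20L), N = 20L)
  sfit <- fitChoiceCurve(sep)
  expect_true(sfit$separable)
  expect_error(fitChoiceCurve(data.frame(dv = 0, n = 1L, N = 2L)),
               "distinct dv")
})

test_that("posterior predictive sessions mirror the generative model", {
  fit <- smallFit()
  ppc <- posteriorPredictiveSessions(fit, 24, dvGrid = c(-0.06, 0, 0.06),
                                     nPerBlock = 60L, seed = 9)
  expect_s4_class(ppc, "ChoiceDataset")
  expect_true(validObject(ppc))
  expect_identical(length(sessions(ppc)), 24L)
  expect_setequal(unique(choiceBlocks(ppc)$subject), c("A", "B"))

  # collapsed posterior: PPC behaves like simulateDataset at that point
  vm <- fullVarMap("A", 2L)
  nd <- 40; nc <- 2
  mk <- function(val) matrix(val, nd, nc)
  draws <- list()
  Vtrue <- c(control = -0.02, female = 0.03, dominant_male = 0.01,
             subordinate_male = 0)
  for (k in seq_len(4)) draws[[sprintf("V[%d]", k)]] <- mk(Vtrue[vm$VMap$catGroup[k]])
  draws[["sigma"]] <- mk(1e-6)
  draws[["omega"]] <- mk(1e-6)
  draws[["ell"]] <- mk(0.05); draws[["sca"]] <- mk(1e-4); draws[["nu"]] <- mk(49)
  for (j in seq_len(nrow(vm$vMap))) draws[[sprintf("v[%d]", j)]] <- mk(0)
  samp <- makeSamples(draws, spec = modelSpec(6), varMap = vm)
  ppc2 <- posteriorPredictiveSessions(samp, 60, dvGrid = c(-0.05, 0, 0.05),
                                      nPerBlock = 400L, seed = 10)
  b2 <- choiceBlocks(ppc2)
  # with sigma, omega ~ 0 and tau ~ 0.05, empirical choice fractions track
  # plogis((dv + V) / tau)
  for (cat in c("female", "control")) {
    for (dv in c(-0.05, 0, 0.05)) {
      rows <- b2$category == cat & abs(b2$dv - dv) < 1e-9
      pExp <- plogis((dv + Vtrue[cat]) / 0.05)
      pObs <- sum(b2$n[rows]) / sum(b2$N[rows])
      expect_lt(abs(pObs - pExp),
                3 * sqrt(max(pExp * (1 - pExp), 0.002) / sum(b2$N[rows])) + 0.01)
    }
  }
})

test_that("posterior predictive refits are indistinguishable from the source", {
  cf <- canonicalFit()
  ppc <- posteriorPredictiveSessions(cf$fit, 160, seed = 12)
  ks <- ppcKsCheck(cf$sim$dataset, ppc)
  expect_gt(ks$valueP, 0.01)
  expect_gt(ks$widthP, 0.01)
  expect_gt(nrow(ks$ppcFits), 100)
})

test_that("model comparison table is ordered and deterministic", {
  sim <- smallSim()
  cfg <- chainConfig(nChains = 2, nAdapt = 200, nBurn = 400, nIter = 1200,
                     thin = 4, seed = 23)
  tab <- compareModels(sim$dataset, list(modelSpec(2), modelSpec(6),
                                         modelSpec(2)), cfg)
  expect_identical(nrow(tab), 3L)
  expect_true(!is.unsorted(tab$DIC))
  expect_true(all(c("Dbar", "pD", "DIC", "maxRhat", "converged") %in%
                  names(tab)))
  # identical spec + identical protocol -> identical DIC (determinism)
  dups <- tab[tab$label == "model2", ]
  expect_equal(dups$DIC[1], dups$DIC[2], tolerance = 1e-10)
})
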