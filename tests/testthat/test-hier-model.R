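# one-session, one-category toy dataset plus a conforming parameter set
toyData <- function(n = 12L, N = 20L, dv = 0) {
  ChoiceDataset(data.frame(subject = "E", session = "s1",
                           category = "female", dv = dv, n = n, N = N),
                c(s1 = "2008-01-01"))
}
toyParams <- function(logitp = 0, v = 0.02, tau = 0.05, omega = 0.4,
                      sigma = 0.02, V = 0.01) {
  list(V = V, v = v, sigma = sigma, omega = omega, tau = tau,
       ell = 0.25, sca = 0.05, nu = 4, logitp = logitp)
}

test_that("log prior matches closed forms and rejects out-of-support values", {
  ds <- toyData()
  spec <- modelSpec(6)
  base <- toyParams()
  lp <- logPrior(base, spec, ds)
  manual <- dnorm(0.01, 0, 0.1, log = TRUE) -           # V
    log(1 - 1e-6) -                                     # sigma ~ U(1e-6, 1)
    log(2 - (-6)) -                                     # log omega ~ U(-6, 2)
    log(0.5 - 0) - log(0.1 - 1e-4) - log(50 - 0.1) +    # tau hyperpriors
    dtplus(0.05, 0.25, 0.05, 4, log = TRUE) +           # tau
    dnorm(0.02, 0.01, 0.02, log = TRUE)                 # v | V, sigma
  expect_equal(lp, manual, tolerance = 1e-12)

  # V at its mode contributes -0.5 log(2 pi 0.01)
  expect_equal(dnorm(0, 0, 0.1, log = TRUE), -0.5 * log(2 * pi * 0.01))

  expect_identical(logPrior(toyParams(sigma = 2), spec, ds), -Inf)
  expect_identical(logPrior(toyParams(omega = exp(3)), spec, ds), -Inf)
  expect_identical(logPrior(toyParams(tau = -0.1), spec, ds), -Inf)
})

test_that("truncated-t prior term is correctly normalized", {
  # density integrates to 1 over the positive half-line
  total <- integrate(dtplus, 0, Inf, location = 0.25, scale = 0.05, df = 4,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # log density = log t - log upper-tail mass at 0
  manual <- dt((0.2 - 0.25) / 0.05, 4, log = TRUE) - log(0.05) -
    pt((0 - 0.25) / 0.05, 4, lower.tail = FALSE, log.p = TRUE)
  expect_equal(dtplus(0.2, 0.25, 0.05, 4, log = TRUE), manual,
               tolerance = 1e-12)
})

test_that("log likelihood composes the logit-normal and binomial layers", {
  ds <- toyData(n = 10L, N = 20L)
  spec <- modelSpec(6)
  par <- toyParams(logitp = 0)
  ll <- logLikelihood(par, spec, ds)
  eta <- (0 + 0.02) / 0.05
  manual <- dnorm(0, eta, 0.4, log = TRUE) +
    (lchoose(20, 10) + 20 * log(0.5))
  expect_equal(ll, manual, tolerance = 1e-12)

  # marginal over the latent logit p: Gauss-Hermite vs adaptive quadrature
  omega <- 0.35
  joint <- function(L) {
    vapply(L, function(l)
      exp(logLikelihood(toyParams(logitp = l, omega = omega), spec, ds)), 0)
  }
  adaptive <- integrate(joint, -30, 30, rel.tol = 1e-12)$value
  gh <- pracma::gaussHermite(60)
  ghVal <- sum(gh$w * dbinom(10, 20, plogis(eta + sqrt(2) * omega * gh$x))) /
    sqrt(pi)
  expect_equal(adaptive, ghVal, tolerance = 1e-8)
})

test_that("likelihood is invariant to session relabeling under complete pooling", {
  sim <- smallSim()
  ds <- sim$dataset
  spec <- modelSpec(2)  # one model per subject
  idx <- socialval:::.modelIndex(spec, ds)
  par <- list(V = rep(0.01, idx$K), omega = rep(0.4, idx$G),
              tau = runif(idx$S, 0.04, 0.06),
              ell = 0.2, sca = 0.05, nu = 5,
              logitp = rnorm(idx$B, 0, 1))
  ll1 <- logLikelihood(par, spec, ds)

  # reverse block order: sessions are discovered in a different order
  b2 <- choiceBlocks(ds)[rev(seq_len(idx$B)), ]
  ds2 <- ChoiceDataset(b2, sessionDates(ds), sessionSubjects(ds))
  idx2 <- socialval:::.modelIndex(spec, ds2)
  par2 <- par
  par2$tau <- par$tau[match(idx2$sessions, idx$sessions)]
  par2$logitp <- rev(par$logitp)
  expect_equal(logLikelihood(par2, spec, ds2), ll1, tolerance = 1e-10)
})

test_that("deviance is the binomial focus only", {
  ds <- toyData(n = 12L, N = 20L)
  spec <- modelSpec(6)
  par <- toyParams(logitp = qlogis(0.6))
  expect_equal(choiceDeviance(par, spec, ds),
               -2 * dbinom(12, 20, 0.6, log = TRUE), tolerance = 1e-12)

  # invariant to prior hyperparameters
  spec2 <- modelSpec(6, priors = priorConfig(VVariance = 1, alphaVariance = 5))
  expect_identical(choiceDeviance(par, spec, ds),
                   choiceDeviance(par, spec2, ds))

  # saturated limit: p -> n/N at n in {0, N} drives deviance to 0
  ds2 <- ChoiceDataset(data.frame(subject = "E", session = "s1",
                                  category = "female", dv = c(-0.05, 0.05),
                                  n = c(0L, 20L), N = 20L),
                       c(s1 = "2008-01-01"))
  par2 <- toyParams(logitp = c(-40, 40), v = 0.02)
  par2$logitp <- c(-40, 40)
  expect_lt(choiceDeviance(par2, spec, ds2), 1e-10)
})

test_that("the hierarchy nests: sigma -> 0 collapses onto complete pooling", {
  sim <- smallSim()
  ds <- sim$dataset
  idx6 <- socialval:::.modelIndex(modelSpec(6), ds)
  idx1 <- socialval:::.modelIndex(modelSpec(1), ds)
  Vval <- rnorm(idx1$K, 0, 0.02)
  logitp <- rnorm(idx6$B, 0, 1)
  tau <- runif(idx6$S, 0.04, 0.06)
  # map each Model-6 cell to its (subject, category) mean and set v = V
  vCollapsed <- Vval[idx6$vMap$k]
  par6 <- list(V = Vval, v = vCollapsed, sigma = rep(1e-9, idx6$G),
               omega = rep(0.4, idx6$G), tau = tau, ell = 0.2, sca = 0.05,
               nu = 5, logitp = logitp)
  par1 <- list(V = Vval, omega = rep(0.4, idx1$G), tau = tau, ell = 0.2,
               sca = 0.05, nu = 5, logitp = logitp)
  expect_equal(logLikelihood(par6, modelSpec(6), ds),
               logLikelihood(par1, modelSpec(1), ds), tolerance = 1e-10)
})

test_that("indifference point is the negated value", {
  expect_identical(indifferencePoint(0), 0)
  expect_equal(indifferencePoint(0.025, units = "ms"), -25)
  # at dv = -v the composed choice probability is exactly 0.5, any tau
  for (tau in c(0.01, 0.05, 0.3)) {
    eta <- (indifferencePoint(0.05) + 0.05) / tau
    expect_equal(plogis(eta), 0.5)
  }
  expect_error(indifferencePoint(Inf))
})
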