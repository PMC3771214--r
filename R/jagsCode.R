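#' @include hierModel.R
NULL

# Generate JAGS model code for a pooling variant. The code mirrors the
# package's own densities in logPrior()/logLikelihood(): an overdispersed
# logit-normal binomial observation layer, a session-value layer whose
# structure depends on the session pooling mode, Normal priors on group
# means and slopes, Uniform priors on sigma and log(omega), and a shared
# positively-truncated t prior on the per-session utility scale.
.jagsCode <- function(spec) {
  p <- spec@priors
  hasV <- spec@sessionPooling != "none"
  hasv <- spec@sessionPooling != "complete"
  valueTerm <- if (hasv) "v[jblk[b]]" else "V[kblk[b]]"
  lines <- c(
    "model {",
    "  for (b in 1:B) {",
    sprintf("    eta[b] <- (dv[b] + %s) / tau[sblk[b]]", valueTerm),
    "    logitp[b] ~ dnorm(eta[b], 1 / (omega[gblk[b]] * omega[gblk[b]]))",
    "    p[b] <- ilogit(logitp[b])",
    "    n[b] ~ dbin(p[b], N[b])",
    "  }")
  if (hasv) {
    mu <- if (!hasV) "0"
    else if (spec@timeTrend) "V[vidx[j]] + alpha[vidx[j]] * tc[j]"
    else "V[vidx[j]]"
    prec <- if (spec@sessionPooling == "partial")
      "1 / (sigma[gcell[j]] * sigma[gcell[j]])"
    else sprintf("%.10g", 1 / p@VVariance)
    lines <- c(lines,
      "  for (j in 1:J) {",
      sprintf("    v[j] ~ dnorm(%s, %s)", mu, prec),
      "  }")
  }
  if (hasV) {
    lines <- c(lines,
      "  for (k in 1:K) {",
      sprintf("    V[k] ~ dnorm(0, %.10g)", 1 / p@VVariance),
      if (spec@timeTrend)
        sprintf("    alpha[k] ~ dnorm(0, %.10g)", 1 / p@alphaVariance),
      "  }")
  }
  lines <- c(lines,
    "  for (g in 1:G) {",
    if (spec@sessionPooling == "partial")
      sprintf("    sigma[g] ~ dunif(%.10g, %.10g)",
              p@sigmaBounds[1], p@sigmaBounds[2]),
    sprintf("    logomega[g] ~ dunif(%.10g, %.10g)",
            p@logOmegaBounds[1], p@logOmegaBounds[2]),
    "    omega[g] <- exp(logomega[g])",
    "  }",
    "  for (s in 1:S) {",
    "    tau[s] ~ dt(ell, 1 / (sca * sca), nu) T(1.0E-6,)",
    "  }",
    sprintf("  ell ~ dunif(%.10g, %.10g)",
            p@tauLocationBounds[1], p@tauLocationBounds[2]),
    sprintf("  sca ~ dunif(%.10g, %.10g)",
            p@tauScaleBounds[1], p@tauScaleBounds[2]),
    sprintf("  nu ~ dunif(%.10g, %.10g)",
            p@tauDfBounds[1], p@tauDfBounds[2]),
    "}")
  paste(lines[!vapply(lines, is.null, TRUE)], collapse = "\n")
}

.jagsData <- function(spec, idx) {
  b <- idx$blocks
  dat <- list(B = idx$B, n = b$n, N = b$N, dv = b$dv,
              sblk = idx$sOfBlock, gblk = idx$gOfBlock,
              S = idx$S, G = idx$G)
  if (spec@sessionPooling != "complete") {
    dat$J <- idx$J
    dat$jblk <- idx$jOfBlock
    if (spec@sessionPooling == "partial")
      dat$gcell <- match(idx$vMap$subjGroup, idx$gLevels)
    if (spec@sessionPooling != "none")
      dat$vidx <- idx$vMap$k
  } else {
    dat$kblk <- idx$kOfBlock
  }
  if (spec@sessionPooling != "none") dat$K <- idx$K
  if (spec@timeTrend) dat$tc <- unname(idx$tcov[idx$vMap$session])
  dat
}

# Crude per-cell value estimate used only to initialize chains: straight
# line through the empirical logits, solved for the 50% crossing.
.cellValueEstimate <- function(dv, n, N) {
  el <- stats::qlogis((n + 0.5) / (N + 1))
  if (length(unique(dv)) >= 2) {
    fit <- stats::lm.fit(cbind(1, dv), el)
    b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
    if (is.finite(b1) && b1 > 1e-6) {
      v <- b0 / b1  # eta = (dv + v)/tau and el ~ b0 + b1 dv => v = b0/b1
      return(max(-0.3, min(0.3, v)))
    }
  }
  0
}

# Dispersed overdispersed starting points; one list per chain, including
# the per-chain RNG seed derived from the master seed.
.jagsInits <- function(spec, idx, config, attempt = 0L) {
  b <- idx$blocks
  cellEst <- if (spec@sessionPooling != "complete") {
    vapply(seq_len(idx$J), function(j) {
      rows <- which(idx$jOfBlock == j)
      .cellValueEstimate(b$dv[rows], b$n[rows], b$N[rows])
    }, 0)
  } else NULL
  el <- stats::qlogis((b$n + 0.5) / (b$N + 1))
  p <- spec@priors
  lapply(seq_len(config@nChains), function(ch) {
    ini <- list(
      logomega = stats::runif(idx$G, max(p@logOmegaBounds[1], -3),
                              min(p@logOmegaBounds[2], 0)),
      tau = pmin(0.45, 0.05 * exp(stats::runif(idx$S, -0.7, 0.7))),
      ell = stats::runif(1, 0.02, 0.3),
      sca = stats::runif(1, 0.02, 0.09),
      nu = stats::runif(1, 1, 20),
      logitp = el + stats::rnorm(idx$B, 0, 0.3),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (config@seed * 1009L + 7919L * ch + 104729L * attempt) %%
        2147483546L + 1L)
    if (spec@sessionPooling != "none")
      ini$V <- stats::rnorm(idx$K, 0, 0.5 * sqrt(p@VVariance))
    if (spec@sessionPooling == "partial")
      ini$sigma <- stats::runif(idx$G, 0.01, 0.2)
    if (spec@sessionPooling != "complete")
      ini$v <- cellEst + stats::rnorm(idx$J, 0, 0.02)
    if (spec@timeTrend)
      ini$alpha <- stats::rnorm(idx$K, 0, 0.02)
    ini
  })
}
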