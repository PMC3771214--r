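# Shared fixtures: built once per test run and memoized, so several test
# files can reuse the same (deterministic) simulated studies and fits.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# desk fixture: 2 subjects x 6 sessions, 3 dv points, 60 choices per block
smallDesign <- function() {
  studyDesign(c(A = 6L, B = 6L), dvGrid = c(-0.06, 0, 0.06), nPerBlock = 60L)
}

smallSim <- function() memo("smallSim", {
  simulateDataset(realisticTruth(smallDesign(), seed = 3), smallDesign(),
                  seed = 4)
})

smallConfig <- function(seed = 11L) {
  chainConfig(nChains = 3L, nAdapt = 300L, nBurn = 800L, nIter = 2000L,
              thin = 4L, seed = seed)
}

smallFit <- function() memo("smallFit", {
  runMCMC(modelSpec(6), smallSim()$dataset, smallConfig())
})

# canonical recovery fixture: 4 subjects x 10 sessions x 4 categories x
# 5 dv values, 30 choices per block
canonicalSim <- function(seed = 101L) {
  des <- canonicalDesign()
  simulateDataset(realisticTruth(des, seed = seed), des, seed = seed + 1L)
}

canonicalChainConfig <- function(seed = 51L) {
  chainConfig(nChains = 3L, nAdapt = 300L, nBurn = 600L, nIter = 1600L,
              thin = 8L, seed = seed)
}

canonicalFit <- function() memo("canonicalFit", {
  sim <- canonicalSim()
  list(sim = sim,
       fit = runMCMC(modelSpec(6), sim$dataset, canonicalChainConfig()))
})

# hand-assembled PosteriorSamples for summary/diagnostic unit tests:
# draws is a named list var -> (iter, chain) matrix
makeSamples <- function(draws, spec = modelSpec(6), varMap = list(),
                        config = chainConfig(nChains = ncol(draws[[1]]),
                                             nAdapt = 1, nBurn = 1,
                                             nIter = nrow(draws[[1]]),
                                             thin = 1, seed = 1)) {
  d1 <- draws[[1]]
  arr <- array(NA_real_, c(nrow(d1), ncol(d1), length(draws)),
               dimnames = list(NULL, NULL, names(draws)))
  for (v in names(draws)) arr[, , v] <- draws[[v]]
  new("PosteriorSamples", draws = arr, varMap = varMap, spec = spec,
      config = config, fingerprint = "synthetic")
}

# varMap for a full-model layout without running MCMC
fullVarMap <- function(subjectsIds, nSessions) {
  cats <- imageCategories()
  VMap <- expand.grid(catGroup = cats, subjGroup = subjectsIds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  VMap <- data.frame(k = seq_len(nrow(VMap)), subjGroup = VMap$subjGroup,
                     catGroup = VMap$catGroup, stringsAsFactors = FALSE)
  sess <- unlist(lapply(seq_along(subjectsIds), function(i)
    sprintf("%s_s%d", subjectsIds[i], seq_len(nSessions[i]))))
  sessTab <- data.frame(s = seq_along(sess), session = sess,
                        subject = rep(subjectsIds, nSessions),
                        stringsAsFactors = FALSE)
  vMap <- expand.grid(catGroup = cats, session = sess,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vMap <- data.frame(j = seq_len(nrow(vMap)), session = vMap$session,
                     catGroup = vMap$catGroup, stringsAsFactors = FALSE)
  vMap$subjGroup <- sessTab$subject[match(vMap$session, sessTab$session)]
  vMap$k <- VMap$k[match(paste(vMap$subjGroup, vMap$catGroup),
                         paste(VMap$subjGroup, VMap$catGroup))]
  list(VMap = VMap, vMap = vMap, sessions = sessTab,
       gLevels = subjectsIds, cgLevels = cats, tcov = NULL)
}
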