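test_that("state initialization applies the one-sided correlation t-test", {
  corr <- correlationData(c(a = 0.9, b = 0, c = 0.5), n = 5)
  st <- initializeStates(corr, alpha = 0.05)
  expect_equal(unname(st), c(1L, 0L, 0L))
  # the borderline cases match the t survival function directly
  expect_lt(pt(0.9 * sqrt(3 / (1 - 0.81)), 3, lower.tail = FALSE), 0.05)
  expect_gt(pt(0.5 * sqrt(3 / (1 - 0.25)), 3, lower.tail = FALSE), 0.05)
  # absolute mode activates strong negative correlations too
  corrN <- correlationData(c(a = -0.9), n = 5)
  expect_equal(unname(initializeStates(corrN)), 0L)
  expect_equal(unname(initializeStates(corrN, negativeMode = "absolute")), 1L)
})

test_that("the E-step combines noise likelihoods with the MRF prior", {
  net <- chainNetwork(3L)
  ids <- interactionIds(net)
  corr <- correlationData(setNames(c(0.9177, 0.3, -0.2), ids), n = 5)
  theta <- noiseParams(0.7, 5)
  # flat prior: posterior reduces to the likelihood ratio
  psiFlat <- singleParamPsi(1, 1, 0)
  p <- eStep(setNames(rep(0.5, 3), ids), corr, theta, psiFlat, net)
  l1 <- likelihoodActive(corValues(corr), 0.7, 5)
  l0 <- likelihoodInactive(corValues(corr), 5)
  expect_equal(unname(p), unname(l1 / (l1 + l0)))
  # the plug-in value for a strong correlation
  expect_equal(unname(p[1]),
               pnorm(1) / (pnorm(1) +
                 pt(0.9177 * sqrt(3 / (1 - 0.9177^2)), 3,
                    lower.tail = FALSE)),
               tolerance = 1e-4)
  expect_equal(unname(p[1]), 0.98370, tolerance = 1e-3)
  # equal likelihoods: posterior reduces to the MRF conditional
  corrEq <- correlationData(setNames(rep(0, 3), ids), n = 5)
  psi <- singleParamPsi(0.5, 1.5, 0.7)
  pin <- setNames(c(0.9, 0.4, 0.6), ids)
  # likelihoodActive(0) != likelihoodInactive(0), so tie the noise term by
  # comparing against the hand-built combination instead
  pout <- eStep(pin, corrEq, theta, psi, net)
  pot <- mechMRF:::.mrfPotentials(psi, pin, mechMRF:::.mrfContext(net))
  l1e <- likelihoodActive(0, 0.7, 5)
  l0e <- likelihoodInactive(0, 5)
  manual <- plogis(log(l1e / l0e) + pot$psi1 - pot$psi0)
  expect_equal(unname(pout), unname(manual))
  # damping blends old and new
  pd <- eStep(pin, corrEq, theta, psi, net, damping = 0.3)
  expect_equal(unname(pd), unname(0.7 * pout + 0.3 * pin))
})

test_that("the M-step recovers parameters and is deterministic", {
  truth <- chainTruth(600L, 400L)
  corr <- simulateCorrelations(truth, 0.7, 0, 5L, seed = 17L)
  net <- simNetwork(truth)
  ids <- interactionIds(net)
  p <- setNames(as.numeric(ids %in% trueActive(truth)), ids)
  cfg <- emConfig(model = "single")
  theta0 <- noiseParams(0.5, 5)
  psi0 <- singleParamPsi()
  up1 <- mStep(p, corr, net, cfg, theta0, psi0)
  expect_lt(abs(up1$theta@rAlpha - 0.7), 0.1)
  up2 <- mStep(p, corr, net, cfg, theta0, psi0)
  expect_equal(up1$theta@rAlpha, up2$theta@rAlpha)
  expect_equal(up1$psi@beta, up2$psi@beta)
  # frozen couplings stay at their initial value
  cfgF <- emConfig(model = "single", freezeBeta = TRUE,
                   psiInit = singleParamPsi(1, 1, 0))
  upF <- mStep(p, corr, net, cfgF, theta0, singleParamPsi(1, 1, 0))
  expect_equal(upF$psi@beta, 0)
})

test_that("with couplings frozen at zero the EM equals the ML baseline", {
  for (seed in c(2L, 5L)) {
    gen <- generateNetwork(simConfig(nInteractions = 80L, seed = seed))
    truth <- applyNinetyTenRule(gen$network, gen$pathwayIds,
                                c("M", "TR"), seed = seed + 100L)
    corr <- simulateCorrelations(truth, seed = seed + 200L)
    tied <- singleParamPsi(1, 1, 0,
                           frozen = c(gamma0 = TRUE, gamma1 = TRUE,
                                      beta = TRUE))
    cfg <- emConfig(model = "single", freezeBeta = TRUE, psiInit = tied)
    res <- runEM(simNetwork(truth), corr, cfg)
    ml <- mlClassify(corr, rAlpha = res@theta@rAlpha, n = 5)
    expect_equal(res@states, ml@states[names(res@states)])
  }
})

test_that("a clean high-signal fixture converges quickly to the truth", {
  net <- chainNetwork(10L)
  ids <- interactionIds(net)
  truthStates <- setNames(c(rep(1L, 5L), rep(0L, 5L)), ids)
  corr <- correlationData(
    setNames(ifelse(truthStates == 1L, 0.95, 0), ids), n = 20)
  res <- runEM(net, corr, emConfig(model = "single"))
  expect_true(res@converged)
  expect_lte(res@iterations, 5L)
  expect_equal(res@states, truthStates)
})

test_that("strong coupling with borderline evidence triggers the runaway
           flag", {
  net <- chainNetwork(12L)
  ids <- interactionIds(net)
  corr <- correlationData(setNames(rep(0.69, 12L), ids), n = 5)
  cfg <- emConfig(model = "single", psiInit = singleParamPsi(1, 1, 8))
  res <- runEM(net, corr, cfg)
  expect_true(res@runaway)
  expect_length(unique(res@states), 1L)
})

test_that("identical configuration gives bit-identical results", {
  gen <- generateNetwork(simConfig(nInteractions = 60L, seed = 4L))
  truth <- applyNinetyTenRule(gen$network, gen$pathwayIds, c("M", "TR"),
                              seed = 14L)
  corr <- simulateCorrelations(truth, seed = 24L)
  r1 <- runEM(simNetwork(truth), corr, emConfig(model = "full"))
  r2 <- runEM(simNetwork(truth), corr, emConfig(model = "full"))
  expect_identical(r1@states, r2@states)
  expect_identical(r1@posteriors, r2@posteriors)
  expect_identical(r1@iterations, r2@iterations)
  expect_identical(r1@trace, r2@trace)
})

test_that("posteriors stay in [0,1], states follow the 0.5 threshold, and
           iteration counts are bounded", {
  for (seed in 1:5) {
    gen <- generateNetwork(simConfig(nInteractions = 50L, seed = seed))
    truth <- applyNinetyTenRule(gen$network, gen$pathwayIds, c("M", "TR"),
                                seed = seed)
    corr <- simulateCorrelations(truth, seed = seed + 50L)
    res <- runEM(simNetwork(truth), corr,
                 emConfig(model = "single", maxIter = 30L))
    expect_true(all(res@posteriors >= 0 & res@posteriors <= 1))
    expect_equal(unname(res@states), as.integer(res@posteriors > 0.5))
    expect_lte(res@iterations, 30L)
    expect_equal(nrow(res@trace), res@iterations)
  }
})

test_that("missing correlations are excluded with a warning", {
  net <- chainNetwork(4L)
  ids <- interactionIds(net)
  corr <- correlationData(setNames(c(0.9, NA, 0.1, 0.2), ids), n = 5)
  expect_warning(res <- runEM(net, corr, emConfig(model = "single")),
                 "missing")
  expect_equal(names(res@states), ids[-2L])
})

test_that("the complete-data log-likelihood matches direct expansion", {
  iso <- interactionNetwork("a", "b", "B")
  id <- interactionIds(iso)
  corr <- correlationData(setNames(0.4, id), n = 5)
  theta <- noiseParams(0.7, 5)
  psi <- singleParamPsi(1, 1, 2)       # isolated: MRF conditional = 0.5
  p <- setNames(0.5, id)
  l1 <- likelihoodActive(0.4, 0.7, 5)
  l0 <- likelihoodInactive(0.4, 5)
  expect_equal(completeDataLogLik(p, corr, theta, psi, iso),
               0.5 * log(0.5 * l1) + 0.5 * log(0.5 * l0))
  # 3-interaction chain, hand-expanded
  ch <- chainNetwork(3L)
  ids <- interactionIds(ch)
  corr3 <- correlationData(setNames(c(0.8, 0.1, -0.3), ids), n = 5)
  p3 <- setNames(c(0.9, 0.5, 0.2), ids)
  psi3 <- singleParamPsi(0.4, 1.0, 0.6)
  manual <- 0
  for (i in seq_along(ids)) {
    nb <- interactionNeighbors(ch, ids[i])
    e1 <- 0.4 * 0 + 1.0 - 0.6 * sum(1 - p3[nb])
    e0 <- 0.4 - 0.6 * sum(p3[nb])
    pr1 <- exp(e1) / (exp(e1) + exp(e0))
    li1 <- likelihoodActive(corValues(corr3)[ids[i]], 0.7, 5)
    li0 <- likelihoodInactive(corValues(corr3)[ids[i]], 5)
    manual <- manual + p3[ids[i]] * (log(li1) + log(pr1)) +
      (1 - p3[ids[i]]) * (log(li0) + log(1 - pr1))
  }
  expect_equal(completeDataLogLik(p3, corr3, noiseParams(0.7, 5), psi3, ch),
               unname(manual))
})

test_that("concentrating posteriors on the better-supported state never
           lowers the noise term", {
  # weighted-sum property of the noise part of the objective
  l1 <- log(likelihoodActive(0.8, 0.7, 5))
  l0 <- log(likelihoodInactive(0.8, 5))
  noiseTerm <- function(p) p * l1 + (1 - p) * l0
  expect_gt(noiseTerm(0.9), noiseTerm(0.5))   # l1 > l0 here
})
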