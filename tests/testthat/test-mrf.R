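test_that("potentials are the bias-minus-coupling form", {
  psi <- singleParamPsi(gamma0 = 0.5, gamma1 = 1, beta = 2)
  expect_equal(potentialSingle(1, 0, psi), 1)
  expect_equal(potentialSingle(1, 3, psi), -5)
  expect_equal(potentialSingle(0, 2, psi), 0.5 - 4)
  psi0 <- singleParamPsi(gamma0 = 0.5, gamma1 = 1, beta = 0)
  expect_equal(potentialSingle(1, 7, psi0), potentialSingle(1, 0, psi0))

  fp <- fullParamPsi(c("B", "TR"))
  fp@gamma["B", "1"] <- 1
  fp@beta[] <- 0; fp@beta["B", "B"] <- 2
  expect_equal(potentialFull("B", 1, c(B = 2, TR = 1), fp), 1 - 4)
  expect_equal(potentialFull("B", 1, c(B = 0, TR = 0), fp),
               fp@gamma["B", "1"])
})

test_that("full potentials with tied parameters collapse to the single form", {
  set.seed(5)
  for (rep in 1:20) {
    g0 <- rnorm(1); g1 <- rnorm(1); b <- rnorm(1)
    sp <- singleParamPsi(g0, g1, b)
    fp <- fullParamPsi(c("B", "M", "TR"))
    fp@gamma[, "0"] <- g0; fp@gamma[, "1"] <- g1
    fp@beta[] <- b
    opp <- setNames(rpois(3, 2), c("B", "M", "TR"))
    expect_equal(potentialFull("M", 1, opp, fp),
                 potentialSingle(1, sum(opp), sp))
  }
})

test_that("conditional state probabilities normalize and saturate safely", {
  expect_equal(conditionalStateProb(1.3, 1.3), 0.5)
  expect_equal(conditionalStateProb(1, -1), 0.880797, tolerance = 1e-6)
  expect_equal(conditionalStateProb(50, 0), 1)
  expect_equal(conditionalStateProb(0, 50), 0)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(conditionalStateProb(x, y) + conditionalStateProb(y, x),
               rep(1, 20))
})

test_that("expected neighbour counts sum posteriors of the opposite state", {
  st <- starNetwork(4L)
  p <- setNames(c(0.5, 0.9, 0.2, 0.5), interactionIds(st))
  e1 <- expectedNeighborCounts(p, st, 1)
  expect_equal(unname(e1["e1"]), (1 - 0.9) + (1 - 0.2) + (1 - 0.5))
  e0 <- expectedNeighborCounts(p, st, 0)
  expect_equal(unname(e0["e1"]), 0.9 + 0.2 + 0.5)
  # complements add to the neighbour count
  expect_equal(unname(e1 + e0), lengths(st@adjacency)[interactionIds(st)],
               ignore_attr = TRUE)
  # per-mechanism split
  stm <- starNetwork(4L, mechanism = c("B", "B", "TR", "M"))
  pm <- setNames(c(0.5, 0.9, 0.5, 0.2), interactionIds(stm))
  em <- expectedNeighborCounts(pm, stm, 1, perMechanism = TRUE)
  expect_equal(em["e1", "B"], 1 - 0.9, ignore_attr = TRUE)
  expect_equal(em["e1", "TR"], 1 - 0.5, ignore_attr = TRUE)
  expect_equal(em["e1", "M"], 1 - 0.2, ignore_attr = TRUE)
  expect_equal(rowSums(em), unname(expectedNeighborCounts(pm, stm, 1)),
               ignore_attr = TRUE)
})

test_that("Gibbs energy counts each unordered neighbour pair once", {
  net <- chainNetwork(2L)
  psi <- singleParamPsi(gamma0 = 0, gamma1 = 1, beta = 2)
  expect_equal(gibbsEnergy(c(e1 = 1, e2 = 1), net, psi), 2)
  expect_equal(gibbsEnergy(c(e1 = 1, e2 = 0), net, psi), 1 + 0 - 2)
  # matches the loop-based oracle on random small networks
  set.seed(11)
  for (rep in 1:5) {
    gen <- generateNetwork(simConfig(nInteractions = 8L, seed = rep))
    net <- gen$network
    ids <- interactionIds(net)
    psiS <- singleParamPsi(rnorm(1), rnorm(1), rnorm(1))
    psiF <- fitPsiFixture <- fullParamPsi(sort(unique(mechanismOf(net))))
    psiF@beta[] <- abs(rnorm(length(psiF@beta)))
    psiF@beta <- (psiF@beta + t(psiF@beta)) / 2
    psiF@gamma[] <- rnorm(length(psiF@gamma))
    for (k in 1:6) {
      s <- setNames(sample(0:1, length(ids), replace = TRUE), ids)
      expect_equal(gibbsEnergy(s, net, psiS), oracleEnergy(s, net, psiS))
      expect_equal(gibbsEnergy(s, net, psiF), oracleEnergy(s, net, psiF))
    }
  }
})

test_that("heuristic conditionals equal exact Gibbs conditionals at
           degenerate posteriors", {
  # across several topologies of <= 8 interactions, every interaction and
  # every rest-configuration
  fixtures <- list(
    chainNetwork(5L, mechanism = c("B", "TR", "B", "M", "TR")),
    starNetwork(4L, mechanism = c("B", "B", "M", "TR")),
    interactionNetwork(c("a", "a", "b", "c"), c("b", "b", "c", "d"),
                       c("B", "M", "TR", "B")),   # parallel pair included
    generateNetwork(simConfig(nInteractions = 7L, seed = 2L))$network)
  set.seed(21)
  for (net in fixtures) {
    ids <- interactionIds(net)
    mech <- mechanismOf(net)
    psiS <- singleParamPsi(0.4, 1.1, 0.8)
    psiF <- fullParamPsi(sort(unique(mech)))
    psiF@gamma[] <- rnorm(length(psiF@gamma), sd = 0.5)
    b <- matrix(rnorm(length(psiF@beta), sd = 0.5), nrow(psiF@beta))
    psiF@beta <- (b + t(b)) / 2
    dimnames(psiF@beta) <- dimnames(psiF@frozen)
    grid <- allStates(ids)
    for (i in seq_along(ids)) {
      for (g in sample(nrow(grid), min(nrow(grid), 16L))) {
        s <- grid[g, ]
        for (psi in list(psiS, psiF)) {
          opp1 <- expectedNeighborCounts(s, net, 1,
                                         perMechanism = is(psi, "FullParamPsi"))
          opp0 <- expectedNeighborCounts(s, net, 0,
                                         perMechanism = is(psi, "FullParamPsi"))
          if (is(psi, "SingleParamPsi")) {
            p1 <- potentialSingle(1, opp1[ids[i]], psi)
            p0 <- potentialSingle(0, opp0[ids[i]], psi)
          } else {
            p1 <- potentialFull(mech[ids[i]], 1, opp1[ids[i], ], psi)
            p0 <- potentialFull(mech[ids[i]], 0, opp0[ids[i], ], psi)
          }
          expect_equal(unname(conditionalStateProb(p1, p0)),
                       oracleConditional(s, ids[i], net, psi),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("pseudo-likelihood matches direct evaluation", {
  # isolated interaction with tied biases contributes log(0.5)
  iso <- interactionNetwork("a", "b", "B")
  psi <- singleParamPsi(1, 1, 2)
  expect_equal(pseudoLikelihood(psi, c(`a|B|b` = 0.3), iso), log(0.5))
  # beta = 0 makes the PL independent of adjacency
  ch <- chainNetwork(4L)
  disc <- interactionNetwork(paste0("x", 1:4), paste0("y", 1:4),
                             rep("B", 4), id = paste0("e", 1:4))
  p <- setNames(c(0.9, 0.2, 0.7, 0.4), paste0("e", 1:4))
  psi0 <- singleParamPsi(0.3, 1.2, 0)
  expect_equal(pseudoLikelihood(psi0, p, ch),
               pseudoLikelihood(psi0, p, disc))
  # 3-interaction chain equals the written-out sum
  ch3 <- chainNetwork(3L)
  p3 <- setNames(c(0.8, 0.5, 0.1), paste0("e", 1:3))
  psi3 <- singleParamPsi(0.2, 0.9, 0.6)
  expect_equal(pseudoLikelihood(psi3, p3, ch3),
               oraclePL(0.2, 0.9, 0.6, p3, ch3))
})

test_that("single and full models agree on every quantity when tied", {
  gen <- generateNetwork(simConfig(nInteractions = 30L, seed = 9L))
  net <- gen$network
  ids <- interactionIds(net)
  set.seed(31)
  p <- setNames(runif(length(ids)), ids)
  sp <- singleParamPsi(0.3, 0.8, 0.5)
  fp <- fullParamPsi(sort(unique(mechanismOf(net))))
  fp@gamma[, "0"] <- 0.3; fp@gamma[, "1"] <- 0.8
  fp@beta[] <- 0.5
  s <- setNames(sample(0:1, length(ids), replace = TRUE), ids)
  expect_equal(gibbsEnergy(s, net, fp), gibbsEnergy(s, net, sp))
  expect_equal(pseudoLikelihood(fp, p, net), pseudoLikelihood(sp, p, net))
})

test_that("fitted parameters attain the grid-search pseudo-likelihood", {
  ch <- chainNetwork(5L)
  p <- setNames(c(0.9, 0.8, 0.3, 0.6, 0.2), paste0("e", 1:5))
  fit <- fitPsi(p, ch, model = "single", bounds = c(-2, 2),
                init = singleParamPsi(1, 1, 0))
  plFit <- pseudoLikelihood(fit, p, ch)
  grid <- expand.grid(g1 = seq(-2, 2, by = 0.05),
                      b = seq(-2, 2, by = 0.05))
  plGrid <- max(vapply(seq_len(nrow(grid)), function(k)
    oraclePL(1, grid$g1[k], grid$b[k], p, ch), numeric(1L)))
  expect_gte(plFit, plGrid - 1e-4)
})

test_that("degenerate all-active posteriors drive beta to the bound", {
  ch <- chainNetwork(6L)
  p <- setNames(rep(1, 6L), paste0("e", 1:6))
  fit <- suppressWarnings(
    fitPsi(p, ch, model = "single", bounds = c(-5, 5)))
  expect_equal(fit@beta, 5)
  expect_true(fit@atBound["beta"])
})

test_that("fitted couplings stay symmetric with sparse pairs frozen at 0", {
  gen <- generateNetwork(simConfig(nInteractions = 40L, seed = 12L))
  net <- gen$network
  ids <- interactionIds(net)
  set.seed(7)
  p <- setNames(runif(length(ids)), ids)
  fit <- suppressWarnings(
    fitPsi(p, net, model = "full", biasMode = "per_mechanism", mMin = 5L))
  expect_equal(fit@beta, t(fit@beta))
  if (any(fit@frozen))
    expect_true(all(fit@beta[fit@frozen] == 0))
  # a pair vocabulary absent from the network cannot gain a coupling:
  # all-B network with a sprinkle of one TR keeps rare pairs frozen
  netB <- chainNetwork(8L, mechanism = c(rep("B", 7L), "TR"))
  pB <- setNames(runif(8L), interactionIds(netB))
  fitB <- suppressWarnings(
    fitPsi(pB, netB, model = "full", biasMode = "global", mMin = 5L))
  expect_true(fitB@frozen["B", "TR"])
  expect_equal(fitB@beta["B", "TR"], 0)
})

test_that("fitted beta rises with the neighbour agreement fraction", {
  nPairs <- 40L
  net <- pairComponents(nPairs)
  betas <- vapply(c(0.5, 0.7, 0.9), function(frac) {
    nAgree <- round(frac * nPairs)
    states <- numeric(2L * nPairs)
    for (j in seq_len(nPairs)) {
      v <- if (j <= nAgree) rep(j %% 2L, 2L) else c(1L, 0L)
      states[c(2L * j - 1L, 2L * j)] <- v
    }
    names(states) <- interactionIds(net)
    fitPsi(states, net, model = "single")@beta
  }, numeric(1L))
  expect_true(all(diff(betas) > 0))
})
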