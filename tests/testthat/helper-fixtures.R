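# Fixture builders and independent oracles used across the suite.

chainNetwork <- function(n, mechanism = "B") {
  if (length(mechanism) == 1L) mechanism <- rep(mechanism, n)
  interactionNetwork(paste0("v", seq_len(n)), paste0("v", seq_len(n) + 1L),
                     mechanism, id = paste0("e", seq_len(n)))
}

starNetwork <- function(k, mechanism = "B") {
  if (length(mechanism) == 1L) mechanism <- rep(mechanism, k)
  interactionNetwork(rep("hub", k), paste0("s", seq_len(k)), mechanism,
                     id = paste0("e", seq_len(k)))
}

## Disjoint two-interaction components (each pair shares one middle node).
pairComponents <- function(nPairs, mechanism = "B") {
  src <- tgt <- character(2L * nPairs)
  for (j in seq_len(nPairs)) {
    a <- paste0("a", j); b <- paste0("b", j); c <- paste0("c", j)
    src[2L * j - 1L] <- a; tgt[2L * j - 1L] <- b
    src[2L * j] <- b; tgt[2L * j] <- c
  }
  interactionNetwork(src, tgt, rep(mechanism, 2L * nPairs),
                     id = paste0("e", seq_len(2L * nPairs)))
}

## Independent Gibbs-energy oracle: explicit loops, no shared code with
## gibbsEnergy().
oracleEnergy <- function(states, net, psi) {
  df <- interactions(net)
  a <- states[df$id]
  e <- 0
  for (i in seq_len(nrow(df))) {
    if (is(psi, "SingleParamPsi")) {
      e <- e + if (a[i] == 1) psi@gamma1 else psi@gamma0
    } else {
      e <- e + psi@gamma[df$mechanism[i], as.character(a[i])]
    }
  }
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (j <= i) next
      shared <- length(intersect(c(df$source[i], df$target[i]),
                                 c(df$source[j], df$target[j]))) > 0L
      if (shared && a[i] != a[j]) {
        e <- e - if (is(psi, "SingleParamPsi")) psi@beta
                 else psi@beta[df$mechanism[i], df$mechanism[j]]
      }
    }
  }
  unname(e)
}

## Exact conditional P(state_i = 1 | rest) from the joint Gibbs
## distribution, by direct evaluation of the two completions.
oracleConditional <- function(restStates, i, net, psi) {
  s1 <- restStates; s1[i] <- 1L
  s0 <- restStates; s0[i] <- 0L
  e1 <- oracleEnergy(s1, net, psi)
  e0 <- oracleEnergy(s0, net, psi)
  1 / (1 + exp(e0 - e1))
}

## Independent pseudo-likelihood evaluation from the written-out formula.
oraclePL <- function(gamma0, gamma1, beta, posteriors, net) {
  df <- interactions(net)
  ids <- df$id
  p <- posteriors[ids]
  total <- 0
  for (i in seq_along(ids)) {
    nb <- interactionNeighbors(net, ids[i])
    e1opp <- sum(1 - p[nb])
    e0opp <- sum(p[nb])
    psi1 <- gamma1 - beta * e1opp
    psi0 <- gamma0 - beta * e0opp
    pr1 <- exp(psi1) / (exp(psi1) + exp(psi0))
    total <- total + p[i] * log(pr1) + (1 - p[i]) * log(1 - pr1)
  }
  unname(total)
}

## All 0/1 state assignments over m interactions.
allStates <- function(ids) {
  m <- length(ids)
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  colnames(grid) <- ids
  grid
}

## A truth object with prescribed class sizes on a chain topology (the ML
## baseline is topology-independent).
chainTruth <- function(nActive, nInactive, mechanism = "B") {
  net <- chainNetwork(nActive + nInactive, mechanism)
  new("SimulationTruth", network = net, pathwayIds = character(0L),
      trueActive = interactionIds(net)[seq_len(nActive)])
}
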