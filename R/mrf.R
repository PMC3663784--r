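## Shared per-network context for the MRF computations.
.mrfContext <- function(net) {
  list(pairs = .pairIndex(net),
       ids = net@interactions$id,
       mechChar = net@interactions$mechanism)
}

## Align a named posterior/state vector to the interaction order of ctx.
.alignTo <- function(x, ids) {
  if (is.null(names(x))) {
    stopifnot(length(x) == length(ids))
    return(setNames(as.numeric(x), ids))
  }
  stopifnot(all(ids %in% names(x)))
  setNames(as.numeric(x[ids]), ids)
}

#' Single-parameter MRF potential
#'
#' The log-potential of assigning an interaction to activity state k given
#' the (expected or observed) number of neighbours not in k:
#' \code{gamma_k - beta * oppCount}.
#'
#' @param state activity state, 0 or 1.
#' @param oppCount count (or expected count) of neighbours not in
#'   \code{state}; may be a vector.
#' @param psi a \linkS4class{SingleParamPsi}.
#' @return Numeric potential value(s).
#' @export
potentialSingle <- function(state, oppCount, psi) {
  stopifnot(state %in% c(0, 1), all(oppCount >= 0))
  g <- if (state == 1) psi@gamma1 else psi@gamma0
  g - psi@beta * oppCount
}

#' Full-parameter (mechanism-dependent) MRF potential
#'
#' The log-potential of assigning an interaction with mechanism s to
#' activity state a given, per neighbour mechanism t, the count of
#' mechanism-t neighbours not in state a:
#' \code{gamma_s^a - sum_t beta_{s,t} * oppCounts[t]}.
#'
#' @param mechanism the interaction's mechanism code.
#' @param state activity state, 0 or 1.
#' @param oppCounts named numeric: per-mechanism counts of neighbours in
#'   the opposite activity state.
#' @param psi a \linkS4class{FullParamPsi}.
#' @return Numeric potential value.
#' @export
potentialFull <- function(mechanism, state, oppCounts, psi) {
  stopifnot(state %in% c(0, 1), all(oppCounts >= 0))
  mechanism <- canonicalMechanism(mechanism)
  g <- psi@gamma[mechanism, as.character(state)]
  t <- names(oppCounts)
  stopifnot(!is.null(t), all(t %in% rownames(psi@beta)))
  g - sum(psi@beta[mechanism, t] * oppCounts)
}

#' Normalized conditional activity probability
#'
#' Converts the active/non-active potentials of an interaction into the
#' conditional probability of the active state,
#' \code{exp(psiActive) / (exp(psiActive) + exp(psiInactive))}, computed
#' without overflow.
#'
#' @param psiActive,psiInactive potentials (vectors of equal length).
#' @return Probability of the active state.
#' @export
conditionalStateProb <- function(psiActive, psiInactive) {
  stopifnot(all(is.finite(psiActive)), all(is.finite(psiInactive)))
  plogis(psiActive - psiInactive)
}

#' Expected opposite-state neighbour counts
#'
#' For each interaction, the expected number of neighbours NOT in the
#' target activity state under the current posteriors: for target state 1
#' this sums (1 - posterior) over the neighbours; for target state 0 it
#' sums the posteriors. With \code{perMechanism = TRUE} the sums are broken
#' down by neighbour mechanism (full model).
#'
#' @param posteriors named numeric posterior of the active state per
#'   interaction.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param targetState 0 or 1.
#' @param perMechanism logical; return a mechanisms-column matrix.
#' @return Named numeric vector (or matrix with one row per interaction).
#' @export
expectedNeighborCounts <- function(posteriors, net, targetState,
                                   perMechanism = FALSE) {
  stopifnot(targetState %in% c(0, 1))
  ctx <- .mrfContext(net)
  p <- .alignTo(posteriors, ctx$ids)
  m <- length(p)
  pr <- ctx$pairs
  contrib <- if (targetState == 1) 1 - p[pr[, 2L]] else p[pr[, 2L]]
  if (!perMechanism) {
    out <- .groupSum(contrib, pr[, 1L], m)
    return(setNames(out, ctx$ids))
  }
  mechs <- sort(unique(ctx$mechChar))
  out <- matrix(0, m, length(mechs), dimnames = list(ctx$ids, mechs))
  nbMech <- ctx$mechChar[pr[, 2L]]
  for (t in mechs) {
    sel <- nbMech == t
    out[, t] <- .groupSum(contrib[sel], pr[sel, 1L, drop = TRUE], m)
  }
  out
}

## Per-interaction potentials (psi1, psi0) under expected neighbour counts.
.mrfPotentials <- function(psi, p, ctx) {
  m <- length(p)
  pr <- ctx$pairs
  ones <- rep(1, nrow(pr))
  if (is(psi, "SingleParamPsi")) {
    S <- .groupSum(p[pr[, 2L]], pr[, 1L], m)        # expected active nbrs
    deg <- .groupSum(ones, pr[, 1L], m)
    list(psi1 = psi@gamma1 - psi@beta * (deg - S),
         psi0 = psi@gamma0 - psi@beta * S)
  } else {
    mechs <- rownames(psi@beta)
    S <- matrix(0, m, length(mechs), dimnames = list(NULL, mechs))
    deg <- S
    nbMech <- ctx$mechChar[pr[, 2L]]
    for (t in mechs) {
      sel <- nbMech == t
      S[, t] <- .groupSum(p[pr[sel, 2L]], pr[sel, 1L], m)
      deg[, t] <- .groupSum(ones[sel], pr[sel, 1L], m)
    }
    B <- psi@beta[ctx$mechChar, , drop = FALSE]
    list(psi1 = psi@gamma[ctx$mechChar, "1"] - rowSums(B * (deg - S)),
         psi0 = psi@gamma[ctx$mechChar, "0"] - rowSums(B * S))
  }
}

#' Unnormalized Gibbs energy of a state configuration
#'
#' The log of the unnormalized joint probability of a full activity
#' assignment. Single model: \code{gamma0*n0 + gamma1*n1 - beta*n01},
#' where n01 counts unordered neighbour pairs in different states. Full
#' model: the per-interaction biases \code{gamma_s^a} minus, for each
#' unordered neighbour pair in opposite activity states, the coupling
#' \code{beta} of its mechanism pair (couplings between same-activity
#' neighbours carry no parameter in the reduced form).
#'
#' @param states named integer/numeric vector of 0/1 activity states
#'   covering the network.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param psi a \linkS4class{SingleParamPsi} or \linkS4class{FullParamPsi}.
#' @return Numeric scalar (unnormalized log-probability).
#' @export
gibbsEnergy <- function(states, net, psi) {
  ctx <- .mrfContext(net)
  a <- .alignTo(states, ctx$ids)
  stopifnot(all(a %in% c(0, 1)))
  pr <- ctx$pairs
  sub <- pr[pr[, 1L] < pr[, 2L], , drop = FALSE]   # each pair once
  disagree <- a[sub[, 1L]] != a[sub[, 2L]]
  if (is(psi, "SingleParamPsi")) {
    psi@gamma0 * sum(a == 0) + psi@gamma1 * sum(a == 1) -
      psi@beta * sum(disagree)
  } else {
    bias <- sum(psi@gamma[cbind(ctx$mechChar, as.character(as.integer(a)))])
    mi <- ctx$mechChar[sub[disagree, 1L]]
    mj <- ctx$mechChar[sub[disagree, 2L]]
    bias - sum(psi@beta[cbind(mi, mj)])
  }
}

#' Pseudo-likelihood of MRF parameters
#'
#' The posterior-weighted sum, over interactions and both activity states,
#' of the log normalized conditional probability of that state given the
#' expected neighbour configuration:
#' \code{sum_i sum_j log(P(state j | E, psi)) * posterior_i(j)}.
#'
#' @param psi MRF parameters (\linkS4class{SingleParamPsi} or
#'   \linkS4class{FullParamPsi}).
#' @param posteriors named numeric active-state posteriors.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param expectations optional precomputed list with elements \code{psi1}
#'   and \code{psi0} (per-interaction potentials); computed from
#'   \code{posteriors} when NULL.
#' @return The pseudo-likelihood (a scalar, non-positive).
#' @export
pseudoLikelihood <- function(psi, posteriors, net, expectations = NULL) {
  ctx <- .mrfContext(net)
  p <- .alignTo(posteriors, ctx$ids)
  pot <- if (is.null(expectations)) .mrfPotentials(psi, p, ctx)
         else expectations
  d <- pot$psi1 - pot$psi0
  .bernLogLik(p, d)
}

#' Fit MRF parameters by pseudo-likelihood maximization
#'
#' Maximizes the pseudo-likelihood over the bias and coupling parameters
#' with a box-bounded quasi-Newton search (\code{optim} L-BFGS-B), holding
#' the expected neighbour counts fixed at the supplied posteriors. Coupling
#' symmetry and the reduced-form structural zeros are enforced by
#' construction. In the full model, mechanism pairs with fewer than
#' \code{mMin} interaction-interaction pairs in the network have their
#' coupling frozen at 0 (an overfitting guard for sparse pairs); fitted
#' parameters that hit a box bound are flagged.
#'
#' @param posteriors named numeric active-state posteriors.
#' @param net an \linkS4class{InteractionNetwork}.
#' @param model "single" or "full".
#' @param biasMode "global" (two bias parameters) or "per_mechanism"
#'   (two per mechanism); full model only.
#' @param bounds length-2 box bounds applied to every parameter.
#' @param init initial parameter object (defaults: standard initialization).
#' @param freezeBeta logical; hold all couplings at their initial values.
#' @param mMin minimum number of I-I pairs a mechanism pair needs before
#'   its coupling is estimated (full model).
#' @return A fitted \linkS4class{SingleParamPsi} or
#'   \linkS4class{FullParamPsi} with \code{frozen}/\code{atBound} flags
#'   set. Optimizer non-convergence is reported with a warning and the
#'   best-found parameters.
#' @export
fitPsi <- function(posteriors, net, model = c("single", "full"),
                   biasMode = c("global", "per_mechanism"),
                   bounds = c(-10, 10), init = NULL, freezeBeta = FALSE,
                   mMin = 5L) {
  model <- match.arg(model)
  biasMode <- match.arg(biasMode)
  ctx <- .mrfContext(net)
  p <- .alignTo(posteriors, ctx$ids)
  m <- length(p)
  pr <- ctx$pairs
  tol <- 1e-6

  if (model == "single") {
    if (is.null(init)) init <- singleParamPsi()
    S <- .groupSum(p[pr[, 2L]], pr[, 1L], m)
    deg <- .groupSum(rep(1, nrow(pr)), pr[, 1L], m)
    D <- 2 * S - deg                      # E0opp - E1opp
    negPL <- function(par) {
      d <- (par[2L] - par[1L]) + par[3L] * D
      -.bernLogLik(p, d)
    }
    start <- c(init@gamma0, init@gamma1, init@beta)
    ## gamma0 is held at its initial value: only the bias difference
    ## gamma1 - gamma0 enters the conditional model, so fitting both
    ## biases would leave a flat direction in the objective.
    fixed <- c(TRUE, init@frozen["gamma1"],
               init@frozen["beta"] || freezeBeta)
    obj <- function(free) {
      full <- start; full[!fixed] <- free; negPL(full)
    }
    if (all(fixed)) {
      est <- start
      conv <- 0L
    } else {
      fit <- optim(start[!fixed], obj, method = "L-BFGS-B",
                   lower = bounds[1L], upper = bounds[2L],
                   control = list(maxit = 500L))
      est <- start; est[!fixed] <- fit$par
      conv <- fit$convergence
    }
    if (conv != 0L)
      warning("pseudo-likelihood optimizer did not converge; ",
              "returning best-found parameters")
    atB <- (abs(est - bounds[1L]) < tol | abs(est - bounds[2L]) < tol) &
      !fixed
    nm <- c("gamma0", "gamma1", "beta")
    return(singleParamPsi(est[1L], est[2L], est[3L],
                          frozen = setNames(fixed, nm),
                          atBound = setNames(atB, nm)))
  }

  ## full model
  mechs <- sort(unique(ctx$mechChar))
  k <- length(mechs)
  if (is.null(init)) init <- fullParamPsi(mechs, biasMode = biasMode)
  stopifnot(all(mechs %in% rownames(init@beta)))
  init@beta <- init@beta[mechs, mechs, drop = FALSE]
  init@gamma <- init@gamma[mechs, , drop = FALSE]
  mechIdx <- match(ctx$mechChar, mechs)

  ## expected-count building blocks, fixed during the fit
  Dm <- matrix(0, m, k, dimnames = list(NULL, mechs))
  nbMech <- ctx$mechChar[pr[, 2L]]
  for (t in mechs) {
    sel <- nbMech == t
    St <- .groupSum(p[pr[sel, 2L]], pr[sel, 1L], m)
    degt <- .groupSum(rep(1, sum(sel)), pr[sel, 1L], m)
    Dm[, t] <- 2 * St - degt
  }

  ## I-I pair counts per unordered mechanism pair
  sub <- pr[pr[, 1L] < pr[, 2L], , drop = FALSE]
  cnt <- matrix(0L, k, k, dimnames = list(mechs, mechs))
  if (nrow(sub)) {
    tb <- table(factor(ctx$mechChar[sub[, 1L]], levels = mechs),
                factor(ctx$mechChar[sub[, 2L]], levels = mechs))
    cnt <- matrix(as.integer(tb) + as.integer(t(tb)), k, k,
                  dimnames = list(mechs, mechs))
    diag(cnt) <- diag(matrix(as.integer(tb), k, k))
  }
  sparse <- cnt < mMin
  frozenMat <- sparse | init@frozen[mechs, mechs]
  betaInit <- init@beta
  betaInit[sparse & !init@frozen[mechs, mechs]] <- 0  # sparse pairs -> 0
  upper <- which(upper.tri(frozenMat, diag = TRUE), arr.ind = TRUE)
  freeBeta <- if (freezeBeta) upper[0L, , drop = FALSE]
              else upper[!frozenMat[upper], , drop = FALSE]

  ## as in the single model, the inactive-state biases are held at their
  ## initial values; only the active-state biases are fitted.
  gamma0fix <- init@gamma[, "0"]
  if (biasMode == "global") gamma0fix[] <- init@gamma[1L, "0"]
  nGamma <- if (biasMode == "global") 1L else k
  unpack <- function(par) {
    g1 <- if (biasMode == "global") rep(par[1L], k)
          else par[seq_len(k)]
    gamma <- cbind(`0` = unname(gamma0fix), `1` = g1)
    dimnames(gamma) <- list(mechs, c("0", "1"))
    B <- betaInit
    if (nrow(freeBeta)) {
      vals <- par[nGamma + seq_len(nrow(freeBeta))]
      B[freeBeta] <- vals
      B[freeBeta[, c(2L, 1L), drop = FALSE]] <- vals
    }
    list(gamma = gamma, beta = B)
  }
  negPL <- function(par) {
    ps <- unpack(par)
    dg <- ps$gamma[, "1"] - ps$gamma[, "0"]
    d <- dg[mechIdx] + rowSums(Dm * ps$beta[mechIdx, , drop = FALSE])
    -.bernLogLik(p, d)
  }
  startGamma <- if (biasMode == "global") init@gamma[1L, "1"]
                else init@gamma[, "1"]
  start <- c(startGamma, betaInit[freeBeta])
  fit <- optim(start, negPL, method = "L-BFGS-B",
               lower = bounds[1L], upper = bounds[2L],
               control = list(maxit = 1000L))
  if (fit$convergence != 0L)
    warning("pseudo-likelihood optimizer did not converge; ",
            "returning best-found parameters")
  ps <- unpack(fit$par)
  atB <- abs(fit$par - bounds[1L]) < tol | abs(fit$par - bounds[2L]) < tol
  labels <- c(if (biasMode == "global") "gamma1"
              else paste0("gamma_", mechs, "^1"),
              if (nrow(freeBeta))
                paste0("beta_", mechs[freeBeta[, 1L]], ",",
                       mechs[freeBeta[, 2L]]))
  new("FullParamPsi", gamma = ps$gamma, beta = ps$beta,
      biasMode = biasMode, frozen = frozenMat,
      atBound = labels[atB])
}
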