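# mechMRF

Mechanism-aware Markov random field recovery of active subnetworks.

## The problem

Pathway databases annotate every molecular interaction with a *mechanism*
from a small controlled vocabulary — binding (B), cleavage (C), covalent
modification (CM), phosphorylation (+P), dephosphorylation (−P),
transformation (T), transport (Tn), catalysis (Z), transcription
regulation (TR), microRNA binding (M). In a given experimental condition
only a subset of the network's interactions is actually functioning (the
*active subnetwork*), and neighbouring interactions tend to be
co-activated in a way that depends on their mechanisms: a phosphorylation
cascade switches on together, the targets of one transcription factor are
co-regulated, a cleavage cascade fires as a unit.

`mechMRF` recovers per-interaction activity states from time-course
expression correlations by combining:

- **a noise model** on each edge's observed Spearman correlation r with
  sample size n. Under H1 (active) the Fisher transform
  z = artanh(r) is Gaussian with mean artanh(r_α) and sd 1/√(n−3), and
  the likelihood is Pr(Z < z); under H0 (non-active) r is converted to
  t = r·√((n−2)/(1−r²)) and the likelihood is the one-tailed survival
  Pr(T₍n₋₂₎ > t);
- **a Markov random field over edge states** in the line graph (two
  interactions are neighbours iff they share a node). The conditional
  log-potential of state a for an interaction of mechanism s is
  γₛᵃ − Σₜ β₍s,t₎·η(t, ā), where η(t, ā) counts mechanism-t neighbours
  *not* in state a. The single-parameter model ties all couplings to one
  β (the Ising / 2-colour form); the full model learns one β per
  unordered mechanism pair;
- **a heuristic-EM algorithm**: the E-step replaces the intractable sum
  over neighbour configurations with expected neighbour counts under the
  current posteriors; the M-step re-estimates r_α (posterior- or
  rank-weighted Fisher-z mean) and maximizes the pseudo-likelihood of
  the MRF parameters under box bounds.

A maximum-likelihood-only baseline (`mlClassify`, no MRF prior) and a
complete seeded simulation harness (synthetic mechanism-structured
networks, the 90/10 activity rule, Fisher-space correlation replicates,
recovery metrics, consensus networks) are included for benchmarking.

## Worked example

```r
library(mechMRF)

cfg   <- simPreset("vegf", seed = 8)            # 1065 interactions, M/B/TR
gen   <- generateNetwork(cfg)
truth <- applyNinetyTenRule(gen$network, gen$pathwayIds, cfg$class1,
                            seed = 18)
corr  <- simulateCorrelations(truth, seed = 28)

fullFit <- runEM(simNetwork(truth), corr, emConfig(model = "full"))
mlFit   <- mlClassify(corr, rAlpha = 0.7)

fullFit
#> EmResult (full): 1065 interactions, 716 active; 22 iteration(s), converged
unlist(evaluateRecovery(fullFit, truth))[c("sensitivity", "specificity",
                                           "percentCorrect")]
#>    sensitivity    specificity percentCorrect
#>       76.14679       73.05699       75.58685
unlist(evaluateRecovery(mlFit, truth))[c("sensitivity", "specificity",
                                         "percentCorrect")]
#>    sensitivity    specificity percentCorrect
#>       71.55963       72.53886       71.73709
```

The mechanism-aware prior lifts the percentage of correctly recovered
interaction states from 71.7% (no-prior baseline) to 75.6% here. The
coupling matrix is the model's biological readout; fitted at the true
states it separates the co-activated (within-class) mechanism pairs from
the cross-class pairs, whose negative couplings encode that a
pathway-class interaction next to an expansion-class one tends to be in
the opposite state:

```r
a <- setNames(as.integer(interactionIds(simNetwork(truth)) %in%
                         trueActive(truth)),
              interactionIds(simNetwork(truth)))
round(fitPsi(a, simNetwork(truth), model = "full",
             biasMode = "per_mechanism")@beta, 3)
#>         B      M     TR
#> B   0.020 -0.066 -0.042
#> M  -0.066  0.010 -0.019
#> TR -0.042 -0.019  0.001
```

(All numbers above are the output of these exact seeded calls; your
platform should reproduce them bit for bit.)

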