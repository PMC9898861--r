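# symptomnet

Network-psychometric analysis of two-wave binary symptom panels, built
around the Problem Gambling Severity Index (PGSI) but applicable to any
set of `p >= 2` dichotomous symptoms measured once or twice per person.
It is aimed at researchers who want, from a single panel dataset:

- **cross-sectional symptom networks** — Ising models estimated by
  node-wise L1-penalized logistic regression with EBIC model selection
  (hyperparameter γ, default 0.25) and AND-rule edge assembly;
- **centrality** — strength, closeness and betweenness for weighted
  undirected networks (edge length 1/|w|), in- and out-strength for
  directed ones, raw and z-scored;
- **replicability diagnostics** — phi correlation of edge presence,
  Spearman rank correlations of edge weights and centralities, and a
  permutation invariance test of the maximum edge difference (M) and
  global strength difference (S);
- **a cross-lagged panel network (CLPN)** — nine LASSO logistic
  regressions of wave-2 symptoms on all wave-1 symptoms, penalty chosen
  by ten-fold cross-validated deviance with the 1SE rule;
- **bootstrap accuracy and stability** — percentile edge CIs, edge and
  centrality difference tests, and case-dropping correlation-stability
  (CS) coefficients;
- **descriptives** — PGSI scoring and risk categories (0 / 1–2 / 3–7 /
  ≥8), prevalence tables, Cronbach's alpha, dependent t and McNemar
  tests;
- **a synthetic generator** — exact (or Gibbs) sampling from an Ising
  model for wave 1 and a conditional logistic transition to wave 2, with
  known ground truth for validation.

At the core are two estimating equations.  Cross-sectionally, each
symptom is regressed on the others along an L1 path and the penalty is
selected per node by

    EBIC_γ = −2·loglik + k·log(n) + 2·γ·k·log(p−1),

with an edge retained only when both directed coefficients survive
(AND rule; the weight is their mean).  Longitudinally, the directed
weight B[j,k] is the coefficient of wave-1 symptom j in the
1SE-penalized logistic regression of wave-2 symptom k on all wave-1
symptoms.

## Worked example

Simulate a PGSI-like two-wave panel (335 persons, nine symptoms with
2–8% endorsement, known sparse network) and analyze it:

```r
library(symptomnet)

sc    <- default_scenario("pgsi")
panel <- generate_two_wave(sc$ising, sc$clpn, n = 335, seed = 2024)

net1 <- estimate_ising(panel_wave(panel, 1))
net1
#> ising_network: 9 nodes, 4/36 nonzero edges (AND rule, gamma = 0.25)

ct <- centrality_table(net1)
head(ct[ct$index == "strength", ][order(-ct$value[ct$index == "strength"]), ], 3)
#>                              node    index value     z
#>                 Feelings of guilt strength  4.71 1.476
#>  Betting more than one can afford strength  4.39 1.301
#>                   Borrowing money strength  2.58 0.292

clpn <- estimate_clpn(panel, seed = 7)
clpn
#> clpn_network: 9 nodes, 12/81 nonzero directed edges (10-fold CV, 1SE rule)

os <- directed_strength(clpn)$out_strength
clpn$labels[which.max(os)]
#> [1] "Health problems"
```

Reading this output: at n = 335 with rare symptoms the EBIC-LASSO
network is deliberately sparse — 4 of 36 possible edges survive the AND
rule, and edge weights are pairwise log-odds (a weight of 2 multiplies
the odds of one symptom by e² ≈ 7.4 when its neighbour is present).  The
CLPN's largest out-strength correctly points to one of the two
generating "driver" symptoms (Health problems), i.e. the node whose
wave-1 state best predicts the wave-2 symptom set.

The full workflow (descriptives → both wave networks → congruence and
invariance → CLPN → bootstrap stability, with all tables written to
disk) runs from one config:

```r
res <- run_full_analysis(analysis_config(scenario = "pgsi", seed = 1,
                                         out_dir = "out"))
summarize_bundle("out")
```

or from the shell via `inst/scripts/symptomnet run --config cfg.json`
(also `simulate` and `report` subcommands).

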