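# ccgrn — Boolean and continuous dynamics of the Arabidopsis cell-cycle GRN

`ccgrn` is an R package for analysing synchronous Boolean models of gene
regulatory networks, built around a 14-node model of the *Arabidopsis
thaliana* cell cycle. The cell cycle is driven by CDK–cyclin complexes
(CYCD3;1 with the constitutive CDKA;1; the mitotic CYCA2;3/CYCB1;1 with
CDKB1;1), restrained by the inhibitor KRP1 and the RBR–E2F axis, relayed
by a MYB transcription-factor wave (MYB77, MYB3R1/4), and reset by the
SCF and APC/C ubiquitin ligases. The package asks — and lets you re-ask
under perturbation — the central dynamical question: do these
interactions suffice to generate the cyclic behavior of the cell cycle?

Under the synchronous update rule

    X_i(t+1) = F_i(X_i1(t), ..., X_ik(t))

every one of the 2^14 = 16,384 network states has exactly one successor,
and the packaged model funnels *all* of them into a single limit-cycle
attractor of 11 configurations that walks through G1, G1/S, S, S/G2,
G2, G2/M, M and mitotic exit.

Functionality:

* **Network core** — parse/serialize BoolNet-style `targets, factors`
  rule files (gene names with `;` and `/` taken verbatim), truth-table
  compilation, signed interaction graphs (`parse_network()`,
  `load_cc_model()`, `interaction_graph()`).
* **Synchronous dynamics** — exhaustive attractor enumeration with exact
  basin sizes over the full state space (C++ engine), canonical cycle
  identity, cell-cycle phase annotation (`find_attractors()`,
  `annotate_phases()`).
* **Robustness** — systematic or sampled truth-table bit flips and
  stochastic state-transition bit flips, classified three ways against
  the unperturbed attractors (`function_flip_robustness()`,
  `transition_flip_robustness()`).
* **Null ensembles** — random Boolean networks matched to the real
  network's in-degree profile, each scored against its own attractors
  (`ensemble_robustness()`, `random_matched_network()`).
* **In-silico mutants** — loss/gain-of-function clamps for every node,
  attractor classification (wild-type-like / endocycle-like / arrest),
  comparison against packaged phenotype expectations (`apply_mutation()`,
  `mutant_scan()`).
* **Continuous approximation** — fuzzy-logic ODE embedding of the
  Boolean rules with a steepness-h sigmoid production term and per-node
  decay, limit-cycle detection, and steepness-by-decay parameter sweeps
  (`continuous_model()`, `integrate_model()`, `detect_limit_cycle()`,
  `parameter_sweep()`).

## Worked example

```r
library(ccgrn)

cc <- load_cc_model()
aset <- find_attractors(cc)
aset
#> Attractor set: 1 attractor(s) over 16384 states ( exhaustive )
#>   #1 period 11, basin 16384 (100.00%)
```

One attractor, period 11, basin 100%: every initial condition ends on
the same 11-configuration cycle. Annotating and clamping:

```r
head(annotate_phases(aset$attractors[[1]], cc)[, 1:3])
#>   position phase state
#> 1        1    G1     0
#> 2        2    G1    73
#> 3        3  G1/S    89
#> 4        4     S   731
#> 5        5  S/G2  4058
#> 6        6  S/G2 12278

# KRP1 knockout: the cycle is untouched (period 11, 100% of states)
find_attractors(apply_mutation(cc, "KRP1", 0))
#> Attractor set: 1 attractor(s) over 16384 states ( exhaustive )
#>   #1 period 11, basin 16384 (100.00%)

# constitutively active APC/C: a period-7 endocycle (S and Gap phases,
# no mitosis-onset configuration)
find_attractors(apply_mutation(cc, "APC/C", 1))
#> Attractor set: 1 attractor(s) over 16384 states ( exhaustive )
#>   #1 period 7, basin 16384 (100.00%)
```

Robustness of the attractor against single-bit rule perturbations, and
the random-network contrast:

```r
function_flip_robustness(cc, "exhaustive")
#> Robustness (function flips (exhaustive)): 522 perturbations
#>   recovered_only          433  (82.95%)
#>   recovered_plus_new        7  (1.34%)
#>   altered                  82  (15.71%)

ens <- ensemble_robustness(cc, n_networks = 100, n_perturb = 100,
                           kind = "functions", seed = 1)
ens$median          # typical random-network recovery fraction
ens$template_fraction  # the cell-cycle network's own fraction
```

So flipping any single output bit of a rule leaves the full attractor
landscape intact in about 83% of the 522 possible perturbations, while
a typical random network of identical degree structure tolerates far
fewer of its own perturbations than the cell-cycle network does.

Continuous check that the cycle is not a discreteness artifact:

```r
model <- continuous_model(cc, h = 50, gamma = 1)
traj <- integrate_model(model, runif(14), t_end = 150)
detect_limit_cycle(traj)$is_cycle
#> TRUE
```

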