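---
title: "Logic-based ODE modeling of cellular cholesterol regulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based ODE modeling of cellular cholesterol regulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholode)
```

# The model

Cellular cholesterol levels are controlled by two coupled processes —
receptor-mediated uptake of lipoprotein cholesterol through LDLR and NPC1,
and de novo synthesis through the mevalonate pathway — under feedback
control of the SREBP and LXR transcription factors. `cholode` encodes this
regulatory system as a hybrid logic-based ODE model over a signed
prior-knowledge network and fits it, per cell line, to perturbation-response
measurements scaled to the unit interval.

## Regulatory dynamics

Every regulatory node $x$ (proteins, enzymatic activities, intracellular
drug pools, medium cholesterol) follows relaxation dynamics

$$\frac{dx}{dt} = \tau_x \, (B_x(\mathbf{x}) - x),$$

where $\tau_x$ is a per-node time constant and $B_x \in [0,1]$ combines the
incoming edges. Each edge contributes a gate $g_e$, the product over its
sources of the *normalized Hill transfer*

$$f(u) = \frac{u^n (1 + k^n)}{u^n + k^n}$$

for activating sources and $1 - f(u)$ for inhibiting ones. The
normalization pins $f(0)=0$ and $f(1)=1$, so $k \in (0,1]$ is the
half-effect level on the data scale and $n \ge 1$ the steepness. Multiple
edges into a node OR-combine as a noisy-OR, $B = 1 - \prod_e (1 - g_e)$;
multi-source edges are conjunctive (AND) hyperedges. We chose the smooth
noisy-OR/product convention of the continuous-logic formalism over max/min
semantics because the optimizer needs a differentiable landscape. siRNA
perturbations enter as dedicated knockdown-input nodes whose steep, fixed
transfer multiplies the target's activation as an AND-NOT factor
$B \cdot (1 - f_{\mathrm{steep}}(\mathrm{si}))$ — a knockdown attenuates
whatever drive the target receives rather than OR-competing with it.

## Metabolic reactions

The mevalonate-pathway intermediates follow explicit rate laws rather than
logic gates:

- acetyl-CoA: zero-order supply $0.5\,k_1$, second-order ACAT2-mediated
  condensation $k_2\,[\mathrm{ACAT2act}][\mathrm{AcCoA}]^2$,
  HMGCS1-mediated synthesis
  $k_3\,[\mathrm{HMGCS1act}][\mathrm{AcCoA}][\mathrm{AcAcCoA}]$, and a
  first-order drain $k_7$;
- acetoacetyl-CoA: the condensation gain minus the synthesis loss;
- HMG-CoA: the synthesis gain minus the HMGCR flux;
- mevalonate: the HMGCR flux minus the export $k_5$;
- ER cholesterol: uptake
  $k_6\,[\mathrm{CholMedia}][\mathrm{LDLR}][\mathrm{NPC1}]$ plus
  $k_5\,[\mathrm{Mev}]$ minus consumption $k_8$;

each scaled by its node's $\tau$. The HMGCR flux is Michaelis–Menten with
*competitive* statin inhibition,

$$v = \frac{k_4\,[\mathrm{HMGCR}]\;S}{k_{M4}\left(1 +
  \frac{[\mathrm{atorvastatin}]}{k_I}\right) + S},$$

the standard competitive-inhibition form; statins compete with HMG-CoA at
the active site, and this reading makes the zero-inhibitor and
$k_I \to \infty$ limits coincide (a property the test suite checks).

Drug uptake and metabolism edges (extracellular dose to intracellular pool,
parent drug to hydroxy/lactone metabolites) use the same bounded Hill
transfer instead of mass action: intracellular drug levels live on the
scaled $[0,1]$ axis, dose-response saturates, and no extra clearance
parameters are needed.

## The packaged network

`cholesterol_pkn()` ships the curated topology: 44 edges over 21 protein
nodes, two activity nodes (ACAT2, HMGCS1), and 11 metabolite species (the
four pathway intermediates, cholesterol split into ER and medium pools, the
three parent drugs and three drug metabolites), plus ten clamped inputs
(four drug doses, LPDS starvation, five siRNAs). SREBP is represented as a
precursor node activating SREBP1 and SREBP2 through fixed edges, with a
hypothetical inhibitory edge from SREBP1 back to SREBP — the simplest
interaction reproducing SREBP2 complementation under SREBP1 knockdown. ER
cholesterol, 25-hydroxycholesterol and the SREBP1 feedback gate SREBP
conjunctively (AND of NOTs), so any strong sterol signal suppresses
activation. 25 nodes are measured; CholER, CholMedia, LDLR and NPC1 are
not. Because the only authoritative source for the full arrow list is a
figure, a few routing choices were made by us and are documented in the
fixture metadata; the printed counts (44 edges, 21 proteins, 11
metabolites, 25 measured nodes, 23 conditions) are enforced as acceptance
constraints on the encoding. The acetyl-CoA supply term has no upstream
species and is therefore carried as a node-level source constant rather
than an edge; hydroxy- and lactone-metabolite nodes are retained in the
topology but flagged unmeasured, which is one of several assignments
consistent with the printed totals.

```{r fixture}
pkn_counts(cholesterol_pkn())
```

## Simulation

Conditions clamp the input nodes (doses on a 0.5/1 scale for low/high,
knockdown efficiencies 0.8/0.7 for the two independent siRNAs) and
integrate from initial levels of 0.5 (0 for intracellular drug pools) to a
quasi-steady state: 100 dimensionless time units for 48-h-class drug
conditions, 150 for 72-h-class siRNA conditions (the model's time units are
not calibrated to hours; these horizons comfortably exceed the slowest
relaxation times at the default bounds). The default integrator is an
embedded Dormand–Prince 5(4) pair with PI step control compiled in C++
(`rtol` 1e-6, `atol` 1e-8), with hard state guards keeping regulatory
states in $[0,1]$ and metabolites non-negative; `method = "lsoda"` runs the
same compiled right-hand side under `deSolve::lsoda` as a stiff-capable
cross-check, and the test suite holds the two routes and a fine-grid Euler
oracle together to 1e-4. Convergence is declared at
$\max_i |dx_i/dt| < 10^{-6}$.

# Data model

Raw signals are scaled per analyte over all cell lines and conditions
jointly, preserving inter-cell-line differences: proteins by global
min–max; drugs and drug metabolites by min–max (removing the signal
offset); endogenous metabolites by 0-to-max, so small steady-state
variation is not inflated into large scaled variation. "Scaled between 0
and 1 in the total range" is read as min–max over the global range; a
0-to-max reading would differ only by the global minimum offset. A
constant analyte under a min–max rule is assigned 0.5 with zero weight
rather than crashing. Datasets serialize to MIDAS CSV (`ID:`/`TR:`/
`DA:`/`DV:` column prefixes); pseudo-timepoints are a derived augmentation
and are regenerated rather than serialized.

Because only terminal measurements exist, three *pseudo-timepoints* per
measured (node, condition) cell anchor the trajectory shape: levels at 0.5,
0.8 and 0.9 of the baseline-to-terminal difference, placed at 1/4, 1/2 and
3/4 of the horizon (the source design places them "in between" without
stating grid positions; the early-saturating 0.5/0.8/0.9 profile penalizes
oscillatory approaches). Weights are 1 for measured points, 2 for points
flagged differential (condition mean deviating from the untreated mean by
more than 0.1 scaled units), 0.5 for pseudo-points — the stated ordering
(higher/lower than measured) with round values, all configurable.

# Objective and ensemble fitting

The loss is the weighted mean of squared residuals over all (pseudo-)
observations plus a penalty $\lambda \cdot \mathrm{mean}\,(x(t) - 0.5)^2$
over the unmeasured nodes (CholER, CholMedia, LDLR, NPC1) along the
untreated trajectory, discretized on the integrator's output grid
($\lambda = 1$ by default). The penalty anchors otherwise unconstrained
latent nodes at the neutral level. A failed integration contributes ten
times the loss of the all-0.5 constant predictor for that condition —
large enough to steer the search away, finite so the optimizer sees a
gradient rather than a cliff. Whether the original objective normalized
per node or globally is unstated; we use one global weighted mean.
Objective-internal tolerances are `rtol` 1e-5 / `atol` 1e-7: residuals at
the loss levels of interest are orders of magnitude above the integration
error, and the looser setting roughly halves fitting time.

Ensembles are fitted by bootstrap: each of `n_models` trainings resamples
the biological replicates of every (node, condition) cell with replacement,
recomputes means and pseudo-points, and runs an independent global search.
The optimizer is a seeded differential evolution (best/1/bin, population
20, Latin-hypercube initialization) over the free parameters within shared
bounds — $k \in [0.01, 1]$, $n \in [1, 10]$, $\tau \in [0.01, 10]$,
metabolic rates $\in [0, 10]$, $k_{M4}, k_I \in [0.01, 10]$, identical for
all cell lines — followed by a Nelder–Mead polish on the remaining
evaluation budget. All seeds derive from a single base seed up front, so
results are independent of execution order and exactly reproducible. The
desk-scale default is 10 models at 2,000 evaluations; the study-scale
configuration (100 trainings, >50,000 parameter sets each) is available as
`study_scale_preset()` but is a multi-day single-CPU computation.

Terminal-state data cannot identify time constants, so the toy-network
parameter table fixes $\tau = 1$ (`fix_tau = TRUE`); recovery is asserted
on predicted observables, not on parameter values, since Hill parameters
are only set-identifiable from steady states.

# Cross-cell-line comparison

Per free parameter, ensembles from different cell lines are compared with a
Kruskal–Wallis rank test across all lines (tie-corrected, chi-squared
approximation), Benjamini–Hochberg adjustment across parameters, and an
effect size. "Cohen's D" across four groups is operationalized as the
maximum pairwise D (one-vs-rest is available behind a flag); the adjustment
method, unstated in the source design, follows the BH procedure used
elsewhere in the same pipeline for metabolites. A parameter is divergent at
$D > 4$ and adjusted $p < 10^{-10}$; an interaction (edge) is divergent if
any of its parameters is — the $k$ and $n$ of an edge are tested
separately, not pooled. Transfer-function curves per ensemble member, with
0.1/0.25/0.75/0.9 quantile bands, export to CSV for plotting.

These thresholds are extremely conservative by design: with ensembles of
100, the null distribution of the max-pairwise D concentrates far below 4,
so the null false-flag rate is essentially zero, while a location shift of
5 pooled SDs is flagged nearly always — both properties are exercised by
simulation in the test suite.

# MS post-processing statistics

The proteomics/metabolomics side of the pipeline is a set of small,
exactly-testable decision rules:

- **Decoy FDR**: $\mathrm{FDR} = \mathrm{FFT} \cdot d / t$ with the
  fraction-of-false-targets correction. The alternative $d/(t+d)$
  denominator fails the published worked examples and was rejected.
- **Presence filters**: an identification survives at m-score $\le$
  threshold in at least a fraction $q$ of all files, or in at least $r$
  biological replicates of one condition; boundaries inclusive.
- **Quantification peptides**: proteotypic only, top 7 per protein by total
  signal, lexicographic tie-break for determinism.
- **Normalization**: total-intensity, global or within tiled 600-s
  retention-time windows (tiled rather than sliding, which is the simpler
  reading of a "window of 10 min"), rescaled by cross-run mean totals.
- **Differential calls**: FDR below threshold and |log2 FC| above 0.5
  against untreated *and* against the vehicle control where one applies.
- **Nested ANOVA / CV**: treatment tested against the
  among-biological-replicate mean square with technical replicates nested
  inside (F on $(t-1, \sum b_i - t)$ df); CV is the SD/mean of biological
  replicate means. Under a Gaussian null its p-values are uniform (checked
  by simulation).
- **Exact-mass annotation**: negative-mode ions match neutral reference
  masses under [M−H]⁻ and [M+F]⁻ within 0.001 Da, above 1,500 counts;
  then per ion keep the best metabolite, per metabolite the best
  annotation, and drop salt-type adducts. The annotation score of the
  original in-house pipeline is undefined in print; we default to the
  negative absolute mass error, so the closest match wins, and accept a
  user-supplied score column instead.

# Synthetic data generator

The generator emulates the study's statistical structure so every stage is
testable without the deposited datasets. Ground-truth parameters are drawn
within the shared bounds (uniformly; or log-uniformly over the central
decade for rate/time constants, which favors balanced fluxes on the full
network) and accepted only if every roster condition integrates, the
untreated condition converges, and the resulting measured states are
informative — each node visible somewhere in the design and a configurable
share of nodes actually moved. The rejection step matters: unconstrained
draws frequently produce runaway metabolite accumulation or an all-zero
observation table, neither of which resembles scaled perturbation-response
data.

Measurements are the simulated terminal states under multiplicative
log-normal noise in the mean-preserving parameterization
($\sigma_{\log}^2 = \log(1 + \mathrm{CV}^2)$), at the design's replicate
structure: CV 0.20 across 3 biological replicates (the printed replicate
CVs are ~20% for metabolites and 22%/11% for proteins), technical
replicates at CV/4 for metabolite-class analytes. The modeling dataset
carries the noisy states directly, clipped to $[0,1]$ — synthetic states
are already on the model scale, and re-scaling an amplitude-multiplied raw
table through the min–max/0-max rules is not the identity, which would
break the exact zero-noise invertibility that anchors the recovery tests.
The class-scaling rules are instead exercised on the accompanying raw
table, which multiplies the same noisy states by class-specific amplitudes.

The reduced toy network (stimulus → TF → two targets; a three-metabolite
chain with one drug-inhibited Michaelis–Menten step; 6 of 8 nodes measured)
runs its 6-condition roster to a 40-unit horizon — a few relaxation times
at $\tau = 1$ — so a full 10x2,000 ensemble fits in about two minutes of
CPU. What passing these tests shows is that the machinery (scaling,
objective, bootstrap, optimizer, comparison statistics) is correct and
well-calibrated under the assumed noise model; it does not show that the
real MS data meet those assumptions (no batch structure, no missingness,
no peptide-to-protein roll-up error is simulated).

# Known limitations

- The full 44-edge topology is a curated reconstruction; arrow-level
  choices beyond the printed counts are ours.
- The explicit Runge–Kutta core is not stiff-capable; the bounds keep time
  constants moderate, and the `lsoda` route exists for pathological
  parameter sets.
- Parameter values themselves are non-identifiable from terminal states;
  all recovery claims are about predicted observables.
- The differential-abundance decision rule is applied to fold-change/FDR
  tables computed from simple replicate statistics; the upstream Bayesian
  differential-expression model of the original pipeline is out of scope.
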