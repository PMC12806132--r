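---
title: "fluxomix: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluxomix: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxomix)
```

This vignette is the package's own account of its methods: the models
and statistics it implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the design decisions taken where more than one reasonable choice
existed. It states no empirical result that the test suite does not
itself compute.

## 1. From transcripts to fluxes

### The constraint-based model

A genome-scale metabolic model is a stoichiometric matrix $S$
(metabolites $\times$ reactions) with flux bounds and gene associations.
Flux balance analysis (FBA) finds a flux vector $v$ maximising a linear
objective — here growth, the standard proxy for proliferating cancer
tissue — under steady-state mass balance:

$$\max\; c^\top v \quad \text{s.t.} \quad S\,v = 0,\qquad
lb_j \le v_j \le ub_j .$$

`fluxomix` stores models as plain R lists (`metabolic_model`), reads
COBRA-style JSON and SBML Level 3 with the fbc extension, and writes
JSON. Gene–protein–reaction (GPR) rules are parsed into ASTs by a
recursive-descent grammar: `and` (enzyme complexes) binds tighter than
`or` (isozymes), parentheses override, identifiers are
whitespace-delimited, and there is no negation (none occurs in
published constraint-based models).

### Irreversible form

Expression caps are one-sided, so the network is first made
irreversible: each reversible reaction is split into `_f` (forward) and
`_b` (reverse, negated stoichiometry) copies that inherit subsystem and
GPR, with split copies adjacent in the original reaction order so flux
matrices are reproducible column for column. Any feasible split flux
recombines as $v_f - v_b$ into a feasible flux of the original model
with the same objective value; the test suite asserts this on toy
networks.

### Reference-anchored normalization

E-flux-style integration needs expression on a bounded, cross-sample
comparable scale. Each sample is min–max scaled with the per-sample
minimum as floor and the expression of one constitutively high
reference gene — pyruvate kinase (`PKM`) by default — as ceiling:

$$e'(g,s) = \frac{e(g,s) - \min_g e(g,s)}
                 {e(\mathrm{ref},s) - \min_g e(g,s)},$$

clipped at 1. Anchoring to a stable reference rather than the
per-sample maximum damps batch effects (the maximum is an extreme
order statistic; a housekeeping anchor is not). *Clipping vs. global
rescaling was a genuinely open choice*: we clip, because it keeps the
reference meaningful as "full activity" and confines overshoot to the
few genes above the anchor; values in $[0,1]$ are required downstream.
Missing values are rejected, not imputed.

### minSum scores and E-flux bounds

Reaction activity for sample $s$ is the GPR tree evaluated with
`min` at `and` nodes and `sum` at `or` nodes. Genes absent from the
data are skipped by default (`missing_policy = "skip"`): an absent gene
does not zero out a complex, and a reaction whose genes are all absent
keeps its default bounds — consistent with real workflows in which only
roughly half of a genome-scale model's reactions receive expression
caps. The alternative (`"zero"`) is available for strict analyses.
Isozyme sums can exceed 1 and are capped at 1 before scaling, so no
reaction's cap exceeds `vmax`; without the cap, isozyme-rich reactions
would dwarf the rest of the network for no biological reason.

Scored reactions get bounds $[0,\; a \cdot v_{max}]$ with
$v_{max} = 1000$, the conventional "effectively unbounded" magnitude in
constraint-based modelling. Exchange reactions are then closed for
uptake except those named in a `medium_spec`, emulating a
semi-quantitative tissue medium (sugars, amino acids, oxygen, growth
factors); each allowed exchange is opened to a common `uptake_limit`.

### The LP solver

No linear-programming package could be assumed available, so the LP is
solved by a two-phase bounded-variable primal simplex written for this
package (`lp_solve()`). Bland's smallest-index rule is used for both
entering and leaving variables: it guarantees termination under
degeneracy and — more importantly here — makes the returned vertex a
deterministic function of the input, so per-sample flux columns are
bit-reproducible. Tolerances: $10^{-9}$ for pivoting eligibility and
feasibility, $10^{-6}$ for downstream mass-balance assertions. FBA
alternative optima are *not* resolved (no pFBA/FVA/geometric
regularisation); plain FBA with a deterministic solver is used, which
is honest about non-uniqueness while keeping runs reproducible.

## 2. Differential statistics

Comparison groups are constructed from sample metadata. The lung
battery enumerates 36 comparisons when all labels are populated:
cancer–normal, small-cell vs non-small-cell, the three-way
normal/adenocarcinoma/squamous comparison and its pairs, the across-stage
k-sample groups and six stage pairs within each of AD and SC, per-stage
AD–N / SC–N / AD–SC, and pooled per-stage vs normal. The published
count of 36 slightly exceeds the groups listed alongside it (32); we
read the missing four as the pooled stage-vs-normal comparisons, which
the battery needs anyway for early-diagnosis contrasts. Groups empty in
the data are dropped with a warning. A two-group pancreas scheme (N–C,
N–S1) and a generic label-driven scheme are also provided.

Flux values are not normal (heavy point mass at bounds and at zero), so
the pipeline always uses rank statistics; a Lilliefors test
(Kolmogorov–Smirnov with estimated parameters, Monte-Carlo null because
estimation invalidates the tabulated distribution) is computed as an
advisory check, mirroring the workflow that motivated it. Two-sample
comparisons use the two-sided Mann–Whitney test with mid-rank ties —
exact by full enumeration of group assignments up to a combined
$n = 20$, normal approximation with continuity and tie correction
above. k-sample comparisons use Kruskal–Wallis with tie correction.
Zero-variance features (e.g. permanently blocked reactions) are
excluded and reported rather than tested, avoiding degenerate ranks.
Raw p-values are adjusted per comparison by the Benjamini–Hochberg
step-up; significance is called on adjusted p at $\alpha = 0.05$. Both
raw and adjusted columns are reported, since staging contrasts are
often examined at both levels.

## 3. Pathway over-representation

Enrichment uses the hypergeometric distribution: a universe of $N$
reactions, a pathway of $m$, a significant set of $n$, an overlap of
$x$. The published account prints the point mass
$P(X\!=\!x) = \binom{m}{x}\binom{N-m}{n-x}/\binom{N}{n}$; a call of
over-representation needs a tail, so the package reports the upper tail
$P(X \ge x)$ (including the observed value; $x=0$ gives 1) and the
point mass alongside for transparency. Binomials are computed in log
space so genome-scale universes do not overflow. A pathway is called
over-represented at tail $p < 0.1$; no correction is applied across
pathways — FDR control belongs to the reaction-level tests that defined
the significant set, and correcting twice would be doubly conservative.
The universe is all subsystem-labelled reactions with `_f`/`_b` split
copies collapsed to their parent id, so a pathway is never
double-counted; whether the original workflow collapsed is unstated,
and this rule is our recorded decision.

## 4. Classification and attribution

One classifier is trained per omic layer on standardised features
(training mean/sd), with no prior feature selection. The forest is a
bagged CART ensemble (Gini impurity, per-node feature subsampling,
midpoint thresholds) implemented in C++ with its own deterministic
PRNG, so a seed fixes the model exactly regardless of R's RNG state.
Probabilities are the average of leaf class-frequency vectors — the
convention of the reference scikit-learn implementation; the printed
hard-vote formula is the degenerate case and agrees in expectation.
Hyperparameters are chosen by mean stratified 5-fold CV accuracy over a
grid scanned in row order, ties to the first row; the conventional full
grid (`default_rf_grid()`: 100/300/500 trees, depth ∞/10/30,
sqrt/log2 features, leaf 1/3, split 2/5) is the documented default,
while tests use reduced grids to stay inside their time budgets.

Layers are combined by soft voting,
$\bar P(k) = \sum_m w_m P_m(k)$ with $\sum_m w_m = 1$ and uniform
$w_m$ by default (a weight hook exists; weight optimisation is
deliberately not implemented). A sample missing any layer is an error —
the ensemble is defined only on samples with complete multi-omic data.
Evaluation reports per-class precision/recall/F1 (zero-division cases
reported as 0 with a flag), accuracy, the confusion matrix, and
one-vs-rest ROC/AUC computed by the rank formulation from the pooled
probabilities.

Marker selection uses path-dependent TreeSHAP: exact Shapley values of
the tree-structured conditional expectation, polynomial time, satisfying
local accuracy (per sample, attributions + expected value = model
output; asserted at $10^{-6}$ against the model and at $10^{-9}$
against a brute-force subset-enumeration oracle on small trees).
Multi-class attributions are averaged as $|{\rm SHAP}|$ over classes
then samples — published accounts of the workflow leave the
aggregation unstated; this symmetric choice is recorded here. Features with mean $|{\rm SHAP}| > 10^{-4}$
are "selected". SHAP is computed on the held-out test partition by
default (configurable): attribution on training data flatters features
the forest memorised. A linear squared-hinge SVM with Platt-calibrated
probabilities is included purely as the comparison baseline the
original study ran; kernels are out of scope.

## 5. The synthetic world

`synthetic_design()` states the world once; the generator never adapts
to test outcomes.

* **Network**: `n_pathways` (4) parallel chains of
  `reactions_per_pathway` (5) reactions from a shared carbon hub to one
  growth precursor, consumed by the objective. Because the pathways are
  *substitutable*, optimal growth is the sum of pathway capacities: a
  planted effect moves only its own pathway's fluxes (plus the truly
  coupled hub/uptake/growth reactions), other pathways stay null —
  exactly the structure pathway-recovery tests need. The glucose
  exchange and hub transporter are reversible so splitting is
  exercised; GPR forms cycle through single-gene, complex and isozyme
  shapes.
* **TX**: per-gene log-normal baselines (meanlog 3, sdlog 0.8 — an
  FPKM-like heavy tail), multiplicative log-normal noise
  (`noise_sd` 0.3), a constant high reference gene (`PKM`, set at the
  baseline distribution's far upper tail), a few near-floor genes so
  the per-sample minimum is stable, and planted effects multiplying a
  pathway's genes in one class (`multiplier` 0.2 for the standard
  strong down-regulation). Stage labels attenuate the effect
  geometrically (S1 weakest: multiplier$^{0.5}$, up to S4: full),
  emulating the observation that stage contrasts are subtler than
  cancer/normal ones.
* **GX**: integer copy numbers 0–4 centred on diploid; planted marker
  genes are amplification-biased in cancer samples with strength
  `gx_shift` — a signal *independent* of the TX pathways, which is what
  makes the ensemble-beats-single-layer property non-trivial.
* **PX**: half of the model genes as proteins proportional to TX with
  extra noise, plus independent nuisance proteins.

**Medium for the toy world.** The generic `medium_spec()` default cap
is 10 flux units per exchange — a sensible semi-quantitative magnitude
for real models whose expression caps are small. For the toy model
`toy_medium()` defaults to 1000: with reference-anchored scores of
order 0.1–1 and $v_{max} = 1000$, a 10-unit medium would be the only
binding constraint, fluxes would be insensitive to expression, and the
whole E-flux premise (transcription limits capacity) would be silently
void. This deviation from the initially specified toy default was
forced by LP arithmetic, decided before any acceptance measurement, and
is recorded in the project ledger.

**What a green test establishes — and what it does not.** The
generator plants clean, monotone, independent effects in a small,
noiseless-solver world. Recovery there demonstrates the pipeline's
plumbing and statistics, not clinical performance: real cohorts add
batch structure, label noise, correlated layers, missing data and
alternative-optima artifacts (futile cycles, transport variance) that
the toy network cannot express. The perfect accuracies in the README
example are a property of the stated strong-effect world, not a claim
about tissue data.

## 6. Numerical choices and degenerate inputs

* LP: Bland pivoting, $10^{-9}$ tolerances, explicit
  infeasible/unbounded statuses — never silent zeros; infeasible cohort
  samples are logged and skipped.
* Hypergeometric: log-space binomials; the test oracle evaluates exact
  rational terms by prime-factorising factorials (Legendre's formula)
  so binomials beyond double precision cancel exactly before one final
  float per term.
* Mann–Whitney exact/approximate cutover at combined $n = 20$;
  constant-valued comparisons return $p = 1$ with a degeneracy flag;
  Lilliefors on constant input reports $p < 1/(n_{mc}+1)$ with a flag.
* BH clips at 1, restores input order, propagates `NA`.
* Splits guarantee at least one sample per class per partition and
  refuse singleton classes by name.
* All randomness (splits, folds, forests, generator) is seed-threaded;
  the forest PRNG is internal (splitmix64-based), so compiled fits are
  reproducible across R sessions and platforms with identical
  floating-point behaviour.

## 7. Known limitations

* Plain FBA only: flux non-uniqueness is acknowledged, not resolved;
  context-specific model extraction (GIMME/iMAT/INIT-style) and model
  pruning are out of scope.
* The lung comparison battery tests stage contrasts but the package
  takes no position on their interpretability; in the motivating
  workflow they were weak.
* GO-style functional profiling against external annotation databases
  is replaced by the generic enrichment engine with user-supplied
  feature-to-term maps (`read_term_map()`, GMT/TSV).
* The SVM baseline is linear; the voting weights are uniform (hook
  only); no covariate adjustment, paired tests or batch-effect
  modelling.
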