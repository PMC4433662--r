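---
title: "Inferring TF-miRNA coregulated gene modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TF-miRNA coregulated gene modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comireg)
```

## The problem

Complex diseases rarely reduce to a list of individually dysregulated
genes: the genes involved tend to act together in functional modules, and
their joint behaviour is shaped by two regulator classes working in
opposite directions — transcription factors (TFs), which act largely at
transcription, and microRNAs (miRNAs), which repress their target mRNAs.
`comireg` implements a complete inference chain for small matched
case/control expression studies (the motivating setting is a 7-vs-7
microarray cohort with both mRNA and miRNA profiled on the same samples):
it finds gene modules that are coherently coexpressed in the disease
state, keeps those enriched in differentially expressed genes, and asks
which differentially expressed miRNAs and which member TFs plausibly
regulate each module. Modules with at least one regulator of each kind
form the final TF-miRNA coregulation network, and a follow-up check asks
whether each regulator miRNA's expression is anticorrelated with its
in-module targets, as repression predicts.

## The pipeline, stage by stage

### Differential calling

Genes and miRNAs are tested feature-by-feature with a two-sided
two-sample Student's *t*-test (pooled variance, `df = n1 + n2 - 2`);
features with raw `p < alpha` (default 0.05, strict) are the DEGs and
DemiRs. Two deliberate choices follow the conventions of the small-cohort
studies this targets: the pooled-variance form is the default (Welch is
available via `varEqual = FALSE`) and **no multiple-testing correction**
is applied by default (Benjamini-Hochberg is available via
`adjust = "BH"`). Both groups constant and equal is reported as a flagged
degenerate result with `p = 1` rather than an error, so batch calls never
abort.

### Coexpression network

The network is built over the **case samples only**, since the modules of
interest describe coordinated expression in the disease state
(`samples = "all"` switches to the full cohort). Two genes are linked iff
their Pearson correlation is positive and two-sided significant at
`alpha` (default 0.05), with the correlation coefficient as edge weight.
The p-value uses the exact null transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ degrees of freedom; at $n = 7$
this makes the decision boundary $r_{crit} \approx 0.7545$. Two
documented choices where the procedure is underdetermined: the network
covers **all measured genes**, not only DEGs — downstream enrichment
needs non-DEGs in the universe — and only **positive** correlations are
admitted ("significantly high" coexpression), which also keeps the
cohesiveness objective's weights nonnegative; `positiveOnly = FALSE`
admits negative correlations with absolute-value weights. An unavoidable
consequence of `alpha = 0.05` at $n = 7$ is that ~2.5% of all null gene
pairs pass the threshold; the module stage must therefore work against a
dense random background, which is why its quality function penalizes
boundary weight.

### Module detection

Modules are grown greedily to local optima of the cohesiveness score
$$f(V) = \frac{w_{in}(V)}{w_{in}(V) + w_{bound}(V) + p\,|V|},$$
where $w_{in}$ is the total internal edge weight, $w_{bound}$ the weight
crossing the boundary, and $p$ a per-node penalty modelling unobserved
connections. From each seed (processed in degree-descending order over
nodes not yet covered by a kept module), the growth evaluates every
boundary-node addition and every member removal, applies the single move
with the largest strict improvement, and stops at a local optimum; ties
are broken by smallest gene id so the procedure is fully deterministic,
and removals that would disconnect the set are skipped, so every module
is connected. Grown clusters below `minSize` (3) or internal density
below `minDensity` (0.3) are discarded, and clusters with match
coefficient $\omega(A,B) = |A \cap B|^2/(|A||B|) \ge 0.8$ are unioned.
The defaults (`penalty = 2`, `minSize = 3`, `minDensity = 0.3`,
`mergeOverlapOmega = 0.8`) are the published defaults of the
cohesiveness-based clustering algorithm this reimplements; none are
stated by the motivating study, so they are pinned here for
reproducibility and all are configurable.

A separate post-hoc pass, `mergeModulesByOverlap()`, merges two modules
when **strictly more than one third** of the smaller module's genes occur
in the larger one. The rule is iterated to a fixed point (merging the
largest-overlap-fraction pair first; ties by larger combined size, then
smallest member id), which is the stronger reading of a rule whose
iteration depth is not specified; merged unions have their statistics
recomputed but are not re-grown, since the rule merges gene sets rather
than re-optimizing them. The exact-one-third boundary case is not merged.

### Enrichment filtering

A module is kept as disease-related when it is enriched with DEGs by the
one-sided Fisher's exact test at `alpha = 0.01` (strict): with universe
size $N$, $K$ DEGs in the universe, module size $n$ and overlap $k$, the
p-value is the exact hypergeometric tail $P(X \ge k)$, computed stably in
log space via `phyper`. The enrichment **universe is the network node
set** — modules live in the network, so the draw is from its nodes; this
is a pinned, configurable choice since the source procedure does not
state its universe.

### Regulators

The consensus target map keeps a (miRNA, gene) interaction when at least
two prediction tools support it **or** it is experimentally validated;
source names are opaque strings, so any tool set works. A DemiR regulates
a module when its consensus targets are enriched in the module (same
Fisher machinery, `alpha = 0.01`, universe = network nodes); miRNAs that
are not differentially expressed are never tested. A TF regulates a
module when it **belongs to the module** and coexpresses with other
members, operationalized as at least `minModuleEdges = 1` internal edge.
Since module members of a coexpression network almost always have
internal edges, the default gate is close to membership itself — the
threshold is configurable (e.g. demand degree 2+) and the near-vacuity is
flagged here rather than silently strengthened. Modules with at least one
regulator of each kind are the coregulated modules assembled into the
final tripartite network.

### Anticorrelation

For each (module, regulator miRNA) pair, the package correlates the
miRNA's profile with each in-module target's profile across **all
matched samples** (cases + controls; a cases-only option exists). The
cross-cohort view is used because repression is expected to show as
opposite expression directions across the whole cohort. The per-miRNA
summary is the **median** target correlation (mean available), chosen for
robustness at 14 samples, and the miRNA is labelled `negative` when the
summary is below zero.

## The synthetic world

`simConfig()`/`simulateDataset()` generate the full input suite with
ground truth. Module coexpression follows a single-latent-factor model:
gene $g$ in module $m$ is
$\sigma(\lambda_m F_m + \sqrt{1-\lambda_m^2}\,\varepsilon)$, so any two
module genes have population correlation $\lambda_m^2$ and the implied
covariance is positive definite by construction. Each module's repressor
miRNA loads on the same factor with negative coefficient $\rho$
(`repressor_loading`), giving population miRNA-target correlation
$\lambda_m \rho$ — the defaults $0.9 \times (-0.89) \approx -0.8$ model
strong repression. Module genes are planted down-regulated in cases and
repressors up-regulated (shift `de_effect = 2` noise-sd units);
background features are differential with probability 0.1 and random
sign. Evidence tables are drawn per source with stated
sensitivity/false-positive rates (defaults 0.7/0.01 for four tools, plus
a 0.1-sensitivity experimental flag), and a 5% background target rate
keeps non-planted miRNAs realistic. The default cohort is 7 vs 7,
matching the motivating study; default dimensions (1000 genes, 60
miRNAs) keep a full run in seconds.

One generator subtlety matters at this cohort size: with only 7 case
samples, *independently drawn* module factors are frequently strongly
correlated in-sample, which makes nominally distinct planted modules
genuinely coexpressed in the realized data (and the clustering then
correctly merges them). The generator therefore decorrelates the factor
realizations exactly (Gram-Schmidt) within the case block and within the
control block, so that the stated property — cross-module correlation
$\approx 0$ — holds in the data actually generated, not just in
population. When more modules are requested than a block can
orthogonalize ($n_{modules} > n_{block}-1$) the generator falls back to
raw standardized draws.

What the generator does **not** emulate: microarray platform artifacts,
probe-level effects, heteroskedastic noise, correlated backgrounds, or
identifier mapping issues. A green planted-recovery test therefore
establishes the correctness of the inference chain on data matching its
assumptions, not robustness to real-platform pathology.

## Numerical and design notes

- All significance gates use strict inequality (`p < alpha`), following
  the "less than" wording of the thresholds.
- Greedy growth uses a $10^{-12}$ strict-improvement margin to avoid
  floating-point move cycles; the one-third merge compares `3*overlap >
  smaller` in integer arithmetic so the boundary case is exact.
- All id-ordering tie-breaks use radix (byte) order, so results are
  locale-independent and runs are byte-identical; `runPipeline()` output
  is reproducible file-for-file given identical config.
- Degenerate inputs: constant features are skipped in network building
  (undefined correlation), constant-vs-constant t-tests are flagged
  rather than raised, and a run with zero coregulated modules produces an
  empty network with a warning, not an error.
- The pipeline's run configuration is a plain R list or JSON file
  (`pipelineConfig()` fills defaults); JSON is used instead of YAML
  because the installation environment provides a JSON parser but no
  YAML package.
- The package's functions (and `runPipeline()`) are the interface; no
  shell entry point is shipped, since the expected use is scripted R.

## Known limitations

- The module counts of any specific published analysis are not
  reproducible from this package alone: they depend on unstated detection
  parameters and on the specific (version-drifting) target databases
  used; this package pins documented defaults instead.
- With `alpha = 0.05` at $n = 7$, the coexpression network's background
  edge rate is substantial; on large backgrounds, greedy growth can
  absorb noise genes adjacent to strong modules, and modules should be
  read as cores plus a noisy fringe.
- The TF "coexpresses with the module" criterion is nearly implied by
  membership at its default strength; conclusions about TF regulation
  rest on the TF annotation list supplied by the user.
- No probe-to-gene mapping, normalization, or batch correction is
  performed; inputs are assumed normalized with harmonized identifiers.
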