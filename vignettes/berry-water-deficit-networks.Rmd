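---
title: "Co-response networks for berry water-deficit multi-omics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-response networks for berry water-deficit multi-omics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrynet)
```

# The analysis

`berrynet` implements an integrated transcriptome-metabolome network analysis
for fruit under water deficit, organized around a two-treatment field design:
control (CT) and water-deficit (WD) vines sampled at several developmental
stages (days after anthesis, DAA) with biological replicates. The statistic
that anchors everything is the stage-wise response

$$\mathrm{log_2FC}_{g,s} \;=\; \log_2\frac{\bar{x}^{WD}_{g,s} + c}{\bar{x}^{CT}_{g,s} + c},$$

the log2 ratio of replicate means per feature $g$ and stage $s$, with a
pseudocount $c$ guarding against zero means ($c = 1$ for counts; for
metabolite concentrations the default is half the smallest positive observed
value, since the data source does not dictate a zero-handling rule).

Downstream of the response profiles the pipeline runs:

1. **Co-response and developmental module detection** (weighted co-expression
   networks): soft-thresholded adjacency ($|r|^\beta$ unsigned, or
   $((1+r)/2)^\beta$ signed), topological overlap
   $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$,
   average-linkage clustering of $1-\mathrm{TOM}$, a height cut, and
   eigengene-based module merging. Co-response ("WD") modules cluster the
   log2FC profiles of differentially expressed (DE) genes across stages;
   developmental ("DEV") modules cluster their normalized expression across
   all samples.
2. **Permutation significance of correlations**: for any pair, the empirical
   p-value of the Pearson coefficient from $n$ label permutations of one
   profile, $p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n+1)$, two-sided.
3. **Promoter element enrichment**: degenerate IUPAC 6--8-mers are scanned
   over 1-kb promoters (both strands by default, overlapping hits counted),
   and per-(module, motif) over-representation is tested with the
   hypergeometric upper tail on gene-level presence, BH-adjusted jointly
   across all pairs; pairs with FDR < 0.01 are reported as enriched with
   score $-\log_{10}(\mathrm{FDR})$.
4. **Module-metabolite co-response and subnetworks**: module representatives
   (eigengene, or mean member profile) are correlated with metabolite log2FC
   profiles; gene-gene and gene-metabolite edges passing PCC > 0.8 with
   empirical p < 0.01 form a typed network (structural gene / TF /
   metabolite) exported as SIF and GraphML.

The DE table itself is an *input*: calling differential expression from
counts is a solved problem belonging to dedicated tools, and this package
only consumes (gene, stage, log2FC, adjusted p) records.

# The synthetic-data generator

Real inputs of this kind (RNA-seq counts, metabolite panels, promoter
sequences) are large and external, so the package ships a generator that
reproduces their statistical structure with planted ground truth:

* **Counts**: negative binomial with global dispersion $\alpha$
  (variance $\mu + \alpha\mu^2$, default $\alpha = 0.1$, a typical RNA-seq
  magnitude), per-gene baseline log2 means uniform on $[4, 10]$. CT means are
  constant across stages; WD means are CT means scaled by
  $2^{\mathrm{log_2FC}}$ where the planted log2FC is a module's stage pattern
  plus gene-level Gaussian scatter (default sd 0.2 — modest biological
  within-module heterogeneity). The default design is 2 treatments x 5
  stages x 3 replicates, the study layout this package targets.
* **Normalized expression**: `log2(count/size_factor + 1)` with
  median-of-ratios size factors (genes containing zeros excluded from the
  geometric-mean reference). This is an explicit stand-in for a
  variance-stabilizing transform: it reproduces the scale and ordering
  properties the pipeline needs without claiming equivalence.
* **DE table**: a moderated t-test per stage (limma on the normalized
  values, mean-variance trend, BH within stage) — realistic power at three
  replicates.
* **Metabolites**: a linked metabolite's log2FC profile is
  $\lambda\,\bar{m} + (1-\lambda)\,\varepsilon$ for module mean response
  $\bar{m}$, link strength $\lambda$, standard normal $\varepsilon$;
  concentrations are log-normal baselines scaled by $2^{\text{profile}}$
  under WD with log-scale replicate noise, hence strictly positive.
* **Promoters**: i.i.d. bases at a configured GC content; each planted motif
  inserts one uniformly sampled concrete expansion at a random position,
  forward strand, in a `carrier_fraction` of the target module's genes and a
  `background_fraction` of the rest. Reverse-strand detection is left to the
  scanner, which is the component under test.

What the generator does **not** emulate: count correlations beyond the
planted modules (library-level covariation, GC bias), metabolite-metabolite
pathway correlations, positional or compositional promoter structure, and
developmental trends in the CT arm. Passing tests therefore demonstrate
method correctness and calibrated error control under the planted model, not
performance guarantees on any particular real dataset.

# Numerical and design choices

**Soft power and tree cut on short profiles.** With five stages, a
correlation is computed from five points, and the connectivity distribution
of the resulting network is not scale-free: the signed scale-free fit index
(equal-width bins, $R^2$ negated for increasing $p(k)$) stays far below the
usual 0.8 target for every power. `select_soft_power()` reports this
honestly (smallest passing power, else best fit with a warning);
`detect_coresponse_modules()` then falls back to the method's canonical
sample-size defaults (unsigned: power 9 below 20 observations, down to 6
above 40). The default cut height is 0.95 on the $1-\mathrm{TOM}$ scale:
with short profiles, cross-module TOM dissimilarities concentrate just below
1, and cuts at 0.97-0.99 fail to separate planted modules that cuts at
0.95-0.96 separate cleanly. The "dynamic" cut option is the simplified
recursive splitter (split any cluster whose subtree exceeds the cut height,
keep clusters of at least `min_module_size`), which for a monotone
dendrogram coincides with the static cut at that height; the full
deep-split heuristics of dedicated tree-cutting packages are intentionally
not reproduced, so module *counts* on real data will differ from any
particular published partition and are not a contract of this package.

**The empirical p-value floor at five stages.** There are only $5! = 120$
permutations of a 5-point profile. With the (standard) +1-corrected
two-sided estimator, the identity permutation always ties the observed
statistic, so even a perfect correlation has expected
$p \approx (1 + n/120)/(n+1) \approx 0.0093$ — barely below the 0.01 edge
threshold — and crosses it in only about two-thirds of permutation streams
at $n = 1000$. Profiles with repeated values are worse: each exact tie among
stage values adds tying permutations and lifts the floor above 0.01
entirely. Consequences embraced by the design: (i) the edge screen at
defaults is extremely conservative in 5-stage mode — reported edges are
near-perfect correlations; (ii) analyses that need finer resolution should
raise `n_perm`; (iii) tests that demonstrate threshold *semantics* use
larger `n_perm` so the estimator can resolve below 0.01. This is a property
of the estimator at $S = 5$, not an implementation artifact.

**Enrichment conventions.** Presence (at least one match), not match count,
feeds the hypergeometric test — enrichment asks how many *genes* carry an
element. The background defaults to the clustered universe (DE genes with
promoters), not the genome: enrichment "in a module" is relative to what
could have been assigned to it. Both-strand scanning is the default because
several canonical elements are palindromic (e.g. CACGTG); a palindrome is
counted once per strand, a deliberate, documented convention. A base `N` in
a promoter matches only an `N` in the motif, never a concrete or degenerate
motif position.

**Determinism and order independence.** Every stochastic step is seeded.
Pairwise permutation tests derive a per-pair seed from a hash of the two
identifiers, so edge screens are reproducible regardless of evaluation
order; the pipeline writes a manifest (inputs, parameters, seed, version)
and re-running a configuration reproduces every numeric output byte for
byte.

**Degenerate inputs.** Zero-variance profiles cannot be correlated: module
detection rejects them (the end-to-end wrapper excludes and reports them),
heatmap clustering sets them aside with a warning and appends them after the
ordered leaves, and the two-group ANOVA reports p = 1 (equal means) or p = 0
(unequal means) when both groups are exactly constant. Readers reject
malformed files with coordinates rather than repairing them. A pipeline run
on data with (almost) no DE genes degrades gracefully to empty module,
enrichment, and network outputs rather than erroring — the correct answer on
null data is "nothing", not an exception.

**PCA conventions.** Scores come from the standard centered (optionally
scaled) singular value decomposition; each component's sign is fixed by
making its largest-magnitude loading positive, so scores are reproducible
across numeric libraries. Scaling defaults: on for metabolites
(heterogeneous units), off for log-scale expression.

# Problem sizes used in validation

The shipped tests and the acceptance script run entirely on generated data
at deliberately modest sizes: the module-recovery scenario uses 1,000 genes
with three planted 100-gene modules (patterns chosen mutually
near-orthogonal with all-distinct stage values, for the reasons above) over
20 seeds; promoter-element recovery and false-positive control use 100 seeds
of 1,000 promoters of 1 kb; permutation calibration uses 1,000 independent
pairs at 1,000 permutations; the demo pipeline analyzes 300 genes and 8
metabolites end to end. These sizes exercise every code path at full
statistical fidelity while keeping a complete validation run in the minutes
range on one CPU.

# Known limitations

* Five-stage mode operates at the resolution limit of permutation inference
  (see above); the module-metabolite screen at defaults will miss moderately
  strong links ($|r| \lesssim 0.95$) by design.
* The normalized-expression transform is a documented approximation, not a
  variance-stabilizing transform; developmental-module results on real data
  should be checked against a proper VST upstream.
* The simplified tree cut can split one planted module into two adjacent
  labels under heavy noise (the merge step usually heals this); module
  counts are data- and parameter-dependent.
* The generator's independence assumptions make null calibration *easier*
  than on real data with correlated backgrounds; FDR control statements are
  with respect to the planted model.
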