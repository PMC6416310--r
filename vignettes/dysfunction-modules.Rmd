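---
title: "Dysfunction modules, pivot regulators and drug reversal: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysfunction modules, pivot regulators and drug reversal: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulepivot)
```

This vignette explains the models behind each pipeline stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the methodology was
genuinely open.

## The co-expression model

The module stage assumes the expression matrix is already normalised and on
a log-like scale; it performs no normalisation of its own. Co-expression is
Pearson correlation between gene profiles. By default the matrix is first
centred within sample groups (`center_by_group()`): with healthy, disease
and treatment groups in one matrix, any two genes responding to the disease
correlate strongly whether or not they are co-regulated, and that
group-mean signal otherwise bleeds into module detection as a spurious
"disease signature block". Group centring removes exactly the group-mean
component and leaves within-group co-variation, which is what a module is
meant to capture. Set `center_groups = FALSE` to correlate the raw matrix,
e.g. when all samples come from one condition.

Correlations are soft-thresholded, `a_ij = |r_ij|^β` (unsigned default; a
signed variant `((1+r)/2)^β` is available), and β is chosen as the smallest
candidate in 1–20 whose connectivity distribution passes the scale-free
topology criterion: bin the connectivities `k_i = Σ_j a_ij` into 10
equal-width bins and require R² ≥ 0.85 for the regression of log10
frequency on log10 mean connectivity, with R² signed negative when the
slope is positive. When no candidate passes — common for matrices whose
true structure is a handful of planted blocks rather than a scale-free
graph — maximising R² is not meaningful: R² typically keeps creeping
upward with β as all connectivities shrink toward zero, and the scan
maximum is just the largest candidate, which annihilates the network. The
fallback is therefore the widely used sample-size rule of thumb (unsigned:
β = 9 below 20 samples, 8 for 20–29, 7 for 30–39, 6 from 40; doubled for
signed networks), with a warning.

The topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                           {\min(k_i,k_j) + 1 - a_{ij}}$$

rewards shared neighbourhoods as well as direct adjacency; `1 − TOM` is the
clustering dissimilarity, with the diagonal set to 1 by convention.
Modules are branches of the average-linkage tree cut at a static height
(default 0.95). Clusters below `min_module_size = 30` genes are labelled
`unassigned`; surviving modules are labelled `M1, M2, …` in decreasing size
order with ties broken by the lexicographically smallest member gene, so
the labelling is deterministic. Oversized modules — at least
`max_module_size = 500` genes — are screened out afterwards
(`filter_modules()`), reflecting the practice of discarding blocks too
large to interpret as a functional unit.

Two defaults deserve justification because plausible alternatives exist:

* **Cut height 0.95, not 0.99.** On the reference synthetic study the two
  cuts recover the same planted modules, but at 0.99 roughly half of the
  unstructured background genes are absorbed into modules (raising the
  worst-seed misassignment substantially), whereas at 0.95 they are left
  unassigned. A cut close to 1 merges branches that are barely more
  similar than random; 0.95 keeps modules tight without fragmenting them.
* **Static cut, not dynamic tree cutting.** A fixed height is fully
  deterministic and transparent; with the soft power chosen as above it
  recovers planted modules reliably. Dynamic hybrid cutting, module
  eigengenes and eigengene-based merging are deliberately out of scope.

## Enrichment

Enrichment is flat over-representation: for module of size $n$ and term of
size $K$ in a universe of $N$, the p-value is the exact hypergeometric
upper tail $P(X \ge k)$ of the overlap $k$. The universe defaults to the
partition's genes intersected with the genes annotated anywhere in the
collection — the dominant convention of enrichment tools — and can be set
explicitly. Terms are tested only when the overlap is at least 1 and the
universe-intersected term size lies in `term_size_range` (default 10–500).
BH adjustment runs within each module's family of tested terms; rows are
kept at `p ≤ 0.01` and `q ≤ 0.01` by default (GO-style), with 0.05/0.2 the
conventional pathway-style alternative. "q value" here means BH FDR. GMT
sets are taken as given: no ontology-graph propagation is performed, so GO
ancestors must be materialised into the GMT beforehand if desired.

## Pivot analysis

A regulator is a pivot of a module when (i) at least `min_pairs = 2` of its
interaction targets lie in the module and (ii) the hypergeometric tail is
below `p_cutoff = 0.01`. The test universe is the set of distinct targets
in the loaded interaction table of the same regulator class — ncRNA and TF
tables describe different interaction spaces, so the two scans run with
separate backgrounds. The raw-p convention (no multiple-testing
correction across regulator–module pairs) follows the field's pivot
analysis practice; `bh = TRUE` switches to BH-filtered calls.
Self-targeting rows are dropped before counting. Every reported p-value is
recomputable from the four reported counts with `hypergeometric_tail()`.

## Differential expression and reversal

Contrasts are fixed as disease = model vs healthy and treatment = treated
vs model, with `log2_fold_change = mean(contrast) − mean(reference)` on the
stored scale. The default test is the limma moderated t: with the three to
five samples per group these designs typically have, per-gene variance
estimates are unstable and the empirical-Bayes shrinkage across genes is
the standard remedy — in the reference simulation it lifts recovery of the
planted reversals from a borderline ~0.75 to essentially complete, at
identical fold-change estimates. A plain Welch t-test remains available
(`method = "welch"`; features with zero variance in both groups get p = 1
when means are equal, p = 0 otherwise, with a logged count). Calls use
`|log2FC| ≥ 1` and BH `q ≤ 0.05` by default.

Reversal is set algebra on the two call sets: *inhibited* = up in disease ∩
down under treatment; *promoted* = down in disease ∩ up under treatment.
The two sets are disjoint by construction and their sizes add up to the
drug's total target count — an identity asserted on every run. The same
machinery applies unchanged to protein quantification tables.

## PPI stage

Edges are kept when the score is strictly above `min_score = 950` (the
convention for 0–1000 interaction scores, in contrast to the inclusive
`≥ 0.5` used for 0–1 regulator-interaction scores — both thresholds are
honoured exactly as conventionally printed). When a node subset (e.g. the
drug-regulated features) is supplied, subset nodes without surviving edges
remain as degree-0 nodes. Hubs are ranked by degree with identifier
tie-breaks; "network clusters" are connected components of at least
`min_cluster_size = 3` nodes — the minimal reading, since no specific
clustering algorithm is implied by degree-based hub analysis.

## The synthetic-data generator

`simulate_study()` emulates the data structure the pipeline assumes, at
desk scale. The defaults are the reference study used by the test suite:
600 genes of which five 100-gene modules and 100 background genes; four
groups (healthy, model, two drugs) of five samples; 50 disease genes
shifted ±2 log2 units in all non-healthy groups with 60% of them exactly
cancelled per drug; 30 module-specific regulators (20 targets each, 80%
drawn from the assigned module) against 200 null regulators; and a
300-protein network with five hubs of ~50 extra edges over an
Erdős–Rényi background of mean degree 4, scores in (950, 1000).

Module genes follow a latent factor model: gene $g$ in module $m$ has
$x_{gs} = \mu + \lambda f_{ms} + \varepsilon_{gs}$. `noise_sd` (default
0.5) is the **marginal** per-gene standard deviation around the group
mean; it splits into $\lambda = \mathrm{sd}\sqrt{r}$ and residual
$\mathrm{sd}\sqrt{1-r}$, so the expected within-module correlation is
exactly `within_module_correlation` and every gene — module, background or
disease — has the same marginal spread. Two further choices matter:

* **Factor realizations are orthogonalised** against the group-indicator
  space and against each other, then scaled to unit sample variance. At 20
  samples, independently drawn factor realizations correlate by chance
  (sd ≈ 0.23, occasionally > 0.5), at which point two "distinct" planted
  modules are genuinely indistinguishable in the data and recovery metrics
  measure luck rather than method. Orthogonalising makes the planted truth
  identifiable by construction; it also keeps module structure out of the
  group-mean space, where the disease shift lives.
* **Reversal is exact cancellation** of the disease shift in the treated
  group — the simplest structure making "up in disease, down after drug"
  well defined.

All generators are pure functions of `(config, seed)`; identical seeds give
identical studies, and every derived quantity (interaction tables, gene
sets, PPI edges) comes with a truth record.

What the generator does **not** emulate: mean–variance relationships and
count noise of sequencing data, heteroscedastic genes (one shared
`noise_sd`; per-gene dispersions would be a config extension), correlated
modules, batch effects, dose–response gradients, or mass-spectrometry
error models. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not robustness to every
artefact of real data.

## Numerical and determinism notes

* Hypergeometric tails use the exact distribution function; tests verify
  agreement with full combinatorial enumeration to 1e-12 for all universes
  up to 25.
* TOM is computed by matrix multiplication and verified against an
  explicit triple-loop recomputation to 1e-10.
* All result tables are written with a locale-independent radix sort over
  all columns, UTF-8, `\n` endings — reruns are byte-identical, and the
  pipeline manifest records MD5 hashes of every output. The run log
  contains stage summaries but no timestamps for the same reason.
* Degenerate inputs fail fast with named errors: duplicate identifiers,
  zero-variance genes before correlation, impossible hypergeometric
  counts, empty universes, disjoint backgrounds, groups with fewer than
  two samples.

## Problem sizes

The test suite runs the reference study (600 genes × 20 samples) for the
end-to-end properties and a 150-gene version for unit-level checks; the
acceptance script adds a 700-gene study with one deliberately oversized
600-gene block to exercise the module screen. These sizes keep the full
suite in the order of a minute while leaving every statistical property
(correlation recovery, calibration, power) in its asymptotically relevant
regime.

## Known limitations

* The static height cut cannot rescue genes whose average dissimilarity to
  their module straddles the cut; such genes end up unassigned rather than
  misassigned — conservative, but lossy for weakly attached members.
* With unsigned networks, a module containing both directions of one
  latent program is recovered as a single module; the signed option splits
  it at the cost of halving effective correlations.
* The enrichment stage treats gene sets as flat; ontology-aware analyses
  need pre-propagated GMTs.
* Pivot calls use raw p-values by convention; at genome-scale interaction
  tables the BH option is advisable.
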