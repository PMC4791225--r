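---
title: "Inferring transcriptional regulator activity from multi-omic evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional regulator activity from multi-omic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itrtools)
library(dplyr)
```

## The problem

Cancers driven by a broadly acting transcription factor — MYCN-amplified
neuroblastoma is the motivating example — rarely show recurrent somatic
mutations that point at drug targets. An alternative is to ask which
*regulators* (transcription factors, signalling proteins, or chemical
compounds) must have changed activity to produce an observed
differential-expression (DE) response, by matching the DE genes against a
curated prior of known regulator→target relationships. itrtools implements
this inference — the regulator calls are conventionally termed *inferred
transcriptional regulators* (ITRs) — together with the integration stages
that make the calls useful: cross-condition comparison, core-network
reconstruction, prognostic gene signatures, RNAi-screen normalization and
ChIP-peak context classification.

## The regulator activity model

Two statistics are computed per regulator against an evidence set (the
significant DE genes of one contrast, or a non-directional gene set such as
ChIP-bound genes, co-precipitated interactors or screen hits) inside a
measured-gene universe of size $N$.

**Overlap enrichment.** If the regulator has $m$ known targets inside the
universe and the evidence contains $n$ genes, of which $k$ are targets, the
overlap p-value is the upper-tail hypergeometric probability

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, m, n),$$

computed with `overlap_pvalue()` and Benjamini–Hochberg adjusted across
regulators. Unknown-sign edges count towards the overlap: enrichment asks
*is the module perturbed*, not in which direction. Regulators are ranked by
raw overlap p-value (the FDR is reported alongside for filtering), with a
deterministic tie-break — larger $|z|$ first, undefined $z$ last, then
regulator name — so rankings are reproducible.

**Activation z-score.** Direction is scored only over signed overlapping
edges. With edge weights $w_g$ and a match indicator
$m_g = +1$ when the predicted direction (activates → up, represses → down)
agrees with the observed DE direction and $-1$ otherwise,

$$z = \frac{\sum_g w_g\, m_g}{\sqrt{\sum_g w_g^2}},$$

which with unit weights reduces to
$(n_\text{consistent} - n_\text{inconsistent}) / \sqrt{n_\text{signed}}$.
Positive $z$ supports activation of the regulator, negative $z$ inhibition;
$|z| \ge 2$ (the conventional threshold, configurable) calls the state.
The commercial tool that popularised this analysis does not publish its
internal edge weighting, so unit weights are the default and the weight
column of the prior is honoured when provided. $z$ is undefined — and the
state indeterminate — when the evidence is non-directional or no signed
edge overlaps.

Negating every observed direction negates $z$ exactly and leaves the
overlap p-value untouched; this antisymmetry is enforced by a property
test.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| `fdr_max` | 0.05 | `significant_set()` | significance alone defines DE; no fold-change cut is imposed by default |
| `min_abs_log2fc` | 0 | `significant_set()` | opt-in effect-size filter |
| `z_threshold` | 2 | `infer_itrs()` | conventional activation call for this statistic |
| `n` (top list) | 100 | `topn_overlap_matrix()`, `common_core()` | the standard cross-condition list size |
| `span` | 0.5 | `loess_normalize()` | the published screen does not state its loess parameters; declared, overridable |
| hit threshold | 1 log2FC | `call_hits()` | viability changed at least two-fold, boundary inclusive |
| promoter window | 2000 bp up / 500 bp down of TSS | `classify_peaks()` | not stated by any standard; explicit and configurable |
| downstream window | 2000 bp past TES | `classify_peaks()` | same |
| `split` | median | `stratify_and_test()` | two-cohort Kaplan–Meier comparison; ties go low |

## Cross-condition integration

Top-$N$ rankings are compared with the overlap percentage
$O_{AB} = 100\,|top_N(A) \cap top_N(B)|/N$, rounded half-up (with $N = 100$
the value is exact). `common_core()` collects regulators present in the
top-$N$ of at least `min_conditions` rankings; `core_network()` induces the
known protein-interaction subgraph on the core, optionally excluding
chemical regulators via a type tag (chemicals belong in ITR rankings but
not in a protein map), and `pathway_enrichment()` scores the core against
pathway gene sets with the same hypergeometric tail. The enrichment
universe defaults to the interaction graph's nodes, because an
interaction-database background is what such tools use; it is overridable
since the choice materially affects p-values.

## Gene signatures and survival

A regulator's *contributing genes* are the overlapping targets on which its
call rests (`itr_contributions()`). Genes observed with a consistent
direction in at least two conditions form a directional signature; genes
with conflicting directions are dropped. The published analysis this
follows does not state how its signature scored the patient cohort, so the
scoring rule here is declared rather than inferred: each signature gene's
expression row is standardized across patients and a patient's score is the
mean of direction-weighted standardized expression. The score is therefore
invariant to per-gene affine rescaling, and flipping all signature
directions negates scores without changing a median-split log-rank p.
Patients are split at the median score (ties to the low group) and compared
with a two-sided log-rank test via the survival package.

## Screen normalization

384-well viability plates are corrected by fitting a locally weighted
quadratic surface of log2 signal over well coordinates, using only the
sample fraction of the plate — lines 1–2 and 23–24 along the 24-position
axis hold controls and are excluded from the fit. A 16-row plate has no row
23, so the published phrase "rows 1-2 and 23-24" is interpreted as
positions along the 24-column axis; the mask is configurable. Corrected
log2 signal is residual plus the grand median of the fitted sample wells,
so a spatially flat plate is returned unchanged. Robust z-scores use
median and MAD with the 1.4826 normal-consistency constant, computed per
plate by default (whether the published screen pooled plates is ambiguous).
Per-gene log2 fold changes (vs the plate's sample median) are averaged over
replicate wells — four siRNAs per gene share one well, so replication is
across wells, not within — and hits are called at ±1 log2FC inclusive.

Loess is a linear smoother, not a projection, so re-correcting a corrected
plate is exactly a no-op only when the spatial structure lies in the local
quadratic span (e.g. a bilinear gradient, which is removed to machine
precision). On noisy plates a second pass perturbs wells by well under 0.1
log2 — far below the hit threshold — and the tests assert both regimes
separately.

## Peak context classification

Peaks are assigned by midpoint with precedence promoter > exon > intron >
immediate downstream > distal; windows are strand-aware. Midpoint
assignment is the simplest deterministic rule and the source analysis never
stated its rule, which is also why published context percentages are not
treated as reproduction targets. The "enhancer" sub-label requires a
user-supplied enhancer catalogue; without one, such peaks stay distal.
Translation invariance and strand-reversing reflection invariance are
enforced by tests (reflection is exact away from window boundaries, and the
synthetic fixture keeps peaks 1 kb clear of every boundary).

## What the synthetic data emulate — and what they do not

The generators produce the *downstream products* of the assays, not raw
reads or spectra:

- `generate_prior_network()`: 200 regulators with Poisson(30) target
  modules over 5,000 genes, signs 60% activating / 35% repressing / 5%
  unknown — a desk-scale stand-in for a curated knowledge base.
- `generate_contrasts()`: planted active regulators perturb each signed
  target with 80% direction consistency over a 5% DE background;
  significant genes get $|log2FC| \sim N(1.5, 0.5)$ truncated above 0.2 and
  FDR $\sim U(0, 0.01)$. DE statistics are generated at the summary level
  because DE calling itself is out of scope and the inference consumes only
  gene, direction and significance.
- `shared_core_conditions()`: three related conditions share a planted
  60-regulator core (plus 15 specific each) and a fourth condition plants a
  disjoint set of 75 — the structure behind a block-patterned overlap
  matrix (observed ≈75% within the trio vs ≈30% against the unrelated
  condition).
- `generate_cohort()`: 300 patients, expression shifted by a latent factor
  along the signature directions, exponential survival with hazard ratio 3
  per latent sd, uniform censoring calibrated to 30%.
- `generate_plate()`: half-log2 bilinear gradient, 10% multiplicative
  noise, 16 hits at −1.5 log2.
- `generate_genome_fixture()`: 5 non-overlapping two-exon genes on one
  synthetic chromosome with a 20-peak plan covering all five context
  categories.

Every generator is a pure function of the master seed (each derives a
stable sub-seed from its name, so adding a generator never perturbs another
stream), and each returns a truth record sufficient to score recovery.

These simulations deliberately omit features of real data: correlated
genes, batch effects, heavy-tailed microarray noise, LD-like structure
between regulator modules, informative censoring, plate-edge evaporation
beyond a smooth surface. Passing tests therefore demonstrate correctness of
the statistics and recovery under the stated generative model, not
performance on any particular real dataset.

## Numerical choices and degenerate inputs

- Hypergeometric tails use `phyper(k - 1, ..., lower.tail = FALSE)`;
  an empty overlap gives exactly 1. Tests cross-check against a
  `choose()`-sum enumeration oracle to 1e-12 on universes up to 25.
- Duplicate prior edges collapse: conflicting signs become `unknown`
  (curated networks contain context-dependent edges; the z-score already
  excludes unknown signs), and the maximum weight is kept.
- Identifiers are upper-cased throughout so mixed-case symbols across omic
  layers join; miRNA names are ordinary identifiers after folding.
- Zero MAD yields all-zero robust z-scores with a degenerate-scale flag.
- Zero-variance or missing signature genes are skipped with warnings; an
  empty signature is an error rather than a silent pass-through.
- `loess(..., surface = "direct")` avoids interpolation error so that exact
  low-order surfaces are removed to machine precision.

## Problem sizes used in the checks

The bundled verification runs use the generative defaults above: 100
seeded replicates for planted-regulator recovery, 20 seeds for the overlap
block pattern, 100 cohorts for survival power plus 1,000 for null
calibration, one plate per screen check, and the 5-gene/20-peak genome
fixture. These sizes give binomial standard errors small enough to resolve
the tested rates while keeping a full run to a few minutes on one CPU.

## Known limitations

- The prior-network TSV schema is a deliberate simplification of commercial
  knowledge bases (no context, tissue or confidence fields).
- Ranking integration treats top-$N$ lists as sets; no rank-weighted
  overlap statistic is provided.
- Survival analysis is limited to two-group Kaplan–Meier/log-rank;
  covariate adjustment (Cox) is out of scope.
- Peak classification is midpoint-based; overlap-fraction assignment would
  differ for peaks spanning category boundaries.
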