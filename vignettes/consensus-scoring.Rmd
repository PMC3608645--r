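---
title: "Vote-counting consensus scoring of receptivity-associated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vote-counting consensus scoring of receptivity-associated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragscore)
```

## The problem and the model

The human endometrium is receptive to an implanting embryo only during a
short window (~day 6 post-ovulation; the pre-receptive biopsy is typically
taken around day 2). Many independent studies have profiled endometrial
gene expression across this transition, but they were run on different
cohorts, platforms and cycle-dating schemes, and their published gene lists
overlap only partially. `ragscore` derives a consensus not from raw
intensities — usually unavailable or incomparable — but from the curated
call each dataset makes about each gene: `expressed` or `not_detected` in a
condition, `up` or `down` across an ordered condition comparison.

The model is deliberate vote counting. Each dataset contributes **two
points** per gene to the score of the call it reports, at most once per
gene and call type. For gene $g$:

$$S_{\mathrm{expressed}}(g) = 2\,n_{\mathrm{expressed}}(g), \qquad
  S_{\mathrm{up}}(g) = 2\,n_{\mathrm{up}}(g),$$

with $n$ counting supporting datasets, and analogously for `not_detected`
and `down`. Cumulative scores add one status and one pattern dimension:

$$C_{\mathrm{UpEx}} = S_{\mathrm{up}} + S_{\mathrm{expressed}}, \qquad
  C_{\mathrm{DownNd}} = S_{\mathrm{down}} + S_{\mathrm{not\_detected}}.$$

Opposing calls are **never subtracted**. The source method says only that
disagreement lowers a gene's standing, without a formula; here the two
opposing scores are kept side by side and disagreement acts through the
*consistency rule*: a Receptivity Associated Gene must have zero
contradicting datasets. This choice reproduces every score in the published
179-gene tables as exactly twice a support count, which an arithmetic
penalty would not.

### Classification

With the default `rag_params()`:

* **Up-Ex**: $n_{\mathrm{expressed}} \ge 1$, $n_{\mathrm{up}} \ge 1$,
  $n_{\mathrm{not\_detected}} = n_{\mathrm{down}} = 0$;
* **Down-Nd**: the mirror image.

The minimum supported cumulative score is therefore $2 + 2 = 4$, which is
also the smallest value in the published tables — evidence that the
published rule tolerated no contradiction and imposed no higher support
floor. `min_status_datasets` / `min_pattern_datasets` raise the floor;
`require_zero_contradiction = FALSE` relaxes the consistency rule, in which
case a gene qualifying for both classes goes to the one with the larger
cumulative score and ties are excluded, so the two classes stay disjoint by
construction.

Only datasets from the cohorts in `cohorts_included` (default: healthy
natural-cycle participants) enter scoring; disorder, stimulated-cycle and
IVF-failure datasets are excluded from consensus building and reappear only
as *case* corpora in `derive_suboptimal()`.

### Direction and tie-breaking conventions

`up` always means higher in the **first** condition of the comparison pair;
a dataset curated against the reversed pair is direction-flipped at scoring
time, making scores invariant to how each source study oriented its
contrast. Ranked output orders by cumulative score descending, then pattern
score descending, then symbol (C-locale lexicographic). The published
tables are compatible with this tie-break wherever their order is pinned by
a unique cumulative score; within tied blocks their order is arbitrary and
not reproduced.

## Ingestion choices

* Delimited text with a header; tab by default, comma auto-detected from
  the header line. Symbols are upper-cased and trimmed before alias lookup,
  because microarray annotation files mix cases freely.
* A gene list with fewer than 5 distinct genes warns (the curation
  threshold used when the original corpus was screened) but is not
  rejected.
* `not_detected` is an explicit curated assertion (repeated
  background-level signal); it is **never** inferred from a gene's absence
  from a list — absence simply casts no vote.
* A dataset asserting both members of an opposing pair for one gene and
  context is rejected at ingestion. If *harmonization* creates such a
  collision (two aliases mapping to one symbol with opposing calls), both
  calls are dropped and logged instead: merging identifiers must not
  manufacture either consensus or contradiction.
* The scoring unit is the dataset (one curated list). The source corpus
  mixed dataset and study counts (84 datasets from 24 studies), so
  `corpus(..., collapse_by_study = TRUE)` offers the publication-level
  alternative, merging same-study datasets by call union (contradictory
  unions dropped pairwise) so each study casts one vote. Dataset mode is
  the default and is what all packaged examples use.
* The condition map shipping with `default_condition_map()` encodes the
  common clinical synonyms (LH+7 / mid-secretory → receptive; LH+2 / early
  secretory → pre-receptive). The original corpus's exact label vocabulary
  is not published; the map is user-overridable and unmapped labels
  canonicalize to a tagged `other:<label>` rather than being dropped.

## The synthetic world

`simulate_corpus()` works at the call level the analysis consumes — it
simulates curation outcomes, not intensities, probes or normalization.
Each gene has a fixed true class (`true_upex`, `true_downnd`,
`background_expressed`, `background_absent`); each dataset reports each
gene independently with probability `p_report` (Bernoulli coverage — a
crude but honest stand-in for platform and design differences); each
reported call is independently flipped to its contradiction with
probability `p_flip`. All randomness derives from one seed, with
per-dataset substreams drawn up front.

Defaults state a scaled-down version of the published corpus: 500 genes
and 12 datasets (vs ~19,000 genes and 84 datasets), true-class fractions
0.008 / 0.0015 (≈ 151 and 28 of 19,285), 63% of background genes expressed
(≈ 12,099 of 19,285), `p_report = 0.5` (a typical list covers a fraction
of the universe), `p_flip = 0.05` (curation noise is low but not zero).
`frac_background_expressed` is defined as a fraction *of the background
genes*, so the three fractions can never be mutually inconsistent.

Under the zero-contradiction rule the noise model has a useful closed
form: a true Up-Ex gene reported in $k$ datasets survives classification
iff none of its $2k$ calls flips, so

$$P(\text{survival}) = (1 - p_{\mathrm{flip}})^{2k}.$$

The test suite checks exact recovery in the noiseless limit, monotone
degradation in `p_flip`, and agreement with this closed form within three
Monte-Carlo standard errors. What a green simulation test does **not**
establish: robustness to correlated errors (a bad platform mis-calling
whole gene families), condition mislabelling, or coverage that depends on
expression level — none of which the generator models.

## Quantification utilities

The companion wet-lab formulas are exact and small: relative expression by
the Livak method, $RE = 2^{-\Delta\Delta C_t}$ with
$\Delta C_t = C_t^{\text{target}} - C_t^{\text{reference}}$ (replicate
$C_t$ values are averaged arithmetically before subtraction; no
amplification-efficiency correction), and spheroid attachment,
$100 \cdot \text{attached} / \text{total}$. "Reduction in percent
attached" is reported in percentage points (`control − treated`) by
default — the reading consistent with published antibody-blocking effect
sizes — with `relative = TRUE` for the relative alternative.

## Known limitations

* The raw curated corpus behind the published consensus is not distributed,
  so corpus-scale totals (12,099 expressed genes, 7,289 not-detected, 159
  upregulated, 125 downregulated) cannot be recomputed here; the packaged
  fixture carries only the downstream 179-gene result.
* The computational rule behind the published 13-gene IVF-failure subset is
  not stated; `derive_suboptimal()` implements a documented
  contradiction-based rule (reference Up-Ex genes reported down or
  not-detected at least once and never up in the case corpus), which should
  not be assumed identical to the original procedure.
* Scores are unweighted: a 4-sample pilot and a 100-sample trial each cast
  one vote. That is faithful to the source method, which shows no evidence
  of weighting by sample size or platform, but it is a modelling choice,
  not a statistical optimum; no significance measure is attached to a
  score.
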