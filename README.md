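# ragscore

Cross-study vote-counting consensus for endometrial receptivity gene
signatures.

Dozens of transcriptomic and proteomic studies have profiled the human
endometrium around the window of implantation, but they disagree on which
genes mark the receptive phase: cohorts, platforms, sampling days and
statistics all differ. `ragscore` implements the reliability-score approach
to that problem: instead of re-analysing raw data, it ingests the *curated
gene lists* each study reports — per-gene calls of `expressed`,
`not_detected`, `up` or `down` — and counts votes across datasets.

## The scoring model

For a gene *g*, a condition *c* (e.g. the receptive phase) and an ordered
condition comparison (e.g. receptive vs pre-receptive, "up" meaning higher
in the receptive phase):

- **status scores** — `S_expressed(g) = 2 · #{datasets reporting g expressed in c}`,
  and likewise `S_not_detected(g)`;
- **pattern scores** — `S_up(g) = 2 · #{datasets reporting g upregulated}`,
  likewise `S_down(g)`; datasets curated against the reversed comparison are
  direction-flipped before counting;
- **cumulative scores** — `C_UpEx(g) = S_up(g) + S_expressed(g)` and
  `C_DownNd(g) = S_down(g) + S_not_detected(g)`.

Opposing calls are never netted: both scores are kept, and a gene is
**consistent** only when one side of each pair is zero. Receptivity
Associated Genes (RAGs) are the consistent genes: **Up-Ex** (expressed and
upregulated in the receptive phase, with zero `not_detected`/`down` votes)
and **Down-Nd** (the mirror image). A dataset contributes at most one vote
per gene and call type, so every score is even and a gene supported once on
each dimension scores the minimum cumulative of 4.

The package also ships:

- a transcription of the published 179-gene consensus (151 Up-Ex + 28
  Down-Nd with their scores) as a regression fixture
  (`load_fixture_tables()`);
- a synthetic corpus generator with known ground truth
  (`simulate_corpus()`) and recovery metrics (`evaluate_recovery()`) so the
  whole pipeline is testable without any download;
- a rule for flagging reference Up-Ex genes that behave *suboptimally* in a
  case cohort such as IVF failure (`derive_suboptimal()`);
- the small validation formulas used alongside such signatures: qPCR
  relative expression by the Livak `2^-ΔΔCt` method and spheroid-attachment
  percentages (`relative_expression()`, `percent_attached()`).

## Worked example

```r
library(ragscore)

# a corpus in which SPP1 gets 6 expressed + 9 up votes, GPX3 6 + 7,
# and E2F2 is not-detected in 6 datasets and downregulated in 1
corp <- corpus_from_votes(data.frame(
  symbol         = c("SPP1", "GPX3", "E2F2"),
  n_expressed    = c(6, 6, 0),
  n_not_detected = c(0, 0, 6),
  n_up           = c(9, 7, 0),
  n_down         = c(0, 0, 1)))

score_all(corp, c("receptive", "pre_receptive"))
#>   symbol expressed_score not_detected_score up_score down_score cumulative_upex cumulative_downnd
#> 1   SPP1              12                  0       18          0              30                 0
#> 2   GPX3              12                  0       14          0              26                 0
#> 3   E2F2               0                 12        0          2               0                14

rags <- derive_rags(corp)
#> filter_datasets: retaining 9 of 9 dataset(s) (cohorts: healthy)
rags$up_ex
#>   symbol gene_name pattern_score status_score cumulative
#> 1   SPP1                      18           12         30
#> 2   GPX3                      14           12         26
rags$down_nd
#>   symbol gene_name pattern_score status_score cumulative
#> 1   E2F2                       2           12         14
```

SPP1's cumulative 30 (18 up + 12 expressed) and GPX3's 26 are the top two
rows of the published Up-Ex table; E2F2's 14 is the top Down-Nd row. The
scores read directly as support: 12 expressed = at least 6 datasets, 18 up
= at least 9.

Parameter recovery on a simulated corpus (5% of calls flipped):

```r
sim <- simulate_corpus(simulation_params(n_genes = 200, n_datasets = 8,
         frac_true_upex = 0.1, frac_true_downnd = 0.05,
         p_flip = 0.05, seed = 42))
evaluate_recovery(derive_rags(sim$corpus), sim$truth)
#>    class n_true n_pred tp fp fn precision recall        f1
#> 1   upex     20     14 14  0  6         1    0.7 0.8235294
#> 2 downnd     10      7  7  0  3         1    0.7 0.8235294
```

Precision stays at 1 — the zero-contradiction rule never admits a flipped
background gene — while recall drops, because a single contradicting vote
disqualifies a true RAG (survival probability `(1 - p_flip)^(2k)` for a
gene reported in `k` datasets).

## Command line

An executable launcher installs under
`system.file("cli", "ragscore", package = "ragscore")`:

```sh
ragscore simulate --n-genes 500 --n-datasets 12 --p-flip 0.1 --seed 7 \
    --out corpus.json --truth truth.json
ragscore score --corpus corpus.json --comparison receptive_vs_pre_receptive --out scores.tsv
ragscore rags  --corpus corpus.json --min-status 1 --min-pattern 1 \
    --cohorts healthy --out-dir out/
ragscore suboptimal --reference out/up_ex.tsv --case-corpus ivf.json
ragscore qpcr --input ct_table.tsv --calibrator control --out re.tsv
```

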