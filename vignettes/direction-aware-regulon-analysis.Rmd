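---
title: "Direction-aware regulon and gene-set activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direction-aware regulon and gene-set activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regdir)
```

## The problem

Gene-set enrichment over regulons — the sets of genes controlled by one
transcription factor or sigma factor — usually summarizes a regulon by the
plain average fold change of its members. That summary breaks down for the
many bacterial regulators that activate some targets and repress others:
for a dual regulator such as *Bacillus subtilis* Spo0A, whose regulon is
roughly half activated and half repressed genes, the up- and
down-regulated halves cancel and the average says nothing about whether
the regulator itself gained or lost activity. The same problem appears in
a milder form for pure repressors: when a repressor becomes more active
its targets go *down*, so a naive average assigns the regulon a negative
value even though the regulator is activated.

`regdir` makes the regulation mode of every regulator–gene link part of
the statistic, following the approach of spreadsheet-based regulon
analysis tools for bacterial transcriptomes.

## The model

The input is a per-gene differential-expression table (log2 fold change
`x_g` with P-values, the shape of a DESeq2 results export) and a regulon
annotation with one row per regulator–gene link carrying a free-text
qualifier ("activation", "sigma factor", "repression", ...). A
`QualifierMap` collapses qualifiers to a mode `m_g ∈ {up, down}`; sigma
factors are positive regulators, so sigma-factor links map to `up`.
Unmapped qualifiers are a hard error that lists them — no link enters the
analysis with a silently guessed mode.

For each regulator the **signed contribution** of a measured target is

    c_g = x_g   if m_g = up
    c_g = -x_g  if m_g = down

so `c_g > 0` always means "this gene's change is what an *activated*
regulator would produce" and `c_g < 0` supports a repressed regulator.
The regulon splits into the activated-consistent group (`c_g > 0`), the
repressed-consistent group (`c_g < 0`) and an uninformative zero set. The
**majority group** is taken as the most plausible regulation state; on a
size tie the group with the larger mean |contribution| wins (comparing
signed means of oppositely-signed groups would be meaningless), and a
double tie is reported as `ambiguous`. The regulon's statistics are then
computed **on the chosen group only**:

* `score` — mean contribution of the chosen group; positive ⇔ activated,
  negative ⇔ repressed. A repressor whose targets all go down therefore
  gets a *positive* score.
* `mad` — median absolute deviation (no consistency constant) of the
  chosen group's log2 fold changes: a robust "how uniform is the
  response" measure.
* `logical_fraction` — `n_chosen / n_nonzero`, the share of informative
  regulon genes consistent with the called direction. By construction it
  lies in [0.5, 1]; 1.0 means every informative gene agrees.

The directionality-ignorant `raw_score`/`raw_mad` (mean/MAD over all
measured members) are kept alongside for comparison and for the raw-mode
bubble plot.

## Significance

Each regulon receives a gene-label permutation P-value built on the
classic weighted Kolmogorov–Smirnov running sum: walking down a ranked
gene list, set members add `|s|^w / Σ_set |s|^w`, non-members subtract
`1/(N−k)`, and the enrichment score (ES) is the maximum positive
deviation, clipped to [0, 1]. The default weight exponent is `w = 1`.

For the directional test the ranking statistic is `d·c_g` for genes
carrying a mode in the tested regulon and `d·x_g` for all other genes,
where `d` is +1 when the chosen direction is activated and −1 when
repressed; the tested set is the chosen group. This construction puts a
direction-consistent regulon at the top of its own ranking, is invariant
under a global sign flip of the data, and lets inconsistent regulons fall
back into the bulk. Whether the original spreadsheet tool tests the
chosen group or the whole regulon is not documented; the chosen group is
used here because all other chosen-group statistics are defined on it.

The null is `nPerm` uniform random gene sets of the same size
(plus-one estimator `(b+1)/(nPerm+1)`, so p is never 0); with
`exhaustive = TRUE` and `choose(N, k) ≤ 1e5` all sets are enumerated
instead. Each regulon's stream is seeded as `seed + rank of regulator
name`, which makes whole-batch results reproducible and independent of
input row order. P-values are Benjamini–Hochberg adjusted per analysis
batch. Note one consequence of testing a post-hoc chosen group: null
regulons' P-values are not uniform but concentrate at moderate values
(the chosen half of a noise regulon always sits somewhat high in its own
ranking), which makes the test conservative at the small-p end; the
synthetic benchmark below quantifies the resulting false-positive rate.

Two classification schemes support filtering and display: P-value
quantile classes (ascending adjusted P-values split at the 10%, 20%, 33%
and 50% ceiling ranks into classes 1–5) and logical-fraction classes
([0.90, 1] → 1, [0.80, 0.90) → 2, [0.75, 0.80) → 3, [0.67, 0.75) → 4,
[0.50, 0.67) → 5, lower-inclusive; class 5 is hidden by default in the
volcano plot because a third or more of the informative genes then
contradict the call).

## Functional categories, per-gene reports, operons

Where regulon knowledge is sparse, hierarchical functional categories
(main category → subcategory → sub-subcategory) are scored without
directionality: mean and MAD of member fold changes plus the fractions of
up-, down- and unregulated members (strict sign; exactly-zero fold
changes form their own bin so the fractions sum to 1). The hierarchy
level is selectable; genes with shallower paths are kept at full depth by
default. Genes under several paths count in each — that is what the
annotation asserts.

The per-gene report inverts the regulon view: for every measured gene it
lists all regulons the gene belongs to with their signed scores and
logical fractions, ordered by fraction then |score| so the most plausible
regulator comes first. The package deliberately does not pick "the"
responsible regulator — the table gives the evidence and leaves the call
to the user.

The operon screen tabulates member fold changes in transcription order
and flags operons containing a gene pair with opposite-sign fold changes,
both `|log2FC| ≥ 1` and `padj ≤ 0.05` by default. Co-transcribed genes
should move together; a flagged operon suggests an internal promoter or a
mis-annotated operon. The thresholds are exposed because the
underlying spreadsheet practice is a visual screen; the quantitative rule
makes it scriptable, and flagging is monotone in the fold-change
threshold.

## The synthetic benchmark

`generateFixtures()` emulates all four input tables with planted truth:
background genes draw `log2fc ~ N(0, σ)`, a planted activated regulator's
up-mode targets shift by `+δ` and its down-mode targets by `−δ`
(reversed when planted repressed), so every informative target's
contribution is `+δ` or `−δ` before noise. P-values come from the known
Gaussian model (two-sided z-test of `fc/σ`) — the package consumes DE
statistics, it never fits them. The default conditions are `δ = 2`,
`σ = 0.3`, regulon size 20, 1000 genes: a strong, clean two-condition
contrast at desk scale. The roster holds three activated, three repressed
and three null regulators plus one 40-gene mixed regulator ("SpoMix",
half activation-type and half repression-type links) emulating the dual
activator/repressor case; some planted regulators have all-repression
link sets, emulating pure repressors like IolR whose activation appears
as downregulation. One operon is planted discordant, one strongly
concordant, one gene sits in two operons, and a few annotation rows refer
to genes by locus tag to exercise the case-insensitive name/uid fallback
matcher.

What the generator does *not* emulate: count overdispersion and
DE-estimator shrinkage, correlated genes within operons or pathways,
overlapping regulons, and annotation errors. Passing the benchmark
therefore shows the machinery is correct under its own model, not that
real annotations are accurate.

```{r, eval = FALSE}
fx <- generateFixtures(seed = 1)
act <- scoreRegulons(fx$de, fx$regulons, nPerm = 2000, seed = 1)
activities(act)
```

The acceptance script (`scripts/acceptance.R`) reruns this benchmark over
100 replicates at 2000 permutations each (a few minutes on one CPU) and
reports planted-direction recovery, the null false-positive rate, and the
mixed regulon's raw vs directional score — the quantitative form of the
method's central claim that averaging without directionality hides a
mixed regulator's activity.

## Numerical choices and edge cases

* Regulons need ≥ 2 measured genes by default (`minSize`); MAD and
  fractions degenerate at n = 1. Singletons, unmeasured and all-zero
  ("uninformative") regulons are listed in a skip report, and skipped
  regulons still appear as `n/a` entries in the per-gene report.
* Zero contributions support neither direction: they are excluded from
  both groups and from the logical-fraction denominator.
* Ranking ties break by gene name; class boundaries use ceiling ranks;
  fraction-class boundaries are lower-inclusive. All of these are
  arbitrary at the margin but fixed, so runs are deterministic —
  identical inputs, parameters and seed give byte-identical output
  tables.
* The directional MAD uses the chosen group's log2 fold changes (not
  |contributions|); for a single-mode group the two differ only in sign,
  and MAD is sign-invariant. For mixed-mode chosen groups the fold-change
  spread is reported as observed.
* Report tables are UTF-8 TSV with 17-digit doubles, so write + read
  round-trips to < 1e-12.

## Limitations

The permutation null ignores gene–gene correlation (as gene-label
permutation always does), so P-values on real data are optimistic for
co-regulated sets. Multi-regulon genes are counted in every regulon they
belong to; no deconvolution is attempted. The enrichment score reports
the positive deviation only — the directional construction makes the
relevant signal positive by design, and a raw-mode analysis of a
downregulated set should be read through its (negative) score rather
than its ES. Annotation-version drift in regulon tables changes results
and is the user's responsibility to track.
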