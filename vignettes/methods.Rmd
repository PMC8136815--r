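---
title: "Motif RNA maps with post-hoc FDP bounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif RNA maps with post-hoc FDP bounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemaps)
```

## The scientific problem

Splicing factors such as the RBFOX proteins regulate cassette exons in a
position-dependent way: binding downstream of an exon tends to promote
inclusion, binding upstream tends to promote skipping. A standard way to
detect such regulation from a differential-splicing experiment is the
*RNA map*: around every regulated cassette exon, extract fixed-length
sequence regions flanking the splice sites, count occurrences of a motif in
sliding windows, and compare the per-window counts against a set of
*background* exons — exons expressed in the same cells but not affected by
the perturbation. A window where regulated exons carry more motif
occurrences than background exons marks a candidate binding position.

`splicemaps` implements this analysis for rMATS-format event tables and
extends its inference step: instead of summarising the 250 highly
correlated window tests by their minimum raw p-value — a quantity with no
error control, strongly biased towards small values — it computes
*post-hoc* upper bounds on the false discovery proportion (FDP) of every
contiguous window interval, so that enriched intervals can be selected at a
user-chosen FDP threshold after seeing the data.

## Event filtering

Events are read from rMATS-format tables (`read_events()`), with the
replicate inclusion/skipping junction counts and PSI (percent spliced-in)
values kept per replicate. Three rules define the event sets:

* **Significant** (`filter_significant()`): total junction read support of
  at least 15 reads (summed over all replicates of both groups), |dPSI| >
  0.10 and FDR < 0.05. The effect-size and FDR rules are strict
  inequalities, read support is inclusive ("at least"). Read support is
  summed over both groups because the count-based evidence for an event is
  pooled across conditions; the threshold is configurable for analysts who
  prefer a per-condition definition.
* **Background** (`select_background()`): FDR > 0.5, maximum replicate PSI
  > 0.15 and minimum replicate PSI < 0.85 — events that are detectably
  alternative (neither constitutively included nor skipped) yet show no
  evidence of regulation. Events lacking PSI values are skipped with a
  warning rather than imputed.
* **Validation candidates** (`select_validation_candidates()`): more than
  50 reads supporting the event within at least one condition, the
  coverage needed for RT-PCR follow-up.

The dPSI sign convention is control minus perturbed, so `spliced_in`
(dPSI > 0) denotes exons preferentially *skipped after* the perturbation
and `spliced_out` the converse.

## Regions and windows

For each cassette (SE) exon, four 300-nt regions are extracted, each
spanning a splice site with 50 nt of exon and 250 nt of intron (the
conventional RNA-map split; both flanks are configurable through
`region_spec()`): R1/R2 flank the upstream intron, R3/R4 the downstream
intron, all reported in transcript orientation with minus-strand sequences
reverse-complemented. A region whose intron is shorter than the intronic
flank (or whose cassette exon is shorter than the exonic flank, for
R2/R3) is dropped rather than truncated or padded: keeping every region
exactly 300 nt means the window family is identical across events, which
is what makes the per-window tests and the post-hoc family well defined.
How sub-length introns should be handled is genuinely open; dropping per
region is the most conservative choice and is reported per event.

Motifs are degenerate IUPAC patterns (`U` accepted), matched on the sense
strand only, since binding sites live on the pre-mRNA. An `N` in the
scanned sequence matches nothing. Matches are aggregated into 50-nt
windows at step 1, a match belonging to a window when its *start offset*
lies inside it. The family consists of the windows starting at offsets
`0 .. region_length − window_width − 1` — exactly 250 windows for the
300/50 geometry, matching the size of the historical window family this
analysis standardises on. (The alternative `− width + 1` convention would
give 251; the convention is recorded in the run metadata.)

## Per-window testing

Each window is tested with the Wilcoxon rank-sum test, regulated versus
background counts, one-sided (`greater`) by default: the analysis looks
for motif *enrichment* around regulated exons; a two-sided mode is
available. Window counts are small, heavily tied integers, so the default
p-value uses midranks with tie-corrected variance and a 0.5 continuity
correction; for pooled sample sizes up to `exact_max_n` (default 10) and
tie-free data the p-value is computed by exact enumeration of rank
assignments. A pooled sample with zero rank variance returns p = 0.5
one-sided (the statistic sits exactly at its null mean). The minimum-p
summary (`summarize_min_p()`) is retained for comparability, but note that
the minimum of 250 positively correlated tests is small even under the
null — this multiplicity artifact is the motivation for the post-hoc
bounds.

## Post-hoc FDP bounds

For the family of $m$ window p-values of one motif in one region, the
Simes/linear-template post-hoc bound is, for any subset $S$,

$$\bar V(S) \;=\; \min_{1 \le k \le |S|}\Bigl[\,\#\{\,p_i \in S : p_i > \alpha k / m\,\} + k - 1\Bigr],$$

clipped to $[0, |S|]$. With probability at least $1-\alpha$,
simultaneously over *all* subsets, $\bar V(S)$ upper-bounds the number of
false positives in $S$; the FDP bound of $S$ is $\bar V(S)/|S|$. Because
the guarantee is simultaneous, the analyst may look at the whole table of
intervals and only then pick the FDP threshold — the "post hoc" in the
name. Validity relies on the Simes inequality, i.e. on the positive
dependence of the window p-values; overlapping sliding windows of the same
counts are strongly positively correlated, which is the canonical setting
for this assumption.

`interval_bounds()` evaluates the bound for every contiguous window
interval using per-$k$ indicator prefix sums (the complete table of
31 375 intervals at $m = 250$ takes a few milliseconds in compiled code),
and `select_intervals()` keeps the intervals with FDP bound strictly below
the threshold (default 0.25), reduced to maximal intervals so that the
report names the widest well-supported binding region rather than all of
its sub-intervals. The per-motif summary `ph_fdp` is the minimum FDP bound
over all candidate intervals of all regions; ranking motifs by `ph_fdp`
gives the RBP-level screen.

Two defaults deserve comment, both configurable:

* **Confidence level** $\alpha = 0.05$. The level of the simultaneous
  bound is distinct from the FDP threshold (0.25); 0.05 is the
  conventional choice for the former.
* **Multiplicity across families.** Each motif × region family carries its
  own bound at level $\alpha$. A screen over $M$ families (20 motifs × 4
  regions = 80 by default) that claimed each family's guarantee separately
  would select something under the complete null with probability close to
  $1-(1-\alpha)^M \approx 1$. `posthoc_screen()` therefore shares the
  level across the families it inspects by a union bound, evaluating each
  family at $\alpha/M$, so the FDP guarantee holds simultaneously over
  every interval of every motif and region it screened — and hence for
  whatever the analyst selects from its output. Single-family entry points
  (`interval_bounds()`, `simes_posthoc_bound()`) use $\alpha$ undivided.

## Overlap and concordance statistics

Cross-dataset comparisons match events by exact coordinate key
(`match_events()`). The overlap of two significant sets of sizes $n_A$,
$n_B$ from a universe of $N$ events is tested against the upper
hypergeometric tail, with expected overlap $n_A n_B / N$. The universe
size is a *required* argument: printed expected overlaps are meaningless
without knowing $N$, and the right universe (e.g. all events with adequate
read support in both datasets) is analysis-specific, so the package
refuses to guess. Direction concordance classifies common events as
`similar`/`opposite` by the sign of their dPSI values; zero or missing
signs are excluded from both counts and reported separately. The 2×2
proportion comparison (`two_proportion_chisq()`) is the Pearson chi-square
without continuity correction (correction available).

## The synthetic-data generator

`generate_dataset()` emits an rMATS-style SE table, a matching genome (one
contig per event: 150-nt flanking exons, 600-nt introns, 120-nt cassette)
and a complete ground-truth record. Its purpose is to make every pipeline
stage testable without downloads; its defaults describe the standard
validation scenario used throughout the tests: 300 regulated and 1000
background events, `TGCATG` planted in region R2 (proximal upstream
intron) at offsets 0–200 with probability 0.6 in regulated and 0.1 in
background events.

* **Sequences** are i.i.d. uniform nucleotides; motif instances are
  *substituted in place* at the drawn offset (fixed-length sequences keep
  the window family uniform), with degenerate positions resolved uniformly.
  Planted offsets are recorded in region coordinates and are re-scannable
  after region extraction on either strand — the generator maps region to
  genomic coordinates by its own arithmetic, independent of the region
  builder, so this round trip is a genuine cross-check.
* **PSI model**: group means at least 0.2 apart for regulated events
  (|dPSI| drawn uniformly from [0.2, 0.4]), dPSI noise with sd 0.02 for
  background events; replicate PSI ~ Beta around the group mean with
  concentration 50.
* **Depth model**: per-replicate totals ~ negative binomial (mean 80,
  dispersion 0.2), split into inclusion/skipping reads binomially by the
  replicate PSI; reported PSI is the observed inclusion fraction rounded
  to 3 decimals, as rMATS prints it.
* **P-values** come from an actual two-sided rank test on the replicate
  PSIs, and FDR from Benjamini–Hochberg across events, so the table is
  internally consistent. This fabricates the columns of the rMATS count
  model; it does not reproduce that model. The default of **6 replicates
  per group** follows from the discreteness of the exact rank test: with 3
  replicates per group the smallest achievable two-sided p-value is 0.1,
  so no event could ever reach FDR < 0.05 and the significance filter
  would be empty by construction; with 6 the floor is 2/924 ≈ 0.0022,
  which BH turns into q ≈ 0.02 for well-separated events.
* **Determinism**: every event draws from its own substream seeded from
  the dataset seed, so identical seeds give byte-identical output and
  subsets are reproducible.

What the generator does *not* emulate: realistic genome composition
(repeats, GC structure, real motif background frequencies), splice-graph
complexity, read-level noise, or the rMATS likelihood model. Passing the
synthetic recovery and null-control suites therefore demonstrates that the
statistical machinery is correct and calibrated under its own assumptions,
not that any particular biological dataset will behave as cleanly.

## Problem sizes used in the validation suites

The test suite validates null FDP control over 200 synthetic null datasets
(150 regulated / 500 background events, the 20-motif example compendium)
and positional recovery over 50 planted datasets at the default 300/1000
scale; the bound-correctness checks compare against naive per-interval
evaluation at family sizes up to 50, where exhaustive evaluation is cheap.
These sizes give binomial standard errors small enough for 3-sigma
acceptance bands while keeping a full run of the suite in the minutes
range.

## Known limitations

* Regions are built from event coordinates only; no annotation (GTF) input.
* Only SE events get regions and maps; other rMATS types are parsed,
  filtered and usable in overlap/concordance analyses.
* The Simes template assumes positive dependence; permutation-calibrated
  templates are out of scope.
* Motif matching is exact IUPAC matching; no PWM scoring or RNA secondary
  structure.
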