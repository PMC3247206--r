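---
title: "Characterizing a de novo transcriptome assembly with txchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a de novo transcriptome assembly with txchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txchar)
```

## The problem

Early long-read (454-era) transcriptome projects for non-model organisms —
corals being a canonical case — produced hundreds of thousands of single-end
reads that were trimmed, assembled into contigs, and then characterized with
a series of small, largely bespoke procedures: how complete is the
transcriptome, how redundant is the assembly, how many genes does it
represent, where are the SNPs and microsatellites, which genes have
duplicated, and which functional categories are over-represented in
candidate-selection gene sets. txchar implements that characterization
toolchain as a set of composable functions, together with a ground-truthed
simulator so that every stage can be validated end to end without any
external data or database.

## The pipeline and its models

### Read QC

Reads are screened for the SMART CAP cDNA-synthesis primer
(`AAGCAGTGGTATCAACGCAGAGT`) at either end — any occurrence of the primer or
its reverse complement within a substitution tolerance (default 2, no
indels) is removed together with the bases outboard of it — and then
filtered whole: reject if more than `max_n` Ns (default 1), arithmetic-mean
phred quality below 20, or length outside 280–530 bp. Boundaries are strict
as quoted: 280 bp, 530 bp and a mean quality of exactly 20 are kept. Primer
clipping runs first because the length window should judge the insert, not
the insert plus primer. "Average quality" is the arithmetic mean of phred
scores rather than the mean error probability; with whole-read filtering the
two rarely disagree, and the simpler definition is the auditable one.

### Completeness, redundancy and gene count

Homology hit tables (12-column `outfmt 6` dialect) drive four procedures:

* `dedup_reference()` removes >90%-identity copies from a reference set,
  greedy longest-first — a sequence is dropped only when it has an
  above-threshold hit to an already-kept sequence. Identity is local-alignment
  identity as reported in the hit table; the original procedure's metric is
  not stated more precisely than "similarity".
* `best_unique_hits()` builds a one-to-one query↔subject map by descending
  bitscore (ties: ascending e-value, then subject id). This is greedy
  assignment, not optimal bipartite matching, matching common practice for
  "best unique hit" filters.
* `length_ratio_summary()` reports per-pair percent length ratios and the
  modal ratio from a histogram with 2%-wide bins (the binning is our choice;
  the upstream description gives none). A modal ratio slightly above 100%
  indicates full-length transcripts.
* `redundancy_factor()` counts distinct assembled sequences hitting each
  single-copy ortholog above stringent cutoffs (bitscore ≥ 130, e-value ≤
  2e-38), and `gene_count_estimate()` deflates the contig count by that mean
  with floor rounding — floor, because 42,630 / 2.2 = 19,377.27 and the
  published estimate prints 19,377. Orthologs with no passing hit are
  excluded from the mean and reported separately; reference analyses had hits
  to every ortholog, so the distinction never arose there.

`select_informative_annotation()` walks ranked hits (bitscore > 45, e-value
< 1e-5) and takes the first whose description avoids a configurable keyword
list ("uncharacterized protein", "predicted protein"); if none qualifies the
best passing hit is kept flagged uninformative. Note the deliberate
asymmetry in cutoff semantics: the completeness map uses bitscore ≥ 45 and
annotation selection uses bitscore > 45, because the two source procedures
quote the two different forms.

### SNP discovery and the Ts/Tv screen

`call_snps()` scans padded contig alignments column-wise. A column is a
candidate SNP iff its non-gap non-N depth is ≥ `min_depth` and the
second-most-common base has count ≥ `min_minor` and frequency ≥
`min_minor_frac`. The upstream caller's thresholds were never published;
ours default to `min_depth = 4`, `min_minor = 2`, `min_minor_frac = 0.2` —
two-read minor support is the conservative convention of contemporaneous
454 SNP pipelines — and all three are exposed. Gaps and Ns never count
toward depth; indels are not called; columns where a third allele also
passes are emitted as the top-2 pair and flagged. Each column is counted as
one SNP regardless of allele count.

Summaries use reporting-scale rounding: SNP density is `floor(bp / n)` (so
19.8 Mb over 72,605 SNPs prints "1 per 272 bp"), percentages round to
integers, and the global Ts/Tv ratio to one decimal. The selection screen
flags contigs with a defined ratio < 1 (candidate positive selection) or
> 5 (candidate purifying selection); contigs with no transversions have an
undefined ratio and are tallied apart rather than treated as infinite. The
empirical percentile of each threshold is reported so users can compare the
fixed thresholds with nominal 5% tails.

### Microsatellites

`find_repeats()` is a pure tandem-run scanner for 2–6 bp motifs, not a
probabilistic alignment model: perfect runs per period are located, runs of
the same canonical class separated by at most one motif length (and no N)
are merged when purity stays ≥ 90%, motifs that are powers of shorter
motifs are reported at the true period, and overlaps resolve longest-first
(then purest, then leftmost). Minimum copy numbers default to 6/5/4/4/4 for
2/3/4/5/6 bp motifs; the original study used an external repeat finder whose
criteria are not recorded, so these are declared defaults, chosen so that
class-level spectra on planted data are reproduced. `canonicalize()` maps a
motif to the lexicographic minimum over its rotations and the rotations of
its reverse complement — A-first labels (AAC, not GTT) as spectra are
conventionally drawn — and there are exactly 10 such trinucleotide classes.

### Paralog groups

`mutual_best_hits()` finds reciprocal-best-hit ortholog seed pairs from a
symmetric bitscore table (bitscore > 40; asymmetric direction pairs
averaged; ties broken lexicographically so results are deterministic).
`cluster_inparalogs()` is InParanoid-style, not an InParanoid clone: a
sequence joins a seed's group iff it scores at least as high against its
own species' seed as the two seeds score against each other. Confidence is
1 for seeds and `(score(x,a) − S) / (score(a,a) − S)` for members when the
seed's self-score is available; without a self-score the membership rule
alone already implies a capped ratio of 1, so confidence defaults to 1. A
sequence qualifying for several groups goes to the one with the highest
confidence (ties: higher seed score), which makes groups a partition — the
full InParanoid bootstrap and group-merging machinery is deliberately out
of scope.

### Statistics

Fisher's exact test (two-sided by the point-probability rule) with
Benjamini–Hochberg adjustment backs the GO-term enrichment of the Ts/Tv
tails; both raw and adjusted p-values are always reported because published
tables of this kind often leave the correction ambiguous. The selection
test is plain likelihood-ratio arithmetic: `2(lnL_alt − lnL_null)` against
a χ² upper tail. One wrinkle: the conventional formula is sometimes printed
with the sign reversed (null minus alternative) even alongside a positive
statistic; we follow the standard convention, and a genuinely negative
statistic yields p = 1 with a warning rather than an error.

## The synthetic data and what it does (not) show

`sim_config()` defaults are the study conditions of the system this package
emulates: transcripts 1030 ± 623 bp, reads 398 ± 118 bp, SMART-primer
carry-over in 10% of read ends, sparse Ns (0.1%/base), clipped-Gaussian
per-read quality (mean 30, sd 6) with per-base jitter. Fragmentation draws
fragments per transcript from a shifted Poisson `1 + Pois(r − 1)` so the
mean equals the requested redundancy (2.2 by default); only the mean is
constrained by the emulated system. Planted SNPs are transitions with
probability `odds/(1+odds)` (default odds 2.4) and each planted site's read
stack guarantees minor support of `max(2, ceil(0.25·depth))`, so a caller at
default thresholds must see it. Planted repeats are perfect tandem tracts
with broken flanks, so recorded coordinates are exactly the maximal locus.
Hit tables are fabricated from the family structure so that each family's
seed pair is the unique mutual best hit and every member passes the
in-paralog rule — noise-free recovery is exact by construction, which is
the point: it validates the bookkeeping, not the biology.

What the simulator does **not** model, and what passing tests therefore do
not show: 454 homopolymer errors (so SNP recall of 100% on synthetic data
says nothing about false positives from sequencing error), chimeric or
mis-assembled contigs, expression-level variation (the emulated library was
normalized), reverse-strand features (everything is planted forward;
reverse-complement handling is exercised only in motif canonicalization),
and real homology-score distributions. Singletons are treated as depth-1
fragments rather than modelling assembler behaviour.

All generators take a single integer seed and are byte-identical under a
fixed seed. Coordinates are 0-based half-open in every ground-truth record
and BED output; hit tables are 1-based inclusive as their format dictates.

## Problem sizes

The bundled analysis scripts and the test suite run at deliberately modest
scale — 150–1000 transcripts, ~10⁴ planted SNP sites for distributional
checks — chosen so the whole characterization re-runs in about a minute
while keeping binomial/Poisson acceptance bands tight enough to be
meaningful (3-sd bands at n ≈ 10⁴ are about ±1.4 percentage points on the
transition fraction).

## A worked fragment

```{r}
truth <- generate_transcriptome(sim_config(n_transcripts = 50, seed = 7))
planted <- plant_snps(truth$transcripts, density = 1 / 272, tstv_odds = 2.4,
                      seed = 7)
calls <- call_snps_all(planted$alignments)
snp_summary(calls)
```

```{r}
likelihood_ratio_test(lnL_null = -1000, lnL_alt = -994.3, df = 4)
```

## Known limitations

* The QC primer screen tolerates substitutions but not indels; 454's
  dominant error mode is an indel, so a real smartscreener-era pipeline may
  clip slightly more reads.
* The in-paralog confidence fallback without self-scores is uninformative
  (always 1); supply self-hit tables when confidence matters.
* `dedup_reference()` requires a precomputed all-vs-all hit table and will
  not align sequences itself.
* Enrichment works on the flat GO map it is given; there is no true-path
  propagation up the ontology.
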