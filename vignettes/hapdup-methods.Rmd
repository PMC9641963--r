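---
title: "Models and methods behind hapdup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hapdup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hapdup)
```

hapdup implements the downstream, decision-making half of a
haplotype-resolved genome characterization: given the outputs of standard
aligners, depth counters and genotypers, it decides which self-alignments
are segmental duplications, which genes are duplicated or collapsed, how
much sequence the assembly is missing, what the trio's germline mutation
rate is, and how the two haplotypes differ. This vignette explains each
model, its tunable parameters, and the judgment calls made where the
procedure was genuinely open. Nothing here states an empirical result that
the test suite or the acceptance script does not itself compute.

## Segmental-duplication filtering

A duplication pair is one pairwise local self-alignment: two intervals,
an identity (matched bases over aligned columns, gap-compressed identity is
not used) and an aligned length. Two filters remove mobile-element
contamination:

* **Repeat-mask filter.** A pair is dropped when either copy is covered
  more than `masked_threshold` (default 0.90) by the union of the repeat
  track's intervals. Masking is computed against the merged track, not per
  repeat family, because the filter targets total masking.
* **High-copy filter.** Every distinct interval in the pair table becomes
  a graph node (distinct by exact coordinates; overlapping-but-unequal
  intervals are separate nodes joined by overlap edges). Edges connect the
  two intervals of each alignment and any two intervals sharing at least
  1 bp — no minimum-overlap threshold, since any overlap transmits copy
  identity. The number of unique intervals in a connected component is the
  component's copy number, which counts transitive copies the aligner
  missed; pairs in components above `max_copies` (default 20) are dropped.
  Whether near-identical intervals should be merged before counting is an
  open modelling question; exact-coordinate merging is the most literal
  reading and the overlap edges keep the component structure right either
  way.

Identity converts to age linearly: `age = (1 - identity) /
divergence_per_100ky * 1e5` years. The calibration constant is
configuration, defaulting to 0.5% per 100 ky with three generations per
year recorded alongside; a user with a different clock changes
`sd_config(divergence_per_100ky = ...)` rather than the code.

The bundled `naive_self_align()` is desk-scale plumbing, not a production
aligner: exact k-mer anchors (k = 25, occurrence-capped at 40 to survive
mobile elements), diagonal-band clustering, and identity computed by
chaining anchors with pairwise alignment of only the inter-anchor gaps.
It refuses genomes above 10 Mb, where a dedicated self-aligner's table
should be read with `read_sd_pairs()` instead. On planted duplications its
reported identities sit within 0.02 of a full dynamic-programming
alignment (tested against that oracle).

## Copy-number HMM for collapsed duplications

Observed data are per-bin read counts (100-bp bins). Hidden states are
copy numbers 0–`max_state` (default 12). Emissions are negative binomial;
state *c* has mean `(c/2) * mu2` and variance `(c/2) * var2`, scaled from
the copy-two baseline, with two numerical guards: the state-0 mean is
`0.02 * mu2` rather than zero so log-likelihoods stay finite, and each
variance is floored at `1.01 * mean` so the negative-binomial size
parameter stays positive. When the baseline itself is underdispersed
(`var2 <= mu2`, e.g. a constant track) emissions fall back to Poisson.

**Baseline estimation.** The copy-two peak is located as the mode of the
trimmed (1%–99%) unit-bin histogram, lightly smoothed with a ±2 moving
average, ties to the lower count. The mode alone is not reported as `mu2`:
for an overdispersed count distribution the mode sits systematically below
the mean (about 2 counts at mean 60, dispersion 3) and a raw unit-bin mode
jitters by several counts even over 10⁴ bins. `mu2` is therefore the
median of the bins between 0.5× and 1.5× the peak — a window that spans
only the copy-two peak, since the copy-one and copy-three means fall
exactly on its edges. This recovers the true mean within ±2 on simulated
tracks and is unmoved by 30% of bins lying in collapsed regions, which is
the point of using a peak-anchored statistic rather than the global mean.

**Decoding.** Transitions are sticky: stay probability 1 − ε with
ε = 10⁻⁴ split uniformly over the other states, matching 100-bp bins
against multi-kilobase duplications; the initial distribution is uniform.
Decoding is by Viterbi in log space — a maximum-likelihood *path*, so the
reported segments are internally consistent, which posterior decoding
would not guarantee. Segments shorter than `min_segment_bins` (default 5,
i.e. 500 bp) are absorbed into whichever neighbouring state explains their
bins with higher emission likelihood. The implementation is checked
against exhaustive enumeration of all state paths on small instances, and
against planted segments (copies 1, 3, 4, 6; ≥ 50 bins each) where at
least 95% of bins must decode to the true state.

Missing sequence follows from the decoded segments: each assembled copy
stands for `decoded / assembled` true copies, so a segment contributes
`length * (decoded - assembled) / assembled` missing bases, with
`assembled_copies = 2` for a combined diploid track and 1 for a single
haplotype.

The read-depth check of duplicated genes is deliberately permissive: a
gene passes if every annotated copy averages at least half the genome mean
depth (`>=` at the boundary), favouring recall over precision since a
spurious extra copy splits its read support. The mean depth is taken as
given and never rounded internally.

## Trio mutation rate

The module consumes per-site genotype tables — variant calling itself is
out of scope, since the bespoke content is everything downstream of the
caller. The filter cascade uses the standard hard thresholds (site: QD < 2,
FS > 20, MQ < 40, MQRankSum outside [−2, 4], ReadPosRankSum outside
[−3, 3], SOR > 3; individual: DP outside [0.5, 2]× the individual's mean
depth, GQ < 60; candidate screening: parental AD > 0, offspring AB outside
[0.3, 0.7] — the allelic-balance filter applies to the offspring only, and
parents are screened through AD). A missing annotation passes its
sub-filter, with a message; silently failing absent annotations would make
sparse tables uncallable.

A de novo candidate must qualify on **both** mapping targets in its dual
configuration (parents 0/0 + offspring 0/1 where the mutant allele is
absent from the reference; parents 1/1 + offspring 0/1 where it is the
reference) and share read-level evidence across the two call sets. Read
names are abstracted to an integer evidence token carried by both tables;
this preserves the intersection semantics exactly without read-level data.
Candidates are screened by the site filters on both mappings — the
stricter of the two defensible readings.

Callability counts sites passing DP, GQ and parental AD for all three
individuals; site-level and AB filters are deliberately excluded there
because their losses are corrected through the FNR. The FNR is calibrated
on obligate-heterozygous transmissions (0/0 × 1/1 parents force a 0/1
offspring): `fnr = 1 - ab_survival * site_survival`. The multiplicative
combination is a modelling choice — the two filter families act on nearly
disjoint site properties, so independence is the natural first-order
assumption and the source procedure states no formula.

The rate is `(n_maternal + n_paternal) / [(C_m + C_p) * (1 - fnr)]`; the
identity `rate × diploid_callable = total candidates` holds exactly by
construction and is asserted in the tests.

## Heterozygosity spectrum

One simplified classifier replaces the usual three-tool stack
(whole-genome aligner plus separate indel/CNV and SV callers). Alignment
blocks carry CIGAR-like operation strings; variants come from:

* mismatch columns in syntenic forward blocks → SNVs;
* maximal gap runs → indels, small ≤ 50 bp, large > 50 bp (the boundary
  follows the `<= 50` convention);
* reverse-orientation blocks at their expected position → inversions;
* blocks of ≥ 1 kb mapping far from the scaffold's dominant diagonal
  (> 20 kb by default) → translocations, inverted when also reversed. The
  1-kb minimum avoids spurious calls on repeats;
* regions of one haplotype covered by a different number of blocks than
  their counterpart → copy-number variants. Double coverage below 50 bp is
  ignored as block-end abutment.

The desk-scale `align_haplotypes()` produces these blocks from unique
k-mer anchors (k = 31): chains split on orientation changes, non-monotone
partners or diagonal jumps above `max_join` (6 kb); equal-offset anchor
gaps are compared positionally (substitution-only divergence never pays an
alignment); unequal gaps are aligned with affine gap scoring that prefers
one mismatch over an insertion–deletion pair, keeping planted
substitutions as single mismatch columns. Large unanchored insertions that
match their flanking sequence at ≥ 90% identity are re-assigned to
duplicate blocks, which is how copy-number gains become double block
coverage. Insertions whose content sits inside a translocated block's
target are suppressed as the paste-site artifact of the move. Block
boundaries are anchor-limited, so block-level variant sizes (inversions,
translocations, CNVs) are exact only to within about one anchor length;
per-column events (SNVs, indels) are exact, and the conservation tests
assert exactly that split: exact positions/sizes for interior SNVs and
indels, ±80 bp for block-level classes.

The gap filter drops variants whose feature is more than half `N`
(strictly greater, so exactly-half survives); SNVs are never gap-composed
and are never dropped. Deletions and inversions are assessed on haplotype
A's N track, insertions on B's when provided.

Heterozygosity uses the affected-bases convention: the SNV rate is SNV
count per aligned base, and the full-spectrum rate adds the sizes of all
indels and SVs to the numerator. A pure event-count rate cannot reach the
order-of-magnitude gap observed between SNV and full-spectrum rates, so
affected bases is the convention that makes the two figures commensurable;
it is a documented choice, not a claim about the source's unstated
denominator.

Size spectra are binned at 100 bp; a peak is a local maximum exceeding
three times the median occupied bin count of its class. With
transposable-element-sized events planted (300 bp, 500 bp, 4.5 kb), the
corresponding bins are detected as peaks over a uniform background.

## Evidence scoring

Composite scores sum fixed source weights — curated gene–disease databases
3, direct text-mining and GWAS catalogs 2, literature-based discovery 1 —
so a gene supported by everything scores 8. The prediction score for a
term pair is `-log10(p) + n_AB / n_B`; base 10 is a configurable choice
(`score_config(skim_log_base = ...)`), since only "negative logarithmic
value" is specified by the formula's source. Ranking is by descending
score with lexicographic tie-breaks, so output order is reproducible.

## What the synthetic data does and does not show

The generators emulate exactly the features each analysis keys on:
high-identity duplications realized by substitutions only (matching the
identity-fraction semantics of duplication tables), mobile elements of the
characteristic 300 bp / 500 bp / 4.5 kb lengths, depth tracks whose
collapsed regions carry proportionally elevated negative-binomial counts,
trio tables with the dual de novo configuration and obligate-heterozygous
transmissions, and a second haplotype with planted SNVs, indels and SVs.
Base composition is uniform over A/C/G/T because no implemented statistic
depends on composition. Annotation values default to clearly passing
(QD = 20, FS = 1, MQ = 60, rank sums 0, SOR = 1, GQ = 99) with violations
injected explicitly, which makes every filter test constructive.

Real data differ in ways the synthetic data deliberately does not model:
repeat families with internal structure and nested insertions,
GC-dependent and mappability-dependent coverage bias, indel-containing
duplication divergence, genotyping error correlated across the trio,
recombination, and population polymorphism. Passing tests therefore
demonstrate the correctness of the decision logic under its stated model,
not robustness to every artifact of real sequencing. Two known
asymmetries: copy-number gains are only detected as duplications in the
second haplotype relative to the first (a loss appears as a large
deletion), and events within one anchor length (~31 bp) of scaffold ends
or block junctions can be missed by the desk-scale aligner.

## Problem sizes and determinism

Every generator is a pure function of its parameters and an explicit seed;
identical calls are byte-identical. The test suite runs on genomes of
50 kb–1 Mb (10⁴ depth bins, hundreds of planted events), sizes chosen so
the full suite exercises every pipeline end-to-end in about a minute and a
half on one CPU while keeping all statistical checks (law-of-large-numbers
depth means, binomial SNV counts, ≥ 95% recovery criteria) comfortably
powered. Exhaustive-enumeration oracles are run where `states^bins` stays
around 10⁵–10⁶; dynamic programming in the implementation and enumeration
in the oracle never share code.
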