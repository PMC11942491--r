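---
title: "Genotyping and classifying STR expansions from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping and classifying STR expansions from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strcaller)
```

# The problem

Disease-associated short tandem repeats (STRs) are runs of 3–12 bp units
whose expansion causes predominantly neurological disease. A clinically
useful call at such a locus is not one number but several coupled
observations: the repeat-unit count of each allele (reported as a *range*,
because somatic mosaicism makes single-molecule counts vary), the motif
composition of the expanded region (at loci like *RFC1* or *FGF14*,
identical lengths of different units have different pathogenicity), the
presence of interruption runs (which stabilize some loci and shift their
pathogenic thresholds), and CpG methylation over the expansion (which
corroborates *FMR1* full mutations). Long reads spanning the whole repeat
make all of this observable per molecule; `strcaller` turns per-read
sequence into those clinical objects and decides, from short-read evidence
alone, when long-read follow-up is warranted.

# The locus catalog

Each locus carries the printed clinical ranges (normal, mutable normal,
intermediate/uncertain, premutation, reduced penetrance) plus a
full-penetrance threshold, repeat-unit sets partitioned by pathogenicity
(benign / pathogenic / uncertain / interruption), inheritance mode, and
two ≥30 bp flanking anchor sequences. `category_bounds()` normalizes the
printed ranges into a total, gap-free partition of `[0, Inf)`:

* counts inside no printed range — including counts *below* the lowest
  printed range — map to `intermediate_uncertain`. Rationale: a count the
  reference tables do not annotate is by definition unannotated; inventing
  a benign call for, say, a 3-unit *FXN* allele (below the printed normal
  range 5–33) would fabricate evidence. A side effect is that category
  severity is not globally monotone in count at loci whose printed ranges
  leave interior gaps (*RFC1*'s reduced-penetrance range 11–200 against its
  threshold of 400 leaves 201–399 unannotated); the monotonicity property
  tests therefore assert monotone severity across *printed* categories and
  treat gap-filled uncertainty as outside the severity scale.
* printed overlaps resolve by most-severe precedence (*C9ORF72*'s
  intermediate 25–60 vs reduced-penetrance 24–60; *CACNA1A*'s one-count
  ranges), implemented by assigning categories in increasing severity so
  later assignments win.
* a locus may lack a full-penetrance threshold (*ATXN8OS*); severity then
  caps at reduced penetrance with an open-ended range.
* interrupted-range overrides (*ATXN1*'s 36–44 normal-with-interruptions
  and 46-unit interrupted threshold) are stored separately and applied only
  when interruption motifs are actually observed in the decomposition.

The bundled fixture encodes 29 loci. Its flanks are fixed synthetic 30 bp
sequences generated once under a recorded seed and screened so that no
12-mer of any locus motif run occurs inside them (real flanks would make
tests depend on reference data the package does not ship); coordinates are
approximate hg38 positions used only for BED export, and a laboratory
catalog with true flanks can be dropped in via `load_catalog()`.
Inheritance modes and motif sets are standard clinical knowledge not
carried by the range table itself. Coordinates are 0-based half-open;
motifs are stored in reference-strand phase and matched without rotation,
so decompositions reproduce left-to-right annotations deterministically.

# Motif decomposition

`decompose()` segments a repeat-region sequence into maximal motif runs and
interruption stretches by exact dynamic programming over states
`(position, last motif)`, minimizing

```
interruption_penalty × interruption_bases + switch_penalty × motif_changes
```

where a motif unit is consumed only on an exact match and interruption
bases do not reset the current motif (a run resumed after an interruption
pays no switch). Defaults: `interruption_penalty = 1` per base,
`switch_penalty = 2`. The switch penalty must exceed 0 to stop spurious
alternation between overlapping motifs (GAA/GGA), and must stay below
`interruption_penalty × min(motif length)` so that genuine composite
alleles (a GAAGGA-dominant *FGF14* expansion, a CTA→CTG *ATXN8OS*
structure) are parsed as motif runs rather than absorbed as interruptions.
One consequence worth knowing: a *single* interior unit of a different
motif costs two switches (2 × 2 = 4) against its interruption cost
(3 bases × 1 = 3), so isolated one-unit insertions inside a long run are
annotated as interruptions — which is also how a human annotator marks
them. Exact matching is deliberate: a substituted base inside a unit
becomes interruption sequence instead of a fuzzy match, keeping composition
and mosaicism metrics crisp.

Ties are broken deterministically — continue the current motif, else the
lexicographically smallest optimal motif, else an interruption base — so
identical inputs always give identical segmentations. Degenerate inputs:
an empty sequence yields an empty decomposition (not an error); non-ACGT
characters are input errors. The DP cost is verified against brute-force
enumeration of all segmentations on 1,000 random sequences (length ≤ 25,
motif sets of ≤ 2 non-homopolymer motifs) in the test suite.

# Allele calling

`extract_region()` locates each flank anywhere in the read by approximate
matching (Hamming distance up to `max_flank_mismatch_frac` — default 0.2 —
of the flank length, no indels), trying the reverse complement when the
given orientation fails. Reads with both flanks give exact regions;
one-flank and flankless repeat-rich reads (≥ 50% motif content) are kept as
length lower bounds; everything else is discarded.

The per-read repeat count used for genotyping is
`round(region_length / unit_length)` — region length, not the sum of
exactly matched units. Interruptions and sequencing errors thus count
toward length (mirroring clinical annotations such as "total expansion of
N repeats, including M canonical units"), and substitution errors, which
preserve length, do not deflate counts; composition is reported separately
from the decomposition.

`call_alleles()` sorts spanning-read counts and splits them into two
clusters iff the largest adjacent gap exceeds
`max(min_gap_units, min_gap_frac × median)` (defaults 5 units and 0.2).
A gap heuristic, not a mixture model, because spanning reads are few
(tens) and clinically separable alleles are far apart; when the rule
fires, the boundary itself is the exhaustive minimal
within-cluster-variance split, which the tests compare against an
independent oracle. Lower-bound reads attach to the highest allele
compatible with their bound; bounds exceeding every spanning cluster by
more than the gap threshold found a `lower_bound_only` allele whose point
estimate is the *maximum* lower bound (the most informative "≥" the data
support). With no spanning reads at all, the bounds themselves are
clustered and every allele is a bound. A lone cluster at ploidy 2 is
flagged homozygous-or-dropout. Ploidy is a caller argument (1 for
hemizygous males at X-linked loci), taken from sample sex.

# Classification

`classify_allele()` reads the category off the range partition at the
point estimate (at the bound for lower-bound-only alleles, where the
category is a minimum severity), then applies two modifiers:

* **composition gate** (threshold 0.5 pathogenic-unit fraction,
  configurable): at loci where length alone cannot establish pathogenicity,
  an expanded-length allele keeps its length-based category only when at
  least half its units are pathogenic motifs; otherwise it becomes
  `uncertain_composition`. The 0.5 default is this package's choice — the
  clinical literature gives presence/absence statements, not a number — and
  every rationale string records the fraction and the gate used.
* **interrupted-range override** where the catalog defines one; a count
  that is full-penetrance only by the uninterrupted threshold falls back to
  `intermediate_uncertain` when interruptions are present.

`boundary_straddle` marks alleles whose mosaic range (or unresolved bound)
crosses a category boundary — the honest representation of a ">200" allele
at a locus with a 400-unit threshold.

`classify_case()` applies dominant / X-linked logic (most severe allele;
premutation maps to reduced penetrance — FXTAS/FXPOI are
reduced-penetrance phenotypes) and recessive logic (pathogenic only with
two alleles at ≥ reduced penetrance; exactly one is a carrier). Special
rules: *PABPN1* 11/11 homozygotes are pathogenic although a lone 11-unit
allele is not; at methylation-relevant loci a hemizygous full-penetrance
call needs a methylated fraction ≥ 0.2 on the expanded allele (the
figures' presence/absence contrast made quantitative; configurable), else
the case is downgraded to uncertain — including when methylation data are
simply absent, since the corroborating evidence is then missing.

# Methylation

`methylation_summary()` counts a CpG as methylated iff its call
probability ≥ 0.5 (the generator emits 0.95/0.05, so any cutoff in (0.05,
0.95] gives the same answer on synthetic data; real callers motivate the
configurable cutoff). 5mC and 5hmC are not distinguished — joint
modified-cytosine calls are summarized as modified. Calls within 100 bp of
the repeat region are retained (configurable window).
`associate_methylation_with_interruptions()` splits reads by the presence
of an interruption-motif run of ≥ 5 units and raises a flag when group
mean fractions differ by ≥ 0.5 — the pattern where methylation sits only
on non-interrupted expanded reads.

# Short-read tier and triage

The short-read estimator classifies 150 bp reads by content (spanning /
flanking / in-repeat), takes exact counts from spanning reads, and
estimates remaining alleles from the in-repeat base mass divided by the
per-haplotype flank depth and unit length. When spanning reads exist but
no in-repeat mass does, the sample is called exact-homozygous rather than
given a zero statistical estimate. Statistical estimates carry a
reliability ceiling of `floor(135 / unit_length)` units; values beyond it
are flagged unreliable but *not* truncated, because the triage rules need
the raw signal. Loci whose normal range is not annotated in the catalog
(*FGF14*, *RFC1*) use an effective normal maximum of 0: any expansion
signal there escalates, which matches how such loci are actually handled.

`triage()` requires long-read follow-up when any of five rules fires: R1 —
an estimate reaches 135 bp (the conservative end of the 135–140 bp window
where 150 bp reads stop sizing reliably; false negatives are costlier than
extra long-read runs); R2 — a statistical estimate above normal at a locus
whose reporting threshold exceeds the read length; R3 — composition
ambiguity with an above-normal estimate; R4 — a recessive locus with both
estimates above normal; R5 — a methylation-relevant locus at or above the
premutation range. All rules are monotone in the estimates, verified by
exhaustive sweeps.

# What the simulators emulate — and what they do not

`simulate_reads()` emulates: segmented allele structure (e.g. 12 CTA + 84
CTG; AAGGG-dominant expansions; GAAGGA-dominant alleles), per-read length
mosaicism as uniform jitter on the largest segment (mosaicism concentrates
in the expanded run; compositional mosaicism is modeled by mixing allele
specs), lognormal long-read lengths (default median 8 kb — a typical
nanopore ligation prep), uniform read placement over a padded molecule so
reads truncate inside long repeats and become one-sided bounds, iid
per-base substitution/insertion/deletion errors, random read orientation,
and crisp per-CpG methylation states (probability 0.95/0.05). Jitter
defaults are chosen to reproduce the width of reported mosaic ranges, not
fitted to data.

It does **not** emulate: basecaller error structure (homopolymer bias,
error bursts), mappability and alignment artifacts, PCR or flow-cell
chemistry effects, diploid phasing noise, or real flanking sequence
context. Passing tests therefore demonstrate algorithmic correctness under
a clean generative model — recovery of planted truth, monotonicity,
determinism — not clinical performance on patient data, which requires
validation against orthogonal assays.

# Problem sizes and numerical choices

The test suite runs at desk scale, chosen to exercise every code path
while keeping a full run around a minute: 1,000-case decomposition oracle
(length ≤ 25), 2 × 50 seeded genotyping simulations at coverage 20 per
allele with 1% substitution error (recovery within ±3 units required in
≥ 95% of runs, a tolerance that follows from length-based counting under
substitution-only errors), exhaustive 0–2000-unit classification and
triage sweeps over all 29 loci. Percentages in cohort tables round half
away from zero to one decimal (the convention of the reference tables,
which base R's round-half-to-even would violate at e.g. 83.95). Floating
DP costs compare with a 1e-9 tolerance; all penalties are effectively
integers, so ties are exact.

# Known limitations

* Exact-match decomposition attributes every sequencing error to
  interruption sequence; at high error rates (>5%) composition fractions
  drift toward interruptions even though length-based counts stay stable.
* The gap-rule clusterer can merge genuinely distinct alleles closer than
  `min_gap_units` when mosaicism is wide; the homozygous-or-dropout flag is
  the guard, not a fix.
* The short-read statistical estimator is a transparent stand-in for
  production short-read STR callers; its absolute estimates are only used
  by the triage rules, which are robust to its scale.
* BAM ingestion (including MM/ML methylation tags) is not implemented;
  inputs are FASTA/character reads plus a methylation sidecar table.
* The catalog's flanks are synthetic; genotyping real reads requires a
  catalog built with true genomic flanks.
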