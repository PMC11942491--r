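# strcaller

Short tandem repeat (STR) expansions cause more than fifty neurological
disorders — Huntington disease, Friedreich's ataxia, fragile-X-associated
syndromes, CANVAS and many spinocerebellar ataxias. Their clinical
interpretation needs more than a repeat length: the *composition* of the
expanded region (benign AAAAG vs pathogenic AAGGG units in *RFC1*,
GAA vs GAAGGA in *FGF14*), somatic length mosaicism across cells,
interruption runs that stabilize an allele (*ATXN1*, *FMR1*), CpG
methylation over the expansion (*FMR1*), and — for recessive loci such as
*FXN* and *RFC1* — the exact length of *both* alleles. Standard 150 bp
short-read sequencing cannot size alleles beyond ~135–140 bp and cannot see
composition; long reads can, but are too costly to run on every sample.

`strcaller` implements, as a tested R package, the analysis layer of a
two-tier diagnostic workflow for laboratories and methodologists working
with long-read STR data:

* **Repeat catalog** — 29 disease loci with normal / mutable-normal /
  intermediate / premutation / reduced-penetrance / full-penetrance
  repeat-count ranges, repeat units, interruption motifs and inheritance
  modes, shipped as an editable JSON fixture
  (`inst/extdata/repeat_catalog.json`) with BED/TSV export.
* **Motif decomposition** — an exact dynamic program segmenting a repeat
  region into maximal motif runs and interruption stretches, minimizing
  `interruption_penalty × interruption_bases + switch_penalty × motif_changes`
  (compiled core, deterministic tie-breaks), with a one-line text rendering
  (`CTA×12 | CTG×84`).
* **Allele calling** — flank-anchored region extraction (Hamming-tolerant
  anchors, both orientations), per-read repeat counts, gap-rule clustering
  into 1–2 alleles reported as *mosaic count ranges*, lower bounds ("≥")
  from non-spanning reads, per-allele composition and methylation.
* **Clinical classification** — per-allele categories from the catalog
  ranges with a pathogenic-unit composition gate and interrupted-range
  overrides; case-level significance under dominant / recessive / X-linked
  logic, with methylation corroboration for *FMR1* males and the *PABPN1*
  homozygosity rule.
* **Two-tier triage** — a short-read statistical length estimator and five
  escalation rules (R1–R5) deciding when a sample needs long-read
  follow-up, anchored on the 135 bp sizing limit of 150 bp reads.
* **Simulators** — long- and short-read generators with segmented allele
  structure, per-read mosaicism, substitution/indel errors and per-CpG
  methylation states (plus truth tables), and a cohort-table generator.
* **Cohort reporting** — reportable-case accounting by variant type and
  sequencing tier, and per-locus tier counts.

## Worked example

Simulate a biallelic *FXN* GAA expansion (100 and 700 units, with somatic
jitter and 1% substitution error), genotype it, and classify the case:

```r
library(strcaller)
catalog <- default_catalog()
fxn <- catalog$FXN

spec <- sample_spec("FXN",
  alleles = list(allele_spec("GAA", 100, jitter = 6),
                 allele_spec("GAA", 700, jitter = 120)),
  coverage = 20, error_rates = c(sub = 0.01), seed = 42)
sim <- simulate_reads(spec)

gt <- genotype_sample(sim$reads, fxn, ploidy = 2)
gt
#> <str_genotype> FXN  ploidy 2  (25 spanning, 15 bounded reads)
#>   allele 94-106  point 100  (19 reads)  composition: GAA 1.00
#>   allele 580-812  point 699.5  (21 reads)  composition: GAA 1.00

classify_case(gt, fxn)
#> <str_classification> FXN: PATHOGENIC
#>   full_penetrance
#>     100 units -> full_penetrance by length
#>   full_penetrance
#>     699.5 units -> full_penetrance by length
```

The two alleles come back as mosaic ranges (94–106 and 580–812 repeat
units) whose widths reflect the simulated jitter; both point estimates sit
at/above the 66-unit full-penetrance threshold of this recessive locus, so
the case is pathogenic. A complex *ATXN8OS*-style region decomposes into
its segment structure:

```r
render_decomposition(decompose(paste0(strrep("CTA", 12), strrep("CTG", 84)),
                               c("CTA", "CTG")))
#> [1] "CTA×12 | CTG×84"
```

and the triage rule flags an *HTT* short-read estimate of 47 units
(141 bp ≥ 135 bp) for long-read confirmation:

```r
triage(short_read_estimate(catalog$HTT, c(47, 18)), catalog$HTT)
#> <triage_decision> HTT: long-read follow-up REQUIRED
#>   R1: allele of 47 units = 141 bp >= 135 bp exceeds reliable short-read sizing
```

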