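---
title: "Mapping a dominant restorer-of-fertility locus with rfmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant restorer-of-fertility locus with rfmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfmap)
```

## The problem

Cytoplasmic male sterility (CMS) is the workhorse of hybrid seed
production in pepper and many other crops: a CMS line sets no viable
pollen, so crossing it to a pollen parent yields pure hybrid seed without
hand emasculation. Whether the hybrid itself is fertile depends on a
nuclear *restorer-of-fertility* (*Rf*) gene contributed by the pollen
parent. `rfmap` implements the statistical and sequence-analysis steps of
a classical forward-genetics campaign to localize such a locus: an F2
population is raised from a CMS line crossed to its restorer, fertility is
scored, and the dominant *Rf* locus is mapped with molecular markers using
only the sterile (homozygous recessive) F2 class.

The package covers six analysis stages — segregation testing, in-silico
bulked segregant analysis (BSA), recessive-class linkage mapping, interval
localization with candidate-gene concordance, qRT-PCR relative expression,
and InDel marker discovery — plus a synthetic-data module that simulates
every input the stages consume.

## Segregation testing

A single dominant restorer predicts a 3:1 fertile:sterile ratio in the
F2. `chi_square_gof()` tests observed counts against any two-class ratio
with a 1-df chi-square,

$$\chi^2 = \sum_{i} \frac{(|O_i - E_i| - \tfrac12)^2}{E_i},$$

applying the Yates continuity correction by default (`correct = FALSE`
gives the plain Pearson statistic). Two numerical choices matter:

* Expected counts always come from the component sum
  `n_fertile + n_sterile`, never from a separately tabulated total, so a
  transcription error in a published total cannot distort the test.
* The corrected deviation $|O-E| - 0.5$ is deliberately **not** clamped at
  zero. With $|O-E| < 0.5$ the statistic stays a tiny positive number and
  the p-value lands near 0.95 instead of exactly 1; this matches how the
  corrected statistic is conventionally reported for near-perfect fits.

The correction makes the test conservative at small family sizes; on
simulated true-3:1 families of 100 plants the type-I error at
$\alpha = 0.05$ sits near 0.03 (the test suite checks it stays within
[0.01, 0.07]).

```{r segregation}
rep <- segregation_report(load_fixture("table2_families"))
rep[rep$family %in% c("P20210", "P20217", "Total"), ]
```

## Bulked segregant analysis

`compose_bulks()` models the pooled-PCR readout of BSA: the observable
for a bulk at a marker is the **set** of parental alleles present among
its members (band presence/absence on a silver-stained gel), not allele
dosage. One member carrying an allele is assumed sufficient to produce a
band — the most permissive reading of gel sensitivity, which makes the
screen conservative: a marker is flagged only when the two bulk patterns
differ as sets, and near the trait locus the sterile bulk is expected to
lack the restorer-parent band entirely. With bulks of 10 sterile plants
the probability that a marker at recombination fraction $r$ still lacks
the restorer band is $(1-r)^{20}$, which decays quickly; this is what
concentrates flagged markers around the locus.

Bulk membership is drawn with a caller-supplied seed; there is no hidden
RNG state anywhere in the package.

## Recessive-class linkage mapping

Every sterile F2 plant is homozygous for the CMS allele at the trait
locus, so at a linked marker each restorer-parent allele it carries marks
one recombinant chromosome. With $N_1$ sterile plants scored homozygous
for the restorer allele (HO), $N_2$ heterozygous (HE), and $N$ scored in
total, the recombination fraction is

$$c = \frac{N_1 + N_2/2}{N},$$

and the genetic distance is Kosambi's map function

$$d = \frac{1}{4}\,\ln\!\frac{1 + 2c}{1 - 2c}\ \text{Morgans},$$

reported in centimorgans (×100). The logarithm is the natural log: this
is the form that reproduces standard published distances, and the
small-distance limit $d \approx 100c$ cM holds as it must. 'A' calls in
sterile plants are non-recombinant by construction of the design and are
never counted; missing calls leave the denominator. Markers with
$c \ge 0.5$ are flagged unlinked and receive no distance.

`locate_interval()` places the locus inside the block of co-segregating
(zero-recombinant) markers and reports the nearest recombinant marker on
each physical side. Two deliberate conventions:

* The interval span is `end − start` with no +1 — the distance between
  the two flanking marker coordinates, matching how physical intervals
  between markers are conventionally quoted.
* A recombinant marker lying physically *inside* the co-segregating block
  can occur in real data (a genotyping inconsistency or a local
  mis-assembly); it is tolerated with a warning and does not shrink the
  interval, because the flanks are anchored on the outermost zero-c
  markers. If no marker co-segregates, the minimum-c block is used with a
  warning; if the zero-c block touches the panel edge the interval is
  open and an error names the side.

```{r linkage}
map <- map_from_tallies(load_fixture("table3_fine"))
head(map[, c("marker", "pos_bp", "n_he", "c", "d_cm", "side")], 8)
suppressWarnings(locate_interval(map))
```

Where several markers tie at $c = 0$ all are reported as co-segregating;
physical position is the only ordering used. For markers with equal $c$
on the same side no further ordering is attempted.

## Candidate genes: variant effects and concordance

`classify_variant()` translates the affected codon before and after a
substitution under the standard nuclear code and labels it SYNONYMOUS,
MISSENSE, STOP_GAIN, or STOP_LOSS. For a stop-loss the supplied sequence
may extend past the annotated stop; `extension_aa` counts the codons
translated after the mutated codon up to (and excluding) the next
in-frame stop, with an `unbounded_extension` flag when none exists in the
supplied sequence.

`concordance_score()` measures how well variants track the trait across
a panel of inbred maintainer and restorer lines. A maintainer is
concordant when it matches the CMS-line reference haplotype at **every**
scored site of the gene; a restorer when it matches the restorer-line
reference everywhere. This full-haplotype rule is intentionally strict —
a line matching at one site but not another is discordant — and only
non-synonymous sites are scored by default (synonymous variants carry no
functional signal for this purpose; a stop-loss site is non-synonymous
and eligible). The two reference lines define the haplotypes and are
excluded from the denominator. `caps_accuracy()` is the same scoring
restricted to a single site, modelling what a CAPS assay reading one
polymorphism can achieve. Per-line verdicts are always returned so that
any discrepancy between a summary percentage and a verbal description of
which lines matched is visible in the output rather than hidden.

```{r concordance}
vm <- load_fixture("table5_matrix")
concordance_score(vm, "Capana06g002968")
caps_accuracy(vm, "Capana06g002969", 318)
```

## Relative expression

`relative_expression()` implements $2^{-\Delta\Delta C_t}$:
$\Delta C_t$ is the replicate-mean target $C_t$ minus the replicate-mean
reference-gene $C_t$ per (group, stage) block, $\Delta\Delta C_t$
subtracts the calibrator block, and the calibrator's fold change is 1 by
construction. The calibrator is a required argument, not a default. A
block whose target gene yields no $C_t$ is reported ND (`NA`), never as
zero expression. No amplification-efficiency correction is applied
(standard-curve methods are out of scope), so fold changes assume
doubling per cycle.

The group comparison is a two-sided Welch (unequal-variance) t-test on
per-replicate $\Delta C_t$ values with the usual `ns` / `*` (p < 0.05) /
`**` (p < 0.01) tiers. The choice of test is an assumption of this
package — three biological replicates per group is the design it
expects — and identical constant groups are defined to give p = 1 rather
than an error.

## InDel discovery

`align_pair()` computes a minimal edit script between two sequences under
a unit insertion/deletion cost model (Myers' shortest-edit-script search
in compiled code, with common prefix/suffix stripping; a mismatch costs a
deletion plus an insertion and is rendered as a substitution op). The
`max_d` guard (default 10,000 edits) bounds memory, which grows with the
square of the edit count; the module is intended for desk-scale windows
of mostly-similar sequence — the scale at which InDel marker screens
select a few Mb around a mapped locus — not for whole-genome alignment.

A shortest edit script over random sequence can legally split one
biological indel across several gap runs separated by chance 1–3 bp
matches. `call_indels()` therefore re-describes each variant cluster —
the script segments between exact-match anchors of ≥ 20 bp — by trimming
the common prefix and suffix of the cluster's reference and alternate
substrings. A cluster whose trimmed remainder is one-sided becomes a
single insertion or deletion; a replacement yields a co-located
deletion-plus-insertion pair. Calls are 1-based, anchored on the last
reference base before the event, left-aligned through repeated context
(so a repeat-unit deletion is always reported at the run start), and
filtered at `min_len` (default 5 bp, the usual threshold for
gel-resolvable length polymorphisms). `design_candidates()` then extracts
500 bp flanks from the reference for external primer design, skipping
calls too close to a sequence end, and names candidates
`P<chrom>gInDel-<ordinal>`. Whether the length threshold applies per
contiguous gap or per clustered variant region is ambiguous in general;
here it applies per call after cluster normalization.

## The synthetic-data module

`simulate_f2()` generates gametes under the no-interference
(Haldane/Poisson) model: the crossover count per gamete is Poisson with
mean equal to the map length in Morgans, crossover points fall uniformly
on the genetic map, and the phenotype follows single-gene dominance.
Distances are *estimated* in Kosambi units while the simulator is
Haldane — the same mismatch inherent in the field's standard workflow, so
recovery tests use standard-error tolerances rather than exact equality.
Defaults mirror the study design the package reproduces: F2 sizes of a
few hundred to ~1700 plants, fine mapping on ~336 sterile plants, bulks
of 10. The genetic-to-physical rate of simulated maps is configurable
(there is no authoritative cM/Mb value for the mapped region; examples
use 1 cM/Mb).

What the simulator deliberately does not model: crossover interference,
segregation distortion, phenotyping error, missing genotype calls (the
readers accept them; the generator does not produce them), PCR/band
artefacts in BSA, and amplification-efficiency variation in qPCR. Passing
recovery tests therefore demonstrate correctness of the estimators under
the design's own assumptions, not robustness to those real-data
complications.

`simulate_variant_matrix()` flips each line's allele to the opposite
reference with a configurable discordance rate; `simulate_ct_table()`
plants $\Delta\Delta C_t$ effects under Gaussian noise;
`plant_indels()` builds a sequence pair with spaced, left-aligned truth
events. All simulators are bit-reproducible under their seed argument.

Transcriptions of the published family counts, recombinant tallies,
interval gene annotation, and line-by-site allele matrix ship as
tab-separated fixtures under `inst/extdata/` and load through
`load_fixture()`. One published family row prints a total (97) that
disagrees with its fertile + sterile components (87); the fixture keeps
the printed value, flags the row, and all computations use the component
sum.

## Problem sizes used by the test suite

The statistical tests run at the sizes the analysis itself uses: 500
replicates for estimator-recovery checks at $r \in \{0.01, 0.05, 0.1\}$,
200 simulated fine-mapping runs at ~336 sterile plants for interval
coverage, 2000 replicates for type-I-error and nominal-level checks, and
a 100 kb pair with 50 planted indels for caller recall. The whole suite
completes in well under a minute on a single core.

## Command line

`rfmap_main()` (installed as `exec/rfmap`) exposes the stages as
subcommands — `segregation`, `bsa`, `map`, `finemap`, `concordance`,
`caps`, `ddct`, `indel-design`, `simulate`, `fixtures` — reading and
writing tab-separated files, with every threshold defaulting to the
analysis' standard values (3:1 ratio, Yates correction on, α = 0.05,
bulk size 10, min InDel length 5 bp, flank 500 bp). Display rounding is
2 decimals throughout, with unrounded machine columns alongside.

## Limitations

* Single biallelic locus, two-class phenotype; no multipoint likelihoods,
  no dominant-marker EM, no QTL interval mapping.
* Marker order is taken from physical positions as given; no ordering
  optimization.
* The aligner is for desk-scale windows; use a genome aligner for
  chromosome-scale comparisons and feed its variants in.
* Concordance scoring assumes inbred (homozygous) panel lines; an allele
  matching neither reference haplotype is counted discordant with a
  warning.
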