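---
title: "Duplex-sequencing mutation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex-sequencing mutation analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmut)
```

`duplexmut` analyses consensus-level variant calls from targeted duplex
sequencing (DS) of paired somatic and germline samples — the motivating
design is six young men with matched blood and sperm, sequenced over a
48 kb panel of twenty 2.4 kb loci to roughly 1.2–1.3 billion informative
duplex bases per sample. This vignette explains the statistical models the
package implements, the parameters that matter and their defaults, what the
synthetic-cohort generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The data model

A **variant call** is one consensus-level record: sample, contig, 1-based
position (for indels and SVs, the anchor base before the inserted/deleted
sequence, as in VCF), ref/alt alleles, a fine-grained type (SNV, MNV,
insertion, deletion, inversion, complex), the number of distinct duplex
molecules supporting the alternate allele (`alt_count`), and the duplex
depth at the site. The variant allele frequency `vaf = alt_count /
site_depth` is computed once at the IO boundary and never recomputed
downstream, so every filter sees the same number. Broad classes for burden
reporting are SNV, MNV, indel (net allele-length change of at most
1000 bp), and SV (larger changes plus all inversions); for complex variants
the *net* change in allele length defines both the indel length and the
insertion/deletion identity.

Panels are BED (0-based half-open) plus FASTA; all coordinate conversion
happens in `read_panel_bed()`/`write_panel()` and nowhere else. Depth
profiles are per-position duplex depths; because panel sequence is pure
ACGT, the depth at reference C/G positions and at T/A positions always sum
to the total duplex bases, and this invariant is enforced by construction
in `depth_totals()`.

## The filtering ladder

`run_filter_ladder()` applies five stages in a fixed order:

1. **Clonal collapse.** Identical mutations in more than one molecule of a
   sample derive from clonal expansion and are counted once; molecule
   counts are summed. Clonality statistics (the fraction of unique
   mutations supported by one molecule) are reported for the final retained
   set, so contaminant or artifact calls cannot dilute them.
2. **SNVs over clonal MNVs.** A no-call at one position of a clonal or
   germline MNV (VAF at or above 1%, assessed after collapse, since
   clonality is a molecule-count property) can masquerade as a partial SNV;
   SNVs inside such spans are removed.
3. **SNVs near indel boundaries.** SNV clusters near indels are
   realignment artifacts. Boundaries are the two reference coordinates
   `{pos, pos + |net length|}` for deletions and `{pos, pos + 1}` for
   insertions; "within 10 bp" is inclusive. Neither convention is forced by
   the data model — endpoints anchored on the VCF-style coordinates are the
   conventional reading, and the inclusive window is the stricter one.
4. **Intra-cohort contamination.** A call with VAF strictly below 1% whose
   identical variant sits at a likely germline frequency (VAF strictly
   above 30%) in at least one other sample is removed; the germline copy is
   untouched.
5. **VAF gate.** Only calls with VAF ≤ 1% (inclusive) enter mutation
   analysis; 2% and 5% are provided as alternatives.

Two ordering decisions deserve explanation. Contamination matching must run
*before* the VAF gate, because the rule references germline-frequency
copies that the gate would have discarded; with the opposite order the
filter could never fire. And the ladder attributes every removed call to
exactly one (the first triggering) stage, so the report satisfies
`input = retained + sum(removals)` — a property the test suite checks on
every generated cohort. The eccDNA analysis consumes the *pre-gate* set,
since no VAF filter applies to large insertions there.

An alternative `shared_mutation_mode` (removing variants present in both
tissues of one individual) is available but off by default; it requires
tissue and individual annotations and is reported separately.

## Burden statistics

The mutation frequency of a class is `MF = m / B` for `m` unique retained
mutations over `B` duplex bases. Two tissue-level summaries differ in
general and are both reported, labelled: the *pooled* MF (summed counts
over summed bases, the natural "total" row) and the *mean of per-sample
MFs* (with SD). Display rounding is two significant figures in scientific
notation (`1.0E-07`), matching how such tables are conventionally printed;
`format_mf()` implements exactly that rounding, and the golden tests
require all per-participant and pooled cells of the shipped reference count
table to reproduce at that precision.

Substitution subtypes are pyrimidine-collapsed (a G>A at a G reference is a
C>T on the other strand) and normalized by the depth at the relevant
reference bases: C-class rates divide by the C/G depth, T-class rates by
the T/A depth. The CpG fraction of C>T mutations uses the NCG trinucleotide
context — reference C followed by G, or G preceded by C. Locus-specific MFs
use strictly in-locus depth; the fold-range (max/min) excludes loci with
zero counts or zero depth, a convention the output flags explicitly.

## Spectrum comparison

Two mutant spectra are compared with the likelihood-ratio statistic for
multinomial homogeneity: with observed counts stacked into a 2×k table and
expectations from the margins,

$$G = 2 \sum_{\text{groups}} \sum_{\text{classes}} O \ln(O/E),$$

referred to a chi-square distribution with k − 1 degrees of freedom. Zero
cells contribute nothing. This equals twice the difference between the
maximized multinomial log-likelihoods under separate versus pooled
proportions, and the test suite checks that identity against a direct
likelihood oracle. Because germline comparisons can involve small counts
(tens of mutations in six classes), a Monte Carlo p-value — multinomial
resampling under the pooled proportions — is available alongside the
asymptotic one; under a null with n = 200 per group the two agree within
0.02 and the asymptotic test's type-I error at α = 0.05 is calibrated
within 0.05 ± 0.01 (measured at 10⁴ replicates).

SBS96 spectra use the flanking bases from the panel sequence, with
purine-reference mutations reverse-complemented into pyrimidine classes
with complemented context, and rows ordered alphabetically on the full
`A[C>A]A`-style label — the ordering used by published signature matrices,
so cosine similarities against signature TSVs are a direct dot product.

## The microDNA caller

Apparent large insertions whose inserted allele (call it `ABCD`) is a copy
of the reference immediately downstream carry a junction joining the end
(`D`) to the beginning (`A`) of the allele — a D-A junction. Such junctions
arise from two mechanisms with identical junction sequence but different
physical support:

* **excision and circularization** of `ABCD`: every sequencing fragment is
  a piece of the circle, so fragment length can never exceed the allele
  length and no fragment contains duplicated or flanking sequence;
* **chromosomal tandem duplication (TD)**: fragments follow the library
  insert-size distribution independent of allele length, and any fragment
  longer than the allele necessarily contains duplicated `ABCD` and
  possibly flanking sequence.

Detection searches the inserted allele against the call's own contig with
`Biostrings::matchPattern()`, allowing `floor(L/50)` mismatches (the "1 per
50 bp" allowance; floor is the stricter reading of an ambiguous rule, and
the rate is configurable). A call is junction-positive only when a match
starts exactly 1 bp downstream of the anchor position — under the
anchor-base convention this is the unique placement making the allele a
downstream copy. A brute-force sliding-window Hamming scan serves as the
independent oracle in tests.

Fragment lengths are inferred from read-pair geometry. Concordant pairs:
insert size plus any 5' soft-clipped bases. Discordant split pairs: a
pseudo-pair is formed from the primary alignment of one read and the
supplementary alignment of the other, and the length is the distance from
the forward member's left-most start to the reverse member's right-most end
(inclusive) plus both members' 5' clips, which align at the other end of
the allele. 3' soft-clips are adapter read-through — only possible on
fragments shorter than ~142 bp — and are ignored. The exact placement of
clipped bases across primary and supplementary records is a convention this
package fixes (and its generator emits), since read-level alignment detail
is otherwise outside the data model; the round-trip test requires the
inference to recover every generated fragment length exactly.

Classification: one fragment containing duplicated/flanking sequence
(fragment longer than allele) suffices to call a TD — a single informative
geometry is decisive evidence, and requiring more would only add false
negatives; all fragments at or below the allele length with none flagged is
circle-consistent; junction-positive calls with no usable fragment are
ambiguous. The boundary case (fragment exactly equal to the allele) stays
circle-consistent, since a circle can be cut once.

The cohort-level test considers junction events with allele length at or
below the median library insert (233 bp by default; supply whole-library
insert sizes to compute it — junction-supporting pairs alone are a biased
sample and are never used for this). Under the all-TD null about half of
these events should be supported by fragments longer than the median; the
package counts events (one representative, the longest and hence most
TD-informative fragment per event) and reports the exact one-sided tail
`P(X ≥ k | n, 1/2)`. Candidate microDNAs are junction-positive events with
allele length strictly greater than 125 bp; no VAF filter applies, though a
VAF-gated count is reported alongside for consistency with burden tables.

## The synthetic-cohort generator

`simulate_cohort()`/`simulate_study()` generate variant tables, depth
profiles, junction-read geometries, and a complete truth table in which
every emitted variant row carries exactly one label. The defaults *are* the
study conditions the package targets:

| parameter | blood | sperm | note |
|---|---|---|---|
| samples | 6 | 6 | |
| duplex bases/sample | 1.25e9 | 1.25e9 | ~26,000x over 48 kb |
| SNV MF | 1.2e-7 | 2.5e-8 | per duplex base |
| MNV MF | 1.3e-9 | 4.0e-10 | |
| ordinary indel MF | 7.6e-9 | 3.3e-8 | see below |
| SV MF | 3.8e-10 | 9.1e-9 | |
| SV composition | all inversions | 5:40:23 del:dup:inv | |
| SBS6 weights | 14/7/53/7/12/7 | 7/7/46/7/26/7 | % C>A..T>G |
| C>T at CpG | 35% | 36% | |
| circles/sample | 0 | Poisson(51) | lengths 180/370/560 ± 25 bp (0.5/0.3/0.2) |
| TDs/sample | 0 | 1 | allele 60–100 bp |
| junction-negative large insertions | 1 | 2 | 21–125 bp, random sequence |
| median insert | 233 bp | 233 bp | |
| contaminant pairs | 5 | 21 (16 in sample 1) | cohort-wide |
| clonal fraction | 4% SNV, 30% other | same | k in 2–5 |
| germline heterozygosity | 1e-3/bp | 1e-3/bp | VAF ~ Binomial(depth, 0.5) |

Notes on the less obvious rows. The sperm *ordinary* indel rate is the
published total indel burden minus the junction events: circles are emitted
as large insertions and, being mostly sub-kilobase, land in the indel class
of burden tables, so the two knobs together reproduce a sperm-like indel
MF near 7.2e-8. The circle length mixture at 180/370/560 bp encodes the
reported multimodality of small-circle sizes at nucleosome-scale spacing;
the modes' exact values are a package choice, as the periodicity is
described but not parameterized in the literature. Circle molecule counts
are ~70% single, with 6% of circles placed above the 1% VAF gate, which
reproduces both the ~70% single-count fraction of non-SNV mutations and the
small gap between ungated (~51) and VAF-gated (~48) candidates per sample.
The 26 contaminant pairs with 16 in one sperm sample follow the reported
cohort-wide total and hotspot; their split across tissues (5 blood /
21 sperm) is the package's own allocation, as no per-tissue breakdown is
published. One spurious partial-MNV SNV and one indel-proximal SNV per
sample keep the corresponding filters permanently exercised.

Each sample draws from an RNG stream keyed by `(seed, sample index)`, so
samples are independently reproducible and whole cohorts are byte-identical
under a fixed seed. Clonal events are emitted as one row with
`alt_count = k` by default, or as k duplicate rows (`clonal_as_rows`) to
exercise deduplication.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: no read-level sequences or consensus errors
(variants appear as clean calls, as if upstream consensus calling were
perfect); panel sequence is random at a genome-like GC fraction rather than
real human loci, so homology artifacts (segmental duplications, repeats)
that could produce spurious junction matches are absent; depth is nearly
uniform, while real capture panels vary severalfold; per-locus mutation
rates are uniform by default (an optional `locus_weights` vector implants a
known fold-spread for testing `per_locus_mf()`), so the 5–6-fold inter-locus
variability seen in real cohorts is not reproduced spontaneously; and
contamination is modelled only as germline leakage between cohort samples,
not as external-source contamination.

## Numerical choices and degenerate inputs

* All thresholds are inclusive/strict exactly as documented: VAF gate ≤,
  contamination < and >, indel window ≤, candidate allele length >, clonal
  MNV VAF ≥.
* `mutation_frequency()` refuses non-positive denominators; subtype rates
  refuse a nonzero count over zero stratum depth; the CpG fraction returns
  `NA` when there are no C>T calls; the binomial subset test returns `NA`
  on an empty subset; Pearson correlation returns `NA` under zero variance.
* Spectrum proportions of an empty spectrum are all zero rather than `NA`,
  so downstream cosine calls fail loudly (zero vector) instead of silently.
* Variants whose trinucleotide context falls off a locus edge are skipped
  with a warning in SBS96 and CpG calculations.
* G-test zero cells contribute zero; the Monte Carlo p uses the
  add-one estimator `(1 + #{G* ≥ G}) / (B + 1)`.
* Ties in classification: a fragment exactly equal to the allele length is
  circle-consistent; an allele of exactly 125 bp is not a candidate; a
  match of the inserted allele anywhere other than `pos + 1` does not count
  as a D-A junction.

## Problem sizes used by the tests and acceptance script

The unit suite works on 1–2-locus panels of a few hundred bp and cohorts of
tens of megabases, where brute-force oracles (O(n²) contamination and
proximity scans, sliding-window Hamming matching, direct multinomial
likelihood maximization) are exact and fast. Recovery and end-to-end checks
run full 6-sample cohorts at 1.25e9 duplex bases; the acceptance script
pools its simulation-derived estimates over six replicate studies (a
variance-reduction choice — the replicate count shrinks Monte Carlo error
on the estimates, while per-sample means stay on the study's 6-sample
scale) and uses 10⁴ replicates for the LR-test calibration. The whole suite
runs in a few minutes on one CPU.

## Known limitations

The package starts from consensus-level calls: it does not parse BAMs,
build duplex consensus reads, or call variants, and the alignment-geometry
records it consumes are a distilled TSV rather than raw SAM. Signature
*decomposition* is out of scope — only cosine similarity to user-supplied
signature matrices is provided. The circle-vs-TD classifier is conservative
by construction: junction-positive events whose fragments are all shorter
than the allele are labelled circle-consistent, which is evidence of
consistency, not proof of circularity; events without informative fragments
stay ambiguous. Finally, the generator's simplifications listed above mean
that green tests validate the *implementation* of the rules, not their
robustness to alignment pathology in real genomes.
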