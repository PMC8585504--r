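---
title: "Surveying the genomic context of BstA-family phage-defense genes"
author: "bstaContext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying the genomic context of BstA-family phage-defense genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bstaContext)
```

## The biological question

BstA is a family of prophage-encoded abortive-infection proteins found in
Gram-negative bacteria. Two genomic signatures characterize the family and
motivate this package. First, *bstA* homologs are overwhelmingly embedded
in prophage regions: genes annotated with phage functions cluster around
them, often with a putative prophage repressor gene immediately 5' of the
homolog (the cI–*bstA* architecture). Second, each *bstA* locus carries a
short DNA element overlapping its own start codon — the anti-BstA (*aba*)
element — which gives the encoding prophage self-immunity against its own
defense protein. The BTP1 *aba* element is 63 bp: 29 bp of upstream
sequence plus the first 34 bp of the coding sequence, bracketed by a
direct `CCCGCC` repeat whose disruption by a single G→T exchange
abolishes immunity.

`bstaContext` implements the comparative-genomics side of this biology:
neighborhood extraction, prophage-association classification, domain
co-occurrence tallies, Needle-convention identity, and sequence-level
*aba* analysis, plus a deterministic synthetic-data generator used to
validate the whole pipeline against known ground truth.

## The classification model

For each focal homolog we extract the region 20 kb either side of the
gene body (a 40-kb neighborhood; `extractNeighborhood()`). Every
annotated gene overlapping that window by at least 1 bp is assigned to
the left or right flank by midpoint. A gene is *phage-annotated* when
its product contains `"phage"` or `"terminase"` as a case-insensitive
substring (`isPhageAnnotation()`); the match is deliberately loose, so
"Prophage integrase" and "bacteriophage holin" count. The call is then:

* **prophage-associated, high confidence** — phage-annotated genes on
  *both* sides of the focal gene. Requiring both sides guards against a
  prophage-independent homolog that merely sits next to an unrelated
  prophage region.
* **prophage-associated, low confidence** — evidence on exactly one
  side.
* **putatively prophage-independent** — no evidence on either side.

Plasmid status is not predicted; it is metadata carried with the
sequence record. An alternative evidence mode matches each gene's best
domain hit against a configurable list of phage-associated domains
(`mode = "domain"`), for annotation sets where product strings are
uninformative; the keyword rule is the default because product text is
what typical re-annotation pipelines provide most consistently.

Domain evidence comes from HMMER3 `--domtblout` tables
(`readDomtblout()`), reduced to one hit per ORF by
`bestHitPerOrf()`: hits with independent E-value above the threshold
(default `1e-3`, the usual HMMER reporting convention; the tool itself
does not define "significant") are discarded and the highest per-domain
bit score wins, with ties broken by lower i-E-value and then by domain
accession so results are order-independent. Ranking by bit score rather
than E-value is the default because per-domain bits are
length-independent; `rankBy = "evalue"` is exposed for the alternative
reading.

## Pairwise identity

Percent identities between homologs are computed under EMBOSS Needle
conventions, since that is the de-facto standard for reporting pairwise
protein identity: EBLOSUM62, gap open 10.0, gap extend 0.5 (a gap of
length L costs `10 + 0.5 (L-1)`), terminal gaps unpenalized but *kept*
in the alignment, and identity = identical columns divided by the full
alignment length, gaps included, reported to one decimal. The aligner
(`needleAlign()`) is a three-state affine-gap dynamic program; among
co-optimal alignments the traceback prefers match/mismatch columns over
gaps in the first sequence over gaps in the second, which fixes a
deterministic representative (identity is reported for the returned
alignment). Full-length sequences are aligned; no trimming is applied.
For display of many homologs against a reference,
`collapseToReference()` removes the alignment columns gapped in the
reference row and reports the removed column ranges, so the collapsed
alignment has exactly the reference's ungapped length.

## The aba element operations

`partitionElement()` splits an element at its start codon; auto mode
takes the *first* forward-strand ATG, which is correct for the BTP1
element (offset 29) and can be overridden with an explicit offset for
elements with upstream ATGs. `findDirectRepeats()` enumerates maximal
repeated substrings (length ≥ `kMin`, ≥ 2 possibly overlapping
forward-strand occurrences; maximal means extending the motif by one
base on either side would lose an occurrence). "Repeat at the terminal
ends" is operationalized by a margin rule (`findTerminalRepeat()`): one
occurrence must start within the first `margin` bases and one must end
within the last `margin` bases; the default margin of 10 bp is a
package choice — the repeat placement is shown but not formally defined
in descriptions of the element — and both parameters are exposed.
Repeat search is forward-strand only: the biological repeat is a
direct, not inverted, repeat. The G positions exchanged in the
repeat-disrupting mutants are located programmatically
(`locateRepeatBase()`) rather than hard-coded, so the same operations
apply to other elements. `scanOrfs()` reports every ATG-initiated
frame; because published statements about short ORFs inside such
elements rarely pin down strand, minimum length or completeness
criteria, the scanner exposes all three as parameters instead of
asserting a fixed count.

## The synthetic survey generator

`generateSurveyBundle()` emulates a curated homolog survey with known
truth. Its defaults are the study conditions of the survey it mirrors:
72 homologs, 79% prophage-associated, zero annotation noise. Quantities
no survey description constrains were fixed once at values a
genome-annotation practitioner would call realistic and are not meant
to be tuned: gene lengths uniform on 300–1500 bp and intergenic gaps on
20–200 bp (typical bacterial gene architecture), 12 flank genes per
side (enough that a 40-kb window is gene-dense), a 60/40 high/low
confidence split among associated homologs, 10% plasmid records ("a
small subset"), and a 0.6 per-gene phage-keyword rate on designated
prophage sides with at least one keyword gene forced per side so that
zero-noise construction always realizes its label.

Label proportions are planted by largest-remainder apportionment
(`apportionCounts()`), so they are exact up to integer rounding and
independent of the seed; 72 homologs at 0.79 gives exactly 57
associated and 15 independent (21% after nearest-integer rounding —
percentages are reported half-up, matching how such proportions are
conventionally printed). A single configuration seed derives a
per-bundle sub-seed by counter, making each bundle independently
reproducible and the written bundles byte-identical across runs.
`annotationNoiseRate` flips gene products between phage-annotated and
neutral after construction, degrading classifier agreement
monotonically in expectation — the property the test suite checks by
Monte-Carlo at fixed seeds.

What the generator does *not* emulate: realistic phage genome
architecture or gene order, sequence homology between planted genes,
HMMER score distributions beyond Gaussian noise on bit scores, and
multi-contig drafts. Passing recovery tests therefore demonstrates the
classification logic and its bookkeeping, not robustness to the
annotation pathologies of real draft genomes (misannotation,
pseudogenes, fragmented contigs). The network-dependent parts of a real
survey — fetching GenBank records, re-annotation, profile-HMM searches
— are out of scope; the pipeline consumes their standard outputs (GFF3,
FASTA, domtblout).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (GFF convention).
* Windows are anchored to the focal gene's outer coordinates, not its
  midpoint; genes partially overlapping the window boundary are
  included, since their annotations still carry evidence.
* Contig edges: windows are clipped and the truncation recorded
  (`leftTruncated`/`rightTruncated`) rather than homologs being
  dropped; circular contigs wrap modulo the contig length, and a window
  spanning the whole circle is a configuration error.
* Neighborhoods never cross contig boundaries.
* Left/right sides are genome-coordinate sides by default; an
  `orientByStrand` mode re-labels them relative to the focal strand.
* Repressor adjacency defaults — same strand required, intergenic gap
  ≤ 1 kb — capture the tight cI–*bstA* arrangement and are fully
  configurable; no published rule exists for this synteny.
* Co-occurrence tallies count a domain once per neighborhood by
  default (`unit = "per_neighborhood"`), so one gene-rich neighborhood
  cannot dominate the top-ten list; per-gene counting is available, as
  it is not documented which convention the original tally used.
* Sequences are uppercased and `U` mapped to `T` on ingest; protein
  ingest strips gap characters.
* Alignment input must be non-empty and covered by the substitution
  matrix; zero-length alignments have undefined identity and raise an
  error.

## Worked example

```{r example, eval = FALSE}
# the shipped 63-bp aba element
rep <- runAbaReport(system.file("extdata", "aba_btp1.fasta",
                                package = "bstaContext"))
rep$report
#   element length upstream coding terminal_repeat repeat_positions n_orfs
#  aba_BTP1     63       29     34          CCCGCC             2,58      1

# a 72-homolog synthetic survey at the default study conditions
sv <- generateSurveyBundle(surveyConfig(seed = 42))
res <- runSurvey(sv)
res$summary
# SurveySummary of 72 homologs
#   prophage-associated:  57 (79%)
#   prophage-independent: 15 (21%)
#   plasmid-encoded:      7
```

The test suite exercises the same closed loop at several problem sizes
(chosen to keep the default run fast: 20–30 homologs in the unit tests,
the full 72 in the end-to-end check, 30 homologs × 3 seeds for the
noise-degradation Monte-Carlo) and verifies the aligner, repeat finder,
neighborhood extraction and best-hit selection against independent
brute-force oracles.

## Known limitations

* The keyword rule inherits the biases of the input annotation; a
  prophage annotated without the words "phage"/"terminase" is invisible
  to it. The domain-evidence mode mitigates but needs a curated domain
  list.
* Identity values depend on full-length sequences; fragmentary homologs
  (N- or C-terminal-only matches) yield low full-length identities by
  construction.
* The auto start-codon rule (first ATG) is wrong for elements with
  ATGs in their upstream region; use an explicit offset there.
* The aligner is a plain R dynamic program, comfortable for proteins of
  a few hundred residues but not intended for genome-scale alignment.
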