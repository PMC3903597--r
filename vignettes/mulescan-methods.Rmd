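---
title: "Methods: structural MULE annotation, defect classification and indel statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural MULE annotation, defect classification and indel statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulescan)
```

## Scope and model

`mulescan` annotates transposase-coding *Mutator*-like elements
(coding-MULEs) and dissects their loss of coding capacity. The structural
model of a coding-MULE is:

```
TSD | TIR_L | ... transposase CDS (possibly degenerate) ... | TIR_R' | TSD
```

where `TIR_R'` is the reverse complement of a sequence similar to `TIR_L`
(inverted orientation, TIR-ends facing outwards), the TIRs are 2–30 kb
apart, and the TSD is an 8–11 bp direct repeat created by the insertion.
An element qualifies as a candidate when all three criteria hold:

1. **TIR pair**: global-alignment identity of `TIR_L` vs
   `revcomp(TIR_R)` strictly above 0.75, identity counted as matches over
   alignment columns with terminal gap runs excluded. The global (not
   ends-free) alignment is deliberate: an ends-free alignment would let a
   short spurious exact match masquerade as a high-identity pair.
2. **Internal homology**: a translated local alignment (BLOSUM62, affine
   gaps, both strands, all six frames) of a reference transposase against
   the region between the TIRs.
3. **TSD**: a valid duplication immediately flanking the TIRs. Validity
   is length-dependent: at 8 bp, one mismatch or one single-nucleotide
   indel; at 9–11 bp, two mismatches, or one mismatch plus one indel.
   A pair whose copies differ in length by one is scored at the longer
   length; lengths outside 8–11 are invalid calls, not errors.

Non-TIR MULEs are out of scope: without long, similar TIRs their termini
and TSDs cannot be located with confidence.

## Coordinate convention

Internal coordinates are 1-based closed intervals throughout — the
IRanges/Bioconductor convention of the ecosystem this package lives in.
The spec-level alternative (0-based half-open) buys nothing in R and
invites exactly the off-by-one drift a single convention is meant to
prevent. GFF3, the RepeatMasker-style table and the TSV dialect are all
1-based inclusive, so file interfaces mostly need no conversion at all;
each reader/writer documents its convention.

## Translated homology search

External search engines are out of scope, so the translated search is a
word-seeded, locally extended scan: exact amino-acid 4-mers shared
between a frame translation and the query are clustered by alignment
diagonal (tolerance ±3 residues, positional gap ≤ 40 residues, at least 3
seeds per cluster) and each cluster is refined with a local BLOSUM62
alignment (gap open 11, extend 1). The raw-score threshold (default 80)
replaces the database-size-dependent e-value of an online search; on
i.i.d. background sequence the seed requirement plus this threshold admit
essentially no hits (property-tested), while even heavily degenerate
transposase fragments score in the hundreds.

Coding-region interruptions leave characteristic signatures in the block
structure, which the defect classifier reads directly:

* a **deletion** shifts the alignment diagonal → separate blocks with a
  reference coverage gap (threshold 30 aa);
* a **frameshift** moves the downstream signal into another frame →
  adjacent blocks in different frames without an intervening reference
  gap (a ≥ 30 aa gap with a frame change records both defects, mirroring
  deletions whose length is not a multiple of three);
* a **premature stop** appears as `*` inside a block (stops before 95 %
  of the aligned reference span count; stops within ±5 residues of a
  frameshift junction are part of that lesion, not an independent
  defect);
* a **start-codon loss** is the absence of an in-frame ATG among the
  element residues aligned to the first 30 reference codons;
* **D/D/E mutations** are read off the columns aligned to the reference
  catalytic positions.

The catalytic domain is present when the three aligned residues are D, D
and E, the element-side first-D-to-E span exceeds 100 aa, and no stop or
frameshift junction falls inside the catalytic region. The DNA-binding
test is a homology surrogate for secondary-structure prediction (an
external web service in the original workflow): the element must align
over ≥ 80 % of the annotated reference HTH segment at ≥ 40 % identity
with no stop or frameshift inside. It is a self-contained predicate, so a
structure-based predictor can be swapped in without touching the
classifier. The 95 % stop threshold, 30 aa deletion threshold and
30-codon start window are explicit stand-ins for operational choices the
original analysis left unstated; all are configurable constants in one
place.

Group labels follow the six-group scheme: I intact, II DDE/start
mutation, III frameshift, IV premature stop, V frameshift + stop, VI
deletion. The redundant scheme admits multiple labels per element; the
non-redundant scheme assigns exactly one, with elements carrying
deletions going to a VI subtype keyed by their remaining defects, so the
subtype counts always partition the element set.

## TIR discovery and boundary placement

Inverted-repeat candidates are seeded with exact 12-mers shared between
the window and its reverse complement; for a true inverted pair the sum
of left and right positions is constant, so seeds cluster on that
anti-diagonal (tolerance ±30 bp). Seed extents are extended outward and
inward base-by-base while complementarity persists (stopping after three
consecutive non-complementary pairs and backing up to the last
complementary one), then validated by global alignment identity. Because
the symmetric extension drifts by the same amount at both ends, the TSD
search scans a wide symmetric offset range (±25 bp with `dr = -dl`) plus
a small independent jitter grid (±6 bp each side); the winning placement
maximizes matching TSD copy bases, then minimizes the offset. This
TSD-anchored refinement is what fixes the element boundary, exactly as in
manual annotation practice. When several TIR pairs explain one homology
hit, a pair with a valid TSD wins, then higher TIR identity, then smaller
span. The TIR search length range defaults to 50–800 bp, a superset of
the canonical 100–500 bp, so boundary cases are not lost.

## LTR dating, indels, Ks

Nested LTR retroelement ages use `T = d / (2r)` with
`r = 1.3e-8` substitutions/site/year: each LTR accumulates change
independently after insertion, hence the factor two. The divergence `d`
comes from a global alignment with gap columns excluded, corrected under
K2P by default (the common default of the software family the original
distance computation belongs to); p-distance and JC69 are selectable.
With LTRs of a few hundred bp the per-element age scatter is substantial
(binomial sampling of a few dozen substitutions), which is why the
validation asserts mean recovery within 15 % and reserves per-element bin
assignment for longer LTRs.

Indel statistics between best homologs use a global affine-gap alignment
(match +1, mismatch −2, gap open 8, extend 1 — defaults in the style of
the classic GCG `gap` program, whose exact parameters are unrecorded).
One maximal gap run is one indel event regardless of length; terminal
runs are excluded; identity is matches over non-gap columns (gap columns
excluded — exposed as the definition, since published identity values do
not state their convention). "Most significant alignment" is
operationalized as longest alignment, identity breaking ties. Only pairs
above 95 % identity enter NIK/LIK, the per-kb normalizations by the
summed length of the two elements. Ks uses Nei–Gojobori (1986): per-codon
synonymous site fractions averaged over the two sequences, pathway-
averaged synonymous differences, Jukes–Cantor correction; codons with
gaps, N or stops are dropped and fewer than 30 comparable codons yield
NA. NG86 is implemented here because no installed package provides it
directly; the test suite checks it against an exhaustive site-counting
oracle. Two-sample comparisons default to Welch's t-test ("t-test"
without a variant named is read as the safer unequal-variance form).

The 2×2 contingency statistic is Pearson's χ² with expected counts from
the margins and **no continuity correction** — only the uncorrected
statistic reproduces published values of this analysis type, which the
acceptance suite verifies for eight printed statistics.

## The synthetic-data generator

Genome-scale reruns require maize/rice assemblies and external masking
tools, so validation runs on synthetic genomes with planted ground truth:

* i.i.d. background at configurable GC (default 0.44, grass-like); no
  isochores or repeat landscape — sufficient for structural callers,
  and a stated limitation for anything sensitive to base composition;
* planted elements: TIRs 100–500 bp at 90 % pairwise identity by
  default, TSDs 8–11 bp (identical copies), a back-translated ~800 aa
  reference transposase CDS with randomized synonymous codons, pads of
  100–400 bp — total spans of roughly 2.9–4.5 kb, inside the 2–30 kb
  envelope;
* the bundled reference transposase is synthetic with the canonical
  architecture (HTH at aa 80–120; D331/D410/E489, first-D-to-E span
  159 aa) but not any real protein's sequence; residues 2–31 are kept
  methionine-free so the start-codon rule is decidable by construction;
* defects are planted one per element for recovery studies (the
  spectrum is a configurable probability vector); a planted deletion
  re-samples its position so it cannot erase another planted defect,
  keeping truth labels independently observable;
* nested insertions arrive at a Poisson rate per element, 70 % RNA
  (LTR retroelements, whose two LTRs are mutated independently with
  per-copy rate `r·T` so the expected divergence is `2rT`), 30 % DNA
  (a 274-bp *Tourist*-like MITE or a generic DNA TE), each with its own
  target-site duplication;
* homolog pairs: substitutions Binomial(L, rate), indel events
  Poisson(L/1000 · rate), indel lengths Geometric(p = 0.3) — a
  short-indel-dominated shape, the standard empirical form, with p
  configurable since no distribution is prescribed by the data;
* ESTs are 300–1500 bp substrings with at most 0.5 % mutation.

Everything is driven by one root seed; a fixed seed gives bit-identical
output. Passing tests on these simulations demonstrates correctness of
the callers under the stated statistical structure; they do not
demonstrate robustness to real-genome features the generator omits
(repeat families confusable with TIRs, soft-masked regions, sequencing
gaps, fragmented assemblies).

## Problem sizes used in validation

Discovery recovery runs 50 planted elements in a 500 kb genome; defect
classification 200 single-defect elements; LTR dating 100 retroelements
per planted age; indel response 100 homolog pairs of 2.5 kb per rate —
sizes at which every recovery metric is stable across seeds while a full
validation pass stays in the minutes range on a single CPU.

## Degenerate inputs and tie-breaks

Empty FASTA files, duplicate record ids, annotations with start > end and
overlapping unmerged insertions are hard errors; TSD lengths outside 8–11
and elements without any transposase alignment are negative calls with a
logged reason. Representative clustering (80 % identity over 80 %
coverage) picks the longest member, ties broken by lexicographically
smallest id. Elements shrinking below 2 kb after stripping stay in the
smallest size bin with a warning. A nested TE excised by annotation
interval leaves its own TSD scar in the host; when the insertion sat in
the coding region that scar can legitimately read as a frameshift — the
disruption is real, and the `insertion_disrupts_coding` flag records it
independently.

## Interfaces

The package's functions are the interface; `run_pipeline()` orchestrates
simulate/load → discover → nest → classify → report from one list or
YAML config, writing GFF3 calls, TSV reports and a JSON manifest, and
`scripts/acceptance.R` regenerates the headline numbers from scratch.
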