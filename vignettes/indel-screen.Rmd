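---
title: "Screening population RNA-seq alignments for fixed coding indels"
author: "cavescreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening population RNA-seq alignments for fixed coding indels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavescreen)
```

## The screen

`cavescreen` looks for insertion/deletion variants that are fixed in one
lineage and absent in another, using nothing but spliced RNA-seq read
alignments against a single reference genome. The motivating system is the
Mexican tetra, with one surface-dwelling population and two independently
derived cave populations (Pachón and Tinaja) aligned to a Pachón-allele
reference. Under that design a lesion shared by the two cave lineages is
*absent* from the cave alignments (they match the reference) and appears as
a fixed variant in the surface alignment; a cave-specific lesion appears in
that cave's alignment only. The package keeps both orientations explicit
throughout: every site carries its observed (read-vs-reference) polarity,
and final mutation names are re-expressed relative to the ancestral allele
once outgroup polarization has decided which allele that is.

The screen proper is a cascade of four inclusive filters:

| filter   | rule                          | default | why |
|----------|-------------------------------|---------|-----|
| scaffold | scaffold length ≥ threshold   | 1 Mb    | small scaffolds are assembly-fragment prone |
| depth    | spanning reads ≥ threshold    | 50      | fixed calls need real coverage |
| genotype | allele fraction ≥ threshold   | 0.98    | "98–100% of aligned reads" ≈ fixed |
| exonic   | inside one exon, ≥ margin from a splice boundary | 10 bp | splice-junction misalignment mimics indels |

Filters are independent predicates: order changes only the audit trace,
never the surviving set (a property the tests assert). Every input site is
logged with one trace row per filter and the measured value, replacing the
manual curation step of screens done by hand. The exon-boundary margin has
no published value — 10 bp is this package's choice, configurable and
recorded in the audit log. Transcript termini are deliberately *not*
treated as splice boundaries by default, because genuine lesions can sit
close to a transcript end in a terminal exon (the *ghrb* fixture lesion is
in the last exon); a flag restores the stricter behaviour.

## Caller semantics

Events come straight from the CIGAR: one event per `I`/`D` operator, an
insertion anchored at the reference base immediately left of the inserted
bases, a deletion at its first deleted base. Two numerical choices matter:

* **Left alignment.** Events are shifted left while the reference context
  allows before merging, so repeat-context indels collapse to one site key
  per locus instead of fragmenting by read phase.
* **Depth.** "Aligned reads at a site" is ambiguous, so the definition is
  explicit. For an insertion, a read counts if it has gap-free aligned
  (M/=/X) bases at both flanking reference positions — which includes
  carriers of any insertion allele there, since an `I` operator does not
  advance the reference. For a deletion, a read counts if it carries the
  `D` operator or its gap-free block crosses a breakpoint of the deleted
  interval. Requiring reference reads to span the *entire* deleted interval
  would make measured depth shrink with deletion length (a 36-bp deletion
  under 100-bp reads at 60× would leave non-carrier populations near 38×,
  below the depth floor); breakpoint-crossing reads are exactly the
  reference-supporting evidence, independent of deletion length. Partial
  overlap without a breakpoint is ambiguous and not counted.

Mapping quality and base quality thresholds default to 0 (the screen
design applies none); multi-mapped reads are counted once via their
primary alignment.

## Coordinates, frames, names

All coordinates are 1-based, fully closed, in genomic, cDNA and protein
space alike; cDNA positions run in transcript orientation, so for a minus
strand gene exon ordinal 1 holds the highest genomic coordinates. One
transcript per gene is modeled (the longest, with a warning, if a GFF3
offers several).

Lesions are named by the positions the affected bases occupy in the
**carrier** allele: inserted bases by their positions in the
insertion-bearing allele's cDNA, deleted bases by their positions in the
allele that still has them. When several lesions share a transcript the
carrier coordinates of a downstream lesion shift by the summed signed
lengths of the upstream ones — this is why a variant observed at reference
anchor 2189 in the fixture's *mki67* can be printed as `Δ2154–2156`: the
upstream 36-bp lesion offsets the carrier frame by −36. The annotator
implements that cascade; the generator implements its inverse; the
round-trip through simulated reads and the full pipeline is the end-to-end
test.

Frame impact is plain arithmetic: a lesion is in-frame iff its length is
divisible by 3; a set of lesions on one transcript is walked in cDNA order
accumulating `signed length mod 3`, and the position at which the offset
first returns to zero after being nonzero is reported as the restoration
position (294 for the fixture's *plg* pair). Protein residues follow
`ceil((cpos − cds_offset)/3)` with a per-gene CDS offset that defaults
to 0. Published protein coordinates for some genes are internally
inconsistent with any single offset (they differ by 1–3 residues between
genes); the configurable per-gene offset absorbs this, and golden tests
assert only the self-consistent rows (*ghrb*, *plg*, *rnf126*). Names use
`Ins`/`Δ` with an en dash; an ASCII alias (`del`, hyphen) is provided for
file-safe output, and both dialects round-trip through the parser.

## Sharing classes and polarization

Per-population genotype states reuse the screen thresholds: variant-fixed
(fraction ≥ 0.98), reference-fixed (≤ 0.02), polymorphic, or low-coverage
(depth < 50, overriding the rest). With three populations and a biallelic
locus the informative patterns are exactly two: the surface population
differs from both caves (`shared-cave`) or one cave differs from the other
two (`single-cave`). Any polymorphic or low-coverage member makes the
locus `uninformative`. The state pattern alone cannot distinguish a
cave-shared derived allele from a surface-specific one — that needs the
outgroup. Polarization aligns each allele's lesion window (±60 bp of cDNA
by default) to the outgroup ortholog with `Biostrings::pairwiseAlignment`
(pattern-global/subject-local; match +1, mismatch −1, gap open 2, gap
extend 0.5 — simple documented defaults) and scores identity as matches
over alignment columns. The allele closer to the outgroup is called
ancestral; ties are unresolved, and a missing outgroup leaves every call
unresolved without stopping the pipeline. A `shared-cave` pattern whose
cave allele polarizes ancestral is refined to `surface-specific`.

## QTL colocalization

Distances from a mutated gene to each marker on the same chromosome are
measured marker-to-nearest-gene-span-boundary (0 inside the span), with a
midpoint mode available because published approximate distances do not
state their measurement point; markers are ranked per gene. Genes on
scaffolds absent from the placement map are reported once as unplaced, and
chromosomes without markers produce an explicit notice row rather than
silence. Published megabase distances to real markers are deliberately not
asserted anywhere: they depend on an external assembly, so the fixture
plants markers at known offsets (600 kb, 750 kb, 290 kb, 0) instead.

## What the synthetic fixture emulates — and what it does not

`build_fixture()` generates, deterministically from `(spec, seed)`:

* scaffolds of 1.1 Mb (one per gene) plus a 0.5 Mb decoy scaffold, uniform
  base composition;
* the seven genes with their published exon counts, mutation exon
  ordinals, cDNA lengths and strands; exon boundaries are otherwise
  unpublished, so the generator places the mutation exon around the lesion
  with a 60 bp margin and splits the rest evenly, recording everything in
  the truth table;
* reference transcripts carrying the Pachón alleles, with both cDNA flanks
  of every planted lesion forced non-repeating so the planted coordinates
  are already left-aligned in both cDNA and genomic space on either
  strand — otherwise the caller's normalization would legitimately shift
  them off the truth table;
* spliced per-population read sets (100 bp, 60× by default, written as
  SAM with `N` operators across the 300 bp introns) tiled in `depth`
  deterministic passes with per-pass phase shifts. Deterministic tiling
  rather than Poisson starts is intentional: the study condition "depth
  60" must actually hold at every lesion, and Poisson coverage at mean 60
  dips below the 50-read floor often enough to corrupt the fixture's
  semantics. Substitution errors (optional) never touch the CIGAR;
* four decoy genes that each fail exactly one filter: an undersized
  scaffold, a lesion 2 bp from a splice boundary, a 50% carrier fraction,
  and a 30× depth;
* an outgroup FASTA equal to the ancestral (surface) allele with 2%
  substitutions outside the lesion windows — enough divergence to be a
  different species, close enough to polarize cleanly;
* truth tables for lesions (expected coordinates, names, frame and
  sharing classes, failing filter) and for reads (which read carries which
  lesion), the oracle for caller equivalence tests.

Real RNA-seq has features the fixture deliberately omits: expression-level
variation across genes and stages (reads here tile uniformly), quality
scores, paired ends, alignment ambiguity and mapping error, GC and repeat
structure, and genuine biological polymorphism within populations. Passing
tests therefore demonstrate the *logic* of the screen — calling,
filtering, coordinate arithmetic, classification — not robustness to noisy
alignment; with real data the aligner, not this package, determines where
reads go.

Fixture scale was chosen so a complete build-plus-pipeline run takes well
under a minute on one CPU (about 42,000 reads over an ~8.2 Mb genome);
property suites use one-gene fixtures on 50 kb or 1 Mb scaffolds.

## Degenerate inputs and tie-breaks

Zero-coverage populations yield low-coverage states, not errors; loci seen
from several populations are merged with their population list retained;
an empty site list flows through to valid, header-only VCF and empty
reports. VCF output uses the anchor-base convention (insertion:
`REF = anchor`, `ALT = anchor + bases`; deletion: `REF = anchor + bases`,
`ALT = anchor`) and refuses to write records whose deleted bases disagree
with the genome. Identity ties in polarization are unresolved rather than
arbitrated. Distance ties in marker ranking break by table order
(`ties.method = "first"`).

## Known limitations

* One transcript per gene; UTR/CDS structure is reduced to a single
  per-gene CDS offset.
* The caller is strictly CIGAR-based: indels the aligner soft-clipped or
  never placed cannot be recovered, and no realignment is attempted.
* Sharing classes assume a biallelic locus across three populations;
  more populations are accepted but only the three-way patterns are
  classified meaningfully.
* Polarization uses a fixed-parameter pairwise alignment on a local
  window; highly diverged outgroups or lesions inside repeats would need
  a proper orthology pipeline.
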