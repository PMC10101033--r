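---
title: "Methods: 16S redundancy, in silico PCR and matching-amplicon metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 16S redundancy, in silico PCR and matching-amplicon metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimatch)
```

## Overview

`amplimatch` quantifies two linked distortions in 16S rRNA amplicon
surveys: intragenomic gene redundancy (multiple, possibly non-identical
16S copies per genome) and matching amplicons (MAs) — amplicons from
*different species* that are 100% identical for a given primer pair and
therefore indistinguishable even at single-nucleotide (ASV) resolution.
The pipeline runs in five stages: genome sanitization and unit splitting,
16S gene detection, per-genome redundancy statistics with taxonomic
aggregation, exact in silico PCR with IUPAC-degenerate primers, and
MA-based coverage metrics.

## Genome handling and sanitization

Each chromosome record is treated as an independent analysis unit
carrying its parent genome's eight-rank taxonomy (superkingdom through
strain; a missing strain label falls back to the species name). Ambiguous
IUPAC nucleotides are replaced by a uniformly random member of their
expansion set — e.g. `R` becomes `A` or `G` — because every expansion is
equally correct and a concrete base is needed for exact matching. The
draws come from one seeded generator consumed in sorted unit-id order, so
a run is bit-reproducible across machines. A unit containing a run of
more than `run_threshold = 10` consecutive ambiguous characters (any
non-ACGT code counts toward a run; a run of exactly 10 is kept) is
excluded: such stretches are assembly gaps, and random-filling them would
fabricate sequence. Exclusion acts at the chromosome-unit level; a
multi-chromosome genome survives through its remaining units. This is a
deliberate choice — excluding the whole genome on one bad plasmid seemed
wasteful, and per-unit exclusion composes cleanly with per-unit analysis.

## Gene detection

The finder follows the k-mer-density idea used by dedicated 16S search
tools: positions whose 13-mers occur in a panel of known 16S genes are
marked, windows of 100 k-mer starts with at least 30% panel hits seed
candidates, adjacent candidates closer than one window merge, and strand
is inferred by majority vote of k-mers that are panel-specific to one
orientation. Candidates are then anchored: the IUPAC consensus of the
panel genes' first and last 20 nt serves as conserved terminal motifs,
matched exactly (IUPAC-aware, zero mismatches — the same policy as primer
matching). A start/end motif pair spanning 1,200–1,900 bp confirms a gene
and fixes homologous endpoints; when several end motifs are admissible,
the span closest to the panel's median gene length wins, and pairing
proceeds greedily left-to-right so tandem copies separated by short
spacers resolve into separate hits. Overlapping hits keep the denser
candidate.

Window (100), density (0.30), length range (1,200–1,900 bp, bracketing
typical full-length 16S genes), k (13) and motif length (20) are exposed
configuration with documented defaults chosen for high margin on the
synthetic communities: a 5% diverged copy still has ≈50% intact 13-mers
(0.95^13 ≈ 0.51), comfortably above the 0.30 threshold, while random
background of any realistic length has essentially zero panel density.
The finder is infrastructure, not the contribution; `run_pipeline(genes =
...)` bypasses it with pre-extracted genes so every downstream metric can
be computed independently of finder heuristics, and the test suite proves
the two paths identical on communities the finder recovers exactly.

## Redundancy statistics

A gene *variant* is counted by exact string identity — equivalent to
"differs by at least one nucleotide from the first-obtained sequence" but
order-invariant; length differences count. Species-level means average
over the species' genome units. Ranks above species use hierarchical
mean-of-child-means, matching a nested per-rank presentation; the pooled
alternative (averaging over all units below the taxon) is available via
`method = "pooled"`. Whether published per-rank tables used one or the
other is not decidable from their values alone; mean-of-means is the
default because the nested table structure implies it. Strain-level
output reports raw per-unit counts with their (max, min) range — not
means. Banded spectra (one copy / two-to-six / seven-plus; archaeal
communities typically one / two-to-three / more) are tallied on species
means, with a species-maximum tally emitted alongside since prose
summaries sometimes mix the two; band edges are arguments.

## In silico PCR

A degenerate primer compiles to a per-position character-class pattern
accepting exactly the Cartesian product of its IUPAC expansion sets —
zero mismatches anywhere, mirroring plain-regular-expression matching.
The search space is the extracted gene sequences, not whole genomes
(gene-restricted search is what makes amplicons-per-genome comparable to
genes-per-genome); the forward primer is matched as given on the sense
gene, the reverse primer as its IUPAC reverse complement. The amplicon
runs from the first base of the *leftmost* forward match to the last base
of the *rightmost* reverse match — the maximal span, both binding sites
included; a gene yields at most one amplicon per pair, and none when
either site is absent or the reverse site does not end beyond the forward
start. Internally coordinates are 0-based half-open; all reference
reports are 1-based inclusive.

Reference positioning (`locate_on_reference()`) demands a *unique* exact
degenerate match: zero matches report `"U"` (unalignable), multiple
matches raise an ambiguity error rather than picking one silently. The
reported span between a forward primer's first and a reverse primer's
last reference position follows the convention `r_last − f_first`; note
this is one less than the inclusive base count, but it is the convention
that reproduces published per-pair span values exactly, so both numbers
are emitted, labelled. Mean amplicon lengths classify pairs as S
(100–300 bp), M (301–600 bp) or L (> 600 bp); means below 100 bp fall
outside the published bands and are labelled `undersized`.

## Matching-amplicon metrics

MA groups are identity equivalence classes of amplicon sequences per
primer pair, kept when they span at least two distinct species; sharing
across strains of one species is not an MA. Comparison is
strand-as-extracted — well-defined because genes are sense-oriented.
Coverage percentages use the full evaluated set as denominator, except
"detected species with MAs", whose denominator is the detected species.
Pairs usable on both domains are evaluated against each domain's set
separately, with a combined row using the pooled two-domain SC-NMA
formula; MA detection stays within each evaluation set.

The overestimation factor is published as a verbal definition
("combination of the copy number of the amplicons and the number of
MAs"), so the arithmetic here is an explicit interpretation, chosen to
reproduce the stated anchors: per detected species *s*, `copies(s)` is
its mean amplicons per detected unit, `foreign(s)` is the total count of
byte-identical amplicons in other species' units divided by the number of
such foreign units (zero when none), `OF = copies + foreign`, and
`OF-MA = OF / copies`. This guarantees OF-MA = 1.00 exactly when and only
when the species has no MAs, OF ≥ OF-MA whenever copies ≥ 1, and OF
collapsing to mean copies per genome when MAs are rare. Because the
original per-unit-versus-per-species pooling cannot be recovered from the
published tables, published OF means are treated as non-reproducible;
tests pin the anchors and exact recovery of the synthetic truth instead.
Percentages are rounded half-up to two decimals at report time only;
internal arithmetic is full precision.

## The synthetic community generator

`generate_community()` emulates exactly the structure the pipeline
measures: per species, a configurable number of 16S copies per
chromosome, variant counts, strand placement, multi-chromosome layout,
ambiguity runs and forced cross-species MA links, plus truth tables. All
genes derive from a bundled 1,550-nt synthetic template — **not** a real
organismal sequence — built by intersecting the IUPAC constraints of all
39 planted primer-binding sites and filling free positions from a fixed
seed. Six primers that do not align to the standard reference gene are
planted at positions chosen to preserve their published amplicon-length
categories. Species sequences diverge from the template by i.i.d.
substitutions (default 2% per base, capped at 10%) outside protected
windows — the primer sites and the 25-nt conserved termini the finder
anchors on, a biologically motivated protection since these regions are
conserved in real 16S genes. Each species additionally carries one unique
deterministic barcode substitution in every sizeable unprotected segment,
so any two species differ inside every amplified window *unless* an MA
link deliberately copies one species' window into another. Variants stack
single substitutions at distinct free positions, so they are pairwise
distinct by construction; background is i.i.d. uniform ACGT, making
accidental primer sites vanishingly rare (≈ degeneracy / 4^length per
position).

Truth tables are computed by direct construction, never by pipeline code:
substitution-only mutation keeps every coordinate fixed, so expected
amplicons are substring extractions at the planted template coordinates,
detection follows from which sites were deliberately corrupted, MA flags
from pairwise string comparison, and the metrics from plain loops. The
bundled `table1_like_spec()` community — 20 species spanning copies 1–11
and variants 1–9, two-strain species, a two- and a five-chromosome
genome, minus-strand copies, one ambiguity-excluded decoy chromosome and
three MA links — is the default recovery fixture: the full pipeline must
reproduce every truth quantity exactly.

What the generator does *not* emulate: indels (so no length variation
between gene copies), rate heterogeneity along the gene, partial or
pseudogenized rRNA copies, sequencing error, or realistic phylogenetic
correlation between species. Passing recovery tests therefore
demonstrates the pipeline's bookkeeping and matching logic are exact
under known structure — not that the gene finder's heuristics are robust
to every form of real-world divergence, which is precisely why the
bypass path exists.

## Problem sizes and determinism

The test suite runs the full pipeline once on the bundled 20-species
community (29 chromosomes, 127 genes, ≈5,000 amplicons, 39 pairs),
checks the compiled matcher against a brute-force per-offset IUPAC-set
scanner on 1,000 randomized cases plus MA grouping against quadratic
pairwise comparison on a 500-amplicon fixture, and verifies finder
exactness on plants diverged up to 5%. Every random draw — sanitization,
community generation, test fixtures — flows from explicit integer seeds;
two runs with the same configuration and seed produce byte-identical
report bundles, which the suite asserts file by file.

## Known limitations

Exact degenerate matching means a single primer-template mismatch counts
as a non-detection, which is stricter than wet-lab PCR; no melting
temperature or 3'-end weighting is modelled. Whole-genome (rather than
gene-restricted) primer search, similarity-threshold (OTU-style)
clustering, and copy-number abundance correction are out of scope. Region
labels for primer pairs are catalogue data passed through from the primer
table, not recomputed from alignments.
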