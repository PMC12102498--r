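---
title: "Anchored neighbourhood and provenance analysis of T4SS loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored neighbourhood and provenance analysis of T4SS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorscan)
library(dplyr)
```

## The problem

Type IV secretion systems (T4SS) are multiprotein translocation machines
whose marker gene, the ATPase *virB4*, is the one component recognisable in
every known system. Surveying a phylum of draft-quality genomes for T4SS
therefore reduces to a chain of well-defined decisions: which genomes are
reliable enough to include, which profile-HMM hits are credible, which hit
means which component, which components co-occur near *virB4*, whether the
gene tree of VirB4 homologues indicates vertical inheritance or
between-class transfer, and whether the major pilin (VirB2) occurs in the
tandem arrays characteristic of antigenic-variation systems. anchorscan
implements that chain as composable functions over data frames, plus a
synthetic-data generator that produces every input format with exact ground
truth, so each decision rule is testable in isolation and end to end.

## Inclusion rules

**Genome gate.** A genome is kept when completeness > 50, contamination
< 10 and the quality score, completeness − 5 × contamination, exceeds 50 —
all strict. The score can exceed 50 while the contamination bound alone
fails, so all three clauses matter (`passes_quality_gate(60, 12)` is
`FALSE` even though the score is 0 ≤ 50; `passes_quality_gate(80, 6)`
fails purely on the score of exactly 50).

**Hit filter.** Profile searches are consumed as per-domain tables. A
domain passes when its independent E-value is strictly below 0.001 *and*
its profile coverage, `(hmm_to − hmm_from + 1) / profile_length`, is
strictly above 0.5. Coverage is measured on profile coordinates, not on
the target protein: the question is how much of the model was matched.
Domains are never merged across rows — each must pass on its own, and a
protein passes if any of its domains does. Both inequalities are strict,
so a hit at i-Evalue 0.001 or coverage exactly 50% is excluded; the
generator plants decoys exactly on those boundaries to keep the
implementation honest.

**Component resolution.** The mapping from (profile set, profile name) to
component ships as a TSV resource. The set is part of the key because the
same profile name can mean different things in different models (TraE of
MPF_B is a pilin; TraE of MPF_F is VirB8). Among a protein's hits mapping
to one category, the highest bitscore supplies the source profile; a
protein may legitimately carry calls in several categories, and both
tallies (once per category, and distinct proteins) are recoverable from
the call table. Unmapped profiles become `Other` and are never treated as
T4SS components downstream.

## Neighbourhood analysis

Distances are CDS-rank distances: the window around an anchor is the 20
coding sequences upstream and 20 downstream on the same contig, regardless
of strand or intergenic spacing. Windows never cross a contig boundary;
truncation at a contig end is recorded (`upstream_truncated_at`,
`downstream_truncated_at`) rather than treated as an error, because draft
assemblies make truncation an expected observation — the near-end fraction
(anchors with fewer than 20 CDS to an end, i.e. exactly the truncated
windows) is itself a reported statistic. Contigs are treated as linear;
the assemblies surveyed are overwhelmingly fragmented drafts, and a
circular-contig flag would change at most the handful of closed genomes.

Positional abundance (counts of each component category at each offset)
is per anchor: a gene inside two overlapping windows counts once per
anchor, matching per-column totals whose 100% is the column. Only anchors
with at least one *other* T4SS component in the window are counted — a
second VirB4 copy is not a companion, since the question is association of
*virB4* with the rest of the machinery. Association summaries partition
each category's proteins exactly into near (inside some window at offset
≠ 0) and far, and `pair_proximity()` applies the same rank-window test
between two arbitrary categories (e.g. relaxase vs coupling protein).

## Provenance from the gene tree

The VirB4 gene tree is consumed as Newick with
`protein|assembly|class` leaf labels (delimiter and fields configurable).
The tree is midpoint rooted and the patristic matrix computed; for every
leaf we take the minimal distance to another leaf of the same class
(`d_same`) and to a leaf of a different class (`d_diff`). A leaf is
classified closest-same when `d_same <= d_diff`: ties go to same-class,
the conservative choice when rarity of between-class proximity is the
conclusion at stake. Leaves whose class has a single member have no
`d_same` and are excluded from the classified denominator but reported;
the summary gives the different-class fraction under both denominators.
Identical homologues are `d_same = 0` exactly by default, with a
configurable tolerance for Newick files written at low precision.
Midpoint rooting cannot change any leaf-to-leaf distance, which the tests
assert matrix-wise, and the matrix itself is checked against a
shortest-path oracle on the tree graph.

## Pilin arrays and sequence clustering

A pilin array is a maximal run of VirB2-called CDS in which consecutive
members are adjacent or separated by exactly one non-pilin CDS
(`max_spacer = 1`): allowing longer spacers would make "array" unbounded,
and the single-spacer reading matches arrays observed as "tandem or
separated by one gene". Two pilins two CDS apart therefore split.
Array identity statistics use global alignment (affine gaps over BLOSUM62,
gap open 11, extend 1; a length-L gap costs open + L × extend). Percent
identity counts identical columns over the alignment length including
internal gaps but excluding terminal-gap overhangs, and coverage of each
sequence is its residues inside the overhang-trimmed region. Because
co-optimal alignments can differ in identity, the traceback tie-break
(diagonal, then gap in the second sequence, then gap in the first) is part
of the function's contract; the test suite holds the implementation to an
independently written dynamic program with the same contract, and
alignment scores are cross-checked against Biostrings.

`greedy_cluster()` is a deliberately simple stand-in for external
clustering tools (equivalence is not claimed): sequences in decreasing
length order join the earliest cluster whose representative they match at
≥ 30% identity and ≥ 70% bidirectional coverage, and clusters of more
than five members are flagged as worth building a search profile from.

## What the generator emulates — and what it does not

`simulate_dataset()` plants, per genome: a T4SS cluster anchored on a
*virB4* gene with category-specific companion probabilities within ±10
CDS; a dnaA-marked origin CDS, near the cluster with probability
`near_origin_prob`, carrying dnaA/dnaN functional-family hits; contig
cuts placing a configurable fraction of anchors within 20 CDS of an end
(the cut never severs the planted ±10 companion zone, so truncation
affects window slots, not the planted truth); pilin arrays with sizes
drawn over 2–11 and single-gene spacers; far-placed coupling-protein and
relaxase genes; and hit tables in which every planted component passes
the filters while decoys straddle the thresholds — half failing on
i-Evalue, half on coverage, the first of each kind exactly on the
boundary. Array paralogs are made by substitution-only mutation of a
per-array ancestor at divergences keeping pairwise identity above roughly
half, so the optimal global alignment is the gapless diagonal and true
identities are computable by construction.

Rates are anchored on the survey being emulated: T4SS presence 0.8,
anchor-near-end rate 0.052, inter-class transfer fraction 0.0067, array
prevalence 0.18, genome sizes 300–2,300 CDS (about 1 CDS/kb over
0.3–2.3 Mb). The default dataset scale is 4 classes × 6 genomes, chosen
as a desk-scale default; tests and the acceptance script pass explicit
sizes (up to 200 genomes / 2,000 anchors, and a 2,425-leaf tree) and the
numbers below always state the size used.

`simulate_labelled_tree()` builds one coalescent subtree per class
(height 1), joins them with stems of length 50, and plants transfers as
leaves attached just above a foreign class's subtree root on a pendant of
length 5. The geometry makes the truth exact rather than probabilistic:
a transplant's nearest leaf is a host-class leaf (≤ ~9.5 away) while its
own class is two stems away, and every resident's nearest same-class leaf
(≤ 2) is closer than any transplant (≥ 5), so the closest-different-class
set equals the transplant set exactly. The number of transplants is the
deterministic `round(f × n)`, so the recovered fraction equals `f` up to
rounding rather than binomially scattering around it. Zero-distance pairs
are zero-length cherries; both members count, mirroring surveys that count
proteins with an identical homologue.

What the generator does *not* emulate: realistic sequence evolution
(substitution-only paralogs, uniform amino-acid composition), HMMER score
distributions beyond threshold placement, operon structure or strand
conventions, and real contig-length distributions. Passing tests
demonstrate that the decision rules are implemented exactly as specified
and are internally consistent at survey scale — not that the rules would
recover the same numbers from real assemblies.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive (the GFF3 convention); CDS rank is
  0-based. Strand is stored but ignored by all rank arithmetic.
* Proteins present in the FASTA but absent from the GFF3 are kept as
  orphans — usable for clustering, invisible to neighbourhood analysis.
* An empty contig is valid input; a duplicate protein id is a hard error;
  a CDS without a protein id is skipped with a counted warning.
* Missing branch lengths read as 0 with a warning; negative branch
  lengths are an error.
* A dataset with no anchor calls produces empty neighbourhood reports and
  a warning, not a failure; a missing tree skips the provenance stage and
  is noted in the run manifest.
* Determinism: one integer seed drives everything; per-genome sub-seeds
  are derived as `(seed × 1000003 + genome) mod 2^31`; cluster assignment
  order, tie-breaks in component calls (bitscore, then profile set and
  name) and in family rankings (count, then name) are all specified so
  reruns are byte-identical.

## Known limitations

* The greedy clustering is quadratic in the number of sequences and is
  meant for anchor-window protein sets, not whole proteomes.
* Percent identity depends on the stated alignment parameters and
  tie-break; numbers from other aligners or local alignment will differ,
  particularly for highly diverged pilins.
* Circular replicons are treated as linear.
* The shipped profile-to-component mapping covers the MPF model sets and
  the pilin Pfam profiles used by the emulated survey; other profile
  collections must be added to the mapping TSV to contribute calls.
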