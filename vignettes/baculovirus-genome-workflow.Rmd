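---
title: "Methods: circular-genome annotation, hr discovery and phylogenomic placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular-genome annotation, hr discovery and phylogenomic placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculokit)
```

baculokit implements the computational workflow of a baculovirus genome
project end to end: ORF annotation on a circular ~120 kb dsDNA genome,
discovery of homologous regions (hrs) as clusters of imperfect ~38 bp
palindromic repeats, promoter-motif screening, in silico restriction
validation, ortholog/unique-ORF classification with synteny and inversion
mapping, and core-gene phylogenomics including a constrained-placement
log-likelihood comparison. This vignette explains the models and rules,
the tunable parameters, and the design decisions taken where the
underlying procedures are conventionally left unstated.

## Coordinates and the circular genome

All internal coordinates are 0-based starts with explicit spans, so a
feature wrapping the replication origin (`start + span > length`) is
representable without special cases; 1-based inclusive coordinates appear
only at I/O boundaries (GFF3, GenBank). A wrap-around feature is written
to GFF3 as two location parts sharing one `ID` and reassembled on
reading. `N` bases are accepted in input and never produced by the
simulators; a scan window containing `N` counts those positions as
mismatches.

## ORF calling

`find_orfs()` reports, in all six frames and wrap-aware, every maximal
ORF: from the most upstream ATG after the previous in-frame stop to its
stop codon, keeping proteins of at least `min_aa` (default 50 aa, i.e.
153 nt including the stop — where a nucleotide threshold of "150 bp" and
a protein threshold of 50 residues disagree by one codon, the protein
criterion governs, because it is the stated selection unit). Internally a
circular genome is scanned as three concatenated copies; any maximal ORF
of span at most one genome length then appears with its full upstream
context in the middle copy, and duplicate calls are collapsed modulo the
genome length.

"Minimal overlapping of adjacent ORFs" is quantified as a deterministic
rule, since annotation practice otherwise hides a manual curation loop:
`resolve_orf_overlaps()` keeps ORFs longest-first and discards a
candidate whose circular footprint overlap with any kept ORF exceeds
`max_overlap_frac` (default 0.25) of the shorter of the two; ties break
by lower start, then `+` strand. Homology evidence does not rescue
discarded ORFs — the rule is pure, so results are reproducible offline.
Both the raw and the overlap-resolved catalogues are available.
`name_orfs()` assigns zero-padded ordinals clockwise from an anchor (the
polyhedrin gene by baculovirus convention; the leftmost ORF by default).

## hr discovery

Palindromicity of a window is scored against the window itself — the
fraction of positions whose base pairs with the base at the mirrored
position — not against a fixed motif, because the repeat consensus is an
*output* of the analysis. The expected score of a random window is 0.25.

`scan_palindromes()` (defaults: `unit_len = 38`, `min_score = 0.6`)
scores every window on the circle and reduces qualifying windows to
non-overlapping peaks by greedy selection: accept the highest-scoring
window (ties leftmost), discard windows overlapping it, repeat. The
greedy rule matters: in a tandem array of a perfect palindromic repeat,
windows phase-shifted by half a unit are themselves perfect palindromes,
so any rule that collapses each run of overlapping qualifying windows to
a single maximum would merge a whole array into one unit. Greedy peak
selection returns exactly one unit per repeat copy on a perfect array.
One consequence of the leftmost tie-break: on a perfectly uniform array
all phases tie, and the chosen phase depends on absolute coordinates, so
a genome rotation can shift it; with any realistic divergence the scores
are generic and the peak set is rotation invariant.

`cluster_into_hrs()` single-links units whose end-to-start gap is at most
`max_gap` (default 500 bp, exposed as a flag — no published value
exists), drops clusters below `min_units` (default 2), and reports each
locus as the minimal hull of its members: on the circle this is the arc
remaining after removing the largest gap between consecutive member
units, which handles origin-spanning loci and the degenerate one-cluster
case uniformly. Printed hr sizes in the literature typically include
flanking context, so size comparisons should use a tolerance rather than
equality. `hr_consensus()` is a column-majority call over the ungapped
unit stack (ties alphabetical) with per-column conservation fractions
attached.

`insilico_pcr()` confirms locus positions the way wet PCR did: primer
sites on opposite strands facing inward within `max_product` (default
5 kb), at most `max_mismatch` mismatches (default 0) and a mandatory
exact-match 3′ terminal base — strictness maximises specificity for a
confirmation assay. Identical forward and reverse primers trigger a
warning rather than a silent assumption of a typo.

## Promoter motifs

`upstream_window()` takes the `window` bases (default 200) immediately 5′
of the start codon on the coding strand, wrapping on circular genomes and
truncating only on linear ones. `scan_motifs()` matches the four
classical baculovirus motifs — late TAAG, TATA-box, CAGT initiator, GATA
— as exact literals on the coding strand only (matching early/late
promoter orientation logic), reporting all overlapping occurrences; the
motif table is user-extensible and supports IUPAC degenerate codes.
Offsets count the motif's 3′-most base from the start codon (offset 1 =
immediately adjacent). Probabilistic motif models are out of scope: the
source analyses used literal screens.

## Restriction digestion

Recognition sites and cut offsets for BamHI (G^GATCC), EcoRI (G^AATTC)
and PstI (CTGCA^G) ship as an editable table of record. A palindromic
site is one double-strand cut; non-palindromic sites are searched on both
strands with the mirrored offset. On a circular genome fragments are the
arcs between consecutive cuts, so the fragment count equals the cut count
and sizes always sum to the genome length — the suite asserts this
conservation law and rotation invariance of the fragment multiset.
`compare_profiles()` matches observed to expected sizes sorted-greedily
one-to-one with a per-pair relative-error tolerance (default 5%),
reporting unmatched sizes both ways.

## Orthology, uniqueness, synteny

Protein pairs are aligned by optimal Smith–Waterman local alignment with
affine gaps (BLOSUM62, gap open 11 / extend 1 — the familiar convention).
E-values use the Karlin–Altschul form `E = K·m·n·exp(−λS)` with fixed
published gapped constants (K = 0.041, λ = 0.267, config-exposed) and
search space `m·n` = query length × summed subject-proteome length,
because the original database searches cannot be reproduced offline; the
constants are a stated convention, not a fit. Orthology is best-hit per
subject genome by raw score (ties: identity, then name), with a
reciprocal-best-hit flag; one-way best hits stay in the table. An ORF
with no hit at `E ≤ 10⁻³` in any subject genome is classified unique.

`synteny_map()` reduces shared orthologs to a signed permutation (focal
gene rank → subject gene rank, sign from strand agreement) and reports
maximal strictly monotone runs of consistent sign as blocks; descending
negative runs are inversions. Strand sign enters the permutation so an
inversion is detectable even when rank order alone stays monotone.
Singleton runs are emitted as length-1 blocks so the decomposition covers
every shared ortholog exactly once. Gene order on a circle is linearised
from the origin; block calls near the origin inherit that convention.

`hr_proximity_test()` asks whether positions (unique-ORF midpoints) sit
closer to hr boundaries than chance: the statistic is the mean circular
distance to the nearest hr boundary (zero inside an hr), the null
repositions the points uniformly, and the one-sided p-value is
`(1 + #{null ≤ observed}) / (n_perm + 1)`, which is valid (never
anti-conservative) by construction. Calibration is checked by a KS test
of the null p-value distribution in the suite.

## Phylogenomics

`concatenate_alignments()` builds a supermatrix from per-gene aligned
proteins with exact partition bookkeeping; taxa missing a gene are
gap-padded (or dropped under `missing = "intersect"`). Distances are
Poisson-corrected p-distances over columns where neither sequence is
gapped, `d = −ln(1 − p)`, with `p` capped at 0.999 (a distance ceiling of
about 6.9) because the correction diverges at saturation. Trees come
from neighbor joining (`ape::nj`) with negative branches clamped to zero
and the clamped deficit recorded. Bootstrap supports resample alignment
columns with replacement, rebuild NJ per replicate, and map bipartition
frequencies onto the full-data tree (seeded, hence reproducible).

Likelihoods use Felsenstein pruning under reversible 20-state models:
Poisson (uniform exchangeabilities/frequencies; the default and the model
of the exhaustive-enumeration oracle) and JTT, shipped as a static table
of the published Jones–Taylor–Thornton exchangeabilities and frequencies.
Rate matrices are scaled to one expected substitution per site;
transition matrices come from the symmetric eigendecomposition
`P(t) = D^{-1/2} U e^{Λt} Uᵀ D^{1/2}`, accurate to better than 1e-10
against the series expansion at small `t`. Gaps are missing data
(all-ones partials); site patterns are compressed; partial likelihoods
are rescaled per node by column sums to avoid underflow. Branch lengths
are optimised by round-robin bracketed scalar search with a monotone
accept rule, so the log-likelihood is non-decreasing across sweeps.

`constrained_topology_compare()` is the placement test used to argue
horizontal gene transfer: an NJ backbone is built without the focal
taxon, the focal taxon is grafted as sister to the stem edge of each
candidate group (at the group's MRCA edge, with a warning, if it is not
monophyletic), branch lengths are re-optimised for each constrained tree,
and `ΔlnL = lnL_B − lnL_A` is returned; a positive value favours group B.
Swapping the groups negates ΔlnL exactly. Full heuristic topology search
(NNI/SPR), rate heterogeneity and MCMC are deliberately out of scope —
the claim being exercised is the *sign* of the comparison, not a tree
search.

## The synthetic-data generator

`generate_genome()` produces circular genomes whose truth table is the
*complete* truth, so exact-count assertions are possible:

* background is i.i.d. at the configured GC content (default 0.41,
  AT-rich as NPV genomes are);
* ORFs (default 134 of 153–1350 nt on a 120,023 bp genome — sized so the
  coding fraction lands near the ~85% typical of these genomes) are
  random sense-codon sequences planted non-overlapping on both strands,
  each with an in-frame stop codon written immediately upstream so the
  planted ATG is always the maximal start;
* each hr locus (default 7) is a tandem array of a genome-wide 38 bp
  perfect-palindrome master unit, each copy independently mutated at
  `unit_divergence`; unit counts default to 3–8 per locus (about five on
  average, matching the repeat census of sequenced NPV hrs), and hr loci
  are placed with 700 bp of mutual clearance so distinct planted loci
  remain distinct under the detector's default 500 bp cluster gap;
* promoter motifs are written at known offsets within a reserved 200 bp
  upstream window of designated ORFs; restriction sites are planted
  per-enzyme on request;
* the background is then scrubbed by point edits until no unplanted ORF
  call at the scrub threshold, no stray planted-enzyme site, and no
  background window at the detector's default palindromicity remains.
  Edits prefer free background; inside planted ORFs only substitutions
  that keep the owner codon sense are allowed; repeat-unit positions are
  a last resort (an edit there only adds divergence to one copy). Edit
  sites are chosen with random jitter because two overlapping spurious
  calls with constrained footprints can otherwise trap a deterministic
  rule in a two-cycle.

Placement lays blocks out in random order around the circle with the free
slack distributed randomly among the gaps, which packs reliably at high
coding density; planted features never wrap the origin (wrap handling is
exercised by rotating finished genomes, which is exact).

`derive_rearranged_genome()` applies inversions, translocations, gene
loss and gain left to right with full coordinate/strand bookkeeping
(operations may not bisect planted features), then diverges the sequence
by point substitution outside motif and restriction-site footprints.
Planted-ORF start/stop codons are restored and internal stops repaired
afterwards (a stop's first coding base is set to C, always yielding a
sense codon), so derived proteomes stay translatable — the property the
orthology and synteny studies need. The truth table keeps source
coordinates and strands next to the derived ones.

What the generator does **not** emulate: real intergenic composition
(background is i.i.d., with palindromic and ORF-like signal scrubbed
*out*, so false-positive behaviour on real genomes is not measured by
these tests), indels, overlapping genes, gene families, repeat classes
other than the single hr master unit, and read-level error. Passing the
planted-recovery suite therefore demonstrates correctness of the
detectors' logic and calibration of the statistics under the stated
model, not performance on real sequence.

## Problem sizes used by the test suite and acceptance script

Unit and property tests run on 3–25 kb genomes; oracle equivalences use
50 random 5 kb genomes (ORFs), a 15 kb genome (palindrome windows),
protein pairs of at most 30 residues (alignment DP) and trees of at most
5 leaves with 6-site alignments (likelihood enumeration). Recovery
studies use 20 seeds of a 20 kb / 10-ORF / 3-hr configuration at 15%
unit divergence; the orthology study uses a 40 kb focal genome with 24
ORFs against five derived relatives at 5% divergence; statistical
calibration uses 200 null permutation datasets, 50 six-taxon NJ
replicates (800 sites) and 50 placement replicates (150 sites). The
acceptance script additionally runs one full-scale genome at the default
120,023 bp / 134-ORF / 7-hr configuration. These sizes are the package's
chosen study conditions: large enough for the statistics to be sharp,
small enough that the whole suite runs in minutes on one CPU.

## Known limitations

* Only ATG starts are considered; GTG/TTG starts, splicing and
  coding-potential statistics are out of scope.
* The palindrome scanner is the package's own detector; it is not a
  reimplementation of wraparound tandem-repeat dynamic programming, and
  unit calls in highly self-similar arrays inherit the greedy rule's
  phase choice.
* E-values depend on the fixed Karlin–Altschul constants; they are
  comparable within a run, not calibrated against any external database.
* NJ plus branch-length optimisation evaluates *given* topologies; no
  heuristic topology search is performed, so the placement comparison is
  only as good as the backbone and the two candidate graft points.
* The p-distance cap (0.999) makes saturated pairs finite but
  arbitrarily compresses distances beyond ~6.9 substitutions per site.
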