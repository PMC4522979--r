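---
title: "Methods: intron phases, microsynteny and the hop/chl-fus gene pair"
author: "hopfus package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron phases, microsynteny and the hop/chl-fus gene pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfus)
```

## The scientific problem

Two plant genes make an unusually informative pair for studying genome
rearrangement after endosymbiotic gene transfer. *hop* encodes the
Hsp70/Hsp90-organizing co-chaperone (TPR1–DP1–Ch.AA, TPR2A, TPR2B–DP2
domains) and is of ancient nuclear origin. chl-*fus* encodes the
chloroplast translation elongation factor G (cEF-G) and was transferred
from the plastid genome to the nucleus early in the history of
photosynthetic eukaryotes. In most flowering plants the two genes sit
side by side in *convergent* transcription (3' ends facing), separated
only by a short intergenic region (IGR). Three lines of evidence bear on
how this arrangement arose and how stable it is:

1. **Microsynteny and microcolinearity** — whether the two genes share a
   chromosome and in what relative orientation, across species.
2. **Exon–intron architecture** — intron counts, positions and phases,
   which record the history of exon shuffling, domain duplication and
   transit-peptide recruitment.
3. **IGR content** — decayed mobile elements, interrupted reading
   frames, deletions and 3' UTR overlaps, which mark the locus as
   recombinationally unstable.

This package implements each of those analyses as reusable, tested
functions, together with a synthetic-genome generator that realizes the
published per-species observations as concrete FASTA/GFF3 fixtures so
the entire pipeline can be exercised end to end with no downloads.

## Intron phase and recombinable modules

The phase of a spliceosomal intron is defined positionally on the
spliced CDS: phase 0 falls between two codons, phase 1 after the first
nucleotide of a codon, phase 2 after the second. `assign_intron_phases()`
computes the phase of intron *k* as the cumulative spliced coding length
upstream of the junction modulo 3. GFF3 `phase` columns are deliberately
ignored: they encode a different quantity (the offset to the next codon
start within a CDS part) and are frequently unreliable in practice; the
positional definition is the one that matters for exon shuffling.

Minus-strand genes are handled by materializing the spliced,
reverse-complemented CDS once; all codon and phase logic then operates
in transcript space, which removes strand special cases everywhere
downstream. Donor and acceptor dinucleotides are likewise read in
transcript orientation, and `validate_splice_sites()` classifies them as
`canonical` (GT..AG), `gc_donor` (GC..AG) or `noncanonical` — a verdict,
never an error, because aberrant junctions are themselves findings.

A *recombinable module* is a run of exons flanked by two boundaries of
the same phase; a symmetric phase-0 module can be excised, duplicated or
shuffled without breaking the reading frame. `find_recombinable_modules()`
enumerates **every** contiguous exon run whose flanking phases agree
(minimal and maximal runs alike), because the biologically interesting
units appear at several scales (single exons, TPR–DP cassettes, whole
TPR–DP–Ch.AA units). Two design choices were genuinely open:

* **CDS termini.** By default (`terminal_phase_policy = "phase0"`) the
  start and stop of the CDS behave as phase-0 boundaries, so 5'-terminal
  modules bounded by the start codon and a phase-0 intron count as
  recombinable. This matches the classical miniexon–phase-0-intron–domain
  picture of gene assembly, but it is an interpretation; the policy is
  switchable (`"excluded"`) for the strict internal-boundaries reading.
* **Phase-1/2 symmetry.** Whether same-phase non-zero boundaries count
  as "recombinable" is not settled; the enumeration reports them all,
  with `flanking_phase` recorded so callers can restrict to the phase-0
  canonical case.

Split codons are reported in the DNA alphabet (`G|AT`), with an RNA-style
rendering option (`G|AU`), so the alphabet in use is always explicit.

`propose_hidden_intron()` formalizes a splice-site-rescue inference: when
a predicted protein exceeds its cross-species reference length by ≥ 10
residues, the CDS is scanned for an interval of exactly the excess
length, bounded by a GT/GC donor and an AG acceptor, whose removal
restores a stop-free protein of the reference length. The 5'-most
satisfying interval is returned (later ones in an attribute) so the
output is deterministic.

## Pair arrangement

`classify_pair()` reduces a (hop, fus) pair to one of three
microcolinearity categories:

* **I** — genes on different contigs: no synteny, no colinearity.
* **III** — colinear in convergent transcription (3' ends facing), the
  dominant arrangement in flowering plants.
* **II** — syntenic but rearranged. The classical instance is chl-*fus*
  transposed just upstream of *hop* with both genes transcribed in the
  same direction (a local inversion). Divergent transcription does not
  occur in the published species set but can occur in randomized
  fixtures; it is also classed II, on the rationale that any syntenic,
  non-convergent layout is one inversion away from the ancestral-looking
  convergent state. The fine-grained `orientation` field preserves the
  distinction.

Orientation is computed purely from strands and relative order of the
annotated spans — never from transcript evidence. Annotated features
falling inside the IGR (retroelement remnants and the like) are reported
in `inserted_features` but never change the category: the species with
IGR insertions are counted among the colinear ones, following the
published per-family tallies rather than a literal "no inserted
elements" reading of the category definition.

The IGR is measured between the genes' outermost annotated CDS/exon
boundaries, not transcript 3' ends — an annotation-level definition that
is reproducible without cDNA evidence. When cDNAs are available,
`detect_utr_overlap()` computes the transcript-level 3' overlap that can
make the IGR vanish in the strict sense. Genes overlapping over more
than half of either span trigger an `annotation conflict` error rather
than a silent category.

## Structure classes

Exon–intron topologies are classed by an ordered rule table
(`load_class_table()`), shipped as an editable JSON file rather than
code because the verbal class definitions and the per-species intron
tabulations conflict in places. The shipped table follows the
per-species tabulation: class h4 admits 7–8 introns (the two
non-angiosperm land plants are tabulated with 8), f3 is the 6-intron
moss form, and the 3-intron `[1,0,0]` chl-*fus* of the conifer falls
into f4 — which is what makes f4 the 47-species class. Users can pin
the alternative reading by editing the JSON.

The combined gene-arrangement letters A–J join the colinearity category
with the two structure labels through a second decision table in the
same file. Unmatched combinations yield `"unassigned"` with a
diagnostic, never an error.

`map_introns_to_alignment()` anchors each intron to a protein-alignment
column: phase-1/2 introns to the residue whose codon they split, phase-0
introns to the residue immediately downstream — one convention, stated,
applied everywhere. `shared_position_matrix()` counts one-to-one matches
(equal phase, column distance within a tolerance that defaults to 0;
strict by default because alignment wobble near splice sites is common
enough that any tolerance should be a conscious choice).

## IGR instability scanning

`scan_orfs()` performs a six-frame scan. Besides plain ATG→stop ORFs, it
detects *interrupted* reading frames — the signature of decaying
insertions such as pararetrovirus pseudogenes — by chaining consecutive
in-frame stop-free stretches of at least `min_fragment_aa` codons
(default 30) separated only by stop codons. The fragment threshold is
what keeps the chaining specific: in random sequence the mean stop-free
stretch is ~20 codons, so chains of ≥ 30-codon fragments are rare by
chance but inevitable in a decayed coding region. A span is flagged
pseudogene-like at `stop_threshold` internal stops (default 3 — one stop
can be a sequencing artefact; several in frame are decay). The reported
minimum length is `min_aa = 50` residues, a conventional ORF-calling
floor.

The repeat finders implement one exact, testable definition: a hit is a
pair of arms (equal for direct repeats, reverse-complementary for
MITE-like terminal inverted repeats) with matching endpoints, at most
`max_mismatch` substitutions (default 1), no degenerate bases inside
either arm (N matches nothing), arm length ≥ `min_arm` (default 10 bp),
non-overlapping arms and a spacer ≤ `max_spacer` (default 1000 bp,
typical MITE scale); a hit is reported unless another valid hit on the
same pairing diagonal strictly contains it. The scan is implemented in
C++ and is exhaustive within a `max_arm` bound (default 2000 bp); the
test suite holds it equal to an all-pairs brute-force enumeration.
Direct-repeat hits whose first arm begins with the pentamer CACTA are
flagged `cacta_like` after the terminal structure of that transposon
family — a flag, not a family identification: homology search against
sequence databases is out of scope by design.

`compare_igr_deletion()` is a prefix/suffix anchoring heuristic: it
reports the longest common prefix as the divergence point and the length
difference as the deletion estimate, with a `clean` attribute when
prefix + suffix anchors tile the shorter sequence (then the estimate is
exact). It requires a shared 5' anchor (default 20 bp) and refuses to
compare otherwise.

## Hydrophobic cluster analysis

HCA projects a protein onto an alpha-helical net (3.6 residues per
turn), duplicated so wrap-around neighbours are visible; patches of
hydrophobic residues ({V, I, L, M, F, W, Y}, the classical set,
configurable) mark regular secondary structures, and proline breaks
clusters. Net adjacency is realized combinatorially — sequence
neighbours plus the i±3 and i±4 helical contacts, with no contact
crossing a proline — rather than by floating-point geometry, for
exactness and testability.

The shape heuristic calls a cluster `strand_like` when its vertical
extent (the minimal circular arc on the net period covering the members'
angular positions, in residue units) exceeds 1.5× its horizontal extent
(sequence span in turns), `helix_like` below 0.67, `indeterminate`
between — vertical clusters code for strands, horizontal ones for
helices. Single-residue clusters are always indeterminate.

`cluster_alignment_score()` is a reproducible surrogate for the visual
net-to-net comparison used for very distant homologues (where conserved
cluster shapes matter more than conserved residues): the ordered cluster
lists are aligned by dynamic programming on (order, length, shape), and
the score is the matched cluster length over the mean total cluster
length. It is a surrogate, deliberately simple; it is not a secondary-
structure predictor and is not benchmarked as one.

## What the synthetic generator emulates — and what it does not

`builtin_fixture_table()` encodes the 53-species study conditions: one
row per species with intron counts and phase vectors for both genes,
the pair arrangement, IGR length and planted inserts. The realized
conditions are:

* 40 of 53 species syntenic (75%); 38 convergent category-III pairs;
  the two Malvaceae as category II; 13 non-syntenic rows (the four
  green algae, the two non-angiosperm land plants — the moss is grouped
  under the "gymnosperm" clade label for convenience — one Musaceae,
  three Cucurbitaceae and three Fabaceae, fixed deterministically as
  *Cajanus*, *Cicer*, *Lupinus* since the published statement names
  only "3 out of 5" with *Glycine* known syntenic).
* hop classes h1 (0 introns) ×2, h2 (one 5' phase-0 intron after the
  MADEHK miniexon) ×1, h3 (12 introns, 9 phase-0) ×1, h4 (8 introns)
  ×2, h5 (6 introns, `[0,1,0,2,0,0]`) ×46, h6 (h5 minus V_h) ×1; fus
  classes f1 ×3, f2 (`[1]` + 8 phase-0) ×1, f3 (6 introns) ×1, f4
  (`[1,0,0]`) ×47, f5 (`[1,0]`) ×1. Every chl-fus gene starts with the
  phase-1 transit-peptide intron, whose split codon is set G|A-N in
  land-plant-like rows and G|C-N in the basal chlorophytes.
* IGR lengths: the two documented extremes (188 bp and 38,523 bp) are
  encoded exactly; the four species carrying decayed retroelement-like
  insertions get IGRs above 10 kb (12,000 / 11,000 / 10,000 / 38,523 bp)
  and an interrupted ORF with 12 in-frame stops planted at a fixed
  offset; the two *Oryza* species get a planted 14-bp terminal inverted
  repeat and *Medicago* a CACTA-prefixed direct repeat; all other
  syntenic rows default to 1,500 bp, inside the typical (< 3,500 bp)
  range.
* Proteins are realistic in size (Hop 545 aa; cEF-G precursor 775 aa
  with a 50-codon transit-peptide exon); one species carries the
  VPEVEKKLEPEPEP motif in three tandem copies where all others carry
  one. Intron lengths are drawn from 80–400 bp; splice sites are GT..AG
  unless the `allow_gc_donor` dialect is requested.

What the generator does **not** emulate: real codon usage and base
composition (exon sequence is uniform over sense codons), sequence
homology between species (each species' proteins are independent random
sequences, so cross-species alignment columns are only meaningful for
fixtures built explicitly for that purpose), intron sequence evolution,
UTRs and regulatory regions, paralogous gene families, and assembly
artefacts. Passing the fixture reproduction therefore demonstrates that
the *measurement* machinery — coordinate handling, phase arithmetic,
arrangement classification, class tables, scanning — is correct on data
whose ground truth is known exactly; it does not validate annotation
quality or alignment choices on real genomes.

## Numerical and engineering choices

* Internal coordinates are 0-based half-open; GFF3 and GenBank I/O
  convert at the boundary. Round-tripping internal → GFF3 → internal is
  asserted to be the identity in the tests.
* Determinism: all generation is driven by a single integer seed;
  identical (table, seed) pairs produce byte-identical files. Reports
  have fixed column and key order.
* The GenBank reader is a minimal flat-file parser (LOCUS, one CDS
  `join(...)`, ORIGIN) with a matching writer used for round-trip
  testing; fuzzy coordinates are rejected outright.
* Problem sizes in the shipped test suite were chosen to keep the whole
  suite in the low minutes on one CPU: oracle-equivalence checks run on
  500 random instances per operation family (genes of up to 10 exons,
  repeat substrates of 35–70 bp against an all-pairs oracle, proteins of
  20–200 residues against a graph-components oracle), parameter recovery
  on 100 random gene pairs, and the full 53-genome fixture once.

## Known limitations

* The colinearity categories collapse all syntenic non-convergent
  layouts into category II; callers needing finer resolution should use
  `orientation`.
* `scan_orfs()` chaining is frame-local and threshold-based; a decayed
  element interrupted by frameshifts (not just stops) will appear as
  several hits rather than one.
* `cluster_alignment_score()` is order-preserving: domain swaps between
  two proteins will not be matched.
* The hidden-intron scan proposes only exact-length, GT/GC..AG-bounded
  intervals; it will not find candidates whose boundaries deviate from
  those dinucleotides.
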