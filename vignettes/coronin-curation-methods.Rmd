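---
title: "Methods: gene-structure-aware curation and classification of coronins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-structure-aware curation and classification of coronins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corofam)
```

This vignette documents the models, rules and numerical choices behind
`corofam`, and what the synthetic families it tests itself on do and do not
show about real data.

## The curation model

Eukaryotic gene predictions routinely carry mispredicted exons and introns,
so a family-wide curation pipeline treats the gene structure as first-class
evidence rather than trusting the translated protein. `corofam` keeps three
coordinate systems and converts at fixed boundaries: genomic coordinates
are 0-based half-open internally (GFF3's 1-based closed convention is
translated at the parser boundary), protein residues are 1-based, and all
minus-strand genes are resolved into transcript orientation once, at parse
time, so every downstream operation sees 5'→3' exons and mRNA-sense
sequence.

**Intron marks.** For each intron we record the cumulative count of coding
nucleotides upstream (`cds_nt_before`), its phase (`cds_nt_before mod 3`,
i.e. 0 for introns between codons, 1/2 for introns after the first or
second nucleotide of a codon), and the 1-based index of the interrupted or
last-completed residue. The phase convention counts coding nucleotides
*before* the intron; it is stated explicitly because conventions differ
between tools, and the whole suite (projection, border support, frameshift
offsets) depends on it being used consistently.

**Splice validation.** Donor/acceptor dinucleotides are read in transcript
orientation and classified by the standard rule table: GT..AG canonical,
GC..AG and AT..AC accepted noncanonical, everything else a violation.
Introns shorter than 4 nt are rejected outright since they cannot carry
both sites.

**Border support.** Intron marks are projected onto a protein multiple
alignment (residue → column, skipping gaps; the map is invertible on
non-gap columns and the package tests the round-trip). A mark is
*supported* when at least `min_support` other genes carry a mark of the
same phase within ± `window` alignment columns, and *suspicious* otherwise.
Defaults are `min_support = 2` and `window = 5` columns: the underlying
idea is comparative — a border shared by two or more independent homologs
at the same phase is very unlikely to be a prediction artifact — and the
window absorbs small alignment wobble without letting distinct conserved
positions (typically > 30 columns apart) support each other. Both are
user-settable because dense samplings of close species can afford stricter
support.

**Mutually exclusive exons.** Duplicated exons that are spliced mutually
exclusively must be interchangeable in their context: both copies need the
same upstream phase and the same length modulo 3 (so the downstream phase
matches too). The detector clusters consecutive internal exons that share
this phase context, have lengths within a relative tolerance
(`len_tol = 0.2`), and whose in-phase translations reach a minimal ungapped
identity (`min_identity = 0.3` — low on purpose: real duplicated exons
diverge substantially while remaining recognizable). Discovery of
alternative 5'/3' splice sites from transcript evidence is out of scope;
the detector covers the exon-duplication case that can be validated from
gene structure alone.

**Completeness and pseudogenes.** A sequence missing nothing relative to
its expected full length is Complete; up to 5% missing is a Partial
(little impact on phylogeny); more is a Fragment. The expected length comes
from the family (median of complete homologs) or, in tests, from generator
truth. A gene is called a pseudogene when coding lesions — frameshift
events plus internal stop codons — reach `lesion_threshold` (default 3;
"too many to be sequencing error" is inherently a judgment call, so the
threshold is exposed), or when even one lesion coincides with more than 20%
missing sequence. Frameshift events are counted as *changes* in the frame
offset between observed intron phases and the family-conserved expected
phases along the gene, plus a terminal check that the total CDS length
returns to frame; a single 1-nt indel therefore counts once no matter how
many introns lie downstream. Without expected phases only the terminal
check is available, which underestimates; callers that have homologs should
pass the consensus phases.

## Domain detection and the architecture grammar

The coronin domain is found with a position-specific scoring matrix built
from a domain alignment: per column, `log2` odds of the pseudocount-
smoothed residue frequency over the background, gaps excluded from counts.
The background defaults to uniform 1/20 and the pseudocount to 1.0 — the
conventional uninformed choice; with a vanishing pseudocount an invariant
column scores `log2 20 ≈ 4.32` bits and absent residues fall to the score
cap (−10 bits, a finite stand-in for minus infinity that keeps window sums
well-behaved). Scanning slides the profile and keeps non-overlapping
windows above `threshold` bits per column (default 0.5), greedily by score;
a tandem coronin yields two hits. Random-sequence windows have negative
expected score per column, so the threshold separates cleanly.

The CA domain (central + acidic, the ARP2/3-binding module at the C
terminus of tandem coronins) is found as a C-region profile hit followed
within `max_linker` residues (default 40, since the inter-region linker is
variable) by an acidic-region profile hit; both profiles are supplied by
the user (or the simulator) as alignments.

Non-coronin domains — PH, gelsolin, VHP, coiled-coils, dUTPase and the
like — are consumed as external annotations, the way a curator would take
them from dedicated predictors; re-implementing those predictors is a
non-goal. `assemble_architecture()` resolves overlaps (score first, then
annotation > pssm > pattern) and emits a canonical string: runs collapse to
`PHx3`, unannotated stretches of at least `min_gap = 15` residues appear as
`U` (unique region), or `X` between two coronin domains (the tandem
linker). Class-4 architectures accept 2–4 PH domains and record the count,
since reported repertoires vary between two and four.

## The trimerization motif and the oligomer rule table

The coiled-coil trimerization motif R-[ILVM]-X-X-[ILV]-E is scanned as all
6-mers of the annotated coiled-coil (or, absent annotation, of the
C-terminal 60 residues). Window classification is exact, not fuzzy:
*classical* (R…E with the hydrophobic core), *swapped* (E…R — the salt
bridge reversed, expected to be as stable, hence still a trimer),
*p1_sub* (position-1 substitution with core and E6 intact), *p6_sub*
(position-6 substitution with R1 and core intact), *p2/p5_sub* (R1 and E6
intact but the core broken). When several windows match, the best class
wins in that order and the leftmost window breaks ties — a repository
decision, since one motif per coiled-coil is reported without a stated
selection rule.

The oligomer call encodes the experimental substitution record: classical
and swapped → trimer; K at position 1 → concentration-dependent
trimer/tetramer equilibrium; A or Q at position 1 → tetramer; Q at
position 6 → effect unanalyzed, reported `unknown`; any other substitution
or no motif → `unknown`; no coiled-coil at all → `no_coiled_coil`
(tandem class-3 coronins, dUTPase-fusion coronins). Norleucine, which also
produces tetramers experimentally, is unrepresentable in standard sequence
alphabets; the alanine rule covers that cell. The table is a total
function over the variant space and the tests enumerate it exhaustively.

## Classification

Class-3 and class-4 are architectural facts: two coronin domains make a
tandem, villin-derived domains make a class-4 (a coronin-domain-only
class-4 is admitted when the tree supports it). Class-1 versus class-2
cannot be told apart by architecture — both are `CORO-U-CC` — so those
calls always rest on the tree: the query takes class *C* exactly when the
smallest clade containing it and at least one reference leaf holds
references of class *C* only; a mixed smallest clade leaves it
unclassified, which is precisely the situation of non-metazoan short
coronins that predate the duplication. Rooting uses a user-supplied
outgroup when given and midpoint rooting otherwise (published coronin
trees are unrooted). Class-variant letters (1A, 1B, …) are reported only
as given on reference labels, never assigned automatically, because
variant designations are not reliable orthology statements.

Distances for the small built-in trees are `1 − fractional identity` over
mutually non-gap columns; pairs sharing fewer than 10 columns are left
undefined rather than imputed, and `nj_tree()` refuses matrices with
undefined entries. Neighbor joining is the classic agglomeration, exact on
additive matrices; published large trees remain external inputs and the
built-in NJ exists for synthetic-scale analyses and tests (it is
cross-checked against an independent implementation in the suite).

Sequence logos report per-column information content
`IC = log2 20 − H` with `H` the Shannon entropy of non-gap residue
frequencies; letter height is `freq × IC`, so stacks sum to the column IC.
The small-sample correction `(20 − 1)/(2 ln 2 · n)` is available but off by
default so that closed-form expectations hold exactly; all-gap columns are
reported missing rather than zero.

## What the simulator emulates — and what it does not

`simulate_coronin_family()` generates a family under the events that shaped
the real one: an ancestral short coronin; a metazoan ancestor that
diverges and then duplicates into class-1 and class-2 ancestors (so the two
classes are monophyletic and sister, while each non-metazoan lineage
diverges independently from the root and is therefore *equally related* to
both — the structural reason such sequences must stay unclassified); a
tandem duplication + fusion creating class-3 genes whose C-terminal domain
stays closer to the short-coronin ancestor than the N-terminal one, ending
in a CA domain; and a villin fusion creating class-4 genes with PH/GEL/VHP
blocks emitted as external annotations.

Defaults are fixed as the package's study conditions: 20 species, half
metazoan; 6 species with a class-3 gene and 4 with a class-4 gene; a
390-residue coronin domain; unique regions of 60–100 residues drawn from a
common template (length variation by C-terminal deletion, which keeps the
emitted alignment exact by construction); a 35-residue coiled-coil — within
the reported 30–40 range — carrying the motif at a fixed offset; motif
variant frequencies 0.80 classical / 0.05 each for K1, Q1, swapped and Q6
(the classical motif dominates real coronins, with substitutions confined
to species or recent branches); six conserved intron positions with phases
cycling 0/1/2 and GT..AG sites at probability 1; substitution divergences
of 0.15 from ancestor to class and 0.05 from class to leaf in the domain,
with the unique region three times faster. Coiled-coil positions outside
the motif avoid R and E so that exactly the planted window classifies —
a deliberate device that makes motif ground truth unambiguous.

Codon-level back-translation uses the standard code with uniform synonymous
choice under the seed; identical parameters (including the seed) give
byte-identical artifacts, and for defect-free genes splicing + translating
the emitted GFF3/FASTA reproduces the emitted proteins exactly. Planted
defects come with a log: border shifts slide a whole intron by `delta` nt
(both donor and acceptor move), so exactly the shifted mark changes phase
by `delta mod 3` and downstream marks are untouched — which is what lets
"k planted shifts → exactly k suspicious flags" be a sharp test; 1-nt
deletions plant frameshifts; TAA overwrites plant internal stops;
truncations shorten protein, gene structure and alignment row coherently.
`plant_mxe()` duplicates an internal exon at the nucleotide level
(preserving length, hence phase context) behind a new canonical intron.

What passing these tests does **not** show about real data: the simulator
has no indels inside domains (alignments are exact by construction, so
alignment-error robustness is untested), no compositional bias or
rate heterogeneity beyond the two-rate domain/unique split, no genomic gaps
or assembly errors other than the planted defect types, star-shaped
within-class phylogenies rather than realistic species trees, and no
whole-genome duplications. Results on real families depend on alignment
quality and on external domain predictions in ways the synthetic tests
cannot certify.

## Problem sizes and determinism

The shipped test suite and the acceptance script run at fixed sizes chosen
to exercise every code path at desk scale: 10,000 random 80-mers for the
motif-scanner/oracle comparison, the fully enumerated variant space
(1,500 cells) for the oligomer table, 100 random 5–8 leaf additive
matrices for NJ recovery, 50 random exon models plus a 20-species family
for the intron arithmetic and projection round-trip, 20-species families
(40 records, 46 domain rows) for exact recovery and planted-defect
counting, and the three logo closed forms at 1e-9. A larger family
(134 species) backs the motif-frequency calibration test. All randomness
flows from explicit seeds; `simulate_coronin_family()` restores the
caller's RNG state.

## Known limitations

* Frameshift counting without expected phases degenerates to the terminal
  mod-3 check; a slid (not shifted) exon border registers as two offset
  changes rather than zero or one, so lesion counts near conserved borders
  should be read together with `flag_borders()` output.
* `assign_class()` resolves nothing inside polytomies: with arbitrary NJ
  resolutions of a true polytomy, the smallest-clade rule can return a
  class where "unclassified" would be fairer; the generator avoids this by
  construction, real data may not.
* The MXE detector reports candidate clusters from gene structure only; it
  does not adjudicate isoform validity, which needs transcript evidence.
* Coiled-coil regions are taken from annotations or a C-terminal window;
  the package does not predict coiled-coils.
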