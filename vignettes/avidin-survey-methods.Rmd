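---
title: "Methods: surveying the bacterial avidin protein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying the bacterial avidin protein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(avidinsurvey)
```

## The problem

Avidins are beta-barrel proteins that bind biotin with femtomolar
affinity.  Beyond streptavidin, putative avidin genes occur across
Actinobacteria, Proteobacteria and Bacteroidetes, in species spanning
soil, aquatic, plant-associated and pathogenic lifestyles.  A survey of
such a family has a characteristic analysis shape: curate a heterogeneous
candidate sequence set, anchor it to a small set of verified family
members, infer a phylogeny and delimit subfamilies, ask which positions —
especially the biotin-binding residues — are conserved in each subfamily,
and relate the genomic and ecological context of the genes to their
possible function.  This package implements that whole chain as tested,
reusable code, exercised end to end on synthetic data with known ground
truth.

## Curation

Candidate records are deduplicated on the exact residue string
(case-insensitive, first-seen record kept), and entries whose id or
description matches a configurable blacklist (`synthetic`, `artificial`,
`vector`, `construct`) are dropped — these are cloning artefacts, not
organisms.  Nucleotide records shorter than 300 bp (too short to encode
the ~128-residue avidin domain) are flagged `needs_extension` rather than
dropped; actually extending them requires the source genome and is out of
scope.  Remaining nucleotide records are translated in frame 0 with the
standard code, stopping at the first stop codon, with ambiguous codons
rendered as `X` — the records a survey meets are annotated CDS features,
so no frame search is needed.  Translations identical to an existing
protein are discarded; the rest join the protein set.

Representative selection collapses near-identical records: single-linkage
clusters at ≥ 95% pairwise identity, represented by the longest member
(ties broken by lexicographic id, so the choice is deterministic).  The
95% threshold is a configuration knob; single linkage is deliberately
conservative — it only merges what a curator would call "the same
protein from closely related strains".  Provenance thresholds from the
original database search (E-value ≤ 0.01, identity > 19%) are carried in
the configuration as record-keeping, not recomputed: the live searches
themselves are out of scope.

## Pairwise statistics

Identity and similarity matrices use optimal global alignment
(Needleman–Wunsch with affine gaps, BLOSUM62, gap open −11 / extend −1; a
gap of length L costs `open + (L−1)·extend`).  Both percentages use the
*shorter-sequence* denominator, the convention of matrix global alignment
tools: identity of a sequence against itself plus a tail is 100%.
Similarity counts aligned pairs that are identical or score positively in
the substitution matrix.  The alignment engine is `Biostrings`; its
optimality is checked in the tests against exhaustive enumeration of all
global alignments of short strings.

## Profile-seeded master alignment

The verified-avidin seed alignment defines the column space of the whole
analysis.  Terminal seed columns that are gaps in more than half the rows
are trimmed (unaligned overhangs of the structural alignment); each
column then becomes a residue-frequency vector with a small additive
pseudocount (0.01).  Every putative sequence is aligned to this fixed
profile independently, by global dynamic programming where the match
score of residue *r* against column *j* is the expected BLOSUM62 score
under the column's frequencies.  Residues that fall *between* profile
columns are written to an insertion log anchored at the preceding column,
never columnised: the master alignment keeps exactly the seed's columns,
so conservation profiles and logos are comparable across clades, and a
fusion partner of any length cannot distort the domain's coordinate
system.  The cost is that lineage-specific insertions are invisible to
column statistics; they remain available in the log.  One-pass
sequence-to-profile alignment (no iterative refinement) keeps the column
space anchored; the refinement a curator would do by hand — and the
manual adjustment around binding positions — is deliberately not
emulated.

Terminal extensions are read directly off this alignment: the span of
residues aligned into master columns is the domain; ≥ 100 residues before
(after) it flag an N- (C-) terminal extension, the regime of the
protease–avidin fusions and the ~150-residue C-terminal extensions seen
in the family.

## Phylogeny

Columns with non-gap occupancy below 95% are removed (partial deletion),
then pairwise distances are computed on positions where neither sequence
is gapped.  Three models: observed proportion *p*; Poisson correction
`−ln(1−p)` (with shape *a*, the gamma-corrected form `a((1−p)^(−1/a)−1)`);
and the default JTT maximum-likelihood distance — the branch length
maximising the likelihood of the observed residue-pair counts under the
Jones–Taylor–Thornton rate matrix, found by one-dimensional optimisation
over the matrix's eigendecomposition (discrete-gamma mixture with 4
categories when a shape is supplied; the shape is user-supplied, never
estimated).  The JTT exchangeabilities and frequencies are taken from the
published model as distributed with `phangorn`, and the *same* matrix
drives the sequence simulator, so estimator and generator cannot drift
apart.  Saturated pairs (p ≥ 1 for the Poisson form, or no overlapping
ungapped positions) are errors rather than silent infinities.

The tree is Saitou–Nei neighbour joining (`ape::nj`) with negative branch
estimates clamped to zero — a deliberate, documented replacement for a
full maximum-likelihood topology search with nearest-neighbour
interchange, which adds hours of computation without changing the clade
structure that the downstream analyses consume.  Bootstrap support
resamples alignment columns with replacement (default 300 replicates,
seeded); the support of each bipartition of the point-estimate tree is
the percentage of replicate trees containing it.  Replicates hitting a
saturated distance are skipped and counted.

Because the stored root of an NJ tree is an artefact of join order, the
point tree is re-rooted at its *center vertex* (the internal node with
the smallest maximum path length to any leaf) before supports are
attached — a pure change of representation that makes rooted traversals
meaningful.

### Clade extraction

Subfamily delimitation is a greedy root-down search for maximal subtrees
satisfying three criteria: bootstrap support ≥ 70, at least 3 leaves, and
a stem branch (the edge subtending the subtree) of length ≥ 0.3
substitutions/site.  The stem criterion is the package's operational
stand-in for what a curator does visually: deep avidin subfamilies hang
off long branches, while the backbone order *between* subfamilies is
effectively unresolved.  Support alone cannot make that distinction — an
arbitrary resolution of a star-like backbone routinely receives
substantial bootstrap support, because the finite-sample noise that
produced it is resampled along with the signal — so a support-and-size
rule merges subfamilies that happen to be adjacent in the point estimate.
All three thresholds are configuration knobs; setting the stem threshold
to 0 recovers the pure support rule.  The root is a clade candidate only
when it carries an explicit support label (bootstrap trees leave it
unlabelled, as its bipartition is trivial); leaves not covered by any
qualifying subtree are reported as outliers, mirroring how a survey
annotates sequences that fit no subfamily.

## Conservation, logos and binding sites

Per master column, gap-excluded residue frequencies, occupancy and
information content (`log2 20` minus the Shannon entropy, so 0 bits for a
uniform column and ≈ 4.32 for an invariant one).  Logo matrices apply the
20% occurrence rule: residues at or below 0.20 frequency are removed and
the survivors are *not* renormalised — the logo shows true occurrence,
which is a display contract, not a probability model.  Conserved
positions are columns whose modal residue reaches a threshold (default
0.9, a knob; "highly conserved" is not a quantity with a canonical
value), reported in the numbering of a named reference row (chicken
avidin) via a strictly increasing column↔residue map.

Binding-site substitution scoring classifies each biotin-contact position
of a row as identical, conservative (same physicochemical class),
non-conservative, or missing (gapped).  The class table is fixed and
documented: aromatic FWY, aliphatic AVLIM, polar STNQ, positive KRH,
negative DE, special GPC.  Under it, the classic binding-killing
substitutions Trp→Lys and Trp→Arg are non-conservative (aromatic →
positive), while Leu→Ile is conservative.

## Neighbourhood enrichment

The vicinity of a focal (avidin) gene is the interval 500 bp upstream and
downstream of its termini, strand-independent, clipped to the replicon.
All coordinates are 0-based half-open, so "abutting the window" is
cleanly not an overlap and interval arithmetic has no off-by-one cases;
GFF3's 1-based inclusive convention is converted at the boundary and
round-trips exactly.  The universe pools all non-focal features across
the genome set; the foreground is the subset overlapping (≥ 1 bp) any
focal vicinity.  Each feature counts once, even near several focal genes,
and focal features are excluded from both sets — they would trivially
enrich their own annotations.  Features without GO terms borrow them from
PFAM/IPR/TIGRFAM accessions through a user-supplied fallback map; terms
are tested exactly as assigned, with no propagation up the ontology graph
(the analysis this emulates gives no evidence of propagation).

Per GO term, a 2×2 table (in/out of vicinity × with/without term) is
tested with the one-sided "greater" Fisher's exact test — the upper
hypergeometric tail, computed with log-gamma accuracy — matching the
question "does this function cluster with avidin genes more often than
expected?".  Benjamini–Hochberg adjustment is applied across terms (the
source analysis is silent on multiplicity; raw p-values are reported too).

## Ecology tabulations

Habitat categories are overlapping sets — a species counts once in every
habitat it occupies, which is why soil (59%) and aquatic (48%) can exceed
100% together.  Percentages are rounded to integers, matching survey
reporting style; the mobile-element fraction is plasmid/(plasmid+genome)
to one decimal.  Copy-number histograms exclude unknown counts, which are
reported separately.  The shipped species table
(`table_s1_synthetic.tsv`) is a **synthetic reconstruction**: the real
supplementary table is not redistributable, so the fixture was generated
to match the survey's published marginal totals (118 species; soil 70,
aquatic 57, pathogens 36, plasmid 5, genome 43, 13 multi-copy) with
plausible genus names; per-species rows are fabrications and only the
totals are meaningful.

## Synthetic data and what passing tests mean

`simulate_family_with_clades` builds a *star* backbone — one long stem
per clade off a central node, each carrying a Yule subtree rescaled to a
mean within-clade edge of 0.05 substitutions/site — and evolves a
128-residue sequence down it under JTT (root drawn from the stationary
distribution; per-branch transition matrices `exp(Qt)`).  Defaults are 5
clades × 6 leaves, stem 0.8: cross-clade identities land in the
"twilight zone" the real family occupies, while clades stay coherent.
The star is a modelling choice, not a convenience: the deep order of
avidin subfamilies is effectively unresolved, and a star is exactly that
regime.  No indels are simulated — synthetic families are ungapped, and
gap handling is exercised by constructed fixtures instead — so passing
recovery tests speak to distance/topology/support behaviour, not to
alignment quality on gappy data.

`simulate_genomes` lays features end to end with exponential intergenic
gaps (mean 100 bp) and exponential gene lengths (mean 400 bp, floor 150),
five genomes of 150 features with five focal genes each, a 25-term GO
vocabulary carried at background probability 0.3, and one planted term
carried at 0.9 by features inside a focal vicinity.  The density was
chosen once so that the pooled foreground is ≈ 80 features: with a
smaller foreground the hypergeometric null is so discrete that the exact
test is visibly conservative and its empirical false-positive rate
cannot sit near the nominal level; at this density it does (≈ 0.045 at
α = 0.05 in the package's own null simulation).  A quarter of features
carry only PFAM accessions translatable through the emitted fallback
map, so the GO-assignment path is always exercised.

Problem sizes used by the shipped analyses and the acceptance script —
30 taxa × 128 residues, 300 bootstrap replicates, 5 toy genomes, 100
power and 200 null simulations — are the package's chosen desk-scale
study conditions; they run in a few minutes on one CPU.

## Numerical choices and degenerate inputs

* Alignment tie-breaks prefer substitution over a gap in the first
  sequence over a gap in the second; profile-alignment traceback prefers
  match over column-deletion over insertion.  Results are deterministic.
* The profile DP is row-vectorised (Gotoh's three-state recurrence with a
  running-maximum unrolling of the horizontal state), so alignments of
  hundreds of residues against a 128-column profile are cheap in plain R.
* Distances: identical rows give exactly 0 under every model; the JTT ML
  optimisation runs on `[1e-8, 15]` with tolerance 1e-6.
* All-gap columns get zero occupancy and zero information rather than
  NaN; empty FASTA files, ragged alignments, duplicate ids, unbalanced
  Newick and malformed fallback maps are errors, not warnings.
* Every stochastic component takes an explicit seed; reruns are
  bit-identical.

## Known limitations

Distance-based NJ replaces full ML topology search; gamma shape is never
estimated; insertions are logged, not aligned against each other; no
signal-peptide or domain-scan predictions (those depend on external
trained models); no ontology-aware enrichment; the species fixture is
synthetic (totals only).  On real data, the manual steps of the original
workflow — structural seed curation, alignment touch-ups around binding
sites, visual clade delineation — are approximated by the documented
automatic rules above, and results can differ in exactly those places.
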