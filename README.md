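# avidinsurvey

Avidins are beta-barrel proteins that bind the vitamin biotin with
extreme affinity (K<sub>d</sub> ≈ 10⁻¹⁵ M for chicken avidin).  Beyond
streptavidin, putative avidin genes occur across Actinobacteria,
Proteobacteria and Bacteroidetes, in bacteria with very different
lifestyles — soil dwellers, marine species, plant symbionts, human
pathogens.  Surveying such a family means answering a fixed chain of
questions: which candidate sequences are real and non-redundant, how do
they align to the verified family members, what subfamilies does the
phylogeny support, are the biotin-binding residues conserved in each
subfamily, what genes travel next to the avidin gene, and what kinds of
bacteria carry it.

`avidinsurvey` implements that chain as a tested R package for anyone
doing protein-family surveys of this shape:

* **Curation** — deduplication, synthetic-entry filtering, flagging of
  nucleotide records shorter than 300 bp, frame-0 translation, and
  representative selection by single-linkage clustering at ≥ 95%
  identity.
* **Pairwise statistics** — optimal global alignment (BLOSUM62, affine
  gaps, open −11 / extend −1) with MatGAT-style identity/similarity
  matrices using the shorter-sequence denominator.
* **Profile-seeded alignment** — a verified-avidin seed alignment is
  trimmed and summarised as a column-frequency profile; every putative
  sequence is aligned to it by dynamic programming, with insertions
  logged rather than columnised, so all sequences share one column space.
* **Phylogeny** — partial deletion at 95% site coverage, pairwise
  distances (p, Poisson `−ln(1−p)`, or JTT maximum likelihood with
  optional gamma rates), Saitou–Nei neighbour joining, bootstrap support
  from 300 column resamples, and clade extraction by support, size and
  stem-branch length.
* **Conservation** — per-column frequencies and information content,
  sequence-logo matrices under the "occurrence above 20%" rule,
  conserved positions in chicken-avidin numbering, and classification of
  biotin-binding-site substitutions as conservative or non-conservative
  (aromatic FWY / aliphatic AVLIM / polar STNQ / positive KRH / negative
  DE / special GPC).  Terminal extensions ≥ 100 residues beyond the
  aligned domain are flagged (N, C or both) — the protease–avidin fusion
  regime.
* **Neighbourhood enrichment** — 500 bp vicinity windows around avidin
  genes, GO assignment with PFAM/IPR/TIGRFAM fallback mapping, one-sided
  Fisher's exact test per term (`P(X ≥ a)`, hypergeometric upper tail)
  and Benjamini–Hochberg adjustment.
* **Ecology** — overlapping habitat tabulations, pathogen counts,
  plasmid-vs-chromosome location with mobile-element fraction, and
  copy-number histograms from a species metadata table.
* **Synthetic data** — families evolved along known trees under the JTT
  model with planted clades, and annotated toy genomes with a GO term
  planted near the focal genes, so the whole pipeline is testable with
  no downloads.

## Worked example

The `analysis/` directory is a numbered end-to-end study on synthetic
data: 30 avidin-like sequences (128 residues, 5 planted clades), a 6-row
seed alignment, five toy genomes (750 features) and the species table.

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_curate_and_align.R
Rscript analysis/03_phylogeny_and_clades.R
Rscript analysis/04_conservation.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_ecology.R
```

prints, among other things:

```
curated 24 -> 22 records (22 clusters)
pairwise identity: median 25.0%, range 18.0-94.5%
master alignment: 28 rows x 128 columns, 0 insertion events
partial deletion: 128 of 128 columns kept
bootstrap: 300 replicates, median support 94
clades: 5 recovered (0 outliers); adjusted Rand vs truth 1.000
enrichment: 25 terms tested, 1 with q < 0.05
top term GO:0000001 (p = 2.09e-24, odds ratio 22.7); planted term was GO:0000001
gene location: plasmid 5, genome 43, NA 70 (mobile 10.4%)
multi-copy species: 13
```

Read: the curated family sits in the "twilight zone" (median 25%
identity between clades), yet the pipeline recovers all five planted
subfamilies exactly (adjusted Rand index 1.0 against the generator's
labels), and the GO term planted next to the avidin genes is the single
significant enrichment hit.  The ecology figures come from the shipped
species table — a *synthetic reconstruction* matching the published
marginal totals of the real survey (118 species; soil 70 = 59%, aquatic
57 = 48%, pathogens 36 = 31%, plasmid 5 vs genome 43, hence > 10% of
locatable genes on mobile elements, 13 multi-copy species); individual
rows are fabricated, only the totals are meaningful.

A classic single computation, the family's oldest benchmark:

```r
library(avidinsurvey)
refs <- avidin_reference_sequences()   # chicken avidin + core streptavidin
global_align(refs$residues[1], refs$residues[2])$identity_pct
#> [1] 33.85827
```

— the two founding avidins share only ~30% sequence identity despite
near-identical folds.

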