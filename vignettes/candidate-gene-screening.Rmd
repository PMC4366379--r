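---
title: "From plastome comparison to incompatibility candidate genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plastome comparison to incompatibility candidate genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidcompat)
```

`plastidcompat` traces nuclear-cytoplasmic conflict in pea from
whole-plastome differences down to a qualitative genetic model of
compatibility. This vignette explains the models and procedures, the
parameters that matter, the synthetic-data design, and the choices made
where the design was genuinely open.

## The biological problem

Crosses between cultivated pea (tester line WL1238) and some wild
accessions fail when an "alien" wild cytoplasm meets the cultivated
allele of the nuclear *Scs1* locus. Among the five accessions handled
here, the cytoplasms of VIR320 and L100 are incompatible with the WL1238
nucleus, while those of JI1794 and 721 are compatible. The package's
working hypothesis, encoded throughout, is an impaired protein-protein
interaction inside the plastidic heteromeric acetyl-CoA carboxylase
(ACCase): the plastid-encoded carboxyltransferase beta subunit (*accD*)
must physically fit the nuclear-encoded biotin carboxyl carrier protein
(BCCP, locus *Bccp3*, the candidate for *Scs1*).

## Variant screening

`align_and_call()` compares two colinear genomes by exact-match
anchoring: k-mers (default `k = 21`) unique in both sequences are
chained colinearly (longest increasing subsequence), adjacent anchors
merge into matched blocks, and the short unanchored segments in between
are aligned globally with Needleman-Wunsch
(`Biostrings::pairwiseAlignment`, match 2 / mismatch −3, gap open 5 /
extend 2). Blocks that overlap by a few bases — possible when an indel's
flanking base repeats — are trimmed so that each event is carried
entirely by one segment. An anchor chain covering less than 50 % of the
shorter genome raises a "not colinear" error; a long unanchored segment
whose reverse complement re-anchors at ≥ 80 % coverage is emitted as a
flagged `inversion` record with breakpoint spans and no effect
classification (inversions are descriptive here; both study breakpoints
are intergenic).

Indels are reported left-normalised (shifted to their leftmost
equivalent placement), which makes counts deterministic in
homopolymer/repeat context — the ambiguity the underlying sequencing
technology is most prone to. Adjacent substituted bases within one codon
merge into a single multi-nucleotide record, matching amino-acid-level
counting in the curated tables. Effects are classified under the
bacterial/plastid genetic code (translation table 11), standard for
land-plant plastomes: `synonymous` iff all affected codons translate
identically; indels are `inframe_indel` when the length change is a
multiple of 3, else `frameshift`; events disrupting the annotated start
codon are `start_loss`; substitutions turning the stop codon into a
sense codon are `stop_loss_extension`; everything outside CDS is
`noncoding`.

The candidate funnel is deliberately simple and fully auditable:
`pattern_filter()` keeps variants present in *all*
incompatible-cytoplasm accessions and absent from *all* compatible ones;
`funnel_summary()` partitions them into noncoding / synonymous /
non-synonymous / indel bins (a conservation invariant checked in the
tests); `nominate_loci()` drops the first two bins and ranks loci by
non-synonymous-plus-indel burden, ties broken alphabetically.

### Coordinate convention

All coordinates are 1-based inclusive, both internally and in every
report and TSV. This is the native R/Bioconductor convention (IRanges,
GFF3) and identical to the reporting frame of the curated tables;
keeping one frame removes an error-prone conversion layer. Insertions
use an empty span: `ref_start = p + 1`, `ref_end = p` for an insertion
between reference positions `p` and `p + 1`.

## Protein analysis

`derive_protein()` translates an annotated CDS and models two observed
rescue modes. If the annotated start codon is disrupted, the first
in-frame `ATG` within 60 codons downstream is used
(`start_mode = "alternative_downstream"`); the scan accepts only `ATG`
because the attested alternative product in this system begins at a
downstream `ATG` (11 codons in), and non-`ATG` starts are unattested
here — 60 codons is a generous cap around that observation. If the stop
codon is disrupted, translation extends into downstream genomic sequence
to the next in-frame stop (`readthrough = TRUE`).

`align_proteins()` is a centre-star progressive alignment: every
sequence is aligned to the first (reference) by global Needleman-Wunsch
with BLOSUM62 and affine gaps (open 10, extend 0.5), and the pairwise
alignments are merged on the reference coordinate frame. Insertions made
by different sequences at the same reference position share
left-justified columns, so independent insertions of different residues
at one position occupy one column, as in the curated tables. The result
is deterministic for a fixed input order; the panel order
(WL1238, JI1794, 721, L100, VIR320) is fixed by convention.

`variable_position_table()` reports differences from the reference in
*alignment-column* coordinates — the frame in which the curated tables
are written — merging adjacent columns into one row only when they share
the difference kind and the exact occurrence set of accessions. That
rule reproduces the published row structure: a two-residue replacement
carried by the same accessions becomes one `SD>IH` row, while adjacent
deletion columns with different carriers stay separate rows. Gap runs
touching the alignment termini are classed as terminal
absence/addition. `exclusive_differences()` selects rows whose
occurrence set equals a target accession set exactly.

### Reconstructed reference profiles

The two bundled variation tables (610-column *accD* frame, 290-column
*Bccp3* frame) are TSV encodings of the published rows. The full-length
underlying sequences are not available in machine-readable form, so the
reference profiles behind `reconstruct_alignment()` are synthetic: every
residue named in a table row, the tandem ISDTND hexapeptide block
(columns 124–135), a second ISDTND copy at 151–156, the zinc-finger
cysteines (columns 228/231/247/250, spacing CX₂CX₁₅CX₂C around the
E→R change at column 240), and the poly-E run at 396–398 sit at their
tabulated columns; all other positions carry deterministic filler drawn
from a fixed-seed stream over an alphabet excluding C and E (so no
accidental cysteine motifs or poly-E runs can arise). Everything the
package asserts about these fixtures — 19 variable positions and 80
indel columns in 610; the exclusive set of 7 replaced residues plus
deletions of 8, 1 and 3 residues; 9 variable positions, no indels and 4
biotinyl-domain exclusives in 290; the 590-residue reference product;
poly-E lengths 3/3/3/4/6 — is recomputed from the profiles, not assumed.
The 290-column *Bccp3* frame itself is fixed by convention, since it is
not derivable from the table rows alone.

Two published counting conventions coexist deliberately: the funnel
counts *variant records* (8 *accD* amino-acid substitutions), while the
exclusive-difference summary counts *replaced residues* (7). Both are
kept with their own operational definitions; they are not forced to
agree. Likewise the printed indel-size list treats the adjacent
31- and 3-residue deletions as one 34-residue event for the accessions
carrying both; the package keeps them as separate rows (their carriers
differ) and uses the 80-column total as the normative check.

### Repeats and motifs

`find_tandem_repeats()` reports maximal periodicity runs with at least
two complete copies for every unit length: overlapping arrays of
different unit lengths are all reported; phase-shifted sub-arrays of the
same unit length are not. The test suite pins it to an independent
brute-force oracle over every (start, unit-length) pair on strings up to
length 30. `poly_run()` returns the leftmost maximal homopolymer run;
`scan_zinc_finger()` matches the fixed-spacing motif with a
lookahead regex so overlapping matches are all found.

## Counterpart search

The partner table is a curated static asset (YAML): the reasoning step
it supports is a lookup, not a computation, and a static asset keeps the
package network-free. "Hypothetical protein" detection and keyword
matching are case-insensitive literal substring tests, matching the
counting basis of the published totals. The syntenic gene-interval table
is generated (`sim_gene_interval_table()`), not shipped: the published
supplement is not machine-readable, so only the landmark genes (the
bordering phospholipase C and NSP2 genes, the BCCP gene, the chloroplast
lumen family protein, and the holocarboxylase synthetase *hcs2* at its
published 534,541 bp distance from BCCP), the interval ends and the
counts (166 genes, 70 hypothetical) are faithful; positions and the
remaining product descriptions are synthetic and labelled as such. The
published interval width in bp is not arithmetically reproducible from
the published end coordinates and is therefore not asserted anywhere.

## RIL linkage

F6 recombinant inbred lines are effectively homozygous; residual
heterozygotes are coded missing, and missing entries are excluded
pairwise. The observed recombinant fraction `R` between two loci
converts to the per-meiosis fraction by the Haldane-Waddington relation
for selfing RILs, `r = R / (2 − 2R)`, and to centimorgans by the Haldane
map function `d = −50 ln(1 − 2r)`. Three-point ordering minimises
apparent double recombinants and *flags* ties as ambiguous rather than
breaking them silently — the placement claim the package makes is
mapping-function-independent, which is why a minimal parsimony ordering
suffices and no multipoint likelihood machinery is included. The bundled
88-line population encodes the published crossover structure exactly
(five crossovers between the flanking markers, split 3 : 2 around the
middle locus, with phenotype cosegregation in all 88 lines); its
parental-line split (42 : 41) and line orientations are arbitrary,
fixed constants that no statistic depends on.

The stochastic generator draws each line's first-locus genotype
uniformly and recombines each interval independently with probability
`R = 2r/(1 + 2r)` — the fixation probability of a recombinant chromosome
under repeated selfing. It deliberately omits interference and
segregation distortion.

## The compatibility rule engine

Each accession carries four booleans: primary/secondary determinant in
the plastid *accD* product (`cyt_primary`, `cyt_secondary`) and the
fitted binding site for each in nuclear products (`nuc_bind_primary`,
`nuc_bind_secondary`). Prediction follows a strict rule order — primary
determinant decides first (compatible iff the primary binding site is
present); otherwise the secondary pair decides; with neither determinant
the cross is compatible, except that a *vacant* secondary binding site
yields partial compatibility (reduced pollen fertility, no lethality).
Masking is structural: when the primary determinant is present the
secondary flags are inert, an invariant tested over the whole flag
space.

The vacancy rule is applied uniformly, including to the one cross whose
published class does not disambiguate it (721 cytoplasm × VIR320
nucleus): the engine returns `partial` there, a single consistent rule
being preferable to a per-case exception, and that cross is excluded
from every concordance check. Outcome granularity stays at three classes;
pollen-fertility percentages are not modelled.

Feature-to-flag derivation: `cyt_primary` means carrying the *complete*
exclusive change set of the incompatible cytoplasms — which individual
change is the physical determinant is unknown, so the all-of predicate
is an explicit convention, and an alternative secondary-determinant
predicate (poly-E run ≤ 3 instead of the ISDTND duplication) is exposed
as an option; on this panel both give the same assignment.
`nuc_bind_secondary` is a curated abstract label for the hypothesised
second nuclear locus (possibly the holocarboxylase synthetase gene): it
is deliberately never derived from the BCCP sequence, because one mRNA
cannot encode both binding sites at once.

`infer_states()` inverts the model: exhaustive search over the 16 flag
combinations per accession, organised as a constraint-satisfaction
problem over per-accession (cyt, bind) pairs (domains of four states,
arc-consistency pruning, backtracking enumeration of *all* solutions).
A flag is reported identifiable when it takes one value across every
solution. With no observations, all `16^n` assignments are trivially
consistent and the solution set is reported by count rather than
enumerated. Inconsistent observation sets return a minimal conflicting
subset found by deletion-based shrinking (minimal, not necessarily
minimum — sufficient for diagnosis at panel scale).

## Synthetic data: what it emulates, and what it does not

`sim_genome_panel()` builds a desk-scale annotated plastome
(alternating spacers and valid gene models, some intron-split, both
strands) and plants variants engineered to produce requested effect
classes, each checked to be stable under left-normalisation and
separated by ≥ 60 bp so that anchoring is clean and truth and calls can
be compared record-for-record. `pea_screen_config()` fixes the study
conditions: four wild accessions against a cultivated reference; 37
variants in the incompatible-cytoplasm pattern composed of 14
non-synonymous substitutions and 3 indels across the four candidate loci
(8 + 3 in a 590-codon *accD*, 1 in *rpoB*, 3 in *ycf1*, 2 in *ycf2*),
5 synonymous substitutions in three further loci, and 15 noncoding
variants over 14 noncoding regions; plus 9 decoys in other presence
patterns that the funnel must reject. Genomes are ~15 kb — an order of
magnitude below a real plastome but large enough for unique-k-mer
anchoring, keeping the full suite fast.

What passing these tests shows: the calling, classification, funnel,
linkage and inference machinery is internally correct and exactly
recovers known truth under clean, colinear, desk-scale conditions. What
it does not show: robustness to read-level sequencing error,
homopolymer miscalls, assembly gaps inside variants, structural
complexity beyond one inversion, or reference-annotation errors — real
data concerns that are out of scope by design (the pipeline consumes
assembled genomes and difference lists, not reads).

## Numerical choices and degenerate inputs

* Anchor `k = 21`: long enough for uniqueness in tens-of-kb genomes,
  short enough to re-anchor between variants ≥ 60 bp apart.
* Gap penalties: nucleotide NW 5/2 keeps desk-scale indels compact;
  protein NW 10/0.5 (BLOSUM62) is the conventional affine setting.
* Ties: gap placement follows the deterministic pairwise aligner;
  insertion blocks are left-justified; ordering ties in `order_three()`
  and locus ties in `nominate_loci()` are flagged/alphabetical, never
  silent.
* Degenerate inputs: empty variant sets, single-sequence alignments,
  repeat-free strings, absent residues, all-identical RIL columns and
  empty outcome lists all return well-defined empty/flagged results
  (tested), not errors; genuinely unusable inputs (multi-record FASTA,
  out-of-bounds features, unanchorable gaps, inverted intervals,
  overlapping exclusivity sets, unresolved determinant flags) raise
  informative errors.
* De novo progressive alignment of the reconstructed *accD* products can
  legitimately float an indel within repeat context (either copy of a
  tandem duplication may be gapped). Exact-column assertions therefore
  run on the fixture-reconstructed alignment, while the de novo path is
  asserted on placement-invariant properties (degapped identity,
  variable-position and indel-column counts, alignment length).

## Problem sizes

The shipped configuration uses ~15 kb genome panels (five accessions,
46 planted variants), 88-line RIL fixtures plus 10,000-line stochastic
populations for recombination-fraction recovery, 100 forward-simulated
cross panels of 4–6 accessions for inference recovery, and brute-force
repeat oracles on strings up to length 30. These sizes were chosen so
that every claim is recomputed from scratch on each run while the whole
suite stays in the tens of seconds.

## Known limitations

* Variant calling assumes colinear, assembled genomes; it is not a read
  mapper and does not model sequencing error.
* Circular genomes are handled linearised at the reference origin;
  features spanning the origin are unsupported.
* The compatibility model is qualitative by construction; it cannot
  score degrees of pollen fertility.
* The syntenic interval table is synthetic apart from its landmark
  genes and counts; conclusions about specific non-landmark genes in it
  would be meaningless.
* Identifiability from small cross panels is inherently partial; flags
  masked by the rule structure (e.g. the secondary determinant of a
  primary-carrying cytoplasm) remain free no matter how many crosses are
  observed.
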