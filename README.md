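# plastidcompat

Candidate-gene screening for plastid-nuclear incompatibility in pea
(*Pisum sativum*).

Crosses between cultivated peas and their wild relatives frequently fail
through nuclear-cytoplasmic conflict: certain wild cytoplasms are lethal
or semi-lethal in combination with the cultivated nuclear allele of the
*Scs1* locus. `plastidcompat` implements the complete computational route
from whole-plastome comparison to candidate incompatibility genes for a
panel of five accessions (the cultivated tester WL1238 and the wild
accessions JI1794, 721, L100, VIR320):

1. **Variant screening** — anchor-based pairwise plastome comparison,
   left-normalised variant records, coding-effect classification under
   the plastid genetic code (translation table 11), and the
   phenotype-pattern funnel: keep variants present in every
   incompatible-cytoplasm accession and absent from every compatible one,
   dismiss noncoding and synonymous changes, rank loci by
   non-synonymous + indel burden.
2. **Protein analysis** — derived-protein construction (alternative
   downstream starts, stop read-through), progressive BLOSUM62 alignment,
   variable-position tables in alignment coordinates, the
   exclusive-difference filter, tandem-repeat / poly-E / zinc-finger
   (CX₂CX₁₅CX₂C) annotation.
3. **Counterpart search** — curated multi-subunit-complex partners of
   plastid loci (for *accD*: the nuclear ACCase subunits) and keyword
   filtering of a syntenic *Medicago truncatula* gene-interval table.
4. **Linkage** — recombinant counting in an F6 RIL population with the
   Haldane-Waddington correction `r = R / (2 − 2R)`, Haldane map
   distances, three-point ordering by double-recombinant minimisation,
   and marker-phenotype cosegregation.
5. **Compatibility model** — the primary/secondary determinant rule
   engine: a cytoplasm carrying the primary determinant is compatible
   only with nuclei carrying the fitted primary binding site; otherwise
   the secondary determinant and its binding site decide; a vacant
   secondary binding site over a determinant-free cytoplasm gives
   partial compatibility (reduced pollen fertility). `infer_states()`
   inverts the model, enumerating all determinant assignments consistent
   with observed crosses and reporting per-flag identifiability.
6. **Synthetic data** — seeded generators for every input: plastome
   panels with planted variants and known truth, RIL populations
   (stochastic or fixed crossover patterns), and cross-outcome panels.

## Worked example

```r
library(plastidcompat)

# seeded plastome panel emulating the five-accession study design
panel <- sim_genome_panel(pea_screen_config(seed = 1))
calls <- lapply(panel$genomes, function(g) align_and_call(panel$reference, g))
pm    <- build_presence_matrix(calls, panel$reference$id, panel$phenotypes)
filt  <- pattern_filter(pm)
unlist(funnel_summary(filt))
#>  n_total  n_noncoding  n_noncoding_regions  n_coding_loci  n_synonymous
#>       37           15                   14              7             5
#>  n_nonsyn_substitutions  n_indels
#>                      14         3
nominate_loci(filt)
#>   locus n_nonsyn_substitutions n_indels
#> 1  accD                      8        3
#> 2  ycf1                      3        0
#> 3  ycf2                      2        0
#> 4  rpoB                      1        0
```

37 phenotype-pattern variants funnel down to four candidate loci with
*accD* on top (8 amino-acid substitutions + 3 indels), exactly the
published screening outcome. The bundled curated tables then localise the
determinants:

```r
ex <- exclusive_differences(accd_variation_table(), c("VIR320", "L100"))
variation_summary(ex)[c("n_replaced_residues", "deletion_sizes")]
#> $n_replaced_residues   # 7 replacements exclusive to the
#> [1] 7                  # incompatible cytoplasms
#> $deletion_sizes
#> [1] 8 1 3              # plus deletions of 8, 1 and 3 residues

exclusive_differences(bccp3_variation_table(), c("VIR320", "L100"))$start
#> [1] 211 252 254 279    # all four in the biotinyl domain

ril <- pea_ril_table()
order_three(ril, "PhlC", "Bccp3", "AJ832139")$order
#> [1] "PhlC"     "Bccp3"    "AJ832139"

forward_panel(pea_determinant_panel())   # 25 directed cross predictions
infer_states(pea_cross_outcomes(include_selfs = TRUE))
#> <compat_inference> 4 consistent assignment(s)
#> (all flags fixed except the masked cyt_secondary of VIR320 and L100)
```

A one-shot orchestration with per-stage TSVs and a Markdown summary:

```r
run_pipeline(run_config(seed = 1), "out/")
```

or from a shell, `Rscript inst/scripts/plastidcompat-run.R --out out/`.

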