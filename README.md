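# mhcvar

Sequence characterization of MHC class I peptide-binding domains in R:
per-site variability, anchor-residue conservation, and Poisson-corrected
neighbor-joining phylogenetics with bootstrap-based lineage assignment.

## The problem

The α1 and α2 domains of MHC class I heavy chains (exons 2 and 3, typically
87 and 93 residues in teleost fish) form the peptide-binding groove. When a
new set of MHC-I sequences is obtained from a species — for example by
amplifying and sequencing the α1/α2 region from a panel of individual fish —
the standard characterization questions are:

1. **How variable is each alignment position?** The variability metric of a
   column is its Shannon entropy over amino-acid types,

   *V* = −Σᵢ Pᵢ log₂ Pᵢ,

   where Pᵢ is the fraction of residues of type *i* and the sum runs over
   the *M* types observed at that column. *V* = 0 at a fully conserved
   column and reaches log₂(n) when all n sequences differ (log₂ 13 ≈ 3.70
   for 13 sequences). Sites with *V* > 1 are called highly polymorphic.
2. **How different are the sequences overall?** Pairwise percent-difference
   matrices per domain, with min/max/mean ± s.e.m. summaries.
3. **Is the peptide-binding machinery intact?** The eight groove anchor
   residues that bind the peptide's N- and C-termini — positions 7, 59, 84,
   143, 146, 147, 159, 171 in HLA-A2 numbering — are audited per sequence
   (YYYYYTKW in mammals; teleosts carry R rather than Y at position 84).
4. **Which lineage do the sequences belong to?** Teleost MHC-I falls into
   six lineages (U, Z, S, L, P, H; U carries the classical
   antigen-presentation function). A neighbor-joining tree on
   Poisson-corrected distances, d = −ln(1 − p), with Felsenstein bootstrap
   (column resampling, 1000 replicates) places query sequences into
   reference lineage clades.

`mhcvar` implements all four steps on pre-aligned amino-acid FASTA input,
plus CDS translation, Newick/TSV output, a one-call pipeline, and a
synthetic sequence-family simulator with known truth (realized tree,
lineage labels, exact per-site entropies) so every stage is testable
without external data.

## Worked example

```r
library(mhcvar)

octet <- c(`7`="Y", `59`="Y", `84`="R", `143`="T", `146`="K", `147`="W",
           `159`="Y", `171`="Y")
sim <- simulate_family(n_lineages = 3, seqs_per_lineage = 4,
                       rate_within = 0.05, divergence_between = 0.5,
                       anchor_columns = octet, seed = 42)

prof <- profile_alignment(sim$alignment, "alpha2")
attr(prof, "n_polymorphic")
#> polymorphic sites in alpha2: 27

s <- summarize_differences(pairwise_difference_matrix(sim$alignment, "alpha1"))
#> alpha1 pairwise differences: 0.00-48.28%, mean 34.81 +/- 2.21%

map <- build_reference_map(sim$alignment, ref_id = "U1", start_position = 1)
head(check_residues(sim$alignment, map, anchor_scheme("fish"))$per_seq, 3)
#>  seq_id n_anchor n_anchor_matched
#>      U4        8                8
#>      U2        8                8
#>      U1        8                8

tree <- bootstrap_support(sim$alignment, replicates = 500, seed = 42)
refs <- sim$truth$lineages[!names(sim$truth$lineages) %in% c("U1", "Z1")]
assign_lineage(tree, refs, c("U1", "Z1"))
#>  query lineage support
#>     U1       U     100
#>     Z1       Z     100
```

The 27 polymorphic α2 sites are those whose entropy exceeds 1 bit under
the simulation's within/between-lineage divergence; the pairwise range
spans 0% (identical lineage-mates under low within-lineage divergence) to
~48% (across lineages); all sequences retain the full anchor octet because
the simulator never mutates anchor columns; and both held-out queries are
returned to their true lineages with 100% bootstrap support.

For a full run writing TSV/Newick reports, see `?run_pipeline` and the
wrapper `inst/scripts/run_pipeline.R`; the methods vignette
(`vignettes/mhcvar-methods.Rmd`) documents the models, parameter choices
and limitations.

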