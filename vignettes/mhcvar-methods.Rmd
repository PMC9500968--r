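---
title: "Methods: variability, conservation and lineage phylogenetics for MHC-I domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variability, conservation and lineage phylogenetics for MHC-I domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcvar)
```

`mhcvar` characterizes aligned amino-acid families of MHC class I
peptide-binding domains. This vignette documents the models it implements,
the conventions chosen where the underlying methods leave room, and what
its synthetic-data tests do and do not demonstrate.

## Per-site variability

The variability of an alignment column is its Shannon entropy over
amino-acid types, $V = -\sum_{i=1}^{M} P_i \log_2 P_i$ (bits), where $P_i$
is the fraction of residues of type $i$ among the counted residues and $M$
the number of observed types. $V$ is 0 at a fully conserved column and at
most $\log_2 \min(20, n)$ for $n$ counted residues.

Conventions:

* **Gaps and `X` are not amino-acid types.** They are excluded from the
  counts; the fractions $P_i$ are renormalized over the remaining
  residues. A column with no residue left is reported as "no data"
  (`V = NA`) rather than `V = 0` — an all-gap column is not evidence of
  conservation — and is excluded from polymorphic-site counting.
* **Polymorphic calling is strict:** a site is highly polymorphic iff
  `V > threshold`, default 1 bit. A two-type equifrequent column sits at
  exactly 1 bit and is therefore *not* called. The count of polymorphic
  sites is monotone non-increasing in the threshold.
* Tables report `V` both raw (6 decimals) and rounded to 2 decimals.

Pairwise differences are percent of differing residues over compared
columns. The default deletion policy for these matrices is **pairwise**
(each pair keeps every column where neither member has a gap or `X`),
matching how interactive pairwise alignment viewers compare two rows;
complete deletion is available by argument. The mean ± s.e.m. summary is
computed over the $n(n-1)/2$ unique unordered pairs — not the full
redundant matrix, which would halve the apparent standard error. With a
single pair the s.e.m. is undefined and reported as 0 with a warning so
that tiny inputs still produce a complete report.

## Conservation auditing

Reports use reference numbering (HLA-A2 mature-protein positions in the
shipped schemes) rather than raw alignment columns. The mapping is derived
from a user-designated reference row: its $k$-th non-gap residue maps to
`start_position + k − 1`, and columns where the reference is gapped are
unmapped. Anchoring numbering on a data row rather than a hard-coded
HLA-A2 sequence keeps the audit applicable to synthetic or non-human data;
for real analyses the user supplies the HLA-A2-style row present in their
alignment.

Two anchor-octet schemes ship with the package: `anchor_scheme("mammal")`
(Y7, Y59, Y84, T143, K146, W147, Y159, Y171 — the octet YYYYYTKW) and
`anchor_scheme("fish")`, identical except that position 84 is R, the
teleost/shark state. The fish octet is sometimes written YYYRFTKW; the F
in that string has no stated position within the octet list above, so the
shipped fish scheme changes only position 84 and leaves the F
uninterpreted — users who know its position can supply their own scheme.
Broader conserved-residue categories (residues predating the class I/II
split; residues common to classical MHC-I) are figure-level annotations
with no enumerable rule, so they are loaded from user-editable TSV files
rather than hard-coded. A gap at a scheme position is a non-match but is
reported with its own status (`"gap"`), and scheme positions outside the
reference map are reported `"unmappable"` rather than dropped.

## Distances, trees and bootstrap

Protein distances are p-distances (fraction of differing residues over
compared columns) with the Poisson correction
$d = -\ln(1 - p)$ substitutions per site, which inverts the expected
fraction of sites hit by at least one substitution event under a Poisson
process. The correction assumes no rate heterogeneity across sites and
ignores multiple hits' identity (a site once substituted stays different);
it saturates at $p = 1$, where the distance is undefined and an error is
raised rather than an infinity propagated.

For tree building the default deletion policy is **complete**: every
column with a gap or `X` in any sequence is removed first, so all pairs
are measured on one shared column set, which is how standard phylogenetics
software arrives at a single "positions in the final dataset" count.
Pairwise deletion remains available.

The neighbor-joining implementation is the classic Saitou–Nei
agglomeration. Conventions where the algorithm itself is silent:

* **Negative branch lengths are clamped to 0** with no transfer to the
  adjacent edge — the simplest defensible convention, and the clamping
  never affects additive input (where NJ is exact; the package's tests
  verify exact topology and path-length recovery against enumeration).
* **Q-matrix ties break to the lowest (row, column) pair** in input order,
  making the output deterministic.
* A 2-taxon input yields the single edge split at its midpoint.
* The last three clusters are joined at one internal node by the
  three-point closed form, giving the standard unrooted basal
  trifurcation.

Bootstrap support follows Felsenstein: columns are resampled with
replacement (same length per replicate, default 1000 replicates), the
distance matrix and NJ tree are recomputed, and each internal edge of the
original tree is annotated with the percentage of replicate trees
containing the same bipartition, rounded to the nearest integer. The seed
is a required argument — there is no silent default, so every tree is
reproducible. Complete deletion, when selected, is applied after
resampling, per replicate. A replicate whose resampled columns saturate a
pair ($p \ge 1$) or leave a pair with no comparable column is discarded
and counted; if more than 10% of replicates are discarded the run aborts
with a diagnostic, since the remaining supports would not be trustworthy.
Sequences are ordered canonically before resampling, so supports are
invariant to input leaf order.

## Lineage assignment

Query sequences are assigned to the lineage of their smallest surrounding
reference clade: among all bipartition sides of the tree containing the
query and at least one reference leaf, the smallest side is taken (ties
broken toward higher bootstrap support); if all references in it share one
lineage label the query is assigned that lineage along with the side's
support, otherwise it is `unassigned`. Assignment operates on the
bootstrap-annotated NJ tree; no maximum-likelihood confirmation tree is
built.

## The synthetic-data generator

`make_variability_fixture()` produces alignments whose per-site entropy is
known *exactly*: unspecified columns are constant and each specified
column carries $k$ residue types at exactly equal frequency
($V = \log_2 k$), which requires $k$ to divide the number of sequences —
an indivisible request is an error rather than an approximation.

`simulate_family()` emulates the shape of an MHC-I domain study: by
default 87 + 93 residue domains (the α1/α2 exon sizes), several lineages
named after the teleost MHC-I lineages (U, Z, S, L, P, H) diverging from a
common ancestor, and a coalescent-shaped random tree within each lineage.
Substitution is a Poisson process, uniform among the 19 alternative
residues, with no rate heterogeneity — deliberately the model that the
downstream Poisson correction assumes, so parameter-recovery tests are
self-consistent. Two conventions fix the rate parameters: each lineage
root sits `divergence_between / 2` from the ancestor (so two roots are
separated by `divergence_between` expected substitutions per site), and
within-lineage coalescent trees are rescaled so root-to-tip height equals
`rate_within`. Anchor columns are never mutated, mirroring the conserved
groove anchors. No indels are simulated — gap handling is exercised with
hand-built fixtures instead — so the emitted truth (tree, lineage labels,
anchor states) is exact.

Because replacement is uniform among the *other* 19 residues, back- and
parallel substitutions occur, and $-\ln(1-\hat p)$ slightly underestimates
large simulated divergences (the 20-state correction would multiply both
sides by 19/20). The package's recovery tests therefore validate the
correction against the Poisson difference model it exactly inverts (a site
differs iff at least one event hit it), and validate the simulator
separately by monotonicity: larger simulated divergence never yields a
smaller expected p-distance.

What passing tests on synthetic data do **not** show: real MHC alignments
have indels (the simulator emits none), strong among-site rate
heterogeneity (peptide-contact positions evolve under diversifying
selection), non-uniform exchangeabilities (JTT/WAG-like), and recombinant
or trans-species allele sharing — all of which can distort distances and
supports in ways the uniform Poisson model cannot produce.

## Pipeline and reproducibility

`run_pipeline()` composes the stages per domain (variability profile,
percent-difference matrix and summary, Poisson distance matrix,
bootstrap-annotated NJ tree, lineage calls) plus a whole-alignment
conservation report, under a single validated configuration (in code or
YAML). Domain boundaries in configurations and reports are 1-based
inclusive — the biological convention — while all internal arithmetic uses
0-based half-open intervals. Outputs are TSV and Newick with fixed numeric
formatting (6 decimals; Newick branch lengths likewise), so identical
configuration + seed reproduces identical bytes; the run log records the
configuration hash, seed, package version and stage timings. Any stage
error aborts the run, names the stage, and removes partial outputs.
Translation of coding sequences uses the standard genetic code with the
Transeq conventions: stops emitted as `*`, codons containing `N` as `X`,
reading frame an explicit argument (never guessed from the data).

## Problem sizes in the test suite

The suite validates NJ on 200 random additive matrices of 4–8 taxa
(with exhaustive least-squares topology enumeration as the oracle up to 6
taxa, where 105 topologies make enumeration cheap), Poisson recovery at
divergences 0.1/0.3/0.6 over 10,000 sites × 50 replicates, bootstrap
behaviour at 1000 replicates on 4-taxon splits, and lineage recovery on a
3-lineage × 6-sequence simulation (between-lineage divergence 0.5, within
0.05) with 200-replicate bootstrap — sizes chosen to exercise every code
path at study-like scale while keeping the default test run fast.

## Known limitations

* Multiple sequence alignment is out of scope: input must be pre-aligned.
* Only the standard genetic code is supported for translation.
* No maximum-likelihood tree, rooting, or molecular-clock machinery.
* The Poisson correction has no multiple-hit identity model or rate
  heterogeneity; for deep divergences a JTT/WAG ML analysis is the
  appropriate confirmation, outside this package.
* Lineage assignment is purely topological; it does not test whether the
  assignment's support is statistically adequate.
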