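---
title: "Rep-gene genotyping of AAV: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rep-gene genotyping of AAV: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavgenotyper)
```

## The problem

Adeno-associated virus (species *AAV A*) has historically been subdivided
into serotypes, a category that mixes serological, genetic and phylogenetic
evidence and is not robust: cross-reactivity is common and most newly
deposited genomes are never typed serologically. A distance-based genotype
definition fixes this, but only if a genome region can be found whose
pairwise distances are not scrambled by recombination. AAV recombines
pervasively; the usable signal is that recombination in the *rep* gene
stays **within** deep lineages while the *cap* gene recombines **between**
them. This package implements both halves of the argument: the
recombination diagnostics that locate the quiet region, and the threshold
classification built on it.

## Distances

All distances are raw p-distances: the proportion of differing sites among
*comparable* sites, where a site counts as comparable for a pair only when
both sequences carry an unambiguous residue (`A/C/G/T` for nucleotides, the
20 standard amino acids for proteins). Gaps, `N`/`X` and IUPAC ambiguity
codes are excluded **per pair** (pairwise deletion), which maximizes the
data used and is the common default for p-distances; published distance
tables to 2 decimals are insensitive to the deletion policy, but the choice
is stated here because exact reproduction of printed tables depends on it.
No evolutionary-model correction (Jukes–Cantor etc.) is applied: the
genotype threshold is defined on raw proportions, and at the ≤ 20%
divergences involved the distinction is immaterial for classification.
Pairs with zero comparable sites are stored as missing (`NA`), never as 0,
and are excluded downstream with a logged message.

## Recombination diagnostics

**PDCP.** For two genome regions, every sequence pair contributes a point
(d in region A, d in region B). Without recombination between the regions
the points fall near a line; segment exchange moves individual pairs off
it. The summary statistic is the root-mean-square error of the points
around the ordinary least-squares regression of `d_B` on `d_A`. OLS is
directional, so for symmetric uses (the PDDM grid) the two directed RMSEs
are averaged; `pdcp()` itself reports the directed fit and keeps per-pair
identities so outlying pairs can be inspected. A regression on points with
zero variance in `d_A` is degenerate; it is flagged (slope 0, intercept
`mean(d_B)`), never silently zeroed.

**PDDM.** The PDCP RMSE for all pairs of sliding windows (default 500 nt,
step 250 — half-overlap resolves the block structure at 103-sequence scale;
the step is a tunable because tools in this family leave it to the user).
Windows start at columns 1, 1+step, …; trailing partial windows are
discarded, but a final full window anchored at the last column is added
when the stride would leave the alignment tail uncovered, so the scan
always covers the 3' end where *cap* recombination concentrates.
`low_recombination_span()` turns the visual "quiet block" reading of a PDDM
heatmap into an explicit rule: windows whose mean RMSE against all other
windows falls strictly below a quantile (default 0.25) of all window means
are low-recombination; the longest contiguous run (earliest on ties) is
merged into one region.

**Similarity scans.** Simplot-style: per full window (default 1000 nt,
step 40), similarity of a query to each panel sequence is `1 − p-distance`
over the window's comparable sites, `NA` where none are comparable. Window
count follows the standard `floor((L − window)/step) + 1` convention with
no tail snapping, matching the similarity-plot tools this mirrors.

**Negative control.** The even- and odd-numbered columns of any region
share one evolutionary history, so their PDCP separates pure sampling noise
from recombination signal. On a simulated clonal, recombination-free
population (single lineage, 103 members) the even/odd RMSE of the rep
region is ≈ 0.008–0.009 — the noise floor against which the rep-vs-cap RMSE
(≈ 0.025 on default simulations) is judged.

## Classification

Two sequences belong to the same genotype when they differ by **less than
10%** of rep nucleotides; a pair at exactly 0.10 is between-genotype
(strict inequality, matching the "less than 10%" rule). Genotypes are the
connected components of the graph with an edge per sub-threshold pair —
single linkage, chosen because the definition is pairwise. Single linkage
can chain; any same-cluster pair at or above the threshold is therefore
reported in `violations` rather than hidden. On real AAV A data the
distance distribution has an empty gap (0.075–0.11), so no violations
occur and the threshold is robust to its exact placement; the package
reports `within_max` and between-cluster minima so users can verify the
gap on their own data.

The nt/aa **cloud partition** formalizes the two-cloud structure of the
rep distance scatter: low cloud at nt ≤ 0.075 and aa ≤ 0.08, high cloud at
nt > 0.11 and aa > 0.06, the remainder unassigned. The clouds overlap on
the amino-acid axis (within-genotype aa distances reach 7.5% while
between-genotype start at 5.5%), which is why the nucleotide sequence, not
the protein, carries the classification.

**Assignment** of a query computes its minimum distance to each cluster
and assigns the unique cluster below threshold; none → `"novel"`, two or
more → flagged ambiguous with no assignment, since an ambiguous query is
evidence of either chaining or a recombinant and deserves inspection.

Cluster numbering is by order of first appearance in the input. With the
serotype reference table, anchor serotypes map cluster numbers to the
conventional genotype names (AAV1 → genotype 1, AAV2 → 2, AAV3 → 3,
AAV12 → 4).

One printed-value caveat: from the published 11-serotype table, the
genotype 2 vs genotype 3 range computes to the point value 0.14 (all three
relevant cells print 0.14), while the published range table shows
0.14–0.15 — presumably rounding of unrounded internal values. The package
reproduces ranges from its input distances; the tests document this single
cell as not derivable from the printed matrix.

## Trees

`neighbor_joining()` is a standard Q-criterion NJ with the usual
branch-length formulas, exact on additive matrices. Two choices are
deliberate: ties in the Q minimization break at the lowest (row, column)
index pair, making output a deterministic function of input order (generic
NJ implementations leave this unspecified); and negative branch lengths
are clamped to zero with a count attached, the common display convention.
Outgroup placement (e.g. an *AAV B* genome) is display-level rooting via
`ape::root()`; the algorithm itself is unrooted. Newick serialization
quotes labels containing reserved characters and round-trips through
`read_newick()`.

## The simulator

`simulate_population()` generates the statistical structure the analysis
assumes, so every stage is testable without downloads:

1. a uniform-random root genome (default 4400 nt — the rep+cap coding
   region scale at which near-complete AAV genomes align);
2. genotype ancestors by independent per-site substitution at rate
   `q = (3/4)(1 − sqrt(1 − 4D/3))` so that ancestor pairs sit at the
   target divergence `D` (the expected-overlap correction for mutations on
   both lineages; substitutions go to one of the 3 alternative bases
   uniformly);
3. clade members by per-site substitution at `within_divergence / 2` from
   their ancestor;
4. Poisson-count segment-copy recombination — a contiguous segment between
   two uniform breakpoints is copied from a donor — confined to
   same-genotype donors in the rep region (rate 1.0 events/sequence) and
   open to any donor in the cap region (rate 0.5).

Defaults mirror the natural AAV A population: 4 genotypes of 30/40/20/13
sequences (103 total), between-genotype divergence 0.13 (the middle of the
observed 0.11–0.16 between-genotype range), within-genotype 0.05 (inside
the ≤ 0.075 within-cloud). All randomness derives from one seed;
identical configurations give byte-identical output.

What the simulator does **not** emulate: coalescent genealogy within
clades (members radiate independently from the ancestor), indels and
alignment error (output is gap-free; the distances are gap-insensitive
under pairwise deletion anyway), rate heterogeneity, selection, and
back-substitution saturation. Passing recovery tests on this generator
therefore shows the pipeline is correct under the assumed cluster
structure — it does not show that real AAV data satisfies those
assumptions; that evidence comes from the empty distance gap and the PDDM
structure on real alignments.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere user-facing; headers are
  truncated at the first whitespace for ids; `U → T` and upper-casing on
  read.
* The reading-frame offset for translating an arbitrary region is a user
  input (default 0): alignment column numbering carries no frame
  information.
* Printed-table comparisons use the tables' 2-decimal precision.
* Missing distances: no edge in clustering (logged), omitted points in
  PDCP (count reported), an error in NJ (with instruction to impute or
  drop taxa — silent imputation would fabricate topology).
* Test problem sizes: recovery checks run 20 replicate populations of 103
  sequences; the clustering oracle sweeps 200 random matrices of ≤ 12
  labels; the full suite and the analysis of one 103 × 4400 alignment each
  complete in well under a minute on one core.

## Limitations

The 10% rule is calibrated on present-day AAV A diversity; more divergent
future taxa may need model-corrected distances and a re-derived threshold.
The package classifies by *rep* only and is a supplement to — not a
replacement for — capsid-based (VP1) typing, which governs tropism and
serology. Explicit recombination-event detection and breakpoint inference
(RDP-style method batteries, bootscanning) are out of scope; PDCP/PDDM
measure aggregate incongruence, not individual events.
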