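---
title: "Variability mapping of small-subunit rRNA alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variability mapping of small-subunit rRNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssuvar)
```

## The problem

18S rRNA is the classic deep-phylogeny marker, and for many invertebrate
groups it is the only marker with dense taxon sampling. Its information
content is structured: base-paired stems evolve slowly under pairing
constraints, loops faster, and nine homologous hypervariable regions
(V1–V9) faster still — with V6 the traditional exception. `ssuvar` turns an
aligned set of 18S sequences, a taxon-to-clade table and a V-region
coordinate table into a *variability map*: per-site relative rates,
distance summaries within and between clades, constant/variable site
counts partitioned by region, indel and deletion-motif characterization, a
nonparametric test battery for rate differences between structural
categories, and a protocol for transferring a core secondary structure
(with pseudoknots) onto exemplar sequences.

## Site rates from pattern congruence

The rate engine is an implementation of the TIGER idea: estimate relative
site rates *without a tree*, from the congruence of site patterns. Column
$i$ partitions the taxa scored at it into state sets (an ambiguity code
puts its taxon into every component state's set; `N`, terminal gaps, and —
by default — internal gaps drop the taxon from the site). The agreement
between columns $i$ and $j$ is

$$\mathrm{pa}(i,j) = \frac{\#\{A \in P_j : A\cap T_i \neq \emptyset
 \text{ and } A\cap T_i \subseteq S \text{ for some } S \in P_i\}}
 {\#\{A \in P_j : A\cap T_i \neq \emptyset\}},$$

and the rate of column $i$ is the mean of $\mathrm{pa}(i,j)$ over all
other columns passing the coverage threshold. Rates live in $[0,1]$:
constant columns are exactly 1 (their single state set contains every
scored taxon, so every restriction nests), and columns that conflict with
most of the alignment score low. Pairs where every restricted set of $j$
is empty are skipped and the denominator of the mean reduced.

Numerical and policy choices:

* **Agreement direction.** The *other* column's sets are tested for
  subset-hood against the focal column's sets. This is the convention that
  forces constant sites to 1, matching the "high value = slow" reading of
  published TIGER tables. The brute-force oracle in the test suite pins
  this convention down on 200 random alignments per run.
* **Internal gaps** are missing data, not a fifth state; a fifth-state
  mode (`gap_as_state = TRUE`) is available for sensitivity analysis.
  Terminal gap runs are treated as incomplete sequence everywhere in the
  package, not as indels.
* **Coverage threshold** (default 0.15): a column enters the analysis only
  if at least 15% of taxa carry an informative (non-gap, non-`N`)
  character; excluded columns take no part in either role, focal or
  comparison.
* **Complexity.** The double loop over column pairs is quadratic in
  alignment length; it runs in C++ on taxon bitsets (64 taxa per machine
  word), which completes ~2,000 columns × 200 taxa in seconds on one CPU.

`rolling_average()` (default window 35, centred, truncated at the ends,
undefined positions skipped) produces the familiar rate profile along the
molecule; `rate_histogram()` bins rates left-closed with an explicit
insufficient-coverage bin.

## Distances

`distance_matrix()` computes uncorrected p-distances under pairwise
deletion; ambiguity codes are treated as missing, so "overlap" means
shared unambiguous nucleotides — the conservative reading when undefined
distances are reported for non-overlapping pairs. GTR
maximum-likelihood distances maximize the pairwise likelihood
$\prod_{\text{sites}} \pi_a P_{ab}(t)$ with the transition matrix obtained
by eigendecomposition of the reversible rate matrix; the optimization is
one-dimensional in the branch length. Parameters are estimated **once** on
the whole alignment (empirical base frequencies; exchangeabilities by
maximizing the summed pairwise likelihood over a deterministic sample of
pairs, alternating with per-pair branch-length updates) and shared across
pairs: per-pair estimation from two sequences is unstable. With all rates
and frequencies equal, the ML distance collapses to the Jukes–Cantor
closed form $-\tfrac34\log(1-\tfrac43 p)$, which the test suite uses as an
oracle. Pairs that are saturated at the optimizer's upper bound are
flagged. Group summaries report mean ± SE (sample SD over defined pairs
divided by $\sqrt{n}$) with undefined pairs counted separately.

## Constant/variable classification and regions

A column is *constant* when some nucleotide state is consistent with
every informative character observed there (so `A` + `R` is constant,
`A` + `G` is not); gaps and `N` are excluded. Region tables give V1–V9 as
1-based inclusive (start, length) pairs; everything else pools as
"non-hypervariable". The bundled `rotifer_regions()` table carries the
V-region coordinates of the aligned rotifer 18S data set.

## Indels and the deletion window

An indel is a maximal gap run in one row relative to the group alignment.
Runs crossing a V-region boundary are split at the boundary so that the
identity *nucleotides + gapped columns = region length* holds exactly per
region (an "assign to majority region" mode was considered and rejected
because it breaks this conservation; the split keeps every table row
checkable). In the pooled non-hypervariable region, runs descending from
terminal gap spans are excluded.

The variably expressed deletion at the 3′ end of V3 is characterized over
a configurable window: by default the last 14 columns of V3 plus the
following 78 columns (92 in total), since the exact aligned coordinates
of the window are derived rather than printed. Motif classes are defined
by the *exact span coordinates* of the gap runs inside the window — not by
their lengths — so convergent equal-length deletions at different
positions are distinct classes.

## Structure transfer

The two-step protocol mirrors how a curated core structure is moved onto
new sequences when no program can fold pseudoknots and honour a partial
structure at once:

1. **Consensus constraint.** Positions consistently paired (same partner
   column) across ≥2 reference maps on a common backbone become forced
   pairs; consistently unpaired positions become `x`; disagreements stay
   unconstrained. All hypervariable regions, pseudoknots and other nested
   pairings are forced unpaired, folding initially as unresolved extended
   loops. Target-only insertions are unconstrained outside hypervariable
   regions and forced unpaired inside them. The constraint is projected
   through the target's gapped row; a pair whose partner is deleted
   degrades to unconstrained.
2. **Region folds and reassembly.** Each hypervariable region folds in
   isolation with a basal "bracket" stem of ≥2 forced pairs — taken from
   the adjacent real sequence where possible, from the region's own ends
   otherwise, or appended artificially (a `GGGG`/`CCCC` frame, removed
   afterwards) where neither is available. Region folds are spliced back
   into the core (collisions are errors, the primary layer must stay
   non-crossing), and pseudoknot pairings are transferred from a reference
   by homologous alignment position into a separate knot layer; pairings
   whose partner lands on a gap are reported, never silently dropped.

The shipped `reference_fold()` engine is a deterministic base-pair
maximizer (canonical pairs, minimum hairpin loop 3, ties broken toward
the 5′-most then shortest-range pair) honouring `x` always and forced
pairs on request; it keeps the suite hermetic and is proven equal to
exhaustive enumeration for short sequences. An adapter for an external
minimum-free-energy folder (`rnafold_engine()`) satisfies the same
contract for realistic folds; energies are out of scope, the structural
protocol is in scope. Nested pairings are treated identically to
pseudoknots (forced unpaired, then transferred), and both the knot
coordinate list and the artificial bracket sequence are configuration
inputs, not constants.

## The test battery

Five tests per data set, mirroring the usual reporting: Wilcoxon
signed-rank between the two rates of each paired position; Mann–Whitney
between collapsed stem rates (each pair contributes its single mean rate,
avoiding pseudoreplication) and loop rates; Pearson chi-square (no
continuity correction, df = 1) on constant/variable × region counts;
Mann–Whitney on rates in non-hypervariable versus pooled hypervariable
regions; Kruskal–Wallis across individual V regions plus the pooled
remainder. All p-values are two-sided from tie-corrected normal or
chi-square approximations with no continuity correction and no
multiple-testing adjustment; W and U are reported as the larger of the
two one-sided statistics, the convention that reproduces published
magnitudes. Only positions that can definitely be assigned paired or
unpaired from a structure map enter the stem/loop analyses.

## The simulator and what passing tests mean

`simulate_alignment()` evolves sequences under GTR down a star-of-crowns
tree: root → three clade ancestors (stem branch) → taxa (crown branch),
with continuous-time transition matrices from the eigendecomposition.
Defaults encode the study-like conditions: 3 × 20 taxa, 1,800 sites, 60%
invariant sites, remaining multipliers Gamma(2) with mean 1, a 3×
multiplier inside hypervariable regions covering roughly a third of the
molecule, crown length 0.02 (within-clade p ≈ 2.4%), stem length 0.32
(expected between-clade p ≈ 18%, inside the 17–22% band typical of the
system), short indels (mean length 1.5) concentrated in hypervariable
regions, and a 92-column deletion window whose motifs (20/35/50/68 bp,
anchored at the 3′ end) are carried by half of clade 1. Indels and
deletion motifs are injected *post hoc* on the true alignment, so truth
coordinates stay exact, and `truth_check()` compares realized
within/between distances against the *exact* expectation
$\frac{1}{S}\sum_s \left(1 - \sum_a \pi_a P_{aa}(m_s t)\right)$ rather
than a small-$t$ approximation.

What the simulator does **not** emulate: compensatory stem covariation,
among-lineage rate variation, alignment error, and region-dependent
invariant-site density (invariant sites are drawn uniformly, so the
simulated constant/variable × region contingency carries no built-in
effect — the rate-based tests are the powered ones). Passing recovery
tests therefore validates the estimators' mechanics under a clean
generating model, not robustness to real-data pathologies.

Problem sizes in the shipped tests were chosen to exercise every code
path at comfortable runtimes: oracle equivalence on 200 random alignments
up to 20 × 50 (rates) and 100 random sequences up to 12 nt (folding);
recovery on one 60-taxon × 1,800-site simulation, where the Spearman
correlation between the true multiplier and $1 - r_i$ reliably exceeds
0.9 (0.7 is the acceptance floor).

## Known limitations

* GTR distance means depend mildly on optimizer settings and the shared
  parameter estimate; equality with values computed by other programs is
  approximate (~1%), as their internal settings (rate heterogeneity,
  parameter sharing) are generally unprinted.
* Published per-dataset constant-site percentages computed on different
  denominators (all sites versus sufficiently covered sites) can differ
  by a point or two; the package reports counts over covered sites, which
  keeps *constant + variable = analysed columns* exact.
* The reference folding engine maximizes pair counts, not free energy;
  use the external-engine adapter when thermodynamic realism matters.
* Subset data sets are produced by row subsetting (dropping all-gap
  columns only for alignment-level statistics), never by re-alignment, so
  subset aligned lengths need not match lengths obtained by re-aligning.
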