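---
title: "Methods: SHAPE-directed pseudoknot structure and dimerization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SHAPE-directed pseudoknot structure and dimerization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipirt)
```

# Scope

`tipirt` reimplements, as a tested pipeline over synthetic data, the
computational chain used in structure-function studies of retroelement RNA
5' leaders such as the Ty1 TIPIRT domain (the region required for
translation initiation, packaging and initiation of reverse transcription):
chemical-probing reactivity processing, pseudo-energy-restrained folding
with H-type pseudoknot discovery, structural and motif annotation,
kissing-loop candidate detection, conservation classification on reference
coordinates, and retrotransposition-frequency statistics. The package makes
no attempt to reproduce the experimentally derived Ty1-H3 fold itself: that
would require the external genomic sequence and the raw probing appendix.
Instead, every stage is validated on generated inputs with known ground
truth, plus the printed worked examples of the study system (the
S1/L2/S2 core coordinates and the SL1a/SL3a motif duplex).

# SHAPE reactivity processing

Raw per-nucleotide reactivity is the difference between integrated peak
intensities of the reagent-treated and control channels. Electropherogram
alignment, decay correction and peak integration are upstream of this
package (ShapeFinder territory); the pipeline starts at per-nucleotide
intensities.

Normalization follows the boxplot/top-10% rule: values above the upper
boxplot fence are flagged as outliers, the scale factor is the mean of the
top `ceil(0.10 n)` remaining values, and everything (outliers included) is
divided by it. Three conventions are pinned down explicitly because the
rule is usually stated loosely:

* the fence is anchored at the third quartile, `Q3 + 1.5 IQR` — the
  standard upper boxplot fence. Only high outliers matter because only
  they can distort the scale; the lower fence is ignored.
* quartiles use linear interpolation of order statistics (the common
  "type 7" convention). `boxplot_normalize()` computes them explicitly in
  code rather than through a default argument, so the convention cannot
  drift silently; the test suite cross-checks it against
  `stats::quantile(type = 7)`.
* outliers are removed from the full value set first, and the top 10% is
  then taken from the remainder ("the most reactive peaks excluding
  outliers").

Negative raw reactivities are retained through normalization (they carry
no structural signal, and are neutralized only when converted to restraint
energies). Positions whose across-replicate standard deviation (n − 1
denominator) exceeds 0.7 normalized units are excluded; profiles from
overlapping transcripts are then averaged per reference position without
weighting. Excluded and uncovered positions are written as −999 in the
`.shape` output.

# Pseudo-free-energy restraints

A normalized reactivity `S` enters the fold as the per-nucleotide
pseudo-energy

    dG(i) = m * ln(S(i) + 1) + b     [kcal/mol]

charged on helix stacks. Defaults are m = 1.8, b = −0.6 kcal/mol, the
widely used values from the restrained-folding literature; the study
itself names only the restraint framework, so both are configuration
parameters (`restraint_params()`) and exact numeric agreement with any
particular published run is not claimed. Missing and negative reactivities
contribute zero.

The stacking charge convention is explicit. With
`double_charge = TRUE` (default) every stack charges all four
participating nucleotides, so a nucleotide interior to a helix is charged
twice and a terminal one once — the convention of the restraint framework.
With `double_charge = FALSE` only the closing (outer) pair of each stack is
charged, i.e. each paired nucleotide at most once. The dynamic program and
the standalone scorer `energy_of()` share one definition, so the two
routes agree to rounding.

# The energy model

The nearest-neighbor model is deliberately simplified
(`default_energy_model()`): stacking energies resolved by the classes of
the two stacked pairs (GC, AU, GU), Jacobson–Stockmayer logarithmic
loop-length extrapolation (slope 1.75·R·T ≈ 1.08 kcal/mol per ln-unit)
from base costs of 5.0 (hairpin, at the 3-nt reference), 3.8 (bulge, at
1 nt) and 4.1 kcal/mol (internal loop, at size 2), an affine multibranch
cost (offset 3.4, 0.4 per branch including the closing pair, 0.1 per
unpaired nucleotide), a pseudoknot initiation penalty of 3.5 kcal/mol per
crossing helix, a minimum hairpin of 3 nt, and a 30-nt cap on
bulge/internal loop size in the DP. The claims this pipeline supports are
about structural topology under SHAPE restraints, not quantitative
thermodynamics, so a small, auditable, JSON-editable table
(`write_energy_model()`) is preferred over a full Turner set; Turner-exact
parameters are out of scope by design.

# Folding

`mfe_fold()` is a Zuker-style dynamic program (implemented in C++ for the
cubic recursions) over nested structures. Determinism is guaranteed by a
two-level tie-break: energies equal within 1e−9 kcal/mol prefer the
structure with fewer pairs, and remaining ties fall to a fixed candidate
evaluation order (hairpin; interior loops by ascending inner 5' index and
descending inner 3' index; multibranch splits by ascending split point).
A full lexicographic comparison of pair lists was considered and
deliberately not implemented: the fixed evaluation order already makes
identical inputs give identical structures, which is the property the
pipeline needs, at none of the bookkeeping cost a lexicographic DP key
would add.

`shapeknots_fold()` discovers H-type pseudoknots with a forced-helix
heuristic in the spirit of helix-candidacy pseudoknot predictors: all
maximal complementary runs of ≥ 3 bp are enumerated and ranked by isolated
helix energy (stacks plus SHAPE charges); each of the top `max_candidates`
(default 20) is forced in turn, its positions masked, and the remainder
refolded by the nested DP. Refolded pairs may then cross the forced helix
— that is where the pseudoknot comes from — while the refold itself stays
internally nested, restricting the search to a single crossing helix
family (the H-type topology of the study system; kissing-hairpin and
higher-order topologies are out of scope). The forced helix contributes
its stacks, its SHAPE charges and the initiation penalty, with no
loop-closure term: its two flanking regions are folded in their own right,
not closed as a hairpin. The plain nested fold competes in the same
minimization, so the result is never worse than the nested MFE.

`energy_of()` scores explicit pseudoknotted structures by the matching
convention: every way of peeling one stem per crossing component that
leaves the remainder nested is evaluated (peeled helix = stacks + SHAPE
charges + initiation penalty; its positions count as unpaired in the
remaining loops) and the minimum is returned. Topologies that no single
peel can planarize are rejected as unsupported.

The DP is verified against exhaustive enumeration: 200 random sequences
of 5–18 nt, where every legal nested structure is generated by direct
recursion and scored through `energy_of()`. The heuristic is additionally
checked on short sequences against a brute-force scan of its own search
space (every maximal-run helix × every nested remainder, helix stacks
summed by hand). The sequence-length caps keep enumeration exact and the
default test run inside a few minutes; they are not a limitation of the
DP, which runs comfortably at leader-domain lengths (hundreds of nt).

# Annotation conventions

Coordinates are 1-based inclusive everywhere internally and in reports,
matching the "nucleotides 155–168" style of the field; BED export converts
to 0-based half-open. Stems are maximal stacks of consecutive pairs; a
single bulged nucleotide splits a stem by default, and the
`collapse_single_bulges` view merges across 1-nt bulges — the
representation in which a bulged hairpin like SL1a reads as one stem.
In the pseudoknot core, S1 is the crossing stem whose 5' strand is
5'-most and S2 the stem it crosses; L2 is the unpaired stretch between
S2's 5' strand and S1's 3' strand. On the printed coordinates of the
study system (1–7 : 264–270 and 255–262 : 319–326) this yields a 7-bp S1,
an 8-bp S2, L2 = {263} and a 3' extent of 326. Structures with more than
one crossing family are rejected rather than guessed at.

# Kissing-loop scanning

An apical motif is a hairpin loop plus the `k` apical stem pairs on both
strands (default k = 2; a 3-nt loop then gives a 7-nt window, the
dimensions of the SL1a motif). Duplex scoring maximizes the longest
contiguous complementary run over all antiparallel alignments.
Candidate calling is strict Watson-Crick by default — "perfectly
complementary" in the motif sense — with G-U wobble behind a flag, since
the study's SL1a:SL3a duplex is pure WC even though the SL1a stem apex
itself uses wobble pairs. Mean loop reactivity is a ranking feature only
(a reactive loop is available for intermolecular pairing), never a filter,
because the underlying argument is qualitative; conservation support is
likewise attached as an optional annotation and never gates a candidate.
A candidate is flagged as a symmetric kissing complex when the motif pair
passes in both orientations across two molecule copies, the configuration
with two intermolecular duplexes. Palindrome scanning reports maximal
even-length windows equal to their own reverse complement.
Thermodynamic scoring of the kissing duplex and any 3D feasibility
assessment are out of scope.

# Conservation classification

Alignment columns map to reference coordinates through the non-gap columns
of the designated reference sequence. Each reference position is
classified as ALL_CONSERVED (one identical non-gap residue in every
sequence), else GROUP_CONSERVED (identical across the focal subgroup),
else VARIABLE. A gap in any participating sequence fails the
corresponding test: "conserved" is read strictly, and since the upstream
convention is not documented, the strict reading was chosen and is stated
here. Comparison is case-insensitive and identifies T with U. The focal
subgroup is supplied as group labels in a manifest; the synthetic manifest
reproduces the study's composition (31 + 15 + 35 + 17 + 4 = 102
sequences, 31 + 35 = 66 focal).

# Retrotransposition statistics

Per-culture frequency is His+ prototrophs over colony-forming units, each
scaled by its plated fraction. The per-strain median (midpoint convention
for even n) carries the exact sign-test order-statistic interval
`(x(k), x(n+1−k))` with `k` the largest order index achieving binomial
coverage ≥ the level — the standard distribution-free interval for a
median of few replicates, chosen because the study names no method. At
n = 7 and 95% this is the full range `(x(1), x(7))`, with 98.4% achieved
coverage. When no k attains the level the interval degenerates to the
full range with a warning. One property often assumed of such intervals —
that their width shrinks monotonically with every added replicate — is
false on the order-statistic grid (the k = 1 interval at n = 8 is wider
in expectation than at n = 7, because k can only jump at discrete n); the
suite therefore tests the true monotonicity, that the selected order
index k is non-decreasing in n, alongside Monte-Carlo coverage at n = 7.
Percent-of-reference is the ratio of medians times 100. A
background-subtraction option for recombination-derived His+ colonies is
deliberately not modeled.

# The synthetic-data generator

The generator exists so every stage is testable without downloads, with
ground truth known by construction:

* `gen_structured_sequence()` plants, at reduced scale, the topology of
  the study system: a 7-bp S1 and 8-bp S2 crossing around a 1-nt L2, an
  SL1a-like hairpin (3-nt loop) in L1, and an SL3a-like hairpin in L3
  whose loop is the reverse complement of the first hairpin's 7-nt apical
  window. Stems draw GC-biased Watson-Crick pairs; unpaired regions draw
  from {A, C}, which cannot pair among themselves, so decoy helices
  between unpaired regions are structurally impossible and the planted
  fold is the clear optimum — the regime in which recovery is a test of
  the pipeline, not of luck.
* `simulate_shape()` draws gamma reactivities with means 0.05 (paired)
  and 0.9 (unpaired) — repo-defined defaults chosen to be separable but
  overlapping, as real profiles are — multiplied per replicate by
  unit-mean lognormal noise (sdlog 0.2, three replicates by default,
  matching the study's replicate count), and embeds them in
  treated/control intensity pairs.
* `gen_alignment()` realizes a per-position category plan exactly:
  GROUP_CONSERVED positions receive ≥ 1 non-focal substitution only,
  VARIABLE positions ≥ 1 focal substitution. No gaps are introduced
  (gap handling is tested by direct construction instead).
* `gen_colony_counts()` draws CFU ~ Poisson(cfu_mean) and
  His+ ~ Poisson(freq × CFU), the natural counting model for plating.

What the generator does *not* emulate — signal decay and primer-extension
dropouts in probing data, indels and phylogenetic correlation in
alignments, plating-efficiency variation between cultures — bounds what
passing tests demonstrate: they validate the algorithms against their
contracts, not the pipeline's robustness to every artifact of real
capillary-electrophoresis or sequence data.

# Problem sizes and numerical choices

The default verification run uses 200 sequences of ≤ 18 nt for the
enumeration oracle, 50 seeded ~100-nt instances for planted-pseudoknot
recovery (pooled pair recall ≥ 0.9 required; the current defaults recover
all of them), 100 seeded alignments for exact conservation recovery, and
10,000 Monte-Carlo draws for CI coverage at n = 7 — sizes chosen so the
full suite completes in well under the time a contributor will give it
while leaving the conclusions unchanged at larger n. Energy comparisons
use a 1e−9 tolerance inside the DP and 1e−6 against the R rescorer;
normalization invariance is asserted to 1e−12.

# Known limitations

One crossing helix family only (H-type); no partition function or
suboptimal ensembles; coarse energy parameters; no electropherogram
processing; no aligner (alignments are inputs); the actual Ty1-H3 fold is
not reproduced, only the printed core coordinates and motif examples are
checked. These boundaries are deliberate and documented rather than
incidental.
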