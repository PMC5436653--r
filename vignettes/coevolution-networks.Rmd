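---
title: "Detecting and annotating networks of co-evolving residue positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and annotating networks of co-evolving residue positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevnet)
```

## The model

A protein super-family alignment mixes three kinds of columns: columns
conserved everywhere (the catalytic machinery), columns that vary freely,
and columns conserved *within* functional subgroups but different
*between* them. The third kind co-varies: knowing the residue at one such
column predicts the residue at another, because both track the hidden
subgroup identity. `coevnet` scores this pairwise covariation, thresholds
it into networks (connected components of the position graph), attaches
literature-derived mutation annotations to positions, and quantifies how
strongly a network concentrates a given functional keyword.

The working coordinate system is the *3D number*: positions are indexed by
core alignment columns shared across the whole super-family, so mutation
data from any homolog — each with its own residue numbering — pools at the
same position label. True structure-based cores come from structural
superposition; here the core is approximated by the per-column gap
fraction (default: at most 30% gaps, `derive_core_positions()`), which is
configurable because no single threshold matches every curated alignment.

## The two scorers

Both operate on the joint residue counts of sequences that are non-gap at
both columns of a pair ("pairwise-complete" gap handling — dropping any
sequence gapped anywhere would discard most of a ragged family, while
per-pair completion keeps marginals consistent within each pair).

**Statistical coupling (`sca`, default).** For each residue $a$ at
position $i$ with at least `min_subset` (default 5) occurrences, condition
the alignment on $a$ and measure how far the residue distribution at $j$
moves from its marginal, in total-variation distance:
$d_a = \tfrac12\sum_b |f_{j|a}(b) - f_j(b)|$. The directed score
$D(i\to j)$ is the count-weighted mean of $d_a$; the reported score
averages both directions. It is dimensionless, bounded by 1, and exactly 0
when either column is conserved, because conditioning on the only residue
reproduces the marginal.

**Normalized mutual information (`nmi`).**
$\mathrm{MI}(i,j)/\min(H_i, H_j)$ with entropies in bits. The score is 1
exactly when the lower-entropy column is a deterministic function of the
other, and 0 for a conserved column (defined as 0 when the minimum entropy
vanishes). No finite-sample bias correction is applied; the MI bias is
approximately $(|A|-1)(|B|-1)/(2n\ln 2)$ bits for alphabets $A, B$ and $n$
complete pairs. Consequences at small $n$ are discussed under
*Limitations*.

Pairs with fewer than `min_pairs` (default 20) complete sequences are
*undefined*, reported as `NA` and excluded from networks — an undefined
score coerced to zero would silently delete true edges, and one coerced to
a value would invent them.

## Networks, cutoffs and calibration

An edge joins positions whose score is defined and at least the cutoff
(inclusive; the choice of inclusivity is a convention and only matters on
exact ties). Isolated positions are not network members, so network size
counts co-evolving positions only. Components are ordered by size with
ties going to the component holding the smallest position; the *hub* is
the maximal-degree node, ties to the lowest position number. Sub-networks
can be obtained by re-partitioning a component at a stricter cutoff.

Because both scorers have a sample-size-dependent null level (smaller
alignments give larger chance scores), `calibrate_cutoff()` estimates the
null by independently permuting each column's residues across sequences —
which preserves every column's composition and gap pattern while
destroying all inter-column dependence — scoring a random set of pairs,
and placing the cutoff a safety margin (default 1.25×) above the largest
null score. When one cutoff must serve a whole subsampling scan, calibrate
at the smallest subset size in the scan: a cutoff calibrated on the full
alignment sits below the null of a small subsample and floods its network
with chance edges.

## Enrichment

For keyword $m$: $\mathrm{Escore} = (K_n/K_t)\cdot(N_t/N_n)$, where $N_n$
is the number of network positions, $N_t$ the total number of core
positions, $K_n$ the network positions annotated with $m$ and $K_t$ all
positions annotated with $m$. Under random placement of annotations the
expectation is 1 (hypergeometric). Enrichment is computed over the union
of all components at the cutoff by default; pass a single component's
positions to `escore()` for per-component enrichment. Degenerate outcomes
stay typed: a keyword with no annotated positions is *undefined* (not 0),
and an empty network is an *empty-network* outcome — conflating either
with 0 would corrupt enrichment-versus-cutoff curves.

No closed-form significance is attempted; `permutation_pvalue()` draws
`n_perm` uniform position sets of the network's size and reports
$(1 + \#\{E^* \ge E_{obs}\})/(n_{perm}+1)$. For a fixed network size the
permutation distribution of $K_n$ is exactly hypergeometric, and the
package's tests verify the Monte-Carlo estimate against that closed-form
tail — the permutation form is kept because it generalizes unchanged to
per-component and multi-keyword variants.

## Text mining

The co-occurrence unit is the sentence. Three mention dialects are
recognized: compact (`S127P`), three-letter (`Glu422Lys`,
case-insensitive) and phrase (`"Trp58 was mutated to Ala"`, with verb
variants mutated/substituted/replaced/changed and connectors
to/by/with/into). Keyword expressions are stems matched case-insensitively
as word prefixes (so `increase` matches `increased`; full morphological
stemming buys little over prefixes for this vocabulary) or conjunctions
(`activity AND increase`) requiring all stems in one sentence.

Every mention is validated before use: the referenced sequence must carry
the stated wild-type residue at the stated (offset-corrected) position,
and the position must map to a core column. Failures are typed rejections
(`wt_mismatch`, `out_of_range`, `not_core`) kept for audit, not errors;
conflicting wild types across homolog numbering are strictly rejected
rather than renumbered. Silent substitutions (`A10A`) are extracted but
excluded from annotation by default. The annotation filter keeps a
(position, keyword) pair only when at least `n_mut` (default 2) *distinct*
articles support it — a single enthusiastic paper is not evidence of a
reproducible association.

## The synthetic test bed

`simulate_family()` draws each sequence by sampling a subgroup (8 equal
subgroups by default), emitting the subgroup's consensus residue at each
planted network position with probability `p_cons` (default 0.9, else a
uniformly random other residue), drawing background positions iid from
per-column Dirichlet(0.5) profiles (heterogeneous, realistically skewed
columns), and applying iid gaps (default 5%). Consensus residues are
distinct across subgroups at each network position. The reference
condition — 5000 sequences, 150 positions, 8 subgroups, one 12-position
network, `p_cons` 0.9 — is the default and is what the acceptance script
and the heavier tests use.

Two-layer families add nested sub-subgroups: a level-2 network is carried
by the sub-subgroup labels *within one parent subgroup*. Outside the
parent, the same consensus mixture is emitted with an independently
resampled label per cell, so level-2 columns have identical marginals
family-wide and their coupling exists only inside the parent. This is the
statistical signature of the layered-network phenomenon: the second layer
is invisible (or at most a minor side component) in the full family and
becomes the main network once the alignment is conditioned on the parent
group's residue at the first network's hub — at which point the
conditioned position itself is conserved and vanishes from every network.

`simulate_corpus()` writes article texts whose mutation mentions are valid
against the simulated alignment (wild type taken from the studied
sequence), cycle through the three dialects, and co-occur with the planted
keyword; decoy keywords and single-article noise mentions exercise the
`n_mut` filter. A perfect mining pass reproduces the generator's expected
annotation table exactly, which is tested end to end.

What the generator does *not* emulate: phylogenetic correlation between
sequences (draws are exchangeable), indel evolution (gaps are iid noise),
substitution-matrix structure, alignment errors, and the biased,
position-correlated way real literature selects "interesting" residues.
Passing tests on this test bed therefore demonstrate correctness of the
machinery and sensible statistical behaviour, not performance on any
particular real super-family, whose curated alignments and bibliomes are
not redistributable here.

## Problem sizes and numerical choices

The packaged analyses use 2000-sequence families (150 positions) for
recovery checks across ten seeds and both scorers, a 5000-sequence family
for the subsample-robustness study with ten 500-sequence replicates, and
10 000-draw Monte-Carlo checks for the hypergeometric identities. Scores
are computed from integer joint-count tables (tabulated in a single pass
per pair); tiny negative MI from floating-point cancellation is clamped to
0 and normalized scores are capped at 1. Random subsets are drawn without
replacement, each reproducible from (seed, fraction index, replicate
index) alone. Tie-breaks are deterministic everywhere (components:
smallest member; hubs: lowest position; codon designs: lexicographic).

## Library design

`top_k_residues()` selects the most frequent residues at a position
(default four, ties alphabetical). `design_codons()` searches all 15³
IUPAC-degenerate codons, keeps the stop-free ones encoding only target
residues, and finds a minimum-cardinality exact cover, breaking ties
lexicographically — exactness (no off-target amino acids) is required
because off-target codons waste screening capacity; a flagged
superset mode exists for targets with no exact cover within the codon
budget. The wild-type residue is deliberately *not* forced into the
target (a warning notes its absence), since a design may intentionally
exclude wild type. Library size is the product of encoded-set sizes over
the jointly randomized group plus the sum over independently randomized
positions; wild-type-equivalent combinations count, as that is what a
transformation plate actually contains.

## Limitations

* The statistical-coupling score is a perturbation-style reconstruction,
  not a bit-exact clone of any particular CMA implementation; absolute
  cutoff values do not transfer between implementations (or between
  scorers), which is why calibration against a permutation null is built
  in and method tags travel with every output.
* Uncorrected NMI inflates for low-entropy (near-conserved) columns at
  small sample sizes: in conditioned subsets of a few hundred sequences,
  residually near-conserved columns can leak into NMI networks. The
  layered-subset analysis is therefore most reliable with the default
  `sca` scorer; NMI is best used on full-size alignments.
* No sequence redundancy weighting is applied; heavily resequenced clades
  count at face value. A weighting hook is a natural future extension.
* Network membership is binary at a cutoff; positions just below a cutoff
  vanish. Enrichment-versus-cutoff curves (`enrichment_curve()`) are the
  intended remedy — read the curve, not a single point.
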