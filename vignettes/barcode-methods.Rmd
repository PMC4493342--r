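---
title: "Distance- and character-based species diagnosis from DNA barcodes"
author: "barcodiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance- and character-based species diagnosis from DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodiag)
```

## The analytical setting

`barcodiag` supports integrative species delimitation from aligned,
species-labelled COI barcodes. Three questions structure the analysis:

1. **How divergent are the putative species?** Within- and among-species
   averages of pairwise genetic distances, in the layout of a standard
   divergence table.
2. **Is there a barcoding gap?** Does interspecific divergence exceed
   intraspecific divergence by a comfortable factor (conventionally 10),
   and do distance clusters at a threshold (conventionally 3%) coincide
   with the named species?
3. **Which alignment positions diagnose each species?** Fixed nucleotide
   states unique to a species, or shared with at most two others, whose
   combination separates the species from everything else sampled.

All coordinates are 1-based positions on a reference frame whose base 1 is
base 1 of the standard 658 bp barcode fragment; alignments may extend
beyond it (the default simulated length is 1011 positions). Gaps (`-`) and
`N`/`?` are treated uniformly as missing data at a site; a record's
coverage is the interval from its first to its last observed position, so a
barcode available only from position 824 onward has coverage start 824 and
still participates in every analysis through pairwise deletion.

## Distance models

For a sequence pair, all models are computed over the jointly observed
unambiguous sites (*pairwise deletion*). IUPAC ambiguity codes are excluded
from distance computation rather than resolved fractionally: an `R` carries
real information for diagnosis (it is compatible with A and G) but only
half a bit for counting substitutions, and the conservative convention is
standard. Complete deletion is deliberately not offered: a single heavily
truncated record would otherwise annihilate most of the alignment.

With mismatch proportion $p$, transition proportions $P_1$ (A$\leftrightarrow$G),
$P_2$ (C$\leftrightarrow$T), transversion proportion $Q$ and pair base
frequencies $\pi$:

* JC69: $d = -\tfrac34 \ln(1 - \tfrac43 p)$
* K2P: $d = -\tfrac12 \ln(1-2P-Q) - \tfrac14 \ln(1-2Q)$, $P = P_1+P_2$
* TN93: $d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3$ with
  $k_1 = 2\pi_A\pi_G/\pi_R$, $k_2 = 2\pi_T\pi_C/\pi_Y$,
  $k_3 = 2(\pi_R\pi_Y - \pi_A\pi_G\pi_Y/\pi_R - \pi_T\pi_C\pi_R/\pi_Y)$,
  $w_1 = 1 - P_1/k_1 - Q/2\pi_R$, $w_2 = 1 - P_2/k_2 - Q/2\pi_Y$,
  $w_3 = 1 - Q/2\pi_R\pi_Y$.

Among-site rate heterogeneity with gamma shape $\alpha$ replaces each
$-\ln w$ by $\alpha\,(w^{-1/\alpha} - 1)$, which decreases monotonically to
$-\ln w$ as $\alpha \to \infty$. The default model is TN93 with
$\alpha = 1$: published divergence tables for barcodes are typically
"maximum-likelihood distances with gamma-distributed rate variation"
without a stated shape, and $\alpha = 1$ is a conventional middle value for
COI; the parameter is exposed and all reductions (TN93 → K2P under uniform
frequencies, K2P → JC69 when $Q = 2P$) are verified in the test suite
against independent formula evaluation and against `ape::dist.dna`.

Numerical choices: distances are undefined (`NA`, counted and reported)
when the joint overlap falls below `min_overlap` (default 100 sites —
distances from a 30-site overlap are noise) or when any logarithm argument
is $\le 0$ (saturation); clamping would silently bias averages. Degenerate
TN93 terms with $k_i = 0$ (a pair with no purines, say) take their limit 0.
The all-pairs path computes the sufficient statistics of every pair with
indicator-matrix products (BLAS) and is tested for exact equality against
the per-pair scalar path.

## Gap, OTUs and delimitation rules

The per-species gap report gives both the extreme-value form (maximum
intraspecific pairwise distance vs minimum distance to any other species'
individual — the standard barcoding-gap definition) and the mean-based form
(mean intraspecific distance vs smallest among-species mean — the
granularity at which divergence tables are discussed). The pass flag uses
the extreme-value ratio against `ratio_min` (default 10); singletons are
reported `n/a` and excluded from the global flag, since one specimen
cannot establish a gap.

OTUs are single-linkage connected components of the graph joining pairs at
distance $\le$ threshold. Single linkage is the only supported linkage: the
threshold rule ("differing by more than 3%") concerns any-to-any
divergence, and other linkages would depend on cluster shape. Undefined
distances never merge clusters. Monotonicity (partitions refine as the
threshold decreases) is property-tested.

Species-pair decisions operate on the among-species mean distance, with
thresholds `near_identical` (default 0.005 — "near identical" is verbal in
practice and had to be quantified; it is configurable), `t_low` (0.02) and
`t_high` (0.03), combined with an optional table of genitalic differences:
near-identical + shared morphology → conspecific; above `t_high` →
heterospecific; in `(t_low, t_high]` with genitalic differences →
heterospecific; anything else is returned as ambiguous rather than forced.

## Character-based diagnosis

A position diagnoses a focal species when all its observed individuals
carry the same unambiguous state there (*focal fixation*; a focal ambiguity
code disqualifies the position, because a printed diagnosis lists exactly
one state). The state must be absent from all other species (*unique*) or
present in at most $k = 2$ of them (*partially shared*). Two asymmetric
conventions matter and are deliberate:

* **Other-species ambiguities count as sharing** when their expansion
  includes the focal state. Treating an `R` in another species as "not A"
  could print a false diagnostic; the conservative direction is to let it
  veto uniqueness.
* **Missing data never vetoes uniqueness** (uniqueness is among observed
  states) **and never counts as exclusion**: in combination verification an
  individual with no observed data at any listed position is *unverifiable*,
  not excluded. Absence of evidence is not evidence of difference.

Sharer qualifiers quantify the verbal conventions of printed diagnoses:
`all` (sharing fraction $f = 1$, rendered as a plain "except"), `most`
($0.5 \le f < 1$), `some` ($0 < f < 0.5$), `rarely` ($f \le 0.1$, or a
single sharing individual in a species with at least 10 observed). The
bands are configurable and the exact fraction always accompanies the TSV
output. Combination verification is performed at the individual level
(stricter than a species-consensus check): the listed characters verify iff
every non-focal individual with overlap conflicts with the focal state at
some listed position. Species with a single barcode get a diagnosis flagged
preliminary.

The unique/shared finders and the verifier are tested for exact agreement
with brute-force enumerators on hundreds of randomized alignments, and the
paper-style renderer (`A (31)`, `T (58, except most X, rarely Y)`) is
round-trip parseable (render → parse → render is a fixed point).

## The synthetic-data generator

`simulate_alignment()` emulates the empirical setting the package targets:
16 species, individuals per species `c(1,1,1,1,3,5,...,97)` (four
singletons, the densest near 100, 331 barcodes in total), 1011 positions,
among-species divergence 2–16%, intraspecific pairwise divergence ~0.2%
(per-individual rate 0.001), 5 planted unique + 3 planted shared diagnostic
sites per species, one singleton species observed only from position 824
onward (with its planted sites placed beyond 824), and a 0.001 rate of
two-fold IUPAC ambiguities.

The design goal is *controlled* divergence with *exactly known* truth, so
three mechanisms differ from a plain Bernoulli mutation process:

* **Star phylogeny, disjoint branch sites, exact counts.** Each species
  mutates exactly `round(b * L)` sites (minus its planted budget) of a
  shared random ancestor, at site sets disjoint across species. Pairwise
  consensus divergence is then exact (no homoplasy, no binomial noise of
  ~20% relative at 2% divergence on 1011 sites), which is what makes a 10%
  reproduction tolerance on planted divergences meaningful. When the
  requested divergences need more sites than the alignment has, the
  configuration is rejected as infeasible rather than silently degraded.
* **Exact per-individual mutation counts.** Every individual carries
  exactly `round(rate * n_mutable)` private mutations at non-planted sites.
* **Planting last, and inviolable.** Planted sites are overwritten after
  branch mutation to guarantee the recorded uniqueness/sharing structure;
  individual mutations, ambiguities and (by placement) truncation never
  touch them, so planted-truth recovery is exact whenever ambiguity
  injection leaves focal states unambiguous — which it always does at
  planted sites.

The returned truth includes the expected pairwise p-distance per species
pair, $E[p_{ij}] = \bigl(D_{ij} + 2m\,(1 - \tfrac43 D^{bg}_{ij}/n_f)\bigr)/L_{ij}$,
where $D_{ij}$ is the realized consensus mismatch count over the pair's
jointly observed window, $D^{bg}_{ij}$ its portion at mutable sites, $m$
the per-individual mutation count, $n_f$ the number of mutable sites and
$L_{ij}$ the window length — i.e. consensus divergence plus the expected
contribution of private mutations (each lands on a matching site with
probability $1 - D^{bg}_{ij}/n_f$, and cancels an existing difference with
probability $\tfrac13$ otherwise).

What the generator does **not** emulate: codon structure and selection
(mutations are uniform over the three alternative bases — which is also why
K2P and TN93 estimates collapse toward JC69 on synthetic data, used as a
cross-model consistency check), among-site rate heterogeneity, genealogy
within species (no coalescent), homoplasy between species, and overdispersed
per-individual mutation counts. Tests passing on synthetic data therefore
validate the *bookkeeping* of the pipeline (coordinates, missing-data
semantics, threshold logic, recovery of a known signal), not the adequacy
of any substitution model for real COI data.

## Problem sizes and determinism

The shipped test suite works at desk scale: brute-force oracle equivalence
on 200+ randomized alignments of up to 6 species × 8 individuals × 60
positions, planted-truth recovery over 20 seeds at 5 species × 300
positions, and one full 16-species × 331-record × 1011-position analogue —
about half a minute in total on one CPU. The acceptance script runs the full
analogue from a single seed; every random draw in the package flows through
`withr::with_seed`, so identical `(config, seed)` reproduces alignments,
reports and JSON byte-identically. Analysis stages contain no randomness at
all; reruns differ only in the log timestamp.

## Known limitations

* The gamma shape of published divergence tables is usually unstated; exact
  cell-level reproduction of any particular published table is not promised,
  only tolerance-based agreement.
* Delimitation decisions use among-species means; a minimum-linkage view is
  available through the OTU partition but is not wired into the decision
  rules.
* Diagnoses are nucleotide-level only (no amino-acid characters) and assume
  the input is correctly aligned to the reference frame; columns that would
  be insertions relative to the reference must be resolved upstream.
* The "4 species were singletons" caveat applies to real use as to the
  simulation: single-record diagnoses are flagged preliminary, and no
  intraspecific variance can be estimated for them.
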