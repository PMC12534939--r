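---
title: "Charge-based global alignment of small molecules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based global alignment of small molecules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smialign)
```

## The model

`smialign` treats a small organic molecule as a *sequence* — the atoms of
its canonical SMILES string in order of appearance — and aligns two such
sequences globally, the way protein sequences are aligned, with atoms
standing in for residues. The per-atom feature driving the alignment is
the Gasteiger partial charge: an empirical electronegativity-equalization
quantity that summarizes how an atom behaves in its bonded context, so
that substituting an atom for one of similar partial charge is cheap and
substituting across a large charge difference is expensive.

Three modelling assumptions follow from this framing and should be kept in
mind when interpreting results:

1. **Canonical order is the sequence.** The canonicalizer (Open Babel,
   through ChemmineOB) fixes the atom order. Alignments are monotone in
   that order, so two structurally corresponding atoms can only be paired
   if canonicalization writes them in compatible positions. The
   `canonization_stability()` experiment (systematic oxygen-to-sulfur
   substitution, then Levenshtein and Tanimoto distances between parent
   and variant canonical strings) exists precisely to probe how fragile
   this assumption is for a given molecule set.
2. **Charges are computed per molecule, compared across molecules.** The
   scoring matrix pools charge differences over a corpus; the alignment
   then scores any atom pair by the bin of its absolute charge difference.
3. **Gaps are atoms without a counterpart.** Additions or removals of
   atoms across a transformation (a phosphate gained, a carboxyl lost as
   CO2) appear as affine-penalized gap runs.

## Scoring matrices

All pairwise absolute charge differences of the corpus are binned in 0.1
steps over [0, 3]; differences of 3 or more fall into the last bin. The
raw score of bin *k* is `log2` of the *survival* fraction — the proportion
of observed differences greater than or equal to the bin's lower edge —
which is 0 for the first bin by construction and non-increasing across
bins. Final scores subtract the raw score of the bin containing the mean
difference, so that bin scores exactly 0, smaller differences score
at or above 0 and larger ones at or below 0.

Design choices made where more than one reading was defensible:

* **Survival form, not per-bin frequency.** The scores are cumulative
  ("difference at least this large"), which yields the characteristic
  steep-then-flat decline and a well-defined largest penalty.
* **Mean anchoring as a shift.** Several transforms could make sub-mean
  differences favorable; the minimal one — subtracting the mean bin's raw
  score from every bin — preserves the survival curve's shape exactly and
  is isolated in one place (`build_scoring_matrix()`) so an alternative
  normalization can be swapped in.
* **Empty-tail pseudo-count.** Once no observation reaches a bin's edge
  the survival fraction is 0 and `log2` undefined; a pseudo-count of one
  observation substitutes `log2(1/N)`, producing a flat largest-penalty
  plateau rather than infinities. This value is the matrix `floor` and is
  corpus-size dependent by design, not a constant.
* **Paired pooling scope.** Element-pair matrices (`build_paired()`) pool
  charges corpus-wide by default — all charges of element A against all of
  element B, mirroring the all-vs-all construction. Pairing only within
  molecules is available (`within_molecules = TRUE`) for users who want
  intra-molecular difference statistics.
* **`min_pair_observations` (default 100).** Survival estimates from a
  handful of differences are degenerate (a few steps and then the floor),
  so rare element pairs resolve to the all-vs-all fallback instead. The
  lookup is total: any element pair scores somewhere.

## The dynamic program

The affine-gap recurrences use three lattices (aligned, gap-in-second,
gap-in-first) with standard Gotoh initialization: `M(0,0) = 0`, first
row/column of `M` impossible, `X(i,0) = -g_open - (i-1) g_extend` and
symmetrically for `Y`. Two consequences of writing the recurrences exactly
as stated:

* there is no direct `X`–`Y` transition, so a gap in one molecule never
  immediately follows a gap in the other, and no column is gap-vs-gap;
* penalties are *subtracted as given*, so negative penalty values act as
  gap rewards. The validation sweep deliberately spans both signs; users
  profiling pathways should prefer non-negative penalties, since strong
  gap rewards make all-gap "alignments" optimal.

Numerical and determinism choices: impossible states carry a finite
sentinel (−1e12) rather than `-Inf` to keep lattice arithmetic total; ties
in every `max` and in the traceback are broken with the fixed preference
M > X > Y, recorded as pointers during the fill, so repeated runs emit
identical alignments; aligning against an empty molecule is legal and
returns the forced single gap run. Bin indices add a 1e-9 guard before
flooring so that differences like 0.3 landing exactly on a bin edge are
not misassigned by binary floating point.

The correctness standard for the aligner is *oracle equivalence*, not
string identity with any particular historical implementation: the test
suite enumerates every affine-gap global alignment exhaustively for all
shapes up to 6×6 under randomized score matrices and penalty settings
(including negative ones) and asserts the lattice optimum equals the
enumerated optimum.

## Validation metrics and the penalty sweep

Similarities are computed on the gapped *atom-token* strings (the
stripped representation the aligner actually works on), not on reinserted
SMILES: `levenshtein_similarity()` is `1 − d/max(|s1|, |s2|)` with `d` the
edit distance, and `exact_similarity()` is the fraction of identical
positions, right-padding with the gap symbol when produced and truth
alignments differ in total gap count. Both definitions are deliberately
simple, standard, and isolated behind single functions. Per molecule pair
the similarity is the mean over the pair's two gapped strings; per sweep
cell the mean over pairs. The sweep covers the integer grid
(g_open, g_extend) ∈ [−5, 5]², 121 cells in g_open-major order, reusing
each pair's substitution matrix across all cells. `best_parameters()`
takes the cell with the highest mean Levenshtein similarity, breaking
ties by the smaller Levenshtein-minus-exact difference and then
lexicographically.

**Truth sets.** The bundled truth files for the Krebs cycle and
glycolysis (`inst/extdata/truth_*.tsv`) are *reconstructions*, not copies
of any published dataset. Because canonicalization orders atoms
differently in consecutive metabolites, the chemically exact atom mapping
of a transformation is frequently non-monotone in string order and cannot
be expressed as a global alignment at all. The reconstruction rule,
applied uniformly and recorded in each file header, is: the maximal
in-order element-identical correspondence between the two canonical
atom-token strings (no mismatch columns; the atoms added or removed by
the transformation appear as gaps), reviewed against the known chemistry
of each step. Equal-composition isomerizations (succinate–fumarate)
reduce to the ungapped alignment under this rule.

## Pathway profiles

`distance_profile()` aligns every unordered molecule pair of a pathway
(and each molecule with itself for distance 0) and groups scores by
pathway distance — `min(|i−j|, n−|i−j|)` for cycles, `|i−j|` for linear
pathways — reporting the mean, the *population* (divide-by-N) standard
deviation, and the pair count per distance. Each unordered pair counts
once; self-pairs appear only at distance 0, where the self-alignment
score has the closed form `n_atoms × scores[1]` whenever penalties are
non-negative. Cyclic profiles are invariant under rotation and reversal
of the starting point, which the tests assert. For linear pathways a
second mode (`mode = "from_start"`) scores each molecule against the
starting molecule only — the natural reading of "distance from glucose"
for glycolysis, and the mode used by the Tanimoto baseline's linear
variant. `tanimoto_profile()` applies the same grouping with the Tanimoto
coefficient over Open Babel FP2 path fingerprints (1024-bit hashed linear
fragments up to seven atoms) as the pair score; the fingerprint choice is
recorded here and in the function documentation because the coefficient's
value depends on it. Two single-heavy-atom molecules have empty FP2 bit
sets and are scored 1 (identical empty feature sets).

Coenzymes are excluded from the bundled pathway files themselves, not by
any code path: profiling a pathway that includes cofactors is possible by
supplying a file that lists them.

## Bundled fixtures and the random generator

The four bundled corpora (`krebs`, 7 primary metabolites in cycle order;
`glycolysis`, 10 metabolites glucose to pyruvate; `ppp`, 8
pentose-phosphate metabolites treated as a cycle; `demo`, 10 elementary
molecules) are reconstructions of standard textbook structures in neutral
protonation without stereo descriptors, chosen once as the package's
study conditions. They are deliberately small: combined they give 35
molecules, 350 atoms and ~61,000 pairwise charge differences, enough to
populate all bins up to the floor plateau while keeping every test and
the acceptance script a matter of seconds.

`random_smiles()` generates test molecules from a small grammar — trees
over C/O/N/S with single and double bonds and branches, plus optional
plain monocycles — tracking valence during generation so every emission
is legal by construction. It deliberately emulates only *structural
variety of small neutral organics*: no charged or bracket atoms by
default, no aromatic systems, no stereochemistry, at most one ring.
Passing the 500-molecule round-trip and parity properties therefore shows
the tokenizer/blueprint machinery is sound over that grammar, plus the
bracketed/aromatic cases covered by targeted unit tests — it does not
certify behavior on exotic SMILES (polycyclics, organometallics, isotopic
labels), which the tokenizer handles structurally but no property test
sweeps.

## Problem sizes and runtime choices

The test suite fixes its problem sizes at: 200 random instances × 20
penalty settings for aligner oracle equivalence (shapes ≤ 6×6, path
enumerations cached per shape); 50 random corpora for the normalization
contract; 500 generated molecules for the round-trip property; the full
121-cell sweep on Krebs consecutive pairs for the sweep properties. These
sizes were chosen once as comfortably demonstrative for desk-scale
verification; the pipeline itself has no built-in limits and the corpus
readers accept arbitrarily larger user-supplied molecule sets (the
full-corpus analyses the method is designed for are exactly such inputs).

## Known limitations

* Alignment quality is bounded by canonicalization stability; molecules
  whose canonical atom order reshuffles under small edits will align
  poorly, and different toolkit versions can shift canonical forms.
* Gasteiger charges are themselves approximate and toolkit-dependent;
  the `charge_provider` contract exists so better charge models can be
  substituted without touching the alignment machinery.
* Reinserted gapped SMILES are display strings only (`-` doubles as a
  bond symbol).
* The method is global alignment only — no local alignment, no suboptimal
  alignment enumeration, and no automated retrieval of pathways from
  external databases.
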