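---
title: "Predicting Dicer cleavage sites from hairpin sequence and structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Dicer cleavage sites from hairpin sequence and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicerscan)
```

## The problem and the model

Dicer excises the miR:miR* duplex from a pre-miRNA stem-loop, cutting each
arm close to the terminal loop and leaving a 2-nt 3' overhang. The cut
position fixes the ends of the mature miRNA, hence its seed sequence and
target spectrum. `dicerscan` treats cut-site recognition as binary
classification of *candidate scissile bonds*: each bond is summarised by a
fixed-width window of the stem duplex centred on the bond, and a
radial-basis SVM assigns it a decision score (higher = more
cleavage-like).

The package assumes its input structures are **nested single stem-loops**
— the natural topology of pre-miRNAs and the output of standard folding
tools. Pseudoknots are rejected at parse time (one bracket family only),
and multiloop structures are reported by `validate_single_loop()` and
skipped (with a warning) by the scanning CLI rather than silently
processed. G:U wobble pairs are first-class: pairing state always comes
from the folder's dot-bracket, never from a Watson–Crick complement table.

## Window geometry

All coordinates are 1-based; a cleavage site is the bond **after**
position `cut_after`. A window of even width `w` spans arm positions
`cut_after − w/2 + 1 … cut_after + w/2`, so the bond sits exactly between
tokens `w/2` and `w/2 + 1`. Windows live on the *duplex alignment*
(`build_duplex_alignment()`): one column per anchoring-arm stem
nucleotide, the opposite token being the pairing partner or a gap. This
arm-anchored mode gives the fixed `w + w` geometry behind the printed
feature dimensionalities. A second, full-alignment mode additionally
inserts gap-on-anchor columns for opposite-arm bulges, reproducing the
information content of aligned structure renderings that print `-`
placeholders; the two gap glyph dialects (`-` and `0`) are unified into a
single internal gap state and only affect text output.

Training windows come in pairs per annotated site: the positive window
centred on the cut, and a negative window whose centre is shifted
`offset ≥ 7` columns into the body of the mature miRNA (toward the 5' end
on the 5p arm, toward the 3' end on the 3p arm). The shift direction
encodes the biological prior that Dicer essentially never cuts in the
middle of a mature miRNA; the floor of 7 omits the six nucleotides
adjacent to the cut, where genuine isomiR variability lives. The exact
centre of the negatives is not uniquely determined by that prior, so
`offset` is an explicit parameter with default 7 (6 omitted + 1).
Boundary handling differs by purpose: single-site extraction gap-pads
windows that overhang the stem (keeping the dataset size equal to the
annotation count), whereas scan enumeration emits only full windows along
the stem (`N − w + 1` windows for an `N`-column stem).

## Feature encodings

Four schemes, all defined over the window's two token rows
(`A/C/G/U`/gap):

| scheme | content | dims at w = 14 |
|---|---|---|
| `comp1/2/3` | overlapping k-mer frequencies, lexicographic (A,C,G,U) order | 4 / 16 / 64 |
| `binary_seq` | 4-bit one-hot per arm token, gap = `0000` | 56 |
| `binary_struct` | arm blocks then complement blocks | 112 |
| `extbinary_struct` | 5-bit one-hot, both rows, gap its own class | 140 |

Composition treats any k-mer touching a gap as unobserved (excluded from
numerator *and* denominator) and is normalised to relative frequency so
windows with different effective lengths are comparable; a raw-count mode
is available behind a flag since counting and normalising differ only by
a scale factor at fixed window width. An all-gap window yields a zero
vector flagged degenerate. No further feature scaling is applied: binary
features are already 0/1 and the SVM backend is run unscaled, matching
the defaults of the classic SVM^light workflow this mirrors.

The extended scheme exists because the plain structure profile conflates
"loop/bulge" with "no information" (both are zero blocks); giving the gap
its own bit lets the classifier use bulge placement as a positive
feature, which is exactly where much of the structural signal near Dicer
cuts resides.

## Classifier and model selection

`dicer_svm()` fits an RBF-kernel C-SVM (via `e1071`/libsvm) over the grid
g ∈ {0.001, 0.01, 0.1}, c ∈ 1..10, j ∈ 1..10, where `j` multiplies the
error cost of the positive class (its classic meaning in SVM^light).
Every configuration is evaluated by **family-grouped 5-fold CV**:
families are packed greedily, largest first, into the currently smallest
fold (ties among equal-sized families broken in a seeded random order),
so no family ever spans a fold boundary and homology cannot leak between
training and test. Per configuration, held-out decision scores are pooled
across folds and thresholded (default 0) into one confusion matrix; the
configuration with the highest pooled-CV accuracy wins, with ties broken
by higher MCC, then smaller `c`, then smaller `j`, then smaller `g`.
Pooled counts were chosen over unweighted per-fold means because they
weight folds by size and keep MCC defined even when a small fold is
single-classed after thresholding. The winner is refit on all data.

Decision scores are computed from the support vectors directly
(`Σᵢ αᵢ K(xᵢ, x) − ρ`), with the sign oriented so that higher always
means more cleavage-like; this makes the JSON model archive
(`write_dicer_model()`) reproduce the in-memory model's predictions
exactly, with no binary serialisation. The decision threshold is a user
parameter: raising it above 0 trades sensitivity for specificity.
Undefined metrics (zero denominators) are reported as `NA` with an
explicit flag, never silently zeroed. ROC AUC uses the rank (Mann–Whitney)
formulation — the probability a random positive outscores a random
negative, ties counted half — which equals the trapezoidal area and is
invariant under monotone score transforms.

## Scanning, PSE and variant effects

`scan_hairpin()` scores every full window along the stem and returns up
to `top_k` (default 3) sites above the threshold, sorted by descending
score with ties broken by ascending position (a pure convention, chosen
for deterministic output). Users should read all three: isomiR data show
the physiological cut itself wobbles by 1–3 nt. Accuracy of a scan
against an annotation is summarised by the Position Shift Error,
`predicted − actual` (negative = upstream), averaged as the mean absolute
value.

The variant classifier compares the top-k ranked lists of a reference and
a variant hairpin. With annotated site `a` (default: reference rank-1):
`loss_of_site` if `a` is absent from the variant's top-k;
`remain_same` if the rank-1 position is unchanged *and* `a` keeps its
rank; `altered` otherwise. This is the minimal rule consistent with the
published example calls for hairpins where variants preserved, shifted or
destroyed the site; it is a convention (the original work never
formalised the labels) and is deliberately a small pure function that a
different policy could replace. By default the variant keeps the
reference structure, isolating the sequence contribution; callers who
want the full effect should refold (e.g. `fold_hairpins()`, which shells
out to an installed RNAfold) and pass the variant structure explicitly.

## The synthetic generator

`make_dataset()` emulates the statistical structure the method assumes:
hairpins with a discriminable sequence-plus-structure context at the true
cut. Each hairpin is a single stem-loop with a 26–32-nt 5p arm, a 4–8-nt
loop, background bulge probability 0.05 per stem position, and 10% G:U
wobble among paired columns. The cut sits 7–10 columns from the loop; the
overhang-offset position (`cut − 2`) is always paired so the two arms'
annotations satisfy the 2-nt overhang relation exactly. Families (default
n/5 of them) share a skeleton (geometry, pairing, cut) and an ancestral
sequence from which members are re-drawn at ~20% of positions, giving the
within-family homology that grouped CV exists to contain.

The planted signal at `signal_strength = s` has two parts, chosen so the
central qualitative claim — structure encodings beat sequence encodings —
is reproducible without copying any real data. A multinomial tilt places
a fixed 4-nt motif at offsets −1..+2 around the cut with per-position
probability `0.25 + 0.75·(0.5·s)` (visible to every scheme), and bulges
are planted at offsets −5 and +3 with probability `0.9·s` (visible only
to structure-aware schemes, since the arm row always carries a base).
The window region around both the positive and the shifted-negative
centre is otherwise kept bulge-free so that at `s = 0` the two classes
are exchangeable and discrimination collapses to chance. What the
generator does **not** emulate: real miRBase base composition,
thermodynamic plausibility of the structures, multi-site isomiR
annotations, and sequencing noise — so passing tests demonstrate the
pipeline's correctness and its ability to exploit planted structure, not
field performance on biological data.

## Numerical and design choices

- 1-based coordinates everywhere; the cut is the bond after `cut_after`.
- `T`→`U` and case normalisation on input; residues outside A/C/G/U are
  rejected (the encodings define exactly four bases, no ambiguity codes).
- The 5p↔3p overhang mapping is exact when the offset position is paired;
  when it is bulged the paper-level definition is ambiguous, so both
  behaviours are exposed: strict (error) and lenient (nearest paired
  neighbour with positional compensation, flagged with a warning).
- All randomness is seeded: fold assignment, subsampling and generation
  derive per-item streams from a single master seed, and seeds are
  recorded in model provenance and output file headers.
- Model selection metric is accuracy (the quantity the original tables
  rank by); the full CV table is returned so any other policy can be
  replayed from it.

Problem sizes in the shipped checks were picked to keep the full suite in
the minutes range while leaving the statistical conclusions
unambiguous: encoder and geometry properties run on exact small
fixtures; the planted-signal recovery runs at 500 hairpins (1000
windows), where the structure-over-sequence gap is ~15 accuracy points;
no-signal controls average five 200-hairpin replicates because a single
grouped-CV AUC on family-structured data has a standard error of a few
hundredths.

## Limitations

- The classifier is only as good as the supplied secondary structure;
  different folders give different bulge placements and measurably
  different models (the two-dialect support exists for this reason).
- Hairpins whose predicted structure forms multiple loops are outside the
  model and are skipped, not approximated.
- One cut per arm is assumed during training-set construction; isomiR
  catalogues with several annotated cuts per arm must be reduced to one
  row each beforehand.
- The variant-effect rule compares ranked lists only; it does not model
  processing efficiency, strand selection or RISC loading.
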