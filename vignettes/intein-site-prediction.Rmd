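---
title: "Predicting intein insertion sites: models, parameters and design choices"
author: "inteinsite package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intein insertion sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inteinsite)
```

## The problem and the model

An intein splices itself out of a precursor protein and religates the two
extein halves. For an intein to function as a switch inside a foreign host
enzyme, the insertion site must tolerate the domain insertion, permit the
splicing chemistry (which requires a Cys/Ser/Thr as the first C-extein
residue, the "+1" position), and leave a foldable mature protein. The
package scores every C/S/T site of a host protein with four features that
discriminate native insertion sites from background C/S/T sites, and calls
sites by fixed per-feature cutoffs plus a conjunctive combined rule.

A candidate site is a C/S/T position whose full −3…+4 window lies inside
the sequence; windows clipped by a terminus are excluded because the
cassette encoding below is undefined without all six flanking residues.
Positions are 1-based throughout and insertion is between −1 and +1, so a
site named S158 means the serine at position 158 is the +1 residue.

### Conservation

Given a PSSM with per-position amino-acid probabilities $p_{ij}$, the
positional entropy is

$$S_i = -\sum_{j=1}^{20} p_{ij}\,\ln p_{ij}, \qquad 0\ln 0 \equiv 0 .$$

Natural logarithms are used; the log base rescales all entropies by a
constant and therefore cannot change any rank, which is the quantity that
matters. Within one extein the candidate sites are ranked by entropy:
rank 1 is the lowest-entropy (most conserved) candidate, rank 0 the
highest-entropy one. With $n$ candidates the rank of a target is the
number of candidates with strictly higher entropy, ties counted ½, divided
by $n-1$. Mid-rank tie handling keeps the statistic deterministic and
symmetric; whether ties should instead be broken by position is genuinely
open, and the choice is configurable only in the sense that ties are rare
with real PSSMs. Ranking is computed over candidate C/S/T sites only, not
all residues.

Probabilities are read from the *weighted observed percentage* block of a
PSI-BLAST (blastpgp) ASCII matrix — these are the empirical amino-acid
frequencies the entropy definition needs — never from the log-odds block.
Rows whose percentages are all zero (positions with no aligned weight) fall
back to the uniform distribution: maximum entropy, i.e. "least conserved",
the conservative direction for a predictor that rewards conservation.
Rows are renormalized to sum to one; entropy refuses unnormalized rows
rather than silently rescaling them.

### The cassette SVM

The insertion-site cassette is the 7-residue window −3…+4. Its six
variable positions are one-hot encoded into a 120-component vector: six
20-component blocks in the fixed order −3, −2, −1, +2, +3, +4, amino acids
alphabetical (A, C, D, …, Y) within each block. The +1 residue is not
encoded — every candidate is C/S/T by construction, so it carries no
signal. Any consistent ordering yields an equivalent model; fixing one
makes weights comparable across runs. An unknown residue (X) leaves its
block all-zero rather than dropping the example, keeping the vector
dimension fixed.

Training pairs native cassettes (target +1) with three decoy cassettes per
extein (target −1), drawn uniformly without replacement from the extein's
non-native candidate sites. The SVM is linear with a positive-class cost
factor of 3, compensating the 1:3 class imbalance. The regularization
constant defaults to $C = 1/6$, the SVMlight-style data-dependent default
$1/\overline{\|v\|^2}$ (a complete cassette vector has exactly six ones);
it is exposed as an argument. Optimization is delegated to libsvm via
`e1071`, with the weight vector and bias extracted so that scoring is a
plain dot product $w\cdot v + b$; positive scores are native-like. libsvm
solves the dual to a tolerance of about $10^{-3}$, so tests assert
determinism and order-invariance at that tolerance, not at machine
precision.

Model quality is measured by a leave-one-extein-out protocol: hold out one
extein, train on the native cassettes of all others plus freshly sampled
decoys, score every candidate site of the held-out extein, and record the
rank of its native site — the fraction of decoy candidates scoring
strictly lower, ties ½. The decoy draw is the only random element, so
"repeat with a different random training set" is interpreted as re-sampling
the three decoys per training extein on each of the 25 repeats while the
positives stay fixed. Before training, exteins whose native cassettes are
identical on the six encoded positions are deduplicated, keeping the
longer extein (ties broken by id for determinism). Decoys are presumed
negatives: un-annotated sites may in truth support splicing, which bounds
the achievable measured performance.

### Structure features

**Distance to function.** The minimum Cα–Cα distance from the candidate
site to any annotated active-site or dimer-interface residue. For the
combined predictor the two annotation sets are merged by taking the
minimum over both. An empty annotation set makes the feature *missing*,
never zero — a zero would silently call every site positive. Structure
numbering is mapped to extein numbering by an explicit offset or map,
never inferred from alignment.

**Secondary-structure junction.** Stride/DSSP one-letter codes are grouped
as H → helix, E → sheet, T/S/C → loop, and G/I/B (3₁₀ and π helices,
bridges) → other. The junction distance of a site is the minimum sequence
separation to the nearest residue of the complementary group: helix and
sheet residues measure to the nearest loop residue, loop residues to the
nearest helix or sheet residue. "Other" residues terminate runs but never
define a junction, and a direct helix–sheet contact defines none either:
there is no helix/sheet bin in the six-bin scheme, and tying the distance
to the same complementary group that defines the bin keeps the two
consistent. Sites within two residues of a junction are binned
AH/L-junction or BS/L-junction; a loop residue within two of both takes
the nearer, with ties going to the sheet junction (native sites are
enriched near sheet ends, making that the more informative call). Reported
junction distances follow the 1 / 2 / ">2" granularity of the case-study
table; `Inf` encodes ">2" internally so the ≤ comparison stays ordinary
arithmetic.

**Burial.** Cβ contact density: the number of other residues' Cβ atoms
within 8 Å (closed ball, `≤`) of the site's Cβ. Glycine substitutes its
Cα, the standard convention. Burial is computed and reported but is not
part of the default combined rule — it does not separate native from
background sites.

**Flexibility.** Over $S$ trajectory snapshots aligned to the first,

$$\mathrm{rmsd}_i = \sqrt{\tfrac{1}{S}\sum_{s=1}^{S}\|x_{i,s}-x_{i,1}\|^2},$$

with snapshot 1 as reference (its term is zero) and normalization by $S$;
the $S-1$ convention is available via the `denominator` argument.
Alignment uses a Kabsch superposition implemented with a base-R SVD and
the determinant correction that excludes reflections; degenerate
(collinear or < 3-point) inputs are rejected. Like burial, flexibility is
reported but not used in the combined call.

## Calling sites

The per-feature operating points — estimated as the Youden points of the
native-set ROC curves — are strict comparisons fixed by the language of
the source analyses: distance **<** 14.1 Å, SVM score **>** 0, junction
distance **≤** 2 residues, conservation rank **>** 0.61. The default
combined rule is the conjunction of the three strong predictors
(conservation, SVM, distance). Sites with a missing feature fail the
corresponding call and are flagged, rather than being imputed; when a
feature required by the combined rule is absent, `call_site()` errors by
default and degrades to a conservative negative only in the end-to-end
report, where partial inputs are expected. The ranked report orders sites
by the number of satisfied predictors, ties broken by conservation rank —
the strongest single sequence-only predictor in the case study.

```{r case-study}
cs <- run_case_study()
print(cs)
```

ROC sweeps classify at every cutoff of a grid (defaults: 0–30 Å by 0.1 for
distance, −10–10 by 0.01 for SVM scores, 0–5 by 1 for junction distances,
0–1 by 0.01 for ranks), anchor the curve at (0,0) and (1,1), and integrate
by trapezoid over points sorted by FPR — equivalent, on a sufficiently
fine grid, to the Mann–Whitney pair-counting statistic with ties ½, which
the tests use as an independent oracle. The Youden cutoff maximizes
TPR − FPR (the point furthest from the chance diagonal; perpendicular
distance is the same argmax), with ties resolved toward the more stringent
cutoff. Rates with a zero denominator are reported missing, never zero,
and printed rates are rounded to whole percent while internal values keep
full precision. Enrichment tests go through base R: two-sided Wilcoxon
rank-sum (`wilcox.test`: exact for small untied samples, tie-corrected
normal approximation otherwise) and Pearson chi-squared without continuity
correction.

## The synthetic generator

Tests and the rank benchmark run on generated data because the native
extein set and its PSSMs, homology models and trajectories are
database-scale inputs. The generator emulates the *structure* of those
inputs, not their biology:

- Sequences draw from the 17 non-C/S/T residues, then plant candidate
  C/S/T sites explicitly (pairwise separation ≥ 2, so motif residues
  written at −1/+2 of one site can never delete a neighbouring site).
  The candidate set is therefore exactly the planted set, and every
  feature of the planted site can be asserted against the generator's
  intent.
- PSSM rows are symmetric-Dirichlet draws (entropy typically 2.2–2.9
  nats); a "conserved" planted site gets 0.97 of its row's mass on the
  observed residue (entropy ≈ 0.22 nats), which guarantees a
  conservation rank ≥ 0.9 among 10–12 candidates and is verified after
  generation.
- Structures are self-avoiding Cα random walks (3.8 Å steps, 4 Å excluded
  volume) with pseudo-Cβ atoms 1.53 Å off each Cα; secondary structure is
  random runs of H/E/C of length 4–8. A "native-like" site is placed one
  residue from a sheet/loop junction with an active-site annotation on its
  sequence neighbour (Cα distance 3.8 Å).
- Snapshots are the reference trace plus isotropic per-residue Gaussian
  jitter with standard deviations drawn from U(0.3, 1.2) Å.

What passing tests on this data do **not** show: real PSSM rows are
correlated along the sequence and shaped by alignment depth; real decoy
cassettes share composition biases with native ones; real protein
geometry, secondary structure and thermal motion are nothing like
independent jitter on a random walk. The synthetic benchmark demonstrates
that the pipeline recovers a signal it is known to contain and finds
none in shuffled labels — a correctness check, not a performance estimate
for real exteins.

The rank benchmark's study conditions are 12 exteins of 120 residues with
1 native + 9 decoy sites each, a two-residue native cassette motif (G at
−1, P at +2), 25 decoy resamplings per held-out extein, and 50 generation
seeds per condition. The label-shuffled control reassigns each *training*
extein's positive to a random candidate site while the held-out extein
keeps its true native; with the 3× positive cost factor balancing the 1:3
class ratio, a shuffled motif contributes zero expected net weight and the
control's mean rank sits at 0.5.

```{r benchmark, eval = FALSE}
mean(vapply(1:50, function(s)
  as.numeric(svm_rank_benchmark(n_exteins = 12, repeats = 25, seed = s)),
  numeric(1)))
# ~0.999 with the planted motif; ~0.49 with shuffle_labels = TRUE
```

## Degenerate inputs and numerical conventions

- Sequences shorter than 7 residues yield an empty candidate set with a
  warning; non-standard residues become X and keep their sites.
- A single-candidate extein has no defined conservation or LOOCV rank;
  both error rather than returning a vacuous value.
- PSSM rows must sum to 1 within 1e−9 at construction; readers renormalize,
  the entropy itself does not.
- Missing Cα for an annotated residue is an error; missing Cβ falls back
  to Cα with a warning (silently for glycine).
- All seeded operations snapshot and restore the caller's RNG state, so
  package calls never perturb an enclosing simulation, and derived seeds
  stay below 2³¹.

## Known limitations

- The native cassette collection behind the published model is not
  distributed with the package, so the published leave-one-out mean rank
  (0.78) is not recomputed; `read_cassette_table()` accepts such a
  collection as a TSV if the user has one. Likewise the native-set AUCs
  and enrichment p-values require database-wide searches and homology
  models and are out of desk scope; the corresponding operations are
  instead validated against independent brute-force oracles.
- The SVM is linear by design; non-linear kernels and probability
  calibration are out of scope.
- Homology-model construction, PSI-BLAST, Stride, and molecular dynamics
  are consumed as files, never executed; their outputs' quality bounds the
  structure features.
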