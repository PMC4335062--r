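---
title: "Scoring and designing bZIP coiled-coil dimers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and designing bZIP coiled-coil dimers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzipspec)
```

bZIP transcription factors dimerise through a parallel two-helix coiled
coil whose sequence is organised in a seven-residue repeat, the heptad,
with positions labelled `a`-`g`. Positions `a` and `d` form the
hydrophobic core; `e` and `g` flank it and carry most of the electrostatic
specificity. This package models the dimerisation affinity of a pair of
registered bZIP coiled coils as an additive function of residue-residue
contacts, learns the contact contributions from censored affinity data,
estimates generalisation honestly under sequence redundancy, and inverts
the model to design new peptides that bind a chosen bZIP while avoiding
specified off-targets.

## The additive contact model

A registered dimer is encoded as sparse counts $x$ over a fixed set of
contact categories: 8 pair types
($a_i\!-\!a'_i$, $d_i\!-\!d'_i$, $g_i\!-\!e'_{i+1}$, $e_i\!-\!g'_i$,
$a_i\!-\!d'_i$, $d_i\!-\!a'_{i+1}$, $d_i\!-\!e'_i$, $g_i\!-\!a'_{i+1}$)
and 10 triplet types built from the same interface positions; the prime
marks the partner helix and the subscript the heptad index. The predicted
score of a dimer is

$$E = \sum_i w_i x_i,$$

on the $\log_{10} K_d$ (nM) scale: lower scores mean tighter predicted
binding, and a score difference of 2 corresponds to a 100-fold difference
in predicted $K_d$. The pair categories $aa'$, $dd'$, $ge'$ and $eg'$ are
symmetric in their residue content (the key stores the two residues in
lexicographic order); each pair category admits 210 (symmetric) or 400
(ordered) residue combinations, each triplet 8,000, for 82,440 features in
total. Only a small fraction is ever observed in data; unobserved features
simply carry no weight.

Two encoding conventions matter and are fixed package-wide:

* **Chain roles.** Every category names one residue set on the unprimed
  helix and one on the primed helix. For all categories except $aa'$ and
  $dd'$ the two role assignments of a dimer (A unprimed/B primed, and the
  swap) are physically distinct contacts and both are counted; for $aa'$
  and $dd'$ the swap maps the contact onto itself, so it is counted once.
  This makes `encode(A, B) == encode(B, A)` exact, with integer counts,
  and gives homodimers even counts in all non-self-symmetric categories.
  A `roles = "single"` switch retains the one-sided convention.
* **Frames and terminal heptads.** Heptad indices follow the canonical
  `a`..`g` frame, anchored on each coil's first complete f-anchored block
  (blocks run `(f,g,a,b,c,d,e)`, the natural unit for design). A
  cross-heptad contact is emitted only when both heptad indices carry the
  required positions on both chains, so terminal heptads naturally lose
  their cross-boundary contacts.

## Learning weights from censored data

Affinities come in two regimes: measured binders ($K_d$ below a ceiling,
5,000 nM by default) and censored non-binders, where only
$K_d \ge$ ceiling is known. The weights solve

$$\min_w\; \lVert w\rVert^2 + C_1 \sum_{k \in \text{binders}} \xi_k
 + C_2 \sum_{k \in \text{non-binders}} \zeta_k$$

subject to $|E_k - y_k| \le \varepsilon + \xi_k$ for binders (a two-sided
$\varepsilon$-insensitive tube with a single shared slack) and
$E_k \ge E_{\text{cutoff}} - \zeta_k$ for non-binders, with
$\xi, \zeta \ge 0$. The one-sided constraint is the correct use of a
censored measurement: a non-binder's score is only pushed *up to* the
floor, never matched to an arbitrary value. We write the non-binder slack
as subtracted; slacks written as added to the right-hand side could never
relax the constraint they penalise. $E_{\text{cutoff}}$ defaults to
$\log_{10}(5000) \approx 3.70$, the censoring ceiling on the working
scale.

The problem is a strongly convex quadratic program. `fit_semisvr()` solves
its dual exactly by coordinate descent (each coordinate update is the
closed-form soft-threshold maximiser, clipped to its box), implemented in
C++. Convergence is declared when the largest per-coordinate update,
scaled by the corresponding kernel diagonal, falls below `tol` (default
1e-9); every fit carries its primal objective, dual objective and duality
gap as attributes, so optimality is certifiable per fit. The test suite
additionally checks the objective against an independent dense QP solver.
Records with empty feature rows decouple from the weights; their slack
cost is constant and handled in closed form.

By default no intercept is fitted — the score is a pure contact sum, which
is what makes the weights interpretable as per-contact stabilities and the
design decomposition exact. `fit_intercept = TRUE` adds a constant feature
that is L2-penalised like any other weight (an unpenalised intercept would
break the box structure of the dual); its fitted value is reported in the
model's `intercept` field.

Hyperparameters $(C_1, C_2, \varepsilon)$ are chosen by grid search under
an inner cross-validation (`default_grid()` spans $10^{-2}$–$10^3$ on both
penalties — bracketing the hard-interpolation and strong-shrinkage regimes
— and $\varepsilon \in \{0, 0.1, 0.2, 0.4\}$; selection is by pooled
Pearson R on binders, ties broken by AUC, then by the smaller
$C_1 + C_2$). Recursive feature elimination (`rfe()`) repeatedly drops the
5% of features with the smallest $|w|$ (stable order on ties) and refits,
returning the subset with the best validation R.

## Honest validation under sequence redundancy

Close homologs in both training and test folds inflate apparent accuracy.
`partition()` therefore builds a record-similarity graph — similarity is
1 minus the Jaccard distance between encoding supports, sparsified to each
record's 20 nearest neighbours — and assigns records to folds so that (i)
within each affinity stratum ($K_d < 50$ nM, 50–5,000 nM, $\ge 5{,}000$
nM) fold sizes differ by at most one, and (ii) similar records share a
fold where the balance allows. Assignment is greedy in cluster order with
attraction to the fold holding a record's most similar members, followed
by same-stratum swap refinement that reduces the cross-fold similarity cut
(refinement is enabled up to 400 records; beyond that the greedy pass
stands). Everything is deterministic given the seed. This is a
self-contained balanced graph partitioner; it plays the role a general
multiway graph-partitioning tool would play in a larger system.

`nested_cv()` wraps this in two levels: the outer loop holds out one fold;
the inner loop re-partitions the remainder and runs the grid search; the
refit model predicts the held-out fold. Pooled held-out predictions give
the Pearson R over binders with $1 < K_d < 5{,}000$ nM and the AUC for
separating strong binders ($K_d < 250$ nM) from weak/non-binders
($K_d \ge 5{,}000$ nM), intermediates excluded; the AUC is the
Mann-Whitney rank statistic with tie correction, oriented so that lower
score = stronger. Companions: `bootstrap_ci()` (percentile CI of R over
1,000 resamples of prediction-truth pairs), `permutation_control()`
(reshuffles affinities jointly with their censoring status and reruns the
whole nested CV — an unbiased protocol yields R near 0 and AUC near 0.5),
`learning_curve()` (stratified subsets from 10% to 100%), and
`identity_split()` (single-linkage protein clustering at an identity
threshold over aligned `a,d,e,g` positions, whole clusters assigned to one
side, giving train/test sets with no cross-side pair above the threshold).

## Dataset curation

Three filters clean an affinity table before training, mirroring how
uncertain register assignments and conflicting measurements are handled in
practice:

1. **Asparagine mismatches.** Asn at an `a` position facing Val/Leu/Ile at
   the aligned `a` position strongly destabilises the dimer and may signal
   a non-canonical alignment; such records are dropped, with the first and
   last aligned blocks exempt (end effects are weak). Coils are aligned
   block-by-block from their first complete blocks.
2. **PSSM outliers.** A position-specific scoring matrix over the
   interface positions scores residue `aa` at position `i` as
   $s_i(aa) = -\log(p_i(aa)/p(aa))$ with add-one smoothing, background
   over all positions. A protein's score is the length-normalised sum over
   its `a,d,e,g` residues (a raw-sum mode exists); the top fraction
   (default 10%, ties broken by id) is removed with all its records. Note
   the formula's behaviour at small n: a residue that occurs *only* at one
   position is position-enriched and scores low, so meaningful outlier
   detection needs a background in which the residue also occurs
   elsewhere — true for any realistically sized dataset.
3. **Variant conflicts.** Records whose two partners present identical
   complete-block sequences but different $K_d$ are conflicting
   measurements of one interaction motif; all such records are removed
   (identical duplicates collapse to one).

Reciprocal measurements of the same unordered pair keep the lower $K_d$
at ingestion. The asparagine and variant filters are idempotent; the
outlier filter removes a fixed fraction by construction and is not.

## Designing selective binders

Designs are assembled from a library of native 7-residue modules
(`build_library()`: f-anchored windows from registered coils, deduplicated,
first-block windows flagged as N-terminal modules, optionally prefiltered
to the frequent core alphabets `a` ∈ {L,N,V,I,K,A,R,T}, `d` ∈
{L,H,V,M,I}). Working with native heptads keeps the design inside the
sequence space the model was trained on and supplies sensible surface
(`b,c,f`) residues the model does not score.

For a fixed partner, `decompose()` sorts every contact instance of the
(design template, partner) dimer by the design-chain blocks it touches:
instances whose design residues sit in one block contribute to the block
score $s_i^j$ of library heptad $j$ at block $i$; instances straddling two
consecutive blocks contribute to the junction correction
$c_{i,i+1}^{j,k}$. Because every pair category has exactly one
design-chain residue, pair contributions are always block-local; junction
corrections arise precisely from the triplets with two same-chain residues
either side of a block boundary. For any assignment the identity

$$\textstyle\sum_i s_i^{j(i)} + \sum_i c_{i,i+1}^{j(i),j(i+1)}
  = E(\text{assembled dimer})$$

holds exactly (to 1e-9 in tests, against a full re-encode).

The optimisation selects one heptad per block minimising the target score
subject to: assignment consistency; junction admissibility (adjacent
heptads allowed only if the three intra-chain junction residue pairs
e–f, d–g and e–a occur at those offsets in at least one native coil);
specificity, either relative ($S^{\text{off}} \ge S^{\text{target}} +
\Delta$ with $\Delta = 2$, i.e. a >100-fold predicted $K_d$ separation; the
default) or absolute cutoffs; and native-composition rules (His at `d`
only in the last block, Glu at `a` only in the first, Asn at `a` only
internal, N-terminal modules only at block 1, at most one Met at `d`, at
most four polar residues at `a`, and a per-block veto of heptads whose
`a`/`d` residue forms a destabilising — coupling energy > 1 kcal/mol from a
user-supplied table — or rarely observed — fewer than two occurrences among
strong binders — pair with the target's opposing residue). Off-targets are
aligned to the design frame at their first complete block and scored over
the block overlap.

`solve_design()` finds the proven optimum by depth-first branch-and-bound
over the block chain: backward dynamic programs give, for every (block,
heptad) state, the best achievable remaining target score and, per
off-target, the best achievable remaining specificity margin; nodes whose
bound cannot beat the incumbent or satisfy a margin are pruned, and
remaining-minimum counters bound the cardinality rules. On instances small
enough to enumerate, the result equals exhaustive enumeration exactly
(this is a standing test). A node limit turns the solver into an anytime
method reporting the best incumbent; `export_lp()` writes the identical
binary program in CPLEX LP format for external solvers, and
`verify_solution()` re-encodes the assembled design from scratch and
re-checks score, margins and composition independently of the solver.

The model scale makes one caveat explicit: scores are predicted
$\log_{10} K_d$, so *lower is tighter*, and reported design scores follow
this convention throughout.

## The synthetic study generator

Because the experimental affinity compendium is third-party data, the
package carries a generator that reproduces the *statistical shape* of
such data so that every stage is testable self-contained:
`simulate_coils()` draws registered sequences position-wise from the
frequent core alphabets (by default exactly; `core_mass < 1` mixes in
off-alphabet residues, e.g. 0.85 to mimic native occupancy), uniform
residues at `b,c,f`; `plant_model()` draws a sparse ground-truth weight
vector whose support always contains the hallmark core elements
(stabilising Asn-Asn$^{aa'}$, destabilising Asn-Leu/Ile/Val$^{aa'}$);
`simulate_dataset()` samples all homodimers plus random heterodimers,
adds Gaussian noise on the $\log_{10}$ scale *before* censoring
(measurement noise), and shifts the intercept so a target fraction
(default 20%) of records falls below the 5,000 nM ceiling. A fixed-seed
12-protein toy (`worked_toy()`) regenerates byte-identically and is
shipped as plain-text fixtures.

What the generator does not emulate: phylogenetic correlation between
proteins, position-position dependence within a chain, non-additive
context effects, and the heavy-tailed measurement error of real titration
data. Passing tests on synthetic data therefore demonstrate the
*machinery* (encoding, censored optimisation, honest partitioning, exact
design), not field performance on real measurements.

Two synthetic-scale observations are worth recording. With dense pairing
of 60 six-heptad proteins, 20% binders and noise SD 0.2, held-out accuracy
on a random split sits around the mid-0.7s in R, and drops to about 0.5
under the similarity-aware nested CV — the partitioner is doing its job of
making the test pessimistic, the same qualitative drop seen when real
models are evaluated across a low-identity split. And removing the
censored non-binders from training consistently lowers the strong-vs-weak
AUC on held-out data, the directional effect that motivates keeping
censored records in the objective at all.

## Numerical choices and problem sizes

* Solver tolerances: dual coordinate descent `tol = 1e-9` on the scaled
  update norm, pass cap 50,000 (a warning reports a hit cap); design
  branch-and-bound uses 1e-9 feasibility/optimality tolerances;
  decomposition exactness is asserted at 1e-9; model JSON serialises
  doubles at 17 significant digits (bit-exact round trip).
* Tie-breaks are always explicit and deterministic: PSSM outliers by
  (score desc, id asc), RFE by feature order, grid selection by
  (R, AUC, $C_1+C_2$), partitioning by seeded order.
* Degenerate inputs: empty feature vectors score the intercept; datasets
  with no binders refuse to fit; empty strata and single-record folds are
  handled; infeasible design constraint sets report `"infeasible"` rather
  than erroring.
* The test suite and the acceptance script run on scaled-down study sizes
  chosen as representative: 3 outer x 3 inner folds with a coarse grid
  for nested CV, up to ~1,800 records, libraries of a few hundred heptads
  for design. These sizes exercise every code path; larger studies only
  change run time.

## Limitations

Only parallel dimers are scored; anti-parallel alignments and higher-order
oligomers are out of scope, as are structure-based terms, solubility or
aggregation constraints, and the derivation of registers from alignments —
registers are explicit inputs here. The additive model treats each contact
independently; context dependence beyond triplets is not captured. The
composition and junction rules are knowledge-based heuristics, not
guarantees of foldedness or function.
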