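---
title: "Methods and design notes"
author: "drugcombnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical procedures in `drugcombnet`, the
defaults they ship with, the reasoning behind the genuinely open design
choices, and what the synthetic-data generator does and does not emulate.

## Disease-relevant gene selection

Two per-gene tests compare the disease and control groups of an
`expression_dataset` (which is assumed to hold already-normalized,
typically log-scale values; the package performs no normalization):

* **Location**: two-sided Wilcoxon rank-sum test. The exact null
  distribution is used when `min(n1, n2) <= 8` and the gene has no tied
  values — a bound at which full enumeration is cheap — otherwise the
  normal approximation with tie correction and continuity correction.
  A gene constant across all samples cannot carry evidence; it gets
  `p = 1` and a `flag_constant`.
* **Stability**: variance-ratio F-test, `F = s²_disease / s²_control`
  with `n − 1` denominators and two-sided
  `p = 2·min(P(F ≤ f), P(F ≥ f))` capped at 1. Genes with zero variance
  in either group are flagged and excluded from multiplicity adjustment
  rather than assigned an arbitrary p-value.

P-values are Benjamini–Hochberg adjusted *within each test family
separately*, so the two FDR levels are interpretable on their own. The
default combination rule is the **union** (`wilcoxon_q < alpha` OR
`f_q < alpha`, `alpha = 0.05`): the two tests are aimed at different
kinds of disease relevance (level shifts and stability changes), and a
gene altered in either sense is a candidate. Because one could equally
read the variance test as a *filter* against unstable genes, the rule is
configurable (`intersection`, `location_only`, `variance_only`).

## Consensus co-expression network

Each method ranks the complete unordered gene-pair universe, rank 1 =
strongest, with average ranks on ties:

* `pearson`, `spearman`: ranked by absolute correlation.
* `clr`, `aracne`, `mrnet`: operate on a mutual-information matrix
  estimated by equal-width binning with `ceiling(sqrt(n))` bins per gene
  — a parameter-free, fully reproducible estimator. CLR scores an edge
  by `sqrt(max(0,z_i)² + max(0,z_j)²)` of its MI against each
  endpoint's background; ARACNE applies data-processing-inequality
  pruning with tolerance 0 (within every triangle the strictly weakest
  edge is removed); MRNET uses max-relevance-min-redundancy forward
  selection per target and keeps the larger of the two directed
  criteria.

One deliberate refinement: edges that ARACNE prunes (or that MRNET never
selects) are not collapsed into one large tie at score zero. They are
ordered *below* every retained edge but keep their relative MI order.
A ranking must be a total order over the whole universe, and discarding
the MI ordering of pruned edges only injects noise into the consensus;
with the refinement, the Borda consensus on planted-block data is at
least as precise as the best single method, which is the behaviour an
ensemble is supposed to guarantee.

Rankings are aggregated by **Borda**: consensus score = mean per-method
rank, re-ranked ascending with lexicographic edge-label tie-breaking so
the output is deterministic and invariant to the order of the inputs.
The default cut keeps the top 5% of edges (`top_frac = 0.05`); the kept
edge weight is `1 − (rank−1)/E ∈ (0, 1]`. Both the method roster and the
cut are configurable because no single choice is canonical.

## Hamming–Ipsen–Mikhailov distance

Drug mechanism-of-action dissimilarity is the HIM distance between
perturbational networks, computed on the union of the two node sets
(nodes absent from one network are isolated in it — drug networks over
different gene universes must remain comparable):

* **Hamming** term: `H = Σ_{i<j} |a_ij − b_ij| / C(N,2)`, the normalized
  edge-weight L1 difference; local information.
* **Ipsen–Mikhailov** term: each graph's Laplacian `L = D − W` yields
  vibrational frequencies `ω_i = sqrt(λ_i)` (i = 2..N; `λ_1 = 0` is
  clipped at numerical zero). The spectral density is a sum of
  Lorentzians of width γ, normalized **in closed form** on `[0, ∞)` —
  each Lorentzian centred at `ω_i` integrates to `π/2 + atan(ω_i/γ)`, so
  `K = 1/Σ_i (π/2 + atan(ω_i/γ))` exactly. IM is the L2 distance between
  the two densities, integrated by adaptive quadrature on
  `[0, ω_max + 20γ]` with absolute tolerance 1e-8 (the tail beyond is
  negligible at that tolerance).
* **Calibration**: γ depends only on the node count `N`. `find_gamma(n)`
  solves `IM(empty_n, complete_n; γ) = 1` by bisection on `[1e-4, 10]`
  to 1e-10 (the distance is monotone decreasing in γ, so the root is
  unique) and caches the result per `n`.
* **Mixing**: `HIM = sqrt(H² + ξ·IM²)/sqrt(1+ξ)`, default `ξ = 1`
  (equal weight to the local and the spectral term). ξ is exposed
  because no canonical value exists; `ξ→0` recovers H and `ξ→∞` IM.

Weights are used as loaded; a `binarize` flag thresholds at `> 0` for
callers who want purely structural comparison.

## Chemical structure comparison

All comparisons canonicalize SMILES first (OpenBabel canonical writer),
so results never depend on the arbitrary input encoding.

* **Fingerprints**: circular Morgan-type fingerprints, default radius 2
  (the ECFP4 equivalent) folded to 1024 bits — standard practice.
  Atom invariants are element, heavy degree, total bond order, estimated
  implicit hydrogen count and aromaticity; neighborhoods are hashed
  iteratively (FNV-1a over sorted neighbor lists, so the result is
  independent of atom numbering) and all environment identifiers are
  folded modulo the bit length. Tanimoto similarity is
  `|A∩B| / |A∪B|`; two empty bit sets are identical objects and score 1
  (logged as degenerate).
* **MCS**: maximal common *connected* substructure under element +
  aromaticity atom matching and bond-order matching (aromatic bonds only
  match aromatic bonds), found by McGregor-style branch and bound with a
  `size + min(remaining)` bound. Similarity is
  `atoms_mcs / (atoms1 + atoms2 − atoms_mcs)`. Worst-case time is
  exponential, so each call has a wall-clock budget (default 10 s) after
  which the best mapping found so far is returned flagged
  `approximate`.
* **Levenshtein**: unit-cost edit distance on canonical SMILES
  (`utils::adist`), normalized by the longer string. The raw-string
  operator is exported separately for direct use.

## Topology on the disease network

The area of action of a drug is
`|(T∩V) ∪ N(T∩V)| / |V|` — its in-network targets plus their direct
interactors over the network size. Targets absent from the network are
ignored (reported, not errors: drug libraries routinely exceed the
disease network's gene universe). The distance between two drugs is the
mean unweighted shortest-path length over all cross pairs of their
in-network target sets; a shared target contributes a zero-length pair
and within-drug pairs are never counted. Pairs in different components
are excluded from the mean by default (with a reported count); the
alternative `penalize` policy scores them `|V|`. Combination coverage is
the area of action of the union of the member drugs' targets, which
makes it monotone under subset inclusion and free of double counting.

## Multi-objective combination search

Candidate subsets are binary membership vectors repaired into
`2 ≤ |S| ≤ max_size` (default 4). The five objectives are subset size,
mean pairwise HIM distance, mean pairwise chemical distance
(Tanimoto-based by default; the "structure" matrix is pluggable), the
coverage above, and the mean pairwise inter-drug target distance.

Objective directions are a genuine modelling choice, so each is
individually flippable. The defaults are: minimize size (parsimony);
maximize MOA and structural dissimilarity (combinations of
similar-acting, similar-looking drugs add little); maximize coverage;
maximize inter-drug target distance (the complementary-exposure
rationale of network pharmacology — drugs hitting well-separated parts
of the disease module).

The engine is NSGA-II: fast non-dominated sorting, crowding distance,
binary tournament on (rank, crowding), uniform crossover
(`p = 0.9`), per-bit mutation (`p = 1/L`), repair-based constraint
handling (infeasible chromosomes are randomly grown to size 2 or pruned
to `max_size` using the run's seeded generator, so every evaluated
vector is feasible and comparable), and elitist environmental selection.
Defaults `pop_size = 100`, `generations = 200` are sized for libraries
of up to ~100 drugs on a desktop. All randomness flows through
`config$seed`; identical configurations reproduce the front exactly.
The returned front is the final population's first front, deduplicated
by subset and sorted by subset label.

## Synthetic data: what it emulates, and what not

`make_expression` draws the control condition as i.i.d. standard normal
genes except for planted blocks sampled from a multivariate normal with
off-diagonal correlation ρ; the disease condition adds a mean shift δ
(in within-gene SD units) to the shifted genes and scales the variance
genes by κ. Planted structures are disjoint by construction. Defaults —
10 samples per condition, δ = 3, κ = 4, ρ = 0.9, blocks of 10 — mirror a
small two-arm transcriptomics study with strong planted effects.

`make_drug_library` hard-codes real small-molecule SMILES (aspirin,
caffeine, ibuprofen, metformin, …) so the cheminformatics code paths see
production-like inputs rather than random strings, assigns each drug two
targets round-robin over the disease network's nodes, and derives
perturbational networks by rewiring a growing number of the disease
network's edges. Rewiring (rather than re-inference from simulated
profiles) gives a controllable, monotone ground truth: more rewires
means a larger expected HIM distance to the base network.

The generator does **not** emulate: count noise or mean–variance
relationships of RNA-seq, batch effects, assay-specific noise of
perturbational profile repositories, or realistic drug–target biology.
Passing tests therefore demonstrate the correctness and calibration of
the algorithms under clean, known-truth conditions — not performance on
real transcriptomics.

Test and verification problem sizes are deliberate package choices
balancing statistical resolution against a fast default test run: the
null-calibration check uses 1000 genes at 10+10 samples; the
network-recovery check uses 30 genes in three ρ = 0.9 blocks at 100
samples per condition, because the equal-width-binning MI estimator
(⌈√n⌉ bins) is seriously biased below ~50 samples and co-expression
cohorts of about a hundred samples are the realistic regime for
MI-based inference; the GA verification enumerates all 375 feasible
subsets of a 10-drug library and checks the evolved front against the
exact one across 10 seeds.

## Numerical choices and degenerate inputs

* Rank-sum exact/approximate switch at `min(n1,n2) ≤ 8` without ties;
  midranks and tie-corrected variance otherwise.
* IM quadrature: absolute tolerance 1e-8, interval `[0, ω_max + 20γ]`;
  γ bisection bracket `[1e-4, 10]`, tolerance 1e-10; Laplacian
  eigenvalues clipped to 0 at −1e-9 and an error raised below −1e-6.
* Borda and threshold tie-breaks are lexicographic by edge label;
  consensus output is therefore byte-stable.
* Duplicate expression rows collapse to the maximum-variance row;
  duplicate network edges keep the maximum weight; self-loops are
  dropped with a logged count.
* Weights outside `[0,1]` are a hard error unless `rescale = TRUE`
  (min-max).
* Unparseable SMILES never abort a library load: the record is kept
  without a structure and excluded from chemical matrices with a report.
* Both-empty fingerprints score Tanimoto 1; a zero-variance group makes
  the F-test undefined (flagged) rather than infinite.

## Known limitations

* Gene identifiers are opaque case-sensitive strings; no alias
  resolution is attempted.
* The MI estimator is equal-width binning only; kernel or k-NN
  estimators are out of scope.
* MCS is exact only within its time budget; on large molecules the
  flagged approximate result is a lower bound.
* Building perturbational networks from raw drug-treatment profile
  repositories (e.g. retrieval or preprocessing of public
  perturbational datasets) is out of scope: users supply edge lists or
  run the network-inference module on their own profile matrices.
* Shortest-path distances are unweighted hop counts by default
  (`weighted = TRUE` uses `1 − weight` lengths).
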