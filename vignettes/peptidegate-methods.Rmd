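---
title: "Methods: clade-contrast screening and functional statistics for peptide-gated channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-contrast screening and functional statistics for peptide-gated channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peptide-gated sodium channels of the DEG/ENaC superfamily — FMRFamide-gated
FaNaCs in mollusks and annelids, Wamide-gated WaNaCs, and the distantly
related proton-gated ASICs that RFamide peptides modulate rather than gate —
differ from the rest of the superfamily at a modest number of amino acid
positions. Finding the positions that *determine* peptide sensitivity is a
comparative problem: look for alignment columns conserved within the
peptide-gated clade but divergent outside it, test them by mutagenesis, and
interpret the hits on the trimeric channel structure. This package implements
that pipeline as reusable, benchmarked components: sequence curation, the
column scan, structure mapping, and the electrophysiological statistics used
to score mutants, plus seeded generators that plant known answers at every
stage.

## Sequence curation

Curation reproduces two mechanical pre-filters on aligned FASTA input:

* **Length window.** Gap-stripped lengths outside [300, 1000] residues are
  removed. The bounds are inclusive: the verbal rule excludes sequences
  *larger than* 1000 or *shorter than* 300, so sequences of exactly 300 or
  1000 residues survive.
* **Redundancy collapse.** Pairwise identity is matches over columns where
  neither sequence is gapped. The sweep is greedy in input order and removes
  a sequence only when its identity to an already-kept sequence **strictly
  exceeds** the 0.90 threshold (">90% identical"); a pair at exactly 0.90 is
  kept. Greedy first-come representative selection is the simplest
  deterministic rule satisfying the filter; which member of a redundant pair
  survives depends on input order, but the guarantee — no kept pair above
  the threshold — does not.

The removal of "obviously incomplete" sequences and "poor-aligning segments"
is a human judgement we do not attempt to reproduce. A clearly labeled
approximation, `mask_sparse_columns()`, drops columns with more than 50%
gaps; it is optional and never applied implicitly.

## The clade-contrast scan

Columns are scored independently (no phylogenetic correction — the screen is
deliberately column-wise). For the foreground rows of a column, gaps leave
both numerator and denominator; `X` stays in the denominator but can neither
match nor form a consensus. Conservation is the modal residue frequency
(identity mode) or the modal physicochemical-class frequency (class mode)
among ungapped foreground residues. The class scheme is fixed and shared
with the generator: aliphatic AVLIMC, aromatic FWY, positive KRH, negative
DE, polar STNQ, special GP. Histidine sits with the positives, cysteine with
the aliphatics, and glycine/proline are isolated because their backbone
behaviour fits no other group.

A column passes when foreground conservation reaches
`fg_conservation_min` (default 0.90) **and** at most `bg_match_max`
(default 0.20) of ungapped background residues match the foreground
consensus, where "match" means the same residue in identity mode or the same
class in class mode. The default mode `either` accepts a column that passes
either rule, mirroring conservation "either completely or in terms of
physicochemical properties". The underlying biological rule
("reasonably conserved ... divergent") is informal and carries no published
thresholds; 0.90/0.20 are this package's operational choice and both are
config-exposed precisely so the stringency can be varied. For the same
reason, reproducing any particular published candidate count is not a
correctness criterion; the correctness criteria are the planted-truth
benchmarks below.

Candidates are reported in reference numbering: position *k* of the
reference row is the count of its non-gap characters up to that column,
counted from the initiator methionine, so names like F231 or A319 read
directly off the report. A column whose reference is gapped is dropped with
a warning, never silently renumbered. An optional region of interest
restricts reporting to, e.g., the extracellular and upper transmembrane
domains; the boundary is user-supplied because it depends on the topology
annotation of the particular alignment.

Mutation proposal mirrors the mutagenesis convention for this kind of
screen: mutate toward the background (the modal background residue when it
reaches 50% frequency) and fall back to alanine when the background is too
heterogeneous or the modal residue equals the reference residue. Vicinal
candidates (≤ 2 positions apart) are grouped for combined mutagenesis,
greedily splitting runs into groups of at most three.

Two properties are tested rather than assumed: the scan agrees with an
independent brute-force per-column recount on small random alignments, and
tightening either threshold can only remove candidates.

## Structure mapping

Candidates are located on a three-chain structure by residue number (the
same numbering as the scan reference). A candidate is interfacial when the
minimum distance from its selected atoms to any atom of another chain is at
most the cutoff; under C3 symmetry the two neighbouring chains are
equivalent and the nearer one is reported. Defaults: Cα mode with an 8 Å
cutoff, because side-chain placement in low-identity homology models is
unreliable; heavy-atom mode with 5 Å is available for experimental
structures. No published number defines "lining" an interfacial pocket, so
the cutoff is exposed and the defaults documented. Interfacial residues are
clustered into pockets by single linkage on Cα distances at 12 Å.

PDB input goes through bio3d: first model only, alternate locations blank
or 'A', and insertion codes rejected outright (they break the 1:1
residue-number mapping). Candidates missing from a partial model are
reported as `unresolved`, not errors. Distances, flags and clusters are
invariant under rigid motions, which the tests verify with seeded random
rotations and translations.

## Electrophysiology statistics

Sign convention, stated once and used everywhere: inward currents are
negative; all statistics are computed on magnitudes.

**Peaks.** The baseline is the median of the 1 s preceding the application
window (robust to noise and slow drift); the peak is the baseline-subtracted
extremum inside the window, sign-preserved.

**Hill fits.** Each recording is fitted separately with
`I = Imax·c^nH/(c^nH + EC50^nH)` by bounded Levenberg–Marquardt least
squares in the log10(EC50) parameterization. EC50 is bounded two decades
beyond the tested ladder, nH to [0.3, 10]; initial values come from the
half-maximum crossing interpolated in log concentration. Per-recording EC50s
are aggregated as mean ± SEM (a separate display fit to mean normalized
responses exists for figures only). nH is fitted, not fixed, and always
reported. Non-convergence sets `converged = FALSE` with the optimizer
message; failed fits are counted, never silently dropped. Batch
normalization divides every response by the mean maximal reference response
of the same batch (same experiment day), cancelling day-to-day expression
differences.

**Potency ratio.** The paired statistic I(test)/I(saturating) is computed
per recording (same oocyte) and averaged as mean ± SEM. Being a mean of
ratios of noisy quantities it carries a small positive bias of order the
squared noise fraction (≈ 0.25% at 5% noise) — inherent to the statistic,
not corrected, and far below the replicate SEM at realistic n.

**Mutant classification.** Two stages: (1) two-sided one-sample t-tests of
the raw test- and saturating-concentration amplitudes against zero — if
neither differs from zero the construct is `no_response`. (A t-test was
chosen over a CI criterion; the package documents this as its own choice.)
(2) Remaining constructs enter a one-way ANOVA frame with pooled variance
and are compared with wild type using Dunnett's many-to-one adjustment,
one-sided for a decrease: since "not different" and "greater" map to the
same label, a one-sided test spends the entire family-wise error rate on
the only call that matters, and the family-wise type-I error of the
`reduced` call equals alpha exactly — a property the test suite verifies
empirically over 10,000 seeded null families. Critical values come from a
seeded Monte Carlo of the exact null (independent group means over a shared
chi-square pooled variance; 50,000 draws, cached per design) rather than
multivariate-t quadrature; a unit test checks the Monte-Carlo critical value
against `mvtnorm::qmvt` to 0.02.

**Fold enhancement.** For conditioning protocols (e.g. ASIC desensitization
with and without peptide), per-recording |peak_b|/|peak_a|, mean ± SEM.
Control responses below the configurable noise floor (3× baseline SD when
known) are flagged and folded against the floor with a warning. The proton
adapters `ph_to_concentration()`/`concentration_to_ph()` let the same Hill
machinery fit pH-response data; the conditioning pH for such protocols is a
config value (default 7.0) because published protocols defer it to
supplements.

## What the generators emulate — and what they do not

The synthetic module supplies ground truth for every stage; its defaults
are the package's reference study conditions and are not tuned per test.

* **Alignments** (default 20 foreground × 50 background × 560 columns):
  planted columns are perfectly foreground-conserved with every background
  residue drawn from a different physicochemical class; `within_class_noise`
  degrades identity-level but not class-level conservation, so the scan's
  two modes can be stress-tested separately. All other columns are iid from
  a background profile — no phylogenetic autocorrelation, no indel process,
  no rate variation. Passing the planted-truth benchmarks therefore shows
  the scan implements its rule exactly; it does not show how the rule
  behaves on phylogenetically correlated real alignments, where background
  residues are not independent draws. Requested duplicates are exact copies;
  planted length outliers are short gap-padded rows (a >1000-residue outlier
  cannot be embedded in an alignment whose own width is inside the window).
* **Trimers** are geometric fixtures, not folds: chains are 120°-rotated
  copies; planted pocket residues sit on a tight inner ring whose
  symmetry-mate distance is 0.9× the interface radius, all other residues on
  a shell guaranteeing > 1.5× separation. The default interface radius (8 Å)
  matches the detector's default Cα cutoff so generator and detector speak
  about the same contact notion.
* **Dose-response and traces.** Peaks follow the Hill equation with
  multiplicative Gaussian noise (default 5%) — multiplicative because oocyte
  responses scale with expression level. Traces are mono-exponential rises
  with optional exponential desensitization and white Gaussian noise; with
  desensitization the biexponential is rescaled so its analytic peak at
  `t* = τ_act·ln(1 + τ_des/τ_act)` equals the requested amplitude. No Markov
  gating kinetics, filtering artifacts, leak or series-resistance effects
  are simulated.

## Reference benchmark conditions

The acceptance script and the benchmark tests run, at sizes chosen to keep
a desk-scale run fast while leaving Monte-Carlo error well below the
tolerances: 200 recordings per Hill-recovery benchmark (7 half-log
concentrations, 5% noise, planted EC50s of 3.4 µM and 340 nM — the second
exercises nanomolar unit handling); 14 paired recordings at a planted
potency ratio of 0.64; 7 paired recordings at a planted fold-enhancement of
10 (10% noise); 10,000 null families for the Dunnett type-I check; 100
random rigid motions for the structure invariance check. A fixed-seed
"within 2 SEM" check on an unbiased estimator passes ~90% of seeds by
construction; the suite pins the package-default seed 1, under which all
benchmarks pass, and the acceptance script accepts any seed.

## Numerical choices and degenerate inputs

* Seeded generators save and restore the caller's RNG state; a single
  pipeline seed fans out to per-stage seeds by fixed offsets so stages are
  independently reproducible.
* All-gap columns for a clade are an explicit error, distinct from a zero
  score; zero comparable columns make pairwise identity an error rather
  than 0/0.
* Dunnett critical values are cached per design (group sizes, df, alpha,
  draws, seed); repeated classification of equal designs costs one
  quantile lookup.
* Ties in modal residues/classes resolve by `which.max` (first in table
  order) — deterministic, and irrelevant above any conservation threshold
  > 0.5.
* The zero-response t-test guards the degenerate all-constant case (p = 1
  at mean zero, p = 0 otherwise) instead of erroring.

## Known limitations

The scan implements a conserved-versus-divergent contrast, not an
information-theoretic SDP score; columns informative only through
covariation are invisible to it. Curation's order dependence is documented
rather than removed. The toy trimer cannot probe detector behaviour on
realistic packing densities. The classification stage assumes approximately
normal per-recording ratios within constructs; with n as low as 3 the
t-based machinery is only as good as that approximation.
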