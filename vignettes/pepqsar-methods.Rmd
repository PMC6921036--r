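---
title: "Methods: z-scale QSAR of cell-penetrating peptides and infusion pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: z-scale QSAR of cell-penetrating peptides and infusion pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepqsar)
```

`pepqsar` models the cell-penetration ability of short peptides from
sequence alone, and simulates the plasma exposure of infused drugs and
drug–peptide conjugates.  This vignette documents the models, their
assumptions, the tunable parameters, and the design decisions taken where
several defensible choices existed.

## 1. Amino-acid z-scales

A z-scale assigns each amino acid a small vector of "principal property"
scores.  `build_zscale()` takes a residues × properties table, autoscales
it (each property column centered to mean 0 and scaled to standard
deviation 1, so heterogeneous units — Å³, Da, logP units, elementary
charges — become commensurable), and extracts the leading principal
components by singular value decomposition of the autoscaled matrix.
Scores are the projections onto the unit-norm right singular vectors; no
further normalization is applied.  Explained-variance fractions are the
squared singular values over their total, hence non-increasing and summing
to at most one for a truncated scale.

Numerical choices:

* **Algorithm.** SVD of the autoscaled matrix (equivalently an
  eigendecomposition of the correlation matrix).  Deterministic — no
  iterative or randomized steps — so rebuilt scales are bit-reproducible.
  The test suite checks the SVD route against an independent
  correlation-matrix eigendecomposition oracle.
* **Sign orientation.** PCA component signs are arbitrary.  They are
  anchored for interpretability: component 1 is oriented so the loading of
  molecular volume is positive (z1 grows with size), component 2 so the
  octanol/water partition coefficient loads positively, component 3 so net
  charge loads positively.  When an anchor property is absent (any
  synthetic or user table), the largest-magnitude loading of the component
  is made positive — deterministic and scale-free.
* **Degenerate inputs.** A zero-variance property column cannot be
  autoscaled and raises an error naming the column (this subsumes the case
  of a table with identical rows).  Component counts above
  `min(n_residues − 1, n_properties)` are rejected.

The packaged default scale (`zscale()`) is a published 3-component scale
for the 20 natural amino acids, derived from 12 computed physicochemical
properties of capped (N-acetyl, C-amide) residues.  The underlying
12-property matrix is not public, so this scale cannot be regenerated from
inputs; it is shipped verbatim as reference data and treated as
authoritative.  `build_zscale()` is therefore validated on synthetic
tables with planted structure, not against the packaged values.
Downstream descriptor arithmetic only consumes the stored numbers, so it
is independent of any construction convention.

One chemistry note: the packaged scale annotates histidine as positively
charged, and the charge descriptors below count it in the cationic set
accordingly.

## 2. Peptide descriptors

Every peptide is encoded as the sequence of its residues' (z1, z2, z3)
triples; `peptide_descriptors()` reduces that encoding to a fixed-order
global descriptor vector suitable for latent-variable modeling.

**Mean z-scores** are component-wise arithmetic means — by convexity they
always lie inside the per-component range of the scale.

**Helical-wheel moments.**  The classical hydrophobic-moment construction
places residue *n* at angle *nδ* on an ideal helical wheel and sums the
per-residue magnitudes as plane vectors; here each z component in turn
plays the magnitude role:

$$\mu_j = \sqrt{\Big(\sum_{n=1}^{N} z_{j,n}\sin n\delta\Big)^2 +
                \Big(\sum_{n=1}^{N} z_{j,n}\cos n\delta\Big)^2}.$$

δ defaults to 100° per residue (the ideal α-helix twist, 3.6
residues/turn) and is exposed as `delta_deg`.  Which single component the
original analysis used is not recorded, so all three moments are computed
and exported.  Two properties worth knowing: the modulus is invariant to
an index-origin shift (a rigid rotation of all phase vectors), and — less
obviously — it is also invariant under sequence reversal, because reversal
maps the complex sum to a rotated complex conjugate.  A large μ₂ flags an
amphipathic helix face; it is the single strongest synthetic-data
discriminator after charge.

**Terminal differences** |Nt − Ct| are component-wise absolute differences
of fragment mean z-scores, with fragments defined exactly as the dataset
truncation rules (Section 3): halves (N-half gets the extra residue on odd
lengths), first/last 5, first/last 10.  Sequences shorter than a cut use
the whole sequence for both fragments, giving a difference of zero; a
warning is emitted because the descriptor is then uninformative.  This
degenerate-input rule was an open choice; zero-with-warning keeps short
peptides in the corpus rather than dropping them.

**Steric bulk** is the mean count of side-chain heavy atoms (Gly 0 … Trp
10) and **net hydrogen-bond donation** the mean of side-chain donor
hydrogens minus acceptor sites.  No authoritative per-residue table
accompanies the original descriptor definitions, so both tables ship as
editable CSVs under `inst/extdata/` following standard residue chemistry
(e.g. Arg 5 donors/1 acceptor, Asp 0/4); every test references the
packaged tables, not external truth, so swapping a convention is a data
edit, not a code change.

**Charge descriptors** count Arg, His, Lys (+1 each) and Asp, Glu (−1):
totals, mean net charge, and the positive/negative ratio, which is
undefined (`NA`) for anion-free peptides — `descriptor_matrix()` therefore
excludes it from the modeling matrix by default.  Termini are treated as
capped and contribute no charge, consistent with the capped-residue
property calculations behind the scale.

**Hydrophilic ratio** is the percentage of residues in a hydrophilic set,
rounded half-up to an integer (62.5 → 63).  The reference values this
descriptor reproduces were produced by an external web calculator whose
set definition is unpublished.  The packaged default {R, K, D, E, N, Q, S}
is the minimal standard choice consistent with all four reference
peptides; His must be excluded (including it breaks the pVEC value), while
Thr, Gly and Tyr are undecidable from the available values because none of
the four peptides contains them in discriminating positions — Thr is
excluded, and the set is an explicit argument for users who disagree.

## 3. Dataset assembly

`dedup_peptides()` compares exact uppercased sequences; the first
occurrence wins, and a sequence appearing with *both* labels is removed
entirely (a peptide cannot be both active and inactive) and logged.
`balance_classes()` down-samples the majority class uniformly at random to
the minority size — the standard remedy for the scarcity of experimentally
validated inactive peptides.  `split_peptides()` extracts a random
fraction (default 50 %) as a test set.  The split is deliberately
*unstratified* by default, matching the plain wording of the procedure it
follows; a `stratify` flag exists but is off.  Every seeded operation
appends `(operation, seed)` to the set's audit attribute (`seed_log()`),
so any derived corpus is regenerable from its manifest.

The six truncation variants (`truncation_datasets()`) — N/C halves,
first/last 5, first/last 10 — isolate the termini's discriminative
contribution.  Halves reconstruct the parent exactly
(`n_half ++ c_half = sequence`), which the suite asserts for every
generated corpus member.

## 4. PLS-DA classifier

`plsda_fit()` regresses the 0/1 class response on the autoscaled
descriptor matrix by NIPALS PLS1 with deflation.  Conventions:

* Class coding 0/1 with a 0.5 decision threshold on the continuous
  prediction (equivalent to symmetric ±1 coding up to an affine map).
* NIPALS start vector: the descriptor column of maximal variance;
  convergence when successive weight vectors change by < 1e−10 in norm;
  500-iteration cap with an error naming the offending component.  (With a
  single response column the inner loop converges in two passes; the loop
  exists so the implementation is the general algorithm, not a shortcut.)
* Autoscaling statistics are computed on training data only and frozen
  into the model for prediction; prediction enforces the training column
  schema and reports missing/extra columns by name.
* Zero-variance descriptors are dropped with a warning (a constant column
  cannot be autoscaled and carries no signal).
* Cross-validated predictive power `plsda_q2()` uses Q² = 1 − PRESS/TSS
  with seeded-shuffle fold assignment, 7 folds by default (a common
  chemometrics software default; the original analysis does not state its
  exclusion pattern, so this default is documented rather than claimed).
  When `n_components` is not fixed, the count maximizing Q² over
  1…`max_components` is chosen and the full trace is stored in
  `training_meta`.

The implementation is cross-checked three ways in the test suite: a
one-component fit against a normal-equations oracle, orthogonality and
residual-norm monotonicity of the extracted components, and numerical
agreement (to 1e−10) with an independent PLS implementation on a small
matrix.

`confusion_metrics()` reports sensitivity, specificity, accuracy and MCC
on a 0–100 scale; zero denominators yield `NA` rather than errors, so
degenerate evaluations stay inspectable.

## 5. Synthetic corpora: what they do and do not show

`generate_corpus()` draws positives from a residue distribution with
boosted Arg/Lys mass (default 35 % cationic mass in the strong preset,
60/40 between R and K) and per-peptide Dirichlet-style composition jitter;
negatives come from a near-uniform composition (10 % cationic mass).  When
`amphipathic` is on, non-cationic positions on one helical face (phase
within 60° of zero at δ = 100°) are replaced by Leu/Ile/Phe/Trp, which
makes the z2 moment respond without diluting the designed charge gap.
Lengths are uniform on 5–30 residues; classes use disjoint random streams
derived from the seed; duplicates within and across classes are redrawn.
Defaults (450 per class at the strong preset) mirror the scale of the real
training corpus the workflow was designed around (900 positives).

The generator emulates exactly the two properties the descriptor set
exploits — cationicity and amphipathicity — and nothing else.  It does not
reproduce the sequence statistics of real CPP databases: no family
structure, no shared motifs, no label noise, no length–class correlation.
Consequently, passing the recovery tests shows the pipeline *can* detect
the designed signal through descriptors, balancing, splitting and PLS-DA;
it does not certify any particular accuracy on real corpora.  The
null-separation preset (identical compositions) closes the loop from the
other side: held-out MCC is centered on zero, so the pipeline does not
manufacture signal where none exists.

`generate_property_table()` produces residues × properties tables as
`scores %*% t(loadings) + noise` with orthonormal factor columns and
decreasing per-component strengths (ratios rank : … : 1, scaled to unit
average signal variance).  The stored generating scores are defined on the
autoscaled noiseless signal via the generator's own SVD — the
representation scale construction works in — so per-component recovery
correlations are identifiable up to sign; with arbitrary rotated factors
that comparison would be ill-posed.

## 6. One-compartment infusion pharmacokinetics

The simulator is an analytic one-compartment model with linear
elimination: volume V = Vc·BW, rate constant k = CL/V, infusion rate
R₀ = Dose/T_inf,

$$C(t) = \frac{F R_0}{CL}(1 - e^{-kt}) \;\; (t \le T_{inf}), \qquad
  C(t) = C(T_{inf})\, e^{-k(t-T_{inf})} \;\; (t > T_{inf}),$$

giving Cmax at exactly the end of infusion and
AUC₀₋∞ = F·Dose/CL independent of V.  Mass balance
CL·AUC₀₋∞ = F·Dose holds to machine precision and is asserted across
parameter sweeps.  The default grid is 1441 points over 24 h (1-minute
resolution) with T_inf inserted exactly so the peak is on the grid;
`pk_auc_t()` integrates trapezoidally and converges monotonically to the
analytic integral under grid refinement.

This model order was chosen because, for the packaged drug/peptide
parameter sets, it reproduces the reference simulations' AUC values
exactly (they are pure F·Dose/CL arithmetic) and conjugate Cmax to within
0.01 % — the conjugates' small distribution volumes (0.11–0.18 L/kg) put
k·T_inf ≫ 1, saturating the peak at the AUC plateau.  For gemcitabine
itself (Vc 1.45 L/kg) the closed-form peak is ≈ 6.02 µg/mL versus the
reference full-PBPK value 5.9505 µg/mL — a documented ≈ 1.2 % surrogate
gap attributable to distribution kinetics the one-compartment model does
not represent.  The reference software's internal compartmental
configuration is proprietary and unprintable, so this gap is documented,
not resolved.  Plasma-protein binding, blood/plasma ratios and liver
concentrations are carried as annotations in `pk_parameter_table()`; no
tissue model is fitted because no governing equations are available for
one.

Units are mg, L, h throughout; concentrations in µg/mL (numerically mg/L),
exposures in µg·h/mL.

## 7. Peptide-level reference scores

`peptide_zscore_reference()` stores published per-peptide z-scores for the
four reference CPPs.  These came from a *peptide-level* PCA over an
undisclosed descriptor matrix, and they do not equal per-residue mean
z-scores (penetratin: stored z1 = 2.3233 vs residue mean 2.1898).  Since
the projection is unrecoverable, the package stores the values as
reference data, asserts the residue-mean value against a hand-summation
oracle, and deliberately does not attempt to reproduce the stored ones.

## 8. Problem sizes and known limitations

The test suite exercises the classification pipeline at 450 + 450 peptides
over 20 seeds (mirroring the design scale of the workflow), property-table
recovery over 50 seeds, and metric bounds over 10⁴ random confusion
quadruples; these sizes keep the full suite around a minute on one CPU
while leaving the stochastic medians stable.

Known limitations:

* Descriptors are global; position-specific features are out of scope by
  design, so the models cannot express positional motifs.
* The hydrophilic set's Thr/Gly/Tyr membership is empirically undecidable
  from the available reference values (documented above).
* The PK surrogate is deliberately minimal: no absorption, distribution or
  tissue compartments, hence the documented Cmax gap for drugs with large
  distribution volumes.
* Synthetic corpora are compositionally realistic but phylogenetically
  naive; performance numbers on them are properties of the generator, not
  estimates of real-world accuracy.
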