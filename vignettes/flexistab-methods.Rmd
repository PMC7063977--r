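---
title: "Designing thermostabilizing point mutations from B-factors and consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing thermostabilizing point mutations from B-factors and consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexistab)
```

## The design idea

Crystallographic temperature factors (B-factors) are proportional to the
mean-square displacement of atoms about their equilibrium positions, so the
per-residue Cα B-factor is a cheap, structure-wide flexibility read-out.
The stabilization strategy implemented here combines two independent lines
of evidence:

1. **Flexibility.** Residues whose normalized B-factor stands well above
   the chain average are candidate weak points: local rigidification tends
   to improve kinetic thermostability.
2. **Consensus.** Across a family of homologs from thermophilic organisms,
   the most frequent residue at a position is, on average, stabilizing.
   Where a flexible position of the target differs from the family
   consensus, substituting the consensus residue is a rational, single-site
   stabilization proposal.

The pipeline therefore proposes, for every residue inside a detected
flexible region whose aligned column has a plurality residue different from
the target's own, the substitution *wild-type → consensus*, labelled in the
usual `K64N` style.

## Normalized B-factors

Raw B-factors are not comparable between crystals (they absorb resolution,
refinement protocol and lattice effects), so the profile is z-scored within
one chain:

$$B'_i = \frac{B_i - \langle B \rangle}{\sigma(B)}$$

`normalize_bfactors()` uses the **population** standard deviation
(divide by *N*) by default, because the chain is the entire population of
interest, and records the convention in its output; the sample convention
is a switch (`sd_convention = "sample"`). The choice only rescales `B'` by
$\sqrt{N/(N-1)}$ and never changes the ranking. The z-score is invariant
under any affine rescaling of the raw values, which the tests exercise
directly.

Parsing rules (`read_pdb_calpha()`): only `ATOM` records (no HETATM, no
waters); author residue numbering throughout, 1-based, inclusive; for
alternate locations the highest-occupancy Cα wins, ties going to the
alphabetically first altloc; insertion-coded residues keep file order;
nonstandard residues are kept with one-letter code `X` and a warning;
normalization is per chain, each chain getting its own mean and sd.

## Flexible regions

`detect_flexible_regions()` reports maximal runs of at least `min_run`
consecutive residues with $B' \ge$ `threshold`. Runs never bridge a chain
break or a numbering gap larger than one. The defaults — `threshold = 1.0`
(one standard deviation above the chain mean) and `min_run = 3` (a single
hot residue is more often noise than a flexible element) — are our own
operating point; no published cutoff exists for this step, which is why
both are plain function arguments and CLI flags. A region is reported with
its span, member positions, and peak $B'$.

## Consensus and mapping

`column_profiles()` counts residues per alignment column and reports the
plurality non-gap residue and its frequency among non-gap characters,
the gap fraction, and a Shannon-entropy conservation score (reported, but
not used for filtering — plurality frequency is the filter because it is
the quantity the consensus argument is actually about). Plurality ties are
broken deterministically by one-letter alphabet order. Columns that are
all gaps are flagged degenerate. The query must already be a row of the
alignment: aligning is a solved problem (mafft, muscle, ...) and deliberately
out of scope; `map_query_to_columns()` only connects structure numbering to
columns through the query row's gap structure plus a user-supplied offset.

Design filters (`propose_mutations()`): a column must have
`consensus_freq >= 0.5` and `gap_frac <= 0.5` to support a proposal. Both
are arguments. Proposed cysteines are flagged (unpaired-cysteine risk) but
not suppressed — that is a wet-lab judgement call, not ours to make
silently. The ranking score
`w1 * min(B'/3, 1) + w2 * consensus_freq` (weights 0.5/0.5, cap at
$B' = 3$) is a deterministic tie-ordering aid only; no candidate is ever
dropped because of its score.

On the worked example shipped in the tests — a flexible stretch
`63-TKWDCK-68` against a family consensus `TNITCT` over the same columns —
the pipeline emits exactly `K64N`, `W65I`, `D66T`, `K68T`: positions 63 and
67 already match the consensus and so yield nothing.

## Enzyme kinetics

`fit_michaelis_menten()` defaults to the Lineweaver–Burk double-reciprocal
fit (ordinary least squares of $1/v$ on $1/[S]$; $V_{max} = 1/\text{intercept}$,
$K_m = \text{slope}/\text{intercept}$), which is the classical assay
work-up. The reciprocal transform is known to inflate the influence of the
smallest rates, so the package also provides a direct nonlinear
least-squares fit of $v = V_{max}[S]/(K_m+[S])$ (Levenberg–Marquardt,
started from the Lineweaver–Burk estimate) as the recommended cross-check;
on noiseless data both recover the generating parameters to machine
precision, and the tests require their agreement on noisy replicates.

The turnover number is handled conservatively: published $k_{cat}$ values
are not always reproducible from $V_{max}$ because the conversion depends
on the mass basis and on whether active sites were titrated. A measured
`kcat_per_s` is therefore accepted as input and used as-is; when absent and
a molar mass is supplied, $k_{cat} = V_{max} \cdot M / 60$ (with $M$ in
mg/µmol, numerically the kDa mass) is computed and labelled `"derived"` —
the two conventions are never mixed silently. Catalytic efficiency is
$k_{cat}/K_m$ in /s/mM; fold-changes are mutant/wild-type ratios, rounded
to two decimals only in reports.

## Thermal inactivation

Residual activity (% of the untreated control) versus incubation time is
modelled as first-order decay. `estimate_half_life()` offers:

* `"first-order-fit"` (default): OLS of $\ln(\text{residual})$ on time over
  the points with positive residual; $t_{1/2} = \ln 2 / k$ holds by
  construction. Non-decaying series are an error, not a negative half-life.
* `"nearest-timepoint"`: the sampled time whose residual is closest to 50%
  (ties toward the earlier time). This is how half-lives are commonly
  quoted straight off an assay grid, and it is the method to use when
  reproducing such quoted values; its resolution is obviously limited to
  the sampling grid.

Residual activities above 100% are retained with a warning — renormalizing
or truncating would silently change later differences. Gains are reported
in percentage points at a common sampled time (`residual_activity_gain()`),
with an exact-time match required rather than interpolation.

## Ensemble post-processing

The MD engine itself is out of scope; the package post-processes
conformational ensembles (multi-MODEL PDB, one MODEL per frame, nanometers
internally, angstrom converted on read).

* **Superposition** (`superpose()`): closed-form least-squares rigid fit
  (SVD of the cross-covariance with a determinant guard so only proper
  rotations occur), selection defaulting to all Cα atoms, reference frame
  1. Fewer than three selected atoms, or a collinear selection, is an
  error: the rotation would be underdetermined. The fit is verified in the
  tests against bio3d's independent implementation and against frames with
  known planted rotations.
* **RMSF** (`compute_rmsf()`):
  $\mathrm{RMSF}_i = \sqrt{\langle |r_i(t) - \langle r_i \rangle|^2 \rangle}$
  per selected atom, RMS-aggregated per residue. Calling it on an
  unsuperposed ensemble is an error unless explicitly overridden, because
  global motion inflates RMSF silently. For isotropic per-coordinate
  Gaussian displacement of width $\sigma$ the expectation is
  $\sigma\sqrt{3}$, which the synthetic generator exploits as ground truth.
* **Hydrogen-bond occupancy** (`hbond_occupancy()`): percentage of frames
  in which the donor–acceptor heavy-atom distance is ≤ 0.35 nm and, only
  when a hydrogen is present and named, the D–H⋯A angle is ≥ 120°. These
  are common MD-practice defaults and both are arguments; the angle test
  is skipped for coarse ensembles without hydrogens rather than silently
  failing every frame.

## Synthetic data and what it does (not) show

All generators are seed-deterministic (one seeded RNG scope per call that
never touches the caller's RNG stream) and return a machine-readable truth
manifest; downstream tests read ground truth only from the manifest.

* `gen_pdb()` writes a single-chain Cα trace on a straight line — geometry
  is irrelevant to B-factor analysis and the documentation says so, so
  nobody mistakes it for a fold. Baseline B-factors are a constant plus
  small clamped noise with **alternating sign** along the chain; this makes
  "the planted bump is the only contiguous stretch above $B' = 1$" a hard
  combinatorial guarantee rather than a high-probability event. Defaults
  (300 residues, bump at 63–68, +10 Å² on a 20 Å² baseline) keep the
  worked example recognizable.
* `gen_msa()` plants a per-column consensus (default frequency 0.70, gap
  rate 0.05, 92 homolog rows — a realistic single-family harvest) around a
  gap-free query row; remaining characters are uniform over the other 19
  residues. Real alignments have phylogenetic correlation and column-wise
  rate variation that this generator deliberately lacks, so passing tests
  demonstrate the counting and mapping logic, not robustness to biased
  taxon sampling.
* `gen_kinetics()` / `gen_decay()` evaluate the closed forms on the
  standard assay designs (doubling dilutions 10 → 0.078125 mM; 50 °C and
  60 °C time grids) with multiplicative Gaussian noise of chosen CV.
* `gen_ensemble()` scatters a helical Cα trace (helical so that
  superposition is well-posed even at $\sigma = 0$) with per-residue
  isotropic displacement, optional per-frame rigid transforms, and an
  optional planted donor–acceptor contact schedule whose occupancy is
  exact by construction (the two atoms are exempted from noise).

Problem sizes used by the shipped test-suite and acceptance script — 1,000
30-residue profiles for the region-scan equivalence, 500 noisy kinetic
replicates at 2% CV, 200 decay replicates, 5,000-frame ensembles for the
RMSF expectation — were chosen so the whole suite runs in well under a
minute per property while keeping Monte-Carlo error far from the asserted
bounds.

## Known limitations

* Consensus is plurality frequency; no phylogenetic weighting, so a
  lopsided taxon sample can masquerade as conservation.
* The Lineweaver–Burk estimator is kept unweighted because that is the
  classical protocol being mirrored; for new data, prefer the nonlinear
  method.
* Half-life read-off resolution equals the sampling grid; the first-order
  fit assumes single-exponential inactivation and will average over
  biphasic decay.
* mmCIF, anisotropic B-factors, occupancy-weighted altloc averaging,
  binary trajectory formats and PBC unwrapping are all unsupported by
  design.
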