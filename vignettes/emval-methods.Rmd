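---
title: "Methods and design of the emval validation toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the emval validation toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emval)
```

`emval` validates 3D electron-microscopy density maps and the coordinate
models fitted into them. This vignette documents the underlying models,
the numerical conventions, the tunable parameters and their defaults, and
what the synthetic test fixtures do and do not demonstrate about real data.

## Map I/O and conventions

Maps are read and written in the CCP4/MRC format (modes 0, 1 and 2 read,
mode 2 written). Two conventions are fixed once, at load time:

* **Axis order.** File axes are permuted so that in-memory data always run
  x-fastest. All downstream Fourier and interpolation code assumes this
  single convention.
* **Origin.** The Ångström-valued MRC2000 origin fields are used when any
  is non-zero; otherwise the start indices times the voxel size. The choice
  is recorded in `origin_source`, since both dialects occur in circulating
  files.

Header statistics are never trusted: they are recomputed from the data, and
a disagreement produces a warning — validation must describe the actual
content of the file, not its label. Because mode-2 files store 32-bit
floats, values are reproduced at single precision; the exported `float32()`
helper predicts exactly what a file will hold, and a once-round-tripped map
round-trips bit-exactly thereafter.

## Fourier Shell Correlation

The FSC between two volumes on the same grid is the normalized cross-power
over concentric shells one reciprocal-grid step wide, with bin index
`round(|s|/Δs)`, `Δs = 1/(N·voxel)`. Shells whose centers exceed Nyquist
(the corner of the Fourier cube) are dropped; the DC term is its own shell
and never participates in resolution estimation. Per-shell counts tally the
independent Fourier voxels of a real-input transform: conjugate pairs count
once, self-conjugate voxels once. Cubic-enough voxels are required
(max/min ratio ≤ 1.001), since spherical shells are meaningless on strongly
anisotropic reciprocal grids.

Resolution is the reciprocal of the first threshold crossing, scanning from
low to high frequency with linear interpolation between adjacent shell
centers — no smoothing, so the estimate is deterministic and reproducible.
Four criteria are provided: fixed 0.5 and 0.143 thresholds, and the
count-dependent half-bit and 3σ curves

$$T_{1/2\mathrm{bit}}(n) = \frac{0.2071 + 1.9102/\sqrt n}{1.2071 + 0.9102/\sqrt n},
\qquad T_{3\sigma}(n) = 3\sqrt{2/n}.$$

No symmetry correction is applied to the counts. Note a structural property
of the 3σ criterion: on small grids its threshold exceeds 1 in the
lowest-count shells, so the first-crossing rule fires immediately. This is
a property of the criterion, not a defect of the scan, and is one reason
estimates under different conventions disagree; the fixed-threshold
criteria are the robust choice at desk scale.

A curve that never crosses reports "not reached" with the Nyquist
resolution as a bound — an answer, not an error.

## Designed-SNR half-map fixtures

The generator builds half-maps as `signal + independent white noise`. For
white noise of variance σ² the expected Fourier power per voxel is
`Nvox·σ²` (unnormalized FFT), so the designed per-shell SNR is
`P_signal(s)/(Nvox·σ²)` with `P_signal` the signal's rotationally averaged
power spectrum, and the expected FSC follows the classical closed form
`SNR/(SNR+1)`. `noise_sigma_for_snr1()` inverts this to place the SNR=1
crossing — where FSC is expected to pass 0.5 — at a chosen frequency, which
is how the test suite checks parameter recovery: over 20 seeds on a 32³
grid, the fixed-0.5 estimate must land within one shell width of the
designed frequency in at least 90% of runs. Per-shell agreement with
`SNR/(SNR+1)` is asserted on the mean over 10 seeds within ±0.05: a single
realization fluctuates with standard deviation ≈ `(1−FSC²)·√(2/n)`, which
already exceeds 0.05 at moderate shell counts, so only the seed-averaged
curve is a meaningful test statistic at these grid sizes.

These fixtures emulate the *statistics* of half-map pairs (independent
additive noise on a common signal, seeded sub-streams per half). They do
not emulate CTF effects, masking bias, alignment errors or non-white noise,
so passing tests demonstrate correctness of the estimator, not performance
on any particular experimental pathology. Masking/phase-randomization
corrections and map-vs-model FSC are out of scope.

## Single-map statistics

The density histogram uses equal-width bins spanning `[min, max]`,
right-open except the last bin, so counts conserve the voxel total. The
volume-versus-contour curve counts voxels *at or above* each level
(`≥`, chosen so the recommended contour encloses its own level set) times
the voxel volume, and is non-increasing by construction. The rotationally
averaged power spectrum reuses the FSC shell machinery. Projections and
central slices use 0-based index conventions with the central plane at
`⌊N/2⌋`. The recommended contour level itself is always an input (the
depositor's display threshold); emval never derives one.

## Trace-model geometry

Trace-only chains are classified structurally: a chain is Cα-only
(resp. P-only) when every residue is a single CA (resp. P) atom; mixed
chains are not traces. Consecutiveness is decided by residue numbering, not
distance: a numbering gap denotes unmodeled residues and is skipped rather
than flagged as an absurdly long bond.

* **Cα–Cα distances** are flagged only when outside the `mean ± 3σ` window
  of *both* the cis and the trans peptide reference distributions (the
  two-window rule: a distance acceptable under either isomer is
  acceptable). The multiplier is configurable; the comparison is strict at
  the boundary. The nearest class by |z| is recorded with each finding.
* **P–P distances** are flagged when strictly below 4.4 Å or strictly
  above 8.0 Å; the bounds themselves are acceptable, reading "shorter
  than"/"longer than" as strict.
* **Pseudo-Ramachandran.** For each residue *i* with consecutive neighbors
  *i−1, i+1, i+2*, the pseudo-angle θ = ∠(CAᵢ₋₁, CAᵢ, CAᵢ₊₁) ∈ [0°, 180°]
  and pseudo-torsion η = dihedral(CAᵢ₋₁…CAᵢ₊₂) ∈ (−180°, 180°] are looked
  up in a 5°×5° reference frequency grid (nearest bin); the residue is an
  outlier when its bin frequency is below a cutoff chosen so that 0.05% of
  reference mass lies below it. Angles are assigned to the second residue
  of the window — one convention had to be fixed, and it is recorded in the
  output metadata.
* **Close contacts** flag pairs with `d < r₁ + r₂ − 0.4 Å` (the common
  clash convention; configurable), excluding pairs within one residue and
  backbone–backbone pairs of consecutive residues, which are bonded or 1-3
  neighbors. A uniform spatial grid with half-space neighbor enumeration
  keeps this near-linear; the suite proves it equal to the all-pairs oracle
  on 200-atom fixtures.
* **Atom inclusion** samples density at atom positions by trilinear
  interpolation (exact at voxel centers; nearest-voxel is exposed as an
  option since production pipelines differ), honors the map origin, counts
  atoms outside the grid as excluded, and is non-increasing in the contour
  level.

### Reference distributions are versioned inputs

The packaged defaults use the canonical peptide-geometry values
(trans 3.81 ± 0.02 Å, cis 2.94 ± 0.05 Å) for the Cα–Cα windows and a
**synthetic** pseudo-Ramachandran grid built deterministically from a
seeded ensemble of coordinate-perturbed ideal helical and extended traces
(120 perturbed copies of 40-residue traces, 0.12 Å coordinate noise). This
grid concentrates mass in the regular-secondary-structure regions of the
(θ, η) plane; it is adequate for validating regular traces and for all
package tests, but will over-flag genuine loop conformations. It stands in
for a grid derived from high-resolution experimental structures, which is
why references carry an id, a documented JSON schema
(`write_reference_json()` / `read_reference_json()`) and are accepted by
every check as an argument: substituting a curated experimental reference
requires no code change.

## Report assembly and sliders

`assemble_report()` runs every assessment its inputs support and never
aborts on a partial failure: each section carries `status = "ok"|"failed"`
with the error message preserved, because a deposition-time report that
dies on its worst input is useless precisely when needed. Indicators
(clashes per 1000 atoms, outlier fractions, atom inclusion) are compared
against reference populations by mid-rank percentile,
`100·(worse + 0.5·equal)/n` — stable, monotone, and symmetric between the
lower-better and higher-better directions. The shipped populations
(`inst/extdata/ref_populations_synthetic.json`) are synthetic samples with
the documented schema, not archive statistics; archive-scale population
curation, and populations stratified by resolution, are explicitly out of
scope. Reports are deterministic given fixed inputs (the timestamp can be
pinned via `config$timestamp`), which the suite checks byte-for-byte.

## Numerical choices and problem sizes

FSC correctness is proven against a direct-summation DFT oracle on 8³ and
12³ grids to 1e-9; null behavior with 20 seed pairs at 32³ against the
`3/√n` counting bound; SNR recovery at 32³ with 10 and 20 seeds as above.
These sizes were chosen as the smallest at which shell statistics are
meaningful, and keep the whole suite around ten seconds. Gaussian-atom
fixtures sample atom Gaussians at voxel centers without integrating over
voxels — adequate for σ ≥ 1 voxel, where the integral check agrees to 1%.
Degenerate inputs have fixed answers rather than errors where a sensible
answer exists: constant maps histogram into one bin, single-residue chains
yield empty findings, a never-crossing FSC yields a bound.

## Known limitations

* The pseudo-Ramachandran default grid is synthetic (above); production use
  should substitute an experimentally derived grid.
* No symmetry-corrected effective voxel counts in the count-dependent FSC
  criteria; imposed symmetry inflates effective counts and biases the
  half-bit/3σ criteria optimistic on symmetric reconstructions.
* Close-contact exclusion is name-based (backbone atom names), not
  connectivity-based; exotic residues with non-standard atom names may be
  over- or under-excluded.
* Full covalent-geometry, torsion, rotamer and ligand validation of
  full-atom models is out of scope here; those assessments belong to the
  established all-atom validation pipelines. emval contributes the
  trace-geometry, map-statistics and FSC layers around them.
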