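# emval — validation of 3DEM maps and atomic models

Single-particle electron cryo-microscopy produces 3D density maps whose
quality cannot be judged from the map alone: resolution claims rest on the
internal consistency of two reconstructions from independent data halves,
and a quarter of EM-derived models in the archive are *trace-only*
(Cα-atom-only protein chains, P-atom-only nucleic acid chains) and escape
conventional all-atom geometry validation. `emval` is an R toolkit for
depositors, curators and methods developers that implements this validation
surface end-to-end on CCP4/MRC-style maps and PDB/mmCIF models.

## What it computes

**Resolution from half-maps.** The Fourier Shell Correlation between
half-maps *a* and *b* over shells of spatial frequency *s*,

    FSC(s) = Re Σ_s F_a F̄_b / sqrt( Σ_s |F_a|² · Σ_s |F_b|² ),

with resolution estimated at the first threshold crossing (linear
interpolation between shell centers) under the common criteria: fixed 0.5,
fixed 0.143, the half-bit curve `(0.2071 + 1.9102/√n)/(1.2071 + 0.9102/√n)`
and the 3σ curve `3/√(n/2)`, where *n* is the per-shell independent Fourier
voxel count. Curves round-trip through the standardized FSC deposition XML.

**Single-map statistics.** Density histogram, rotationally averaged power
spectrum, enclosed volume versus contour level, orthogonal projections and
central slices.

**Trace-model geometry.** Consecutive Cα–Cα distances are flagged when they
fall outside the ±3σ windows of *both* the cis and the trans peptide
reference distributions; consecutive P–P distances when strictly shorter
than 4.4 Å or longer than 8.0 Å; pseudo-Ramachandran outliers from the
(pseudo-angle θ, pseudo-torsion η) of each Cα window of four against a
reference frequency grid; plus van-der-Waals close contacts and model atom
inclusion in density at a contour level (trilinear interpolation).

**Validation report.** A JSON report with the map information table, the
findings, key quality indicators and percentile "sliders" against reference
populations (mid-rank percentiles), plus PNG plots.

**Synthetic fixtures.** Seeded generators for Gaussian-atom maps, half-map
pairs with a designed per-shell SNR (expected FSC = SNR/(SNR+1)), ideal and
perturbed helical Cα traces and collinear P traces make every computation
testable end-to-end without archive data.

## Worked example

```r
library(emval)

# a 10-residue ideal helix rendered into a 32^3 map, 1 A voxels
model  <- helix_trace(10)
a <- model$atoms; ctr <- (32 - 1) / 2
a$x <- a$x - mean(a$x) + ctr; a$y <- a$y - mean(a$y) + ctr
a$z <- a$z - mean(a$z) + ctr
model  <- atom_model(a)
signal <- gaussian_atom_map(model, dim = 32, voxel_size = 1, sigma = 1.5)

# half-maps with the SNR=1 crossing designed at 0.25 1/A (4 A)
halves <- half_map_pair(signal, noise_sigma_for_snr1(signal, 0.25), seed = 42)
estimate_resolutions(compute_fsc(halves$a, halves$b))
#>     criterion resolution crossing_frequency reached
#> 1   fixed-0.5   3.980146          0.2512471    TRUE
#> 2 fixed-0.143   3.380807          0.2957874    TRUE
#> 3    half-bit   3.556422          0.2811815    TRUE
#> 4 three-sigma  32.000000          0.0312500    TRUE
```

The fixed-0.5 estimate (3.98 Å) recovers the designed 4 Å SNR=1 frequency to
within one shell width; the 3σ criterion fires at the first shell on such a
small grid because its threshold exceeds 1 where shells hold only a handful
of voxels — the reason different criteria disagree in practice.

```r
pp_distance_outliers(p_trace(spacing = c(4.3, 6.0, 8.1)))
#>   chain resno_a resno_b distance reason outlier
#> 1     A       1       2      4.3  short    TRUE
#> 2     A       2       3      6.0   <NA>   FALSE
#> 3     A       3       4      8.1   long    TRUE

atom_inclusion(model, signal, contour = 0.2)$fraction
#> [1] 1
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/emval.R synth --kind halves --out fix/ --seed 4 --size 32
Rscript inst/cli/emval.R fsc --half1 fix/half1.mrc --half2 fix/half2.mrc --out curve.xml
Rscript inst/cli/emval.R modelcheck --model model.pdb --out findings.json --strict
```

Exit codes: 0 success, 1 findings present under `--strict`, 2 usage/input
error.

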