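# megarray: minimum-assumption MEG sensor-array design

Magnetoencephalography (MEG) measures the magnetic fields of neuronal
currents with an array of point magnetometers around the head.  `megarray`
treats array design as a well-posed measurement-engineering problem: under
a bandlimited vector-spherical-harmonics (VSH / signal-space-separation)
field model, any noiseless full-rank array reconstructs the field in the
sensor region exactly, so competing designs differ only in how much they
amplify sensor noise.  The package is aimed at instrumentation researchers
designing on-scalp (e.g. optically-pumped magnetometer) and conventional
MEG arrays.

## The figure-of-merit

With measurements `phi = S x` (S the m-by-n VSH measurement matrix,
n = La(La+2) + Lb(Lb+2) for internal/external cutoffs La, Lb), the
neuronal field component at any location-orientation pair (r, e) is
estimated by the virtual sensor

    phi_a(r, e) = s_{r,e} I_a S^+ phi ,

and i.i.d. sensor noise of sd sigma propagates to the estimate with sd
`||s_{r,e} I_a S^+|| sigma`.  The design score is the worst case

    q(xi) = max_{r in V_samp, ||e|| = 1} ||s_{r,e} I_a S^+(xi)|| ,

the noise-amplification factor over a helmet-shaped sampling volume.  The
package provides the basis and q machinery, helmet/shell geometry with
quasi-uniform spiral point sets, a seeded simulated-annealing optimizer
over sensor positions and orientations, and an independent validation
metric — the Shannon channel information capacity of the array under a
random-dipole, spherically-symmetric-conductor source model.

## Worked example

```r
library(megarray)

spec <- multipole_spec(10, 3)   # La = 10, Lb = 3
spec$n_components
#> [1] 135

surf <- helmet_surface()        # R = 0.15 m, 0.15 m band, pi/2 face opening
round(surface_area(surf), 2)
#> [1] 0.25

arr  <- radial_array(surf, 240) # uniformly-spaced radial reference array
grid <- sampling_grid(surf)     # 1000-point evaluation grid
figure_of_merit(arr, spec, grid)
#> Noise amplification over 1000 grid points: q = 123.6, mean = 71.72
```

A worst-case amplification of 123.6 means that, at the least favourable
location and orientation in the helmet, the interpolated neuronal field
component carries 123.6 times the noise of a single physical sensor —
the quantity the optimizer then minimizes.  A scaled-down optimization
(40 sensors, n = 32 basis components, 50 annealing iterations):

```r
spec4 <- multipole_spec(4, 2)
init  <- radial_array(surf, 40)
traj  <- optimize_array(init, surf, spec4, grid,
                        optimizer_config(iterations = 50, seed = 1))
traj
#> Annealing run: 21000 cost evaluations, q 40.34 -> 2.112 (seed 1)
```

Orientations spread away from radial while the worst-case amplification
drops ~19-fold; `array_capacity()` scores the same arrays in bits per
sample under the default 1000-dipole source model.  The
`run_radial_sweep()`, `run_optimization_experiment()` and
`evaluate_array()` drivers script these workflows, and
`inst/cli/megarray` exposes them as shell commands (`radial-array`,
`evaluate`, `optimize`, `capacity`, `radial-sweep`).

See the methods vignette (`vignettes/array-design.Rmd`) for the model,
the numerical conventions (pseudoinverse equilibration, pole handling,
spiral construction) and the limitations of the idealized design
conditions.

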