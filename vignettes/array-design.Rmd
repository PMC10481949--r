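---
title: "Minimum-assumption MEG sensor-array design with megarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-assumption MEG sensor-array design with megarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megarray)
```

## The design problem

Magnetoencephalography (MEG) measures, outside the head, the magnetic
fields of neuronal currents with an array of point magnetometers.  Most
figures-of-merit for array design score how well an array supports source
estimation, which forces assumptions about the sources.  `megarray` takes
the minimum-assumption view: the array's only job is to measure the
*neuronal component of the magnetic field* accurately everywhere sensors
could have been placed.  Under a bandlimited field model, any noiseless
full-rank array does this perfectly, so arrays differ solely in how much
they amplify sensor noise — and that amplification factor is the quantity
we minimize.

## Field model

In the source-free sensor region the field is curl- and divergence-free,
so it is the gradient of a harmonic scalar potential and can be expanded
in vector spherical harmonics (VSH), the basis familiar from signal space
separation (SSS):

$$
B(r) \;=\; \sum_{l=1}^{L_\alpha}\sum_{m=-l}^{l} \alpha_{lm}
  B^\alpha_{lm}(r)
\;+\; \sum_{l=1}^{L_\beta}\sum_{m=-l}^{l} \beta_{lm} B^\beta_{lm}(r),
$$

with internal components $B^\alpha_{lm} = -\nabla\!\left(r^{-(l+1)}
Y_{lm}\right)$ describing fields of sources inside the helmet (the brain)
and external components $B^\beta_{lm} = -\nabla\!\left(r^{l}
Y_{lm}\right)$ describing far-away interference.  The truncation
$(L_\alpha, L_\beta)$ gives $n = L_\alpha(L_\alpha+2) +
L_\beta(L_\beta+2)$ components; the package default $(10, 3)$ gives
$n = 135$.  Components are ordered internal-first, degree then order
ascending; this ordering is part of the public contract.

The basis normalization is a fixed documented convention: orthonormal
real spherical harmonics (with the Condon–Shortley phase carried by the
associated Legendre functions of `pracma::legendre`) and unit leading
coefficients in the potentials.  The figure-of-merit below is provably
invariant under any fixed per-component rescaling of this convention when
the measurement matrix has full column rank, and the test suite checks
that invariance explicitly, so the choice is immaterial for the results.

An array $\xi$ of $m$ sensors $(r_i, e_i)$ measures $\phi = S x$, where
row $i$ of the $m \times n$ matrix $S$ holds $e_i \cdot B_j(r_i)$.

## Noise amplification figure-of-merit

Solving $\phi = S x$ by the Moore–Penrose pseudoinverse and keeping only
the internal block (selector $I_\alpha$) yields a *virtual sensor*: the
estimated neuronal field component at any location–orientation pair,

$$
\hat\phi_\alpha(r, e) = s_{r,e}\, I_\alpha S^+ \hat\phi .
$$

With i.i.d. sensor noise of standard deviation $\sigma$, the estimate's
noise is Gaussian with standard deviation $\lVert s_{r,e} I_\alpha S^+
\rVert\,\sigma$.  The figure-of-merit is the worst case over the sampling
volume and all orientations,

$$
q(\xi) = \max_{r \in V_{\mathrm{samp}},\ \lVert e\rVert = 1}
  \lVert s_{r,e}\, I_\alpha S^+(\xi) \rVert ,
$$

the worst-case noise amplification factor.  The inner maximization over
orientations is computed exactly as the largest singular value of the
$3\times m$ matrix $F(r)\, I_\alpha S^+$, where the rows of $F(r)$ are
the Cartesian basis-field components at $r$ ($s_{r,e} = e^\top F(r)$ is
linear in $e$); a dense-orientation brute force is retained only as a
test oracle.  The spatial maximum is approximated on a fixed
discretization grid (below); `mean_amp` reports the arithmetic mean over
grid points of the *per-point worst case over orientations* — the
orientation treatment of the mean is a documented package choice.

### Numerical notes

The pseudoinverse is SVD-based.  Because the raw VSH columns of $S$ span
roughly ten orders of magnitude ($r^{-(l+2)}$ versus $r^{l-1}$ radial
scaling), the numerical rank is decided on a column-equilibrated copy
$S D^{-1}$ ($D$ = column norms) with relative cutoff
$\max(m,n)\,\varepsilon\,\sigma_{\max}$; a plain relative cutoff on the
raw matrix misdetects the rank (it reports 128 of 135 for the default
240-sensor radial array).  For full column rank the equilibrated route
returns exactly the Moore–Penrose inverse — the same diagonal-rescaling
invariance as above.  When $S$ is rank deficient (e.g. $m = 120 < 135$),
the minimum-norm pseudoinverse is computed in the raw basis convention
(top-rank singular triplets of the raw SVD), which is what reference SSS
pipelines produce for underdetermined arrays; the result is flagged.
Minimum-norm inverses are convention-dependent objects, so rank-deficient
$q$ values should be compared only within one convention.

Spherical-gradient formulas are singular on the polar axis; evaluation
points are displaced off the axis by clamping the polar angle at
$10^{-10}$ rad (a sub-picometre displacement at helmet radii), which the
finite-difference oracles in the tests show is far below all tolerances.

## Geometry and grids

The sampling volume is helmet-shaped: a hemisphere of radius $R$ joined
to a cylindrical band extending 0.15 m below the equator, with a
$\pi/2$-wide azimuthal opening for the face removed from the band.  The
2D volume is that surface (default $R = 0.15$ m); the 3D volume is the
shell between the $R = 0.15$ m and $R = 0.25$ m surfaces.  The face
opening's azimuthal placement (centred on $+x$) is a fixed convention;
the metric is indifferent to it by symmetry.

Quasi-uniform point sets are laid with a single golden-angle spiral over
the helmet treated as a surface of revolution parameterized by cumulative
area; band candidates falling in the face opening are rejected and the
candidate count is raised until exactly the requested number survive.
This generalizes the classic spiral-on-a-sphere construction to the
helmet while staying deterministic.  *Uniformly-spaced radial arrays* —
spiral points oriented along the outward normal — are the non-optimized
reference design.

The default figure-of-merit grids are 1000 spiral points for 2D volumes
and 5 concentric helmet surfaces times 500 points (2500 total) for the 3D
shell.  The five shell radii are evenly spaced over $[0.15, 0.25]$ m
endpoint-inclusive, i.e. 0.025 m apart: a five-shell grid on that
interval cannot have 0.02 m spacing, so the shell count, interval and
total point count take precedence.  $q$ on a grid is a lower bound on the
continuous maximum; grid refinement is available through the grid
configuration and convergence in grid density is a diagnostic the user
can run, not an automatic refinement.

## Optimizing an array

Sensor placement is a continuous box-bounded problem by construction:
each sensor carries a cumulative-area coordinate $u \in [0,1]$ and a
scaled azimuth $v \in [0,1]$ (the band part of the $v$ range excludes the
face opening), a radial coordinate $t \in [0,1]$ for 3D shells, and two
orientation angles.  Every point of the box decodes to an admissible
array, so the search can never propose an infeasible configuration.
Orientation poles are a benign chart degeneracy (the cost is continuous
there).

The annealing engine is `stats::optim(method = "SANN")` — Belisle's
Metropolis annealer with logarithmic cooling — driven on the $\log q$
scale so that the temperature parameter has a scale-free meaning
(`temp = 1` accepts an $e$-fold worsening of $q$ with probability
$e^{-1}$ at unit temperature).  The proposal kernel perturbs one randomly
chosen sensor per step with Gaussian steps whose size decays
geometrically from 60% to 2% of each coordinate's range across the run;
azimuthal coordinates wrap, the others reflect at the bounds.  One
*iteration* is a block of `evals_per_iteration` cost evaluations (default
twice the parameter count, the scale used by generalized
simulated-annealing implementations); budgets default to 1000 iterations
and at most $10^7$ cost evaluations.  A box-constrained local search
(L-BFGS-B on $\log q$, capped by `polish_budget` evaluations) finishes
the run from the best configuration, mirroring the local-search stage of
dual annealing.  A single integer seed fixes the whole trajectory
bitwise.

## Channel information capacity

As an independent check, designs are scored by Shannon channel capacity
under a random-source model: $p = 1000$ current dipoles uniform in a ball
of radius 0.07 m about the origin (radius by the inverse-CDF rule
$r = R u^{1/3}$), orientations uniform on the sphere, independent
amplitudes with equal variances summing to the squared total RMS moment
$2\times10^{-8}$ A·m.  The forward model is the closed-form field of a
current dipole in a spherically symmetric conductor centred at the
expansion origin — the same spherical symmetry assumed throughout, and
the model in which radial dipoles are exactly silent (the classic
unmeasurable source).  With lead field $L$ and sensor noise
$\sigma = 10^{-14}$ T,

$$
I = \tfrac12 \sum_i \log_2\!\left(\lambda_i/\sigma^2 + 1\right),
$$

over the eigenvalues $\lambda_i$ of $L \Sigma L^\top$ (tiny negative
eigenvalues within $-10^{-12}\lambda_{\max}$ are clipped; anything more
negative is an error).  The source covariance structure beyond the RSS
constraint is a package choice (equal diagonal), and the dipole ensemble
is fixed per evaluation run by its seed.

## A worked example at reduced scale

The full design conditions (240 sensors, $n = 135$, 1000 iterations)
make optimization a multi-day computation.  The package's automated
checks therefore exercise a scaled-down replica whose behavior mirrors
the full problem: 40 sensors, $(L_\alpha, L_\beta) = (4, 2)$ so $n = 32$,
the 2D helmet surface at $R = 0.15$ m with its 1000-point grid, and 50
annealing iterations.

```{r scaled-run, eval = FALSE}
spec  <- multipole_spec(4, 2)
surf  <- helmet_surface()
grid  <- sampling_grid(surf)
init  <- radial_array(surf, 40)
traj  <- optimize_array(init, surf, spec, grid,
                        optimizer_config(iterations = 50, seed = 1))
traj
c(initial = array_capacity(init, seed = 1),
  final   = array_capacity(traj$final, seed = 1))
```

In such runs the worst-case amplification drops well over fivefold from
the radial starting point (the test suite asserts exactly this), sensor
orientations spread away from radial, and — in 3D runs started on the
outer shell surface — a substantial fraction of the sensors migrates
down to the inner surface.  These are the qualitative signatures expected
of the full-scale optimization.  Two of them are scale-dependent, and at
reduced problem size they appear only partially: the inward migration
reaches a sizeable minority rather than a near-total majority of sensors
(with a low-degree basis the fields are smooth enough that inner-wall
proximity matters less), and the channel capacity, after its
characteristic early dip, recovers toward — but not fully back to — the
radial starting level, because with few sensors each orientation matters
for source coupling.  The automated checks assert the trends that do
reproduce at reduced scale and compute both capacities explicitly.

## What the synthetic conditions do and do not show

All evaluation inputs are generated internally: helmet geometry, spiral
grids, random dipole ensembles, bandlimited random coefficient vectors.
They emulate the idealized design setting — point sensors, exactly
bandlimited fields, i.i.d. Gaussian sensor noise, a spherically symmetric
conductor.  Passing tests therefore demonstrate the correctness of the
machinery and the internal consistency of the design metric; they do not
speak to truncation error from real unbandlimited fields, correlated or
non-Gaussian sensor noise, realistic head conductors, or the correlated
noise of multi-sensor virtual arrays, all of which are outside the model.
The interpolation-noise statistic describes a single virtual sensor at a
time; a virtual *array* assembled from it would have correlated noise.

## Known limitations

* Anatomically constrained volumes (MRI head surfaces) are not
  implemented; the volume abstraction leaves room for them but no MRI
  reader is provided.
* Rank-deficient ($m < n$) figures-of-merit depend on the pseudoinverse
  convention, as discussed above.
* $q$ is a grid maximum; pathologically narrow amplification peaks
  between grid points would be missed at the default densities.
* Only single-axis point magnetometers are modelled — no gradiometers or
  multi-axis sensors.
* Full-scale optimization (240 sensors, 1000 iterations) is a multi-day
  computation; the automated suite exercises scaled-down replicas, and
  the scale-dependent signatures noted above transfer only qualitatively.
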