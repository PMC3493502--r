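---
title: "Coordinated map optimization: model, numerics, and pinwheel statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated map optimization: model, numerics, and pinwheel statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(mapcrystal)
```

## The model

`mapcrystal` simulates the joint development of visual cortical maps as a
gradient flow of coupled two-dimensional order-parameter fields on a
periodic domain.  The orientation-preference (OP) map is a complex field
$z(\mathbf x)$: the preferred orientation is $\theta = \tfrac12\arg z$ and
$|z|$ is the orientation selectivity.  Ocular dominance (OD) and further
columnar systems are real fields $o_i(\mathbf x)$; their zero contours are
the OD borders and a constant bias $\gamma_i > 0$ represents contralateral
dominance.  Pinwheels — point defects of $z$ around which every orientation
is represented once — carry a topological charge $q = \pm\tfrac12$
(half the winding of $\arg z$).

Each field on its own follows Swift–Hohenberg dynamics, the canonical
pattern-forming system with a supercritical bifurcation at a preferred
wavelength.  In Fourier space the linear operator is diagonal with spectrum
$$\lambda(k) = r - \left(k_c^2 - k^2\right)^2/k_c^4 ,$$
maximal ($= r$) on the critical circle $|k| = k_c$.  We use dimensionless
units: the OP wavelength is $\Lambda_z = 1$ (so $k_{c,z} = 2\pi$), a real
field $i$ has $k_{c,i} = 2\pi w_i$ with wavelength ratio $w_i$, and time is
measured in the intrinsic unit $\tau = 1/r_z$, i.e. the whole right-hand
side is rescaled by $1/r_z$ so the fastest OP modes grow at unit rate.  The
coupled flow is
$$\partial_t z = \frac{1}{r_z}\Big[\hat L_z z - |z|^2 z
  - \frac{\delta U}{\delta \bar z}\Big], \qquad
  c_i\,\partial_t o_i = \frac{1}{r_z}\Big[\hat L_i o_i - o_i^3 + \gamma_i
  - \frac{\delta U}{\delta o_i}\Big],$$
the descent of the energy
$E = \big\langle -\bar z \hat L_z z + \tfrac12|z|^4\big\rangle
 + \sum_i \big\langle -\tfrac12 o_i \hat L_i o_i + \tfrac14 o_i^4
 - \gamma_i o_i \big\rangle + \langle U \rangle$.
The inter-map coupling energies form the symmetry-classified family
$$U = \alpha\, o^2|z|^2 \;+\; \beta\,|\nabla z \cdot \nabla o|^2
  \;+\; \tau\, o^4 |z|^4 \;+\; \varepsilon\,|\nabla z \cdot \nabla o|^4,$$
with $\nabla z\cdot\nabla o = \partial_x z\,\partial_x o + \partial_y
z\,\partial_y o$ a complex scalar.  The package implements each term for
arbitrary field pairs (complex–real and real–real) and sums pairwise terms
for multi-map models.  The quartic gradient coupling
($\varepsilon$-term) is the default in all crystallization experiments: it
favours high-gradient regions of the two maps crossing at right angles,
reproduces the contour relationships observed between OP and OD maps, and
cannot suppress the OP map outright.

Two conventions deserve note.  First, coupling forces are computed
spectrally in divergence form, and the spectral derivative operators drop
the single-sided Nyquist mode of even grids; this makes the derivative an
exactly antisymmetric real-linear map, so the implemented forces are the
*exact* discrete gradients of the implemented energies (verified in the
test suite by central differences at single grid points — the
self-consistency contract that fixes all prefactor conventions).  Second,
the time-unit factor $1/r_z$ multiplies *every* field's right-hand side, so
a bias $\gamma$ acting on a zero state gives $\partial_t o =
\gamma/(c\,r_z)$.

## Implicit integration

The dynamics is stiff ($\lambda \to -\infty$ off the critical circle) and
attractor approach is slow, so the package integrates fully implicitly:
a Crank–Nicolson step
$F(u') = u' - u - \tfrac{dt}{2}\left[N(u') + N(u)\right] = 0$
is solved by an inexact Newton method.  The Jacobian is never formed: its
action is a forward finite difference
$[F(u+\epsilon v) - F(u)]/\epsilon$ with
$\epsilon = \sqrt{\epsilon_{mach}}\,(1 + \lVert u\rVert)/\lVert v\rVert$,
and each Newton system is solved by restarted GMRES (Arnoldi with modified
Gram–Schmidt, Givens-updated Hessenberg least squares; restart dimension
30, relative tolerance $10^{-4}$).  The preconditioner is the inverse of
the linearized Crank–Nicolson operator, diagonal in Fourier space, with a
small shift $\eta = 0.01$ against singular factors; the integrator also
folds the mean-field cubic stiffness ($2\langle|z|^2\rangle$,
$3\langle o_i^2\rangle$) into that diagonal, without which the Krylov
iteration degrades once amplitudes saturate.  A backtracking line search
on $g(s) = \tfrac12\lVert F(u + s\,\delta u)\rVert^2$ (plain halving until
decrease) guards Newton globally; convergence is declared at RMS residual
$10^{-8}$, and a failed solve rejects the time step.

Step control is by step doubling: one full step is compared against two
half steps, the RMS difference divided by $2^2 - 1 = 3$ is the local error
estimate, accepted against tolerance $10^{-4}\,\mathrm{RMS}(u) + 10^{-9}$,
and the step grows by at most $1.5\times$ (shrinks by at least
$0.5\times$).  Global order 2 against the exact linear propagator, energy
monotonicity and bitwise determinism are asserted in the test suite.
Snapshots are stored on an exponential schedule
$t_j = t_0\,(t_f/t_0)^{j/(J-2)}$ with $t_0 = 0.1\tau$, preceded by the
initial condition at $t = 0$ (150 frames by default); the step is clamped
to land on frame times exactly.  A run ends at `t_end` or when the RMS
right-hand side stays below $10^{-6}$ for one $\tau$.

## Initial conditions

All generators are deterministic in (parameters, seed):

* **Band-pass Gaussian white noise** — independent Gaussian amplitudes on
  the annulus $|k/k_c - 1| \le b/2$ (relative bandwidth $b = 0.2$ by
  default), normalized to the target power exactly.  The default initial
  OP power is $2\%$ of $r_z$, the power of the saturated stripe attractor,
  matching a low-selectivity immature map.  Ensembles of such maps have
  mean pinwheel density slightly above the Gaussian lower bound $\pi$.
* **Stripes** — $z = A e^{i(\mathbf k \cdot \mathbf x + \phi)}$ on a
  lattice wavevector; pinwheel-free, and stationary at $A = \sqrt{r_z}$.
* **Hexagons** — three lattice wavevectors near $|k| = k_c$ at mutual
  $120^\circ$ summing to zero exactly, resonant phases
  $\phi_1+\phi_2+\phi_3 = 0$, plus a mean offset.  The generator refuses
  grids whose lattice cannot host a near-$120^\circ$ triad (default
  tolerance $4^\circ$).

Domain lengths must hold an integer number of wavelengths of every field
(enforced at model construction), which keeps the discrete critical circle
balanced; meshes resolve at least 8 points per wavelength.

## Pinwheel detection, tracking, and statistics

Pinwheel centres are crossings of the zero contours of $\mathrm{Re}\,z$
and $\mathrm{Im}\,z$: in every mesh cell with sign changes in both parts
the two bilinear interpolants are intersected exactly (elimination yields
a quadratic), giving subcell positions on the periodic domain.  Charges
are half the winding number of $\arg z$ on a circular loop of radius 1.5
cells (24 samples, retried at twice the radius on ambiguity); non-simple
zeros are flagged, never silently dropped.  The pinwheel density is
$\rho = N\Lambda^2/(l_x l_y)$, dimensionless.  Nearest-neighbour distances
(any / equal / opposite charge) use the minimal-image torus metric in
units of $\Lambda$.  Density variability is measured by the standard
deviation of pinwheel densities over random circular regions, binned in
area ($[0.25, 9]\,\Lambda^2$, 30 log bins, up to 1000 regions per bin)
and fitted with $SD(A) = c\,A^{-\gamma_v}$ on log–log axes; a Poisson
pattern gives $\gamma_v = \tfrac12$.

Tracking matches pinwheels between consecutive frames when they carry the
same charge and lie within $0.2\,\Lambda$ (greedy by increasing distance,
one-to-one).  Unmatched pinwheels count as annihilated or created, so
$N_{j+1} = N_j + c_j - a_j$ holds exactly; rates are per hypercolumn per
$\tau$, and their stability is checked by doubling the frame count.
Survival fractions $s(t_0, t)$ follow lineages from a reference frame; the
reference for "power saturation" is the first frame with OP power at 95%
of its final value.  The matching radius is not dictated by theory; the
suite reports the sensitivity of event counts over radii
$[0.1, 0.3]\Lambda$.

## Study conditions and their calibration

The crystallization experiments (`kinetics_config()`) use $r_z = 0.05$,
$r_o = 0.25$ — OD dominant, $r_z/r_o \ll 1$, the regime in which
inter-map coupling can restructure the OP map.  The OD bias must lie in
the range where the *uncoupled* OD equation selects hexagons; sweeping
$\gamma$ at $r_o = 0.25$ the package finds stripes up to $\gamma \approx
0.10$ and clean hexagons from $\gamma \approx 0.15$ (mode amplitude
$\approx 0.15$, mean $\approx 0.16$), so the experiments fix $\gamma =
0.15$ and seed the OD map with that hexagonal pattern plus band-pass
noise.  The OP map starts from band-pass noise at 2% of the stripe power.
The quartic gradient coupling strength is quoted in raw units of
$\varepsilon$; the package's reference values — `eps_weak()` and
`eps_strong()`, the defaults of `kinetics_config()` — were located by a
coarse logarithmic sweep of final planforms: around `eps_weak()` runs
converge to stripes or rhombic pinwheel crystals depending on the seed, in
the transition band above it stripes still occasionally win, and from
`eps_strong()` upward the hexagonal pinwheel crystal dominates (stripes
were never observed to form there, the defining property of the
high-coupling regime).  All qualitative outcomes are invariant under a
common positive rescaling of $\varepsilon$.

Simulation sizes in the package's tests and acceptance runs are chosen for
a desk-scale reproduction: $8\times8\,\Lambda^2$ domains at $64^2$ mesh
(8 points per wavelength, $\gtrsim 200$ pinwheels per noise map) with
small ensembles of 3–5 seeds, rather than the much larger domains a
production study would use.  This size is also where crystallization is
*reliable*: on larger desk-scale domains ($10\,\Lambda$ and up) strong
coupling frequently leaves long-lived mixed stripe/rhombic/hexagon states
within affordable integration times, exactly the inter-digitated domain
competition expected of this dynamics.  Crystal *densities* are
essentially insensitive to domain size (every crystallized run lands at
5.0–5.25 per hypercolumn, set by the lattice geometry); the *kinetic*
statistics are not.  In particular, at 8–10 $\Lambda$ crystallization completes shortly
after the OP power saturates, so the fraction of saturation-time pinwheels
surviving to the attractor comes out high (roughly 0.75–0.9) compared with
large-domain runs, where rearrangement continues long after saturation and
only about two thirds survive.  Growing the domain restores the timescale
separation but at a computational cost outside a desk-scale suite; the
acceptance material reports the desk-scale value and this caveat rather
than tuning either.

Two further desk-scale observations.  Uncoupled runs usually collapse to
pinwheel-free stripes, but individual runs can lock into a metastable
stripe grain boundary carrying a short chain of defects (density
$\approx 0.5$); collapse is therefore asserted on small-ensemble means.
Weak-coupling runs anneal slowly and may end in mixed rhombic/stripe
states; genuine rhombic pinwheel crystals are identified by requiring two
*balanced* active mode directions (`classify_pattern()$balance`
$\ge 0.5$) in addition to the rhombic mode count.

## What the generators do not emulate

The synthetic initial conditions are statistically homogeneous and
isotropic; they contain no retinotopic structure, no areal borders, no
measurement noise, and no biologically derived correlations (e.g. from
retinal ganglion cell mosaics).  Passing tests therefore demonstrate the
internal consistency of the model, integrator and statistics — not that
cortical development follows this dynamics.  The crystalline attractors
the model reaches are themselves known to differ qualitatively from the
irregular layouts of real OP maps; reproducing that disagreement
(pinwheel densities near 5.2 or 3.5 rather than the experimental
$\approx\pi$) is the point of the numerical study.

## Numerical choices and degenerate inputs

* Tolerances: Newton $10^{-8}$ RMS, GMRES $10^{-4}$ relative, step control
  $10^{-4}$ relative; halving the step tolerance changes final states by
  less than the tolerance ratio (self-convergence test).
* Degenerate detection cells (all four corners zero) are flagged with a
  cell-centre position rather than dropped; duplicate crossings within a
  tenth of a cell are merged.
* Charge loops crossing further zeros: retried at doubled radius, then
  flagged with the measured winding.
* Tie-breaks in tracking are resolved by global distance ordering, which
  is deterministic.
* The stationarity stop requires the RMS right-hand side to stay below
  tolerance for a full $\tau$, so transient near-stationary saddle
  passages (common during mode competition) do not end runs prematurely.

## Example

A small uncoupled run — band-pass noise decaying to stripes, the pinwheel
density collapsing towards zero:

```{r example, eval = FALSE}
cfg <- kinetics_config(seed = 1, epsilon = 0, nx = 64, L = 8,
                       t_end = 1000, frame_count = 30)
fs <- run_simulation(cfg)
bundle <- analyze_frames(fs)
bundle$final_density          # ~ 0: pinwheel-free stripes
plot(fs)                      # power plateau -> rise -> saturation
render_map(fs$frames[[length(fs$frames)]], pinwheels = TRUE)
```

Strong coupling (`epsilon = kinetics_config()$model$couplings[[1]]$strength`
by default) instead drives the map to a hexagonal pinwheel crystal with
density near 5.2 per hypercolumn, most of whose pinwheels are created — not
preserved — during crystallization.

## Known limitations

* Attractor identity at small domains can depend on the seed (stripe,
  rhombic and hexagonal domains compete); classification by active Fourier
  modes is provided to separate the outcomes.
* The amplitude-equation analytics (phase diagrams, stability boundaries)
  are outside the package's scope; coupling strengths are located
  numerically, not from the analytical critical values.
* No shift–twist coupling, non-periodic boundaries, or long-range
  interactions.
```
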