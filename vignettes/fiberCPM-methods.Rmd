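---
title: "Modelling cell-matrix mechanical reciprocity with fiberCPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell-matrix mechanical reciprocity with fiberCPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberCPM)
```

## The model

fiberCPM couples three sub-models of a single contractile cell on a fibrous
extracellular matrix (ECM):

1. **Cell shape: a cellular Potts model (CPM).**  The cell is the set of
   lattice sites with spin 1 on a square grid (default 200 x 200 sites,
   one site = 0.25 µm).  Shape evolves by Metropolis dynamics on the
   Hamiltonian

   $$H = \lambda A^2
       + J \sum_{\vec x}\sum_{\vec x' \in NB(\vec x)}
         \mathbb 1\,[\sigma(\vec x) \ne \sigma(\vec x')]
       - \lambda_c \frac{A}{A + A_h},$$

   with $A$ the cell area, $NB$ the Moore (second-order) neighbourhood,
   $\lambda$ a quadratic contractility, $J$ an interfacial line tension and
   $\lambda_c, A_h$ a saturating substrate-adhesion gain.  The double sum
   counts each unordered mismatched pair twice; $J$ is calibrated under
   that convention.  One Monte Carlo step performs as many elementary copy
   attempts as there are lattice sites: a random site copies its spin onto
   a random Moore neighbour with probability $1$ if $\Delta H \le 0$ and
   $e^{-\Delta H/T}$ otherwise — the standard energy-minimising Metropolis
   convention.  Copy
   attempts into the outermost lattice ring are rejected, keeping the cell
   away from the clamped ECM boundary.  Cell connectivity is not enforced.

2. **ECM mechanics: a cross-linked bead-spring network.**  Each fiber is a
   chain of beads joined by harmonic springs (stiffness $K$, rest length
   $r_{\mathrm{polymer}}$); consecutive triples carry a harmonic bending
   potential $\tfrac{K_{\mathrm{bend}}}{2}(\theta - \theta_0)^2$ with
   $\theta_0 = \pi$.  Cross-links are short springs (stiffness
   $K_{\mathrm{cross}} = K$) joining beads of different fibers.  Beads obey
   the overdamped Langevin equation
   $\gamma\,\dot{\vec b}_i = \vec F_i + \vec W_i$ with
   $\langle \vec W_i \rangle = 0$,
   $\langle \vec W_i^2 \rangle = 2\gamma T_{\mathrm{ECM}}/\Delta t$.  Beads
   whose initial position falls outside the domain are clamped.

3. **Focal adhesions (FAs): catch-slip integrin clusters.**  An FA binds
   one lattice site to one ECM bead (pinned to the site centre).  Its
   integrin count obeys

   $$\frac{dN}{dt} = \gamma_b (N_{\mathrm{tot}} - N)
     - d_0\, d\!\left(\frac{f^{*}\Phi}{N}\right) N,
   \qquad d(\varphi) = e^{\varphi - \phi_s} + e^{\phi_c - \varphi},$$

   so detachment is fast at low tension (catch branch), minimal at
   $\varphi = (\phi_s + \phi_c)/2 = 5.89$, and fast again at high tension
   (slip branch).  The steady state
   $N^*(\varphi) = \gamma_b N_{\mathrm{tot}}/(\gamma_b + d_0 d(\varphi))$
   is unimodal in $\varphi$ — this is the mechanosensing kernel of the whole
   model: adhesions mature only where the ECM lets tension build.

The sub-models are coupled by **operator splitting**.  One coupling step
(2.88 s of physical time; 10^4 steps ≈ 8 h) executes, in order: (i) one CPM
sweep, during which an accepted extension over a free bead creates a
nascent FA ($N = N_0$) and an accepted retraction over an FA removes it;
(ii) cell centre-of-mass refresh; (iii) one greedy displacement attempt per
FA — the Moore neighbour best aligned with the centre direction is accepted
iff it lowers $E_{\mathrm{cyto}} + E_{\mathrm{ecm}}$, where
$E_{\mathrm{cyto}} = \tfrac{K_{\mathrm{cyto}}}{2}\lVert \vec x -
\vec x_{\mathrm{centre}}\rVert^2$ and $E_{\mathrm{ecm}}$ sums only the
springs attached to the FA bead; (iv) network relaxation with clamped and
FA beads held fixed; (v) tension update; (vi) one step of the integrin ODE
per FA.  Retractions over sites whose FAs have grown beyond $N_0$ pay the
saturating energy penalty
$\Delta H_{\mathrm{FA}} = \lambda_{\mathrm{FA}}\,X/(X + N_h)$ with
$X = \max(0, \sum (N - N_0))$; the numerator is clamped at zero so a
shrunken adhesion never *rewards* retraction.  This penalty is the ratchet
that converts transient protrusions into lasting spread area wherever
adhesions mature.

## What the tension on an adhesion is

The FA sits between two springs: the cytoskeletal spring pulling it toward
the cell centre and the ECM resisting.  At a displacement stall the two
force magnitudes coincide; away from stall they differ, and only the ECM
side reports substrate stiffness.  `fa_params(tension_source=)` offers both
readings.  The default is `"ecm"`: $\Phi$ is the magnitude of the resultant
network force on the pinned bead after relaxation.  We chose this over the
cytoskeletal reading ($K_{\mathrm{cyto}}\,\lVert\vec x -
\vec x_{\mathrm{centre}}\rVert$) because the cytoskeletal force is blind to
stiffness once displacement stalls — it cannot produce the biphasic
stiffness response — whereas the ECM force naturally scales with
$K \times$ (lattice-scale stretch), which at $K = 0.031$ N/m is 8–16 nN,
exactly the reported traction scale.  On soft networks each greedy move is
accepted and the network follows, so tension never builds; at intermediate
stiffness moves stall with a few nN sustained, adhesions mature and the
cell spreads; on very stiff networks the first accepted moves already load
nascent adhesions into the slip branch and they die, rounding the cell.

## Units and parameter values

Mechanical quantities are handled internally in micrometres, nanonewtons
and femtojoules (1 fJ = 1 nN µm = 10⁻¹⁵ J); all user-facing parameters are
physical (N/m, N m, Pa, µm, s).  Reference values: contractility
$\lambda = 4.96\times 10^{7}\,$N m⁻³, line tension
$J = 9.30\times10^{-3}\,$N m⁻¹, adhesion $\lambda_c = 3.87\times
10^{-13}\,$N m, $T = 50$, $\lambda_{\mathrm{FA}} = 800$,
$K_{\mathrm{cyto}} = 3.10\times10^{-4}\,$N m⁻¹, fiber stiffness
$K = 3.10\times10^{-2}\,$N m⁻¹ (from a cylindrical collagen rod:
$K = Y \pi (d/2)^2 / L$ with $Y = 10^6$ Pa, $d = 0.125$ µm, $L = 0.4$ µm,
see `modulus_to_spring_constant()`), $K_{\mathrm{bend}} =
3.88\times10^{-15}\,$N m rad⁻², fiber density 0.48 µm⁻², binding/unbinding
rates $\gamma_b = 2.88\,$s⁻¹, $d_0 = 0.0288\,$s⁻¹, force scale
$f^{*} = 1.29\times10^{10}\,$N⁻¹, $\phi_s = 4.02$, $\phi_c = 7.76$,
$N_{\mathrm{tot}} = 390$, ECM noise $T_{\mathrm{ECM}} = 0.001$.

Three constants are not fixed by those values and were set as the package's
own calibration, once, before the behavioural test suite was frozen:

* **`energy_unit` (default 4 × 10⁻¹⁷ J).**  The Hamiltonian coefficients are
  physical but the Metropolis temperature is dimensionless, so an energy
  scale must be chosen.  We calibrated it on the cell *without* ECM — the
  stated purpose of the CPM coefficients — so that the free cell keeps a
  stable area (~150–250 sites) with visible boundary activity: the
  interfacial cost of one boundary step is then ≈ 1 T, the contractility
  derivative reaches T at ≈ 5000 sites (≈ 320 µm², the spread-cell scale),
  and the FA penalty saturates at 16 T, making retraction over a mature
  adhesion essentially forbidden.  A four-fold smaller unit freezes the
  boundary (protrusion acceptance < 1%) and the adhesion ratchet stalls.
* **`A_h` (default 3.125 µm² = 50 lattice sites).**  The printed saturation
  constant (50, with an inconsistent unit) only yields a stable free cell
  when read in lattice sites; read as 50 µm² the adhesion gain can never
  beat the line tension — the ratio is independent of the energy unit — and
  the cell evaporates.
* **Fiber discretisation**: `r_polymer` = 0.4 µm (the segment length that
  makes the rod formula reproduce K = 3.1 × 10⁻² N/m) and `n_beads` = 31,
  i.e. a 12 µm contour, roughly one cell length.

Two more FA constants appear only in the retraction penalty and are
config-exposed: $N_0 = 25$ (just above the zero-tension steady state
$N^*(0) = 15.95$, so unloaded nascent adhesions decay and release no
penalty) and $N_h = 100$ (spanning the observed range of mature sizes up to
$N_{\mathrm{tot}} = 390$, so the penalty discriminates soft from stiff).

## Network generation

Random networks draw `round(fiber_density * area)` fibers: the middle bead
uniform in the domain, the orientation von Mises$(\mu, \kappa)$ (sampled
with the Best–Fisher rejection method; $\kappa = 0$ is isotropic,
$\kappa = 10$ the anisotropic condition), beads laid out straight through
the middle bead.  Cross-linking enumerates all bead pairs on distinct
fibers within a 0.5 µm capture radius, shuffles them, and accepts pairs
until `round(crosslink_density * area)` cross-links are placed (rest length
0.1 µm); exhaustion of candidates is a warning, not an error.  The exact
procedure of the work this generator follows is not public; the capture
radius and sampling order here are explicit stand-ins, which is the likely
reason the generated networks percolate from ≈ 0.4 µm⁻² cross-links rather
than ≈ 1 µm⁻².  Regular ("grid") networks are axis-aligned strands spanning
the domain, cross-linked at every intersection with the rest length equal
to the creation distance, so the undeformed grid is stress-free.
Percolation (`is_percolated()`) means a connected bead component touching
two opposite domain sides, in either axis.

## Numerical choices

* **Relaxation.**  Explicit overdamped Euler steps with
  $\Delta t = 0.1\,\gamma/k_{\max}$ ($k_{\max}$ the stiffest spring
  constant, including $K_{\mathrm{bend}}/r_0^2$).  With the reference noise
  level the force-based convergence test cannot trigger (the noise floor
  exceeds any useful tolerance), so in the coupled loop each relaxation
  runs a fixed substep budget (`relax_max_steps`, default 200; the initial
  relaxation 2000) — a quasi-steady-state schedule in the spirit of
  operator splitting.  Standalone `relax_network()` keeps a convergence
  tolerance (`force_tol`, default 10⁻⁴ nN) and a 10⁴-substep cap.
* **Integrin ODE.**  In the slip branch the detachment rate can exceed
  10²⁰ s⁻¹; explicit stepping is hopeless.  `integrate_integrins()` uses
  exponential (exact-linear) substeps: the rate is frozen at the current
  $N$, the then-linear ODE is solved exactly, ten substeps per coupling
  step.  This is unconditionally stable and reproduces the analytic fixed
  points to better than 1%.  $N$ is clamped to $[N_{\min}, N_{\mathrm{tot}}]$
  with $N_{\min} = 1$ (the per-integrin tension diverges as $N \to 0$).
* **Degenerate geometry.**  Two adhesions may legally pin their beads to
  the same site centre, making an interior fiber angle undefined.  Exported
  energy/force functions treat a coincident triple as an error; the
  integrator and the tension update skip it (its force limit at the
  straight rest state is zero anyway).
* **Bending force.**  The harmonic angle gradient contains a
  $(\theta - \theta_0)/\sin\theta$ factor; it is continuous through the
  straight state and the (measure-zero) fully folded state is skipped.
* **Sigmoid fits.**  `fit_sigmoid()` uses Levenberg–Marquardt least squares
  initialised at $L$ = series maximum, $t_0$ = first half-maximum crossing,
  $k$ = 4 / rise interval, with $k$ bounded positive; constant series and
  fits whose onset lands outside the observed range (± one span) are
  flagged degenerate and excluded from lag distributions.
* **Shape statistics.**  The nematic order parameter is the resultant form
  $S = \lVert \langle e^{2i\theta} \rangle \rVert$ (weights = segment
  lengths; matches the stated endpoints $S = 0$ isotropic, $S = 1$
  aligned).  Eccentricity uses the covariance eigenvalues of the cell-site
  centres, $e = \sqrt{1 - \lambda_2/\lambda_1}$.  The annulus statistic
  averages final-time bin order parameters between $r$ and $1.5r$ from the
  cell centre with $r$ the mask's major-axis length.
* **RNG.**  One master seed feeds separate named streams (CPM, network
  generation, ECM noise, adhesions), so toggling ECM noise does not perturb
  the CPM draw sequence; trajectories are bit-reproducible for a fixed seed
  and schedule.

## What the generator emulates — and what it does not

The synthetic networks emulate the *geometry and connectivity* of dilute
cross-linked collagen: straight semiflexible fibers of one cell length,
tunable orientation order and tunable connectivity.  They do not emulate
fiber plasticity (no breakable cross-links), excluded volume (the cell body
can overlap fibers it is not adhering to), strain stiffening, fiber
bundling, or three-dimensional topology.  Passing behavioural tests
therefore show that mechanosensitive adhesion kinetics *suffice* for
stiffness-biphasic spreading, elongation along fiber anisotropy and
remodel-before-spread in this idealised geometry; they do not validate the
mechanical constitutive behaviour against real gels.

## Problem sizes used by the test suite

The reference configuration (200 × 200 sites = 50 × 50 µm, 1200 fibers,
10⁴ steps) is what `run_simulation()` defaults to.  The test suite runs the
same model on reduced instances chosen as the smallest that still express
each behaviour: 64 × 64 sites (16 µm domain, ≈ 120 fibers) with 500–2000
coupling steps and 2–3 seeds per condition for the spreading, anisotropy
and displacement sweeps; 60 × 60 sites with per-step recording for the
onset-lag analysis; the full 50 × 50 µm domain for network percolation
(20 replicates per cross-link density).  At these sizes median adhesion
tensions sit in the 10⁻¹⁰–10⁻⁸ N range; the 8–15 nN single-adhesion band
reported for fully spread cells corresponds to centre distances of tens of
µm and is reached only at the full scale.

## Known limitations

* The energy-unit and `A_h` calibrations are reconstructions; other
  combinations could reproduce the same qualitative behaviour with shifted
  time scales.
* FA lifetimes are unrealistically long: nothing ruptures a mature
  adhesion at the cell rear, so simulated cells spread but do not migrate.
* The cross-linking algorithm is a stand-in (see above), shifting the
  percolation threshold relative to the generating procedure it replaces.
* With ECM noise on, "steady state" is a fixed relaxation budget, not a
  convergence certificate; doubling `relax_max_steps` changes desk-scale
  results only marginally but has not been profiled at full scale.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulation_config(scenario = "anisotropic", seed = 1,
                         lattice_size = 64, n_steps = 1000,
                         cell_radius = 12, output_every = 50)
tr <- run_simulation(cfg)
summary(tr)
plot(tr)

# shape and adhesion statistics
st <- tr$final_state
cell_eccentricity(st$grid)
hist(fa_angles(st$fas, st$center), breaks = 20)

# fiber order around the cell
bs <- binned_series(tr, bin = 8, window = 5)
annulus_alignment(bs, st$center, r = mask_major_axis(st$grid))
```
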