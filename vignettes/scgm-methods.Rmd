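---
title: "The single-cell growth model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The single-cell growth model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgm)
```

## The model

A walled cell is described by three coupled quantities: the osmotically
active volume $V_\mathrm{os}$ (total size $V_t = V_\mathrm{os} + V_b$,
with $V_b$ the solvent-inaccessible solid volume), the internal
osmolarity $c_i$, and the turgor pressure $\Pi_t$ carried by the cell
wall. Water crosses the membrane down the combined hydrostatic and
osmotic gradient (Kedem–Katchalsky),

$$\dot V_\mathrm{os} = -J_w, \qquad
  J_w = L_p G\,(\Pi_t + \Pi_e - \Pi_i),$$

with $G$ the surface area of the (spherical) cell and osmotic pressures
from Boyle–van't Hoff, $\Pi = cRT$. Osmolytes are taken up across the
surface, consumed in the volume, and diluted by growth:

$$\dot c_i = \frac{1}{V_\mathrm{os}}
  \left(k_\mathrm{uptake} G - k_\mathrm{consumption} V_t
        - c_i \dot V_\mathrm{os}\right).$$

The wall is a thin elasto-viscoplastic shell: a Hookean element (strain
$\varepsilon = \frac{1-\nu}{E}\frac{\Pi_t r}{2d}$) in series with a
Bingham element that yields only above the critical turgor
$\Pi_{ct}$ at a rate set by the extensibility $\phi$. Differentiating
the serial strain gives a single turgor ODE,

$$\dot\Pi_t = \frac{2Ed}{1-\nu}\frac{\dot r}{r^2}
  - \Pi_t\frac{\dot r}{r}
  - \frac{E\phi}{1-\nu}\,f_m(\Pi_t,\Pi_{ct}),
  \qquad f_m = \max(\Pi_t - \Pi_{ct},\,0).$$

During undisturbed growth the system settles into a moving quasi-steady
state with $\Pi_t \to \Pi_{ct}$ and
$c_i \to c_e + \Pi_{ct}/RT$, and the radius follows

$$\tilde r(t) = r_\mathrm{final} - (r_\mathrm{final} - r_0)\,
  e^{-\lambda (t - t_0)}, \qquad
  \lambda = \frac{k_\mathrm{uptake} R T}
                 {r_\mathrm{final}(\Pi_{ct} + \Pi_e)},$$

with the size limit $r_\mathrm{final} = 3\,k_\mathrm{uptake}/
k_\mathrm{consumption}$: surface-limited uptake balances volume-limited
consumption, and no wall or membrane parameter enters the limit.
`r_final()`, `growth_law()` and `steady_osmolarity()` expose these
closed forms; the tests require the ODE plateau to match `r_final()` to
0.1% and $\tilde r(t)$ to 5% after the initial transient.

### Which volume consumes osmolytes

The consumption term uses the total cell volume $V_t$, while dilution
and the concentration itself live in the osmotic water $V_\mathrm{os}$.
This choice makes the fixed point exact: with consumption scaled by
$V_\mathrm{os}$ instead, the stationary radius would sit at
$r^3 = 3\,k_{u/c}\,r^2 + r_b^3$, about 0.1% above
$3\,k_{u/c}$ for the default solid radius — a small but avoidable bias
against the closed-form limit. Because the solid fraction of a newborn
cell is small, the difference is otherwise negligible.

## Units

Internally: length µm, time s, pressure Pa, amount mmol, concentration
mmol µm⁻³. Concentrations enter and leave the API in mM
(1 mM = 1 mol m⁻³ = 10⁻¹⁵ mmol µm⁻³), times in seconds (CSV interfaces
in minutes, matching 3-min microscopy sampling). In this system
$k_\mathrm{uptake}$ (mmol µm⁻² s⁻¹), $L_p$ (µm s⁻¹ Pa⁻¹) and
$RT$ compose without conversion factors, and the dimension check
$r_\mathrm{final} = 3 k_\mathrm{uptake}/k_\mathrm{consumption}$ (µm) is
a unit-system test.

The default parameter set (`default_params()`) is the standard
parameterization: $E = 2.58\times10^6$ Pa, $\nu = 0.5$, $d = 0.115$ µm,
$L_p = 1.19\times10^{-6}$ µm s⁻¹ Pa⁻¹, $\Pi_{ct} = 0.2$ MPa,
$\phi = 10^{-3}$ Pa⁻¹ s⁻¹, $k_\mathrm{uptake} = k_\mathrm{consumption}
= 2\times10^{-16}$, $c_e = 240$ mM, $T = 303$ K, initial radii
0.1 µm (osmotic) and 0.3 µm (solid), initial turgor 0.2 MPa. The
initial osmolarity defaults to the value that balances the initial
turgor, $c_e + \Pi_t^0/RT \approx 319.4$ mM (the printed 319.17 mM
differs by ~0.07%, consistent with rounding of $RT$).

## Numerical choices

`simulate_scgm()` integrates with `deSolve::lsoda` (adaptive, stiff
capable) at `rtol = 1e-8` and per-state absolute tolerances. The fast
mode is membrane water exchange (sub-second relaxation) against
hour-scale growth; `lsoda` switches to BDF automatically. Shock
protocols are piecewise constant and the integration is restarted at
every step time, so the discontinuity in $c_e$ never falls inside a
step. The wall-yield kink $f_m$ is continuous (C⁰), which adaptive
error control resolves without explicit event location; runs at
10× tighter tolerance are indistinguishable at the reported precision.
Turgor has a floor at zero: when shrinkage would pull it negative, the
membrane is taken to detach rather than the wall to be pulled inward,
and $\dot\Pi_t$ is clamped. The reference radius — the accumulated
irreversible deformation, constant in purely elastic episodes — is
co-integrated in log form, $\mathrm{d}\ln r_\mathrm{ref}/\mathrm{d}t =
(\phi r/2d) f_m$.

## The coupled mother–bud model

Two (or three) model instances share water and osmolytes. The intended
regime is explicit: exchange coefficients are arbitrary but fast enough
that inter-compartment gradients vanish on the time scale of interest.
What that demands quantitatively is severe: with $\phi = 10^{-3}$
Pa⁻¹ s⁻¹ the wall yields so readily that osmolyte-limited growth runs
at working over-pressures of order $10^{-2}$ Pa. Any finite exchange
coefficient an explicit stiff integrator can carry leaves Pa-scale
gaps, within which a young bud's own surface uptake self-pressurizes it
and it expands at *any* extensibility ratio — destroying the
bud-expansion threshold the coupled model exists to produce.

The default integration path therefore implements the fast-exchange
(shared-cytoplasm) limit exactly. Each compartment's wall obeys the
integrated elasto-viscoplastic relation

$$\ln r_j = \ln r_{\mathrm{ref},j} + a_j \Pi r_j, \qquad
  a_j = \frac{1-\nu}{2 d E_j},$$

all compartments share one osmolarity and one turgor $\Pi$, and $\Pi$
evolves by differentiating the shared-water constraint
$\sum_j V(r_j) = V_\mathrm{tot}$ — an ODE that reduces *exactly* to the
single-compartment turgor equation when only one compartment exists.
Slow states are the total osmotic volume, total osmolyte amount, the
shared turgor, and one reference radius per compartment; the radii are
recovered per step by a safeguarded Newton solve of the wall relation.
In this limit the threshold behaviour is sharp: with the mother budding
at 93 min, buds expand only for
$\phi_\mathrm{bud}/\phi_\mathrm{mother} \gtrsim 10^{1.5}$, and the
outcome is monotone in the ratio.

An explicit finite-exchange path (`exchange = "explicit"`, coefficients
$L_x = 10^6 L_p G$, $k_x = 10^9 k_\mathrm{uptake} G/c_e$, the fastest
reliably integrable scale) is retained. It is the right tool when the
pressure differences of interest are elastic-scale ($10^4$–$10^5$ Pa),
as in `sweep_young_modulus()`: a strongly softened bud
($E_\mathrm{bud} \lesssim 0.1\,E_\mathrm{mother}$) expands through an
elastic instability whose dynamics are limited by the finite water
supply through the neck — a regime the algebraic limit cannot represent
(no mechanical equilibrium exists). There the finite-exchange gaps are
genuinely negligible relative to the driving pressures.

Bud initialization: at $t_\mathrm{budstart}$ the bud starts from the
mother's initial osmotic radius (both compartments start from the same
small volume), inherits the mother's instantaneous turgor and
osmolarity (continuity of the shared cytoplasm), and carries a solid
volume scaled by the cube of its initial osmotic radius. Its wall
differs only in extensibility, $\phi_\mathrm{bud} = q\,
\phi_\mathrm{mother}$ (optionally in $E$).

In `sweep_extensibility()` a bud counts as *expanding* when its total
volume grows at least 10-fold over the horizon (default 480 min).
Below the threshold a stalled bud still creeps by up to ~7× over eight
hours (elastic stretch plus residual yield); above it the gain is two
to three orders of magnitude, so any factor between roughly 7 and 700
identifies the same transition.

## The active osmotic-stress response

The HOG-type extension is a deliberately minimal deficit-sensing
surrogate with the coupling contract of the full signaling cascade:
input turgor, output osmolyte production. An active fraction
$H \in [0,1]$ follows

$$\dot H = k_\mathrm{act}\,\max\!\left(0,\,1 -
  \Pi_t/\Pi_\mathrm{ref}\right)(1 - H) - k_\mathrm{deact} H,$$

and drives an internal glycerol pool
$\dot c_\mathrm{gly} = k_\mathrm{gly} H - k_\mathrm{leak} c_\mathrm{gly}
- c_\mathrm{gly}\dot V_\mathrm{os}/V_\mathrm{os}$ that adds to
$\Pi_i$. A mechanistic cascade model can be slotted in behind the same
interface (`hog_rhs()` documents the contract). Defaults
($k_\mathrm{act} = 0.02$ s⁻¹, $k_\mathrm{deact} = 0.002$ s⁻¹,
$k_\mathrm{gly} = 1$ mM s⁻¹, $k_\mathrm{leak} = 10^{-4}$ s⁻¹,
$\Pi_\mathrm{ref} = \Pi_t^0$) were calibrated once so that a
hyperosmotic step of a few hundred mM is compensated within roughly
10–30 simulated minutes, and the response is silent (max $H < 0.05$)
during unperturbed growth. With $k_\mathrm{gly} = 0$ the volume
dynamics reduce exactly to the passive model. HOG-coupled runs default
to initial radii of at least 1.2 µm; in smaller cells growth dilution
makes signaling-species concentrations unphysiologically small, and
`simulate_with_hog()` warns.

## Fitting

`fit_pair()` fits six parameters per mother–bud pair — $k_\mathrm{uptake}$,
$k_{u/c} = k_\mathrm{uptake}/k_\mathrm{consumption}$,
$\phi_\mathrm{mother}$, $q$, $r_0$ (initial osmotic radius) and
$t_\mathrm{budstart}$ (dropped from the free set when supplied by the
data) — by bounded Levenberg–Marquardt least squares on

$$\chi^2 = \frac{1}{\sigma^2}\sum_t
  \left[(V_{m,\mathrm{obs}} - V_{m,\mathrm{sim}})^2
      + (V_{b,\mathrm{obs}} - V_{b,\mathrm{sim}})^2\right],$$

bud terms counting only where an observed bud exists. $\sigma$ is a
declared per-dataset volume noise scale (default 1 µm³); the
$\chi^2 \le 50$ retention rule is meaningful only relative to that
scale and the trajectory length. Observed volumes are matched to total
volume $V_t$ (microscopy sees the whole cell); the solid volume is held
at its default newborn value (0.3 µm radius) rather than scaled with
$r_0$ — scaling it proportionally would give a fitted 1.2 µm cell a
solid volume 27 times its osmotic volume, which is not a plausible
cytoplasm.

Multi-start strategy: a seeded Latin hypercube over the bounds
($k_\mathrm{uptake} \in [10^{-17}, 10^{-14}]$, $k_{u/c} \in [0.3, 3]$ µm,
$\phi_\mathrm{mother} \in [10^{-9}, 10^{-1}]$ Pa⁻¹ s⁻¹,
$q \in [1, 10^6]$, $r_0 \in [0.5, 3]$ µm, $t_\mathrm{budstart}$ up to
80% of the observation span; all but $t_\mathrm{budstart}$ log-scaled),
every start screened by its initial $\chi^2$, the best few polished by
`minpack.lm::nls.lm`. The numeric-Jacobian step is set well above the
ODE solution noise (`epsfcn = 1e-8`, i.e. relative steps ~10⁻⁴ in the
transformed parameters); with machine-epsilon steps the Jacobian
drowns in integrator noise and the optimizer stalls. Profile fits
(`fixed = c(q = ...)`) accept an `init` vector for the usual
continuation from the unconstrained optimum. Fits are deterministic
given the seed and never throw on optimizer failure.

Identifiability, measured on noiseless synthetic data at the
cohort-median parameters: $k_\mathrm{uptake}$, $k_{u/c}$, $r_0$ and
$t_\mathrm{budstart}$ are recovered to well under 1%;
$\phi_\mathrm{mother}$ is flat at its generating value of
$5.5\times10^{-4}$ Pa⁻¹ s⁻¹ (the wall is not limiting there); $q$ is a
lower bound — fixing it anywhere above $10^3$ changes $\chi^2$ by well
under the noise variance per observation and leaves the other
parameters untouched. Because the median $q = 230$ sits only ~7× above
the expansion threshold, $\chi^2$ does still distinguish $q = 10^2$
from $10^3$ on noiseless data at $\sigma = 1$ µm³; practical
unidentifiability is a statement relative to measurement noise, not an
exact flatness.

## Synthetic cohorts

`generate_cohort()` is the stand-in for the microscopy pipeline: the
coupled model simulated forward at parameters drawn from independent
log-normals centred on the cohort medians
($k_\mathrm{uptake} = 1.4\times10^{-16}$, $k_{u/c} = 1.21$ µm,
$\phi_\mathrm{mother} = 5.5\times10^{-4}$, $q = 230$, $r_0 = 1.2$ µm,
$t_\mathrm{budstart} = 93$ min), with log-sds chosen to reproduce the
reported interquartile spreads (0.48, 0.05, 0.58, 0.5, 0.19, 0.32
respectively; the $q$ spread is nominal since $q$ is only
bounded below). Volumes are sampled every 3 min over a 300-min horizon
and perturbed by additive i.i.d. Gaussian noise (default
$\sigma = 1$ µm³) — the simplest model of segmentation-area jitter.
Draws whose bud never expands are flagged, not dropped.

What the generator does *not* emulate: segmentation bias and outliers,
ellipsoidal geometry (volumes are spheres-from-areas in the real
pipeline), lineage-assignment errors, parameter correlations between
cells, and cell-cycle structure beyond a single bud. Passing
recovery tests therefore demonstrates the estimator's correctness
under the model's own assumptions, not robustness to microscopy
artifacts.

Problem sizes used by the test-suite experiments: single cells for
recovery and profiles, a 6-cell noisy cohort for the summary
round-trip, 13-point extensibility sweeps, and plateau runs of
1500–2000 simulated minutes; these keep the full suite at a few
minutes while every check retains a comfortable margin.

## Known limitations

* Spherical geometry throughout; no wall-thickness dynamics, no
  spatially resolved stress, no neck geometry or bud-site polarization.
* Plasmolysis (turgor at the zero floor) is a clamp, not mechanics; the
  model text defines no negative-pressure behavior.
* The fast-exchange coupled model admits no mechanical equilibrium when
  a compartment's wall is soft enough for elastic runaway; that regime
  is delegated to the explicit-exchange path.
* One mother and at most two simultaneous buds; no successive cell
  cycles, septation, or division.
* The stress response is phenomenological; transcriptional delay,
  Fps1 gating and two-branch signaling are out of scope.
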