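---
title: "Passive biaxial mechanics of the murine ascending aorta: model, fitting, and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive biaxial mechanics of the murine ascending aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamech)
```

## The problem

Thoracic aortopathy — in Marfan syndrome and related connective-tissue
disorders — remodels the ascending aortic wall long before a frank aneurysm
appears: elastic fibers fragment, collagen accumulates, and the tissue
stiffens. Passive inflation–extension testing of excised murine aortas is the
standard way to quantify this remodeling. A cannulated segment is pressurized
over 10–140 mmHg while held at fixed axial stretches, and axially stretched
while held at fixed pressures, recording pressure, outer diameter, axial
length, and axial force. `aortamech` turns such records into constitutive
parameters, in-vivo mechanical metrics, an allometric dilatation call per
vessel, and cohort-level correlations between mechanics and dilatation.

## Constitutive model

The wall is modelled as an incompressible hyperelastic membrane with a
four-fiber-family stored energy (units kPa):

$$W = \frac{c}{2}(I_C - 3) + \sum_{i=1}^{4} \frac{c_{1i}}{4 c_{2i}}
      \left\{ \exp\!\left[c_{2i}\,(IV_{Ci} - 1)^2\right] - 1 \right\},$$

with $I_C = \mathrm{tr}\,C$, $IV_{Ci} = M_i \cdot C M_i$, family directions
$M_i = (0, \sin\alpha_{0i}, \cos\alpha_{0i})$ measured from the vessel axis:
axial ($0$), circumferential ($90^\circ$), and two diagonal families at
$\pm\alpha_0$ sharing one stiffness and one exponent. The isotropic term
represents the elastin-dominated matrix; the exponential families represent
collagen (and passive smooth muscle in the circumferential direction). Eight
parameters are free: $c$, $(c_{11}, c_{21})$, $(c_{12}, c_{22})$,
$(c_{1,34}, c_{2,34})$, and $\alpha_0$.

Deformations are biaxial with incompressibility enforced exactly,
$\lambda_r = 1/(\lambda_\theta \lambda_z)$, so $F =
\mathrm{diag}(\lambda_r, \lambda_\theta, \lambda_z)$. Cauchy stress follows
from $\sigma = -pI + 2F (\partial W/\partial C) F^T$ with the Lagrange
multiplier fixed by the membrane condition $\sigma_{rr} = 0$:

$$\sigma_{\theta\theta} = c(\lambda_\theta^2 - \lambda_r^2)
  + \sum_i c_{1i} q_i e^{c_{2i} q_i^2} \lambda_\theta^2 \sin^2\alpha_{0i},
  \qquad q_i = IV_{Ci} - 1,$$

and analogously for $\sigma_{zz}$ with $\cos^2\alpha_{0i}$. The mirror
symmetry of the two diagonal families cancels all shears. A thick-wall
(mean-wall equilibrium) treatment would shift normal stresses by less than
half the luminal pressure at the thickness-to-radius ratios of the loaded
murine aorta (h/r ≈ 0.04–0.08 at physiologic pressure); because the same
membrane relation is used for both data reduction and model evaluation, that
choice cancels out of the fitting objective entirely. The closed form is
chosen because it is testable against independent finite-difference oracles.

Linearized (small-on-large) stiffness about a finite biaxial state uses the
incompressibility-reduced energy $\hat W(x, y)$ with $x = \lambda_\theta^2$,
$y = \lambda_z^2$, $C_{rr} = 1/(xy)$:

$$\mathcal{C}_{\theta\theta\theta\theta} = 2\sigma_{\theta\theta} + 4x^2 \hat W_{xx},
 \quad \mathcal{C}_{zzzz} = 2\sigma_{zz} + 4y^2 \hat W_{yy},
 \quad \mathcal{C}_{\theta\theta zz} = 4xy \hat W_{xy}.$$

Equivalently $\mathcal{C}_{\theta\theta\theta\theta} = \lambda_\theta\,
\partial\sigma_{\theta\theta}/\partial\lambda_\theta$ at fixed $\lambda_z$ —
the form the test suite uses as one of two independent finite-difference
checks (the other assembles the second energy derivatives directly).

### Numerical choices

* The $c_{2i} \to 0$ limit of a family term is the exact quadratic
  $(c_{1i}/4)q_i^2$; the implementation switches to it below
  $c_{2i} < 10^{-8}$ because bundled reference rows contain exponents printed
  at $10^{-14}$, where the generic expression is 0/0.
* Fiber invariants are computed as $q_i = (\lambda_\theta^2 - 1)\sin^2\alpha
  + (\lambda_z^2 - 1)\cos^2\alpha$ with $\cos^2 = 1 - \sin^2$ enforced, so
  the stored energy and stress are *exactly* zero at the reference state.
* Angles are degrees at every user-facing boundary and radians internally;
  stresses kPa, pressures mmHg at I/O (1 mmHg = 0.1333224 kPa), forces
  gram-force at I/O (1 gf = 9.80665 mN), radii and thickness in µm.

## From raw records to stresses

Each acquisition row holds pressure, outer diameter, axial length, and axial
force under a protocol tag (`pd_*` for pressure sweeps, `fl_*` for axial
sweeps). Reduction keeps the last cycle per protocol (earlier cycles are
preconditioning), derives the loaded annulus from incompressible volume
conservation, $r_i = \sqrt{(od/2)^2 - (R_o^2 - R_i^2)/\lambda_z}$, the
mid-wall circumferential stretch $\lambda_\theta = (r_i + h/2)/R_m$, and mean
wall stresses

$$\sigma_\theta = \frac{P r_i}{h}, \qquad
  \sigma_z = \frac{f + P \pi r_i^2}{\pi h (2 r_i + h)}.$$

Rows outside acquisition sanity bands (pressure outside 0–200 mmHg, force
outside −2–10 g, non-positive diameter or length) are rejected with logged
reasons; volumetrically impossible diameter/stretch pairs are dropped per
point.

The in-vivo axial stretch is estimated from the force–length protocols as
the stretch at which axial force is invariant to pressurization: per distinct
axial length, the least-squares slope of force against pressure; then linear
interpolation of the slope's zero crossing in stretch. The estimator refuses
to extrapolate (a no-crossover error) when all slopes share a sign.

## Parameter fitting

The objective is least squares on both stress components, each normalized by
its per-component mean experimental stress — balancing circumferential
stresses (hundreds of kPa) against axial ones and making the objective
invariant to stress units and scale:

$$\Phi(\theta) = \sum_k
  \frac{(\sigma_\theta^{mod} - \sigma_\theta^{exp})_k^2}{\overline{\sigma_\theta^{exp}}^2}
+ \frac{(\sigma_z^{mod} - \sigma_z^{exp})_k^2}{\overline{\sigma_z^{exp}}^2}.$$

Fitting on stresses (rather than raw pressure and force) follows the
established practice for this model family. At least 16 points (twice the
parameter count) and both protocol types are required.

Minimization is bounded multi-start Levenberg–Marquardt
(`minpack.lm::nls.lm`): stress-like parameters in [0, 500] kPa, exponents in
[0, 30], angle in [0°, 90°]. The start set combines three deterministic
anchors at canonical soft-to-stiff arterial magnitudes with Latin-hypercube
draws over the bounds; the LHS coordinates of stress-like and exponent axes
are mapped through $u^2$ to bias draws toward the physically common low
range, since a uniform draw near $c_2 = 30$ overflows the exponential at
large stretches and starts the solver in a flat plateau. Each start is re-run
from its own solution until the objective stops improving (at most four
rounds): Levenberg–Marquardt can stall on its damping schedule in those
plateaus and exit prematurely; a restart resets it. Among starts whose final
objectives tie within relative $10^{-10}$, the smallest-norm parameter vector
wins — a reproducible tie-break for near-non-identifiable parameters (a
family with $c_1 = 0$ leaves its exponent undetermined). Everything is
deterministic given the seed: identical configuration and data give
bit-identical results.

The reported `rmse` is $\sqrt{\Phi/(2n)}$ — a dimensionless per-residual
error that is zero for perfect fits and grows with measurement noise. It is
an internal goodness-of-fit diagnostic, not comparable across differently
normalized objectives.

## In-vivo metrics

Transmural pressures of 80 and 120 mmHg represent diastole and systole.
The structural response closes the constitutive law through thin-wall
equilibrium: $P(\lambda_\theta; \lambda_z) = \sigma_\theta h / r_i$ with
loaded geometry from volume conservation. States at target pressures are
obtained by bracketed root search in $\lambda_\theta \in [0.5, 3]$ (the
bracket shrinks automatically away from wall collapse at the lower end and
exponential overflow at the upper end; residual below $10^{-8}$ mmHg).
Reported per sample at the estimated in-vivo stretch: biaxial stretches,
wall stresses (kPa), circumferential and axial small-on-large stiffness
(MPa), stored energy (kPa), loaded thickness and luminal diameters (µm), and
cyclic distensibility

$$D = \frac{d_{i,sys} - d_{i,dia}}{d_{i,dia}(P_{sys} - P_{dia})},$$

reported both raw (mmHg⁻¹) and ×10³ for display — cohort distensibilities in
the literature are conventionally printed on the ×10⁻³ mmHg⁻¹ scale.
Diameters entering $D$ are model-predicted at 80/120 mmHg rather than raw
loop readings, decoupling the metric from acquisition noise.

## Allometric classification

Luminal diameter scales with body mass as $d_i = \alpha\,BM^\beta$; taking
logs gives an OLS problem whose intercept and slope recover $\alpha$ and
$\beta$, with residual log-scale SD $s$ (denominator $n-2$). The model is fit
on wild-type vessels only and applied to all genotypes. A vessel is *dilated*
when its log-diameter exceeds the upper bound of the 95% **prediction**
interval for a new individual, $z_{0.975}\, s \sqrt{1 + 1/n + \ell(BM)}$
with $\ell$ the regression leverage — classification targets individual
vessels, for which the mean-response confidence band is too narrow (it is
available behind the `interval = "confidence"` flag). Only the upper bound
triggers the dilated call; lower-tail vessels are flagged `small`, not
dilated. A vessel is *aneurysmal* when its normalized diameter
(measured / expected) exceeds 1.5, the clinical convention. By construction
a healthy cohort is called dilated at ≈ 2.5% (the upper tail of the
two-sided 95% interval); the test suite verifies this empirically at
n = 2000.

## Cohort statistics

Spearman's rank correlation uses mid-ranks for ties. Strength labels follow
the conventional bands: mild for $|r_s| \le 0.5$, moderate for
$0.5 < |r_s| \le 0.75$, strong for $|r_s| > 0.75$. Two p-value routes are
implemented: the $t$ approximation $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$
degrees of freedom, and exhaustive enumeration of all $n!$ rank permutations
(two-sided). The default uses the exact enumeration whenever $n \le 8$ —
there it is cheap and removes any approximation concern at the sample sizes
where the $t$ reference is least reliable — and the $t$ approximation
otherwise. No multiple-testing correction is applied across metrics
(correlations are reported per metric); this is recorded in the output
metadata. Group summaries report mean ± SEM, with SEM left missing (not
zero) for singleton groups. The routine normality/ANOVA/post-hoc chain is
delegated to `stats::shapiro.test`, `stats::aov`, and `stats::TukeyHSD`
behind a convenience wrapper.

## The synthetic-data generator

No raw biaxial records are distributed with studies of this kind, so the
generator is a first-class module: it makes every pipeline stage testable
against known ground truth. A simulated vessel follows the four-fiber-family
law exactly, with bundled reference parameter rows (per genotype and age) as
defaults; printed magnitudes below $10^{-3}$ kPa in those rows are treated
as exact zeros, since they are numerically indistinguishable from zero for
stress-like quantities and make fixtures reproducible.

* **Geometry fixture.** Unloaded outer radius 540 µm, thickness 90 µm,
  length 4 mm — chosen once so the loaded state lands in the physiologic
  range of the murine ascending aorta (luminal diameter ≈ 1.2–1.7 mm, loaded
  thickness ≈ 30–50 µm at systole). These are fixtures of the package, not
  measured claims.
* **In-vivo stretch.** The force-invariance stretch is an *emergent*
  property of parameters + geometry; the generator computes it by root
  search on the modelled force–pressure slope rather than accepting it as a
  dial (an override field exists for deliberately mis-specified scenarios).
  For the bundled rows it lands between ≈ 1.5 (double mutant) and ≈ 1.76
  (wild type), in the physiologic range.
* **Protocols.** Pressure sweeps realise each grid pressure exactly by root
  finding (the exact limit of sweeping stretch and resampling onto the
  pressure grid), at the in-vivo stretch and ±5%; force–length sweeps run on
  a common stretch grid at 10/60/100/140 mmHg, truncated to the −0.5–5 g
  window. Two cycles are emitted so readers exercise the keep-last-cycle
  convention.
* **Noise.** Multiplicative Gaussian on diameter (CV 1%) and force (CV 2%),
  additive 0.5 mmHg jitter on pressure — typical camera/load-cell/transducer
  precision. All noise is seed-deterministic, and zero-noise runs round-trip
  the reduction exactly.
* **Cohorts.** Body masses uniform on 15–35 g; diameters from the allometric
  law with log-normal scatter (default $s = 0.04$, a realistic ≈ 4% CV for
  aortic caliber) times per-genotype dilatation multipliers. Each animal's
  vessel geometry is rescaled so its modelled systolic diameter equals the
  drawn target — exact, because the structural response is invariant to a
  common geometric scale.

What the generator does **not** emulate: hysteresis and pseudo-elastic
cycling, preconditioning drift, viscoelastic creep, smooth-muscle tone,
transmural heterogeneity and residual stress (opening angle), cannulation
artifacts, or dissection events. Passing tests therefore demonstrate
correctness of the analysis given the model class, not robustness to every
failure mode of real acquisitions; fits to real data additionally absorb
model error that the synthetic round trip cannot probe.

## Problem sizes and design of the validation suite

The validation suite fits two synthetic subjects (≈ 130–140 points each)
with 24 multi-starts, checks the analytic stress and stiffness against
finite-difference oracles on 100 random parameter/state draws, calibrates
the dilatation classifier on a 2000-animal healthy cohort, verifies the
Spearman implementation against exhaustive permutation enumeration at
$n \le 8$, and round-trips a full simulate → fit → metrics chain within 3%.
These sizes were chosen as the smallest that exercise every code path with
comfortable statistical margins. The decision agreement between the $t$
approximation and enumeration is asserted at $n = 7$–8; at even smaller
samples the discreteness of the permutation distribution makes borderline
disagreements expected behaviour, which is exactly why the package defaults
to the exact method there.

## Known limitations

* Membrane (thin-wall) stress resolution: no transmural stress gradient,
  no residual-stress correction. Consistent within the pipeline, but
  parameters are "membrane-equivalent" values.
* The fitted exponents of families with vanishing stiffness are not
  identifiable (any value fits equally well); the smallest-norm tie-break
  pins them to 0 reproducibly rather than estimating them.
* The allometric classifier assumes log-normal scatter and a single power
  law across the healthy mass range; it is a screening rule, not a growth
  model.
* `fit_rmse` is objective-specific and not comparable to error columns
  computed under other normalizations.

## A minimal session

```{r example, eval = FALSE}
spec <- simulation_spec("WT", 12, noise = noise_model(0, 0, 0), seed = 1)
rec  <- simulate_subject(spec, "wt-01")
fit  <- fit_parameters(rec, fit_config(seed = 1, n_starts = 24))
fit$par
compute_invivo_metrics(fit, rec)
```
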