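---
title: "Models and numerical methods in clotsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in clotsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

clotsim studies how red blood cell (RBC) and platelet content drive the
computed-tomography appearance and compressive mechanics of reconstituted
blood clot analogues. This vignette records the models behind each module,
the reasoning behind the default parameters, and the numerical choices and
their limitations. It is the design document for the package; the worked
numbers live in the README and the test suite.

## 1. Recipes and blending (`recipe`)

A clot analogue is reconstituted from three blood fractions of one donor:
platelet-rich plasma (PRP), packed RBCs, and platelet-depleted plasma
(PDP). For a recipe with target platelet concentration $C$ (in
$10^3/\mu l$), RBC volume fraction $f$, and total volume $V$, the blending
volumes solve platelet-number and volume conservation:

$$v_{\mathrm{prp}} = \frac{C\,V}{C_{\mathrm{PRP}}}, \qquad
  v_{\mathrm{rbc}} = f\,V, \qquad
  v_{\mathrm{pdp}} = V - v_{\mathrm{prp}} - v_{\mathrm{rbc}}.$$

PDP and packed RBCs are treated as platelet-free, so PRP is the only
platelet source. A recipe is infeasible when $v_{\mathrm{pdp}} < 0$, i.e.
the donor's PRP is too dilute to reach the target concentration once the
RBC volume is reserved. `compute_blending_volumes()` raises an error in
that case rather than clamping: a clamped recipe would be a different
experiment, not an approximation of the requested one. `blend_cohort()`
can instead drop infeasible rows, which is how a factorial design over a
donor panel loses its unreachable cells.

The default design is the $3 \times 5$ factorial of platelet
concentrations $\{30, 90, 270\}$ crossed with RBC fractions
$\{0, 0.5, 2, 5, 40\}\%$. With the default six-donor panel
(`default_donors()`), three donors' PRP cannot reach the densest recipe
(270 at 40% RBC requires $v_{\mathrm{prp}} > 0.6 V$ for
$C_{\mathrm{PRP}} < 450$), so the 90-cell cross yields an 87-clot cohort.

## 2. Cyclic compression mechanics (`mech`)

A mechanical test record is (time, strain %, force N) for ten triangular
compression cycles to 80% strain at 10%/s. Processing:

1. **Nominal stress.** $\sigma = F / A_0$ with $A_0$ the initial
   cross-section, reported in kPa. The initial area is used throughout
   (nominal, not true, stress).
2. **Cycle segmentation.** Strain peaks are found by an $O(n)$
   hysteresis-band turning-point detector: a candidate maximum becomes a
   peak once strain falls a prominence band (default 5% strain) below it,
   which is robust to sensor jitter without any smoothing of the recorded
   channels. Each cycle is split at its peak into a loading and an
   unloading branch that share the peak sample.
3. **Secant stiffness.** The low-strain (0–10%) and high-strain (75–80%)
   moduli are the OLS slopes of stress on strain (strain as a fraction)
   over those windows of the first loading branch, with a free intercept.
   A free-intercept slope, unlike a two-point secant, uses every sample in
   the window and is insensitive to a baseline force offset.
4. **Hysteresis loss.** $100\,(A_{\mathrm{load}} -
   A_{\mathrm{unload}})/A_{\mathrm{load}}$, both areas by the trapezoidal
   rule over the sampled branches of the first cycle. The ratio is
   invariant to stress rescaling, so it is independent of the
   cross-section estimate.
5. **Plastic strain.** On the first unloading branch, the strain at which
   stress first returns to baseline, located by linear interpolation
   between the bracketing samples. Real load cells never read exactly
   zero, so the crossing is taken at `baseline + baseline_tol` (default
   0.01 kPa). With a finite tolerance this measures the *baseline-return
   strain*, which is slightly above the true permanent set; the synthetic
   module provides the exact closed form of the same quantity
   (`analytic_return_strain()`), so the extractor is validated against
   the quantity it actually measures. If stress never returns to
   baseline, the minimum-strain point is returned with a `no_return`
   flag instead of a fabricated crossing.

## 3. CT densitometry (`ctimg`)

Images are 3-D Hounsfield-unit grids with a clot mask. The measurement
protocol places three circular regions of interest (ROIs), each half the
sample diameter, on three distinct axial slices, centred on the per-slice
mask centroid; the reported density is the unweighted mean of the per-ROI
voxel means. Placing all three ROIs in a single cross-section is
geometrically impossible without overlap at half the sample diameter,
which is why the protocol distributes them axially; slices are chosen
evenly spaced among those that can inscribe the ROI, making placement
deterministic. A voxel belongs to an ROI when its centre lies inside the
disc — the same convention the synthetic phantoms use, so noise-free
round trips are exact.

Contrast-enhanced density increase is the paired difference of clot means
between the aligned contrast-enhanced and non-contrast grids, using the
identical ROI set (mismatched ROI geometry is an error). It is the
in-vitro analogue of thrombus perviousness.

## 4. Histology quantification (`histo`)

Label masks assign each pixel one class: background (0), RBC (1),
platelet (2), fibrin/other (3), white cell (4). Content is component area
over clot (non-background) area, in percent. Because MSB-stained and
CD42b-stained sections are different physical slices, RBC content comes
from the MSB-like mask and platelet content from the CD42b-like mask; the
*normalized composition* puts both on one denominator,
$\mathrm{rbc} + \mathrm{platelet} + \mathrm{fibrin}$ areas combined, so
the three normalized percentages sum to 100. Per-clot values average the
available sections field-wise.

## 5. The synthetic study (`synthetic`)

The generator's defaults *are* the study conditions; every downstream
stage is validated against its closed forms.

**Contraction model.** Platelets actively contract the fibrin network and
expel serum. Retained serum fraction decays with platelet concentration
$P$:
$$s(P) = s_{\min} + (1 - s_{\min})\, e^{-P/\lambda},$$
with $\lambda = 40 \times 10^3/\mu l$ and $s_{\min} = 0.002$. Conserved
volumes per unit initial volume are the packed RBCs $V_r = f$, an
effective platelet-mesh volume $V_p = w P$ ($w = 4.7\times10^{-5}$ per
$10^3/\mu l$), and retained serum $V_s = (1 - f - wP)\,s(P)$; the
retained fraction is $\phi = V_r + V_p + V_s$ and contents are
$100\,V_r/\phi$ and $100\,V_p/\phi$. The construction guarantees the two
contents sum to at most 100 and reproduces the qualitative signature of
real contraction: RBC-rich clots concentrate to near-total RBC content at
high platelet counts, while platelet-pure clots contract to small dense
bodies. Clot diameter scales as $d_0\,\phi^{1/3}$ with the syringe
diameter $d_0$ (the 40%-RBC recipes use the narrow syringe). Lognormal
jitter (sd 0.2) on the platelet-mesh and serum volumes supplies
clot-to-clot contraction variability.

**Observable models.** Each observable is linear in realized contents:
NCCT density $= \beta_0 + \beta_r\,\mathrm{rbc} + \beta_p\,\mathrm{plt} +
\varepsilon$; contrast-density increase adds a diameter term; the four
mechanical features follow the same form. Noise is additive Gaussian per
feature. A multiplicative (lognormal) option exists, but the additive
default is deliberate: the recovery criterion scores t-based 95%
confidence intervals, whose coverage is exact under additive Gaussian
errors and would be systematically distorted by heteroscedastic
multiplicative noise — the defaults must satisfy the package's own
stated invariants. The default noise scales represent instrument-level
repeatability, not biological dispersion, which is why pipeline
regressions recover the generative slopes tightly.

**Closed-form traces.** The loading branch is
$\sigma(\epsilon) = A\epsilon + B\epsilon^5$. Its window-OLS slope over a
continuous window is $A + B\,c_w$ with
$c_w = \mathrm{Cov}(\epsilon, \epsilon^5)/\mathrm{Var}(\epsilon)$ a
closed-form constant of the window, so target low/high stiffnesses give a
$2\times2$ linear system for $(A, B)$. The unloading branch is the power
law $\sigma = \sigma_{\max} ((\epsilon - \epsilon_p)/(\epsilon_{\max} -
\epsilon_p))^q$, which vanishes at the target plastic strain; its area is
$\sigma_{\max}(\epsilon_{\max} - \epsilon_p)/(q + 1)$, so
$q = \sigma_{\max}(\epsilon_{\max} - \epsilon_p)/A_{\mathrm{unload}} - 1$
makes the hysteresis ratio exact. Feasibility requires $A > 0$, $B \ge
0$, $q \ge 1$; infeasible targets (e.g. low hysteresis combined with
large permanent set) error with the computed $q$. Later cycles are
scaled copies (softening factor 0.95 per cycle), so the hysteresis ratio
is cycle-invariant by construction.

**Phantoms and masks.** CT phantoms are uniform cylinders in
contrast-free media (10 HU; contrast adds 250 HU to the media and the
penetration increment, floored at zero, to the clot), built with the same
voxel-centre convention as the ROI reader. Histology masks come in two
styles: `"exact"` allocates pixel counts (10 000 clot pixels reproduce a
content given to 0.01% exactly) and `"blob"` thresholds a box-blurred
random field at the empirical quantile, giving spatially coherent regions
within about 1% of the target.

**Parameter recovery.** `recover_truth()` draws replicate cohorts, refits
the generative multiple regressions, and scores every slope for bias and
95% CI coverage. Slopes, not intercepts, are scored: a relative-bias
criterion is meaningless for an intercept whose Monte-Carlo standard
error exceeds a small multiple of its value. With 200 replicates the
binomial standard error of a 95% coverage estimate is 1.5 percentage
points, so the acceptance band [92, 98]% is roughly $\pm 2$ standard
errors and a fixed seed is required for a sharp pass/fail decision.

## 6. The pipeline (`cli_pipeline`)

`run_pipeline()` chains generation, trace extraction, phantom
densitometry, mask quantification and the regression tables, all seeded
from one integer; sub-stage seeds are fixed offsets so stages are
individually reproducible. In `"trace"` mode the mechanical targets drawn
from the truth are first projected into the region the synthetic curve
family can realise (`clip_mech_features`: stiffness floor, hysteresis in
[0.5, 99.5]%, plastic strain at most
$\epsilon_{\max} - 2A_{\mathrm{unload}}/\sigma_{\max}$, the $q \ge 1$
boundary); clipped clots are flagged `mech_clipped`. Because the additive
noise model can propose feature combinations no passive material could
produce, clipping is a property of trace realisation, not a data
correction — `"cohort"` mode bypasses traces entirely and uses the drawn
observables. Runs can flag a fraction of clots as compromised
(`flag_prob`) and exclude them from the mechanical fits only
(`exclude_flagged`), mirroring how pre-deformed specimens are handled in
practice.

## 7. Numerical choices, in one place

- Trapezoidal integration for branch areas: error $O(\Delta\epsilon^2)$
  for the smooth branch families used here; the default sampling step of
  0.1% strain keeps feature-extraction error well below 0.5% relative.
- Window slopes are discrete OLS against the generator's continuous
  moment constants; the discretisation gap is $O(\Delta\epsilon^2)$ and
  negligible at the default step.
- Linear interpolation for the baseline crossing; exact for the piecewise
  linear test cases, $O(\Delta\epsilon^2)$ otherwise.
- Type-7 (linear interpolation) quantiles for median/IQR — a documented
  convention choice.
- t-based OLS intervals via `lm()`/`confint()`, verified against an
  explicit normal-equations oracle rather than re-derived.

## 8. Limitations

- The contraction model is phenomenological: one exponential in platelet
  concentration, no fibrinogen or haematocrit dependence, no kinetics.
- Observables are linear in contents by construction; the generator
  cannot express saturation or interaction effects, so recovery exercises
  the estimation machinery, not model misspecification.
- Phantoms are noise-optionally uniform cylinders; no beam hardening,
  partial-volume or scanner point-spread effects.
- The trace family has a single loading shape ($A\epsilon + B\epsilon^5$)
  and softening as pure scaling; real clots show cycle-dependent shape
  change.
- Default noise levels are instrument-scale; cohort-level biological
  dispersion would widen every interval and is intentionally out of
  scope.
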