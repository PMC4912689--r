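---
title: "Quantitative pharmacology of receptor alanine scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pharmacology of receptor alanine scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alascan)
```

## The problem

Alanine-scanning mutagenesis of a G protein-coupled receptor — here
modelled on the extracellular loops (ECLs) of the GLP-1 receptor —
produces, for every point mutant, concentration-response curves for
several peptide ligands across several signaling pathways, competition
radioligand-binding curves, and a cell-surface expression measurement.
The analytical task is to turn those raw curves into per-residue,
per-ligand, per-pathway statements: does this residue matter for binding,
for signaling efficacy, for one pathway more than another, and for one
peptide more than another? `alascan` implements that pipeline end to end,
together with a synthetic-data generator that emulates the experimental
design so every stage can be validated against known ground truth.

## Models

**Concentration-response.** Curves are summarised with the
three-parameter logistic (Hill slope 1),

$$Y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + 10^{(\log \mathrm{EC}_{50} - \log [A])}},$$

fitted per independent experiment after averaging technical duplicates,
with experiment-level estimates pooled as mean ± SEM (the emulated design
is 4–6 independent experiments conducted in duplicate).

**Binding.** Competition curves are fitted with a one-site model and
IC~50~ is converted to K~i~ by the Cheng–Prusoff correction
$pK_i = pIC_{50} + \log_{10}(1 + [L]/K_d)$, with the tracer concentration
and K~d~ supplied through the run configuration (they are assay
properties, not constants of the method).

**Operational efficacy.** Signaling is quantified with the Black–Leff
operational model in the form

$$Y = \mathrm{Bottom} + \frac{E_m - \mathrm{Bottom}}
      {1 + \left(10^{\log K_A} + 10^{\log [A]}\right) /
           10^{(\log \tau + \log [A])}},$$

where $\tau$ is the operational efficacy (coupling of the occupied
receptor to the response, which also absorbs receptor density) and $K_A$
the functional dissociation constant. Derived $\tau$ values are corrected
to measured cell-surface expression,
$\log \tau_c = \log \tau - \log_{10}(f_\mathrm{mut}/f_\mathrm{wt})$, with
expression SEMs moved to the log scale by the delta method
($s_{\log x} = s_x / (x \ln 10)$) and combined with the $\tau$ SEM in
quadrature, assuming the functional and expression measurements are
independent.

**Comparison and classification.** Mutant-minus-wild-type differences in
pK~i~ and $\log \tau_c$ are tested per ligand family with one-way ANOVA
and Dunnett's post-test (two-sided, pooled variance, adjusted p from the
multivariate t distribution with exact pairwise correlations), and
significant losses are binned by fold change into the heat classes
3–5, 5–10, 10–30, and >30-fold, with half-open lower-inclusive
boundaries (a 5.0-fold loss is a 5–10 class effect). Significant effects
below 3-fold render as *no effect* on heatmaps — in either direction —
but remain in the tables with their p values.

**Bias.** Pathway preference is quantified through transduction
coefficients $\log(\tau_c/K_A)$, normalised first to a reference ligand
within each pathway ($\Delta$) and then to a reference pathway within
each ligand ($\Delta\Delta$). The double normalization cancels any
pathway-wide scaling of responses or shared offset in $\log K_A$, which
is what makes $\Delta\Delta\log(\tau/K_A)$ a system-independent bias
measure. The "web of bias" export plots $10^{\Delta\Delta}$ per pathway
spoke, one polygon per ligand.

## The identifiability problem and the fitting policies

With the transducer slope fixed at 1, the operational curve is *exactly*
a logistic with plateau $(E_m - b)\,\tau/(\tau+1)$ and
$\mathrm{EC}_{50} = K_A/(\tau+1)$. A functional curve therefore carries
two pieces of information, while the model has three parameters: $E_m$,
$\tau$ and $K_A$ lie on an exactly flat ridge, and sharing $E_m$ across
ligands does not break it (one shared $E_m$ adds one parameter and one
constraint per ligand simultaneously). Only the transduction coefficient
$\tau/K_A$ and the derived pEC~50~ are identified without further input.
Three anchors are available:

* `ka_policy = "fix_to_binding"` (the pipeline default) fixes
  $\log K_A = -pK_i$ from the construct's own competition binding. One
  anchored ligand identifies $E_m$ and thereby every other ligand's
  parameters. By default every ligand with binding data is anchored
  (`near_full_threshold = 0`): the classical operational-model practice
  of equating $K_A$ with binding affinity is safest for partial
  agonists, and each additional anchor stiffens the solution. The pK~i~
  estimation error displaces $\log \tau$ by roughly $(\tau+1)/\tau$ log
  units per log unit — identically in every experiment — so that
  component is propagated into `sem_log_tau` explicitly rather than
  through the between-experiment scatter, which cannot see it.
* `fix_em` fixes the system maximum directly; with `fix_bottom` this is
  the fully identified single-curve configuration.
* Within `analyze_panel()`, `em_policy = "shared_per_pathway"` treats
  $E_m$ as a property of the cell line and pathway rather than of the
  construct: it is estimated on the wild-type panel and fixed for the
  mutants. In a single stable cell background the downstream
  amplification ceiling is not altered by a receptor point mutation, and
  this choice keeps $\tau$ for strongly impaired mutants determined by
  their plateau instead of multiplying the binding-anchor error by
  $(\tau+1)/\tau$ (which is large exactly when $\tau$ is small).
  `em_policy = "per_curve"` retains fully per-construct maxima as a
  sensitivity option.

Plain `ka_policy = "fit"` remains available; its $\tau$ and $K_A$ are
then one point of the ridge and only ridge-invariant quantities
(pEC~50~, plateau, $\tau/K_A$) should be interpreted.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.05 | — | family-wise significance level of Dunnett's test |
| `fold_bins` | 3, 5, 10, 30 | fold | heat-class boundaries, lower-inclusive |
| `tracer_kd`, `tracer_conc` | 1e-9, 5e-10 | M | Cheng–Prusoff correction (assay properties) |
| `reference_ligand_id`, `reference_pathway_id` | GLP-1, cAMP | — | bias normalization references |
| `em_policy` | shared_per_pathway | — | system maximum shared from wild-type vs per construct |
| `ka_policy` | fix_to_binding | — | K_A anchoring (see above) |

## The synthetic-data generator

`scenario_library()` encodes ground-truth panels for the phenotype
classes an alanine scan produces: a wild-type panel with a strong
reference agonist, a low-efficacy partial agonist carrying a built-in
+1.0 log-unit $\Delta\Delta\log(\tau/K_A)$ bias toward pERK, and a
near-unbiased strong agonist; mutant classes with 4-, 7-, 18- and
50-fold losses in affinity or efficacy (one mid-bin representative per
heat class); an expression-deficit mutant (30% of wild-type surface
expression, intrinsic coupling untouched — the defining test case for
$\tau_c$); an enhanced/mixed-direction mutant; a dead-surface mutant
(no expression, no response, no binding); and a 56-residue panel tiling
ECL1 (201–223), ECL2 (285–307) and part of ECL3 (372–381) for the
structure-mapping stage.

`generate_panel()` draws from those truths: operational-model means on a
10-point 3-fold dilution grid (1 pM–1 µM, plus a basal well),
multiplicative Gaussian noise with 5% CV (constant-CV noise matches
plate-reader heteroscedasticity; an additive mode exists), 5 independent
experiments in duplicate by default, a 5%-SD between-experiment shift of
the system maximum so that per-experiment fitting and SEM aggregation
are exercised honestly, one-site binding curves with 5-percentage-point
additive noise, and Gaussian expression observations. Functional
$\log K_A$ equals $-pK_i$ throughout, so the binding-anchored policy is
generatively consistent; affinity-loss mutants shift both together.
Everything is deterministic under a seed.

What the generator does *not* emulate: Hill slopes different from 1,
correlated noise across concentrations, plate/edge effects, constitutive
activity, system desensitisation, or real disagreement between
functional $K_A$ and binding affinity. Passing tests therefore validate
the statistical machinery under the stated generative assumptions, not
the biology of any particular receptor dataset.

## Numerical choices

* Nonlinear fits use bounded Levenberg–Marquardt least squares with
  data-driven starts (bottom = min, top = max, pEC~50~ at the half-span
  crossing; for the operational model, $\tau_0$ from the plateau ratio
  against the applicable $E_m$ and $K_{A,0}$ from the EC~50~ identity).
  The logistic fits use three starts (±1 log unit around the midpoint
  estimate) with the lowest residual sum of squares winning.
* Bounds: $\log \tau \in [-3, 4]$, $\log K_A \in [-12, -4]$; a fit with
  $\log \tau$ at the upper bound is flagged `not_converged`.
* Flat curves are detected with an F-test of the logistic against an
  intercept-only model (p > 0.05 → `no_response`), so "no appreciable
  response" constructs are reported rather than force-fitted. In the
  comparison tables such mutants are floored to the >30-fold class when
  the wild-type response window is at least 30-fold above replicate
  noise, and `not_determined` otherwise.
* Dunnett probabilities integrate the multivariate t numerically
  (absolute tolerance 1e-5) on a fixed internal quasi-random stream, so
  repeated calls are reproducible and the caller's RNG state is
  untouched; a Monte-Carlo oracle in the test suite checks the values
  independently.
* Duplicates are averaged within an experiment before fitting (the
  design intends duplicates as technical replicates); fitting them as
  individual points is available via `average_duplicates = FALSE`.
* Heat-bin boundaries are lower-inclusive half-open intervals; the
  boundary convention is asserted by tests at exactly 3-, 5-, 10- and
  30-fold.

## Problem sizes used by the test suite

The suite validates parameter recovery with 100-seed simulate-and-refit
runs at the emulated design (three ligands, one pathway), the $\tau_c$
compensation contract with 200 seeds, Dunnett p values against a
10^6^-draw Monte-Carlo null plus a 1000-panel family-wise error check,
and bias recovery with 100 seeds; these sizes give Monte-Carlo standard
errors comfortably below the decision margins they support while keeping
a full run in a few minutes on one core. `scripts/acceptance.R`
recomputes the same quantities at 50–100 seeds.

## Known limitations

* The operational model is fitted with unit transducer slope only;
  systems with steep or shallow transduction need a different model.
* $K_A$ anchoring equates functional and binding affinity; where
  effector coupling reshapes agonist binding strongly, anchored $\tau$
  inherits that discrepancy (the `"fit"` policy and `fix_em` are the
  escape hatches).
* One binding site, monophasic curves, no kinetic models.
* Wootten-style class-B position numbers are attached from a
  user-supplied lookup; no computed assignment is attempted.
* The structure writer encodes categories in the B-factor column, which
  any viewer can color, but it does not render figures itself.
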