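---
title: "Assessing torsade-de-pointes risk from simulated action-potential shapes"
author: "torsadeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing torsade-de-pointes risk from simulated action-potential shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drug-induced torsade de pointes (TdP) is a lethal ventricular arrhythmia
whose cellular signature is delayed repolarization of the ventricular
action potential (AP), most often through block of the rapid
delayed-rectifier potassium current IKr (hERG). A pure hERG assay is
sensitive but not specific: many drugs that block IKr also block inward
currents (ICaL, late INa) and never cause TdP. The regulatory CiPA
paradigm therefore characterizes a drug on seven ion channels, feeds the
measured pharmacology into a mechanistic human ventricular myocyte model,
and classifies proarrhythmic risk from the simulated cellular response.

torsadeNet implements that pipeline end to end, with a twist on the final
step: instead of hand-engineered biomarkers (APD90, qNet, triangulation),
the raw 1000-point AP shape is classified by a small one-dimensional
convolutional network into three TdP-risk classes (high, intermediate,
low).

## Stage 1 — dose-response uncertainty (`hillBlock`, `fitHill`, `bootstrapPanel`)

Fractional block of a channel at free drug concentration $D$ follows the
Hill equation
$$b(D) = \frac{1}{1 + (IC_{50}/D)^h},$$
and the channel's maximal conductance is scaled by the unblocked fraction
$1 - b(D)$, so the drug-free limit reduces exactly to the unmodified
model and $D = IC_{50}$ halves the conductance. An infinite $IC_{50}$ is
the "no measurable block" sentinel.

Patch-clamp block measurements are noisy and sparse (typically four
concentrations with a handful of replicates), so a point fit of
$(IC_{50}, h)$ understates uncertainty. `bootstrapPanel()` resamples
replicates with replacement within each concentration, refits until B
fits are accepted, then discards fits whose $\log_{10} IC_{50}$ falls
outside the central 95% interval of the accepted set and redraws from the
retained fits back to B — the returned set is "B Hill curves within the
95% confidence band" (B = 2000 in the production protocol). A posterior
(MCMC) sampler would be a natural extension point; the nonparametric
bootstrap was chosen because it is assumption-free, fully seeded and
reproducible. Designs with fewer than two replicates everywhere fall back
to a residual bootstrap with a warning. The least-squares fit runs in
$(\log_{10} IC_{50}, h)$ with $h \in (0, 10]$, from three starts, ties
broken by lower residual then lower $h$ — log-parameterization makes the
optimization scale-invariant across the nanomolar-millimolar range.

## Stage 2 — the cell model (`ordConfig`, `runToSteady`, `simulateDrug`)

The simulator is the O'Hara–Rudy dynamic human ventricular myocyte model
(endocardial variant) with the Dutta conductance optimization of the five
repolarization-critical currents (IKr ×1.013, IKs ×1.870, IK1 ×1.698,
ICaL ×1.007, INaL ×2.661), stored in a versioned YAML file
(`inst/extdata/ord_dutta_conductances.yaml`) rather than hard-coded.
Static drug block multiplies each channel's maximal conductance by its
scale factor from Stage 1 at 1, 2, 3 and 4 times the drug's peak serum
concentration (Cmax).

Numerics: fixed-step forward Euler at dt = 0.1 ms with Rush–Larsen
exponential updates for all Hodgkin–Huxley-type gates — the community
standard for this model and the scheme matching the protocol's stated
fixed step. The stiff fast phases (sodium upstroke, rapid phase 3) are
beyond a plain 0.1 ms Euler step's accuracy (it shifts APD90 by about
2 ms), so any step that moves V by more than 0.1 mV is redone as ten
substeps — deterministic, confined to a few milliseconds per beat, and
reducing the dt-halving APD90 difference to about 0.3 ms (asserted in
the tests). The hot loop is compiled (Rcpp); GHK driving terms are
series-guarded near V = 0 to avoid 0/0.

Pacing protocol: cycle length 2000 ms (bradycardia, 30 bpm, the
TdP-provocative condition), stimulus −80 µA/µF for 0.5 ms at each cycle
start, membrane potential recorded at 2 ms over the half-open cycle
[0, 2000) — exactly 1000 points per beat. The protocol is silent on cell
type and stimulus; endocardial and the model's default stimulus are used
and flagged here as assumptions. Drug runs start from the drug-free
steady state reached after 10,000 pacings, shipped as a plain-text
fixture (`ord_endo_steady_cl2000.txt`, resting potential −85.8 mV) and
regenerable with `runToSteady(n_beats = 10000)`; the fixture carries the
conductance-set version tag and is checked against the configuration.

## Stage 3 — beat selection and biomarkers (`selectBeat`, `apd`, `detectEad`)

Early beats after drug onset are transient, so the classifier input is
taken from the late window of the run — the last 250 beats (751–1000) of
the production protocol. Within the window the beat with the *maximal*
repolarization-phase slope is selected: a normal repolarization has
strictly negative dV/dt, so this rule picks the beat carrying an early
afterdepolarization (EAD) whenever one occurs, and the latest beat under
ties. ("Maximal slope" could also be read as steepest descent; the
EAD-capturing reading is adopted because capturing EAD beats is the
stated purpose of the selection, and it is configurable.)

Conventions, chosen once and used everywhere: the resting potential is
the first (pre-stimulus) sample of the beat; the activation time is the
end of the steepest upstroke interval; APD at level $x$ is the time from
activation to the first crossing of
$V_{peak} - x \cdot (V_{peak} - V_{rest})$, linearly interpolated between
the 2 ms samples (the grid is coarse; interpolation keeps the APD error
below one sample). A beat that never recrosses the threshold returns the
trace duration with a `did_not_repolarize` flag rather than failing —
those beats are real, informative EAD/arrest morphologies. The
repolarization window for slope and EAD detection starts 50 ms after the
peak, skipping the phase-1 notch, which can produce a brief positive
dV/dt that is not an EAD; the EAD detector requires dV/dt > +0.01 mV/ms
on at least two consecutive samples, making it robust to the 2 ms grid.

## Stage 4 — datasets (`assembleAPDataset`, `makeFolds`)

Selected traces become a `SummarizedExperiment`: the 1000-point shapes as
the `"ap"` assay, drug / Hill-sample / Cmax-multiple / risk label as
`colData`. With 2000 Hill samples per drug and 4 concentrations, each
drug contributes 8000 shapes; the 12-drug training panel yields 24,000
rows and the 16-drug test panel 32,000. The protocol's description also
mentions a 500-per-drug subsample (6000 training shapes); both are
supported (`subsample_per_drug = 500`) and the full-pool default is used.
Shapes are deliberately **not** normalized — amplitude and baseline carry
physiology — normalization happens inside the network (one batch-norm
layer). Cross-validation folds are stratified by risk class (the
label-balance protects the 3-way softmax; the protocol is silent on the
stratification variable). Fold assignment is greedy least-filled-first
within class, giving per-fold sizes and per-fold class counts both within
one of balance, deterministically per seed.

## Stage 5 — the classifier (`cnnArchitecture`, `trainConvNet`)

Three 1D convolutions with two filters each (kernels 32, 16, 8), batch
normalization after conv1, max pooling after the first two conv groups,
20% dropout between conv2 and its pool, a 5-node ReLU hidden layer and a
3-class softmax. The published description pins two sizes — conv1 output
485 and 214 flattened features — but not every stride; exhaustive search
over the pooling/stride assignments consistent with the description gives
a unique chain hitting both anchors:

    1000 -(conv 32, stride 2)-> 485 -(pool 4, stride 1)-> 482
         -(conv 16, stride 2)-> 234 -(pool 8, stride 2)-> 114
         -(conv 8, stride 1)->  107   × 2 filters = 214

This reconstruction is the default and is asserted at construction:
`cnnArchitecture()` fails loudly, printing the whole chain, if a
configuration misses either anchor; alternates are constructible by
waiving the anchors. Training uses categorical cross-entropy with Adam at
learning rate 0.01 (production: 100 epochs, 10-fold cross-validation;
batch size is unstated, default 32). The network and its
backpropagation — including through the batch statistics — are
implemented in compiled code in this package, since the full computation
graph is small enough (about 1300 parameters) that a framework is
unnecessary; gradients are verified against finite differences in the
test suite. Inference disables dropout and uses the batch-norm moving
averages, so prediction is deterministic and batch-invariant; inputs of
the wrong length are rejected, never cropped.

## Stage 6 — evaluation (`repeatedTest`)

Repeated resampled testing: per repeat, draw `per_drug` shapes without
replacement from each drug's pool, predict, reduce one-vs-rest, and
compute per class the ROC AUC (Mann–Whitney statistic, ties at 0.5),
sensitivity TP/(TP+FN), specificity TN/(TN+FP), and likelihood ratios
LR+ = sens/(1−spec), LR− = (1−sens)/spec with an ε = 10⁻⁴ floor on both
denominators so perfect specificity yields a large finite LR+ (ratios are
always computed from unrounded values). The production protocol uses
10,000 repeats; `per_drug` is the harness's main free parameter (the
protocol does not state it; default 100). Points are means over repeats;
intervals are central 95% percentile intervals, extended to cover the
mean in the rare skewed/discrete cases where a mean leaves the percentile
band. The percentile interval's width converges to the per-repeat
sampling spread as repeats grow (it does not shrink to zero); what
shrinks is the Monte-Carlo error of the point estimates, and the test
suite asserts exactly that.

## The synthetic study system

Everything above runs without external data on seeded generators:

* `defaultPanel()` — nine drugs, three per class, with designed
  pharmacology following the torsadogenic mechanism: high-risk drugs
  block IKr with IC50 at Cmax (conductance scale 0.5 → 0.2 across 1–4×
  Cmax), intermediate-risk drugs at twice Cmax, low-risk drugs block all
  measured channels only weakly (IC50 ≥ 15× Cmax, scales > 0.9 at
  therapeutic exposure). Replicate noise σ = 0.02 on the block fraction
  over four log-spaced concentrations (0.3–10× Cmax) with six replicates
  emulates a tight patch-clamp assay.
* `makeSurrogateAps()` — parametric 1000-point AP templates (rest
  −85 mV, fast upstroke, plateau, sigmoidal repolarization placed
  analytically so the measured APD90 equals the requested value,
  optional EAD bump, σ = 0.25 mV noise) with class-dependent APD shifts
  (+120/+60/0 ms) and EAD probabilities (0.5/0.1/0). These exist so
  classifier and evaluation tests never pay the ionic-model cost.

What the synthetic system does *not* emulate: real drugs' multichannel
block patterns (e.g. verapamil-style balanced IKr+ICaL block),
inter-laboratory assay variability, and the heavy-tailed bootstrap
uncertainty of sparse real assays. A green test suite therefore shows the
machinery is correct and the designed signal is recoverable — it does not
certify classification accuracy on the real 28-drug panel, which needs
the external experimental data and a full-scale training campaign.

## Problem sizes used by the tests and the acceptance script

The mechanistic smoke run uses the 9-drug panel, bootstrap B = 50, 12
Hill samples per drug at 4 Cmax multiples, 20 paced beats from the
shipped steady state with selection over the last 5 beats, 15 training
epochs and 100 evaluation repeats. Drug effects on APD stabilize within a
few beats when starting from the drug-free steady state, and the
selection rule is window-size agnostic, so this 1/50-scale protocol
exercises every production code path; the production-scale constants
(1000 beats, window 751–1000, B = 2000, 100 epochs, 10 folds, 10,000
repeats) remain the documented defaults of their respective functions.
On this reduced protocol the high- and low-risk classes separate with
one-vs-rest AUC well above 0.8; the intermediate class, whose IKr
potency sits between its neighbours, is the hardest — exactly the
pattern expected from the pharmacology.

## Known limitations

* Static (conformation-independent) block only; hERG state-dependent
  binding kinetics are out of scope.
* Single endocardial cell; no transmural coupling, pseudo-ECG, or qNet.
* The architecture's pooling strides are a documented reconstruction
  constrained by the two printed anchors, not a published listing.
* Forward Euler at 0.1 ms (with fast-phase substepping) is the
  protocol-faithful integrator, not the most efficient one; the
  dt-halving test bounds its APD error.
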