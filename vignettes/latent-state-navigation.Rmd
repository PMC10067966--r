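---
title: "Models and statistics for latent-state navigation analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and statistics for latent-state navigation analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

`latentnav` implements the computational apparatus for studying how a neural
population tracks a continuously varying *latent state* during closed-loop
navigation. The task it models: a subject steers with a joystick toward a
target that is flashed briefly on a textured ground plane and then
disappears. There are no landmarks, so the only way to know where the target
is relative to oneself is to integrate self-motion velocity — conveyed by
optic flow — over time (path integration). The subject's time-varying
distance and angle to the remembered target are therefore latent variables:
they are defined by the task but never directly observable, and must be
computed internally from sensory history.

The package provides every stage of the analysis as reusable, tested code:

1. a **closed-loop behavioral simulator** with the task's geometry, kinematic
   limits, timing, and three manipulations (optic-flow density, joystick
   gain, trajectory perturbation);
2. a **generative coupled Poisson spiking model**, so that every fitting
   stage can be validated by parameter recovery against a known ground
   truth;
3. **behavioral ROC/AUC psychometrics** referenced to a target-shuffled null;
4. a **coupled Poisson generalized additive encoding model (GAM)** with MAP
   estimation and grouped backward elimination;
5. **population sequence statistics** on time-rescaled rate maps;
6. **linear population decoding** with smoothing-timescale selection and
   error-propagation analyses;
7. **stability, mixed-selectivity and dimensionality statistics** for
   manipulation experiments; and
8. a **closed-loop recurrent network** trained by backpropagation through
   time on the same task.

# The behavioral task and simulator

Targets appear within a sector of radius 0.7–4 m and ±40°, sampled uniformly
over ground-plane *area* (so the radial density grows linearly with r; a
flag switches to (r, θ)-uniform sampling). The joystick maps to linear and
angular velocity with limits 2 m/s and 90°/s; the target is visible for
300 ms; trials time out at 7 s; reward follows stopping within 0.6 m of the
target after a truncated-exponential delay (0.1–0.6 s, mean 0.25 s).

Because no animal supplies behavior here, a synthetic agent closes the loop.
It is plumbing, not a scientific claim: the agent observes its own velocity
through noisy channels (Ornstein–Uhlenbeck noise, 100 ms time constant),
integrates the observations into an internal pose estimate under unicycle
kinematics, and steers toward the remembered target with a saturating
proportional controller, releasing the joystick when its estimated distance
falls below a stopping distance. Kinematics use the convention heading 0 =
straight ahead (+y), positive angular velocity = rightward, and are
integrated by forward Euler at the behavioral sample rate (833⅓ Hz; the step
is 1.2 ms, so the integration error at task speeds is far below the reward
radius).

Two noise scales are the agent's only free behavioral parameters. The
defaults (`sensory_noise_sd = 0.5` m/s, `motor_noise_sd = 0.15` m/s) were
chosen so that the simulated behavior lands in the empirically reported
regime for this task — mean stopping error ≈ 0.4–0.5 m and roughly
two-thirds of trials rewarded — and are not adjusted per analysis. The
density manipulation multiplies only the sensory noise (low optic-flow
density makes velocity estimation harder; it never touches the kinematic
limits), the gain manipulation scales both commanded velocities by the same
factor, and the perturbation manipulation adds a Gaussian-profile velocity
pulse (sd 0.2 s, support 1 s, amplitudes up to ±2 m/s and ±120°/s) at a
random time within 1 s of movement onset.

Trials in which the agent never moves or fails to stop before timeout are
flagged by `exclude_disengaged()` and dropped from all analyses, mirroring
standard disengagement exclusion.

```{r}
library(latentnav)
cfg <- task_config()
trials <- simulate_trials(200, cfg, controller_params(), seed = 1)
trials <- exclude_disengaged(trials)
response_regression(trials)        # slopes near 1: unbiased navigation
behavior_auc_from_trials(trial_table(trials))
```

# Behavioral ROC/AUC

For each hypothetical reward boundary on [0, 4] m (200-point grid; the
resolution does not affect the area) we compute the fraction of trials whose
stopping location falls within the boundary, and the same fraction after
shuffling target locations across trials. Plotting true against shuffled
proportions gives an ROC curve; its trapezoidal area is 0.5 for responses
unrelated to targets and 1 for error-free responses. The endpoints (0, 0)
and (1, 1) are appended before integration because shuffled errors can
exceed 4 m, so the raw curve need not span the unit square. The shuffle is a
derangement — no trial keeps its own target — so the null fully destroys
the target-response pairing and error-free responses give an AUC of exactly
one. One shuffle with a caller-controlled seed is the default; averaging
over many shuffles is available.

# The generative spiking model

Ground truth for recovery tests is a coupled Poisson model on 6-ms bins.
Each neuron's log rate is a sum of piecewise-constant tuning functions of
the continuous task variables, convolved event filters (target onset,
reward), optional acausal motor-channel kernels, its own spike history, and
sparse directed coupling filters from other neurons, plus a baseline.
Emission is Poisson per bin (counts above one allowed), generated
sequentially bin by bin so that history and coupling act causally; filters
never leak across trial boundaries. Spike times are placed uniformly within
their bin.

The default tuning shapes follow the qualitative structure reported for
parietal cortex in this task: preferred speeds tile the velocity range, most
neurons prefer small target distances and extreme target angles, and spiking
probability peaks 18° before the trough of a ~15 Hz LFP oscillation. The bin
width of 6 ms is the smallest decay constant of the coupling re-expression
basis and is exposed in the configuration. Gaze channels are smoothed noise:
they complete the nine-variable predictor set but do not model oculomotor
behavior, so analyses of gaze tuning on synthetic data say nothing about
real eyes. More generally, passing these recovery tests demonstrates that
the estimators are consistent when the model class matches the generator; it
does not certify behavior under real-data model mismatch.

# The encoding model

The GAM relates binned spike counts to `N_C` continuous variables (through
arbitrary tuning functions), `N_E` binary events and past spiking:

- tuning functions: ten boxcars per variable, spanning the 1st–99th
  percentile of the variable over the session (so outer bins are never
  empty); LFP phase always spans the full circle and its smoothness penalty
  wraps around;
- motor channels: phasic, so they are fit with non-causal temporal kernels
  ([−300, 300] ms raised cosines) rather than tuning curves;
- event filters: ten raised cosines over 600 ms, causal [0, 600] ms for
  target onset, non-causal otherwise;
- spike-history and coupling filters: ten causal raised cosines, log-spaced,
  spanning 350 ms and 1.375 s respectively.

Because the model is linear in all coefficients after these expansions, the
fit is a penalized Poisson GLM. The MAP objective subtracts a smoothness
penalty (squared first differences of adjacent basis weights; weight
λ = 100 for tuning, γ = α = 10 for temporal filters) and a sparseness
penalty on coupling. The sparseness prior is the ℓ1 norm of the coupling
*filter* over its time samples, which in coefficient space is an
area-weighted ℓ1 penalty (weight β times each basis function's area). This
choice matters: penalizing raw coefficients equally would make exact zeros
essentially unattainable for the broad log-spaced basis elements, whereas
the filter-ℓ1 form yields the reported regime of sparse coupling with true
interactions retained.

Numerical choices: each boxcar block is reparameterized onto the sum-to-zero
subspace (removing the exact collinearity between a partition of indicators
and the intercept), a ridge of 1e-8 makes the objective strictly convex, and
the solver is diagonally preconditioned accelerated proximal gradient
descent (FISTA) with backtracking and adaptive restart. Convexity means the
optimum is unique: two fits from different starting points agree in
objective to better than 1e-6 relative tolerance, which the test suite
checks. `fit_gam_population()` solves all neurons jointly as a masked
multi-response problem sharing one design matrix — mathematically identical
to per-neuron fits (verified in tests to ~1e-8 relative agreement) but much
faster, because each gradient step is a single matrix-matrix product.

Backward elimination groups the predictors (each continuous variable, each
event filter, spike history, and all coupling filters as one group), holds
out 10% of trials for final evaluation, and cross-validates the remaining
90% in ten folds by trials — trials, not bins, are the sampling unit, to
prevent temporal leakage. A group is dropped when removing it does not
reduce the mean cross-validated log-likelihood by more than one standard
error of the *paired* fold-wise differences; the paired form is essential
because between-fold variation in overall rate is much larger than any
single group's contribution.

Goodness of fit is reported as a likelihood pseudo-R² (normalized between a
constant-rate null and the saturated model) and as a conventional R² against
the observed rate smoothed with a 60-ms Gaussian, pooled across neurons by
summing numerator and denominator variances. Marginal tuning curves follow
the factorized-marginal approximation — exp of the variable's tuning times
the empirical-marginal expectations of the other variables' gains times the
time-averaged event gain times exp of the baseline (included explicitly so
the curves have spike-rate units); history and coupling gains are treated as
unity since their modulation of the mean rate is close to one. Coupling
strength is the time-average of the exponentiated filter, so a null filter
has strength exactly 1, values above 1 are net excitatory; filters can be
re-expressed on seven exponentials (6–384 ms) with a power-law fit of weight
magnitude versus timescale.

# Population sequences

Rate maps rescale each trial's spike times by its duration (target onset to
movement end), histogram them into M = 50 bins (an exposed default), average
over trials and peak-normalize each neuron; peaks tie-break to the earliest
bin. The sequentiality index is the geometric mean of peak sparseness (the
normalized entropy of the peak-bin distribution) and temporal sparseness
(one minus the average normalized entropy of the per-bin activity
distribution across neurons), using natural logarithms and the 0·log 0 = 0
convention; silent neurons and empty bins are excluded. It is 1 for a
perfect one-neuron-per-bin sequence and 0 when all neurons peak together.
Pattern similarity between two maps is the Pearson correlation of the
flattened matrices, with a per-bin (population-vector) timecourse.

The cross-correlation function is implemented exactly as its printed
formula: R_ij(τ) = (1/(N·r̄_i)) Σ_t r_i(t) r_j(t−τ) − r̄_i. Note that with
this baseline independent trains converge to r̄_j − r̄_i, not zero; since
the zero-baseline property and the printed form cannot both hold, an
alternative subtracting r̄_j is provided and both are labeled.

# Linear decoding

Population rates are obtained by convolving each spike train with a causal
exponential kernel (unit-normalized, so a steady train of rate λ converges
to λ). For each task variable, ordinary least-squares weights
w = (RᵀR)⁻¹Rᵀx are fit on 80% of trials; the smoothing timescale η is
selected on a validation 10% from eight log-spaced values in [25, 250] ms by
minimizing the root-sum-squared decoding error; performance is the Pearson
correlation on the final 10%. Decoding uses the bins between target onset
and stop — the epoch over which the latent variables are defined — and
distance-to-target is recomputed from the trajectory in every bin (it is the
time-varying latent state, reaching zero at a perfect stop), not the static
target distance.

The error-propagation analyses compute per-trial time-averaged decoding
errors and relate them to behavior: correlation with the signed behavioral
error (negative = undershoot), a rank-based ROC/AUC separating undershoot
from overshoot trials by the distance-decoding error, and sensory-to-latent
error correlations (linear velocity vs target distance, angular velocity vs
target angle). Because decoder weight vectors are generally not orthogonal,
a surrogate null fixes the geometry: random unit-vector pairs separated by
exactly the decoders' angle are projected onto the activity and the same
per-trial correlation is computed.

# Manipulation statistics

Representation change across conditions is quantified by Pearson
correlations between components of two fits: per directed pair for coupling
filters, per neuron for tuning (sensory = concatenated linear and angular
velocity curves; latent = concatenated distance and angle curves; motor =
concatenated motor kernels). Tuning curves are always evaluated on the
baseline fit's variable domain, since manipulations change the variable
distributions. The stability index SI = (ρ − ρ0)/(ρ* − ρ0) normalizes the
median baseline-vs-manipulation correlation ρ between a shuffled-pair
chance level ρ0 and an odd/even-baseline noise ceiling ρ*; it is reported
unclipped.

Mixed selectivity is the participation ratio (Σv)²/Σv² of the variance
contributions of the six task variables, between 1 (one variable) and 6
(uniform mixing). Task-relevant dimensionality applies the same
participation ratio to the canonical *covariances* (as defined, not
correlations) of an iterative CCA between the six-variable task block
(linear and angular velocity, target distance and angle, two motor
channels; LFP phase and gaze are excluded from this block) and the neural
block; successive pairs are constrained uncorrelated with previous
canonical variables by residualizing both blocks against them, with
unit-norm direction vectors. Coupling geometry on the electrode array bins
directed-pair gains by inter-electrode distance in multiples of the 400-µm
pitch, reporting excitatory (gain > 1) and inhibitory (gain < 1) branches
separately.

# The closed-loop recurrent network

The network has 100 tanh rate units with a 20-ms time constant, integrated
by Euler steps of 10 ms (τ/2; the paper-level description fixes τ but not
the step). Four input channels carry a 300-ms pulse whose amplitude encodes
the 2D target location (scaled by the 4-m task range) and two feedback
channels carrying the network's own self-motion velocity. The two outputs
encode acceleration: they are integrated once — with process noise, so the
network cannot learn a purely autonomous policy — to velocity, which is fed
back with sensory noise, and again to position. The loss sums the squared
distance to the target over the steps after the deadline t*, the travel
time along an idealized circular trajectory at maximum speed (arc
d·ψ/sin ψ for a target at distance d and bearing ψ), with a 0.6-s hold
period inside the 2–3 s trial. Noise levels (process 0.1 m·s⁻¹·s^−1/2,
sensory 0.05 m/s) are fixed defaults chosen so a trained network's
behavioral AUC lands near the empirical ~0.88 regime.

Gradients flow through the closed loop — including the feedback path from
output to future input — by backpropagation through time, verified against
finite differences in the test suite. Training uses Adam with global
gradient-norm clipping on batches of random targets and halts when the
network's behavioral AUC (computed by the very same psychometric machinery
as for the agent) reaches a criterion. A metabolic variant adds penalties on
output and activity amplitudes and their fluctuations, which makes activity
sparser and more sequential. Manipulation retraining freezes the input and
output weights bit-exactly and updates only the recurrent weights; added
sensory noise is conventionally evaluated without retraining. Unit
representations are assessed with a Gaussian-likelihood encoding analysis
(activity regressed on boxcar expansions of velocity and of
distance/angle-to-target; a unit counts as latent-tuned when removing the
latent columns drops held-out R² by more than 0.01), since unit activity is
continuous rather than a count.

# Problem sizes used by the test suite

The end-to-end checks run at sizes chosen to exercise the estimators
meaningfully on a single CPU: encoding-model recovery uses a 20-neuron,
500-trial session with 10 true couplings at the study's hyperparameters
(λ = 100, γ = α = 10, β = 10), with a 90/10 trial split for held-out model
comparison; the stability pipeline uses an 8-neuron population with motor
kernels and 10 couplings, 80-trial sessions, and odd/even and
half-session splits; the network trains with a 20,000-trial budget and
batches of 16. Unit tests use smaller six-neuron, 40-trial sessions.

# Known limitations

- The synthetic agent is a proportional controller; it reproduces trial
  statistics (durations, error magnitudes, reward rates) but not strategy-
  level phenomena such as distance-dependent undershoot biases.
- The generative model and the encoding model share basis families, so
  recovery tests do not probe basis mismatch.
- Exact zeroing of absent couplings depends on session length relative to
  the fixed sparseness weight; very long sessions will retain tiny nonzero
  coefficients (the filter gains remain indistinguishable from 1).
- The Gaussian-likelihood analysis of network units is a deliberate variant:
  unit activities are not counts, and a Poisson path through stochastic
  spike emission would add a layer of arbitrary scaling.
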