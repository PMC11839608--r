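---
title: "Adaptive physical-education optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive physical-education optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apeo)
```

`apeo` is a closed-loop simulator for EEG-informed adaptive physical-education
(PE) programmes. It couples five model layers — a synthetic participant
cohort, an EEG affect read-out, linear state dynamics under PID control,
tabular reinforcement learning for activity personalization, and a gamified
engagement/feedback layer — into a monitor–classify–act loop. This vignette
documents the models, the tunable parameters, the numerical choices, and what
the simulator does and does not establish.

## The participant model

Each participant carries a state vector $S_i(t) = [F_i(t), E_i(t), A_i(t)]$:
a standardized fitness vector, an engagement level and an adherence level,
the latter two clamped to $[0,1]$ after every update. The controlled update is
linear,

$$S_i(t+1) = S_i(t) + W_s\,u_i(t) + D_s\,d_i(t),$$

with intervention vector $u$, disturbance $d$, and response matrices
$W_s, D_s$. Orthogonal to this, each participant relaxes autonomously toward
a baseline with a personal time constant $\tau_i$,
$S(t) = S^\ast + (S_0 - S^\ast)e^{-t/\tau}$. The two laws overlap as stated;
we resolve this by *summing* them: the closed-loop runner applies the
controlled update and then one relaxation step at the participant's
$\tau_i$. This both bounds steady-state fitness (at roughly
$\tau_i\,w_F\,I$ for sustained intensity $I$) and makes $\tau_i$ an active
individual difference. An early design without the relaxation term let
fitness grow without bound, which distorted the reinforcement-learning reward
toward maximal intensity; the relaxation term is the principled fix, not a
patch.

Fitness attributes follow the standard definitions: relative aerobic gain
$F_1 = (\mathrm{VO_2max} - \mathrm{VO_2baseline})/\mathrm{VO_2baseline}$ and
strength-to-weight ratio $F_2 = W_{max}/W_{body}$. Physical literacy is a
latent forward model $L = W X + \varepsilon$ with Gaussian noise (the noise
law is our choice; only "noise" is specified upstream). We deliberately do
*not* fit this factor model — ordinary least squares on simulated data
recovers $W$ within three standard errors at $n = 5000$, which is the
identification check in the test-suite. Participation is a logistic model
$P = \sigma(E^\top w_E + C^\top w_C)$.

### Cohort generation

`generate_profiles()` draws traits from configurable distributions
(defaults: body mass $\mathcal N(55, 8^2)$ kg, baseline VO$_2$
$\mathcal N(40, 5^2)$ mL/kg/min, $\tau \sim U(2,8)$ steps, enjoyment
$\mathrm{Beta}(2,2)$, perceived effort $U(0.2,1)$, skill requirement
$U(0.3,1)$ — a deliberately generic school-age cohort, since no upstream
distributions exist). Each participant owns an RNG stream whose seed is an
arithmetic function of the master seed and the participant index, so growing
a cohort never perturbs existing participants. Disturbances are i.i.d.
Gaussian by default with an AR(1) option for serially correlated sources
such as accumulating fatigue.

## The EEG affect read-out

The synthetic EEG generator produces band-limited oscillations at 6, 10 and
20 Hz (theta, alpha, beta carriers) plus broadband Gaussian noise at a
configurable SNR. Band definitions are the conventional theta 4–8, alpha
8–13, beta 13–30 Hz. Per-state *band-power signatures* (multipliers on the
resting power) encode the five affective states:

| state | theta | alpha | beta |
|---|---|---|---|
| stress/anxiety | 1.00 | 1.00 | 4.00 |
| relaxation / low engagement | 1.35 | 1.80 | 1.00 |
| overload / fatigue | 0.50 | 1.20 | 1.00 |
| focus | 2.50 | 1.00 | 1.00 |
| lack of interest | 0.40 | 0.40 | 0.40 |

The classifier applies threshold rules on the ratio of measured band power
to a per-participant resting baseline: "elevated" means a ratio above 1.5,
"depressed" below 0.67 (both configurable). Rules fire in a fixed
precedence: depressed theta/alpha ratio (overload/fatigue) first — the
safety-critical condition — then elevated beta (stress), elevated theta
(focus), elevated alpha (relaxation), and jointly depressed beta and alpha
(lack of interest). If nothing fires, a neutral `NONE` sentinel is returned
with a warning rather than a silent guess.

The signature values were chosen *jointly* with these thresholds so that
each state trips exactly its own rule. The binding constraint is the
relaxation row: raising alpha alone would depress the theta/alpha ratio and
mis-fire the fatigue rule, so the relaxation signature raises theta mildly
(×1.35) alongside alpha (×1.8), keeping the ratio at 0.75 — above the 0.67
fatigue threshold with margin for spectral-estimation error. These margins
give an exactly diagonal confusion matrix on noiseless traces; under noise
(SNR 25 in the runner) occasional confusions occur, which is intended.

Numerics: power spectral density by Welch's method (2 s Hann windows, 50 %
overlap; near-exact for tones aligned to the 0.5 Hz bin grid). The 1–50 Hz
band-pass is a cascade of 2nd-order Butterworth high- and low-pass filters,
each applied forward–backward (zero-phase, so band power is not
phase-distorted). The cascade is numerically stabler than a single
4th-order band-pass at the very small normalized lower edge and attenuates
more than 20 dB one octave outside the band.

## Control

The PID law is implemented in discretized form: rectangle-rule integral,
backward-difference derivative, explicit `dt`, and an anti-windup clamp on
the integral term (interventions are box-constrained, so an unbounded
integral is meaningless). The test-suite verifies the two classical
contracts on a scalar plant: with integral action the steady-state error
vanishes (|e| < 1e-3 within 500 steps for a constant target), and
pure-proportional control leaves exactly the first-order offset
$e^\ast = (aT - d)/(a + bK_p)$.

## Biomechanics

Joint kinetics follow Newton's second law ($F = ma$, central differences
for derivatives, trapezoid rule for integrals, `dt` explicit). Single-joint
inverse dynamics $\tau = I\ddot q + C(q,\dot q) + G(q)$ is checked against
a finite-difference potential-energy gradient on a pendulum model.
Mechanical energy is kinetic plus accumulated work. Force optimization
descends the inefficiency loss $L = \lVert F - F^{opt}\rVert^2$ with exact
gradient steps, contracting geometrically with ratio $|1-2\eta|$; an
energy cap is enforced by scaling back steps (halving) rather than Lagrange
multipliers — the simplest sound treatment of a hard cap. The *source* of
optimal forces is undefined upstream ("norms, body parameters, energy
minimization"); the package accepts $F^{opt}$ as input and offers a
body-mass-scaled reference profile as an explicit stand-in. Per-modality
joint trajectories are synthetic sinusoidal templates, labelled as such.

## Engagement, gamification and the recurrent predictor

Engagement decomposes into intrinsic motivation $M$ = enjoyment/effort,
social influence $S = \sum_j w_{ij} E_j$, and competency $C$ = skill
gain/requirement. Peer weights are a softmax over embedding dot products
(computed with max-subtraction; positive, unit-sum, shift-invariant). The
map from $(M,S,C)$ to engagement is specified only as "a learned non-linear
mapping"; we realize it as a logistic-linear read-out with a pluggable
`link`. Rewards are multi-layer ($\beta_1 T + \beta_2 E + \gamma B$ with
milestone bonus $B = \max(0, T - T_{thr})$), challenge balance couples the
performance gap to rewards, targets adapt with rate $\eta \in (0,1]$, and
engagement decays geometrically toward the reward level
($E(t+1) = \alpha E + (1-\alpha) R$).

The engagement predictor is a deliberately minimal recurrent network
($h_t = \tanh(W_h x_t + U_h h_{t-1} + b_h)$,
$\hat E_{t+1} = \sigma(W_e h_t + b_e)$) written from scratch with full
backpropagation through time and plain full-batch gradient descent — no
adaptive optimizer, so determinism is trivial and the analytic gradient is
checkable against central finite differences (to 1e-5 relative in the
tests). Parameter recovery is tested teacher–student: 200 sequences of
length 8 from a known 3-unit teacher with observation noise
$\sigma = 0.05$; after 400 epochs at learning rate 0.002 the held-out MSE
must sit within twice the noise floor $\sigma^2$.

## Reinforcement learning

Individual and group personalization share one tabular update,

$$Q(s,a) \leftarrow Q(s,a) + \eta\,[r + \gamma \max_{a'} Q(s',a') - Q(s,a)],$$

with quantile-binned states, an intensity × duration × modality action
grid, epsilon-greedy exploration with exponential decay, and deterministic
tie-breaking (lowest action index). Because the reward writes a *vector*
fitness into a scalar, we scalarize as the mean of standardized components.
On deterministic MDPs, learning-rate-1 sweeps over all state–action pairs
coincide with asynchronous value iteration; the test battery checks
agreement with an independently implemented value-iteration oracle to 1e-6
on every MDP up to 5 states × 5 actions. Group-level learning reuses the
same update over bins of the mean group state with the group reward
$-L_{group} + \alpha_1 E_{group} + \alpha_2 F_{group}$; constraint handling
is action *masking* (infeasible actions excluded from behaviour and argmax),
so recommended schedules can never leave the feasible box. Both cohesion
notions are implemented — sum of squared deviations from the group mean,
and mean pairwise squared difference over graph edges — and cross-checked
on complete graphs, where they are algebraically related.

## Feedback

Goals adapt as $G \leftarrow G + \eta(T^{opt} - M)$. Performance classes
use threshold comparisons; the stated conditions leave a gap when
$\epsilon < \lVert M - G\rVert \le \kappa$, which we label `MARGINAL`
("monitor, no adjustment") rather than silently mislabelling. The
motivational function $h$ is undefined upstream; the default is the
least-squares slope of the last five history points, pluggable. Fatigue
risk is $\alpha H + \beta V - \zeta R$ with $H$, $V$ expected as z-scores
against a rolling baseline so the weights stay scale-free; in the runner
the reward term is the previous step's normalized reward (a rolling
one-step baseline), not the raw cumulative total, which would otherwise
dominate the score as the session progresses. When risk exceeds
$\tau_{fatigue}$, intensity drops by $\rho$ times the detected deviation
and is clamped into its box.

## The closed loop

`run_simulation()` wires the layers together per step and participant:
latent affect (from engagement, fatigue and prescribed intensity) → 2 s
synthetic EEG at 128 Hz, SNR 25 → band-pass → band powers → rule engine →
activity adjustment; then the policy (random / PID-only / Q-learning /
Q-learning + fatigue gating) picks intensity and modality; rewards,
engagement decay, state evolution and logging follow. Task scores reward
choosing the modality the rule engine recommends (weight 0.7) and an
intensity near the participant's comfort level (weight 0.3). The
emotion-to-mental-health read-out is an occupancy-weighted index over
classified states — explicitly a placeholder, as no validated mapping from
affective-state occupancy to mental-health scores exists.

Problem sizes used by the test-suite and the acceptance script — 20 seeded
runs of 100 steps with 3 participants for the policy comparisons, 1000
transitions for dynamics recovery, $n = 5000$ for loading recovery, 200
sequences for the recurrent teacher–student check — were chosen as the
smallest sizes at which the corresponding statistical checks are stable,
and are stated here as the package's reference conditions.

## What passing tests do and do not show

The synthetic cohort and EEG emulate the *statistical structure the models
assume*: band-limited oscillatory power encoding affective state, linear
state responses, engagement that follows rewards. Passing tests show the
machinery is implemented correctly and that the closed loop behaves as
designed *under these assumptions*. They do not show that real adolescent
EEG separates affective states this cleanly (real signatures overlap and
drift), that real engagement follows a geometric decay toward rewards, or
that the policy comparison transfers to real classrooms. Known limitations:
no artifact rejection or spatial filtering, no real EEG file formats, a
1-DOF biomechanical model, tabular (not function-approximation) RL, and the
placeholder mental-health read-out.
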