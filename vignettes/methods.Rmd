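---
title: "Organism-niche synchrony by reciprocal free-energy minimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organism-niche synchrony by reciprocal free-energy minimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nichesync` simulates two active-inference agents — synthetic songbirds —
coupled through a shared Markov blanket: each bird's emitted song is the
other's sensory input. Both birds carry the same *kind* of hierarchical
generative model of song, perceive by gradient flows on a variational free
energy, act by voicing their predictions, and slowly adapt an order
parameter of their model. The package quantifies the generalized synchrony
that emerges when they can hear each other, scores their mutual attunement
("complementarity") as the sum of their free energies, and simulates
ecological inheritance by letting one agent — the niche — persist across
generations of the other.

This vignette is the package's own account of its models, parameters,
numerical scheme and design decisions. It states no empirical result that
the test suite or `scripts/acceptance.R` do not themselves compute.

## The generative model

Each agent entertains a two-level hierarchical dynamic model of its
sensorium:

* **Fast level ("HVC")** — three hidden states $x^{(1)}$ obeying Lorenz
  dynamics $\dot x = f(x;\sigma,\rho,\beta)/\tau_1$ with $\sigma = 10$,
  $\beta = 8/3$, $\tau_1 = 0.25$ s. This level generates the song itself.
* **Slow level ("area X")** — three hidden states $x^{(2)}$ obeying a slow
  Lorenz flow ($\tau_2 = 8$ s, fixed $\rho_2 = 28$). Its output cause
  $v = P \cdot x^{(2)}$, with $P = (0, 0, 0.2)$ reading the slow $z$-state,
  modulates the fast level's $\rho$:
  $$\rho_{\text{eff}} \;=\; \theta + c \tanh(v / c), \qquad c = 8 .$$

$\theta$, the fast level's base $\rho$, is the **learnable order
parameter**: it sets the regime of the song (its mean pitch and the
character of its chaos) and is the model's analogue of a slowly varying
phenotypic trait. Each agent holds a Gaussian belief over $\theta$
(posterior mean and log-precision) anchored to a fixed prior.

Three design choices here deserve comment:

* *The cause reads the slow $z$-state.* The slow $z$ is strictly positive
  (mean $\approx \rho_2 - 1$), so $\rho_{\text{eff}}$ stays inside the
  chaotic band ($\approx$ 25–29.5) in every epoch and the song never
  collapses to a steady whistle. Maps that read the signed slow states put
  $\rho_{\text{eff}}$ below the chaotic threshold whenever the slow state
  visited its negative wing, silencing the song for whole epochs and
  degenerating every synchrony statistic.
* *The modulation is bounded* ($c\tanh(v/c)$). An inferred cause can then
  never push the song out of its dynamical regime; without the bound,
  transient inference kicks during entrainment drove $\rho_{\text{eff}}$
  to absurd values and the filter into a pathological basin.
* *The learnable parameter lives at the fast level.* With $\tau_2 = 8$ s
  the slow states traverse roughly one correlation time per four epochs, so
  a listener cannot identify the *slow* level's $\rho$ from 2-s song
  snippets (we verified that the corresponding gradient carries no
  systematic sign). The fast base $\rho$, in contrast, is directly audible
  as the song's regime. The slow level's $\rho_2$ is therefore a fixed
  model constant and $\theta$ shapes the song's chaotic structure directly.

**Sensory channels.** Inference exchanges two channels that are linear in
the fast states: $(y,\; z - z_{\text{ref}})$ with $z_{\text{ref}} = 25$.
The audible presentation — amplitude
$\mathrm{softplus}(a_0 + a_1 y)$ and frequency
$f_{\text{mid}} + f_{\text{gain}}(z - z_{\text{ref}})$ Hz clipped to
2–5 kHz — is applied only when rendering songs and sonograms. A softplus
amplitude used *as the inference channel* makes half the attractor a
gradient-dead "silence" zone and traps listeners in wing-mirrored local
minima; linear observation channels remove that degeneracy.

## Scaled generalized coordinates

Expectations are carried in generalized coordinates of motion: each block
stores its value and temporal derivatives up to an embedding order
($n = 4$ for hidden states and sensory channels, $n = 2$ for the cause).
Derivatives are stored in the generating level's *dimensionless time*:
order $k$ holds $T^k\, d^k x / dt^k$ with $T = \tau/\sigma$ (fast level and
sensory: $T_1 = 1/40$ s; slow level and cause: $T_2 = 0.8$ s).

This scaling is load-bearing. At the fast level's rate
($\sigma/\tau_1 = 40\,\mathrm{s^{-1}}$), raw derivative magnitudes grow
like $40^k$; with uniform precisions the top orders dominate the free
energy by ten orders of magnitude, and with precisions decayed in natural
units the top orders become effectively unconstrained while still feeding
lower orders through the shift operator. In scaled units every order is
$O(x)$, uniform per-block precisions are exactly equivalent to the
roughness-weighted precisions of generalized filtering (order-0 precisions
keep their nominal values), and every order is equally constrained. The
shift operator becomes $D/T$ per block; reported trajectories are always
unscaled back to natural units.

**Prediction errors.** With $\tilde\mu$ the stacked scaled blocks,

* sensory: $\eta_z^{(k)} = \tilde y^{(k)} - \tilde g^{(k)}(\tilde\mu)$,
  all orders, with the constant observation Jacobian;
* states: $\eta_w^{(k)} = Z_{k+1}/T - f^{(k)}(\tilde\mu)$ for orders
  $0..n{-}1$ (order 0 uses the exact nonlinear flow; higher orders the flow
  linearized at order 0);
* cause: $\eta_v^{(k)} = V_k - P\,Z^{(2)}_k$.

State errors stop at order $n{-}1$ — each order of motion is compared
against its shifted partner — so that *any* flow-consistent trajectory is
an exact solution of the generalized constraint. Including a top-order
error (comparing 0 against $f^{(n)}$) makes fixed points the only exact
solutions, and a precise state prior then collapses free-running
expectations onto the quiescent fixed point within a few ticks: no chaos,
no song.

**Precisions.** Diagonal throughout, in log-precision parametrization:
sensory $\gamma_z = 4$, states $\gamma_w = 8$ ("trust the flow more than
the sound channel"), cause $\gamma_v = 6$. The sensory log-precision falls
by 2 per derivative order: hearing conveys a song's value and low
derivatives reliably, not its fourth derivative; without this decay,
derivative-channel mismatches during chaotic transitions dominated the
listener's free energy by two orders of magnitude. Heard samples carry
additive Gaussian noise with the matching per-order standard deviation
$e^{-(\gamma_z - 2k)/2}$, drawn from a dedicated seeded substream.

## Free energy

The Laplace-approximated free energy of a configuration is the
precision-weighted sum over error blocks,
$$F = \tfrac12 \sum_b \big[\eta_b^\top \Pi_b \eta_b - \ln|\Pi_b|
      + d_b \ln 2\pi\big]
    + \tfrac12\big[\pi_\theta (\theta - \bar\theta)^2 - \ln \pi_\theta
      + \ln 2\pi\big],$$
under the fixed-form convention that the posterior entropy is constant
(zero), so `energy = F`; `accuracy` is minus the sensory terms and
`complexity` the state/cause/parameter terms, keeping
$F = \text{complexity} - \text{accuracy}$ exact. The divergence and
log-evidence terms are flagged as intractable for the dynamic model.

On the static linear-Gaussian family (`gauss_model()`) every decomposition
term is exact and closed-form: this family is the package's oracle for the
evidence bound ($F \ge -\ln p(s)$ with equality only at the true
posterior), for the three-way decomposition identity, and for posterior
recovery by gradient flow. Units are nats everywhere.

## Perception, action, learning

**Listener (perception).** A listening agent runs the generalized filter:
$$\dot{\tilde\mu} = D\tilde\mu - \kappa_\mu\, \partial F/\partial\tilde\mu,$$
integrated by local linearization (matrix exponential of the flow
Jacobian), with the gradient assembled from a central finite-difference
Jacobian of the errors, $g = J^\top \Pi \eta$, and Gauss–Newton curvature
$H = J^\top \Pi J$. Numerical settings: $\kappa_\mu = 2$ (at 0.5 the
listener under-tracked the live chaotic song by a factor of two in
normalized deviation), 4 local-linearization substeps per 1/256-s sample
tick, a trust region capping each substep's update at L2 norm 10, and an
explicit-Euler fallback when the Jacobian solve fails. One structural
asymmetry: the cause-prior link is top-down only at the fast timescale —
the slow states contextualize the cause but are not revised through it
tick by tick (their own flow governs them). Without this, listening epochs
dragged the listener's slow $z$-state toward the inferred cause and
silently absorbed the very displacement that carries the order-parameter
evidence.

**Singer (action).** A singing agent voices its predictions: its
expectations evolve by integrating its *own* generative model (order-0
states by local linearization; derivative orders rebuilt flow-consistently
each tick), which is exactly the zero-prediction-error limit of the filter
("pure prior prediction"), and the emitted sample is the observation map
applied to them. The singer hears itself noiselessly, so its sensory error
is identically zero; its free energy reduces to the normalization constant
plus the parameter prior term. Running the full filter for the singer
instead is unstable: with no informative sensory anchor the free-running
filter slowly drifts off the attractor.

**Uncoupled mode.** The cross-wiring is severed ("the birds are too far
apart"): each agent hears only its own emission, which for the silent
partner's slot is the zero-amplitude sample. The non-voicing agent's
expectations follow prior prediction (there is no usable signal on the
severed channel), but its free energy is evaluated against the silence it
hears at full sensory precision: unanswered song is surprising. This is
what makes coupled complementarity lower than uncoupled.

**Learning.** Once per 2-s epoch (fast inference, slow learning), each
agent updates its order parameter. Because $\theta$ and the cause $v$ act
on the song through the same lever, stationarity of $F$ in $v$ gives the
exact identity
$$\partial F/\partial\theta \;=\;
  -\,\Pi_v\,(v - P x^{(2)})\,/\,(1 - \tanh^2(v/c))$$
at the cause's equilibrium, and $v$ relaxes within tens of milliseconds.
The epoch's learning trace uses this equilibrium form per tick: it is
robust to the tracking lag that biases the raw tick-wise product gradient
(whose measured value has no systematic sign), vanishes identically for a
self-consistent singer and for the uncoupled listener, and is proportional
to the persistently inferred song-regime offset when listening to a
partner. The update is a damped Bayesian step: posterior precision first
accrues the epoch's information (epoch-median curvature $\times$ epoch
seconds $\times$ $e^{-\gamma_v}$, floored at zero — the discount makes one
epoch contribute order-one information about a quasi-static parameter),
then $\theta$ moves by the 20%-trimmed epoch-mean gradient plus the prior
pull, divided by the updated precision, scaled by $\eta_\theta$ and capped
at 2 per epoch. Posterior precision never decreases, so 90% confidence
intervals shrink monotonically. Learning is skipped during the first
exchange (two epochs): gradients collected before entrainment are
unreliable. This scheme reproduces the textbook behaviour on a quadratic
objective (convergence to the precision-weighted compromise between data
and prior).

## Synchrony metrics

* `identical_sync_deviation()` — RMS pointwise distance between the two
  agents' matched expectation trajectories, normalized by the pooled
  standard deviation: 0 on the diagonal synchronization manifold,
  $\approx \sqrt2$ for independent equal-variance signals.
* `generalized_sync_score()` — the $R^2$ of the least-squares affine map
  from one agent's expectations (optionally with first temporal
  derivatives) to the other's, averaged over target dimensions, with
  columns standardized on the fit window and a ridge fallback for
  rank-deficient designs. An optional holdout evaluates the map out of
  sample; the packaged experiments use the in-sample form on the final
  quarter of ticks.
* `complementarity()` — the pointwise sum of the two free-energy traces
  (free energies are extensive); lower values mean greater organism–niche
  attunement.
* `sonogram()` — an amplitude-modulated sinusoid at the instantaneous
  frequency, then Hann-windowed short-time spectral power (64-ms window,
  16-ms hop, 16-kHz synthesis).

Synchrony is compared at the **fast ("HVC") level** in the packaged
experiments. `synchrony_report()` defaults to the slow ("area X") level
and both are always reported, but with $\tau_2 = 8$ s the slow states
traverse only about two correlation times in a 16-s duet, so slow-level
state-space synchrony cannot form within a run; slow-level alignment is
instead expressed through the learned order parameter (the teacher–learner
experiment). For the same reason the chaotic-divergence control starts the
severed pair from adjacent initial conditions (displaced by $10^{-6}$):
from the default far-apart random initializations, fast-level distance
saturates within the first epoch and no growth trend is observable.

## The experiments

**Duet** (`run_duet()`): two agents with identical models (precise
$\theta$ priors at 24) but different initial expectations (order-0 values
uniform on $[-8, 8]^3$ per level, flow-consistent higher orders) alternate
2-s singing turns for 8 epochs. Outputs: synchrony reports at both levels,
per-epoch distances, the coupled/uncoupled contrast, sonograms, and the
matched divergence control.

**Precision asymmetry** (`run_precision_asymmetry()`): the teacher holds
$\theta$ prior mean 24 at log-precision 8; the learner mean 16 at
log-precision 0; $\eta_\theta = 2$; 24 epochs. The learner's $\theta$
climbs toward the teacher's while the teacher is essentially immobile
(displacement ratios in the hundreds), intervals shrink monotonically, and
the uncoupled control retains the full prior gap. One honest limitation:
the learner's final gap settles at a floor of roughly 1 unit
($\approx$ 12–18% of the initial 8), set by the epoch-to-epoch wander of
the slow chaotic state that anchors the cause; the wander is correlated
over $\sim$4 epochs, so longer runs do not remove it.

**Niche inheritance** (`run_niche_inheritance()`): agent N (the niche)
persists across 10 trials — its learned $\theta$ and posterior precision
carry over — while a fresh organism with precise priors ($\theta = 24$) is
drawn each trial and duets with it for 16 epochs. The niche learns slowly
(`niche_learning_scale = 0.2` scales its gradient steps, step cap and
precision accrual; 0 freezes it). The niche starts *hot* ($\theta = 32$):
as successive organisms tame it toward 24, the organisms' cost of tracking
the niche's song and the attunement mismatch both fall, so trial-mean
joint free energy (a 20%-trimmed mean over post-burn-in ticks; the raw
trace has heavy right tails at chaotic transitions) declines across
generations. Started *mild*, those two costs point in opposite directions
and cancel — a caution for interpreting summed free energy as attunement
when the compared regimes differ in intrinsic predictability. Per-trial
chaotic variability leaves a few adjacent-trial increases against the
overall decline; the frozen-niche control shows no parameter movement and
no systematic decline.

## What the simulations do and do not show

The synthetic songs emulate: turn-taking on a fixed 2-s schedule; chaotic,
individually distinct song with sensitivity to initial conditions; a
slow contextual modulation of song structure; sensory noise in hearing;
and a parameterized "trait" expressed in the song's regime. They do not
emulate: realistic syrinx acoustics or auditory periphery, overlapping or
asynchronous song, more than two agents, spatial acoustics, or selection
among competing models. Passing tests therefore show that the *mechanisms*
— evidence-bounded inference, entrainment through a shared blanket,
precision-weighted teaching, slow environmental learning — behave as the
theory predicts inside this model family; they are not evidence about real
birds.

Known numerical limitations: the listener's tracking of live chaos has an
irreducible lag (normalized deviation $\approx$ 0.1–0.5 at the fast
level), so identical synchrony is approached but not attained; free-energy
traces spike at chaotic lobe transitions (robust summaries are used where
single ticks should not dominate); and all gradient machinery assumes the
diagonal-precision Laplace form — there is no curvature propagation and no
non-Gaussian inference.

## Reproducibility

Every run is fully determined by `(config, seed)`. One master seed spawns
named substreams (`init_<agent>`, `noise_<agent>`, `trial_<k>`) so that
toggling one randomness source never shifts another; noise is indexed by
tick, so severing the coupling does not reorder draws. All artifacts are
written as delimited text and JSON with fixed numeric formatting; repeated
runs are byte-identical, and `render_report()` regenerates a deterministic
summary from the files alone.
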