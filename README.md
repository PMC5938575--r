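# nichesync

Active-inference simulation of organism–niche synchrony and ecological
inheritance.

`nichesync` is for computational biologists and cognitive scientists who
want a runnable, testable model of the variational account of niche
construction: an organism and its niche, coupled through a shared Markov
blanket, end up *inferring each other*, and their mutual attunement can be
scored as the sum of their variational free energies. The package makes
that story concrete with two synthetic songbirds that take 2-second turns
singing and listening.

## The model in brief

Each agent carries a two-level hierarchical generative model of song in
generalized coordinates of motion:

- a fast chaotic level ("HVC"): Lorenz dynamics
  `xdot = f(x; sigma, rho_eff, beta) / tau1` with `sigma = 10`,
  `beta = 8/3`, `tau1 = 0.25 s`, voiced as a two-channel song
  (amplitude, frequency in the 2–5 kHz band);
- a slow contextual level ("area X"): Lorenz dynamics with `tau2 = 8 s`,
  whose output cause `v` modulates the fast level's rho inside a bounded
  band, `rho_eff = theta + 8 tanh(v / 8)`.

`theta` — the fast level's base rho — is a learnable **order parameter**
with a Gaussian posterior: the model's analogue of a phenotypic trait,
audible as the song's regime.

Perception is a gradient flow on the Laplace-approximated variational free
energy `F` (precision-weighted prediction errors in generalized
coordinates), action is voicing one's predictions, and learning is a slow,
precision-accruing gradient step on the epoch-averaged `F`. The free
energy obeys the standard decompositions
`F = energy − entropy = complexity − accuracy = divergence − log-evidence`
(exact on the package's linear-Gaussian oracle family) and is an upper
bound on surprisal, `F ≥ −ln p(s)`.

Three packaged experiments:

| experiment | question |
|---|---|
| `run_duet()` | do coupled singers reach generalized synchrony that severed singers do not? |
| `run_precision_asymmetry()` | does a precise "teacher" shape an imprecise "learner" and not vice versa? |
| `run_niche_inheritance()` | does a persistent, slowly learning niche lower the joint free energy experienced by successive organism generations? |

## A worked example

```r
library(nichesync)

sysc <- couple(ns_agent(birdsong_model(), id = "A"),
               ns_agent(birdsong_model(), id = "B"),
               mode = "coupled", schedule = epoch_schedule(n_epochs = 8))
sim <- simulate_duet(sysc, seed = 1)
sim
#> <duet_sim: coupled, 8 epochs x 2s, agents A + B; seed 1>

synchrony_report(sim, level = 1)
#> <synchrony_report (coupled run, level 1 expectations)>
#>   full run   : deviation 0.380, generalized R2 0.683
#>   final 25%  : deviation 0.471, generalized R2 0.671
#>   final-epoch mean joint F: 2906.00 nats (lower = more attuned)
```

The report says: over the final quarter of the 16-s duet, the two birds'
fast-level expectations sit close to the identical-synchrony (diagonal)
manifold — their normalized RMS distance is 0.47, versus ≈ 0.85–1.0 for a
severed pair — and the optimal affine map from one bird's expectations to
the other's explains 67% of the variance, versus ≈ 8% when the birds
cannot hear each other. Lower joint free energy means the pair predicts
each other better than two birds singing alone against silence
(≈ 5000 nats).

Everything is a tibble underneath: `tidy(sim)` gives the long
expectation trajectories, `glance(sim)` a one-row summary, and
`autoplot(sim)`, `plot_sync_manifold(sim)`,
`autoplot(sonogram(sim$song$amplitude, sim$song$frequency))` the standard
figures. A thin command-line wrapper lives at `inst/cli/nichesync.R`:

```sh
Rscript inst/cli/nichesync.R duet --seed 1 --out duet_out
```

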