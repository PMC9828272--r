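---
title: "Spatially varying movement characteristics from GPS trajectories"
author: "crwgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially varying movement characteristics from GPS trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`crwgp` infers *where* animals move differently, from timestamped planar GPS
positions of multiple individuals. Two movement characteristics are mapped
over space:

* **directional persistence** $\tau(x)$ — the velocity autocorrelation
  timescale (time units); large $\tau$ means long, straight movement;
* **velocity variance** $\sigma^2(x)$ — the stationary per-axis variance of
  the velocity (distance$^2$/time$^2$); reported on the speed scale as
  $\sigma\sqrt{\pi/2}$, the mean speed of a 2-D isotropic Gaussian velocity.

The generative model has two layers.

**Top layer — a continuous-time correlated random walk.** Velocity follows
an Ornstein–Uhlenbeck process and position is its time integral. With
constant parameters the velocity covariance is exponential,
$\mathrm{Cov}(v_t, v_s) = \sigma^2 e^{-|t-s|/\tau}$, and the position
covariance is its double time integral. When the parameters vary over space
they vary along the trajectory, and we assume they are constant within each
between-fix interval, evaluated at the straight-line midpoint of the two
observed fixes (the true positions between fixes are unobservable, so
midpoints of the *observed* track are used). Parameters from two intervals
$p, q$ are blended as
$$
\tau_{pq} = \sqrt{\tfrac{\tau_p^2 + \tau_q^2}{2}}, \qquad
\sigma^2_{pq} = \sigma_p \sigma_q
  \sqrt{\tfrac{2\tau_p \tau_q}{\tau_p^2 + \tau_q^2}},
$$
the standard construction for non-stationary exponential kernels that
preserves positive semi-definiteness. The position covariance then reduces
to a double sum of closed-form terms over interval pairs
(`integrated_ou_cov()`), anchored at the first observation of a segment:
its first row and column are zero and the segment mean is the first
observed position. Observed positions add i.i.d. Gaussian noise with
variance $\omega^2$; the two coordinate axes are conditionally independent
given the fields and share the kernel.

**Bottom layer — latent spatial fields.** $\log\tau(x)$ and
$\log\sigma^2(x)$ get independent sparse GP priors represented at an
inducing grid, with an RBF kernel for open landscapes or an exactly periodic
kernel for environments that tile (the synthetic study below). Field values
at trajectory midpoints are obtained by conditioning on the inducing values.
The mean of each field is a constant, optionally plus a linear term in
standardised environmental covariates, whose coefficients carry mean-field
Gaussian posteriors with standard-normal priors — so `covariate_effects()`
can report credible bands for response curves.

## Inference

The marginal likelihood integrates over the latent fields and is
intractable, so the model is fitted by stochastic variational inference:
trajectories are segmented (`segment_trajectories()`), segments are treated
as conditionally independent given the fields, and minibatches of segments
give unbiased estimates of the evidence lower bound
$$
\mathcal{L} = \tfrac{N}{|B|} \sum_{b \in B}
  \mathbb{E}_q\!\left[\log p(y_b \mid \tau, \sigma^2, \omega^2)\right]
  - \mathrm{KL}_\tau - \mathrm{KL}_\sigma ,
$$
with the expectation estimated by reparameterised draws of the inducing
values. The variational posteriors are whitened: the inducing values are
$u = m(Z) + L\nu$ with $K_{ZZ} = LL^\top$ and $q(\nu) =
N(\text{whitened mean}, SS^\top)$; in these coordinates the KL to the prior
is hyperparameter-free and the optimisation is well conditioned. Draws of
the midpoint fields are *linear* in the variational parameters, so the
gradient of a segment's log-likelihood with respect to every parameter is
available in closed form once $\partial \ell / \partial
(\log\tau_p, \log\sigma^2_p)$ is known; that gradient is computed by an
adjoint pass through the kernel's prefix-sum structure at the same
$O(n^2)$ cost as the likelihood, and is verified against finite differences
in the test suite. Optimisation uses Adam with the data set reshuffled
every epoch, and training halts early once the epoch-mean loss has not
decreased over `patience` epochs.

Three choices keep the stochastic optimisation well behaved. The
variational scale is diagonal (mean-field) in the whitened coordinates by
default (`q_diag`): a full triangular scale adds tens of thousands of noisy
degrees of freedom whose one-sample gradients mix heavy-tailed outliers
into the scale estimate, and in long runs this can inflate the posterior
variance of the variance field until the fit degrades; the diagonal family
gives up only the posterior correlations between inducing values. The field
means are warm-started from crude whole-data moments (the variance and
lag-1 autocorrelation of finite-difference velocities), which removes most
of the early-epoch thrashing that prior-mean initialisation produces.
Finally, each step's global gradient norm is capped (`clip_norm`), because
an occasional extreme reparameterised draw — a sampled timescale far in the
tails — otherwise produces a gradient spike that Adam turns into a lasting
perturbation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `segment_length` | 500 | observations per segment; choose it large relative to the largest plausible $\tau$ divided by the fix interval |
| `batch_size` | 4 | segments per gradient step |
| `learning_rate` | 0.01 | Adam step size |
| `patience` | 5 | epochs without loss decrease before stopping |
| `n_mc` | 1 | Monte Carlo field draws per segment and step |
| `grid_nx`, `grid_ny` | 15 | inducing-grid resolution per axis |
| `amplitude` | 1 | prior s.d. of the log-scale fields |
| `lengthscale` | 1 | kernel lengthscale (distance units for RBF; dimensionless sine-feature scale for the periodic kernel) |
| `omega2` | learned | fix the observation-noise variance instead of learning it |
| `q_diag` | `TRUE` | mean-field (diagonal) whitened variational scale |
| `clip_norm` | 5000 | global gradient-norm cap per step |

Kernel amplitude, lengthscale and period are *held fixed* during
optimisation rather than learned. Three reasons: the whitened KL does not
depend on them, so all per-segment conditioning matrices can be computed
once and cached for the whole run; an amplitude of 1 on the log scale
already spans a factor of $e^{\pm 2}$ in the movement parameters, which is
generous for most telemetry data; and learning them would require
differentiating through the prior Cholesky factor for marginal benefit from
a two-hyperparameter kernel. If the fields look over- or under-smoothed,
refit with a different `lengthscale`.

The observation noise $\omega^2$ is learned by default (log-parameterised,
initialised at 5% of the mean squared between-fix displacement); fix it via
`crwgp_config(omega2 = ...)` when the collar error is known.

## The synthetic study

`simulate_crw()` generates the validation data: individuals follow
$df = v\,dt$, $dv = -a(f)\,v\,dt + b(f)\,dW_t$, integrated by
Euler–Maruyama with 10 substeps per observation interval. The mean
reversion $a$ and volatility $b$ vary over a square environment built from
warped sines,
$\mathrm{wsin}(v) = \sin(2\pi v)\sqrt{(1+\alpha^2)/(1+\alpha^2
\sin^2 2\pi v)}$, with $\alpha = 2$ giving flattened, patch-like regions;
each field is `low + (high-low)(1 + wsin(x/L)wsin(y/L))/2`. The
environment has periodic boundaries: field lookups wrap modulo the domain
length while recorded positions stay unwrapped, so animals see an
infinitely tiled landscape and domain edges never influence movement — and
correspondingly the model is fitted with the exactly periodic kernel, whose
period is the domain length. The stationary velocity distribution links the
generator to the model: $\tau = 1/a$ and $\sigma^2 = b^2/(2a)$, which
`ground_truth_on_grid()` tabulates.

Default generator conditions, chosen to be realistic for the design and
stated once: domain length $L = 4$, $a \in [0.5, 2]$ (so $\tau$ spans
0.5–2 time units), $b$ such that $\sigma^2$ spans 0.5–2, observation
interval 0.1 (between 1/5 and 1/20 of the persistence timescale),
observation noise s.d. 0.02 (a few percent of a typical between-fix step,
as for GPS error against hourly ungulate displacements), and initial
velocities drawn from the local stationary distribution so trajectories
start without transients. Note a deliberately hard property of these
levels: the diffusivity $\sigma^2 \tau$ equals 1 in both patch types, so
fast-and-tortuous patches and slow-and-persistent patches produce the same
long-range displacement statistics and can only be separated through the
short-lag velocity structure — precisely the information the
integrated-OU kernel carries.

The recovery study in the tests and the acceptance script uses 40
individuals × 400 observations with a 15 × 15 inducing grid spanning one
period of the torus, 150 epochs maximum and patience 15 (the epoch-mean
loss at batch size 4 is noisy, and a patience of 5 applied to that noisy
trace tends to halt before convergence; the stopping rule itself is
unchanged and unit-tested). Recovered fields are compared with the truth at
grid cells at least 0.1 domain-lengths from any region boundary: near the
boundaries a lag between entering a region and the change becoming
detectable in the velocity process blurs the transitions, which is a
property of the data, not the inference.

What passing these tests does and does not show: the generator matches the
model's assumptions exactly except for the piecewise-constant-parameter
approximation and the observed-midpoint lookup, so recovery demonstrates
that the inference machinery works and that those approximations are
benign at these fix rates. It does not probe irregular sampling schedules,
heavy-tailed or spatially varying measurement error, behavioural switching,
or covariate-driven non-stationarity beyond the linear mean terms — all of
which real telemetry data may contain.

## Numerical choices

* **Stabilising jitter.** The anchored kernel is singular at the first
  observation, so `1e-6 * mean(diag(K))` is added before factorisation; the
  jitter's dependence on the parameters is carried through the analytic
  gradient exactly. Cholesky factorisations retry with escalating jitter.
* **Cancellation-safe kernel evaluation.** The four exponentials in the
  interval-pair term cancel to second order when $\tau_{pq}$ is much larger
  than the segment time span; evaluated naively this makes $K$ numerically
  indefinite for large sampled $\tau$. The bracket is therefore evaluated
  with `expm1`, whose error stays relative to the surviving terms.
* **Link clipping.** Log-scale field values are clipped to $\pm 20$ before
  exponentiation; clipped values get zero gradient.
* **Remainder segments.** A final partial segment is kept when it has at
  least `max(2, segment_length/5)` observations, dropped otherwise.
* **Degenerate inputs.** Non-increasing times, duplicated timestamps,
  non-positive parameters and mismatched lengths are rejected with
  informative errors; a non-finite training loss aborts with a diagnostic
  rather than continuing silently.
* **Reproducibility.** All randomness in a fit flows from `config$seed`;
  identical seeds give bit-identical fits, and prediction summaries take
  their own seed.

## A worked run

```{r example}
library(crwgp)

sim <- simulate_crw(sim_config(n_individuals = 40, n_obs = 400, seed = 11))
L <- 4; nx <- 15
fit <- crwgp(sim$obs, kernel = "periodic", period = L,
             config = crwgp_config(max_epochs = 150, patience = 15,
                                   seed = 2),
             domain = list(xlim = c(0, L - L / nx),
                           ylim = c(0, L - L / nx)))
print(fit)
maps <- predict(fit)
plot(fit, maps = maps)

truth <- ground_truth_on_grid(sim$fields, fit$grid)
head(truth)
```

## Known limitations

* **Velocity transients.** The kernel assumes the velocity process is at
  its local stationary variance within each between-fix interval. The
  mean-reversion *rate* (hence $\tau$) is identified locally, but the
  *variance* takes $\sim\tau$ to equilibrate after a region change, so an
  animal carries its old velocity variance roughly one relaxation length
  ($\approx$ speed $\times \tau$) into a new region. Where region size is
  comparable to that length — as in the default synthetic study, whose two
  patch types share the same diffusivity $\sigma^2\tau$ — the
  $\sigma^2$ map is systematically flattened: inflated in slow regions,
  deflated in fast ones, beyond the visible blurring of the borders. The
  recovery tests quantify this: the persistence field is recovered well in
  patch interiors while the variance field retains a bias that more
  training does not remove.
* The midpoint approximation degrades when animals cross several field
  patches between fixes; subsample-aware users should keep the fix interval
  small relative to the environmental grain.
* Segmentation assumes segments are long compared to $\tau$; short segments
  waste the anchoring observation and leak autocorrelation across cuts.
* The variational posterior is Gaussian in the whitened inducing
  coordinates; strongly multimodal fields are summarised by a single mode.
* Measurement error is homoscedastic and Gaussian by construction.
* Inputs must be planar; projecting geographic coordinates is the user's
  responsibility.
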