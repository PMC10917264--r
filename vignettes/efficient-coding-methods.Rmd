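---
title: "Methods: metabolically efficient information transmission in a recurrent spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolically efficient information transmission in a recurrent spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

A population of cortical neurons that is tuned to a common stimulus
receives part of its input from shared presynaptic (thalamic) fibers.
Shared input induces *noise correlations* — trial-to-trial covariation of
spike counts at a fixed stimulus — which inflate the variance of the
summed population activity and so degrade the information it carries about
stimulus intensity.  Recurrent inhibitory feedback can cancel much of the
shared fluctuation and decorrelate the population, but inhibition is
metabolically expensive: an inhibition-dominated network needs stronger
excitatory drive (and hence more ATP spent on action potentials and
synaptic currents) to reach the same firing rate.  `enercode` implements
the complete computational chain needed to ask whether the information
gain from decorrelation pays for its metabolic cost: a spiking network
simulator, spike-count statistics, an ATP cost model, and
information-theoretic optimization of the stimulus distribution under a
metabolic budget.

## Network model

The simulated circuit has three populations: `n_ext = 1000` external
Poisson neurons, and `n_exc = 800` excitatory plus `n_inh = 200`
inhibitory leaky integrate-and-fire neurons with conductance-based
synapses,

\[ C_m \dot V_i = g_L(E_L - V_i) + I^{\mathrm{rec}}_i + I^{\mathrm{ext}}_i
   + I^{\mathrm{bcg}}_i, \]

where each current is a product of an exponentially decaying synaptic
conductance and its driving force.  A spike is fired when \(V\) crosses
the population threshold (−55 mV excitatory, −60 mV inhibitory, the lower
inhibitory threshold mimicking fast-spiking interneurons) and \(V\) resets
to \(E_L\).  Each presynaptic spike increments the target conductance by
the synaptic amplitude: `a_ext` = 1 nS for external synapses, `a_rec` for
recurrent excitatory synapses and `alpha * a_rec` (with `alpha` = 20) for
recurrent inhibitory synapses.  All four recurrent blocks are wired with
probability `P_rec` = 0.2; external fibers connect with probability
`P_ext`, the parameter that controls input sharing.

Background synaptic bombardment from unmodeled cortex is an
Ornstein–Uhlenbeck conductance pair whose mean and stationary standard
deviation match exponentially filtered Poisson shot noise at 0.5 kHz
(excitatory) and 0.125 kHz (inhibitory, amplitude `alpha * a_ext`),
giving the in-vivo-like inhibitory/excitatory mean conductance ratio of 5
and a spontaneous rate in the 0.5–1 Hz range.

### Numerical choices

* **Integration.** Exponential (exact) updates for synaptic decay and the
  OU processes; forward Euler for the membrane equation at `dt` = 0.1 ms.
  A single-neuron test against a 1000-fold finer reference integrator and
  the closed-form constant-current rate agrees within 1%.
* **Spike propagation.** No synaptic delays or refractory period; a spike
  takes effect on the next integration step.
* **Background clipping.** The OU *state* is never clipped.  By default
  negative conductance excursions are *not* zeroed where they enter the
  currents either: the background equations are integrated exactly as
  written.  This choice matters — the inhibitory background has
  \(\sigma \approx 0.9\,\mu\), and removing the depolarizing effect of its
  negative excursions suppresses the spontaneous rate from about
  0.88 Hz to about 0.02 Hz, far below the 0.5–1 Hz regime the
  parameterization is built to produce.  A `clip_background` switch provides the clipped
  variant for sensitivity analyses.
* **External input.** The stimulus `lambda_ext` is the mean summed input
  rate per postsynaptic neuron; each external neuron fires at
  `lambda_ext / (n_ext * P_ext)` so the mean drive is independent of
  `P_ext`, while the across-neuron variance of the drive scales as
  \((1-P)/P\).  Per-step spiking uses \(p = 1 - e^{-\lambda_0 dt}\).
* **Initial conditions and warm-up.** \(V(0) = E_L\), synaptic
  conductances zero, OU states at their means; a 200 ms warm-up is
  discarded before the 1 s counting window \(\Delta T\).
* **Seeding.** One base seed derives named streams (connectivity, trial,
  probe, subsample), so any single trial is reproducible in isolation and
  whole ensembles are bit-reproducible.

## From spikes to a channel

The network's output is the summed excitatory + inhibitory spike count in
\(\Delta T\) = 1 s.  An ensemble samples 31 (desk profile: 9–11)
equidistant stimuli from 0 to \(\lambda_{max}\), the input at which the
mean output reaches 30 Hz per neuron; \(\lambda_{max}\) is found by
bracketing and bisection of the simulated rate curve followed by a local
linear refinement against probe noise.  Empirical means and variances of
the total count are linearly interpolated onto a dense grid (1000 points
at full scale, 201–301 at desk scale), and the channel
\(f(n\,|\,\lambda)\) is a row-normalized discretized Gaussian on counts
\(0..n_{max}\) with \(n_{max} = \lceil\max(\mu + 6\sigma)\rceil\)
(truncation below 1e-8 of mass).  Zero-variance rows degenerate to a point
mass at `round(mu)`.

Noise statistics use the unbiased sample variance throughout; silent
(zero-mean) neurons are excluded from single-neuron Fano means and
zero-variance neurons from pairwise correlation averages, which avoids
0/0 without biasing populated cells.  The population Fano factor is
reported with its exact decomposition into mean variance and mean
covariance, and with the homogeneous-population approximation
\(FF_0 (1 + (n_{tot}-1) r)\).

## ATP cost model

Costs count the ATP needed to pump out Na⁺:

* **Action potentials.**  Depolarizing 150 pF (a 69 μm cell at
  1 μF/cm²) by 100 mV needs \(1.5\times10^{-11}\) C, i.e.
  \(9.375\times10^7\) Na⁺ ions; quadrupled for simultaneous K⁺ flux,
  costed at one ATP per 3 Na⁺ (\(1.25\times10^8\) ATP), and quadrupled
  again because ~75% of the cost arises in the axon: \(5\times10^8\) ATP
  per spike, applied to all three populations.
* **Excitatory synaptic currents.**  The synaptic conductance is split
  into Na⁺ and K⁺ channels (reversals +90 / −105 mV) that jointly
  reproduce the total current, giving the voltage-independent fraction
  \(g_{Na} = G\,(E_K - E_e)/(E_K - E_{Na})\); the Na⁺ current is
  accumulated at every integration step over the counting window and
  costed at \(|I_{Na}|\Delta T/(3e)\).  Inhibitory (Cl⁻) currents and
  synaptic currents inside the external population are not metered.
* **The cost curve** \(w(\lambda)\) sums the evoked-AP, external-AP
  (total external rate \(\lambda/P_{ext}\)) and synaptic components; its
  value at \(\lambda = 0\) is the resting cost \(W_0\).

## Information-theoretic analysis

The capacity–cost function \(C(W)\) is the largest mutual information
between stimulus and count achievable by any input distribution whose
average cost does not exceed \(W\).  It is computed by Blahut–Arimoto
iteration with an exponential cost tilt \(2^{-s w(\lambda)}\) and an outer
bisection on the multiplier \(s\ge 0\) (with \(s=0\) when the
unconstrained optimum is feasible; where the optimal cost jumps in \(s\),
the two endpoint solutions are mixed to meet the budget exactly, which is
optimal on the linear segments of \(C(W)\)).  The strict inequality in
the budget is implemented as \(\le\) with relative tolerance 1e-9, since
the supremum is attained on the closure.

The information–metabolic efficiency \(E = \max_W C(W)/W\) (bits per
10¹² ATP) is obtained directly by a Jimbo–Kunisawa-style ratio maximizer,
implemented as Dinkelbach fractional programming: each outer step solves
\(\max_p I(p) - E_k W(p)\) with the tilted Blahut–Arimoto update and
resets \(E_{k+1} = I/W\); at the fixed point the tilted value vanishes.
On random fixtures this agrees with a dense \(C(W)/W\) sweep within 1%.

**Stopping rules.**  Small fixtures run to a Csiszár double-bound gap of
1e-9 bits.  On wide network channels (thousands of output symbols) the
upper bound closes only at \(O(1/t)\) while the capacity estimate itself
stabilizes orders of magnitude sooner, so network-scale runs add a
plateau rule (stop when the lower bound improves by less than 1e-6 bits
over 50 iterations) and report the residual gap as a diagnostic.  The
update uses a safeguarded over-relaxation exponent (1.6, reset to 1 if
the objective ever decreases), and warm starts are blended with 1% of
the uniform distribution because exact zeros are absorbing under
multiplicative updates.

### Low-noise approximation

In the low-noise regime the capacity-achieving density is
\(p(\lambda) \propto \sqrt{J(\lambda)}\, e^{-\lambda_W w(\lambda)}\) with
\(J = \mu'^2/\sigma^2\) the (second-moment) Fisher information; the
normalization multiplier is eliminated analytically and \(\lambda_W\) is
found by bracketed root finding on the average-cost constraint.  The
associated capacity estimate \(\ln Z + \lambda_W W\) (nats) is reported
in bits.  The derivation is natural-log native and the package converts
all returned quantities with \(\log_2 e\); on the linear-Gaussian
surrogate (gain \(g\), constant Fano factor, affine cost) this
reproduces the closed form
\(C_{low}(W) = \tfrac12\log_2[(W - W_0)/(w_{AP}\,FF)]\),
\(w_{AP} = w_0/g\), to 1e-6.

Integrals use adaptive quadrature for analytic inputs (handling the
\(\lambda^{-1/2}\) endpoint singularity and unbounded support of the
linear model) and composite 7-point Gauss–Legendre per grid interval for
interpolated network curves, whose kinks defeat adaptive subdivision;
the multiplier search runs on the dimensionless scale \(u = \lambda_W W\)
so bracketing is insensitive to the 10¹²-ATP magnitude of the costs.
The low-noise *efficiency* evaluates the exact mutual information of the
low-noise distribution on the discretized channel over a sweep of
budgets (with two rounds of local refinement around the best ratio) and
takes the best ratio — a strict lower bound on the Jimbo–Kunisawa value.
Parameter sweeps use the same device for their \(C(W)\) tables: each
cell is the exact mutual information of the low-noise distribution at
that budget, which makes a 9-point grid tractable on one core, while
`capacity_cost_curve()` provides the exact constrained Blahut–Arimoto
values for any single channel.

### Population decoding

Beyond the summed count, the package bounds what an optimal unbiased
decoder could extract from the full rate vector: responses pooled across
all stimuli are reduced by PCA (loadings fitted once, 500 components at
full scale, 20–50 at desk scale), the multivariate Gaussian Fisher
information
\(J_{pop} = f'^{\top}\Sigma^{-1}f' + \tfrac12\mathrm{Tr}[(\Sigma^{-1}\Sigma')^2]\)
is estimated with central differences across the sampled stimulus grid
(one-sided at the ends) and diagonal loading \(10^{-6}\,\overline{\mathrm{diag}\,\Sigma}\),
and an efficient estimator's conditional law
\(\hat\lambda \sim N(\lambda, 1/J_{pop})\) defines a noisy identity
channel whose efficiency is computed as above.  The printed form of the
covariance term is implemented as the standard Gaussian Fisher
expression; the mean term dominates in practice and both terms are
exposed separately for verification.  Finite trial counts bias
information estimates upward; the efficiency is therefore recomputed on
disjoint halves and quarters of the trials and extrapolated to infinite
data through \(E_k = E_0 + a/k + b/k^2\).

## The synthetic fixtures and what passing tests show

Two synthetic layers stand in for cluster-scale data.  The
linear-Gaussian surrogate channel (mean \(g\lambda\), variance
\(g\lambda FF\), affine cost) makes every information-theoretic stage
testable against closed forms in seconds, but has constant gain and Fano
factor — it cannot exhibit the correlation structure that drives the
scientific result.  The 1:5 scaled network (200/160/40 neurons, identical
single-neuron parameters; recurrence strengths scaled ×5 so the total
recurrent drive matches full-size values) preserves per-neuron input
statistics through the external-rate scaling and reproduces the
qualitative phenomena — decorrelation by inhibitory feedback, the
resting-cost increase with recurrence, the efficiency peak at
intermediate recurrence under full input sharing — but its absolute
capacities and costs are not those of the 1000-neuron system, and
small-trial ensembles (16–32 per stimulus versus 10 800) carry sampling
noise in the variance estimates.  Tests passing at desk scale therefore
validate the machinery and the direction of the effects, not the full-size study's
absolute numbers; the full profile (31 stimuli, 10 800 trials, the
9 × 10 parameter grid) is available through the same functions.

Problem sizes used by the bundled analyses and checks: 9-point stimulus
grids with 16–32 trials per stimulus, 201-point dense grids, a 3 × 3
(`a_rec`, `P_ext`) sweep, and 4 s spontaneous-activity runs across three
connectivity draws — chosen as the smallest sizes at which the
qualitative results are stable across seeds.

## Known limitations

* No spike-frequency adaptation, synaptic delays, refractoriness, or
  heterogeneity beyond the exc/inh threshold difference; no plasticity.
* The channel treats 1 s counts as the code; temporal structure within
  the window is invisible.
* The Gaussian channel discretization and the second-moment Fisher
  approximation both assume unimodal, roughly Gaussian count
  distributions; at very low rates the truncation at zero biases the
  channel mean upward.
* `C(W)` values on network channels carry the plateau-rule tolerance
  (~1e-4 bits) rather than a closed double bound.
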