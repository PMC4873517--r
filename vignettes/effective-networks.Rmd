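---
title: "Effective brain networks from EEG: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective brain networks from EEG: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pdcnet estimates *effective* (directed) connectivity between EEG channels
and contrasts the topology of the resulting networks between two mental
states, "play" (an attention-demanding video game) and "rest". This
vignette describes the statistical model behind each stage, the parameters
that matter, what the synthetic data generator does and does not emulate,
and the design decisions taken where the method leaves room.

## The model

### MVAR and partial directed coherence

Each analysis window of the multichannel recording is modeled as an
order-$p$ multivariate autoregression (MVAR),

$$X(t) = \sum_{r=1}^{p} A(r)\, X(t-r) + E(t),$$

where $X(t)$ stacks the $m$ channel samples at time $t$, $A(r)$ holds the
lag-$r$ coefficients, and $E(t)$ is zero-mean Gaussian noise with diagonal
covariance. Coefficients are estimated by ordinary least squares on lagged
regressors (`fit_mvar()`); the model order is chosen per subject by
minimizing the mean Akaike information criterion across windows,
$\mathrm{AIC}(p) = n \ln \det \hat\Sigma + 2 p m^2$ (`select_order_aic()`).

The frequency-domain transfer of the fitted model is

$$\bar A_{ij}(f) = \delta_{ij} - \sum_{r=1}^{p} a_{ij}(r)\,
  e^{-i 2\pi (f/f_s) r},$$

and partial directed coherence from source channel $j$ to target $i$ is the
column-normalized magnitude

$$\mathrm{PDC}_{ij}(f) = \frac{|\bar A_{ij}(f)|}
  {\sqrt{\bar a_j^{H}(f)\, \bar a_j(f)}},$$

so that $\sum_i \mathrm{PDC}_{ij}(f)^2 = 1$ for every source $j$ at every
frequency — each source's outflows are measured relative to its total
outflow. This normalization identity is enforced to $10^{-10}$ in the test
suite on every fitted window; it is the hardest-to-fake correctness signal
the PDC stage has. PDC magnitudes (not squares; a `pdc_squared` flag is
available) are averaged over the grid frequencies inside each rhythm band
and arithmetically across the sliding windows.

### Graphs and efficiency

Band matrices are binarized by *proportional thresholding*
(`threshold_proportional()`): the connection density $T \in (0, 1]$ fixes
the number of retained directed edges at round-half-up of $T\,N(N-1)$,
keeping the strongest entries. Ties at the cut break deterministically by
ascending (row, column) index. Adjacency entry $(i, j) = 1$ means an edge
$j \to i$, matching PDC's source-to-target semantics; this orientation is
stated on every function that touches adjacency because transposition is
the classic failure mode of directed-graph code.

With $d_{ij}$ the directed shortest-path length (in hops, $\infty$ when
unreachable),

$$E_{glob} = \frac{1}{N(N-1)} \sum_{i \neq j} \frac{1}{d_{ij}}, \qquad
  E_{loc} = \frac{1}{N} \sum_i E_{glob}(A_i),$$

where $A_i$ is the sub-graph induced on the neighbors of node $i$ (nodes
linked to $i$ by an edge in either direction, excluding $i$; neighborhoods
with fewer than two nodes contribute 0). The either-direction neighborhood
matches the binary directed convention of the established brain-connectivity
tooling. Both quantities are validated against an independent
Floyd–Warshall brute force on every 4-node graph (all $2^{12}$ adjacency
patterns) and 200 random graphs up to 8 nodes.

### Group statistics

Per-subject efficiencies enter (1) two-sided paired t-tests play vs rest at
every density on the sweep grid 0.1–0.9 (step 0.05), with 95% confidence
intervals, and (2) a two-way fixed-effects ANOVA with factors condition and
band at the illustration density $T = 0.35$. No multiple-testing correction
is applied across densities (a Bonferroni flag exists but is off by
default), mirroring common practice of reading the significant
sub-interval. When all paired differences are exactly zero the t statistic
is reported as 0 with $p = 1$; an exactly constant nonzero shift reports
$\pm\infty$ with $p = 0$ — both arise at saturated densities where
efficiencies coincide across subjects.

## Electrode screening (LMD + classifier)

Local mean decomposition (`lmd_decompose()`) splits a channel's signal into
*product functions* — envelope times frequency-modulated carrier — by
iterative sifting: local means and magnitudes are step functions over
midpoints of successive extrema, smoothed by a moving average whose span is
the largest inter-extrema gap (forced odd; boundary segments extend by
mirror reflection of the extrema sequence). The implementation adds two
safeguards the textbook construction omits: sifting keeps the iterate with
the flattest smoothed magnitude and stops after three iterations without
improvement, and any iterate whose FM part exceeds 10 in magnitude aborts
the sift. Broadband noise never satisfies the flat-magnitude criterion, and
without these guards the repeated division by sub-unity magnitudes grows
envelopes without bound; with them, additivity (PFs + residual = signal)
holds to $10^{-8}$ relative error on every fixture including white noise.
Any residual FM overshoot is folded into the envelope, which leaves the
product unchanged and keeps $|\mathrm{FM}| \le 1 + \texttt{env\_tol}$.

Each 2-s window is one classification trial; its feature vector is the
energies (mean squared amplitude) of the first four product functions. The
"first four energies" phrasing of the screening method is ambiguous between
a 4-vector and a summed scalar; the 4-vector is used because a scalar would
leave an RBF classifier nearly powerless and the vector subsumes the
scalar. The classifier is a pluggable contract with a radial-basis SVM
default; hyperparameters (cost, gamma) can be tuned by a seeded genetic
algorithm (population 20, 30 generations, tournament-of-3 selection,
Gaussian mutation in log2 space) or an exhaustive grid for small spaces,
with ties broken toward the smaller cost — among equally accurate models
the less complex one generalizes better. Electrodes whose leave-one-out
precision strictly exceeds 60% become network nodes; on the published
16-electrode reference table this reproduces the canonical 10-node set
(F3, F4, C3, C4, P3, P4, T3, T4, T5, T6) exactly.

## Bootstrap edge significance

The significance of a band-averaged PDC edge is assessed against a
surrogate null that destroys directed cross-links while preserving each
channel's spectrum: every bootstrap replicate regenerates the *whole
session* from the session-level fitted model with all cross-channel
coefficients zeroed (each channel driven only by its own past) and with
residuals resampled independently per channel; the surrogate is then cut
into the same overlapping windows as the observed data and the full model
refitted per window. Generating surrogates at session level matters:
50%-overlapping windows correlate the observed window-averaged statistic,
and surrogates drawn independently per window would understate the null
variance, inflating the empirical type-I edge rate to the edge of its
calibration band (measured 0.10 vs 0.076 with session-level surrogates at
$\alpha = 0.05$). An edge is significant when its observed value exceeds
the $(1-\alpha)$ null quantile. On planted unidirectional coupling the
forward edge is flagged in $\ge 90\%$ of replicates with the reverse edge
essentially never flagged.

Whether masks are applied before thresholding is an open methodological
question; `mask_before_threshold` exposes both orderings and defaults to
thresholding raw PDC.

## The synthetic generator

`make_task_pair()` draws both conditions of one subject from known MVAR
models. Channels are damped AR(2) oscillators: the first half resonate at
20 Hz (beta, pole radius 0.74), the second half at 6 Hz (theta, radius
0.58). Directed coupling is planted through damped-cosine lag kernels
(`coupling_kernel()`, 8 lags, damping 0.85, unit L1 norm) centered on the
group's resonance. A single lag-1 cross coefficient — the obvious simpler
choice — has a frequency-flat transfer numerator, so coupling planted in
one band bleeds into every other band's PDC; the kernel concentrates the
numerator near the intended rhythm. Because short kernels are still
spectrally broad, the two conditions are additionally distinguished by
*topology*: play plants a dense clique among the beta oscillators (per-edge
kernel budget $0.15/(g-1)$), rest a directed ring among the theta
oscillators (per-edge budget 0.15). Leakage of the ring into the beta band
then cannot mimic the clique's local clustering, which is exactly the
contrast the pipeline is meant to detect: higher beta-band local efficiency
during play. Coupling budgets were chosen once so the companion spectral
radius stays below 1 up to `effect_size` ≈ 1.2 (the stationarity gate
rejects stronger coupling) and the planted beta-band PDC (~0.14 analytic)
clears the finite-sample PDC noise floor; `effect_size = 0` removes all
cross-coupling from both conditions, making them identically distributed.

Noise is i.i.d. Gaussian with unit standard deviation per channel — the
signal-to-noise of real scalp recordings is not characterized by the study
conditions, so unit noise against coupling budgets of ~0.15 is a documented
package choice. The autoregression is defined at the 250 Hz analysis rate;
requesting a higher digitization rate (default 1000 Hz) polyphase-
interpolates the band-limited series, emulating acquisition of a sub-30-Hz
process. Burn-in discards `max(1000, 10p)` samples so the zero initial
state is forgotten.

What the generator does **not** emulate: volume conduction and common
reference (which induce instantaneous zero-lag correlations PDC is blind
to), ocular/muscle artifacts, nonstationarity within a session, and 1/f
background spectra. Passing tests therefore show the pipeline recovers
planted lagged directed structure under its own model class — not that real
scalp EEG satisfies that model.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `target_fs` | 250 Hz | analysis rate after anti-alias decimation |
| `window_s`, `overlap_frac` | 2 s, 0.5 | sliding-window segmentation |
| band edges | 1–4–8–13–30 Hz | delta/theta/alpha/beta, half-open `[lo, hi)` |
| frequency grid | 0.5–30 Hz by 0.5 | PDC evaluation grid (≥ 6 points per band) |
| `p_min`–`p_max` | 2–20 | AIC order search range |
| `n_boot`, `alpha` | 200, 0.05 | bootstrap replicates and edge level |
| `t_min`–`t_max`, `t_step` | 0.1–0.9, 0.05 | density sweep (17 graphs) |
| `fixed_T` | 0.35 | illustration density for ANOVA and headline |
| `cutoff_pct` | 60 | strict electrode-selection cutoff |
| `env_tol`, `max_sift_iter`, `max_pfs` | 0.01, 50, 8 | LMD stopping rules |

Band edges are the conventional clinical definitions; the acquisition the
pipeline models is band-limited to 0.05–30 Hz, so nothing above beta is
analyzed. The anti-alias filter is a zero-phase order-6 Butterworth at
`0.4 * target_fs` (applied forward-backward), chosen zero-phase so window
positions stay aligned with the original time axis.

## Numerical conventions and degenerate inputs

* Round-half-up for the retained edge count; index-order tie-breaks make
  thresholding deterministic.
* Duplicated (linearly dependent) channels make the lagged regressor
  rank-deficient; the fit aborts naming the offending channels.
* A constant or monotone signal yields an empty PF list with the signal as
  residual; fewer than `k` PFs zero-pad the energy vector.
* Unreachable node pairs contribute 0 to efficiency; neighborhoods smaller
  than 2 contribute 0 to local efficiency.
* One master seed expands into per-stage, per-subject seeds through an
  affine hash (`split_seed()`), so any subset of subjects can be
  regenerated independently and the full pipeline is byte-reproducible.

## Problem sizes used in the shipped analyses

The packaged analysis scripts and validation suites run on simulated
cohorts of 19 subjects with 8 channels at 250 Hz: 60-s sessions in the
interactive scripts and 180-s (3-minute, the emulated session length)
sessions for the end-to-end contrast check, with a fixed order 8 matching
the planted kernel length. Bootstrap calibration uses 3-channel,
12-s recordings with 100 replicates per run. These sizes were chosen as the
smallest at which the planted effects are comfortably detectable; the
pipeline itself accepts the full 16-channel, 1000-Hz configuration.

## Known limitations

* PDC is estimated per window by OLS; heavily nonstationary windows violate
  the model and no stationarity test is run.
* The bootstrap null preserves univariate spectra but not cross-spectral
  structure under the null of no *direct* coupling; indirect-path nulls are
  out of scope.
* Weighted-graph efficiency, DTF, and time-varying (adaptive) MVAR are
  deliberately not implemented.
* Reported Table-1-style precisions depend on the original recordings and
  are not reproducible from synthetic data; only the selection *rule* is.
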