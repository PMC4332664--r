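---
title: "Methods: source-space lagged phase synchronization networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space lagged phase synchronization networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `lpsnet`, the rationale
for every default parameter and design decision, and the known limits of the
synthetic generator. The pipeline analyzes event-related EEG in source space:
regional time series are reconstructed with a standardized minimum-norm
inverse, connectivity is quantified with lagged phase synchronization (LPS)
in the upper alpha band, sub-networks are identified by average-linkage
clustering, and group effects are tested with family-wise-error-controlled
permutation statistics.

# 1. The connectivity measure

For two signals with band-averaged complex coherency $\rho$, the lagged
phase synchronization is

$$\mathrm{LPS} = \frac{\operatorname{Im}(\rho)^2}{1 - \operatorname{Re}(\rho)^2}.$$

The coherency is computed from *phase-only* (unit-modulus) Fourier
coefficients: each trial's discrete Fourier coefficient at each frequency bin
is normalized to modulus one before averaging across trials and then across
the bins of the analysis band. This makes the measure a pure phase statistic,
insensitive to amplitude covariation.

The defining property of LPS is immunity to zero-lag (instantaneous)
coupling: volume conduction and inverse-solution leakage mix signals with
zero phase delay, which contributes only to $\operatorname{Re}(\rho)$ and is
divided out by the denominator. The degenerate case
$\operatorname{Re}(\rho)^2 = 1$ (perfect instantaneous coherence, e.g. a
channel correlated with itself) is defined as 0, since there is no lagged
component.

**Band and binning.** The analysis band is upper alpha, 10–12 Hz. With the
default 2-s epochs at 250 Hz (500 samples, 0.5 Hz resolution), the band
covers DFT bins 20–24, i.e. five frequency bins, selected by
`band_bins()` with half-open rounding guards so that exact band edges are
included deterministically.

# 2. Source reconstruction

`make_leadfield()` builds a spherical-head gain matrix: electrodes on a
deterministic Fibonacci lattice over the upper hemisphere of the unit
sphere, scalar (fixed-orientation) sources on a cortical shell at radius
0.9 beneath the cap, each gain column being a spatial spread function
(Gaussian in chord distance, width `spread = 0.2`) re-centred to zero mean
for consistency with common-average-referenced data.

*Why a cortical shell rather than volumetric source positions:* with a
strictly upper-hemisphere electrode cap, sources in the lower hemisphere are
essentially unresolvable — their spread patterns at the cap become nearly
collinear, producing standardized-inverse crosstalk that destroys both
localization and partition recovery. Restricting sources to the shell under
the cap mirrors the physical situation (cortical generators under the
sensors) and gives exact single-source localization: for the default
64-channel / 84-source geometry, the standardized resolution matrix has its
absolute maximum on the diagonal for **all 84** columns. A small seeded
positional jitter (`jitter = 0.03`) breaks lattice symmetries.

`build_inverse_operator()` implements a standardized minimum-norm
(sLORETA-style) inverse: Tikhonov-regularized minimum norm
$W_0 = K^\top (K K^\top + \lambda I)^{-1}$ followed by row-wise
standardization by $\sqrt{[W_0 K]_{jj}}$, giving zero localization bias for
single sources in the noiseless case. The default regularization is
$\lambda = 10^{-4} \cdot \mathrm{tr}(K K^\top)/n_\text{channels}$ — small
enough not to blur the noiseless resolution matrix, large enough for
numerical stability; it is exposed as a parameter for noisy regimes.

# 3. Region-of-interest scheme

84 regions: 42 Brodmann areas per hemisphere, labelled `"<area>L"` /
`"<area>R"` (Brodmann areas 12–16 are not distinguishable cortical areas in
the usual nomenclature and are excluded; the 47 remaining numbers minus the
5 exclusions give 42). `roi_labels_for(n)` truncates this list for
reduced-size simulations.

# 4. Synthetic generator

`simulate_source_epochs()` generates trials directly in the frequency
domain. Within each trial and frequency bin of the coupling band:

- Each of the four sub-network groups has a latent complex Gaussian factor.
- Every node loads on its group's factor with gain `coupling_within`
  (default 1) and carries an individual lag implemented exactly by the
  shift theorem (a phase ramp $e^{-2\pi i f \tau_v}$; lags drawn uniformly
  from `lag_range` = 8–40 ms, within-band-period delays typical of
  cortico-cortical conduction).
- Every pair of groups shares a *bridge* latent with gain
  `coupling_between` (default 0.75) entering both groups' composite
  latents. For groups $g, h$ with total squared bridge gains $B_g, B_h$,
  the analytic between-group coherence magnitude is
  $b_{gh}^2 / \sqrt{(1 + B_g)(1 + B_h)}$, which the package exposes through
  the `ground_truth` object and verifies in tests.
- Each node adds independent complex noise scaled to the configured
  `snr_db` (default 5 dB in-band), plus a broadband $1/f$ background.

**Unit-power latent normalization.** The composite group latent is divided
by $\sqrt{1 + B_g}$ (with $B_g$ computed from the *current window's* bridge
gains), so node signal power is identical across windows and conditions.
Without this, boosting a bridge gain in one condition raises node power,
hence effective SNR, hence *within*-group coherence estimates — a confound
that produced spurious intra-group "effects" in early pilots. After
normalization, conditions differ only in cross-group phase structure, which
is exactly the planted effect. A corollary: boosting planted bridges makes
them a larger share of the fixed latent power, so non-planted pairs touching
a planted group are slightly *diluted* — the model's analogue of
connectivity redistribution, asserted in tests as decrease-or-equal.

**Planted design.** The default design has 16 subjects, four conditions in
a 2×2 layout (`WE-IL`, `WE-IT`, `NE-IL`, `NE-IT`), two planted group pairs
(1:2 and 3:4) whose bridge gains increase by `il_boost` (default
×2) in the post-stimulus (SDP) window of `*-IL` conditions only, and
baselines that are condition-invariant. A designated `target ROI`'s
engagement level modulates per-subject mean response times through
`rt_link` (linear link, slope 0.4, noise SD 0.11 s, intercept 0.8 s);
subject mean RTs are truncated at a 0.15 s physiological floor.

**Scalp and artifacts.** `project_to_channels()` applies the leadfield
instantaneously (sample-by-sample $Gs$), optionally adding sensor noise at
a given SNR. `inject_artifacts()` adds ocular blinks (low-frequency frontal
templates) and myogenic bursts (high-frequency, edge-weighted topography) at
configurable rates, for exercising the artifact-removal stages.

The `noise_max_hz = 40` configuration caps the generated background
spectrum: the preprocessing band-pass is 1–30 Hz, so synthesizing background
above 40 Hz would cost time without affecting any analyzed quantity. The cap
is validated to cover the coupling band.

# 5. Preprocessing

`band_pass_filter()`: 4th-order Butterworth, 1–30 Hz, applied zero-phase
(forward–backward), preserving band phases exactly — essential for a phase
connectivity measure. `common_average_reference()` is idempotent and
matches the zero-mean leadfield columns. `remove_eog_sobi()` separates
sources by joint diagonalization of lagged covariances (SOBI) and removes
components correlated with the EOG channel above threshold;
`remove_emg_bss_cca()` removes low-autocorrelation (white) canonical
components typical of myogenic activity. `extract_epochs()` cuts baseline
and SDP windows; `reject_noisy_trials()` drops trials with extreme
amplitude or variance.

One deliberately *causal* filter exception: `emg_envelope()` (for
response-time extraction) band-passes with a causal Butterworth filter
before rectification. A zero-phase filter spreads burst energy backward in
time and biased detected onsets ~0.25 s early in pilots; the causal version
has ~17 ms median onset error.

# 6. Network analysis

- **Event-related indices.** `event_related_index()` computes
  $c_1 = (\mathrm{SDP} - \mathrm{baseline})/\mathrm{baseline}$ (relative
  change) and $c_2 = \mathrm{SDP}$ (absolute). At the *group-sum* level the
  pipeline computes $c_1$ as a ratio of sums,
  $(\sum \mathrm{SDP} - \sum \mathrm{base})/\sum \mathrm{base}$: edgewise
  division by near-floor baseline LPS values is catastrophically
  heavy-tailed (edge means $\sim 10^4$ in pilots), whereas normalizing
  after aggregation is stable and answers the same question.
- **Sub-network identification.** Node dissimilarity is
  $1 - \mathrm{cor}$ of connectivity profiles (diagonal excluded) — chosen
  over $1 - \mathrm{LPS}$ because profile correlation sees group structure
  even when direct within-group edges are noisy. Average-linkage (UPGMA)
  agglomeration, cut at $K = 4$ groups (the planted design size).
- **Group sums.** `group_connectivity()` returns intra-group and
  inter-group-pair sums over the upper triangle; intra + inter exactly
  conserves the total (asserted to $10^{-10}$).
- **Weighted clustering coefficient.** Onnela et al.'s formulation:
  weights scaled by the graph maximum, triangle intensity
  $(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$ averaged over neighbour pairs
  $k_i(k_i - 1)$; verified against a brute-force triple loop.

# 7. Inference

- `paired_tmax()`: paired-difference $t$ statistics across subjects,
  sign-flip permutation of subject differences, null distribution of the
  *maximum* $|t|$ over variables; corrected $p$ = proportion of null maxima
  ≥ observed $|t|$, with the observed statistic included (add-one rule), so
  $p \ge 1/(n_\text{perm}+1)$ and the test is exact. For $n \le 14$
  subjects the full $2^n$ sign-flip enumeration is used; otherwise Monte
  Carlo (the `"auto"` scheme).
- `max_stat_spearman()`: the same max-statistic construction over Spearman
  correlations of one vector against many ROIs, permuting the vector;
  exhaustive over $n!$ permutations for small $n$.
- `rt_correlation_analysis()` min–max normalizes mean RTs and each ROI's
  event-related clustering coefficient to $[0,1]$ before testing — a
  monotone map that leaves Spearman statistics unchanged but reports on a
  standard scale.

**Empirical operating characteristics** (from the acceptance suite):
family-wise error of the tmax test on 84 AR(1)-correlated Gaussian nulls
($\phi = 0.8$, $n = 16$, 1000 repetitions) was 0.046; power on a planted
single shift of 1.1 SD was 0.57 versus 0.50 for Bonferroni — the expected
ordering under positive dependence.

# 8. The pipeline flag rule

`run_full_analysis()` compares the leakage (`*-IL`) and truth (`*-IT`)
conditions with the paired tmax test on the **absolute SDP inter-group sums
($c_2$)**, flagging group pairs with corrected $p < 0.05$ *and* a positive
$t$ (directional, since the planted effect is an increase). Rationale:
baselines are condition-invariant by construction, so baseline
normalization only adds noise to the contrast; $c_2$ is the efficient
detector. This rule was fixed at the first desk-scale pilot and not tuned
afterwards. The same test on intra-group sums serves as a negative control:
the generator plants no intra-group condition differences, so flags there
estimate the family-wise false-positive rate (0/40 in design pilots,
≤ 10 % asserted in tests at 50 repetitions with binomial slack).

# 9. Acceptance-test configurations

The acceptance suite and `scripts/acceptance.R` use reduced, *frozen*
configurations chosen once at design time so the full suite runs on one CPU
inside the time budget:

- **Zero-lag immunity**: one source, purely instantaneous 64-channel
  mixing, no sensor noise, 25 trials. Sensor noise is excluded on purpose:
  with any finite number of trials the sample LPS has a noise-floor of
  order $1/\sqrt{\text{trials} \times \text{bins}}$ that, maximized over
  3486 pairs, approaches the 0.05 criterion regardless of the noise
  amplitude — a property of the estimator, not of zero-lag leakage. The
  noisy zero-lag case is covered separately in the unit tests.
- **Estimator consistency**: 3 ROIs in one group, 400 trials, 20 dB SNR,
  compared against the analytic LPS of the planted lag difference (the
  high-trial regime where estimator bias, not variance, dominates). Three
  ROIs rather than two so that the RT-link target ROI does not coincide
  with a measured pair node.
- **Partition recovery**: full 84-ROI layout, 8 subjects, grand-mean LPS
  matrix; adjusted Rand index 1 at 30 dB, ≥ 0.8 at 0 dB.
- **Pipeline effect recovery**: 8 subjects, 28 ROIs, 32 channels, 50
  repetitions; exact flag set {1:2, 3:4} in ≥ 80 % and intra false alarms
  ≤ 10 %.
- **RT-link recovery**: 16 subjects, 28 ROIs, 80 trials per condition
  (connectivity-estimate noise, not the behavioral link, limits power at
  the default 25 trials), 25 repetitions, plus a 500-repetition null in
  which independent RT vectors are redrawn against a fixed dataset — valid
  by the conditional (on the data) exactness of the permutation test.

# 10. Resolved ambiguities and limitations

Decisions taken where the methodology leaves latitude, and their grounds:

1. **Scalar sources** (fixed orientation), not 3-D dipoles: orientation
   modelling adds nothing to a connectivity-methods testbed.
2. **RT measured from stimulus onset** of the SDP window, detected from the
   EMG envelope threshold (baseline mean + 3 SD sustained ≥ 100 ms).
3. **Profile-correlation distance** for clustering (see §6).
4. **$K = 4$** clusters, matching the planted design; the dendrogram is
   returned so other cuts remain available.
5. **Generator realism limits**: linear instantaneous head model; Gaussian
   latents; stationary within windows; artifacts are stylized templates;
   coupling is band-limited with flat in-band profile. The generator is a
   ground-truthed testbed for the *analysis* chain, not a biophysical brain
   model — effect sizes transfer qualitatively, not quantitatively.
6. **Condition-invariant baselines** are an idealization that makes $c_2$
   the efficient contrast; with drifting real-world baselines the $c_1$
   contrast (also computed and tested by the pipeline) is the robust
   choice.
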