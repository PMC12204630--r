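---
title: "Parameterizing extracellular spike units: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing extracellular spike units: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpspike)
```

This vignette is the package's own account of its methods: the model, the
estimators, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the design decisions that were genuinely open.

## The decomposition model

A band-passed microelectrode trace is modeled as a sum of scaled, stereotyped
action-potential shapes plus a residual:

$$V(t) = \sum_k \alpha_k\, C_{n(k)}(t' + \tau_k) + V_o(t)$$

where $C_n(t)$ is the *canonical shape* of sorted unit $n$ — its mean
waveform over the unit's significant spike window $[\tau_i, \tau_R]$, scaled
to unit L2 norm — $\alpha_k$ is a per-spike scalar weight, and $V_o(t)$
collects everything that is not a spike of a sorted unit: narrow-band
oscillations, 1/f broadband, and instrument noise. Because $\lVert C\rVert_2
= 1$, the least-squares weight is the plain inner product $\alpha_k =
\langle v_k, C\rangle$ on the voltage scale, and the decomposition identity
is exact by construction (it is asserted to machine precision in the test
suite). The scaled weight $\alpha'_k = \alpha_k/\sqrt{T}$ ($T$ window
samples) equals the RMS voltage deflection of a spike exactly proportional
to $C$, which makes it comparable across units with different window
lengths.

Two per-spike quality metrics follow from the residual $V_o = v_k -
\alpha_k C$ inside the window: the LFP energy $V_o^\top V_o$ and the
explained variance $1 - V_o^\top V_o / v^\top v$. The conventional
signal-to-noise ratio $\alpha_k / V_o^\top V_o$ is reported as printed in
the field even though it is dimensionally odd (voltage over squared
voltage); a scale-consistent variant $\alpha'_k / \mathrm{rms}(V_o)$ is
emitted alongside (`snr_rms`). A perfect fit ($V_o = 0$) reports the capped
sentinel `1e12` rather than infinity.

## Spike-window discovery

The window is found empirically, not assumed. For candidate windows $w$
growing from the alignment extremum (time 0) toward the frame end, each
spike contributes a semi-normalized projection onto the unit mean:

$$p_k(w) = \frac{\langle v_k[w],\, m_{-k}[w]\rangle}{\lVert v_k[w]\rVert}$$

with $m_{-k}$ the leave-one-out mean. The profile $\bar S(w) = \mathrm{mean}_k\,
p_k(w)$ rises while the window still adds consistent signal and falls once
it only adds noise (the numerator saturates while the denominator keeps
growing), so its argmax marks the spike end $\tau_R$; a reverse sweep
anchored at $\tau_R$ marks the start $\tau_i$. Design choices here:

* **Normalization by the projecting spike's own window norm.** Normalizing
  instead by the mean waveform's tail norm would make the profile plateau
  rather than peak, because the mean tends to zero outside the support. A
  config switch (`target`) offers the plain-mean and t-statistic profiles as
  robustness checks.
* **Plateau tie-break:** the earliest duration within relative tolerance
  `1e-9` of the profile maximum, so flat maxima resolve deterministically to
  the shortest window.
* **Polarity invariance:** flipping every waveform flips both the spikes and
  their leave-one-out mean, so the profile — and hence the window — is
  invariant under a global polarity flip.
* The reverse sweep only considers starts strictly before the extremum and
  windows are forced to at least 4 samples, so every window contains the
  alignment peak.
* Units with fewer than 5 spikes fall back to the full 2 ms frame, flagged.

At 44 kHz the 2 ms extraction frame is 88 samples with the extremum at
sample 23 (0.5 ms pre, 1.5 ms post); all window indices are half-open
conventions internally and seconds-relative-to-extremum at the interface.

## Detection and sorting parameters

| parameter | default | units | rationale |
|---|---|---|---|
| band-pass | 300–9000 | Hz | standard spike band; 4th-order Butterworth applied forward–backward so phase distortion cannot deform shapes |
| threshold | −4 | robust noise SD | `median(|x|)/0.6745` estimates the noise SD insensitively to the spikes themselves |
| extraction frame | 2 (0.5 pre / 1.5 post) | ms | covers the longest physiological spike shapes |
| alignment search | 0.6 | ms after crossing | window for the largest-magnitude sample |
| crossing collapse | 0.5 | ms | two crossings closer than this are one spike |
| fit tolerance | 0.02 | MSE / full-scale² | see below |
| refractory ISI | 2 | ms | physiological firing limit; >2% violations flags the unit |

The **fit tolerance** deserves a note. Vendor sorters express it in A/D
counts (e.g. "5 in units of 0.01% of the maximum A/D value"), which is
hardware-specific and, read literally as a normalized per-sample RMS bound
(≈ 5·10⁻⁴ of full scale), would reject every waveform at any realistic
noise level. We therefore define tolerance as mean per-sample squared error
divided by the squared full-scale range of the trace — unit-free and
portable — and default it to 0.02, which admits waveforms whose residual is
on the order of the in-band noise at the −4 SD detection threshold while
rejecting gross mismatches. `plexon_fit_tolerance()` documents the literal
vendor-unit conversion for users who need to mirror a vendor setting.

Template seeding follows the conventional recipe: PCA of the extracted
waveforms, k-means in the first two score dimensions (fixed seed, 10
restarts), per-group means as templates, then one template re-estimation
pass after the first assignment. Assignment ties go to the lower-indexed
template and are logged. QC failures are flagged and reported, not silently
"refined": the analogous manual step in clinical practice is a judgment
call, so the package surfaces the flag and leaves the decision to the user
(an optional retry with one extra cluster can be scripted from the flag).

## Serial overlap resolution

Units are processed in descending template-amplitude order. For each unit:
parameterize, subtract $\alpha_k C$ from the *filtered* trace, re-detect
with the *same* threshold, template-match the new detections against the
remaining units' templates, merge, and recompute refractory rates (a
recovered spike may belong to another unit, so QC must be reassessed).

One subtlety matters in practice. When a smaller spike trails a larger one
by less than the extraction frame, the compound often produces a *single*
threshold crossing whose waveform matches no template — the leader is then
unassigned and would never be subtracted. The serial stage therefore first
re-matches unassigned events against the current unit *over that unit's
spike window only*: contamination outside the window is precisely what the
empirical windowing says to ignore. The leader is then assigned, subtracted,
and the hidden follower appears in the re-detection. Events exactly
coincident at the alignment extremum remain unresolvable; the result
reports an expected count of such chance coincidences from the units'
rates (`unresolved_overlap_estimate`).

Spike removal for LFP isolation applies the same subtraction to the
*unfiltered* trace (with $\alpha$ estimated on the filtered one). The
canonical shape is band-limited, so low-frequency spike remnants survive in
$V_o$; this is an acknowledged approximation, and the spectral test below
guards the direction that matters (removal must never *add* power).

## Shape similarity and clustering

Two units are compared over the union of their windows
$[\min \tau_i, \max \tau_R]$, both aligned at their extremum on the common
2 ms frame. Each mean waveform is centered (mean voltage zero) and divided
by its L2 norm — centering alone cannot bound a dot product, so the unit
norm is what pins the score to $[-1, 1]$ — and the similarity is the dot
product: amplitude-free by construction, since raw amplitude mostly encodes
electrode-to-cell distance, not cell type.

For clustering, similarities are clamped at zero *before* the distance is
formed ($d = 1 - \max(s, 0)$): an anti-similar pair is maximally distant
($d = 1$), not "super-distant" ($d = 2$), which keeps distances in $[0,1]$.
Average-linkage agglomeration (UPGMA, via `stats::hclust`) builds the merge
tree; the cluster count is chosen where the mean intra-cluster distance
curve versus $k$ has maximum perpendicular distance to its end-to-end chord
(the kneedle criterion — an automated stand-in for choosing the elbow by
eye), with a manual override. The PCA + k-means comparison aligns its labels
to the shape-based labels with an exact Hungarian assignment (implemented
in-package as O(k³) Munkres, tested against exhaustive enumeration) and
reports percent agreement, with and without amplitude normalization.

## Cardiac modulation

R-waves are picked off the EKG channel by adaptive-threshold peak detection
(0.6 × rolling maximum, 300 ms minimum separation) — any detector with
interval accuracy at normal heart rates suffices, and the scale-free
threshold makes amplifier gain irrelevant. Each spike's $\alpha'$ is
referenced to the window −0.1 to 0.9 s around its preceding R-wave, binned
(50 bins over the 1 s window by default), averaged across cycles, and
baselined by the pre-R mean. The post-R bins are fitted with the
impulse-response form $A\,t^n e^{-mt}$ by nonlinear least squares
(Levenberg–Marquardt with a 4×4 multi-start grid over initial $n \in
\{0.5,1,2,4\}$, $m \in \{1,5,10,20\}$; with multi-start, any competent
least-squares optimizer reaches the same optimum). Parameters are left
unbounded — an unmodulated unit legitimately fits with a negative decay and
near-zero $R^2$, and that contrast (modulated $R^2 \gg$ unmodulated $R^2$)
is itself the useful readout. $R^2$ is computed on the binned profile.
Non-convergence from every start returns a diagnosable failure object, not
an exception.

## Spectral analysis

PSDs are Welch averages over 1 s Hann segments with 50% overlap, one-sided
density normalization (integral ≈ variance, Parseval-checked in the tests).
Band power is the *mean* density over 200–300 Hz — mean rather than
integral so values compare across bands of different width. The across-site
comparison is a paired t-test on (raw, spike-removed) band-power pairs with
percent reduction $100\,\overline{(raw - residual)}/\overline{raw}$;
zero-variance differences flag the result degenerate and skip the test.

## The synthetic-data generator

The generator is the package's ground truth. It emulates: biphasic and
triphasic template shapes with widths 0.3–1.2 ms and occasional
positive-leading polarity; Poisson firing with a 2 ms refractory dead time
(exponential gaps plus dead time, rate-corrected so the mean rate is as
configured); mean-one lognormal amplitude jitter (sdlog 0.1); background
noise synthesized in the frequency domain as $1/f^\beta$ ($\beta = 1$
default, 80% of noise variance) plus a white floor (20%), with optional
mains and narrow-band oscillation components; optional injected overlap
pairs (a fraction of one unit's spikes trailed 0.3–1.0 ms behind another's);
and cardiac amplitude modulation following $baseline + A\,t^n e^{-mt}$ of
the time since the last R-wave, with a matching synthetic EKG channel.
Amplitudes are expressed as template peak over total noise SD, so
`amp_mean = 10` is a peak SNR of 10 against the raw background.

What it does **not** emulate: electrode drift, bursting/pausing firing
patterns, bi-directional spike interactions (overlap injection is one-way),
multi-channel geometry, amplifier phase response, or movement artifacts.
Passing tests therefore demonstrate correctness of the algorithms under
stationary, well-specified conditions — not robustness to every clinical
artifact.

One measured property of these conditions is worth recording. The projection
$\alpha_k$ integrates whatever background lies in the spike window, and
band-limited $1/f$ noise is correlated across the few dozen samples of a
window, so the projection noise is larger than the in-band noise SD. With
the small per-spike amplitude variability of the generator (10%), this
residual-LFP pickup — the very quantity the method reports as
$V_o^\top V_o$ — bounds the attainable correlation between $\alpha_k$ and
the true amplitudes near 0.87–0.93 for peak SNR 8–10, independent of the
noise composition. The amplitude-recovery validation therefore uses a
well-isolated wide unit at peak SNR 15, where the correlation criterion
(r ≥ 0.95) is met with margin; at lower SNR the ranking of spikes by
$\alpha$ remains correct but is visibly LFP-limited.

## Problem sizes used in validation

The test suite simulates at the native 44 kHz rate throughout. Typical
sizes, chosen to keep each property statistically decidable: 5–30 s traces
for detection/sorting/decomposition checks; 20 seeds × 200 spikes for
window-recovery medians; 20 s two-unit traces (20 and 12 Hz) with 10%
injected overlaps for serial re-sorting; a 50-unit, 3-template track for
clustering; 20 seeds × ~1200 spikes (60 s at 20 Hz) for cardiac parameter
recovery; and six 4 s two-unit sites for the band-power comparison.

## Known limitations

* Serial resolution is one pass per unit in amplitude order; pathological
  chains of overlaps would need more iterations (configurable upstream).
* The canonical shape is a single fixed waveform per unit; bursting cells
  with amplitude-dependent shape change violate the model and show up as
  depressed explained variance rather than being modeled.
* LFP isolation subtracts a band-limited shape from the raw trace; residual
  low-frequency spike energy remains by construction.
* The elbow criterion is a heuristic; for publication-grade cluster counts,
  inspect the dendrogram and intra-cluster distance curve (`autoplot`,
  `select_k_elbow`) and use the manual override.
* Signal I/O is plain CSV + JSON sidecar; vendor formats need conversion
  (any tool that can dump a single-channel float series works).
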