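---
title: "Modelling a mobile EEG telemetry path: adaptive delta coding, filtering and alpha-paradigm validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a mobile EEG telemetry path}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegstream)
```

## What this package models

Low-cost mobile EEG systems stream multichannel data over Bluetooth Low
Energy, a transport whose bandwidth cannot carry 24 channels of raw 24-bit
samples at 250 Hz. The firmware therefore transmits *quantised first
differences* (an ADPCM-style scheme) instead of absolute samples, and the
companion application reconstructs the signal, monitors packet loss, and
lets the user trade resolution against robustness through a handful of
settings: PGA gain, bits per channel, a per-channel adaptive bit shift, a
safety factor, and an IIR filter menu.

`eegstream` is a complete software model of that path, plus the analysis
used to validate such systems: the eyes-open/eyes-closed alpha paradigm,
30-s epoching, multitaper spectra, and a cluster-based permutation test
over channels x frequencies. Everything runs on synthetic recordings
produced by a generator that emulates the validation experiment, so every
claim made here is checked end to end by the test suite.

## The ADC front end

A delta-sigma converter with reference voltage $V_{ref}$ (2.5 V), PGA gain
$g \in \{1,2,4,8\}$ and $b$ output bits resolves

$$\Delta = \frac{2 V_{ref} / g}{2^{b}}$$

volts per least-significant bit over the bipolar range $\pm V_{ref}/g$. At
gain 1 and 24 bits this is about 0.298 µV/LSB over ±2.5 V; at gain 8 about
0.037 µV/LSB over ±312.5 mV. Codes are signed two's-complement centred on
0 V: EEG is a bipolar signal, so the unsigned ranges sometimes quoted for
bit depths (0–65,535 at 16 bits) are only an illustration of code-space
size. Quantisation rounds half away from zero so positive and negative
voltages behave symmetrically, and out-of-range input saturates (as a real
converter does) rather than erroring. Requantisation to 10/14/16 bits is a
pure arithmetic right shift — no dithering — the simplest model consistent
with truncating transmission depth.

## The adaptive delta codec

Every channel keeps a closed-loop DPCM state: the encoder quantises the
difference between the current sample and *its own previous
reconstruction* (never the true previous sample), so quantisation error
cannot accumulate. A transmitted symbol is

$$q = \mathrm{round}\!\left( \frac{x_t - \hat x_{t-1}}{2^{s}} \right),
  \qquad \hat x_t = \hat x_{t-1} + q \, 2^{s},$$

saturated to the $\pm(2^{b-1}-1)$ range of the payload width $b \in
\{10,14,16\}$ bits. The shift $s$ sets the trade-off: larger $s$
represents larger single-sample changes but in coarser steps of $2^s$
codes; the per-sample error is bounded by $2^{s-1}$ codes whenever the
quantiser does not clip.

Once per statistics window (1 s) each channel recomputes the population
standard deviation $\sigma$ of its first differences and selects

$$s = \mathrm{clamp}\left(\,\mathrm{bits}(\,\mathrm{round}(f\sigma)\,)
      - (b - 1),\; 0,\; s_{\max}\right),$$

where $\mathrm{bits}(v)$ is the minimal number of magnitude bits covering
$0..v$ and $f$ is the safety factor: the largest single change that must
survive untruncated, expressed as a multiple of the recent $\sigma$. With
$f = 8$ this costs exactly four more high-order bits than covering
differences strictly below $\sigma$ (baseline $\mathrm{bits}(\sigma-1)$),
trading resolution for headroom against large spikes. The clamp
$s_{\max}$ deliberately sacrifices artifact-sized jumps (blinks, electrode
pops) to preserve resolution; the difference simply clips ("cutting off
the peaks") and the stream continues.

Design choices the device description leaves open, resolved here:

* **Shift semantics.** $s$ counts low-order bits dropped from the 24-bit
  difference, which is what "a larger bit shift enables larger signal
  changes but reduces resolution" requires numerically. The complementary
  picture — leading zero bits of a *small* difference being skipped — is
  the same allocation seen from the other end.
* **Window cadence and keyframes.** The shift is refreshed once per 1-s
  window from the *previous* window's statistics and announced in a
  keyframe packet that also carries the absolute 24-bit codes of the
  window's first sample. Keyframes give the decoder an exact
  resynchronisation point after packet loss; one per second bounds the
  damage of any loss burst to under a second.
* **Bootstrap.** The first window has no prior statistics and uses
  $s = s_{\max}$ — conservative against early saturation while the
  tracker warms up.
* **Framing.** Delta packets carry 25 samples per channel (10 per second
  at 250 Hz), so a single lost packet costs at most 100 ms.
* **$\sigma$ on differences.** The quantity the safety factor bounds is a
  *single signal change*, so $\sigma$ is computed on the first-difference
  signal, not the raw signal.

The packet stream is serialised in a little-endian binary format
(`DMP1`): per packet a 16-bit sequence number (wrapping), a keyframe flag,
the per-channel shifts, and either absolute int32 codes (keyframe) or
int16 difference symbols. 10- and 14-bit symbols are stored in int16
rather than bit-packed; the format favours auditability over the last few
percent of compression.

**Loss handling.** The decoder maps each received packet to its sample
span from sequence arithmetic, holds the last reconstructed value across
gaps (flagging those samples), and resynchronises exactly at the next
keyframe. A monitor compares the loss fraction — computed purely from
sequence numbers — against a threshold (default 1%; the notification
shown by the companion app in the motivating example fires at 3%) and
recommends lowering the payload width or sampling rate when exceeded.

## The filter bank

The firmware samples at 500 Hz, filters, then decimates to 250 Hz (or
167 Hz = every third sample). The menu is a fixed set of IIR designs:
high-pass 0.8/1.0/1.7 Hz (orders 2–4), low-pass 45 Hz order 4 or 60 Hz
order 6, band-stop 46–54 or 48–52 Hz at total order 6 or 4, each stage
optionally off. The default chain is HP 1 Hz (4), LP 45 Hz (4), BS
46–54 Hz (6).

The device description says only "IIR" with orders and cutoffs; this
implementation uses **Butterworth** designs — the standard maximally flat
choice for EEG front ends, and the one that makes "order" and "cutoff"
unambiguous (−3 dB at the cutoff). Band-stop "order" is read as *total*
polynomial order (an order-6 band-stop is a 3rd-order prototype mirrored
around the stop band). Filtering is causal (forward-only), as a streaming
firmware must be; zero-phase forward–backward filtering is available
behind a flag for offline use. The chain order HP→LP→BS only affects
transients, since the stages are linear. Stability of every menu design is
verified at construction (all poles strictly inside the unit circle with
margin 1e-9). Decimation keeps sample 1 and every k-th sample after; the
chain's 45 Hz low-pass is the anti-alias stage (new Nyquist 125 Hz), and
decimating unfiltered data logs a warning. A sweep harness injects a
1–70 Hz chirp and reports the filtered/unfiltered power ratio per
frequency bin — the software replica of feeding a signal generator into
the device with filters on and off; the 50 Hz notch shows as a ratio
below $10^{-4}$ in power.

## The synthetic validation experiment

The generator emulates the validation protocol: five cycles of 2-minute
eyes-closed / 2-minute eyes-open (20 min, starting eyes-closed) on the
24-channel 10–20 montage (FP1…O2, mastoids M1/M2; schematic 2-D positions
bundled as a plain-text table, since only the labels are standardised).

Signal content and default magnitudes (all configurable):

* **1/f background**, 10 µV RMS on every channel — the dominant broadband
  floor of resting EEG;
* **posterior alpha**, ~10 Hz, 20 µV peak with slow amplitude and
  frequency jitter, on POZ/O1/OZ/O2 (full) and P3/PZ/P4 (half amplitude),
  present only while eyes are closed. The parietal half-amplitude copy
  gives the effect the occipital–parietal spatial spread that a cluster
  test should recover as one contiguous cluster;
* **frontal delta**, 15 µV RMS band-limited 0.5–4 Hz drift on FP1/FPZ/FP2
  during eyes-open, plus **blinks**: Poisson-placed (0.25/s) smooth
  biphasic ~300 ms transients, 100 µV on the frontopolar channels,
  confined to eyes-open spans;
* optional common-phase **50 Hz mains** at 5 µV.

These magnitudes are physiologically plausible resting-EEG values and give
the cluster test high power at the study's epoch counts; they are the
package's fixed reference conditions, not tuning knobs. The generator is
deterministic under its seed (one Mersenne-Twister stream seeded at
entry). What it does *not* model: volume conduction from dipolar sources,
inter-subject variability, non-blink artifact classes, electrode
impedance drift. Passing tests therefore demonstrate that the *software
path* preserves and recovers a known contrast — not that the statistical
pipeline would behave identically on human data.

## The analysis pipeline

1. **Channel screening.** Bad channels are dropped automatically by a
   log10-variance rule: robust z (median / 1.4826·MAD across channels)
   above 5 *and* variance at least 10x the channel median (or flat/dead
   channels). Two details matter. A plain (mean, sd) z-score cannot work
   here: with 24 channels a single outlier's z is algebraically bounded
   by $(n-1)/\sqrt{n} \approx 4.7$, below any sensible threshold. And
   with a MAD alone, synthetic data bites back: many background-only
   channels have *identical* variance (the generator normalises RMS
   exactly), the MAD collapses to zero and every channel becomes an
   outlier. The 10x ratio guard makes the rule scale-free and safe in
   both regimes.
2. **Epoching.** Non-overlapping 30-s epochs cut strictly inside
   condition blocks (tails discarded): the default session yields 40
   epochs, 20 per condition.
3. **Multitaper spectra.** Thomson's method with DPSS tapers at
   half-bandwidth $W$ = 1 Hz and $K = \lfloor 2TW \rfloor - 1 = 59$
   tapers for $T$ = 30 s; eigenspectra averaged with equal weights;
   one-sided density in µV²/Hz. The tapers come from the classical
   symmetric tridiagonal eigenproblem, solved by Sturm bisection plus
   inverse iteration (unit-tested against a dense eigensolver at small
   n); spectra are evaluated on a power-of-two zero-padded FFT grid
   (4096-point FFTs for 30-s epochs at 250 Hz would truncate, so 8192).
4. **Band powers.** Delta 1–4, Theta 4–8, Alpha 8–12, Beta 12–30 Hz,
   half-open intervals that partition 1–30 Hz.
5. **Cluster-based permutation test.** Pooled-variance two-sample t per
   (channel, frequency) cell on log10 power — EEG power is strongly
   right-skewed and the t-statistic behaves far better on the log scale
   (the choice is exposed). Cells with $|t|$ above the two-sided critical
   value at `cluster_alpha` = 0.01 form clusters under the adjacency:
   neighbouring frequency bins within a channel, spatially neighbouring
   channels (Euclidean distance ≤ 0.4 head radii) within a bin. Positive
   and negative clusters are kept separate; each is scored by its summed
   t and referred to the permutation distribution of the maximum
   absolute cluster score over both signs (family-wise control). Monte
   Carlo p-values use the +1/+1 correction, so p is never zero and the
   test is exact-conservative; everything is deterministic under the
   config seed. The tested range is restricted to 1–30 Hz, the union of
   the classical bands. Cluster significance defaults to 0.05;
   topographies in validation studies are often thresholded at 0.01, so
   both levels are independent knobs.
6. **Effective channels.** The union of channels in significant
   clusters, in montage order. On synthetic data this recovers the
   posterior alpha set (and, with the frontal generators on, the
   frontopolar delta/blink set) — the software analogue of selecting the
   most effective channels in a validation study.

**End-to-end fidelity.** `compare_pipelines()` correlates the
per-channel eyes-closed-minus-open band-power contrast between a clean
recording and its processed twin. Round-tripping through ADC (gain 8) +
codec (b = 16, f = 8) + the default chain leaves the alpha topography
correlated at r > 0.95 — the quantitative stand-in for "both systems
produce nearly identical outcomes".

## Numerical and testing choices

* Rounding is half-away-from-zero throughout (ADC and codec), keeping
  signs symmetric.
* The loss fraction is computed as `(expected - received)/expected` so
  that, e.g., 30/1000 compares exactly against a 3% threshold in floating
  point.
* The cluster permutation loop and component labelling, the codec's
  closed-loop encoder, the DPSS solver and the taper-FFT accumulation are
  compiled (Rcpp); the FFT packs two real series per complex transform.
* Problem sizes in the test suite: unit tests run seconds-scale
  fixtures; the statistical acceptance checks run 200 null simulations
  (200 permutations each) for type-I calibration and 50 seeded full-scale
  recovery runs (20-min sessions, 20 vs 20 epochs, 199 permutations) for
  power — the permutation count is the smallest that can resolve
  p < 0.01, and with the default effect sizes the observed cluster score
  exceeds every permutation maximum in practice.
* A criterion the test suite asserts but that deserves a caveat: the
  type-I rate of the cluster test is checked within three binomial
  standard errors of 0.05 over 200 simulations — a calibration check,
  not a proof of exactness at every configuration.

## Limitations

The packet channel is ordered and lossy but does not model reordering,
duplication or corruption within a packet (a real BLE stack handles
those). The codec does not implement the "automatic artifact filter"
sometimes attributed to ADPCM schemes beyond saturation clipping — no
concrete mechanism exists to model. XDF/LSL streaming is out of scope;
CSV is the interchange format. The montage's 2-D coordinates are
schematic, adequate for neighbourhood structure but not for source-level
interpretation.
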