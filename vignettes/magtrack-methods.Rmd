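---
title: "Models, calibration and numerical choices in magtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and numerical choices in magtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magtrack)
```

`magtrack` implements the computational chain of a magnet-based eye
tracking system for mice: a forward model of the magnetic angle sensor, the
dual-angle video-oculography geometry used to calibrate it, the signal
conditioning and regression machinery of the calibration itself, and the
oculomotor metrics computed from calibrated traces. This vignette is the
package's own account of those models, the parameters that matter, and the
numerical decisions taken where the design was genuinely open.

## The sensor model

A magnet implanted in the eye rotates with it. A two-channel
anisotropic-magnetoresistive (AMR) angle sensor fixed to the skull above
the eye senses the direction of the magnet's field. Each channel is a
Wheatstone bridge of AMR elements operating in magnetic saturation, so its
differential output depends on the *angle* of the in-plane field, not its
magnitude:

$$V_c(\theta_m) = A\,\sin\!\big(2(\theta_m - \phi_c)\big) + b_c, \qquad
\phi_2 - \phi_1 = 45^\circ .$$

Two consequences shape everything downstream. The response is
180°-periodic (the bridge cannot tell N from S), and near a zero crossing
of one channel the other channel is at an extremum — the 45° stagger
guarantees that at least one channel is in its steep, nearly linear region
at any eye angle.

**Sensitivity** is defined operationally, as on a bench: the absolute slope
of voltage against magnet angle, averaged within ±22.5° of each zero
crossing of the channel, then averaged over crossings
(`estimate_sensitivity()`). For an ideal channel this mean slope is
$A\sqrt{2}/45$ per degree, which the package uses to convert between
amplitudes and sensitivities. The amplitude attenuation with magnet
distance is anchored at bench measurements of 224.7, 127.0 and
28.1 mV/° at vertical distances of 0, 3 and 5 mm, joined by a monotone
piecewise-cubic (Hyman-filtered) interpolant and held constant beyond
5 mm — the measurements are point values, and a shape-preserving
interpolant adds no spurious structure. The horizontal-offset factor
follows the inverse-cube falloff of a dipole field about a 3 mm reference
depth, $\big(d_0^2/(d_0^2+\delta_h^2)\big)^{3/2}$ with $d_0 = 3$ mm, so it
is 1 at zero offset and monotone decreasing.

Misalignment is modeled by a **point dipole** riding the eye's rotation at
a lever arm from the rotation axis (`dipole_field_angle()`): the field
angle at the sensor is computed exactly from the dipole equation, and the
voltage follows by passing that angle through the bridge response. A
finite-magnet integration would change the quantitative attenuation but
not the qualitative behaviour this model exists to exercise: off-axis
placement flattens the angle-to-angle mapping, while tilting an *aligned*
magnet changes nothing, because on the axis the in-plane field direction
tracks the in-plane moment direction regardless of tilt, and the saturated
bridge ignores the accompanying loss of field magnitude.

## Dual-angle video-oculography

Two cameras view the eye with their axes $\alpha = 40^\circ$ apart and
equidistant lenses, so both images share one spatial scale. Subtracting
the corneal reflection (CR) of a camera's own LED from the pupil center
cancels translation of the eye relative to that camera; the remaining
signed horizontal distance is pure rotation:

$$\Delta_1 = R_p \sin\theta_1, \quad \Delta_2 = R_p \sin\theta_2, \quad
\theta_1 + \theta_2 = \alpha,$$

with $R_p$ the distance from the pupil plane to the center of corneal
curvature. The ratio $\Delta_1/\Delta_2$ eliminates $R_p$ — the decisive
property, since $R_p$ varies across animals and with pupil dilation.
`angle_from_deltas()` implements the inversion in two-argument arctangent
form,

$$\theta_2 = \operatorname{atan2}\!\big(\Delta_2 \sin\alpha,\;
\Delta_1 + \Delta_2 \cos\alpha\big),$$

rather than the algebraically equivalent
$\arctan\big(\sin\alpha / (\Delta_1/\Delta_2 + \cos\alpha)\big)$: the
quotient form is singular at $\Delta_2 = 0$ although the geometry is not,
and the atan2 form extends smoothly to signed distances on both sides of
each camera axis. Round trips through the forward model are exact to
better than $10^{-9}$ degrees across the working range.

Reported angles use a **symmetric-zero convention** — zero on the bisector
of the camera axes, i.e. $\theta_2 - \alpha/2$ — because the rig is aligned
so the resting pupil sits roughly centered between the two CRs. Which
camera lies nasal differs between eyes, so the sign mapping is a
configuration flag (`positive_toward_cam2`).

## Pupil and CR detection

Frames are grayscale matrices in $[0,1]$. Bright CRs are localized with a
circular Hough transform over a configured radius range (default 2–6 px),
refined to sub-pixel precision by a brightness-weighted centroid using
only supra-threshold pixels, which stays symmetric even when the dark
pupil edge crosses the refinement window. The *reference* CR is the peak
nearest the image center; the reflection generated by the opposite
camera's LED lands elsewhere and is thereby ignored. Detected CRs are
masked — pixels inside 1.5× the detected radius are replaced by the median
of a surrounding annulus — so glints cannot masquerade as pupil edges.

The pupil is found Starburst-style: `n_rays = 36` rays cast from a seed
point, the strongest outward dark-to-light gradient along each ray taken
as a candidate edge (sub-pixel, via parabolic interpolation of the
gradient peak), the seed re-centered on the candidate centroid and the
process iterated, then an ellipse fitted by random-sample consensus with a
direct least-squares conic fit and a final refit on the inliers. The
consensus draws use a fixed, configurable seed so the stochastic fit is
reproducible. Ray count, gradient threshold, Hough radius range and mask
safety factor are exposed as arguments; the defaults were chosen for the
package's rendered frames, and on those renders the detector localizes
pupil centers to about 0.1–0.2 px. Batch processing seeds each frame at
the darkest point of a box-smoothed image, which is robust across the full
sweep of eye positions without inter-frame state.

## Signal conditioning and alignment

*Filtering.* The acquisition low-pass is an order-4 Butterworth applied
forward–backward for zero phase. Because the double pass squares the
magnitude response, the design corner is placed (using the bilinear
tangent-warping relation) so that the *combined* response is −3 dB at the
nominal cutoff, and odd-reflection padding suppresses edge transients.

*Differentiation.* Velocity is the least-squares slope in a centered
50 ms sliding window — a fit, not an endpoint difference (an endpoint
variant is available), because a fit is exact on ramps and maximally
noise-averaging. The window attenuates a sinusoid by a known factor; where
a gain is computed from windowed velocity, `gain_phase()` divides that
factor out, so gains are unbiased even at 5 Hz where the raw attenuation
approaches 10%.

*Desaccading.* Samples with |velocity| above threshold (video 50 °/s,
sensor 5 mV/ms) are marked, dilated by a 50 ms pad on each side — saccadic
transients have sub-threshold shoulders — and merged. Masks from the video
and sensor streams are unioned: a segment removed in either stream is
removed from both.

*Alignment.* Both streams see the same 1 Hz, 30 ms LED flashes (as camera
frame brightenings and as TTL pulses). With a strictly periodic train the
clock offset is only identifiable modulo the period, so the aligner
evaluates every candidate pairing of the first flash, keeps the candidates
matching the most flashes, and breaks ties by the smallest absolute
offset — correct whenever the true offset is under half the flash
interval, and robust to single missed detections through nearest-neighbour
matching. A linear fit of TTL times on flash times yields offset and
drift; the video trace is then re-expressed in sensor time and linearly
interpolated onto the sensor grid.

## Calibration

Three position models regress video-derived eye position on the sensor
channels: each channel alone (ordinary least squares; the channel more
strongly correlated with video is selected, by |r| because implant
polarity may invert the sign), both channels with an L2 penalty, and both
channels plus their squares. The two sensor channels are strongly
correlated over the small angular range of a head-fixed eye, which is the
motivation for ridge regularization. The penalty is selected by 10-fold
cross-validation with **contiguous time blocks** rather than interleaved
folds — oculomotor traces are strongly autocorrelated, and interleaved
folds would leak nearly identical neighbouring samples between train and
test. The grid spans $10^{-6}$–$10^3$ in 25 log-spaced steps after
regressor standardization (coefficients are returned on the original
scale); after selection the regression is re-run on all calibration data.
Both choices — blocked folds and standardization — are recorded in the
fitted object.

The velocity method fits sines at the known stimulus frequency to the
differentiated video and sensor traces and takes the amplitude ratio
$A_{vid}/A_{mag}$. Sine fitting uses a linear sin/cos + DC basis — the
stimulus frequency is experimenter-controlled, making the fit convex and
exact, and tolerant of masked gaps. Amplitudes are phase-invariant, so the
method needs no temporal registration of the two streams at all. The
video trace is upsampled to the sensor rate *before* differentiation, so
the 50 ms window averages over the interpolated frame noise and both
streams pass through the identical differentiator, whose frequency
response then cancels in the ratio.

Day-to-day stability is summarized by
$\Delta k_n = |k_n - k_1| / k_1 \cdot 100\%$.

## Oculomotor metrics

Gain is the sine-fit amplitude of desaccaded eye velocity divided by the
stimulus amplitude (the commanded peak velocity by default; a fitted
stimulus amplitude is available). Phase is reported relative to the ideal
compensatory response — 0° means the eye exactly opposes the stimulus,
positive values lead — a convention chosen so the ideal vestibulo-ocular
response is the natural zero; it is stored with the output.

Spatial resolution is the SD of eye position in stationary 2 s epochs,
three epochs averaged. "Stationary" is judged by two criteria: no saccades
(50 ms velocity never reaches 50 °/s) and no net drift (the epoch-level
least-squares slope below 0.5 °/s). The drift criterion is deliberately
*not* an instantaneous-velocity criterion: white measurement jitter — the
very quantity being estimated — inflates instantaneous velocity estimates
without the eye moving, and would disqualify every epoch at high jitter.
Epoch-level drift is insensitive to jitter yet still rejects slow eye
movements. The estimator is unbiased within 10% for jitter SDs from 0.05°
to 0.5°.

The motion index subtracts the pixel-wise mean background from overhead
frames, takes the mean absolute difference between consecutive frames,
smooths with a centered 2 s moving average, and labels the upper tertile
of smoothed values Active and the lower tertile Still (ties broken by
first occurrence, keeping tertile counts within one of $n/3$). Background
subtraction makes the index invariant to static scene content and global
brightness offsets. Binocular summaries average per-eye statistics across
the two eyes before reporting, and divergence is right-minus-left in a
common rightward-positive convention (the sign convention is a
configuration choice; none is canonical).

## The synthetic-data generator

The generator produces every stream the pipeline consumes, under the
standard study conditions: sinusoidal stimuli at 0.2, 0.5, 1, 2 or 5 Hz
with ±10 °/s peak velocity; a 60 s calibration session at 1 Hz; sensor
sampling at 1 kHz (the acquisition rate is not dictated by the method; 1
kHz is typical and makes the 100 Hz filter meaningful); 30 fps video; 1 Hz,
30 ms sync flashes. The eye response has configurable gain (default 0.8,
typical of vestibular responses in the light), phase, Poisson saccades
(0.2 Hz, amplitude 5 ± 1.5°) as 20 ms linear ramps — the pipeline removes
saccades rather than modeling them, so any fast supra-threshold transient
serves — white fixation jitter (0.02°), sensor noise (5 mV), and landmark
noise of 0.15 px, matching the measured precision of the package's own
detector on rendered frames. Saccade direction is biased toward
re-centering (probability 0.8), as in fixating animals; without this the
saccade sequence is an unbounded random walk that carries the eye into the
sensor's nonlinear range, which real mice do not do.

Rendered eye frames are deliberately schematic: a uniform iris, an
anti-aliased dark pupil ellipse, Gaussian CR glints composited over the
scene (a specular glint stays bright even in front of the dark pupil), a
displaced distractor glint, and white pixel noise. They exercise the
detectors' geometry — localization, masking, distractor rejection — but
not eyelid occlusion, uneven illumination, torsion or pupil-diameter
dynamics. Passing tests on these renders therefore validate the
algorithmic chain, not performance on any particular real video. The same
caveat applies pipeline-wide: the generator realizes exactly the
statistical structure the pipeline assumes (white noise, stationary gain,
linear small-angle sensor response around the operating point), so
recovery results bound what the method can do under its own assumptions,
not under violations of them.

## Problem sizes and tolerances

The test suite and the acceptance script run 60 s sessions at 1 kHz (the
standard calibration length), a ±25° rendered sweep at 2.5° steps for the
image chain, and a 120 s three-level overhead video at 15 fps — sizes
chosen to estimate every quantity with comfortable statistical margin
while keeping a full run in the tens of seconds. Geometry round trips are
held to $10^{-9}$ degrees (pure floating-point algebra); calibration
recovery to 5% with all noise sources at their defaults and 1% with noise
disabled; gain to 0.02 and phase to 2° across the frequency battery;
rendered-sweep angle errors to 0.5°. Degenerate inputs fail loud and
specific: constant sensor channels are marked unusable rather than fitted,
frames without a detectable pupil or CR are flagged invalid and excluded
rather than interpolated, all-invalid frame sets and insufficient
stationary epochs raise errors that name the shortfall.

## Known limitations

The dipole misalignment model is a point-dipole approximation; it
reproduces the qualitative offset and tilt behaviour but not exact field
maps of a finite cylinder magnet. The sensor model omits amplifier
electronics, thermal drift, magnetic saturation limits and bilateral
magnet–sensor crosstalk. The video geometry is purely horizontal;
vertical and torsional components are out of scope. Alignment assumes the
camera clock offset is below half the flash interval. Calibration assumes
the eye stays within the sensor's monotone response region around the
operating point; the quadratic model extends, but cannot remove, that
assumption.
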