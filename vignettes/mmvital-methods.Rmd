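---
title: "Methods: models, parameters and numerical choices in mmvital"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in mmvital}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mmvital simulates and processes the sensing chain of a seatbelt-integrated
beam-focusing metasurface radar: a flexible transmitarray lens focuses a
60 GHz FMCW radar on the occupant's chest, the slow-time phase of the
selected range bin encodes chest displacement, variational mode
decomposition (VMD) separates respiration and heartbeat, and an EWMA
variance statistic on the range envelope detects seat occupancy. This
vignette records the models, the parameters that matter, and the numerical
decisions behind the implementation.

## Lens design

A unit cell of pitch 1.6 mm on polyimide (relative permittivity 3.5) is
about 0.6 guided wavelengths at 60 GHz
(`guided_wavelength(60e9, 3.5)` = 2.67 mm), small enough to suppress
grating lobes. The 37 × 37 aperture (59.2 mm square) focuses by imposing
the hyperbolic equal-path phase
$\Delta\varphi_i = k(\sqrt{R_i^2+F_t^2}-F_t) \bmod 2\pi$ per element.

Two conventions for this profile circulate, differing by a factor of two
(one-way transmission phase versus a round-trip form). We adopt the
one-way $2\pi/\lambda$ profile as canonical — it is the standard lens
phase and reproduces focusing at the design distance in the diffraction
engine — and expose the round-trip variant behind `two_way = TRUE`.

Full-wave characterization of the unit cell (patch side $L$ versus
transmission phase/magnitude) is out of scope; `phase_lookup_synthetic()`
ships a monotone stand-in spanning 350° over $L \in [0.2, 1.2]$ mm with
magnitude no worse than −3 dB, and `read_phase_lookup()` accepts measured
CSV tables. Quantization picks the wrap-aware nearest entry on the phase
circle; exact ties break toward the smaller $L$ for determinism.

The rotation angles of the gradient pair used for the fabricated lens are
not fixed anywhere; `beam_angles()` therefore takes them as free inputs
and validates the propagating-wave condition
$\sqrt{k_x^2+k_y^2} \le k_0$, raising an explicit domain error for
evanescent combinations.

## Scalar diffraction

The aperture is many wavelengths wide and only power patterns are needed,
so propagation is scalar. `propagate_angular_spectrum()` decomposes the
sampled field into plane waves (2-D FFT), advances each by
$e^{ik_z z}$, $k_z = \sqrt{k^2-k_x^2-k_y^2}$, and recomposes; evanescent
components decay as $e^{-|k_z|z}$. Because the FFT box is periodic, plane
waves steeper than $\arctan(L/2z)$ would wrap around rather than leave the
box; the propagator is band-limited to exclude them (the band-limited
angular-spectrum method). This is what lets far-field checks against the
sinc² closed form hold to better than 1%.

Default grids: 0.25 mm sampling ($\lambda/20$ at 60 GHz), power-of-two
grids at least twice the aperture, z-scans from 10 to 300 mm in 1 mm
steps. The on-axis scan is evaluated directly from the propagating part of
the spectrum (a weighted sum per z) rather than by per-z inverse FFTs.

With $F = 150$ mm and a 59.2 mm aperture at 5 mm wavelength, only about
1.2 Fresnel zones fit across the aperture. The axial intensity peak of
such a weakly focused aperture sits well short of the geometric focus;
the simulation reports this focal shift honestly rather than forcing the
peak to the design distance. For the same reason the simulated spot FWHM
(near the diffraction limit $0.886\,\lambda z/D$) is smaller than the
roughly 20 mm spot a fabricated lens with element-level amplitude taper
and quantization shows — element amplitudes are not available to match.

**Bending.** The sheet is wrapped isometrically (arc length preserved)
around a cylinder subtending the stated angle; each element keeps its arc
coordinate and acquires the chord (projected) position and an extra
transmission phase $k_0 \times$ sag. Bending along one axis is a
cylindrical (astigmatic) aberration: it moves the axial peak and deforms
the spot. Focal position and width are therefore reported per
configuration, while the SNR used to compare bend angles is measured in a
fixed plane — the unbent design's focal plane, which is where the radar
actually aims — with a fixed exclusion mask of twice the unbent FWHM
(peak power over mean power outside the mask, in dB). The SNR metric
itself is our definition; no standard one exists for this setting.

**Layered media.** `tmm_reflection()` is a textbook characteristic-matrix
solver (TE/TM, oblique incidence, loss via $\epsilon_r(1-i\tan\delta)$),
checked against Fresnel closed forms to 1e-10. The exact seatbelt stack
behind published matching-layer maps is described only qualitatively, so
`matching_sweep()` exposes the sweep machinery over any user stack rather
than reproducing a specific map.

## FMCW simulator

Chest displacement:
$R(\tau) = d_0 + A\sin(2\pi f_r \tau) + B_h \sin(2\pi f_h \tau) + m(\tau)$,
with $d_0 = 0.6$ m inside the 0.5–0.8 m acquisition gate. Chest-wall
amplitudes are nowhere published for this system; we use literature-typical
$A = 4$ mm (respiration) and $B_h = 0.3$ mm (heartbeat). Per-condition
rates default to the published spectral peaks (with lens: 0.45/1.12 Hz
standby, 0.53/1.20 Hz driving, 0.52/1.18 Hz bumpy; analogous values
without the lens), and the vibration level to the measured RMS
accelerations (0.030/0.200/0.310 m/s² with lens, 0.037/0.325/0.470
without).

**Vibration model.** $m(\tau)$ is white Gaussian acceleration band-passed
to 8–20 Hz, doubly integrated spectrally, with the acceleration RMS scaled
exactly to the condition's level. Two physical facts force the band
choice: (i) acceleration with DC content has an unbounded double integral
— the seat would random-walk out of the range gate; (ii) at these RMS
levels any band below a few Hz implies millimetre-scale displacement whose
per-frame phase step exceeds $\pi$ at the 13.25 Hz frame rate, so
unwrapping fails and *no* processing could recover rates — contradicting
the working system the model emulates. Road and drivetrain vibration
transmitted through a car seat is in fact concentrated above the
whole-body-resonance region; 8–20 Hz is above the slow-time Nyquist rate
(6.62 Hz), so the series is generated on an oversampled grid and decimated
to the frame rate, aliasing into the samples exactly as it would at the
radar. The sub-0.1 mm displacement this leaves is what perturbs interval
estimates progressively from standby through bumpy.

**Radar signal.** Per frame $m$ the fast-time samples carry
$f_b = 2BR(\tau_m)/(cT_c)$ and the slow-time phase
$4\pi R(\tau_m)/\lambda$; a 0.6 m target lands in range bin 20 at the
0.03 m bin spacing. Complex white noise meets the per-sample scenario SNR
(default 20 dB with lens; the lens benefit is modelled as a +10 dB SNR
offset, the gain itself being unpublished), independently per RX channel —
the three RX channels are noise replicas since the processing chain uses
no angle information. Residual chirp phase noise and the quadratic
$\pi B T_c t_d^2$ term are neglected, as in the underlying signal model.
The ramp-duration and frame-time symbols are disambiguated as
`chirp_time` (32 µs, sets $f_b$) and `frame_time` (75.476 ms, sets the
slow-time rate); scenario construction asserts that the heart band stays
below the slow-time Nyquist rate.

**What the generator does not emulate.** Body scattering geometry,
multi-target scenes, RX-channel angle diversity, non-sinusoidal heartbeat
waveforms, heart-rate variability, and posture shifts. Passing tests
therefore demonstrate correctness of the chain under the stated model,
not clinical performance on real subjects.

## Vitals pipeline

Fast time is Hann-windowed (normalized to unit coherent gain) before the
range FFT; the gated bin with maximum mean power is selected, ties to the
lowest bin. Channel phases are unwrapped separately, mean-centred, and
averaged; a linear detrend precedes decomposition.

The single-bin DFT phase of a symmetric window carries, besides
$4\pi R/\lambda$, a beat-frequency leakage term that is also proportional
to $R$: the total slope is $(4\pi/\lambda)(1+\rho)$ with
$\rho = (N-1)B\lambda/(2cN)$ (≈ 4.1% here). Rate estimation is
scale-invariant, but the displacement inversion divides this known factor
out, which is what makes the noise-free round trip accurate to below
1 µm RMS.

**VMD** is implemented in-package as the frequency-domain ADMM: Wiener
mode updates, power-weighted centre-frequency updates, optional dual
ascent (step `tau`). Defaults: $K = 4$, penalty $\alpha = 2000$,
$\tau = 0$ (relaxed reconstruction, appropriate with noise),
tolerance 1e-7, 500 iterations, mirror extension by half the signal on
each side, uniform centre-frequency initialization over the band.
Hitting the iteration cap flags (not fails) the result; on realistic
noisy phase series the relative-change criterion often stays just above
1e-7 while the centre frequencies are long settled, so the flag is
informational. None of these constants are published for the system;
all are arguments.

Respiration and heart modes are the highest-power modes inside
0.1–0.7 Hz and 0.8–2.5 Hz — bands chosen to cover every rate the system
reports; a band without a mode raises a missing-vital flag. Rates are
parabolic-interpolated spectral peaks of the assigned mode; intervals are
successive peak times of the time-domain mode (sub-sample parabolic
refinement, minimum peak distance 0.6 of the rate period), flagged short
when fewer than three peaks exist. Sliding 30 s windows with 50% overlap
supply per-window rates for CV statistics; window length is a trade
between rate resolution and stationarity, and is configurable.
Reference-versus-radar interval pairing uses the constant ground-truth
period of the generator, so Bland–Altman inputs are aligned by
construction.

## Occupancy detection

The envelope is the per-frame peak magnitude inside the range gate
(averaged over channels) — a fixed bin cannot follow a scene whose
occupant, bag and seat surface sit at different ranges. The EWMA variance
recursion and the cutoff-to-$\alpha$ identity
$\alpha = \cos\Omega - 1 + \sqrt{\cos^2\Omega - 4\cos\Omega + 3}$,
$\Omega = 2\pi f_c T_s$, are implemented exactly as stated; the identity
is verified in tests against the measured half-power point of the one-pole
filter.

The cutoff default is 1.5 Hz, sized so that the statistic decays from a
full-scale transition spike ($\sigma \sim$ envelope step over $T_s$) down
to a calibrated threshold within the 1 s decision hold at the 13.25 Hz
frame rate; slower cutoffs smooth more but leave the detector lagging
a vacated seat. Classification is strictly greater-than (at threshold is
not-person), and state runs shorter than the 1 s hold merge into the
preceding state to suppress chatter.

Threshold calibration is the geometric mean of the mean person-$\sigma$
and the maximum empty/object-$\sigma$, failing loudly when the classes
overlap. Frames within 2 s of a scripted transition are excluded from
calibration: the statistic's own transient would otherwise dominate the
empty-class maximum and misplace the threshold.

The scripted scenario (empty 0–20 s, bag 20–40 s, person 40–80 s, empty
80–120 s) models the seat surface and bag as static reflectors (envelope
levels about 0.2 and 0.35) and the person as a 0.5-level reflector whose
amplitude is modulated 15% by breathing — the person's micro-motion is
what the variance statistic keys on. Envelope noise is kept small
(0.004 per fast-time sample) because the statistic divides differences by
$T_s$: frame-to-frame envelope noise enters as $2v/T_s^2$ regardless of
$\alpha$, and separation of person from empty requires the
breathing-slope term to dominate it.

## Determinism and problem sizes

Every stochastic quantity flows through a scenario or function seed; the
global RNG state is saved and restored around generation, so repeated
calls are bit-identical. The test suite exercises 300 s single runs
(3974 frames) for rate recovery, a 10-seed × 3-condition ensemble of 60 s
runs for the interval-degradation study, the full 120 s occupancy
timeline (1589 frames), and 512–1024-point grids for the diffraction
checks — sizes chosen so the whole suite runs in well under a minute on
one core while keeping spectral resolution (0.0033 Hz at 300 s) far below
the 0.05 Hz recovery tolerance.

## Known limitations

- The diffraction study is free-space; tissue enters only through the
  transfer-matrix stacks. The published bending fields through tissue are
  qualitative and not reproduced pixel-for-pixel.
- The low-Fresnel-number focal shift means simulated focal distances are
  systematically short of the geometric design value; comparisons across
  configurations (bends) are made in a fixed plane for that reason.
- Without-lens bumpy scenarios can lose the heart mode entirely (the
  missing-vital flag) — consistent with the degraded no-lens behaviour the
  system is designed to avoid, but it means downstream statistics for that
  combination may be undefined.
- The EWMA detector separates person from not-person only; it cannot
  distinguish an empty seat from a static object, and its performance
  depends on envelope noise being small relative to breathing-induced
  amplitude modulation.
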