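# mmvital

Simulation and signal-processing toolkit for a seatbelt-integrated,
beam-focusing metasurface radar that monitors vital signs inside a car. A
flexible transmitarray lens woven into the seatbelt focuses a 60 GHz FMCW
radar beam on the occupant's chest; the slow-time phase of the reflected
signal carries chest displacement from respiration and heartbeat, which is
decomposed into rates and beat-to-beat intervals, while an
exponentially-weighted variance statistic on the range envelope decides
whether the seat holds a person, an object, or nothing.

The package is aimed at radar / biomedical signal-processing engineers who
want to study this sensing chain end to end on synthetic data: every stage
is an ordinary R function with a tested contract, and the simulator
generates the inputs the hardware would produce.

## What is implemented

**Lens design.** The transmitarray is a 37 × 37 grid of 1.6 mm unit cells
(59.2 mm square). Each element at radius \(R_i\) from the aperture centre
must impose the hyperbolic focusing phase

\[ \Delta\varphi_i = k\,\bigl(\sqrt{R_i^2 + F_t^2} - F_t\bigr) \bmod 2\pi \]

for focal length \(F_t\) (150 mm default). `aperture_layout()` builds the
grid, `quantize_phases()` maps each target phase to the nearest realizable
unit cell from a measured or synthetic phase lookup, and `beam_angles()` /
`zero_tilt_residual()` evaluate the beam-tilt geometry of a pair of
phase-delay gradients \(p_1, p_2\) at rotation angles \(\alpha_1,
\alpha_2\) (broadside requires \(p_1^2 + p_2^2 + 2p_1p_2\cos(\alpha_1 -
\alpha_2) = 0\)).

**Diffraction.** `propagate_angular_spectrum()` is an exact scalar
plane-wave-spectrum propagator (band-limited against FFT wrap-around);
`focus_metrics()` and `bend_study()` measure focal position, spot FWHM and
focal SNR for the flat and cylindrically bent lens; `tmm_reflection()` and
`matching_sweep()` solve layered dielectric stacks (seatbelt matching
layer, four-layer tissue model) by the transfer-matrix method.

**FMCW simulation.** The chest is modelled as
\(R(\tau) = d_0 + A\sin 2\pi f_r\tau + B_h\sin 2\pi f_h\tau\) plus a
band-limited vibration term scaled to the RMS acceleration of the standby
/ driving / bumpy conditions. `beat_signal()` emits the complex baseband
cube with beat frequency \(f_b = 2BR/(cT_c)\) and slow-time phase
\(\phi_b = 4\pi R/\lambda\) at the radar's parameters (64 samples / 32 µs
chirp, 5 GHz bandwidth, 75.476 ms frames, 1 TX / 3 RX).

**Vitals pipeline.** `range_fft()` → `select_bin()` (0.5–0.8 m gate) →
`extract_phase()` → `vmd()` — an in-package ADMM implementation of
variational mode decomposition — → `assign_modes()` (respiration
0.1–0.7 Hz, heart 0.8–2.5 Hz) → `estimate_rates()` (spectral-peak rates,
inter-beat and breath-to-breath intervals) → `agreement()` (Bland–Altman
mean difference and ±1.96 SD limits, CV, error %).

**Occupancy.** `ewma_sigma()` implements
\(\sigma^2[n] = \alpha\,((y[n]-y[n-1])/T_s)^2 + (1-\alpha)\sigma^2[n-1]\)
on the range-gate peak envelope, with `alpha_from_cutoff()` mapping a
half-power cutoff to \(\alpha\); `classify_occupancy()` applies a
calibrated threshold \(\sigma_{th}\) with a 1 s hold.

## Worked example

```r
library(mmvital)

sc <- vital_scenario("driving", duration = 120, seed = 42)
res <- run_end_to_end(sc, window_s = NULL)
res$estimate
#> vitals_estimate: respiration 0.530 Hz (31.8 /min), heart 1.199 Hz (72.0 bpm)
#>   63 breath intervals, 143 beat intervals
res$agreement_hr
#> agreement_report (driving): mean diff -0.618, LoA [-90.45, 89.21], error 0.0742%, n = 143
```

The driving scenario generates 120 s of baseband data for a chest
breathing at 0.53 Hz with a 1.20 Hz heartbeat under 0.200 m/s² RMS
vibration; the chain recovers 0.530 Hz and 1.199 Hz (71.96 bpm). The
agreement report compares the 143 radar inter-beat intervals against the
ground-truth beat period: the mean difference is −0.6 ms and the
Bland–Altman limits span roughly ±90 ms under driving vibration.

The lens itself:

```r
lay <- aperture_layout(lookup = phase_lookup_synthetic())
focus_metrics(lay)
#> focus_metrics (bend 0 deg): peak_z 119.5 mm, shift -30.5 mm, FWHM 9.3 mm, SNR 31.3 dB
```

With only ~1.2 Fresnel zones across the 59.2 mm aperture at 150 mm focus,
the simulated axial peak sits short of the geometric focal length — the
expected low-Fresnel-number focal shift — with a 9.3 mm spot and 31 dB
focal SNR; `bend_study(lay)` shows the SNR degrading monotonically as the
sheet is bent up to 40°.

A thin command-line wrapper covers the same chain:

```sh
exec/mmvital design-lens --freq 60e9 --n 37 --focal 0.150
exec/mmvital simulate --scenario bumpy --duration 300 --seed 7 --out cube
exec/mmvital process cube --k 4 --alpha 2000
exec/mmvital occupancy cube --fc 1.5 --sigma-th auto
```

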