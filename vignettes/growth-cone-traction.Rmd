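---
title: "Traction force dynamics of axonal growth cones with gctfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traction force dynamics of axonal growth cones with gctfm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gctfm)
```

# The problem

The growth cone of an advancing axon pulls on its substrate through a
fluctuating population of adhesion sites. On a soft polyacrylamide gel seeded
with fluorescent beads these pulls are observable: the beads move, the
displacement field can be inverted for the traction stress field, and the
stress field can be followed in time. `gctfm` implements this chain end to
end — traction reconstruction, stress-based growth-cone tracking, averaging
in the co-moving frame of the growth cone, stress-peak lifetime statistics,
and the fluctuation analysis of the axon tension — together with a
ground-truthed simulator of a migrating growth cone so every stage can be
validated without microscopy data.

# Traction reconstruction (FTTC)

The substrate is treated as an elastic half-space with Young's modulus
$E = 2G'(1+\nu)$ (shear storage modulus $G'$ from rheology, Poisson ratio
$\nu = 0.45$ for polyacrylamide). The surface displacement $\mathbf u$ is the
convolution of the surface traction $\mathbf t$ with the Boussinesq Green's
tensor; in the spatial-frequency domain the relation is the per-wavevector
product $\hat{\mathbf u}(\mathbf k) = \hat G(\mathbf k)\,\hat{\mathbf t}(\mathbf k)$ with

$$
\hat G(\mathbf k) = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix}
(1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y \\
-\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2
\end{pmatrix}.
$$

`forward_displacement()` multiplies by $\hat G$, `compute_traction()` inverts
the $2\times2$ tensor per wavevector, with an optional zeroth-order Tikhonov
term $\lambda$. Numerical conventions:

* **Zero padding.** Fields are zero-padded (default factor 2, rounded to a
  power of two) to suppress wrap-around of the long-ranged $1/r$ kernel.
* **Uniform mode.** The $\mathbf k = 0$ mode is set to zero in both
  directions: an absolute rigid translation of the substrate surface is
  unobservable after drift correction, and the half-space response to a net
  force has no finite mean. Consequently a reconstructed or forward-modeled
  field is defined up to an additive constant; comparisons with closed-form
  solutions align this mode first.
* **Regularization.** The default is $\lambda = 0$. The synthetic validation
  fields are noise-free, where the direct inverse is exact on the padded
  grid; for noisy experimental displacement fields a small $\lambda$ chosen
  by the L-curve (the corner of the residual-norm versus solution-norm
  trade-off) is the usual practice.
* **Accuracy.** A grid delta is band-limited by the grid's Nyquist frequency,
  so per-node agreement with the continuous point-force solution is limited
  by scale-free ringing near the force axis (a few percent); the azimuthally
  averaged radial profile of $|\mathbf u|$ agrees with the closed form to
  better than 2% beyond three grid spacings. The forward–inverse round trip
  is exact up to the cropped padding, so its error concentrates in a few
  boundary rows; interior relative RMS is well below 5%.

# From bead images to displacements

`project_stack()` median-filters each z-slice (3×3) and takes the pixelwise
maximum projection. `correct_drift()` measures the rigid shift of each frame
against the first frame in the four 1/5 × 1/5 corner regions (outside the
cell's reach) from the cross-correlation peak, and applies the componentwise
median of the four corner shifts — robust to one corner being disturbed.
Correlations are computed zero-padded (linear, not circular) and normalized
by the per-shift overlap area, which removes the bias toward zero shift that
raw correlation has at image edges; shifts are subpixel via parabolic
interpolation. `compute_reference_image()` takes the pixelwise temporal
median of the corrected series as the zero-stress bead configuration (a bead
displaced in fewer than half of the frames medians out to its rest
position). `measure_displacements()` then runs windowed cross-correlation on
a 0.75 µm grid (window 4× grid spacing, search radius one grid spacing by
default), refines peaks to subpixel, and smooths the scattered estimates
onto the grid with quality-weighted Gaussian interpolation (kernel 1.5× grid
spacing); low-texture windows are flagged and filled by their neighbors. The
window and kernel sizes are configuration, not measured constants: defaults
were chosen as the smallest windows that comfortably contain the search
radius and one bead spacing at the default bead density.

# Growth-cone localization and trajectory

For each traction map the stress noise is
$S_\mathrm{noise} = \mathrm{median}$ of the four corner-region maxima of
$|\mathbf t|$, and the detection threshold is
$S_\mathrm{threshold} = 3\,S_\mathrm{noise}$. The corner-region size reuses
the 1/5 × 1/5 drift-correction convention. All nodes at or above threshold
form the traction footprint; the growth-cone position is the area centroid
of the convex hull of the footprint (the polygon centroid, not the vertex
mean, which is robust to clustered vertices; fewer than three non-collinear
points fall back to the point mean). Thresholding is scale-equivariant, so
localization is insensitive to overall stress calibration.

Raw positions are smoothed by a centered moving average whose window is a
function of the frame interval, $W = \max(3, \mathrm{odd}(T_s/\Delta t))$
with $T_s = 360$ s by default — three points at the 120–180 s intervals of
the low-time-resolution acquisitions, 181 points at 2 s. $T_s$ is a
documented default, not a measured constant. Velocities are forward
differences $\mathbf v_n = (\mathbf r_{n+1}-\mathbf r_n)/\Delta t$. Steps
where $\mathbf v_n \cdot \mathbf v_{n+1} < 0$ (strictly) indicate stalling
or reversal; both steps involved are excluded from all downstream averages.
We read "those time points" as both frames of the offending pair — the more
conservative of the two possible readings.

# The co-moving average

`rotate_map_to_frame()` translates the grid so the centroid is the origin
and rotates by the angle that maps the velocity direction onto $(-1, 0)$,
rotating stress vectors by the same angle, then resamples onto a regular
grid at the original spacing by bilinear interpolation of the components.
Output nodes mapping outside the source grid carry *no* sample (they are
never zero-filled) and `average_frames()` accumulates per-node sums and
counts over valid frames only, so partially covered borders remain
unbiased. For a symmetric growth cone the average field shows the
characteristic structure: two strong maxima on the flanks pointing inward
toward the neck, and a net force parallel to the direction of travel whose
magnitude is the axon tension (sign convention: traction is the stress the
cell exerts on the substrate; the axon tension is equal and opposite to the
growth cone's net traction force; 1 Pa µm² = 1 pN).

# Stress peaks and lifetimes

`detect_peaks()` takes local maxima of $|\mathbf t|$ above the frame
threshold, suppresses any peak within `min_sep` (default 2 µm) of a stronger
one (ties broken toward the lower node index), and refines positions by 1D
quadratic interpolation. `link_peaks()` implements deterministic
nearest-neighbor association: a peak A in one frame links to peak B in the
next frame only if B is the closest detection to A and the distance is at
most the link distance (default 2 µm at $\Delta t = 2$ s, exposed as
configuration because "small enough" is not a measurable constant).
Candidate links are resolved in order of increasing distance and each B is
consumed at most once; unmatched detections start new tracks, and a missed
detection terminates a track (no gap closing — the association rule is
strictly frame-to-frame). A track with $k$ detections has lifetime
$(k-1)\Delta t$, so a single-frame appearance has lifetime 0 and falls in
the "very short" class that the histogram display omits (bins below 15 s
or above 600 s are hidden but retained internally).

`fit_exponential_lifetime()` fits a least-squares line to
(bin center, log count) over the 30–150 s window — the exponentially
decaying regime between the excess of very short-lived peaks and the
long-lived tail — and reports $\tau = -1/\mathrm{slope}$. For an exponential
law, binned log counts are exactly linear in the bin center, so the binning
itself introduces no bias. A maximum-likelihood fit of the window-truncated
exponential (`fit_exponential_lifetime_ml()`) is provided as a cross-check;
the two agree within sampling error on simulated draws. No censoring
correction is applied for tracks cut by the observation window: at 1800 s
capture length the correction for 30–150 s lifetimes is negligible.

# Tension fluctuations

The tension series is $F(t) = |\mathbf F_\mathrm{net}(t)|$ per frame. The
autocorrelation follows the standard normalized form

$$R(\tau) = \frac{\langle (F(t)-\mu)(F(t+\tau)-\mu) \rangle}{\sigma^2},$$

averaged over all available pairs at each lag (lags are integer multiples of
$\Delta t$, up to 480 s), with $\mu$ and $\sigma$ the series mean and
standard deviation (denominator $n$, so $R(0) = 1$ exactly). Negative values
are legitimate and reported; only the log-linear decay fit over 10–80 s
excludes them. The MSD is
$\mathrm{MSD}(\tau) = \langle (F(t+\tau)-F(t))^2 \rangle$ for lags up to
900 s but never beyond half the series duration, normalized by $\mu^2$. With
that normalization the saturation level of a bounded stationary series is
$2\sigma^2/\mu^2$, which exceeds unity exactly when the fluctuations are
large relative to the mean tension — making the normalization dimensionally
coherent with the observation that saturation can occur above one. The
$\sigma^2$ normalization of the autocorrelation is taken as definitive; no
second normalization is applied to $R$. The two estimators are linked by
$\mathrm{MSD}(\tau)/(2\sigma^2) + R(\tau) \approx 1$ for weakly stationary
series, which the tests verify on simulations. The power-law exponent is the
log–log least-squares slope of the MSD over 2–200 s.

**Finite observation length matters here.** For a mean-reverting process
with correlation time $\tau_c = 95$ s observed for 1800 s (about 19
correlation times), the sample autocorrelation centered on the sample mean
is biased downward by roughly $(1 + 2\sum_k \rho_k)/n \approx 0.11$, and the
log-linear fit over 10–80 s consequently *underestimates* the correlation
time by 20–30% (median over many realizations ≈ 70–80 s). This is a
property of the estimator at this series length, not an implementation
error: the identical code recovers $\tau_c$ to a few percent on series 100×
longer, and recovers an exactly exponential $R$ to machine precision. The
practical implication runs the other way too: a decay time fitted from an
1800-s recording understates the true correlation time of the underlying
process.

# The synthetic growth cone

`simulate_traction_series()` emulates the regime the analysis targets: a
growth cone advancing at constant heading whose traction field is a
superposition of (i) contractile stress foci born on its flanks by a Poisson
process, living for exponentially distributed times, pointing inward toward
the neck and riding along with the growth cone; (ii) a neck patch carrying
the prescribed axon tension rearward; and (iii) i.i.d. Gaussian observation
noise. The residual of the areal force balance (focus imbalance plus noise
mean) is removed as a uniform offset each frame, so the net traction force
of every frame equals the prescribed tension vector *exactly* — the ground
truth is a construction identity, which is what makes the recovery tests
sharp. Defaults (all configurable):

| parameter | default | rationale |
|---|---|---|
| field size / grid | 72 µm / 0.75 µm | trajectory plus stress structures stay inside the field for a 2 h capture; grid matches the displacement-detection grid |
| frame interval, frames | 120 s, 60 | the low-time-resolution acquisition regime (1–2 h at 1–5 min); high-resolution runs use 1–2 s |
| speed | 0.006 µm/s (~22 µm/h) | mid-range of steadily advancing DRG growth cones |
| focus birth rate, lifetime | 0.15 /s, 38 s | ~6 active foci on average; the lifetime scale of stress peaks |
| focus peak stress, width | 60 Pa, 1.5 µm | tens of Pa peaks on 150–400 Pa substrates, micron-scale foci |
| flank geometry | anchors at (1.5, ±3.5) µm, scatter 1 µm; neck 3.5 µm behind, width 2 µm | the apparent geometry of the average stress field at the ~5 µm scale |
| tension | mean 2 nN, sd 0.6 nN, mean-reverting with τ = 95 s | nN-scale DRG neurite tension; the measured fluctuation timescale |
| observation noise | 2 Pa per component | sets corner-noise thresholds ~20 Pa, well below the foci |

The mean-reverting (Ornstein–Uhlenbeck) tension uses the exact
discretization with a stationary start; a fractional-noise mode
(`tension_model = "fgn"`, Hurst exponent H, exact Cholesky-factorized
covariance) generates tension whose theoretical MSD exponent is $2H$, used
to validate the anomalous-exponent fit ($H = 3/14$ gives exponent $3/7$).
The tension magnitude is floored at zero; at the default mean/sd ratio the
floor is hit with probability ~$4\times10^{-4}$ and does not distort the
statistics. `render_bead_images()` forward-models the imaging: uniformly
scattered beads advected by the interpolated displacement field, Gaussian
spots, additive noise, plus the true zero-stress reference frame.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: filopodial protrusion and retrograde flow,
stress-fiber anisotropy of foci (foci are isotropic Gaussians with a single
orientation), growth-cone turning and pausing, focus maturation (amplitude
is constant over a focus's life), 3D gel mechanics and finite gel thickness,
and spatially correlated measurement noise. Recovery results on synthetic
data bound the algorithmic error of the pipeline, not the biological or
optical variability of an experiment.

# Degenerate inputs and tie-breaks

Uniform maps produce an empty suprathreshold set and an invalid frame;
frames without valid velocity (stalled or at the series end) are excluded
from the co-moving average; zero-velocity rotation is an error by contract
(stall filtering must run first). Equal-height detection ties break toward
the lower node index; linking ties resolve by distance, then track id. The
log fits require at least three usable points and flag non-decaying inputs
invalid rather than returning a negative decay time.

# Problem sizes in the test suite

The suite simulates 60-frame low-resolution series on a 96×96-node grid for
localization and averaging, a 900-frame high-resolution series for track
recovery, 5000-draw lifetime samples, 20×900-sample tension series for the
stochastic recovery checks (and 3×10⁵-sample series for the long-series
estimator check), and 64×64 traction grids with padding factors 4–16 for the
elastic-theory comparisons. These sizes hold the full suite to a few minutes
on one CPU while keeping every stochastic tolerance at least several
standard errors wide.
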