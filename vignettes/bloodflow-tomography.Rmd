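---
title: "Electromagnetic blood-flow tomography: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electromagnetic blood-flow tomography: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement physics

Blood is a conductor. When it flows axially (along $+z$) through a static
magnetic field $B$ applied along $+x$, the Lorentz force polarizes the moving
charges and a potential field builds up in the surrounding tissue. With
Ohm's law $J = \sigma(E + v \times B)$, charge conservation
$\nabla\!\cdot\!J = 0$ and $E = -\nabla u$, the potential obeys

$$\nabla\!\cdot\!(\sigma \nabla u) \;=\; \nabla\!\cdot\!(\sigma\, v \times B),$$

with the zero-flux condition $J\cdot n = 0$ on the skin. For $B = B\hat{x}$
and $v = v\hat{z}$ the impressed field $v \times B$ points along $+y$ with
magnitude $vB$. Twelve electrodes sit on the skin; e0 is the grounded
reference and e1–e11 measure potential differences $U_k = u(e_k) - u(e_0)$.

`solveFlowPotential()` discretizes this equation with a cell-centred
5-point finite-difference scheme. Face conductivities are harmonic means of
the two adjacent cells, so current is conserved exactly across tissue
jumps, and faces into non-conducting cells (air outside the neck, the
tracheal and esophageal lumina, which carry $\sigma = 0$) simply vanish,
which realizes the insulating boundary without special casing. The
operator is factorized once per conductivity map (sparse Cholesky) and
re-used across all time samples and reciprocal solves. The potential is
gauged by pinning $u(e_0) = 0$. A manufactured-solution test
($u^* = \cos\pi x \cos\pi y$ with its matching impressed field) confirms
second-order convergence.

Because the equation is linear in $B$ (and in any global velocity scale),
the dataset generator solves once per flow state at unit field strength
and scales the voltages to each requested $B$ — exactly equivalent to
solving per $B$, and verified to $10^{-6}$ relative by the linearity test.

## The weight matrix

The reciprocity theorem converts the forward map into an explicit linear
sensitivity: driving unit current through electrode pair $(e_k, e_0)$
yields the reciprocal current density $J_A^{(k)}$, and

$$U_k \;=\; \sum_{i=1}^n \big(J_A^{(k)}(x_i,y_i) \times B\big)_z\, v_i\, S_i
 \;=\; (Wv)_k,$$

with one row per measuring electrode and one column per reconstruction
unit ($S_i$ = cell area). With $B$ along $+x$ the integrand reduces to
$-J_{Ay} B$, fixing the sign convention of `assembleWeightMatrix()`.

A numerical subtlety: evaluating $J_{Ay}$ by central differences of the
reciprocal potential is badly behaved across the artery/muscle
conductivity jump (the tangential gradient is discontinuous). The package
instead averages the two *face* current densities per direction — the
same harmonic-face fluxes the operator itself uses. With that choice $W$
is the exact discrete adjoint of the flow solve, and the reciprocity check
$\lVert Wv - U_{\mathrm{PDE}}\rVert / \lVert U_{\mathrm{PDE}}\rVert$ sits
at rounding level on a matched stenosis-free phantom (the acceptance test
grants 5%).

The inverse problem is deliberately mismatched, mirroring the study
design: measurements come from the full heterogeneous PDE on the stenosed
phantom, while $W$ always comes from the stenosis-free phantom at 0.10 T.

## The phantom and its flows

The published neck cross-section was digitized from anatomical fascia
coordinates that are not available, so `buildPhantom()` rasterizes a
parametric stand-in: an elliptical neck with annular skin (2 mm) and fat
(4.5 mm) layers over muscle, disc organs (trachea, esophagus, cervical
spine, two glands) and disc vessels, every placement configurable as a
fraction of the domain. Conductivities are the standard literature values
(skin 0.005, fat 0.1, muscle 0.2, spine 0.001, glands 0.6, trachea and
esophagus 0, artery and vein 1.12 S/m). The blood area stays below 10% of
the cross-section at every preset, and the square ROI window of $n$
reconstruction units (51×51 = 2601 at full scale) contains both vessels.
Electrodes sit on the outermost conducting cell along 12 rays at 30°
spacing; the reference angle defaults to $-90^\circ$ (posterior) and is
configurable, since only a drawing of the electrode layout exists.

**Stenosis.** A fraction `rate` ∈ {0, 0.1, …, 0.9} of the artery cells is
occluded by a half-plane sweep along $+x$ or $-y$; ties at equal
coordinate break by ascending linear cell index, which makes masks nested
across rates and bit-reproducible. Stenosed cells carry zero velocity.
Whether they should also be removed from the conduction model is genuinely
ambiguous in the source description ("removing a portion of the artery"
vs. "velocity … set to 0"); the package defaults to velocity-only
(`stenosisAltersConductivity = FALSE`) and exposes the flag.

**Waveform.** The carotid pulse is modelled as a clipped two-harmonic
$w(t) = v_{\max}\max(0, a_0 + a_1\sin 2\pi t/T + a_2\sin(4\pi t/T+\phi))/\text{peak}$
with $a_0 = 0.8$, $a_1 = 0.55$, $a_2 = 0.25$, $\phi = \pi/4$, normalized
so the systolic peak equals $v_{\max} = 1$ m/s at $t \approx 0.13T$,
with a near-zero end-diastolic dip — a plausible carotid envelope, not a
fit to any published trace; substitute coefficients via `flowConfig()` if
you have one. The vein flows steadily at 0.08 m/s in $-z$.

**Stenosis speed-up.** The residual lumen accelerates. The reference study
read coefficients off an unpublished CFD model; the package defaults to
flux continuity $c(r) = 1/(1-r)$ (capped at 10) and accepts a
rate→coefficient override table, which is where CFD-derived values would
plug in. Continuity is exact for a 1D two-segment pipe and an
overestimate for real recirculating flow — a documented approximation.

**The factorial design.** One period $T = 0.85$ s sampled every 0.01 s
with inclusive endpoints gives 86 instants (the published sample total
8170 = 5 × 19 × 86 forces the inclusive reading); 5 field strengths
0.02–0.10 T; 19 stenosis configurations (rate 0 once, 9 positive rates ×
2 directions). The 80/20 split (6536/1634) is uniform random under a
recorded seed, and all randomness in the package flows from one master
seed through named substreams.

## The reconstruction chain

**CAE.** The 11×2601 weight matrix is z-scored (single mean/sd over all
entries — "standardized" is otherwise unspecified) and compressed by a
three-block convolutional encoder (conv–conv–maxpool, tanh, 1×l valid
kernels, stride 1 throughout — the published output sizes force stride 1
even for pooling) into the 11×11×60 feature tensor $W'$. The mirrored
decoder (bilinear upsample + deconvolutions; the two deconvolutions
undoing the exact-halving convolutions run at stride 2 with same padding,
the rest at stride 1 valid) reconstructs the input under the MAE loss,
$\mathrm{Loss} = \tfrac1n\sum_i |W_i - \hat W_i|$, with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; only the
learning rate was published). "Iterations" are full passes over the single
matrix. The decoder is kept after training solely as a reconstruction
diagnostic.

**Domain transformation.** Each of the $p$ channels of $W'$ is an 11×11
sub-matrix $W_{\mathrm{sub}}$; the voltages map into velocity-domain
features by $v_{\mathrm{sub}} = W_{\mathrm{sub}}^{-1} U$, stacked into the
11×p matrix $v'$. An ideal encoder never emits a singular channel, but a
learned one can come close, so `invertSubfeatures()` gates on the
condition number (default $10^8$) and falls back to the Moore–Penrose
pseudo-inverse, flagging the channel in its report — a robustness
extension beyond the source semantics.

**CNN.** $v'$ is normalized per feature (z-score across training samples,
sd floored at $10^{-12}$) and mapped to the $n$ velocity labels (kept in
m/s; label z-scoring exists as an option but defaults off) by three
conv+BN+activation+maxpool blocks (sigmoid, sigmoid, relu; filters 6, 12,
24), a flatten (1584 at full scale), a relu dense layer of $n$ units,
dropout 0.5, and a linear dense readout. Batch-norm statistics freeze at
inference (standard practice; the source is silent). The BP baseline is a
single-hidden-layer perceptron on the 11 voltages (hidden width 512 by
default — a package choice, the baseline's architecture was never
specified), and the plain-CNN baseline feeds the voltages directly into
the same CNN block pattern.

**Initialization.** Fan-based uniform (Glorot) everywhere except the final
linear readout, which starts at exactly zero. The zero readout matters:
with the MAE loss and labels that are zero on the large majority of units,
a randomly initialized readout biases early predictions positive (relu
activations are nonnegative), and the resulting sign gradients push the
whole relu dense layer into the dead regime, collapsing the network to a
constant output. A tanh control confirms the architecture itself is fine;
the zero-initialized readout removes the asymmetry while keeping the
published layer stack intact.

**Tikhonov baseline.** $\hat v = (W^\top W + \lambda I)^{-1} W^\top U$,
computed through the push-through identity
$\hat v = W^\top (WW^\top + \lambda I)^{-1} U$ (exact, and an 11×11 solve
instead of $n\times n$). $\lambda = 0$ with rank-deficient $W$ falls back
to the SVD pseudo-inverse and is flagged. No regularization weight was
published, so $\lambda$ is chosen on a seeded logarithmic grid (scaled by
$\mathrm{tr}(WW^\top)/m$) minimizing mean RMSE on a held-out quarter of
the training split.

**Metrics.** Per-sample RMSE and Pearson correlation, averaged over a
seeded evaluation subset (half the test split). The printed correlation
formula in the source mixes $\bar v$ into the $\hat v$ deviation — an
apparent typographical slip; standard Pearson is implemented. Constant
vectors have no defined correlation: the function warns and returns NaN.
Noise tests add white Gaussian noise per sample at
$\sigma = \mathrm{RMS}(U)\cdot 10^{-\mathrm{SNR}/20}$; all methods see the
same noisy voltages at a given SNR.

## What the desk-scale benchmark does and does not show

The published headline averages (RMSE 0.0333, CC 0.9721 over 817 test
samples) depend on the unpublished neck geometry and a 12.7 h training
run, so they are not reproducible here and the package does not try.
`runSmallBenchmark()` instead fixes a scaled study — 48×48 grid, 21×21 ROI
(441 units), one field strength (0.10 T), all 19 stenosis configurations,
10 time samples (190 samples, 152/38 split), p = 12 CAE channels, 500
optimizer steps per network at learning rate $10^{-3}$ full batch, BP
hidden width 128 — and grades the *structure* of the result: the CAE-CNN
chain must beat the tuned Tikhonov baseline on both mean RMSE and mean CC
noiselessly, every method must degrade monotonically from 60 dB to 20 dB,
and CAE-CNN must stay ranked above Tikhonov at 20 dB. Those are the
qualitative claims of the study, and they are what passing tests certify.
(The benchmark also reproduces a finer observation: the domain
transformation amplifies measurement noise, so the CAE chain degrades
faster than the plain CNN at low SNR while still dominating the linear
baseline.)

The non-paper network sizes come from a width planner that interpolates
the intermediate widths geometrically, keeps the block pattern, makes the
last two encoder convolutions exact halvings (so the mirrored stride-2
deconvolutions undo them), and lands the final pool on width $m$; the
reference sizes (n = 2601, p = 60) are emitted verbatim and every
published output-size cell is asserted by tests.

## Known limitations

* The phantom is a 2D parametric stand-in: no patient geometry, no 3D
  return currents, point electrodes (no contact impedance), static fields
  only.
* The stenosis speed-up is flux continuity, not CFD; real post-stenotic
  recirculation is not represented, and the velocity profile across the
  lumen is flat.
* Synthetic data cannot expose the method to bio-potential interference
  (ECG-band signals), electrode placement error, or inter-subject
  anatomical variation — a model that passes here is validated against
  the simulation physics, not against clinical measurements.
* At desk scale the networks are small and the sample manifold is low
  dimensional (19 stenosis patterns × a scalar waveform amplitude), so
  the benchmark measures ranking behaviour, not clinical accuracy.
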