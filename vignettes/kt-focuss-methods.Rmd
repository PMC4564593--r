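---
title: "Compressed-sensing reconstruction and evaluation for non-EPI fMRI: methods"
author: "ktfmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-sensing reconstruction and evaluation for non-EPI fMRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktfmri)
```

## The problem

Steady-state sequences such as balanced SSFP (bSSFP) and spoiled gradient
echo (GRE) are attractive for functional MRI at high field because they avoid
the distortion of echo-planar readouts, but they acquire one phase-encode
(PE) line per TR and are therefore slow. Compressed sensing offers a way to
recover the lost temporal resolution: sample only a fraction of the PE lines
of each time frame (incoherently across frames) and reconstruct the dynamic
series by exploiting its sparsity in a temporal transform domain.

`ktfmri` implements a complete retrospective test bed for this idea:

1. a synthetic generator of phase-cycled bSSFP / GRE 2D+time data with a
   block-design activation (`make_phantom()`, `simulate_timeseries()`,
   `to_kspace()`),
2. the k-t undersampling mask family (`gen_uniform()`, `gen_gaussian()`,
   `gen_mixture()`, `gen_mixture_center1()`, `gen_center_only()`,
   `gen_pairwise()`),
3. k-t FOCUSS reconstruction with temporal Fourier and Karhunen-Loève
   sparsifying transforms (`ktfocuss()`, `reconstruct_series()`),
4. activation statistics and fidelity metrics (`tscore_map()`,
   `threshold_and_cluster()`, `roc_curve()`, `frame_nmse()`,
   `average_mse()`), and
5. an experiment driver tying the stages together (`run_experiment()`).

## Data model and conventions

A dynamic acquisition is a complex array $U = [u_1, \dots, u_T]$ of
$N_{RO} \times N_{PE}$ frames. k-space uses the centred index grid
$k_y \in \{-(N_{PE}/2 - 1), \dots, N_{PE}/2\}$ with DC stored at row
$N_{PE}/2$ (for $N_{PE} = 192$ this is the PE index range $-95..96$); all
DFTs are unitary so Parseval's identity holds exactly between domains. The
default desk-scale matrix is $64 \times 48$, the same 4:3 ratio as the
$256 \times 192$ acquisition it stands in for, with $N_{PE}$ divisible by 12
as the mixture patterns require.

## The synthetic generator

The phantom is an ellipse with a cortical rim; proton density is expressed
in arbitrary units with peak 1000, the magnitude scale of raw scanner data.
This scale matters: the reconstruction's regularization factors (0.1 and
0.01) are absolute quantities, and they behave as intended — small relative
to the transform-domain coefficients — only when the data carry a realistic
raw-data scale. The relaxation maps (T1 ≈ 1750–1900 ms, T2 ≈ 38–48 ms) are
typical of rodent brain at high field with TR/TE = 10/5 ms (bSSFP, flip 16°)
and 20/10 ms (GRE, flip 8°).

Signal models: GRE uses the Ernst steady state with $e^{-TE/T_2}$ decay
(T2 standing in for T2*; a simplification, noted) and off-resonance phase at
TE. bSSFP uses the standard steady-state profile as a function of the per-TR
precession angle $\beta = 2\pi \Delta f\, TR + \theta_{pc}$, refocused to
TE = TR/2, which produces the characteristic pass-band/stop-band (banding)
structure: an on-resonance pixel is bright at 180° phase-cycling and dark at
0°.

Two activation foci are placed in the rim at off-resonance values 0 and
60 Hz — more than $1/(2TR) = 50$ Hz apart — so different phase-cycling
angles weight the two foci differently: the stimulus-minus-baseline
difference map peaks at different foci for different angles. This reproduces
the spatially heterogeneous, angle-dependent activation patterns seen in
phase-cycled high-field data, and is the feature the pattern-comparison
experiments must preserve.

The BOLD response is a multiplicative amplitude change (peak 6%, Gaussian
profile within each focus) applied during the stimulation block of a
16/8/24 pre/stim/post paradigm (halved to 8/4/12 for GRE). This is a
deliberate simplification — no T2/T2* mechanism, no hemodynamic lag beyond
an optional 1-frame linear onset/offset ramp (`ramp = TRUE`), no
physiological noise, motion, or coil structure — sufficient for detection
statistics, and the paradigm-block t-test does not use response shape.
Measurement noise is additive complex Gaussian in k-space with per-channel
standard deviation set from a target baseline-image SNR
(`noise_sd_for_snr()`); the default experiment SNR of 50 emulates the
averaged acquisitions such protocols analyse (15–25 repetitions), while
SNR ≈ 20 emulates a single run. Consequences of these simplifications:
passing tests show that the pipeline orders sampling strategies and
transforms correctly under Gaussian noise and a rectangular response; they
do not certify behaviour under physiological confounds or motion.

## Undersampling masks

Every mask samples exactly $N_{PE}/D$ distinct PE lines per frame
($D = 4$ throughout the emulated protocol):

* **R** — uniform random lines, independent frames;
* **G** — lines drawn from the centre-weighted Gaussian density
  $P(k_y) \propto e^{-k_y^2 / 2\sigma^2}$, $\sigma = N_{PE}/9$, renormalized
  on the discrete grid;
* **GR** — $N_{PE}/6$ Gaussian-drawn lines plus $N_{PE}/12$ uniform lines
  from the remainder (a 2:1 mixture; for per-frame counts not divisible by
  3 the Gaussian share is rounded up);
* **GRC1** — as GR but with the DC line guaranteed in every frame, the
  remaining $N_{PE}/D - 1$ lines split 2:1;
* **CENTER_ONLY** — the deterministic contiguous central block, the
  non-CS low-frequency control (reconstructed by zero filling, not by
  k-t FOCUSS, mirroring its role as a control);
* **GRC1_PAIRED** — adjacent-index line pairs (0-based rows $(2m, 2m+1)$,
  the pair containing DC always sampled) drawn with GRC1-style weights
  summed within pairs, for eddy-current suppression in bSSFP.

Without-replacement weighted draws use randomized systematic
probability-proportional-to-size selection (random line order, systematic
thresholds), whose per-line inclusion probability is *exactly*
$n \cdot p_i$ whenever $n \max_i p_i \le 1$ (true for all shipped patterns
at $D = 4$). The common alternative — sequential draws with renormalization
— biases inclusion probabilities by several percent near the density peak at
these sampling fractions, which would make the empirical line frequencies
systematically miss the nominal density; exactness of the marginals is the
property the density-convergence checks rely on. If a caller supplies a
density too concentrated for exact marginals, the generator falls back to
sequential renormalized draws rather than failing.

## k-t FOCUSS reconstruction

With the readout axis fully sampled, one inverse DFT along readout
decouples the problem; each reconstruction then solves, per readout
position, for the transform-domain coefficient stack $x$ linked to the
sampled data $y$ by

$$ y = M\, F_{PE}\, \Phi^H x $$

where $\Phi$ is a unitary temporal transform (DFT, or the data-driven KLT),
$F_{PE}$ the unitary spatial DFT along PE, and $M$ the mask. FOCUSS
(FOCal Underdetermined System Solver) promotes sparsity of $x$ by iterative
reweighting: with $W = |x^{(k-1)}|^{p}$ (elementwise, floored at
$10^{-12} \max |x|$ to avoid permanent zero-locking), each outer iteration
solves

$$ (W A^H A W + \lambda I)\, q = W A^H y, \qquad x^{(k)} = W \odot q $$

by `n_cg` conjugate-gradient iterations and defaults $p = 0.5$ (whose fixed
points match the minimum-$\ell_1$ solution), $\lambda = 0.1$ (FT) or
$0.01$ (KLT), `n_cg = 30`. Numerical choices worth recording:

* **CG starts at zero** each outer iteration. From the origin the CG
  iterate norm is nondecreasing while the quadratic objective decreases, so
  the recorded data residual $\|y - A W q\|^2$ is provably nonincreasing
  within every inner solve — the convergence diagnostic
  (`residual_trace`) users should expect to see flatten well before 30
  iterations. A warm start at the previous iterate would begin at a
  data-consistent point and the residual would *rise* toward the
  regularized optimum, which makes the diagnostic unreadable.
* **Fully determined case.** With a full mask and $\lambda = 0$ the
  operator is square and unitary, so the unique least-squares solution is
  $x = A^H y$ for any weighting; it is computed directly (no iteration),
  making the full-sampling reconstruction exact to machine precision.
* **Initialization** is the adjoint (zero-filled) reconstruction
  transformed to the sparse domain — deterministic and standard.
* **Early exit** when the CG gradient norm falls below $10^{-12}$.
* **Stopping rule.** With `n_foc = "auto"` the outer loop stops at the
  first $k$ with $\|\hat U^{(k)} - \hat U^{(k-1)}\|_F / \|\hat U^{(k)}\|_F
  < 0.1$, counting the zero-filled initialization as $\hat U^{(0)}$; a hard
  cap (20) returns a `converged = FALSE` flag rather than an error.
  `select_nfoc_cv()` wraps this in subject-based leave-one-out selection
  with a mode consensus (ties toward the smaller count).
* **Convergence speed caveat.** With $p = 0.5$ the reweighted iteration
  contracts spurious (aliased) transform components only *linearly*, at a
  rate set by the sampling geometry. On adversarial 1D instances —
  near-regular sample sets that alias a sparse spectrum onto a competing
  support — reaching $10^{-3}$ coefficient accuracy can take hundreds of
  reweightings even though the iteration provably heads to the
  $\ell_1$ vertex. The package's sparse-recovery tests therefore verify
  $\ell_1$-oracle equivalence at convergence; fixed small reweighting
  budgets (the 3–5 selected by the stopping rule) should be read as "good
  reconstruction", not "exact $\ell_1$ optimum".

The KLT variant estimates the temporal covariance $C = \hat U^H \hat U$
from a 2-iteration preliminary Fourier reconstruction; the eigenvectors of
$C$ (descending eigenvalues) form $\Phi$, updated once (`n_klt = 1`).

## Statistics and evaluation

Activation maps use the Welch (unequal-variance) statistic per pixel on
magnitude images, baseline block vs stimulation block (optionally shifted
by a hemodynamic delay, default 0), with Welch–Satterthwaite degrees of
freedom. The statistic is computed as baseline minus activation, so
activated pixels carry negative scores; all thresholding is two-sided on
$|T|$ at significance 0.05, followed by removal of 4-connected clusters
smaller than 6 pixels. Pixels with zero variance in both blocks receive a
signed sentinel ($\pm 10^6$) and a flag rather than NaN. The ROI for
time-course comparison is the active mask of the fully sampled data, defined
per dataset.

Fidelity metrics: frame-wise normalized MSE
$\|u_t - \hat u_t\|^2 / \|u_t\|^2$ and the average MSE
$\sum_t \|u_t - \hat u_t\|^2 / (TN)$, both against the *acquired* fully
sampled data (noise included), as a reconstruction of undersampled data
cannot and should not reproduce unobserved noise.

Detection performance is an ROC sweep of the two-sided $|T|$ threshold over
pooled score quantiles (200 by default) plus the class-boundary operating
points (so a perfectly separating reconstruction attains AUC exactly 1),
anchored at (0,0) and (1,1), with trapezoidal AUC. Ground truth is the
thresholded map of the fully sampled data. AUC is invariant under monotone
transforms of the scores and is cross-checked against the rank-statistic
estimate in the test suite.

## The experiment driver

`run_experiment()` simulates each subject × contrast (four bSSFP
phase-cycling angles and GRE by default), acquires noisy full k-space,
derives the ground-truth map and ROI, then reconstructs and evaluates every
pattern × transform cell; `compare_patterns()` aggregates and flags whether
the expected qualitative ordering holds (on AUC, GRC1 ≥ GR ≥ G > R for CS
patterns; on NMSE, every Gaussian-weighted pattern below the centre-block
control), reporting violations rather than hiding them. All child seeds
derive deterministically from the master seed; artifact directories get a
hashed manifest.

Problem sizes used throughout the package's own experiments: $64 \times 48$
matrix, 48 (bSSFP) or 24 (GRE) frames, 1–3 synthetic subjects — chosen so a
complete pattern-comparison study runs in minutes on a laptop while keeping
$N_{PE}/D$, the mixture splits and the paradigm structure of the emulated
protocol intact.

## Known limitations

* The generator omits physiological noise, motion, multi-coil reception and
  3D effects; orderings measured here may compress or reorder on real data.
* The BOLD model is a multiplicative amplitude change, not a relaxation
  change.
* The t-test contrasts blocks; event-related designs would need a GLM,
  which is out of scope.
* FOCUSS fixed small-budget runs approximate, but do not exactly attain,
  the $\ell_1$ solution (see the convergence caveat above).
* The centre-block control is deliberately reconstructed by zero filling;
  running it through k-t FOCUSS would measure a different (and less
  standard) control.
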