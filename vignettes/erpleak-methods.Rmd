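---
title: "Evaluating ERP side-channel leakage: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ERP side-channel leakage: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`erpleak` treats an EEG recording the way a hardware security lab treats
the power trace of a chip: as a noisy side channel from which a secret —
here, which of six displayed 4-digit codes is the user's real PIN — may
be partially recoverable. This vignette explains the statistical
machinery, the synthetic data generator that stands in for human
recordings, and the design decisions taken where the problem left
genuine freedom.

## The experiment being modeled

One *session* is 6 codes × 150 presentations = 900 one-second epochs at
1000 Hz on 32 scalp channels (10-10 montage) plus two EOG channels, with
a stimulus onset asynchrony of 1.009 s and the constraint that two
presentations of the same code are always separated by at least two
other codes. Tag 1 marks the real PIN. Familiar stimuli evoke an extra
late positive ERP component (P300-like, 300–600 ms) over parietal
electrodes; random codes do not. The evaluation is deliberately binary —
real versus random (`p ∈ {0, 1}`) — rather than six-way: a user has no
reason to treat different random codes differently, and a binary model
is what scales to realistic attacks where profiling all 10,000 possible
PINs is infeasible.

## Pipeline and estimators

**Preprocessing.** Epochs are bandpassed 0.5–30 Hz (slow-drift removal
below, muscle/line-noise removal above). The filter is the squared
magnitude response of a 4th-order Butterworth high-pass/low-pass pair —
i.e. exactly the steady-state response of forward–backward (zero-phase)
filtering — applied in the frequency domain on a mirror-extended epoch.
This realization was chosen over a time-domain `filtfilt` because a
transfer-function Butterworth at a normalized cutoff of 0.001
(0.5 Hz at 1000 Hz) is numerically ill-conditioned: in testing it left a
0.67 µV DC residual on a 10 µV constant and reached only −21 dB at
50 Hz, while the frequency-domain form is exactly linear, exactly
zero-phase (ERP latencies are preserved), nulls DC identically, and
attenuates 50 Hz by ~36 dB. The mirror extension makes the implicit
periodic signal continuous; epochs must be at least three filter time
constants long (`3·fs/(2π·lo)` samples), which the 1 s epoch satisfies.
Epochs whose EOG peak-to-peak exceeds 100 µV (a standard blink
criterion; the generator's blinks are 175–325 µV) are rejected.
Observation vectors are the concatenated selected electrodes — P7 and P8
by default, configurable since the informative parietal set varies
between individuals.

**Dimensionality reduction.** Two PCA variants. The *average PCA*
diagonalizes the covariance of the six per-tag mean traces; with six
rows at most five eigenvectors have nonzero eigenvalue, so attacks are
at most five-dimensional. It uses only public tag labels, never the
real/random split, so it is legitimate in a non-profiled attack. The
*raw PCA* diagonalizes the covariance of the raw epoch vectors; it
scales to many codes but extracts the discriminant directions less
directly. Both default to five dimensions. Eigenvector signs follow a
deterministic convention (largest-magnitude coefficient positive);
centering is the basis's own center (grand mean of tag means,
respectively of epochs — global, not per-electrode).

**Density models.** After PCA the score dimensions are orthogonal and
are modeled as independent, reducing one 5-variate estimation problem to
five univariate ones per class. Backends: Gaussian templates, or
Gaussian-kernel KDE with the robust Silverman rule
`h = 0.9·min(sd, IQR/1.34)·n^(−1/5)` (sample sd with `n−1`, quartiles by
linear interpolation; if the IQR degenerates to zero the sd is used).
KDE is the default: it converges more slowly but assumes nothing about
the shape of the score distributions. Per-dimension log2 densities are
floored at −1000 before summing so a single extreme outlier cannot make
the PI infinite.

**Perceived information.** The central metric,

$$\mathrm{PI}(P;O) = \mathrm{H}[P] + \sum_p \Pr[p]\,
  \mathbb{E}_{o|p}\, \log_2 \hat{\Pr}_{\mathrm{model}}[p|o],$$

is estimated by cross-validation: fit the class densities on each
profiling set, evaluate the log2 posterior of the true class on the
held-out observations. The default is leave-one-out — with only ~900
observations per session the evaluation can afford the ~900 model fits,
and every observation then contributes one log term. Rather than
averaging per-fold PI values (ill-defined for single-observation test
sets: the per-fold class count $n_p^j$ is zero for one class), all
per-observation log terms are pooled and weighted once by the empirical
class priors (1/6, 5/6); for equal-size folds this is algebraically
identical to fold averaging.

Two prior conventions coexist deliberately. Inside the PI's logarithm
the Bayes inversion uses the **empirical** priors: only then does PI
equal the mutual information for a perfect model, vanish for an
uninformative one, and match the magnitudes that make PI interpretable
(this is what `estimate_pi` defaults to). The **attack decision
metrics**, by contrast, classify with uniform-prior (maximum-likelihood)
posteriors: a 5/6 prior toward "random" inflates false negatives on the
real PIN, which is exactly what an enumerating adversary must avoid.
Both are switchable via `prior_mode`.

**Outlier clipping.** Raw-PCA pipelines clip per-observation posteriors
below 0.001 up to that floor, without renormalizing, before the log —
bounding the weight any outlier contributes to the PI sum. Average-PCA
pipelines do not clip (their targeted single dimension rarely produces
outliers). Clipping is applied to per-observation posteriors first;
attack products over `q` observations are formed afterwards.

**Confidence.** A percentile bootstrap on the per-observation log terms:
100 resamples drawn with replacement *within class* (preserving the
class weighting), the PI functional recomputed on each, and the 5th and
95th percentiles reported. The same seed machinery drives every
stochastic stage (`derive_seed` expands one master seed into independent
per-stage streams), so a run's outputs are reproducible bit for bit.

**Security metrics.** The per-tag success rate draws `q` observations of
one tag without replacement, multiplies their class posteriors, and
scores a success when the true class's product wins; the average rank
scores all six tags by their product of *real-PIN* posteriors only and
records the real PIN's position (ties averaged — a measure-zero event
under continuous densities). Both resample (default `R = 1000` draws)
because a single pass at large `q` would give one Bernoulli trial.

## Attack drivers

*Profiled*: the full pipeline with leave-one-out CV, plus a
PI-versus-profiling-set-size learning curve (stratified subsets, PI
evaluated on the held-out remainder). *Non-profiled*: the PI computed
six times, each time assuming a different tag to be the real one, models
estimated on the fly with leave-one-out CV inside the attack set; the
assumed tag with maximal PI wins. Its dimensionality reduction is the
average PCA recomputed from the attack subset — tags are public, so this
stays unsupervised. With the true tag assumed, the non-profiled estimate
*is* the profiled estimate (asserted as a test invariant).
*Portability*: basis and model of user A applied to user B's
observations, PI on B's labels; `all_against_one` pools the seven other
users' observations into a single foreign model. *Identification*: the
same machinery with the user variable U in place of P, restricted to
real-PIN epochs, multi-class over users.

One leakage subtlety: the per-user mean traces that feed the
identification basis are label-dependent (unlike the per-tag means of
PIN mode, which use public tags). Computing that basis from the full
dataset lets the held-out epochs' identities leak into the
dimensionality reduction, and in testing made two *literally identical*
users separable through finite-sample noise means alone (partial PI
≈ 0.3–0.45 bits of pure artifact). `identify_user` therefore re-estimates
the basis inside every cross-validation fold from profiling epochs only;
with that correction identical users correctly yield partial PI ≤ 0.

## The synthetic generator, and what it does not claim

No recordings for this paradigm are publicly available (the original
ones were deleted for confidentiality), so the generator is a
first-class, tested module rather than a fixture. Each synthetic user
has: a generic visual evoked response shared by all tags (three smooth
damped-oscillation components, 0.8–2.4 µV, random per-channel gains —
deliberately variable across users, since individual ERP morphology
differences are what make EEG biometrics work); a familiarity component
added only to tag-1 epochs — a Gaussian bump in time (default peak
400 ms, width 60 ms) weighted over P7/P8/Pz/O1/O2 with P7/P8 dominant,
matching P300 morphology; background noise as an equal-power sum of
1/f^α (α = 1, spectral synthesis) and white Gaussian noise, 10 µV total
by default; and optionally a *parasitic tag* receiving a scaled copy of
the familiarity component (a random code that happens to be familiar).
Eye blinks are stereotyped biphasic 175–325 µV deflections on the EOG
channels with attenuated frontal copies, injected with probability 0.05
per epoch and recorded as ground truth. The tag schedule is drawn by
sequential constrained sampling (each event uniform over tags with
remaining quota that do not violate the two-code separation, restarting
on dead ends) — a full-permutation rejection sampler is infeasible at
900 events, where a random permutation violates the constraint hundreds
of times in expectation.

The familiarity amplitude is the one knob the experiment's description
cannot pin down, so it was calibrated once against the attack-complexity
regime the method is known to operate in — real PIN exactly extractable
within 5–40 observations depending on the user — and then frozen: 5 µV
for the default user (PI ≈ 0.08–0.18 bits across sessions, rank 1 and
every per-tag success rate above 0.95 by 40 observations) and 8 µV for
a high-SNR user (rank 1 by 10 observations, PI ≈ 0.26–0.33 bits,
matching the most informative individuals). The calibration was performed with the
leak-free in-fold-basis estimator described above. The cohort generator
draws per-user amplitudes, latencies, widths and noise levels around
these centers with a `spread` parameter, so a simulated cohort spans
the whole 5–40-observation complexity range; `spread = 0` produces
literally identical users, the upper-bound fixture for portability.

What the generator does *not* emulate: volume-conduction correlations
between channels (channel noise is independent), non-stationarity and
drift across the session, inter-trial ERP variability in latency or
shape, muscle or movement artifacts beyond blinks, and continuous
between-epoch recording (only epoch windows are materialized). One
consequence worth naming: on real recordings the average PCA converges
with markedly fewer profiling traces than the raw PCA, because the
discriminant direction there carries little raw variance; in this
generator the familiarity component is prominent enough in raw variance
that the raw PCA finds it early, and only the *asymptotic* ordering
(average extracts more information than raw at full profiling sets)
carries over. Passing tests therefore certify the *estimators and
attack logic* under a controlled generative model with realistic SNR —
not that any particular human population leaks at these rates.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with classed errors: zero-spread samples
(Silverman undefined), empty tag classes, profiling folds missing a
class, schedules with fewer than three tags, epochs too short for the
0.5 Hz high-pass. PCA ranks are checked against an explicit
`1e-10 × largest eigenvalue` threshold. Raw PCA runs through the Gram
matrix (epochs × epochs), the economical side for 900 × 2000 data.

The test suite exercises the full session geometry (900 × 34 × 1000)
where the claim depends on it — mutual-information recovery, the
permutation null, calibrated attack complexities, the parasitic-tag rank
plateau of ≈ 1.5, the non-profiled sweep and its degradation at
q = 100 — and a reduced geometry (250 Hz, 250-sample epochs, 25–50
repetitions per tag) for structural and invariance checks, keeping the
whole suite inside ordinary desk-scale runtimes. The analysis drivers
under `analysis/` run the eight-user cohort at full scale.

## Known limitations

The independence assumption across PCA dimensions is exactly the
template-attack simplification — adequate here, but a joint density
would capture residual dependence. Bandwidths are fixed by a heuristic
rule, not cross-validated. The non-profiled driver recomputes the PCA
per attack subset but shares it across assumed tags (it cannot depend on
the hypothesis, tags being public). Mixture-model profiling across users
and key-rank enumeration over the full 10^4 PIN space are out of scope.
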