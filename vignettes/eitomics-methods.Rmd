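---
title: "Methods: EIT-based sub-phenotyping of ARDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EIT-based sub-phenotyping of ARDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific problem

Acute respiratory distress syndrome (ARDS) is clinically heterogeneous:
patients with similar oxygenation can have very different regional lung
physiology, and hence respond differently to ventilator settings such as
positive end-expiratory pressure (PEEP). Chest electrical impedance
tomography (EIT) observes this regional physiology non-invasively at the
bedside: a belt of electrodes reconstructs a pixel grid of thoracic
impedance over time, in which tidal ventilation and cardiac-synchronous
blood volume shifts (pulsatility, a proxy for regional perfusion Q) leave
distinct spectral signatures.

`eitomics` implements a complete unsupervised pipeline that turns
pixel-level EIT recordings acquired during a decremental PEEP trial
(18 to 4 cmH2O in 2-cmH2O steps) into patient sub-phenotypes:

1. separate ventilation- and cardiac-frequency signal components per pixel;
2. derive regional ventilation and pulsatility maps and classify every
   lung pixel into ventilation/perfusion (V'/Q) unit types;
3. summarise each recording as a fixed panel of 180 regional variables;
4. average PEEP steps into levels, scale, and cluster patients with
   agglomerative nesting (AGNES), choosing the PEEP grouping and linkage
   by an agglomerative-coefficient sensitivity analysis and the number of
   clusters by internal stopping rules;
5. identify the variables that discriminate the clusters and validate the
   clusters externally against respiratory drive, effort and outcome.

Because real patient recordings cannot be shipped with a package, a
synthetic cohort generator with *planted* sub-phenotype archetypes makes
every stage testable end to end: the generator's ground truth is stored
apart from the recordings, the analysis never reads it, and recovery is
scored with the adjusted Rand index only after the fact.

# Synthetic recordings

## Signal model

Each recording is a pixels-by-samples matrix. A lung pixel $i$ carries

$$ x_i(t) = b + v_i \, w_\mathrm{resp}(t) + q_i \, w_\mathrm{card}(t)
   + \varepsilon_i(t), $$

with baseline $b$ (default 10 impedance units), iid Gaussian noise
$\varepsilon$ (`noise_sd`, default 0.05), and

* $w_\mathrm{resp}(t) = \left(\tfrac{1 - \cos 2\pi f_R t}{2}\right)^2$, a
  raised-cosine tidal profile in $[0, 1]$ at the respiratory rate
  ($f_R$ = 15/min). Squaring sharpens expiration relative to inspiration,
  as in real tidal impedance curves; its spectrum has tones at $f_R$ and
  $2 f_R$ only. Because the profile spans exactly $[0,1]$, the
  end-inspiratory minus end-expiratory pixel difference equals $v_i$, the
  planted tidal amplitude.
* $w_\mathrm{card}(t) = \sin(2\pi f_C t + \varphi)$, a unit sinusoid at
  the cardiac rate ($f_C$ = 80/min) with a patient-specific phase, scaled
  by the planted pulsatility amplitude $q_i$ (about a quarter of the
  tidal amplitude, matching the order of magnitude of cardiosynchronous
  impedance signals).

Off-mask pixels contain noise only. The lung mask is two ellipses on the
grid (default 16 x 16; row 1 ventral). The configuration validator
rejects settings in which the cardiac fundamental does not clear the
second respiratory harmonic, because the two components would then be
spectrally inseparable in principle.

Each PEEP step lasts `step_duration` seconds. The default is 32 s — a
deliberately desk-sized scale (clinical steps are minutes long) chosen as
an integer number of breaths at the default respiratory rate, so the
tidal tones fall exactly on Fourier grid frequencies and spectral leakage
between the respiratory and cardiac bands is negligible.

## Planted archetypes

Three `phenotype_archetype()` objects shape the per-pixel amplitude
templates $(v_i, q_i)$:

* **unmatched V'/Q**: a ventral region keeps ventilation but loses
  pulsatility (dead space) and a dorsal region keeps pulsatility but
  loses ventilation (shunt);
* **mismatched V'/Q**: ventilation and perfusion are tilted against each
  other along a smooth spatial field, widening the distribution of
  regional V'/Q ratios without frank unmatched regions;
* **inhomogeneous ventilation**: a patchy multiplicative field roughens
  the ventilation map while perfusion stays matched.

Severity is `peep_response(peep) * separation`: by default derangements
are fully expressed at PEEP 4 and fall linearly to 30 % at PEEP 18
(partial recruitment), and the global `separation` knob scales all
archetype effects (0 = identical patients, 1 = study condition). Patient
random effects (global amplitudes, cardiac phase, field phases, extent
jitter) are drawn once per patient so the same lungs persist across PEEP
steps. Archetype counts follow deterministic largest-remainder rounding
of the mixture (default 0.5/0.3/0.2 over 30 patients: 15/9/6).

Each patient also receives archetype-linked external validation
variables never seen by the clustering: P0.1 (respiratory drive),
esophageal and transpulmonary pressure swings per PEEP level, a
personalised PEEP (emulating an overdistension/collapse balancing
algorithm) and ICU length of stay. At the low PEEP level the planted
drive/effort means are ordered unmatched > mismatched > inhomogeneous;
the ordering dissolves at higher PEEP.

Every random draw is derived deterministically from the master seed, so
a cohort is reproducible bit for bit from its configuration.

# Signal separation

`decompose()` removes each pixel's mean and linear trend, then computes a
principal-component decomposition (SVD) of the lung-pixel-by-time matrix,
retaining components up to 99 % cumulative explained variance. Each
retained component is labelled respiratory or cardiac by the dominant
periodogram peak of its temporal score (respiratory band 0.1–0.6 Hz,
cardiac band 0.8–3.0 Hz); if no retained component peaks in the cardiac
band the recording is rejected with a classed error ("pulsatility not
resolvable") and excluded from feature extraction with a logged note.

Assigning *whole* components to one source fails when the ventilation and
perfusion spatial patterns are correlated — which is the physiological
norm — because individual principal components then mix both sources. The
package therefore splits each retained component's temporal score into
its respiratory-band, cardiac-band and out-of-band parts by Fourier
masking before reconstruction. The split is exactly additive:
`resp + card + residual` equals the detrended input to machine precision,
and the residual collects out-of-band energy plus discarded components.

From the separated components:

* `ventilation_map()` detects breaths as peak–trough pairs on the global
  (mask-summed) respiratory waveform and averages the end-inspiratory
  minus end-expiratory pixel differences over breaths (at least 3 breaths
  required; anti-phase pixels are clipped at zero);
* `pulsatility_map()` estimates each pixel's cardiac amplitude as
  $\sqrt{2}$ times the root-mean-square of its cardiac reconstruction —
  the exact amplitude of a sinusoid — making the map invariant to cardiac
  phase. (The absolute scale cancels when maps are normalised.)

# V'/Q classification and the 180-variable panel

Both maps are normalised to fractions of their mask totals. A pixel is
*ventilated* (*perfused*) if its fraction exceeds 10 % of the map
maximum. Ventilated-only pixels are dead space; perfused-only pixels are
shunt; matched pixels are split by their normalised V'/Q ratio into high
(> 2), low (< 0.5) and normal units. Pixels that are neither ventilated
nor perfused — including everything off-mask — are background.

The feature registry (`default_feature_registry()`) defines 180 named
variables per recording:

* **64 ventilation/perfusion variables** (32 per map): ROI fractions,
  centres of distribution (ventral–dorsal and left–right first moments),
  global inhomogeneity index, coefficient of variation, active-area
  fraction and distribution entropy, each at the global scope and in four
  ventral-to-dorsal ROIs, plus dorsal and right fractions.
* **116 V'/Q-matching variables**: ventilation and perfusion allocated to
  each unit type, unit-type area fractions, and log10 V'/Q-ratio
  statistics (mean, SD, median, IQR, high-side fraction, spatial V'–Q
  correlation) at the same five scopes, plus six whole-lung summaries
  (dorsal/ventral wasted ventilation and perfusion, total wasted
  fraction, V'/Q mismatch index).

Allocation fractions are expressed relative to the *functional* mass
(total ventilation on ventilated pixels, total perfusion on perfused
pixels), so dead space + high + low + normal ventilation fractions sum to
1 exactly, and likewise for perfusion. Degenerate denominators (e.g. an
empty ROI) yield 0 with a logged note rather than a missing value,
keeping feature tables complete. The registry also flags which variables
are ratio-scaled and thus log-transformed before standardisation.

# Preprocessing and clustering

Per-step feature tables are averaged into PEEP *levels* (adjacent steps
treated as replicates). Patients with a partial set of steps in a level
keep the mean of their available steps; patients missing a level
entirely are dropped from it, with logged notes either way. Ratio-scaled
variables are shifted-log transformed, `log(x + eps)` with `eps` half the
smallest positive value of the column, then all variables are z-scored
and zero-variance columns dropped. Patient dissimilarity is Euclidean.

`agnes_tree()` implements AGNES via the Lance–Williams recurrence for
single, complete, average and Ward linkage. Ward follows the "ward.D2"
convention (recurrence on squared dissimilarities, heights reported on
the original scale), so for Euclidean input the heights match the
classical AGNES reference implementation. Ties are broken
deterministically by the lexicographically smallest pair of cluster
creation indices. The merge matrix follows the `hclust` convention and
trees convert losslessly via `as.hclust()` (and to Newick via
`write_newick()`).

The *agglomerative coefficient* — the mean over items of one minus the
ratio of first-merge to final-merge height — measures clustering
strength. `sensitivity_analysis()` computes it for every combination of
candidate PEEP grouping (all partitions of the sorted trial steps into
2–4 contiguous groups of at least 2 steps; 12 candidates for the 8-step
trial), level and linkage, and selects the (grouping, linkage) pair with
the highest mean coefficient.

The number of clusters is chosen by majority vote of five internal
validity indices evaluated on cuts at k = 2..6: mean silhouette width,
Calinski–Harabasz, Dunn, C-index and Davies–Bouldin. A vote tie is
resolved toward the k with fewer negative silhouette widths (fewer
apparently misclassified patients). The original analysis consulted a
larger battery of indices; this five-index suite spans the same families
(compactness, separation, and their ratios) and is implemented
in-package so the vote is fully reproducible. `run_config(k = ...)`
overrides the vote when a fixed k is wanted — for instance k = 3 when
scoring recovery of the three planted archetypes.

# Feature selection, naming, external validation

Each feature is compared across clusters with one-way ANOVA when
Shapiro–Wilk (on the ANOVA residuals) and Levene's test both fail to
reject at 0.05, otherwise Kruskal–Wallis. Raw p-values are
Bonferroni-corrected over the number of features actually tested
(constant features are skipped with a note), and a feature is *selected*
when its adjusted p-value is below 0.01. The one-way random-effects
intraclass correlation ICC(1A,1) — with the unequal-group-size correction
$k_0 = (N - \sum n_g^2 / N)/(G - 1)$ and the conventional thresholds of
0.6 (good) and 0.75 (excellent) — is reported for every tested feature as
a descriptive measure of within-cluster consistency; it does not
participate in selection.

Clusters receive advisory names from their feature profile (highest dead
space + wasted perfusion = "unmatched V'/Q"; highest log10 V'/Q-ratio
dispersion among the rest = "mismatched V'/Q"; remainder "inhomogeneous
ventilation"); exact ties leave clusters numbered. Names are metadata
only and never feed back into the analysis.

External validation variables are compared across clusters at the 95 %
level, with Tukey's HSD (parametric) or Dunn's test with Bonferroni
correction (non-parametric) as post-hoc analyses and chi-square tests
for categorical variables. Only at this reporting stage are the truth
labels consulted, to compute the adjusted Rand index.

# Reproducibility and interfaces

`run_pipeline(run_config())` executes the whole analysis; with an
`out_dir` it writes plain-text artifacts (feature tables, distance
matrices, Newick dendrograms, heatmap matrices in leaf order, per-level
cluster/selection/validation tables, a JSON report).
`report_summary()` extracts the deterministic numeric core of a run:
identical configuration and seed reproduce it exactly, which the test
suite checks byte for byte on the written artifacts. Run configurations
serialise to YAML (`write_run_config()`), cohorts to CSV + JSON manifest
(`write_cohort()`), and `scripts/acceptance.R` reproduces the headline
numbers from the command line:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

# What the generator does and does not emulate

The generator reproduces the *structure* of the measurement — spectral
superposition of tidal and cardiac components, gravity-dependent
perfusion, PEEP-dependent severity, archetype-linked drive/effort/outcome
distributions — but it is a stylised model: it uses stationary sinusoidal
dynamics (no arrhythmia, no breath-to-breath variability), iid Gaussian
noise (no electrode drift or motion artifacts), a fixed elliptical mask
(no anatomical segmentation), and its parameter values are plausible
round numbers, not fitted estimates. Conclusions about the pipeline's
statistical behaviour therefore transfer to real data only insofar as
real recordings satisfy the same spectral-separability assumptions.
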