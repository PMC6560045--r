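---
title: "Virtual lock masses: detection, correction and alignment of mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual lock masses: detection, correction and alignment of mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlmalign)
```

## The problem

High-throughput ionization sources (LDTD, DART) produce large batches of
centroided mass spectra without chromatographic separation: each sample is a
single list of (m/z, intensity) peaks. Batches are acquired over days, on
re-calibrated or different instruments, so the m/z axes of the spectra drift
relative to one another. Time-of-flight mass analyzers have a *relative*
mass error — the uncertainty grows linearly with m/z — so the drift is well
described as a small multiplicative distortion of the axis, and all
tolerances in this package are expressed in relative units (ppm).

The classical remedy is a *lock mass*: a compound of known exact mass spiked
into every sample, whose observed position calibrates the axis. Samples of
the same nature, however, already share many compounds (plasma contains
glucose and amino acids; urine contains urea and creatinine). A **virtual
lock mass** (VLM) is such a shared peak discovered from the data itself and
used as a calibration anchor. Correction against VLMs aligns spectra to each
other, not to true masses; it composes cleanly with a classical external
lock mass if absolute calibration is also needed.

## Definitions

Given a set $\mathcal{S}$ of $m$ spectra and a window half-width $w$ (in
relative units), a point $v$ on the m/z axis is a VLM when a peak set
$\mathcal{P}$ exists with:

1. exactly one peak from each of the $m$ spectra;
2. $v$ equal to the mean m/z of $\mathcal{P}$;
3. every peak of $\mathcal{P}$ inside $[v(1-w),\,v(1+w)]$;
4. no other peak of $\mathcal{S}$ inside that interval;
5. every peak intensity inside $[t_a, t_b]$.

Two VLMs *overlap* when their windows intersect; only *isolated* VLMs (those
overlapping none) are retained, since a peak serving two anchors would make
the correction ambiguous. An **alignment point** relaxes property 1 to "1 to
$m$ peaks from distinct spectra", drops the intensity bounds, and adds
maximality: no further peak of $\mathcal{S}$ can be added without breaking
the other properties.

## The detection sweep

`detect_vlms()` pools the peaks of all spectra in m/z order through a binary
min-heap holding one pending peak per spectrum, and grows/shrinks an *active
sequence* of consecutive peaks — a candidate group. A new peak is appended
when its spectrum is not yet represented and both the group's first peak and
the newcomer fit the window of the updated running mean; when insertion
fails, the last state that satisfied the definition is recorded as a
candidate and the group's oldest peak is dropped. Overlapping candidates are
removed pairwise at the end. Each peak is pushed and popped at most once, so
the heap performs at most $2n + m$ operations on $n$ pooled peaks and the
sweep runs in $O(n \log m)$ — the property that makes the method practical
at a million peaks, where any quadratic clustering approach stalls.

Two details of our implementation are worth stating. First, emission works
from a snapshot of the last valid state, the state is re-validated after
every lower-bound advance (with a guard that discards states whose left
extension is itself valid, i.e. non-maximal states), and a pending snapshot
separated from a newly valid state by an invalid insertion is emitted in its
own right. These refinements matter only in relaxed (alignment) mode, where
a strictly greedy sweep can otherwise drop maximal groups at the tail of the
pooled sequence; `brute_force_vlms()`, a direct $\Omega(n^2)$ transcription
of the definitions, is kept in the package as an independent oracle and the
test suite checks exact agreement (values to $10^{-12}$ relative, identical
member sets) on hundreds of seeded instances in both modes.

Second, the sweep has a known blind spot that we deliberately preserve
because it is intrinsic to the published insertion rule: a peak is tested
against the window of the *running* mean of the current prefix, so when a
group's internal spread approaches the full window width $2w$, a peak can be
rejected that the final group mean would have covered. In stress tests with
windows comparable to the typical peak spacing (hundreds of ppm on densely
packed peaks) the sweep can therefore miss groups the definition admits.
The window-size selection below chooses $w$ precisely so that within-group
scatter is small relative to $w$; in that operating regime we observe exact
agreement with the oracle throughout.

Peaks with intensity outside $[t_a, t_b]$ never enter the heap. A
consequence is that a sub-threshold peak cannot veto a window through
property 4 either. The definition's "no other peak" carries no intensity
qualifier, so both readings are defensible; we default to the algorithmic
reading (the sweep never sees filtered peaks) and expose
`strict_exclusivity = TRUE`, which re-checks candidate windows against every
peak post hoc.

### Choosing the window size

The isolated-VLM count behaves unimodally in $w$: windows too narrow cannot
span the scatter of a shared peak; windows too wide merge neighbours and die
in overlap removal. `scan_window_sizes()` evaluates a grid (default: 20
geometric points over 1–200 ppm, reflecting the practical observation that
about 20 values suffice) and returns the count-maximizing $w$, ties broken
toward the smaller window.

## Correction

For a spectrum of the detection set, each $v_i$ matches exactly one peak
$\mu_{\alpha_i}$ (property 4 guarantees uniqueness). `correct_spectrum()`
maps every peak between the first and last matched peaks through the
piecewise linear function with segments

$$a_i = \frac{v_{i+1} - v_i}{\mu_{\alpha_{i+1}} - \mu_{\alpha_i}}, \qquad
  b_i = v_i - a_i\,\mu_{\alpha_i},$$

so matched peaks land exactly on their $v_i$ (we assign them directly, which
also makes re-correction bit-stable) and intermediate peaks are
interpolated. Intensities are never modified, and positive slopes preserve
peak order. Peaks outside the outermost matched VLMs could only be
extrapolated, which is unreliable; they are removed by default
(`trim = TRUE`) or passed through unmodified and flagged. A spectrum *not*
in the detection set may present zero or several peaks in some window; that
VLM is reported unmatched and the interpolation bridges over it — the
behaviour the inductive workflow needs to correct unseen spectra. Fewer than
two matches leaves no interpolation interval and is an error; we define no
constant-shift fallback.

Each spectrum's `source_index` traces surviving peaks back to the input, so
different corrections of the same spectra can be compared peak-by-peak
(`correction_rmse(..., match_by = "source")`), e.g. under different trims.

## From correction to alignment

After correction, VLM member peaks agree exactly across spectra, but peaks
of other shared compounds only approximately. To pick the small window
$\theta \ll w$ that re-groups them, each interior VLM $v_i$ is left out of
the correction in turn: its member peaks, corrected by the bridge between
$v_{i-1}$ and $v_{i+1}$ (only those two segments change, so each deviation
costs $O(m)$), spread around $v_i$ by at most $\theta_i$. The default
$\theta$ is the 95th percentile of the $\theta_i$ — the nearest-rank order
statistic $\lceil 0.95\,r' \rceil$, i.e. the smallest window covering 95% of
the VLMs. The maximum ($z = 100$) is available but is an overestimate, since
the real correction never leaves a VLM out; in inductive learning workflows
the percentile is the natural hyperparameter to cross-validate.

Alignment points are then detected by the same sweep in relaxed mode, and
`represent()` turns a corrected spectrum into a feature vector: per point,
the intensity of the in-window peak closest to the point's mean (0 when the
window is empty). The alignment-set definition admits at most one peak per
spectrum per window, so a second in-window peak is off-model; taking the
closest one is deterministic and order-independent, and we prefer that to
summing, which would silently change intensities. `bin_spectrum()` provides
the conventional fixed-bin baseline (half-open bins, edge peaks to the
right, sum or max aggregation) for comparison.

`run_pipeline()` wires the stages into the two evaluation workflows:
*transductive* (detect, correct and align on all spectra, then split) and
*inductive* (every model frozen on the training spectra; test spectra are
matched to training windows, bridged over unmatched VLMs, and never
re-clustered). Feature columns in inductive mode are the training-time point
means.

## The synthetic generator

No study data ship with the method, so `generate_spectra()` emulates the
structure of a pooled-plasma batch with known ground truth: $K$ compound
masses drawn over 50–1000 Th with a minimum relative separation, a subset
present in every spectrum and the rest present per-spectrum with probability
$p$; per-spectrum multiplicative drift $(1+\varepsilon_\sigma)$ — the scale
error a ToF instrument accumulates and piecewise-linear correction can
remove — and per-peak multiplicative jitter $(1+\eta)$. Jitter is uniform by
default so worst-case deviations are bounded and recovery bounds can be
asserted exactly; a Gaussian option exists. Intensities are log-normal
(default meanlog $\log 5\times10^4$, sdlog 0.8 — a bright centroid
population for which counts below the usual 1000-count detection threshold
are rare), with an option to force a fraction of common compounds under the
threshold. The generator models the mass axis only: no isotope patterns,
adducts, chimeric peaks or intensity drift. Tests passing on these data
therefore validate the mass-axis behaviour of the pipeline, not its
robustness to intensity artefacts.

Default study conditions are 50 spectra, 100 common compounds, 30 variable
compounds at $p = 0.5$, 20 noise peaks per spectrum, 200 ppm minimum
separation, ±10 ppm drift and ±5 ppm jitter; the detection defaults are
$w = 40$ ppm and $t_a = 1000$ counts with $t_b$ unbounded.

### Which conditions which experiments use

* **Recovery (recall/precision of planted masses).** Run without noise
  peaks. This is not a relaxation: a single spurious peak falling inside a
  window disqualifies that lock mass *by definition* (property 4), so with
  1000 uniform noise peaks a handful of the 100 planted compounds are
  expected to be vetoed and a 100% recall target would be meaningless. With
  noise retained, the same run yields recall ≈ 0.95 at $w = 40$ ppm — the
  definition working as intended, not a detection failure.
* **Learning curves** (held-out spectra corrected by models trained on 10 to
  160 spectra, 20 replicates, medians) use the full noisy defaults at
  $m = 185$; variable compounds and noise are what make the VLM count fall
  with training size, as observed on real data.
* **Stability** ($k$-fold re-finding of training VLMs in held-out spectra,
  $k \in \{3, 5, 10\}$) and **homologue consistency** (full set vs
  half-splits) use the defaults, stability without noise peaks since its
  100% criterion demands *exactly one* peak per window in every test
  spectrum.
* **Alignment fidelity** uses common compounds only: corrected VLM peaks
  have zero spread, so the planted compounds and the alignment points must
  correspond one-to-one at any positive $\theta$, which isolates the theta
  selection and relaxed detection machinery from sampling noise.
* **Complexity checks** use $m = 10$ spectra of 1 000 and 10 000 peaks
  (20 ppm separation, $w = 5$ ppm): heap operations stay under $2n + m$ and
  a tenfold peak increase costs well under fifteenfold the time.

These problem sizes keep the whole suite under a couple of minutes while
leaving each protocol statistically unambiguous.

## Numerical choices and degenerate inputs

* Window membership is closed (`mz` equal to an edge counts as inside),
  everywhere and consistently.
* Candidate means are recomputed by a fresh left-to-right sum at emission,
  so reported values match a direct computation to machine precision rather
  than accumulating running-sum round-off.
* Heap ties on m/z break by spectrum index; detection output is invariant
  to the order spectra are supplied in (up to re-indexing).
* The last-removed-peak marker starts as "none" (outside every window)
  rather than 0, which would also work for positive masses but documents
  intent less clearly.
* Duplicate m/z values within one spectrum are retained on reading —
  centroiders emit near-duplicates, and merging would alter intensities;
  detection's one-peak-per-spectrum rule simply never admits both.
* Zero-intensity peaks are kept on reading; thresholding belongs to the
  detector ($t_a$), not the parser.
* All-equal leave-one-out deviations of exactly zero (possible on noiseless
  synthetic data) would give $\theta = 0$; `alignment_model()` then falls
  back to the smallest positive window doubles can express, which still
  groups exactly-coincident peaks.
* `detect_vlms()` refuses VLM mode with fewer than two spectra (a VLM of a
  single spectrum is vacuous); single-spectrum sets are legal in alignment
  mode.

## Known limitations

* The greedy insertion rule's blind spot for groups whose spread approaches
  the full window width, discussed above.
* Correction aligns spectra to the *batch mean* axis, not to true masses;
  compose with an external lock mass for absolute calibration.
* Spectra must share enough compounds: the method assumes samples of the
  same nature, and works best with many more peaks than spectra.
* Peaks outside the outermost VLMs are discarded by the default trim; with
  sparse VLM coverage at the range edges this can remove real signal.
* One-dimensional peak lists only: no ion mobility or chromatographic
  dimension.
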