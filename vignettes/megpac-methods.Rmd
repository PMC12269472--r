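---
title: "Methods: PAC-based resting-state networks and their group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAC-based resting-state networks and their group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`megpacr` estimates cortical resting-state networks (RSNs) from source-space
MEG time series through the megPAC construction, and compares those networks
across a four-condition clinical design: medication ON/OFF crossed with
recording session (before electrode implantation vs. about one year later),
with unequal usable cohorts of 18/18/17/19 subjects drawn from a pool of 20.
Because the corresponding patient recordings are not redistributable, the
package ships a synthetic source-space generator with planted ground truth;
every stage of the pipeline is exercised and tested against that ground
truth.

The processing chain is:

1. **Maximum PAC search** (`pac_map`): for every vertex, find the frequency
   pair $(\hat f_\phi, \hat f_a)$, $f_\phi \in [2,30]$ Hz,
   $f_a \in [80,150]$ Hz, that maximizes the direct phase-amplitude coupling
   estimator
   $$\mathrm{PAC} = \frac{\left|\sum_t a(t)\,e^{i\phi(t)}\right|}
   {\sqrt{N}\sqrt{\sum_t a(t)^2}},$$
   where $\phi(t)$ is the analytic phase of the low-frequency band and
   $a(t)$ the analytic amplitude of the high-gamma band. The estimator is
   scale- and offset-invariant and bounded in $[0,1]$ by Cauchy-Schwarz.
2. **megPAC synthesis** (`synthesize_megpac`): sample the high-gamma
   amplitude at the extrema of the low-frequency component, interpolate
   linearly between extrema, and resample to 10 Hz, yielding a slow
   surrogate signal comparable to BOLD-rate dynamics.
3. **Surface smoothing** (`smooth_series`): Gaussian kernel with
   FWHM = 7 mm over inter-vertex distances.
4. **Network extraction** (`extract_rsns`): z-score each subject's series,
   concatenate subjects, correlate over an evenly distributed vertex subset
   (farthest-point sampling), take the SVD of the correlation matrix, keep
   ten spatial modes, and back-project to full resolution by correlating
   every vertex with each mode's time course. Maps are rectified and scaled
   so each lies in $[0,1]$ with maximum 1 ("coupling strength").
5. **Group statistics** (`run_jackknife`, `vertex_anova`, `hc_overlap`,
   `lowfreq_anova`): leave-one-out jackknife ensembles per condition,
   template matching via the phi coefficient at a 40% threshold,
   vertex-wise two-factor ANOVA (medication x session) with Welch post-hoc
   tests and Benjamini-Hochberg FDR, overlap tests against external
   templates with Bonferroni correction, and a three-factor ANOVA of the
   per-network median maximum-coupling phase frequency with partial eta
   squared effect sizes.

# Signal model of the synthetic generator

For a vertex $v$ of network $k$:
$$x_v(t) = \sin(2\pi f_\phi t + \theta_v)
 + \kappa_{\mathrm{eff}}\, m_k(t)\, g(\phi_v(t)) \sin(2\pi f_a t)
 + \varepsilon_v(t),$$
with $g(\phi) = (1+\cos\phi)/2$ gating the fast carrier by the slow phase,
$m_k(t)$ a slow non-negative envelope (white noise low-passed at 0.5 Hz,
standardized, then $m = \max(0, 1 + 0.4z)$) shared by all vertices of the
network, $\theta_v$ a uniform random phase offset per vertex, and
$\varepsilon$ white noise (sd 0.3 by default). Background vertices carry
only a slow oscillation (random frequency in $[2,30]$ Hz) and noise;
their coupling is exactly zero. $\kappa_{\mathrm{eff}}$ is the network
coupling strength (default 0.9) times any condition multiplier planted in
an effect region (default multiplier 1.5).

This multiplicative, phase-gated model was chosen because it produces the
two properties the pipeline exploits: high PAC at the planted pair, and
network-structured megPAC correlations through the shared envelope. The
0.5 Hz envelope cutoff keeps the shared fluctuation well below the 5 Hz
Nyquist of the 10 Hz megPAC rate while mimicking BOLD-like slow dynamics.

Default study conditions: cohort sizes 18/18/17/19 obtained by dropping
distinct random subject subsets from a pool of 20 (so the per-condition
subject sets differ, and only unpaired tests are possible); sampling rate
600 Hz ($\geq 4\times$ the highest amplitude frequency); 120 s per
recording ($\geq 240$ cycles at $f_\phi = 2$ Hz).

**Heterogeneous network extents.** The three default networks use size
ratios 1.5/1.0/0.6. Real RSNs differ in spatial extent, and the choice is
also load-bearing: planted networks of identical size and strength give the
group correlation matrix nearly degenerate leading eigenvalues, and under
near-degeneracy the singular vectors are free to rotate inside the network
subspace, mixing the maps. Distinct extents separate the spectrum so each
mode locks onto one network.

**No effect-size anchor exists for the planted condition effects**; the
1.5x multiplier in effect regions is a repository convention. Effect
subregions are planted at sub-peak baseline coupling (0.55 vs. 0.9) so that
even after the 1.5x boost their coupling stays below the network's peak:
each map is normalized by its maximum, so an effect that moved the peak
itself would renormalize the entire network map and appear (inverted)
everywhere except in the planted region.

# Numerical choices in the PAC core

**Band extraction.** Bands are isolated by a zero-phase frequency-domain
bandpass whose positive-frequency content is inverted directly into the
analytic signal — algebraically the same object as band-passing and then
applying the Hilbert transform, computed in one FFT pass. The band signals
are decimated in the frequency domain to an internal analysis rate of about
150 Hz; amplitude bands are shifted to baseband first (which leaves the
envelope modulus untouched), and the rate is chosen so that both the band
content and the spectrum of the product $a(t)e^{i\phi(t)}$ stay below the
decimated Nyquist, leaving the time-averaged estimator unchanged. Whole
recordings are transformed once per vertex; the grid search then reuses the
spectrum for every band.

**Phase bands** have half-width $\max(1, f_\phi/4)$ Hz.

**Adaptive amplitude bandwidth.** The amplitude band around $f_a$ must pass
the modulation sidebands at $f_a \pm f_\phi$, so its half-width must exceed
$f_\phi$. A single fixed width wide enough for $f_\phi = 30$ Hz (35 Hz or
more) would make neighbouring cells of the 5 Hz amplitude grid contain
identical sideband content, destroying the search's frequency resolution in
$f_a$. The half-width therefore adapts to the phase frequency of the pair
under test: the smallest of {12, 19, 35} Hz that is at least
$f_\phi + 5$ Hz. Quantizing to three width classes keeps the number of
distinct band extractions per vertex at 29 + 3x15 rather than 29x15.

**Argmax ties** are broken toward the lowest phase frequency, then the
lowest amplitude frequency, so runs are bit-reproducible. In practice the
recovered phase frequency scatters by about one grid step around the
planted value: every phase band containing the spectral line estimates
essentially the same phase, and narrower neighbouring bands admit less
noise, so the argmax occasionally prefers a band centred one step away.
This is a resolution property of bandpassed PAC estimation, not of the
argmax rule.

**Extrema sign convention.** The megPAC construction samples the high-gamma
amplitude at the extrema of the low-frequency component. A signed variant
(+ at maxima, - at minima) is available (`signed_extrema = TRUE`), but the
default is unsigned: with random per-vertex phase offsets the signed series
is dominated by a zero-mean carrier at an arbitrary phase, which splits
each network into a pair of quadrature modes and suppresses within-network
correlations, whereas the unsigned series retains the shared slow envelope.
Before the first and after the last extremum the series is extended with
the nearest extremum value; resampling to 10 Hz uses linear interpolation
onto a uniform grid (the extrema-interpolated signal is already slow and
non-uniformly sampled, so decimation filters would add nothing).

**Degenerate inputs.** An amplitude band with no energy (beyond FFT
round-off, judged relative to the total signal energy) returns PAC = 0
rather than NaN; signals shorter than 10 cycles of the phase frequency are
rejected; a low-frequency component with fewer than 4 alternating extrema
raises an error naming the vertex.

# Network extraction choices

Each subject's megPAC series is z-scored per vertex before concatenation so
high-variance subjects cannot dominate the group correlation. The SVD is
taken of the Pearson correlation matrix over the subset vertices (the
correlation-matrix and time-series readings give the same mode subspace up
to singular-value scaling; the correlation reading is adopted). Full-cortex
maps are recovered by correlating every vertex's concatenated series with
each mode's time course; maps are then rectified and divided by their
maximum, which makes "40% of the maximum coupling strength" well defined.
Zero-variance vertices get correlation 0 by convention. Distances for
smoothing and subsetting are Euclidean; at 7 mm kernels on toy meshes the
difference from geodesic distances is negligible. The default subset size
is `min(n_vertices, 1000)`.

The smoothing weight matrix is balanced to (near-)doubly-stochastic form by
Sinkhorn iteration: rows sum to one exactly (a weighted average per vertex)
and columns to one within 1e-12, so the global mean of each time sample is
preserved.

# Group statistics choices

**Jackknife variance correction.** Leave-one-out group maps vary about
$(N-1)$ times less than the underlying subject-level variability: the
leave-one-out means of an i.i.d. sample have standard deviation
$\sigma/(N-1)\sqrt{N/(N-1)}$-fold smaller than the subject values.
Statistics computed across jackknife runs therefore inflate each group's
standard error by $N-1$ (equivalently $t / (N-1)$, $F / (\bar N-1)^2$)
before p-values. The correction is a switch (`jackknife_correction`,
default on) because run-level uncorrected tests are also in circulation;
both modes are tested.

**Unbalanced ANOVA.** Cohorts are unbalanced (18/18/17/19), so the two-way
and three-way ANOVAs use Type II sums of squares via `car::Anova`.

**Post-hoc contrasts** are the four comparisons of interest: OFF vs. ON
within each session and first vs. second within each medication state, as
two-tailed unequal-variance (Welch) tests. The per-condition subject sets
differ, so paired tests are not possible anywhere; unpaired Welch tests are
used throughout, and no paired variant is implemented.

**Multiplicity.** Vertex-wise post-hoc p-values form a single
Benjamini-Hochberg family across vertices x networks x contrasts. Overlap
tests are Bonferroni-corrected over the 6 condition pairs x 3 networks = 18
tests. The low-frequency ANOVA corrects its post-hoc pairwise level
comparisons by Bonferroni within the significant factors.

**Vertex inclusion** for the ANOVA: a vertex enters a network's analysis if
it reaches 40% of the maximum coupling strength in at least one of the four
condition templates; the condition templates are the full-cohort
(no-leave-out) RSNs, matched by phi to reference maps (the planted
ground-truth maps in synthetic studies, or user-supplied maps such as
healthy-control templates).

**Degenerate phi tables** (any zero marginal) return 0 with a warning so
that jackknife aggregation never silently drops runs.

# Problem sizes used in the shipped studies

The package documents two standard configurations:

* the **default study** — 162-vertex icosphere (or any user mesh), 600 Hz,
  120 s, full 29 x 15 grid — matching the default `sim_config()`;
* the **reduced study** (`reduced_study_config()`) — 42-vertex icosphere,
  400 Hz, 20 s recordings, phase grid 3-14 Hz in 1 Hz steps, amplitude
  cells at the three planted carriers — chosen so that a full
  four-condition jackknife analysis (72 recordings, 72 leave-one-out
  extractions, all statistics) completes in well under a minute on one
  core, which makes replicate-based error-control studies practical.

Simulation studies shipped with the package use the reduced configuration
for error control and power (20 replicates for the null false-discovery
study) and a 300-vertex planar grid with 8 subjects and full-length 120 s
recordings for network recovery. The grid spacing (7 mm) is commensurate
with the smoothing kernel, as in down-sampled cortical source grids.

# What passing the synthetic studies does and does not show

The generator emulates: planted cross-frequency coupling with known
frequency pairs, network-structured slow envelopes, unequal cohorts with
differing subject subsets, and condition effects confined to subregions.
It does **not** emulate: sensor-level physics and source leakage (every
vertex is an independent measurement channel up to the planted structure),
1/f background spectra, artifacts, inter-subject anatomical variability
(all subjects share one mesh, standing in for surface registration to a
common template), or clinically realistic effect sizes. Passing recovery
and error-control studies on this generator therefore validates the
*computational chain* — estimators, resampling, corrections, and their
calibration under the stated model — not the clinical sensitivity of the
method on real MEG.

# Known limitations

* The maximum-PAC search is recomputed per recording (per subject and
  condition); sharing the pair across a subject's conditions is not
  implemented.
* Phase-frequency recovery is limited to about one grid step by the
  band-noise asymmetry discussed above.
* The frequency-domain bandpass assumes stationary segments and whole
  recordings; no epoching or artifact handling is provided (out of scope).
* `hc_overlap` compares against user-supplied template maps; with the
  synthetic generator these are ground-truth maps, which are labelled as
  synthetic stand-ins for healthy-control templates.
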