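---
title: "Methods: OPLS-based NMR metabolic fingerprinting in oplsnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OPLS-based NMR metabolic fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oplsnmr)
```

This vignette documents the models, numerical choices and free parameters
behind `oplsnmr`, and states explicitly what the synthetic-data tests do
and do not establish.

## The spectral model and preprocessing chain

A 1D ¹H spectrum is represented as intensities on a strictly monotone
chemical-shift grid in ppm, stored high-to-low (the display convention; a
single normalization point for sign conventions in window arithmetic).
Preprocessing follows the order **phase → align → exclude → normalize →
threshold → pick peaks → z-score**, and the order matters:

* **Phase correction** minimizes the sum of squared negative excursions of
  the real part over zeroth- and first-order phase angles (an absorptive
  spectrum is non-negative up to noise). On real-valued input it is the
  identity. The zeroth/first-order pair is not identifiable on sparse
  spectra (a linear phase ramp can mimic a constant offset at the few
  populated regions), so `first_order = FALSE` is available and the
  optimizer seeds from a 5° coarse scan of the zeroth-order angle.
  Whether the original processing chain phased manually or automatically
  is unknown; automatic minimization is this package's choice.
* **Alignment** finds the tallest local maximum within ±0.15 ppm of the
  6.5 ppm fumarate target and shifts the whole spectrum (linear
  re-interpolation onto the original grid) so that maximum sits on the
  grid point nearest 6.5. This corrects a *global* per-sample offset —
  exactly what an internal standard can correct — not per-peak drift.
* **Exclusion windows** default to residual water 4.70–5.10, methanol
  3.32–3.35, the fumarate reference 6.45–6.58, and propylene glycol
  1.10–1.15, 3.40–4.43, 3.436–3.442, 3.509–3.521, 3.53–3.54,
  3.841–3.884 ppm. The 3.40–4.43 window swallows a full ppm of spectrum
  and is very likely a typographic variant of 3.40–3.43 (it envelops the
  separately listed sub-windows between 3.43 and 3.89); both behaviours
  are implemented (`default_exclusion_windows(narrow_pg_window = TRUE)`),
  the as-printed version is the default for fidelity, and no test asserts
  either reading as *intent*.
* **Normalization** divides each spectrum's *retained* points by their
  sum (unit total area). Normalizing before exclusion would let excluded
  contaminant area leak into the scale factor; a test asserts the
  implemented order is exclusion first.
* **Noise thresholding**: the noise level is defined as the per-sample SD
  of intensities in 0–0.2 ppm (the convention chosen here; the source
  procedure says only "noise level"), the threshold is exactly 5σ of the
  *sample's own* noise, and a chemical shift is discarded iff strictly
  more than 50% of samples lie below their threshold. Retained values are
  never modified.
* **Peak picking** takes strict local maxima of the across-sample mean
  spectrum, so all samples share one feature set; plateaus resolve to
  their lowest-ppm point. Per-sample picking followed by cross-sample
  matching was the alternative; the consensus mean was chosen because it
  needs no matching tolerance and is deterministic.
* **Z-scoring** (mean 0, SD 1 per feature, n−1 denominator) is computed
  within each pairwise comparison's samples only, because each model in
  the four-comparison design is fit on its own pair of groups.
  Zero-variance features are dropped with a warning.

## The OPLS model

For predictors $X$ (n × p, z-scored) and centered response $y$ (binary
group membership encoded 0/1), each orthogonal component is computed as

$$w \propto X'y,\quad t = Xw,\quad p = X't/(t't),\quad
  w_o \propto p - (w'p)\,w,\quad t_o = Xw_o,\quad
  p_o = X't_o/(t_o't_o),$$

followed by the deflation $X \leftarrow X - t_o p_o'$; after $k$
deflations the predictive component $t = Xw$, $c = y't/(t't)$ is fit on
the deflated matrix. This is the single-response (PLS1-style) variant of
the Trygg–Wold deflation. Invariants enforced and tested: $\lVert w
\rVert = \lVert w_o \rVert = 1$, $w \perp w_o$, $t \perp t_o$,
mean(VIP²) = 1.

* **R²Y(cum)** = 1 − SS(y − ct)/SS(y) on the training data; non-decreasing
  in $k$.
* **Q²(cum)** = 1 − PRESS/SSY under stratified k-fold cross-validation
  (default 7 folds, the common chemometrics default). Fold assignment is
  deterministic: samples sorted within class, classes concatenated, dealt
  cyclically to folds — so `folds = n` is exact leave-one-out and results
  are reproducible without an RNG. Negative Q² is a meaningful outcome
  (model worse than predicting the mean) and is representable everywhere,
  including in permutation summaries.
* **Automatic component selection** adds orthogonal components greedily
  while Q² improves by more than 0.01. The reference software's rule is
  proprietary; 0.01 is this package's documented approximation and `k` is
  always user-overridable (`opls(..., n_orth = 3)`).
* **VIP** uses the total formula over predictive plus orthogonal
  components, $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a
  (w_{aj}/\lVert w_a\rVert)^2 / \sum_a \mathrm{SSY}_a}$ with
  $\mathrm{SSY}_a$ the y-variance explained by component $a$. Orthogonal
  components have SSY ≈ 0, so the predictive term dominates; a
  predictive-only variant sits behind `vip(model, "predictive")`. In the
  noiseless single-informative-feature limit the formula gives
  $\sqrt{p}$, which is tested exactly.
* **Permutation validation** refits the model under shuffled labels
  (default: reusing the fitted number of orthogonal components; per-
  permutation reselection is available), records (|corr|, R², Q²), and
  reports y-intercepts of ordinary least-squares lines through all points
  including the unpermuted model at corr = 1 — the convention of the
  standard validate plot.
* **Hotelling's T²** score ellipses use the closed form
  $s_i\sqrt{\tfrac{2(n^2-1)}{n(n-2)} F_{\alpha}(2, n-2)}$ on the two
  score axes.

## Univariate statistics

Classical equal-variance two-sample Student's t per feature on z-scores,
two-sided p from the t distribution with $n_1+n_2-2$ df, no multiplicity
adjustment (FDR control in this design applies to pathways, not
features). Welch's correction is available behind `welch = TRUE`. The
effect column is the mean z-score difference, comparison minus reference.

## Pathway stage

Features with VIP > 1 collapse to metabolites: the highest-VIP feature
represents each metabolite (ties break to the lower chemical shift, for
determinism); unassigned and ambiguous features — two different
metabolites' lines within the 0.01 ppm annotation tolerance — are
excluded, mirroring the exclusion of overlapping peaks from pathway
analysis. Enrichment per pathway is the hypergeometric upper tail
P(X ≥ hits) with the universe defined as all compounds of the loaded
library (reference-metabolome choices vary between software versions;
this one is explicit and configurable via `universe_size`). The impact
score is the matched share of total betweenness centrality on the
undirected pathway graph (all-zero centrality ⇒ impact 0, e.g. two-node
pathways). P-values are Benjamini–Hochberg adjusted across pathways and
the dual rule — adjusted p strictly < 0.05 AND impact strictly > 0 —
selects pathways of interest; zero-impact pathways stay in the report,
flagged unselected. The bundled library is a *synthetic miniature* with a
KEGG-like schema (name, compound set, edge list), built for testability;
it is not a database export, and real analyses should load their own
library via `read_pathway_library(path)`.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` draws, per sample: metabolite concentrations
(baseline × 2^log2FC group effect × log-normal biological variation), one
global chemical-shift jitter, and Gaussian noise, then renders pure
absorptive Lorentzian multiplets (first-order binomial line ratios,
J-couplings converted at the configured spectrometer frequency) plus
contaminant lines placed strictly inside the default exclusion windows.
Defaults, chosen once as a realistic 600 MHz serum world where the source
procedure states no value:

| parameter | default | why |
|---|---|---|
| grid | 0–12 ppm, 16384 points (~0.73 mHz/pt) | matches the analysis window; step ≪ linewidth |
| halfwidth (HWHM) | 0.0025 ppm ≈ 1.5 Hz | typical serum small-molecule linewidth |
| noise_sd | 0.004 (intensity units) | line SNR ≈ 10–100×, comfortably astride the 5σ threshold |
| shift_jitter_sd | 0.02 ppm | referencing errors the fumarate alignment must fix |
| biological_sdlog | 0.25 | ~25% between-animal concentration CV |
| group sizes | 5 / 4 / 9 / 9 | the study design |

Not simulated: T1/T2 relaxation and lineshape distortions, solvent
suppression artifacts beyond a static water hump, baseline roll, 2D
spectra, and per-peak (as opposed to global) shift drift beyond the
optional `per_metabolite_jitter_sd`. Consequently a green end-to-end test
establishes that the *statistical chain* recovers known truth under
idealized lineshapes — it does not validate robustness to baseline or
alignment pathologies that real spectrometers produce.

One behaviour worth knowing when interpreting VIP > 1 sets: in a
comparison with little true signal, z-scoring gives every null feature
unit variance and the VIP normalization then places a large fraction of
features near 1, so chance VIP > 1 rates of 30–40% per null feature are
expected at these sample sizes. The set-difference logic of
`unique_stroke_changes()` is therefore only informative when the
background (diet) comparisons carry substantial genuine signal — which is
the biologically expected situation after months of high-fat feeding, and
how the recovery tests are constructed.

## Numerical and degenerate-input choices

* Interpolation (alignment, resampling) is linear; exact on linear data
  and within 1% of peak height for Lorentzians with HWHM ≥ 4 grid steps
  (tested). Interpolation always operates on ascending-sorted copies —
  `stats::approx`'s tie handling silently misbehaves on descending input.
* σ = 0 in the noise model gives threshold 0 and discards nothing (no
  value is strictly below 0).
* `X'y = 0` (response orthogonal to every predictor) and `n_orth` at or
  above the rank of X are errors, as are folds that strip a class from a
  training set.
* Permutation records with zero spread in |corr| fall back to the mean
  for the intercept (the regression is degenerate).
* Hypergeometric inputs are validated (hits ≤ min(selected, pathway
  size), pathway ≤ universe) rather than clamped.

## Known limitations

Annotation is nearest-line matching against a nominal shift table, not
spin-system fitting; heavily overlapped regions (0.9–1.05 ppm among the
branched-chain amino acids, 3.4–3.9 ppm among sugars) produce ambiguous
or unassigned features by design rather than guessed assignments. The
permutation intercept convention, CV fold count, VIP variant and
auto-selection threshold are all parameterized because the upstream
tools' exact settings are not public; results at the defaults are
reproducible but not guaranteed to equal any specific commercial
implementation.
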