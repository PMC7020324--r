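---
title: "Multi-block FT-MIR chemometrics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block FT-MIR chemometrics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Wild porcini mushrooms (four species here: *Boletus edulis*,
*Leccinum rugosiceps*, *B. tomentipes*, *B. umbriniporus*) are valuable,
morphologically confusable, and traded in processed forms that defeat visual
identification. Mid-infrared absorbance spectra (4,000–400 cm⁻¹) of dried
fruiting-body powder act as chemical fingerprints: band positions are shared
across species while band intensities differ with composition. Each fruiting
body contributes two spectra — one from the cap, one from the stipe — and the
analytical question is whether combining the two blocks (data fusion)
discriminates species better than either block alone, and whether the same
spectra predict total-polyphenol content (Folin–Ciocalteu, gallic-acid
equivalents, mg/g dry weight).

`mirfuse` implements that entire workflow as composable R functions: spectral
I/O and pairing, pretreatments, Kennard–Stone partitioning, low- and
mid-level fusion, NIPALS PLS2 discriminant analysis, RBF-SVM classification
and regression with grid-search and particle-swarm tuning, exact t-SNE
display, and the polyphenol assay arithmetic — plus a synthetic-spectra
generator so that every stage can be exercised and validated without
instrument data.

# The synthetic-data generator

No public FT-MIR dataset exists for these specimens, so the generator is a
first-class module, not a test shim. It emulates the statistical structure
the analysis assumes:

* **Bands.** Nine Gaussian bands at the positions characteristic of dried
  mushroom powder (broad O–H/N–H near 3,350; C–H stretch at 2,928; amide
  I/II at 1,640/1,543; O–C–H and C–H bends at 1,402/1,377; C–H in-plane bend
  at 1,313; polysaccharide C–O at 1,082/1,025 cm⁻¹). Positions and widths
  are shared by all classes; species and part modulate intensities
  multiplicatively (5–15%), so classes differ in profile, not in peak
  placement — the regime the discrimination methods assume.
* **Polyphenol link.** A designated phenolic band (aromatic-ring region,
  1,515 cm⁻¹) has height exactly affine in the sample's polyphenol content
  (`height = content / 50` by default). With all noise off, band height is
  an exact function of content, which is what makes exact recovery tests of
  the regression stage possible.
* **Contents.** Per species × part, content is drawn from a normal
  distribution truncated at 0.1 mg/g, with means/SDs set to the package's
  reference summary table (e.g. *B. edulis* caps 15.10 ± 1.37 mg/g dw).
  Truncation at ~3 SD changes cell means by at most ~0.02 mg/g, well inside
  the 3-SE recovery tolerance used in the tests.
* **Artifacts.** A random quadratic baseline (amplitude 0.02 AU),
  multiplicative scatter `a·x + b` with `a ~ N(1, 0.02)`,
  `b ~ N(0, 0.01)` — the distortion MSC/SNV are designed to remove — and
  iid Gaussian detector noise (SD 0.005 AU).
* **Grid.** 4,000–400 cm⁻¹ at 2 cm⁻¹ spacing (1,801 points), the
  conventional digitisation at 4 cm⁻¹ optical resolution.
* **Reproducibility.** One master seed; every sample's randomness comes from
  a counter-indexed substream, so generation order is irrelevant and
  datasets are bit-reproducible.

Defaults are fixed once: 25 fruiting bodies per species (100 bodies, 200
spectra), the band table above, and the noise scales above. What the
generator does **not** model: Voigt line shapes, water-vapour interference,
instrument drift, replicate measurements of one specimen, and
between-specimen biological covariance beyond the content link. Passing
tests therefore demonstrate algorithmic correctness and sane statistical
behaviour under the stated structure — not performance on real instrument
data, for which the class overlap is surely less convenient.

# Pretreatments

* **Savitzky–Golay smoothing** fits a local polynomial (default order 2) in
  a sliding window; edge points are fitted on the window truncated at the
  boundary, so length is preserved. Interior points reproduce
  `signal::sgolayfilt`; the truncated-window edges are checked against
  explicit sliding least squares.
* **Derivatives** are SG-derivatives: local polynomial of degree
  `max(2, order)`, returning the fitted first or second derivative with
  respect to wavenumber. Defaults are a 15-point window with unit gap — the
  usual derivative settings for matrices of this kind; `gap > 1` gives a
  gap-segment-style variant.
* **MSC** regresses each spectrum on a reference and inverts the fitted
  affine map. The reference defaults to the *training* mean spectrum and is
  frozen at fit time (`fit_chain()`), so test spectra never influence the
  correction.
* **SNV** centres/scales each spectrum by its own mean and n−1 SD.
* **Min–max 1–2** maps each column to `[1, 2]` using training ranges;
  constant training columns map to 1.5 and test values extrapolate
  unclipped. The scope is a choice: `normalize_scope = "train"` (default,
  leak-free) computes ranges on training rows only; `"all"` reproduces
  workflows that normalise before partitioning.

Chains are written exactly as practitioners name them — `"SNV+FD+SG(9)"`,
`"No"` — applied left to right, with at most one derivative step.

# Partitioning

`kennard_stone()` is the classic deterministic max–min selection: seed with
the most distant pair, then repeatedly add the sample farthest from the
selected set, until `floor(fraction · n)` training samples are chosen
(66/34 at n = 100 with the default 2/3). Ties break to the lowest row
index; no RNG is involved. Distances are Euclidean on the matrix handed to
the model. In the prediction study one split per morphological part is
computed on the raw spectra and shared across treatment rows, so every
treatment is judged on the same test specimens; in the discrimination study
each strategy's split is computed on its own base matrix.

# Fusion

Low-level fusion concatenates the paired cap and stipe matrices
(`p_cap + p_stipe` columns). Mid-level fusion selects features per block
and concatenates the selections:

* **e** — PCA on standardised columns (correlation convention, the only one
  in which the Kaiser eigenvalue > 1 rule is meaningful), retaining
  components with eigenvalue > 1;
* **q** — PLS-DA X-scores at the component count maximising cross-validated
  Q²(cum) (first maximum on ties; `a_max` defaults to 15);
* **v** — original columns with VIP > 1, computed at the Q²-optimal
  component count.

All selectors are fit on training rows only and project test rows through
the stored weights; re-applying a fitted selector to its training rows
reproduces the stored features bit-for-bit. Because the training rows must
be known before the selectors are fitted, the mid-level strategies compute
their Kennard–Stone split on the concatenated (low-level) matrix — the spec
of the split is otherwise circular. This ordering is a design choice;
fitting selectors on all rows before splitting would leak test information
into the feature definitions.

# PLS-DA

Classes are one-hot coded; X is mean-centred (unit-variance scaling
available via `scale = "uv"`); components come from NIPALS PLS2 with
per-component deflation. Diagnostics follow the standard cumulative
definitions: `R²Y(cum) = 1 − ‖Y − Ŷ_A‖²/‖Y − Ȳ‖²` in-sample;
`Q²(cum) = 1 − PRESS(A)/SS` from venetian-blind k-fold CV (7 folds by
default; fold assignment rotates deterministically if a fold would lose a
class); RMSEE and RMSECV are per-dummy-column RMS errors averaged over
columns. VIP uses the usual weight-based formula whose mean square is 1.
Class prediction is the argmax of the predicted dummy responses, ties to
the lowest class index. At full rank the fitted values coincide with
multivariate OLS, which the tests verify. A printed-formula variant of R²
that divides by `Σ(ŷ − ȳ)²` circulates in the applied literature; it tends
to 0, not 1, for good fits and is documented but not implemented — the
standard coefficient of determination is used throughout.

# SVM

Classification is one-vs-one C-SVC and regression ε-insensitive SVR, both
RBF-kernel (`exp(−g‖x − z‖²)`), delegated to libsvm via `e1071` with
`scale = FALSE` so that normalisation stays an explicit pipeline step. The
package authors the tuning layer: `cv_fitness()` (deterministic
venetian-blind CV; accuracy % or −RMSECV), exhaustive `grid_search()` over
log₂c ∈ [−5, 21], log₂g ∈ [−21, 7] (bounds wide enough to reach optima of
order 10⁶ and 10⁻⁶; ties prefer smaller c then smaller g), and canonical
`pso_maximize()`/`pso_svm()` in (log₂c, log₂g) with constriction constants
w = 0.729, c₁ = c₂ = 1.49445, swarm 20, 100 iterations, positions clamped
to the box, fully seed-reproducible, gbest monotone. ε defaults to 0.1;
tests that demand near-exact recovery of a noiseless response use a
tighter tube, which is a modelling choice, not a constant of the method.
Correctness of the fitted duals is checked against a generic
interior-point QP solver (`kernlab::ipop`) on small problems.

# t-SNE and ellipses

`tsne()` is the exact algorithm (all-pairs affinities; sample sizes here
are ~100): per-point bandwidths solved by bisection to entropy
log₂(perplexity) within 1e-5, symmetrised joint P, Student-t Q, gradient
descent with momentum 0.5→0.8, early exaggeration 12 for the first quarter
of the iterations, learning rate 200, 1,000 iterations, perplexity 10 by
default. Group display uses mean/covariance ellipses scaled by
`sqrt(qchisq(0.95, 2))`; these are descriptive regions in embedding space,
not inferential statements.

# Quantification

The Folin–Ciocalteu bookkeeping inverts the assay chain: gallic-acid
calibration line (OLS), dilution fold `(aliquot + diluent)/aliquot`
(0.1 ml into 7.9 ml → 80), then
`content = (A − intercept)/slope × fold × extract_volume / sample_mass`
with defaults 25 ml and 0.2500 g. The fold factor excludes the Folin and
carbonate volumes on the assumption that calibration standards undergo the
same reagent additions, so those dilutions cancel. Extraction percentage is
`content/10` (mg/g → % of dry weight). Below-intercept absorbances clamp
to zero content with a warning rather than erroring. Summaries report
arithmetic mean, n−1 SD (flagged 0 for a single record), median (central
pair averaged for even n), range, and the per-species cap/stipe
bioconcentration factor `median_cap / median_stipe` (displayed at 2
decimals). Model assessment uses RMSECV/RMSEP with the relevant set's n as
divisor, standard R², `RPD = SD(test)/RMSEP`, and half-open RPD bands:
< 1.5 insufficient, [1.5, 2) low/high discrimination, [2, 2.5) rough
prediction, ≥ 2.5 excellent (2.5 rather than 3 is taken as the
"excellent" edge).

# Problem sizes and numerical choices

The validation suite runs the full study conditions — default generator,
100 fruiting bodies, 1,801-point grid — for the parameter-recovery checks
(10 seeds for the classification recoveries; a compact tuning grid with
unit-coverage of the log₂ bounds at stride 6 and 5-fold fitness, since on
these conditions the fitness surface is broad). Unit tests use a coarser
grid (16 cm⁻¹) and 24 bodies, which exercise identical code paths at a
fraction of the cost. `scripts/acceptance.R` mirrors the recovery runs at
3 seeds for the averaged accuracies. Other numerical choices: NIPALS
convergence 1e-12 on the score vector (max 1,000 iterations), components
stop early when the X residual is exhausted; PCA drops zero-variance
columns with a warning; SNV refuses constant rows; KS requires n ≥ 3;
degenerate SVR problems (response inside the tube, empty support set) fall
back to the bias-only solution.

# Known limitations

Synthetic class overlap is mild, so discrimination accuracies near 100%
are expected and recovery thresholds (≥ 95%) test the machinery rather
than forecast field performance. JCAMP-DX support covers the AFFN and
SQZ/DIF/DUP ordinate dialects, read-only; vendor binary formats are out of
scope. Only the exact t-SNE is provided. High-level (decision) fusion,
block-weighted PLS, alternative splitters (SPXY, duplex) and wavelength
selectors beyond VIP are deliberately absent.
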