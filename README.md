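# mirfuse

Multi-block mid-infrared chemometrics for mushroom authentication:
species discrimination and total-polyphenol prediction from paired
cap/stipe FT-MIR spectra.

## The problem

Wild porcini mushrooms (here four species: *Boletus edulis*,
*Leccinum rugosiceps*, *B. tomentipes*, *B. umbriniporus*) are valuable,
easy to confuse, and often sold processed, so morphology fails.
A mid-infrared absorbance spectrum of the dried powder (4,000–400 cm⁻¹)
is a chemical fingerprint, and each fruiting body yields two of them —
one per morphological part (cap and stipe). `mirfuse` implements the full
multi-block workflow a chemometrician would run on such data:

* **spectra I/O** — wide CSV matrices, a JCAMP-DX (AFFN/DIFDUP) reader,
  cap/stipe pairing by fruiting body;
* **pretreatments** — Savitzky–Golay smoothing and derivatives, MSC, SNV,
  min–max normalisation to [1, 2], composed as chain strings such as
  `"SNV+FD+SG(9)"` with train-only fitted state;
* **partitioning** — deterministic Kennard–Stone splitting (2/3 training
  by default);
* **fusion** — low-level splicing of the two blocks, and mid-level fusion
  of per-block features selected by eigenvalue > 1 (PCA), maximum Q²(cum)
  (PLS latent variables), or VIP > 1;
* **models** — NIPALS PLS2 discriminant analysis with R²Y(cum), Q²(cum),
  RMSEE, RMSECV and VIP diagnostics; RBF-SVM classification and
  ε-regression tuned by exhaustive grid search or particle swarm
  optimisation over log₂c ∈ [−5, 21], log₂g ∈ [−21, 7];
* **assessment** — RMSECV/RMSEP, R², residual predictive deviation
  (RPD = SD/RMSEP) and its interpretation bands;
* **display** — exact t-SNE with per-species 95% confidence ellipses;
* **quantification** — Folin–Ciocalteu arithmetic from 760-nm absorbance
  through gallic-acid calibration, 80-fold dilution and extraction
  bookkeeping to mg/g dry weight, per-species summaries and the cap/stipe
  bioconcentration factor (median cap / median stipe);
* **synthetic data** — a generator producing cap/stipe spectra with shared
  band positions, species-modulated intensities, scatter/baseline/noise
  artifacts and a phenolic band exactly affine in polyphenol content, so
  the whole pipeline is testable without instrument data.

## Worked example

```r
library(mirfuse)

cfg <- synthetic_config(seed = 7)   # 100 fruiting bodies, 4 species
ds  <- generate_dataset(cfg)
print(ds$caps)
#> FT-MIR spectra block: 100 spectra x 1801 wavenumbers (4000-400 cm^-1)
#>   species: B_edulis (25), B_tomentipes (25), B_umbriniporus (25), L_rugosiceps (25)
#>   parts:   cap (100)

run_discrimination(ds, strategies = c("cap", "stipe", "mid_q"),
                   svm_strategies = character(0), a_max = 8)
#> == PLS-DA discrimination ==
#>  strategy n_lv r2y_cum q2_cum rmsee rmsecv test_accuracy
#>       cap    8   1.000  0.995 0.009  0.031           100
#>     stipe    8   0.999  0.992 0.010  0.038           100
#>     mid_q    8   0.998  0.996 0.019  0.026           100

summarize_species(ds$contents)
#> B_edulis         cap    n=25   15.06 +/- 1.31  median 14.79  range 13.10-18.48  extraction 1.51%
#> B_edulis         stipe  n=25   15.59 +/- 4.42  median 15.57  range 7.01-26.52  extraction 1.56%
#> ...
#> BCF (cap/stipe): B_edulis 0.95, L_rugosiceps 1.01, B_tomentipes 1.04, B_umbriniporus 0.87
```

Each PLS-DA row reports the latent-variable count chosen by maximum
Q²(cum), the cumulative fit (R²Y) and predictivity (Q²) of the training
set, the in-sample and cross-validated errors, and the test-set accuracy
from the Kennard–Stone split. The content summary gives per-cell mean ± SD
(mg/g dry weight, gallic-acid equivalents), median, range, extraction
percentage (mean/10), and the per-species cap/stipe bioconcentration
factor. On this synthetic run every strategy reaches 100% test accuracy —
the generator's class overlap is mild by design; the numbers exercise the
machinery rather than forecast field performance.

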