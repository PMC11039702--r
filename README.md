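# brgdgt

Branched GDGT (brGDGT) lipid proxies for benthic oxygen uptake in marine
sediments.

## What this is for

Branched glycerol dialkyl glycerol tetraethers are bacterial membrane
lipids preserved in sediments. In deep-sea settings they are produced in
situ by benthic bacteria, and the isomerization/methylation degree of the
acyclic compounds tracks the diffusive oxygen uptake (DOU) of the
sediment — the key metric of benthic microbial diagenetic activity and
organic-carbon degradation. `brgdgt` is for organic geochemists and
paleoceanographers who want to go from an HPLC-APCI-MS peak table to DOU
estimates and source diagnostics with auditable intermediate steps.

At its core is the IMBT index over the five acyclic brGDGTs,

```
IMBT = −log10[(IIIa′ + IIa′) / (IIIa + IIIa′ + IIa + IIa′ + Ia)]
```

and its log-linear transfer function to DOU (µmol m⁻² d⁻¹),

```
log10(DOU) = 1.5 · IMBT + 2.1        (r = 0.88, RMSE = 400 µmol m⁻² d⁻¹)
```

shipped as a constant model and refittable from user data by ordinary
least squares. Around it sit:

* **Quantification** — internal-standard (C46-GTGT) concentrations in
  ng g⁻¹ dry sediment, optional TOC normalization and response factors;
* **Index suite** — IMBT, BIT, ΣIIIa/ΣIIa, IR, MBT′5ME, CBT5ME, ternary
  (tetra/penta/hexa) coordinates, plus a registry for user indexes;
* **Source attribution** — BIT and ΣIIIa/ΣIIa threshold classifiers with
  a transparent combined decision table;
* **Statistics** — Bray–Curtis dissimilarities, PCoA with negative-
  eigenvalue reporting, Pearson correlation maps (DOU on a log scale),
  one-way ANOVA;
* **Synthetic data** — a generator that inverts the calibration into
  study-like surveys (cores × horizons, compositional noise, covariates,
  idealized oxygen microprofiles) so the full pipeline is testable.

## Worked example

```r
library(brgdgt)

# a synthetic survey: 13 cores x 5 horizons along a DOU gradient
d   <- generate_dataset(synthetic_config(), seed = 10)
idx <- compute_indices(d$samples)          # accepts areas, conc or fractions
head(idx[, c("sample_id", "imbt", "bit", "siiia_siia", "ir", "mbt5me")], 3)
#>   sample_id      imbt        bit siiia_siia        ir    mbt5me
#> 1   C01-H01 0.3561955 0.05275966  1.2000593 0.5685526 0.5312951
#> 2   C01-H02 0.3306631 0.02410867  1.0418658 0.5790273 0.3996220
#> 3   C01-H03 0.3721359 0.12179372  0.7504722 0.5854256 0.5004800

fit <- fit_dou_calibration(idx$imbt, d$samples$dou)
fit
#> IMBT-DOU transfer function
#>   log10(DOU) = 2.123 + 1.404 * IMBT
#>   r = 0.7877, n = 65, RMSE = 175.5 umol m-2 d-1 (0.1854 log10 units)
#>   applicable DOU range: 100-2000 umol m-2 d-1

predict(fit, imbt = c(0.2, 0.6), interval = "rmse")
#>   imbt      dou      lwr       upr extrapolated
#> 1  0.2 253.5618 165.4685  388.5548        FALSE
#> 2  0.6 924.2104 603.1182 1416.2480        FALSE

attribute_source(idx$bit, idx$siiia_siia)[1:3, c("bit_class", "combined_call")]
#>     bit_class                         combined_call
#> 1 open-marine marine, minimal terrestrial influence
#> 2 open-marine marine, minimal terrestrial influence
#> 3 open-marine  marine, slight terrestrial influence

invert_dou_to_fraction(c(100, 500, 2000))
#>    dou        imbt     f_raw         f truncated
#> 1  100 -0.06666667 1.1659144 1.0000000      TRUE
#> 2  500  0.39931334 0.3987371 0.3987371     FALSE
#> 3 2000  0.80068666 0.1582389 0.1582389     FALSE
```

Reading the output: each sample's IMBT feeds the transfer function, whose
refit on this noisy synthetic survey lands near the generating truth
(slope 1.5, intercept 2.1). Predictions carry back-transformed ±1-RMSE
bands and an extrapolation flag. Low BIT plus a high ΣIIIa/ΣIIa ratio
reads as in-situ marine production. The inversion shows the 6-methyl
share of the acyclic compounds implied by a DOU value: at 100 µmol m⁻²
d⁻¹ the raw value exceeds 1 and is capped at 100%; at 2000 it is 15.8%.

A thin CLI over the same functions is installed at
`system.file("exec", "gdgt", package = "brgdgt")`
(`gdgt quantify|indices|predict-dou|attribute|calibrate|simulate`).

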