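# hpflux

Simulation, reconstruction and cohort analysis for hyperpolarized
[1-¹³C]pyruvate chemical-shift imaging (CSI) of brain tumours.

Tumours shift metabolism from oxidative phosphorylation (OXPHOS) toward
glycolysis, overproducing lactate (the Warburg effect). Hyperpolarized
[1-¹³C]pyruvate MRSI watches that balance in vivo: injected pyruvate is
converted to ¹³C-lactate (glycolysis) and ¹³C-bicarbonate (OXPHOS), and
the **Lac/Bic signal ratio** is a tissue-level Warburg index. In
glioma-bearing rats treated with an anti-VEGF antibody, the *direction*
of the tumour Lac/Bic change 48 hours after dosing predicts long-term
survival: responders normalize their metabolism (Lac/Bic falls),
non-responders do not. This package makes the whole analysis
exercisable end to end with no external data, for methodologists who
want to probe each stage of such a study:

- **kinetics** — a calibrated precursor–product model
  (`simulateDynamics`) with gamma-variate input and RF-sampling loss,
  reproducing the pyruvate/lactate/bicarbonate peak times (≈20/28/33 s)
  and the selection of the 19 s imaging window (`selectWindow`);
- **phantom** — a two-compartment digital rat brain (`makePhantom`),
  complex phase-encoded k-space synthesis (`synthesizeCsi`, 16×16
  encodes, 64 mm FOV, 5000 Hz × 256 samples), dynamic FID series, and a
  cohort generator (`makeCohort`) with the study's group structure
  (6 deceased / 7 survivors / 12 controls) and survival distribution;
- **csi_recon** — 15 Hz Lorentzian apodization, ×4 Fourier
  interpolation in space (k-space zero-padding) and frequency (FID
  zero-filling), zero-order phase correction and absorption-mode peak
  integration (`reconstructMaps`);
- **quantify** — ROI metabolite ratios (`roiRatios`), response
  classification by the sign of the 48-h Lac/Bic change
  (`classifyResponse`), planimetric tumour volumes and growth rates;
- **cohort_stats** — exact Clopper–Pearson binomial intervals,
  sensitivity/specificity, Wilcoxon signed-rank tests (exact under
  ties), Kaplan–Meier curves, the log-rank test, and cohort summary
  tables;
- **pipeline** — `runExperiment()` chains everything into one seeded,
  reproducible run with CSV/NIfTI/JSON artifacts.

## Worked example

```r
library(hpflux)

# dynamic timing experiment: when do the metabolites peak, and where
# should the 19 s imaging window start?
curves <- simulateDynamics(kineticParams(), tEnd = 90, dt = 0.1)
peakTimes(curves)
#>  pyr  lac  bic
#> 20.1 27.7 32.7
selectWindow(curves, duration = 19)
#> [1] 20.4

# one imaging session: phantom -> k-space -> metabolite maps -> ROI ratios
ph    <- makePhantom(phantomSpec(seed = 42))
ph
#> Phantom: 16x16 grid, 5 tumor / 26 normal voxels
#>   truth Lac/Bic: tumor 9.83, normal 6.07
ds    <- synthesizeCsi(ph, acqParams(),
                       noiseSd = calibrateNoiseSd(ph, snr = 500), seed = 42)
maps  <- reconstructMaps(ds)
masks <- tissueMasks(ph)
roiRatios(maps, masks$tumor)
#> RatioSet (sum over 35 voxels, 0 masked): Lac/Pyr 0.451, Bic/Pyr 0.046, Lac/Bic 9.77
roiRatios(maps, masks$normal)
#> RatioSet (sum over 162 voxels, 0 masked): Lac/Pyr 0.492, Bic/Pyr 0.091, Lac/Bic 5.41
```

The metabolites peak at 20.1, 27.7 and 32.7 s after the start of
injection, and the window maximizing lactate + bicarbonate signal
starts 20.4 s in — the protocol timing. The reconstructed tumour
Lac/Bic (9.77) recovers the phantom's ground truth (9.83) within 1%,
and the normal brain (5.41 vs 6.07) sits within the documented
cross-talk bound; the tumour reads roughly 1.8× the contralateral
brain, the contrast the response biomarker rides on.

Exact binomial intervals for the small-cohort classifier performance
(6/6 sensitivity, 5/7 specificity at 95%):

```r
round(clopperPearson(6, 6, 0.95) * 100, 1)
#> lower upper
#>  54.1 100.0
round(clopperPearson(5, 7, 0.95) * 100, 1)
#> lower upper
#>  29.0  96.3
```

A full simulated study — cohort generation, 50 imaging sessions,
reconstruction, classification, survival analysis — is one call:

```r
report <- runExperiment(experimentConfig(masterSeed = 1), "results/exp1")
report$logrank$p_value    # log-rank p for increased vs decreased Lac/Bic
```

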