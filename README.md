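# nigrascan

Quantification of the substantia nigra (SN) and locus coeruleus (LC) from
neuromelanin- and iron-sensitive MRI, with the cohort statistics used to
relate those measures to striatal dopamine-transporter (DAT) binding in
Parkinson's disease (PD).

Neuromelanin-sensitive MRI shows NM-rich nuclei as hyperintense; their
volume and contrast shrink as dopaminergic and noradrenergic neurons are
lost. The package implements the standard threshold-based measurement
chain on such images, a two-point R2\* relaxometry fit for iron-sensitive
imaging, ROI sampling of susceptibility maps, and the group-level
statistical layer — everything driven and validated by a synthetic phantom
and cohort generator with exact ground truth, since no patient data ship
with the package.

## What it computes

**Neuromelanin chain** (`nmPhantom()`, `regionStats()`, `binaryMap()`,
`segmentSN()`, `cnrSN()`, `locateLC()`, `cnrLC()`, `measureNM()`):

- Background reference statistics MN_CC, SD_CC from circular 4 mm ROIs in
  the cerebral crus, per slice and side (population SD).
- Binary map of voxels with intensity **> MN_CC + 3 × SD_CC** (strict
  inequality), restricted to a declared mesencephalic search region.
- SN segmentation: largest 8-connected in-plane component per slice and
  side, stacked over the best four consecutive slices;
  **volume = voxel count × voxel volume**.
- **CNR_SN = (MN_SN − MN_CC) / SD_CC** per slice, averaged (unweighted)
  across slices.
- LC localisation as the highest-intensity voxel adjacent to the fourth
  ventricle (LC_MAX); LC intensity as the mean of LC_MAX and its four
  in-plane abutting voxels; **CNR_LC = (MN_LC − MN_TG) / SD_TG** against a
  6 mm pontine-tegmentum ROI, averaged over three slices.
- `%CNR` normalisation to the healthy-control median, asymmetry index
  **AI = |(ipsi − contra)/(ipsi + contra)| × 200**, and four-repeat
  averaging with re-placed (jittered) reference ROIs.

**Iron chain** (`dualEchoPhantom()`, `fitR2Star()`, `sampleSnRois()`):

- Voxelwise **R2\* = ln(S(TE1)/S(TE2)) / (TE2 − TE1)** from a dual-echo
  magnitude pair (exact log-linear fit for two echoes), apparent negative
  rates clamped to zero and flagged.
- Unweighted SN-ROI means of R2\* and susceptibility maps over up to six
  slices, with two-repeat averaging.

**Cohort statistics** (`groupCompare()`, `spearmanBattery()`,
`rocAnalysis()`, `clopperPearson()`, `iccReliability()`, `predictDAT()`):
Mann-Whitney U (exact enumeration at small n), Spearman batteries with
Benjamini-Hochberg FDR, empirical ROC with AUC, the three named cut-offs
(100% sensitivity, 100% specificity, best accuracy) with exact
Clopper-Pearson 95% intervals, ICC(2,1) reliability, and least-squares DAT
prediction with PRESS.

## Worked example

```r
library(nigrascan)

# a noisy phantom whose true SN volume and contrast are known
ph <- nmPhantom(snVolume = c(236, 236), snCNR = c(4.28, 4.28),
                noiseSD = 10, seed = 42)
m <- measureNM(ph$volume, ph$config, repeats = 4, seed = 7)
m$summary
#>    side    measure    mean       sd
#> 1  left volume_mm3 201.000 2.669270
#> 2  left     cnr_sn   4.245 0.038798
#> 3  left     cnr_lc   2.616 0.009708
#> 4 right volume_mm3 222.562 3.261997
#> 5 right     cnr_sn   4.640 0.153248
#> 6 right     cnr_lc   2.598 0.043703
```

The recovered volumes (201–223 mm³ against a 236 mm³ truth) show the
expected behaviour of threshold segmentation at realistic noise: voxels
whose noisy intensity dips below MN + 3 SD are lost, so volumes are
slightly conservative while CNR_SN is recovered closely; the repeat SD
(under 2% of the mean) is the intra-rater variability induced by ROI
re-placement.

```r
# ROC of contralateral SN volume on a large synthetic cohort
coh <- simulateCohort(nPD = 5000, nHC = 5000, seed = 1)
rocAnalysis(coh, "sn_volume_contra", direction = "lower")
#> RocResult: AUC = 0.9375 (5000 positive vs 5000 negative, lower tail)
#>   sens100  cut-off 426.5: sens 100.0% (99.93-100.00), spec 5.5% ...
#>   spec100  cut-off 156.6: sens 5.8% ..., spec 100.0% (99.93-100.00) ...
#>   best     cut-off 294.1: sens 88.9% ..., spec 83.4% ..., acc 86.1%
```

With group distributions N(236, 50²) for PD and N(344, 51²) for controls,
the accuracy-maximising cut-off lands near 292–294 mm³ with sensitivity
≈ 89%, specificity ≈ 83–84% and accuracy ≈ 86%.

An end-to-end simulated run (per-subject phantoms → measurement → cohort
table → statistics, with a manifest) is one call:

```r
cfg <- readRunConfig(system.file("extdata", "demo_run.yaml",
                                 package = "nigrascan"))
res <- runPipeline(cfg, outDir = "demo_out")
```

A command-line front end with the same subcommands
(`phantom`, `nm`, `iron`, `stats`, `run`, `accept`) is installed at
`system.file("scripts", "nigrascan.R", package = "nigrascan")`.

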