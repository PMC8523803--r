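# cardiofib

Microscopic cardiac fibrosis quantification coupled to image-based bidomain
simulation of ventricular conduction.

End-stage heart failure remodels ventricular tissue in etiology-specific
ways: ischemic cardiomyopathy (IC) tends to produce large patchy or compact
fibrotic regions, nonischemic cardiomyopathy (NIC) a more diffuse,
interstitial expansion of extracellular space. `cardiofib` is for
computational electrophysiologists and quantitative histologists who want to
(i) quantify that remodeling from segmented microscopy masks, (ii) classify
etiology from the resulting statistics, and (iii) propagate the measured
microstructure into tissue-scale conduction simulations.

The pipeline:

1. **Fibrosis quantification** — from registered binary masks (extracellular
   space, fibroblasts, myofibroblasts), the composition fractions
   `V_nm = V_e + V_f + V_mf`, the fibrosis measure
   `V_nm − mean(V_nm, donors)`, the intra-subject heterogeneity
   `σ_intra` = sample SD of `V_nm` over 50-µm tiles, and moment-ellipse
   geometry of fibrotic patches (8-connected components > 150 µm²).
2. **Etiology classification** — restarted k-means (50 restarts, lowest
   within-cluster sum of squares) on fibrosis features; the lower centroid is
   labeled NIC; accuracy/sensitivity/specificity/PPV/NPV with IC positive.
3. **Bidomain conduction** — images downsampled to 50-µm elements carrying
   fraction-scaled anisotropic conductivities (`σ_myo = V_myo σ̄_myo`,
   `σ_e = V_e σ̄_e`, anisotropy 10 and 2) and myocyte density
   `β_myo = V_myo / 41,073 µm³`; the coupled elliptic/parabolic bidomain
   system with a ten Tusscher 2006 human ventricular myocyte membrane
   (compiled, lookup-table accelerated) is advanced by operator splitting
   at dt = 1e-8 s; the protocol clamps one edge at 1 mV for 2 ms after 2 ms
   equilibration.
4. **CV vector analysis** — activation = time of maximal upstroke within
   (−60, 0) mV; at L-shaped grid triplets,
   `|CV| = l/√(tx² + ty²)` with a direction-specific tilt angle from the
   stimulus normal; block detection, boundary-effect errors against a
   homogeneously extended 5-mm domain, and passive space constants
   `λ = √((R/β)·σ_myo σ_e/(σ_myo+σ_e))`.
5. **Statistics** — Welch t, one-way ANOVA, variance-ratio F tests, and
   linear regressions of CV summaries on the fibrosis measures.

A seeded synthetic-tissue generator (`generate_tissue()`,
`generate_cohort()`) emulates donor / NIC / IC composition, pattern and
heterogeneity at the segmented-mask level, so the whole chain runs and is
tested without any imaging data.

## Worked example

```r
library(cardiofib)

# a synthetic cohort: 5 donors, 8 NIC, 8 IC, 1 mm^2 each
cohort <- generate_cohort(5, 8, 8, seed = 20211005,
                          image_edge_um = 1000, pixel_size_nm = 1000)
quant <- quantify_cohort(cohort)
hf <- quant[quant$group != "donor", ]
feature_comparison(hf, hf$group,
                   feature_sets = list(sigma_intra = "sigma_intra",
                                       V_nm = "V_nm"))
```

```
     features accuracy sensitivity specificity   ppv       npv    threshold
  sigma_intra     87.5        87.5        87.5 0.875 0.8750000 2.010803e+01
         V_nm     75.0        50.0       100.0 1.000 0.6666667 5.318012e-01
```

Clustering on the heterogeneity statistic separates IC from NIC at 87.5%
accuracy with a decision threshold of `σ_intra` ≈ 20.1%, while the mean
non-myocyte fraction alone reaches 75% — heterogeneity, not amount, of
fibrosis carries the etiology signal.

```r
# donor-mean tissue: homogeneous mesh, longitudinal stimulus, full protocol
mesh <- homogeneous_mesh(V_e = 0.201, V_f = 0.01, V_mf = 0.01)
rec  <- simulate_bidomain(mesh, simulation_config(dt = 1e-8,
                                                  stimulus_edge = "left"))
cv   <- cv_vectors(activation_map(rec))
median(cv$magnitude_m_per_s)   # 0.3665 m/s longitudinal, tilt 0 deg
```

The numbered scripts under `analysis/` run the full study workflow
(generate cohort → quantify → classify → simulate conduction on all
subjects → CV statistics), writing tables under `results/`.

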