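# myoseg

MRI-based quantification of skeletal muscle composition — contractile
tissue, intramuscular adipose tissue (IMAT) and intramuscular connective
tissue (IMCT) — and of intrinsic (specific) plantarflexor strength, for
the triceps surae complex (gastrocnemius medialis, GM; gastrocnemius
lateralis, GL; soleus, SOL). The package targets researchers studying
sarcopenia and myosteatosis who need per-muscle tissue volumes and
specific-force estimates from multi-contrast MR acquisitions, plus a fully
synthetic phantom so every stage can be validated without scan data.

## What it computes

**IMAT** is segmented from water-saturated gradient-echo volumes, where
muscle and connective tissue are suppressed and fat is bright. After
polynomial bias-field correction and cropping to the muscle masks, each
slice's in-mask intensities are clustered by three-cluster fuzzy C-means
(FCM, fuzziness m = 2, ≤ 100 iterations, convergence 1e-5) and thresholded
at the membership valley between the two brightest clusters — for scalar
FCM, the midpoint of their centroids:

    u_ik = 1 / Σ_j (|x_k − v_i| / |x_k − v_j|)^(2/(m−1)),
    threshold = (v_2 + v_3) / 2

**IMCT** comes from a dual-echo ultra-short echo-time (UTE) pair
(TE1 = 8 µs, TE2 = 2.6 ms). The mono-exponential decay
S(TE) = S0·exp(−TE/T2*) gives per voxel

    T2* = (TE2 − TE1) / ln(M1 / M2)

Voxels with T2* < 8 ms (muscle ≈ 14–19 ms, IMAT ≈ 4–6 ms,
IMCT ≈ 2–4 ms) are non-muscle; removing the IMAT voxels yields the
fat-free IMCT map. A 3×3×3 neighborhood statistic quantifies how closely
fat tracks the connective tissue.

**Strength**: tendon force F = T/MA (MVC torque over the Achilles moment
arm, obtained from a Reuleaux-style circle fit to the talus), per-muscle
PCSA = Vol·cos θ / Lf summed over the triceps surae, specific force 1 =
F/PCSA, and specific force 2 using the PCSA of the contractile volume
(total − IMAT − IMCT). Group contrasts use Shapiro–Wilk-gated t / Mann–
Whitney tests with effect sizes r = √(t²/(t²+df)) or |Z|/√N, and the
symmetrized percent difference 100·|a−b|/((a+b)/2).

## Worked example

```r
library(myoseg)

spec <- phantom_spec(seed = 42)             # old-like synthetic leg
res  <- run_pipeline(default_run_config("demo_out", seed = 42,
                                        phantom = spec, verbose = FALSE))
res$composition
#>   muscle total_cm3 imat_cm3 imat_pct imct_cm3 imct_pct contractile_cm3
#> 1     gm     60.93    4.939    8.106    8.156    13.39           47.84
#> 2     gl     45.45    3.679    8.094    6.154    13.54           35.62
#> 3    sol    203.67   16.492    8.098       NA       NA          187.18
#> 4     ts    310.05   25.110    8.099   14.310       NA          270.63
```

The phantom was built with 8.1 % IMAT per muscle; the pipeline recovers
8.10 % on the triceps-surae row at the default 5 % noise, and IMCT is
reported for the gastrocnemius heads only (the short-T2* threshold is
validated there). `res$strength` carries the force chain for the same
subject:

```r
res$strength$tendon_force_n     # 1400  (70 Nm / 0.05 m)
res$strength$specific_force_1   # 26.7  N/cm^2 (F / PCSA)
res$strength$specific_force_2   # 30.6  N/cm^2 (F / corrected PCSA)
```

Cohort-level comparison on a synthetic young/old sample:

```r
co  <- cohort_strength(generate_cohort(5, 5, seed = 1))
summary_table(co, variables = c("vol_gm_cm3", "tendon_force_n",
                                "specific_force_1"))
#>         variable mean_a   sd_a mean_b    sd_b         test statistic p_value effect_size_r percent_difference
#> 1     vol_gm_cm3  162.6  31.93 112.98  19.009            t      2.99 0.01742         0.726               36.0
#> 2 tendon_force_n 1568.5 391.11 921.49 115.028 mann_whitney     24.00 0.01587         0.760               52.0
#> 3 specific_force_1  17.0   3.63   8.96   0.882            t      4.83 0.00130         0.863               62.2
```

Each row reports group means ± SD, the gated test that was used, the
two-tailed p value, the effect size r and the symmetrized percent
difference of the group means.

See `vignettes/muscle-composition.Rmd` for the full account of the models,
parameter defaults, and what phantom-based validation does and does not
demonstrate.

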