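# thermodigest

Analysis toolkit for thermophilic, semi-continuously fed anaerobic digesters
converting lignocellulosic feedstock (e.g. milled switchgrass) to biogas, and
for the metagenome-assembled genome bins recovered from such reactors.

It is written for two audiences that usually meet in the same study:

* **reactor engineers** who measure fractional carbohydrate solubilization
  (FCS) at several residence times (RT) and want a descriptive rate law,
  steady-state predictions, and mass/COD balance closure;
* **microbiome analysts** who bin metagenomes sampled from the same
  reactors and need to recognise the *same organism* across samples, filter
  bins on quality, and profile each tracked organism's CAZymes and
  metabolic marker pathways.

## The models and algorithms

**Solubilization kinetics.** Fractional carbohydrate solubilization is
`FCS = (m_in − m_out)/m_in` on a monomer-equivalent basis. At steady state
each residence time contributes one point `C = C0 (1 − FCS)`,
`r = C0 · FCS / RT`, where `C0` is the carbohydrate concentration entering
the reactor. The package fits the recalcitrant-fraction first-order rate law

    r = k (C − C0 · f_r)

by ordinary least squares: `k` (1/day) is the first-order rate constant in
*accessible* substrate and `f_r` is the extrapolated fraction of entering
carbohydrate that remains unconverted at infinite residence time. The
steady-state closed form under continuous washout,
`FCS(RT) = (1 − f_r) · kRT/(1 + kRT)`, gives predictions, and a two-pool
semi-continuous reactor simulator (discrete feed events, first-order decay
of the accessible pool) generates synthetic data under the same feeding
protocol used at the bench (one-tenth volume replaced, ten times per RT).

**Cross-sample bin matching.** Every pair of bins from different metagenome
samples is compared by protein best hits: the fraction of one bin's
proteins whose best local-alignment identity in the other bin exceeds 90%.
Two bins are called the same organism when either directional proportion
reaches 70% (so a complete bin matches its own low-coverage fragment).
Candidate protein pairs come from a lossless exact 8-mer prefilter; scoring
is exact Smith–Waterman (BLOSUM62, affine gaps) with identity normalised by
the shorter sequence length. Edges touching bins with contamination > 20%
or completeness < 40% are removed, bins with fewer than three surviving
edges are pruned iteratively, and connected components spanning more than
three samples become *organism tracks* with ANI-based species labels,
coverage-share abundances, majority-rule consensus markers, CAZyme
inventories and pathway-completeness calls.

**Ground-truthed synthetic data.** Seeded generators produce reactor
datasets obeying the rate law, and multi-sample genome/bin communities with
controlled completeness, contamination, divergence and marker profiles —
every pipeline stage is validated against this truth, including the
100%-mapping-accuracy benchmark.

## Worked example

```r
library(thermodigest)

# Feed: mid-season switchgrass, quantitative-saccharification composition
sw <- feedstock_composition(
  glucan_frac = 0.306, xylan_frac = 0.229, arabinan_frac = 0.0407,
  moisture_frac = 0.0605, ash_frac = 0.0592, cod_per_gram = 1.22
)
c0 <- feed_carbohydrate_concentration(sw, solids_loading = 30)
#> 17.271  (g monomer-equivalent / L)

# Steady-state FCS means at four residence times
obs <- tibble::tibble(
  rt_days   = c(20, 10, 5, 3.3),
  fcs_total = c(0.711, 0.654, 0.581, 0.538)
)
fit <- obs |>
  steady_state_points(c0 = 17.3) |>
  fit_recalcitrant_first_order(c0 = 17.3)
fit
#> Recalcitrant-fraction first-order solubilization fit
#>   r = k (C - C0 fr),  C0 = 17.3 g/L,  n = 4 points
#>   k   = 0.725 +/- 0.073 1/day
#>   fr  = 24.8 +/- 1.5 %
#>   R^2 = 0.9801
predict_steady_state_fcs(fit, 20)
#> 0.7035426
```

`k ≈ 0.73 day⁻¹` says the accessible carbohydrate pool turns over in less
than a day and a half; `f_r ≈ 25%` says a quarter of the fed carbohydrate
is recalcitrant no matter how long it stays in the reactor; the closed form
predicts 70% solubilization at a 20-day residence time.

Bin tracking on a ground-truthed synthetic community:

```r
sc   <- community_scenario(seed = 1)        # 10 genomes x 4 samples
smp  <- sample_bins(generate_community(sc)) # bins + QC + truth
out  <- run_pipeline(smp$bins, smp$qc,
                     annotations = smp$annotations, coverage = smp$coverage)
mapping_accuracy(out$edges, smp$truth)$accuracy
#> 100
```

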