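# iekappa

Information-equilibrium analysis of single-channel EEG voltage time
series. The package estimates, at each instant of a recording and for a
grid of time intervals, the **information-transfer constant**

κ(t; Δt) = ln|V(t + Δt) − V(t)| / ln Δt   (Δt in seconds, natural logs),

the exponent a local power law |ΔV| ∼ Δt^κ would need to produce the
observed voltage increment. Segments (one-minute epochs of a
polysomnogram, typically) are summarized by the mean κ, the fraction of
low-information-transfer instants (κ < 0.2 at the sampling-rate lag), and
the periodicity of the κ-value distribution, measured as the
significance-thresholded normalized Lomb-Scargle power of its kernel
density estimate. States of consciousness — waking vs sleep stages — are
then compared segment-wise with a repeated-measures ANOVA (state and
subject fixed effects, segments as replicates) under Bonferroni
correction.

It is aimed at researchers working with sleep EEG or other nonstationary
voltage signals who want a probability-free, power-law-flavoured feature
set alongside spectral analysis. The package includes:

* readers for EDF/EDF+ and a `time_s,voltage` CSV dialect, hypnogram-style
  TSV annotations, and epoch segmentation (`read_recording`,
  `segment_recording`);
* the κ estimators (`kappa_series`, `kappa_summary`,
  `multiscale_summaries`, `estimate_hurst`);
* the distribution-periodicity chain (`estimate_pdf`, `lomb_scargle`,
  `significant_power`, `kappa_periodicity`);
* cohort statistics (`cohort_table`, `rm_anova`, `bonferroni`,
  `compare_all`);
* a synthetic-signal generator with analytic ground truth — ramps,
  fractional Brownian motion via exact circulant embedding,
  power-law-increment signals, and multi-subject cohorts
  (`synth_spec`, `generate_segment`, `cohort_spec`, `generate_cohort`);
* a CLI (`inst/cli/iekappa.R`) with `simulate`, `kappa`, `periodicity`
  and `compare` subcommands.

## Worked example

One minute of fractional Brownian motion with Hurst exponent 0.5 — a
surrogate whose expected κ is known in closed form — analyzed at the four
default time scales:

```r
library(iekappa)
seg <- generate_segment(synth_spec("fbm", hurst = 0.5, sigma = 0.1, seed = 42),
                        subject_id = "s01", state = "stage3")
multiscale_summaries(seg)
#>   subject_id  state segment_id delta_t_s kappa_avg low_it_fraction n_values
#> 1        s01 stage3     seg001     0.004     1.028               0    14999
#> 2        s01 stage3     seg001     0.040     1.414               0    14990
#> 3        s01 stage3     seg001     0.400     3.701               0    14900
#> 4        s01 stage3     seg001     4.000    -1.557               1    14000
```

`kappa_avg` falls out of the fBm law E[κ] = H + (ln σ + E ln|Z|)/ln Δt: at
Δt = 0.004 s the predicted value is 0.5 + (ln 0.1 − 0.635)/ln 0.004 ≈ 1.03,
matching the printed 1.028. The sign flip at Δt = 4 s happens because
ln Δt turns positive while the voltage increments stay below one unit; at
that scale every κ is negative, so the low-IT fraction saturates at 1.

A ten-subject synthetic cohort contrasting a waking-like (H = 0.30) and a
deep-sleep-like (H = 0.50) state, eight one-minute segments each, analyzed
end to end:

```r
cs <- cohort_spec(
  n_subjects = 10, segments_per_state = 8,
  states = list(waking = synth_spec("fbm", hurst = 0.30, sigma = 0.1),
                stage3 = synth_spec("fbm", hurst = 0.50, sigma = 0.1)),
  subject_effect_sd = 0.03, seed = 1)
gen <- generate_cohort(cs)
sums <- do.call(rbind, lapply(gen$segments, function(s)
  multiscale_summaries(s, delta_ts = c(0.004, 4))))
compare_all(cohort_table(sums), "waking", metrics = "kappa_avg")
#>   state_b delta_t_s  mean_a mean_b   f_stat df_den p_adjusted
#> 1  stage3     0.004  0.8362  1.036 627817.5    149 1.180e-271
#> 2  stage3     4.000 -1.8339 -1.618    138.8    149  9.323e-23
```

The mean-κ contrast at the sampling-rate lag (1.036 − 0.836 ≈ 0.20) is the
Hurst difference of the two states, recovered by the pipeline; both scales
separate the states decisively after Bonferroni correction across the time
scales.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/iekappa.R simulate --out_dir demo --seed 1
Rscript inst/cli/iekappa.R kappa --input demo/s01_waking.csv \
    --annotation demo/s01_waking.tsv --out_dir demo
```

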