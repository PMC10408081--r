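# cetuxcea

Cost-utility and budget-impact modelling of first-line cetuximab added to
FOLFOX or FOLFIRI chemotherapy for KRAS wild-type metastatic colorectal
cancer (mCRC), in the Indonesian setting.

Anti-EGFR therapy with cetuximab is covered by Indonesia's national health
insurance for confirmed KRAS wild-type mCRC, at a drug cost roughly three
times the chemotherapy backbone. This package implements, as tested and
reusable R code, the health-economic evaluation behind that coverage
question: does the modest progression-free benefit of adding cetuximab
justify its price, and what would continued coverage cost the payer?

It is written for health-economics and HTA analysts who want to rerun,
stress or adapt the evaluation: every published model input ships as a
structured configuration, every modelling assumption is a setting, and a
synthetic-data module stands in for the study's primary data (patient
interviews, trial tables, claims inputs) so the full pipeline runs
end-to-end with nothing to download.

## The model

A three-state Markov cohort model over the states *progression-free*
(stable, on first-line therapy), *progressive* (on second-line therapy) and
*dead*, with no remission path. A cohort enters progression-free and is
propagated in monthly cycles over a 30-year (lifetime) horizon with
half-cycle correction. Transition probabilities are time-banded:

- stable→stable: four quarterly bands per strategy (months 1–12),
- stable→death: five yearly background-mortality bands (years 1–5),
- progressive→death: six half-yearly bands (months 1–36), shared across
  strategies by default because every arm's second line is the same proxy
  regimen.

Banded probabilities are converted to the cycle length with the
constant-rate formula `p' = 1 − (1 − p)^(t'/t)`, and the last band is held
beyond its window. State costs (direct medical, direct non-medical,
indirect, drug — all 2023 IDR) accrue per month of state occupancy; the
cetuximab acquisition cost accrues only in the stable state and only for
the first 12 months. Costs and outcomes are discounted at 3%/year.

Decision measures are the standard ones: per strategy lifetime cost,
life-years (LY) and quality-adjusted life-years (QALY, utilities 0.798
stable / 0.443 progressive); the incremental cost-effectiveness ratio
(ICER) `ΔC/ΔE` versus the FOLFIRI reference; and the net monetary benefit
`NMB = λ·QALY − cost` at willingness-to-pay `λ` (packaged: IDR 215 million
per QALY). Uncertainty is handled by one-way deterministic sensitivity
analysis (tornado, bounds at mean ± 1.96 SE) and probabilistic sensitivity
analysis (5000 Monte-Carlo draws of every parameter from moment-fitted
beta/gamma/lognormal distributions) summarized as a cost-effectiveness
acceptability curve. A five-year payer-perspective budget-impact projection
compares coverage with and without cetuximab, with mortality dropout taken
from the same Markov model. A small fixed-effect network-meta-analysis
module reproduces the evidence-synthesis machinery (log-RR contrasts,
inverse-variance pooling, Bucher indirect comparisons) on synthetic trial
tables.

## Worked example

```r
library(cetuxcea)
cfg <- load_model_config()              # packaged published inputs
bc  <- run_base_case(cfg)               # societal perspective
ce  <- incremental_analysis(bc, "FOLFIRI")
ce[, c("strategy", "cost", "ly", "qaly", "icer_qaly")]
#>       strategy      cost    ly  qaly icer_qaly
#>         FOLFOX 6.492e+08 2.167 1.086        NA
#>        FOLFIRI 6.418e+08 2.170 1.090        NA
#>   CETUX_FOLFOX 1.003e+09 2.325 1.235 2.480e+09
#>  CETUX_FOLFIRI 9.283e+08 2.263 1.179 3.195e+09
```

Reading: the chemotherapy-only strategies are economically
indistinguishable (FOLFOX gains no QALYs over FOLFIRI, so its ICER is
undefined). Adding cetuximab buys about 2 incremental months of life
(cetuximab+FOLFOX vs FOLFIRI) and about 1 quality-adjusted month
(cetuximab+FOLFIRI vs FOLFIRI) for roughly IDR 290–360 million extra —
ICERs of IDR 2.5–3.2 billion per QALY, more than tenfold the IDR 215
million/QALY threshold, so both cetuximab strategies are classified not
cost-effective. The same conclusion holds across the PSA
(`run_psa(cfg, 5000, seed = 1)` then `compute_ceac()`: the cetuximab
strategies are optimal in ~0% of iterations at the threshold) and the
payer projection (`run_bia(cfg)`: IDR ~1.31 vs ~0.59 trillion over five
years with vs without cetuximab coverage).

`run_full_analysis(NULL, "out")` chains all stages and writes
`ce_table.csv`, per-strategy traces, `tornado.csv`, `psa_outcomes.csv`,
`ceac.csv`, `bia.csv`, a rendered `report.md` and a reproducibility
manifest.

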