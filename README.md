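# hetfx

Heterogeneous treatment effects of AI assistance in multi-reader
multi-case (MRMC) diagnostic studies.

## What this solves, and for whom

When radiologists read cases with an AI model's predicted probabilities on
screen, the *average* effect on diagnostic accuracy says little about who
is helped and who is harmed. Quantifying per-reader effects runs into
three statistical traps that this package is built around:

1. **Noise masquerading as heterogeneity.** Per-reader treatment effects
   `t_r = mean(unassisted error) − mean(assisted error)` are noisy; their
   raw spread overstates true heterogeneity. `hetfx` applies
   normal–normal empirical Bayes shrinkage with a method-of-moments prior:
   `posterior_mean = (σ_r² μ₀ + σ₀² t̃_r) / (σ₀² + σ_r²)`, with
   `σ₀² = Var(t̃_r) − mean(σ_r²)` clipped at zero.
2. **Reversion to the mean.** Regressing the treatment effect on the
   reader's baseline error using the same reads manufactures a positive
   slope even when none exists. `hetfx` builds split-sampling designs in
   which the outcome comes from a held-out case and the baseline from the
   remaining unassisted cases — plus the deliberately biased "naive"
   design as a diagnostic.
3. **Attenuation bias.** The split baseline is still measured with error,
   so the slope is shrunk by the reliability ratio
   `λ = (Var(x) − E[η²]) / Var(x)`; the corrected slope is `β̂ = γ̂ / λ̂`
   with standard errors divided by `λ̂` too.

Inference throughout is OLS with two-way (patient-case × reader)
cluster-robust covariance `V = V_case + V_reader − V_case∩reader`, with a
battery of Wald joint-equality tests, an unpaired t-test for the oracle
subgroup comparison, Benjamini–Hochberg correction across 15 pathologies,
and a between/within F-test for binned AUROCs. Subgroups come from median
splits (experience, thoracic subspecialty, AI-tool experience), an oracle
split on shrunk effects, and a cross-fitted combined-characteristics
model; AI-error bins relate the quality and sign of the AI's own
prediction to the treatment effect it induces.

Because the study data this emulates is access-restricted, the package
ships a first-class synthetic generator (`generate_study()`) that emits a
reader-study bundle *plus* a sealed truth record (true per-reader skill
`μ_r` and effect `τ_r`), so every estimator has an end-to-end recovery
test.

## Worked example

```r
library(hetfx)

cfg <- analysis_config(sim = sim_config(), seed = 7L)   # 140 readers, 324 cases
rep <- run_full_analysis(cfg)
print(rep)
#> <analysis_report>
#>   reads: 215100, readers: 140
#>   TE range [-1.014, 1.220], IQR 0.529 (shrunk: TRUE)
#>   split TE slope beta = -0.028 (p = 0.413); naive beta = -0.006

print(rep$shrinkage_all)
#> <shrinkage_result> 140 readers (0 excluded)
#>   prior: mu0 = 0.09355, sigma0^2 = 0.3743

print(rep$oracle$subgroups)
#>    subgroup         te         se      ci_lo      ci_hi      n
#> 1:     high  0.5930069 0.05330703  0.4885270  0.6974867 106200
#> 2:      low -0.4303869 0.07224608 -0.5719867 -0.2887872 108900

print(rep$te_regression)
#> <attenuation_estimate> gamma = -0.02741 (se 0.03345), lambda = 0.9772
#>   beta = -0.02805 (se 0.03423), 95% CI [-0.09515, 0.03904], p = 0.413
```

Reading the numbers: the simulator planted true effect heterogeneity
`σ_τ² = 0.35` with no link to baseline skill. The shrinkage prior
recovers `σ₀² = 0.374`; the oracle split (median of shrunk effects)
shows the heterogeneity an ideal predictor could exploit (+0.59 vs −0.43,
t-test p ≈ 3e−29); and the attenuation-corrected split-sampling slope of
treatment effect on unassisted error is, correctly, indistinguishable from
zero. On a single pathology (where per-case noise is large) the naive
design's slope hallucinates ≈ 0.36 while the split design stays at zero —
that demonstration is run by the acceptance script.

The AI-error bin analysis (`rep$abs_error_bins`) reports treatment effects
by AI absolute-error range with a joint equality test; with the default
direct-mode generator (reader errors independent of AI quality) it is
null, and in mechanistic mode (readers anchor on the AI) it turns
monotone-harmful, as the bin tests detect.

Command-line front end (same pipeline):

```sh
Rscript inst/cli/hetfx simulate --out study_dir --seed 2
Rscript inst/cli/hetfx analyze --in study_dir --out results_dir --seed 2
```

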