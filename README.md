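# titipop

Bayesian age-structured population assessment of the New Zealand tītī
(sooty shearwater, *Ardenna grisea*), 1976–2005.

Tītī are the most numerous seabird of the New Zealand region, and their
chicks are traditionally harvested by Rakiura Māori. Several abundance
indices indicate a substantial decline over recent decades, with four
candidate drivers: El Niño–Southern Oscillation (ENSO) climate variation,
fisheries bycatch (mainly North Pacific driftnets before the 1991 ban),
depredation of eggs and chicks by introduced weka, and the chick harvest
itself. This package implements a population-dynamics assessment that
separates those influences: it fits an age-structured projection model to a
relative-abundance series and demographic constraints inside a Bayesian
framework, selects among climate-lag structures by WAIC, and attributes the
decline to each threat with counterfactual "virtual population"
projections. It is written for quantitative ecologists who want to rerun,
extend or stress-test that analysis.

The harvest-diary CPUE series that anchors the original analysis is
confidential, so the package ships a first-class synthetic-data generator
that reproduces the statistical shape of every input (SOI series, harvest
and bycatch forcing, observation noise); the full pipeline runs offline on
that stand-in, with a truth record for parameter-recovery checks.

## The model

Abundance `n[i,t]` in age classes `i = 0..14` (class 14 a plus group)
follows a post-breeding census projection:

    n[0,t]  = 0.5 (1 - w) f_t N_a[t]
    n[1,t]  = (1 - b[t-1]) s_j[t-1] (n[0,t-1] - H[t-1])
    n[2,t]  = (1 - b[t-1]) s_j[t-1] n[1,t-1]
    n[i,t]  = (1 - b[t-1]) s_a[t-1] n[i-1,t-1]          (i = 3..13)
    n[14,t] = (1 - b[t-1]) s_a[t-1] (n[13,t-1] + n[14,t-1])

where `w` is the weka depredation probability (0.11), `H_t` the chick
harvest, `b_t = B_t / N_t` the bycatch mortality rate, and `N_a[t]` the
number of mature birds under a probit maturity curve. Adult survival and
fecundity follow scaled logistic links to annual means of the Troup
Southern Oscillation Index,

    s_a[t] = 0.98 / (1 + exp(-(alpha_s + beta_s z_s[t])))
    f_t    = 0.90 / (1 + exp(-(alpha_f + beta_f z_f[t])))

with juvenile survival `s_j = r s_a`, and model-specific lags on each link
(an `S-1F0` model drives survival in year `t` with the covariate of year
`t+1` and fecundity with the contemporaneous covariate). The initial age
structure is the stable-age distribution of an initializer Leslie matrix
passed through a five-year run-in. The likelihood combines the CPUE index
(`I_t ~ N(k n[0,t], sigma^2)`), the adult-abundance trend
(`0.983 ± 0.002`), window-averaged generalized logits of adult survival,
fecundity and juvenile survival, and a 2005 chick-abundance estimate
(`2.787M ± 0.132M`). Posteriors are sampled by adaptive Metropolis MCMC;
candidate lag models are compared by WAIC weight
`w_m = exp(-dW_m/2) / sum_k exp(-dW_k/2)` and pooled by weighted
resampling for model-averaged quantities.

## Worked example

The numbered drivers under `analysis/` run the whole assessment at desk
scale on the synthetic bundle (about ten minutes in total):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_models.R
Rscript analysis/03_counterfactuals.R
Rscript analysis/04_process_error.R
Rscript analysis/05_sensitivity.R
```

Step 1 prints the generated study conditions:

    synthetic bundle written to results/synthetic
      total population 32.7M (1976) -> 19.5M (2005), 1.78%/yr decline
      chick harvest 7-15% of chicks, peak bycatch rate 0.0160
      survival covariate range [-1.66, 1.31]

Step 3 prints the threat attribution from the model-averaged posterior —
the baseline decline, and how much of it each removed mortality source
would have avoided (negative numbers are growth):

    posterior predictive check: 18/19 observed CPUE values inside the 95% interval
    baseline               decline  2.10%/yr (95% CI  1.72- 2.46)
    no_harvest             decline  1.55%/yr (95% CI  1.15- 1.93)
    no_bycatch             decline  1.56%/yr (95% CI  1.10- 1.96)
    no_weka                decline  1.44%/yr (95% CI  1.06- 1.80)
    no_climate_survival    decline -3.59%/yr (95% CI -5.00--1.68)
    no_all_managed         decline  0.54%/yr (95% CI  0.11- 0.98)

Removing any single managed threat buys roughly half a percentage point of
growth per year, while removing the SOI–survival link turns the decline
into growth — climate dominates the managed threats, which is the
assessment's central finding. Step 4 adds pre-specified process error to
both climate links and reports how much the CPUE prediction intervals
widen (35% on this bundle), and step 5 refits the model under perturbed
harvest and trend inputs. Tables land in `results/`.

Equivalent calls from R: `generate_dataset(preset_paperlike(seed))`,
`fit()`, `compute_waic()`, `waic_table()`, `model_average()`,
`run_counterfactual()`, `process_error_config()`,
`fit_with_process_error()`, `run_sensitivity_suite()`.

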