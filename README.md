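# glucodyn

Short-term forecasting of continuous glucose monitoring (CGM) traces from
their nonlinear dynamics, for researchers working on glucose prediction
and decision support in type 1 diabetes.

CGM sensors report subcutaneous glucose every 5 minutes for days.
`glucodyn` treats such a trace as the observable of a weakly chaotic
dynamical system: it reconstructs the system's phase space by Takens
delay embedding,

    z_t = [x_t, x_{t+tau}, ..., x_{t+(m-1)tau}],

with the delay `tau` chosen from the average mutual information (or the
ACF 1/e crossing for linear models) and the dimension `m` from Cao's
nearest-neighbour method, and fits regime-switching autoregressions to
predict the next observation from the current delay vector.  Five model
families are provided — linear AR (LAR), additive AR with penalized cubic
splines (AAR), neural-network AR (NNAR), self-exciting threshold AR
(SETAR), and logistic smooth-transition AR (LSTAR):

    SETAR:  x_{t+1} = theta_1' z_t + e   if Y_t <= th
            x_{t+1} = theta_2' z_t + e   if Y_t  > th
    LSTAR:  x_{t+1} = (1 - G) theta_1' z_t + G theta_2' z_t + e,
            G(Y_t; gamma, c) = 1 / (1 + exp(-gamma (Y_t - c)))

A sliding pipeline retrains on the trailing 8 monitoring hours,
log-transforms and differences to stationarity (Augmented Dickey–Fuller
checked), denoises the window in phase space, and iterates one-step
predictions to 30- or 60-minute horizons.  Forecasts are scored by
RMSE/MAE/MAPE and by continuous glucose error-grid analysis (CG-EGA,
zones A–D combining point and rate accuracy).  Chaos diagnostics
(largest Lyapunov exponent by nearest-neighbour divergence,
Grassberger–Procaccia correlation dimension, recurrence plots) and the
standard glycemic-variability and risk indices (SD, CV, J-index, MAGE,
CONGA, MODD, GVI, PGS; LGI/HGI with their published category cut-points)
round out the analysis, reported per landmark interval of the day.  A
seeded synthetic CGM generator with controllable hypo-/hyper-glycemia
intensity provides reproducible test data, and canonical chaotic systems
(logistic, Hénon, Lorenz) serve as benchmarks with known invariants.

## Worked example

```r
library(glucodyn)

gs <- simulate_cgm(cgm_sim_config(days = 5, seed = 42, noise_sd = 5))
gs
#> <glucose_series> 1440 samples @ 5 min, 2023-04-01 .. 2023-04-05 23:55:00
#>   glucose [mg/dL]: min 66.5 / median 130.6 / max 214.1; 0 gap(s)

ri <- risk_indices(gs$glucose)
classify_risk(ri$lgi, ri$hgi)
#> LGI 0.24 (minimal risk of hypoglycemia)  HGI 2.54 (low risk of hyperglycemia)

tr  <- transform_series(gs$glucose)          # log + first difference
rep <- chaos_report(tr$w, max_lag = 20, m_max = 6)
#> tau 5   m 6   D2 5.13   lambda 0.393

res <- sliding_predict(gs, pipeline_config(ph_minutes = 30,
                                           model_kind = "lstar"))
head(res, 3)
#>             timestamp   actual predicted ph_minutes landmark
#> 1 2023-04-01 08:25:00 160.8046  129.2123         30  morning
#> 2 2023-04-01 08:55:00 178.8059  155.5501         30  morning
#> 3 2023-04-01 09:25:00 156.1372  172.9254         30  morning

ev <- evaluate_predictions(res)
#> RMSE 16.80  MAE 13.06 mg/dL over 224 forecasts
ev$cg_ega
#> <CG-EGA> 224 pairs; zones: A=89.7% B=10.3% C=0.0% D=0.0%
```

Reading the numbers: the simulated trace stays mostly euglycemic (low
LGI/HGI), its differenced series has a positive Lyapunov exponent
(~0.39 per 5-min step — sensitive dependence, but slow enough that
30-minute forecasting is meaningful).  The LSTAR forecasts land within
~17 mg/dL RMSE at the 30-minute horizon, and about 90% of them would not
change a clinical decision (zone A); none reach the dangerous C/D zones.

`run_pipeline("config.yaml")` executes the whole workflow
(simulate/load → characterise → forecast → evaluate) and writes
predictions CSV plus JSON reports and a run manifest;
`inst/scripts/glucodyn-cli` exposes the same steps as shell subcommands.

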