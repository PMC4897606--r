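# pondcast

Hybrid dissolved-oxygen (DO) forecasting for outdoor aquaculture ponds.

Dissolved oxygen is the water-quality variable that most directly decides
whether pond-reared crabs (and fish) thrive or suffocate, and managers need
short-horizon forecasts to act before it crashes. The catch is that the DO
sensors feeding such a model are themselves unreliable: in field data the
same pond shows readings of exactly 0.00 mg/L (dropouts), isolated values far
above their neighbours (spikes), and whole sensors that persistently read
low. pondcast implements a two-stage method built for exactly this situation:

1. **Multi-sensor fusion.** The `S` simultaneous DO readings are fused into
   one credible value by a three-layer radial basis function (RBF) neural
   network. Hidden unit `j` applies a Gaussian activation
   `phi_j(x) = exp(-||x - c_j||^2 / (2 sigma_j^2))` around a center `c_j`
   chosen by K-means clustering; widths follow `sigma = d_max / sqrt(2K)`;
   and because the hidden-to-output map is linear, the output weights are an
   exact linear least-squares solve against a reference sensor's readings.
2. **LSSVM forecasting.** The fused series is forecast one step ahead (20-min
   interval) from water temperature, solar radiation, wind speed, rainfall,
   humidity and the previous fused DO value, using a least-squares support
   vector machine with RBF kernel `K(x,z) = exp(-||x - z||^2 / (2 sigma^2))`.
   Training solves the dual KKT system
   `[[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]`
   in one dense symmetric solve. The hyper-parameters `(gamma, sigma)` are
   tuned by an improved particle swarm optimizer (IPSO): velocity update
   `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with a per-particle
   inertia weight `w` adapted to each particle's fitness relative to the
   swarm's best and average, plus a uniform position mutation with
   probability `pm` to escape local optima. The fitness of a particle is the
   RMSE of its LSSVM on held-out validation rows.

A synthetic pond-data generator (diel DO cycle phase-locked to solar
radiation, temperature coupling, AR(1) residual, per-sensor noise and
injected dropout/spike/bias faults) makes every stage runnable and testable
without any external dataset. Forecast quality is scored with MAE, RMSE,
MSE, MAPE, the Nash-Sutcliffe efficiency coefficient (NSC) and R².

## Worked example

```r
library(pondcast)

cfg <- experiment_config(
  synthetic = synthetic_config(n_samples = 1008, seed = 1),  # 14 days, 20-min
  models = c("ipso_lssvm", "cv_lssvm"),
  pso = pso_config(bounds = rbind(c(-2, 6), c(-2, 2))),      # log10 gamma, log10 sigma
  seed = 1)
res <- run_experiment(cfg)
print(res)
```

```
<do_experiment> seed 1 | fusion 500/200 | forecast 120/79
  ipso_lssvm gamma = 126.588, sigma = 17.8119
  cv_lssvm   gamma = 100, sigma = 10
      model    mae   rmse    mse  mape    nsc     r2  n
 ipso_lssvm 0.2767 0.3888 0.1511 5.262 0.9487 0.9517 79
   cv_lssvm 0.2904 0.3979 0.1583 5.452 0.9463 0.9486 79
relative improvement of ipso_lssvm (% of reference error):
 reference  candidate rel_mae rel_rmse rel_mse
  cv_lssvm ipso_lssvm    4.75     2.29    4.54
```

Reading this: the first 500 rows of the simulated frame train the fusion
network and the next 200 fused rows form the forecasting table (lag-1
supervision leaves 199 usable rows, split 120 train / 79 test). On the
79-row test period the swarm-tuned LSSVM reaches a test RMSE of 0.389 mg/L
and NSC 0.949 (1 = perfect forecast, 0 = no better than the mean), and
improves on the 5-fold cross-validated LSSVM baseline by 2.29% in RMSE.
MAE/RMSE/MSE are in mg/L, (mg/L)² for MSE; MAPE is in percent.

Individual stages are available directly: `simulate_frame()`,
`fit_fusion()` / `fuse_frame()`, `build_forecast_table()`, `tune_lssvm()`,
`train_lssvm()` / `predict()`, `compute_metrics()`. A command-line interface
with subcommands `simulate`, `fuse`, `tune`, `train`, `predict`, `evaluate`
and `run-all` wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pondcast.R", package = "pondcast"))')
Rscript $CLI simulate --n 1008 --seed 1 --out frame.csv
Rscript $CLI fuse --in frame.csv --train-rows 500 --out fused.csv
Rscript $CLI run-all --seed 1 --out-dir out/
```

The CSV dialect used throughout has header
`timestamp,water_temp,solar_rad,wind_speed,rainfall,humidity,do_s1..do_sS[,do_truth][,do_fused]`
with ISO-8601 UTC timestamps. `metrics.json` written by `run-all` contains
the seed, the split sizes, each model's tuned `(gamma, sigma)`, its
MAE/RMSE/MSE/MAPE/NSC/R² on the test period, and the relative-difference
block.

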