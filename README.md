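# landsim

A daily time-step, grid-based simulator of agricultural landscapes for
exploring trade-offs between production and the environment.  Each grid
cell couples:

- a three-layer capacity ("tipping-bucket") **soil water** model with
  retention curves from the HYPRES pedotransfer functions and dynamic
  topsoil bulk density;
- **soil organic matter** turnover in the RothC pool structure
  (DPM/RPM/BIO/HUM + inert), extended with parallel nitrogen and
  phosphorus stocks so that mineralisation and immobilisation emerge from
  pool stoichiometry:

  M&#8342; = Δ&#8342;/ρ&#8342; − B&#8342;/ρ_BIO − U&#8342;/ρ_HUM

- **mineral N** dynamics: deposition, fertiliser, runoff mixing over the
  top 20 mm, convective nitrate leaching, nitrification with an N₂O
  by-product, and denitrification N₂O
  (`0.000735·NO₃·f(WFPS)·exp(−0.00045(T−23.65)²)`) and N₂ kernels;
- **mineral P** in available/non-available pools with a daily first-order
  re-equilibration whose rate follows an Olsen-P vs total-P regression
  (half-life ≈ 65 days at Broadbalk-like total P);
- a generic light-use-efficiency **crop/grassland** model
  (`dB = Q·ε·W_rf·N_NI·P_NI`) with thermal-time development, root-weighted
  water stress, nutrient nutrition indices, senescence, cutting, grazing
  and manure return;
- **lateral routing** of runoff and dissolved N/P between cells down the
  elevation field into ditches, aggregated to catchment discharge and
  loads;
- a **Pareto optimiser** (non-dominated sorting + differential evolution)
  over fertiliser timing and amount against yield, nitrate leaching and
  N₂O objectives.

Everything is testable offline: `synth_weather()` generates calibrated
synthetic station weather and `build_fixture_farm()` ships classical
long-term-experiment-style plot and catchment configurations.

## Worked example

Three years of continuous winter wheat at 144 kg N ha⁻¹ on a
Broadbalk-like silty clay loam, under synthetic SE-England weather:

```r
library(landsim)

weather <- synth_weather(years = 3, latitude = 51.8, seed = 1,
                         start_year = 2001)
farm <- build_fixture_farm("broadbalk_like_plot", n_rate = 144,
                           years = 2001:2003)
sim <- run_simulation(farm$grid, weather, farm$management, farm$params)

sim$harvest[, c("date", "yield", "grain_n", "grain_p")]
#>        date    yield  grain_n  grain_p
#>  2002-08-09 5.630045 95.80696 9.953592
#>  2003-08-08 6.139124 80.92151 8.972740

colSums(sim$fluxes[, c("n_leached", "n2o", "drainage")]) / 3
#> n_leached       n2o  drainage
#>      7.69      1.26     99.76
```

The first harvest falls in August of the year after autumn sowing; yields
are t ha⁻¹ at 85 % dry matter, grain N and P in kg ha⁻¹.  The second line
gives mean annual nitrate leached and N₂O emitted (kg N ha⁻¹ yr⁻¹) and
drainage (mm yr⁻¹).  Model-vs-observation comparison uses the standard
statistics suite:

```r
st <- summary_stats(obs = c(5.2, 6.1), sim = sim$harvest$yield)
sprintf("RMSE%% %.1f  r %.3f", st$rmse_pct, st$r)
#> "RMSE% 5.4  r 1.000"
```

Trade-off frontiers come from the optimiser:

```r
opt <- optimise_fertiliser(weather, farm, pop_size = 40,
                           generations = 60, seed = 1)
head(opt$front)   # fert_day, fert_amount, yield, leaching, N2O; rank 0
```

A command-line wrapper with `run`, `synth-weather`, `evaluate` and
`optimize` subcommands lives at `inst/cli/landsim.R`.

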