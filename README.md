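# pulsim

Simulation and recurrent surrogate modelling of pulsed radio-immunotherapy.

## The problem

Widely spaced ("pulsed") radiotherapy appears to interact with immune
checkpoint blockade: a radiation pulse releases tumour antigen and recruits
T cells over the following days, and anti-PD-L1 can reinvigorate that
response — but only if its timing overlaps the window in which the immune
response is active. Preclinical evidence comes from syngeneic mouse cohorts
(7–8 animals per group, caliper volumes `xyz/2` on a handful of days, large
error bars), which makes the *temporal* structure of the synergy hard to
read off directly.

`pulsim` implements a complete in-silico workflow for this question:

* a **mechanistic cohort simulator** — exponential growth at rate ρ,
  linear-quadratic radiation kill `SF(d) = exp(−(αd + βd²))` applied on
  pulse days, and a delayed immune kill `κ` active inside the window
  `[pulse + delay, pulse + delay + duration]` when anti-PD-L1 is on board
  (`κ_bare` otherwise), with log-normal inter-animal variability;
* **pre-processing** that augments group mean/SD summaries into training
  samples (Gaussian draws with the SD shrunk 5-fold) and encodes each
  schedule as an 18-step × 2-channel input (LQ effect; drug code 0/1/2)
  with masked volume-change targets `ΔVC_i = V_{i+1} − V_i`, i = 1..5;
* a **many-to-one LSTM surrogate** (hand-written forward/backward/Adam in
  base R, gradient-checked) trained with the masked squared-error loss
  `Σ_i (ΔVC_i − ΔVC′_i)²` over measured intervals only;
* **hidden-unit interpretation**: per-schedule 100 × 18 activation maps and
  between-arm difference maps that localize each stimulus's effect in time;
* **in-silico schedule scoring** by accumulated volume change
  `AVC = Σ ΔVC′_i` (lower = better tumour control), including sweeps of the
  anti-PD-L1 onset offset after the first pulse.

## Worked example

Simulate a study whose arms vary the drug onset around a single 10 Gy
pulse, fit the surrogate, and ask it when anti-PD-L1 should start:

```r
library(pulsim)

params <- dynamics_params(alpha = 0.05, beta = 0.005)  # volume-response LQ scale
study  <- generate_study(recovery_study_config(), params, seed = 101)
ds     <- build_dataset(study, n_samples = 50, seed = 102)
fit    <- train(ds, model_config(hidden_units = 50, epochs = 500,
                                 batch_size = 100, seed = 103,
                                 holdout_groups = 0))

avc(fit$model, study$groups[[1]]$schedule)   # untreated control
#> [1] 13710.93
avc(fit$model, study$groups[[2]]$schedule)   # 10 Gy alone
#> [1] 5828.576

sweep <- sweep_offsets(fit$model,
                       sweep_spec(data.frame(step = 3, dose_gy = 10),
                                  n_drug_days = 4, offsets = 1:14))
sweep$offset[which.min(sweep$avc_mm3)]
#> [1] 9
```

The control AVC (~13,700 mm³ accumulated growth over the window) dwarfs the
radiation-only arm (~5,800 mm³), and the predicted best drug onset is 9 days
after the pulse — inside the simulator's true optimal band (the immune
window opens 7 days post-pulse). `extract_hidden_map()` /
`difference_map()` / `region_summary()` expose the fitted network's
internal account of the same effects, and `run_pipeline()` orchestrates all
stages (simulate → augment → train → crossval → interpret → sweep) with
per-stage seeds, CSV/JSON artifacts and a hash manifest.

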