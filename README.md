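# eshpflow

Personalized coronary blood flow (CBF) settings and continuous metabolic
monitoring for normothermic/subnormothermic **ex situ heart perfusion
(ESHP)**.

Donor hearts preserved on a Langendorff-mode perfusion machine are typically
run at 700–800 ml/min coronary flow — two to three times the flow of a
resting adult heart — while the unloaded, 34 °C myocardium consumes
relatively little oxygen. The resulting supranormal delivery is suspected of
driving myocardial edema and graft dysfunction. `eshpflow` computes, for an
individual donor heart, the flow at which oxygen delivery balances expected
consumption, and then tracks the actual oxygen handling of the heart over
the perfusion run.

## The model

Myocardial oxygen consumption obeys the Fick principle,
`MVO2 = CBF × (CaO2 − CvO2) / 100` ml O2/min, with perfusate oxygen content

```
CaO2 = 1.34 · [Hb] · SaO2 + 0.0031 · PaO2     (ml O2/dL)
```

Heart weight is estimated from donor sex and body weight
(`HW = 2.153·BW + 104.6` g female, `HW = 2.492·BW + 141.2` g male), expected
consumption is `0.10 ml O2/min per gram` of myocardium, and the target
oxygen extraction ratio is `0.80`. Solving the Fick relation for flow gives
the unnormalized requirement

```
CBF = HW · mvo2_per_gram · 100 / (CaO2 · OER)  =  (HW / CaO2) · 12.5
```

which is mapped onto the clinically validated 500–800 ml/min window by a
sex-specific min-max normalization (anchors 133/333 female, 178/431 male)
with clamping. Once paired arterial/venous samples arrive, the estimated
consumption term is replaced by the measured MVO2 and the recommendation
updates serially. The session layer also derives MDO2, MEO2, ΔPO2
(arterial − venous PO2) and CVR (mean aortic pressure / CBF), classifies
lactate trends by least-squares slope (±0.1 mmol/L/h), and raises
electrolyte advisories (ionized calcium < 1.1, bicarbonate < 21 or
pH < 7.30, potassium outside 3.5–5.5 mmol/L; all configurable).

## Worked example

```r
library(eshpflow)

donor <- donor_profile("male", 80)            # heart weight estimate 340.56 g
rec <- personalize_cbf(donor, hb = 9, so2 = 1.0, po2 = 350)
rec
#> Recommended CBF: 600 ml/min (raw 601.5, basis: estimated mvo2)
#>   heart weight 340.6 g | CaO2 13.14 ml O2/dL | unnormalized 323.8 ml/min
```

The perfusate (Hb 9 g/dL after prime dilution, fully saturated, PaO2
350 mmHg) carries 13.14 ml O2/dL, so 323.8 ml/min would already cover this
heart's expected 34.1 ml O2/min consumption at 80% extraction; normalization
onto the protocol window recommends 600 ml/min at the pump — well below the
700–800 default, with delivery still ~2.3× consumption.

Running a simulated session and recalibrating from measured consumption:

```r
cfg <- synthetic_run_config(donor, seed = 42)     # 4 h run, 3% analyzer noise
log <- simulate_run(cfg)
s <- add_samples_from_log(perfusion_session(donor), log)
s
#> Perfusion session: male donor, 80 kg | 40 samples, 20 snapshots, 21 recommendations
#>   latest CBF advice: 580 ml/min (measured mvo2) at t = 240 min
lactate_trend(s)
#> lactate trend over 5 points: stable (-0.09 per hour)
```

The same pipeline is scriptable from a shell via `inst/cli/eshpflow`
(subcommands `recommend`, `add-sample`, `report`, `simulate`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package: the baseline recommendation for a typical 80 kg male
donor, then a seeded 4-hour synthetic run ingested through the session
layer with its serial recalibrations, trend classification and report. Run
it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It logs the computed quantities to standard error and writes the JSON
results file.
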