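---
title: "Personalized coronary flow and metabolic assessment on ex situ heart perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized coronary flow and metabolic assessment on ex situ heart perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eshpflow)
```

## The problem and the model

A donor heart on an ex situ perfusion machine beats unloaded at 34 °C and is
perfused retrogradely through the aorta (Langendorff mode). Its oxygen
consumption is governed almost entirely by its mass: heart rate is narrow
(~65–80 bpm), the ventricle does no external work, and contractility varies
little between preserved grafts. The machine protocol nevertheless
prescribes a fixed coronary flow of 700–800 ml/min for every heart, two to
three times resting physiologic flow — and excess flow is implicated in
myocardial edema and graft dysfunction.

`eshpflow` computes the equilibrium flow for an individual heart from three
relations:

1. **Fick consumption.** `MVO2 = CBF · (CaO2 − CvO2) / 100` ml O2/min.
   Oxygen contents are per dL and flow per ml, hence the explicit /100.
2. **Oxygen content.** `CaO2 = 1.34 · Hb · SaO2 + 0.0031 · PaO2` ml O2/dL —
   hemoglobin-bound (Hüfner constant 1.34 ml O2/g) plus dissolved oxygen.
3. **Heart-weight regression.** `HW = 2.153·BW + 104.6` g (female),
   `HW = 2.492·BW + 141.2` g (male); a measured heart weight, when
   available, overrides the estimate.

Setting consumption to `HW · mvo2_per_gram` and extraction to the target
`OER` and solving for flow:

```
CBF_required = HW · mvo2_per_gram · 100 / (CaO2 · OER)
```

At the defaults (`mvo2_per_gram = 0.10` ml/min/g, `OER = 0.80`) the constant
`100 · 0.10 / 0.80 = 12.5` appears, i.e. `CBF = (HW / CaO2) · 12.5`. These
two defaults sit inside their physiologic ranges (0.08–0.13 ml/min/g;
extraction 0.70–0.80) and were chosen jointly so that the multiplier is
exactly the printed 12.5 of the sex-specific equations; both are
configurable, with a warning outside the physiologic range.

## Normalization onto the protocol window

For a typical donor the required flow is ~300–400 ml/min — physiologic, but
far below flows with established preclinical safety. Preclinical work
demonstrates adequate perfusion at 500 ml/min, and 800 ml/min is the
protocol ceiling, so the raw requirement `x` is min-max normalized onto
[500, 800]:

```
rec = 500 + 300 · clamp((x − sex_min) / sex_range, 0, 1)
```

with anchors `sex_min/sex_range` of 133/333 (female) and 178/431 (male),
derived from the extreme donor/perfusate combinations seen in practice.
Values outside the window are **clamped, not extrapolated**: the floor is a
safety bound, the ceiling a protocol bound. Flows below 500 ml/min are
deliberately never recommended. The `clamped` field records when the raw
position left the window, and unclamped recommendations invert exactly back
to `x`.

A note on the mid-range claim: at the centre of the physiologic mid-range
(male 80 kg, Hb 9 g/dL, SaO2 1.0, PaO2 350 mmHg) the unnormalized
requirement is 323.8 ml/min, and the median over the surrounding box
(75–85 kg × Hb 8–10 × PaO2 300–400) also sits in 300–400 ml/min; extreme
corner combinations (light donor, high Hb *and* high PaO2) drift down to
~280 ml/min. The 300–400 band is a central-tendency statement, not a
uniform bound over input corners.

### Serial recalibration

Once paired arterial/venous samples exist, the estimated consumption term is
replaced by the *measured* MVO2: `x = MVO2 · 100 / (CaO2 · OER)`. The
**target** extraction ratio stays in the denominator rather than the
measured one — the recommendation's purpose is to drive extraction toward
the physiologic target; dividing by the measured extraction would make the
update a no-op that always returns the current flow. This is a genuine
design choice (the alternative is defensible) and is configurable only by
changing `oer_target`. No temporal smoothing is applied across serial
updates: the latest snapshot wins, matching a per-sample clinical workflow.
A snapshot with negative measured extraction (venous content above arterial)
withholds the update entirely, since a site swap is the likeliest cause.

## Session semantics and units

Samples are stored in canonical units — saturation as a fraction,
hemoglobin in g/dL, PO2 in mmHg. At ingestion, saturations above 1 are read
as percent; hemoglobin in mmol/L converts at 1.6113 g/dL per mmol/L
(monomer convention; configurable because lab conventions differ).
Duplicate (time, site) samples are rejected, which makes re-ingesting a log
idempotent.

Arterial and venous samples within ±5 min of each other pair into one
metabolic snapshot timestamped at their midpoint. The snapshot's MVO2 uses
the **pump flow actually set** (the last settings entry at or before the
snapshot time), never the recommendation — the recommendation is advice,
the setting is fact. Derived panels: MDO2 = CBF·CaO2/100;
MEO2 = MVO2/MDO2, identically the measured extraction (CaO2−CvO2)/CaO2;
ΔPO2 = arterial − venous PO2; CVR = mean aortic pressure / CBF with venous
pressure taken as zero (freely drained, unloaded preparation). The last two
definitions are this package's conventions — the quantities are routinely
displayed clinically but their formulas are convention-dependent; both are
stated here rather than asserted as universal.

Lactate trends use the least-squares slope over the last *k* (default 5)
lactate-bearing arterial samples, classified rising/falling/stable at
±0.1 mmol/L/h; at least three points are required. Arterial lactate is used
(configurable choice) since the arterial line reflects the recirculating
perfusate pool. Electrolyte advisories fire when ionized calcium < 1.1
mmol/L, bicarbonate < 21 mmol/L or pH < 7.30, or potassium leaves
[3.5, 5.5] mmol/L — standard clinical reference bounds, all overridable;
advisories are free-text, dosing is out of scope.

## What the synthetic runs emulate — and what they don't

`simulate_run()` states a ground truth and constructs data consistent with
it. Defaults describe a standard machine session: 4 h duration sampled
every 12 min (20 arterial/venous pairs), perfusate hemoglobin at the
protocol minimum prime (14 g/dL donor blood diluted by 1200:500:100 ml
blood:crystalloid:albumin → 9.33 g/dL), hyperoxic arterial PO2 ~350 ± 25
mmHg from the 85% O2 sweep gas, true consumption 0.10 ml/min/g, and 3%
multiplicative analyzer noise.

Venous values are **derived from the oxygen budget**, not sampled: the
venous content is what closes the Fick balance at the pump flow, and the
venous saturation/tension split uses a crude monotone saturation→tension
lookup (piecewise-linear pseudo-dissociation shape). No real
oxyhemoglobin-dissociation physiology (P50, temperature, pH shifts) is
modelled; the lookup only guarantees a monotone, invertible mapping so the
pipeline's content reconstruction is exact in the noise-free case. Noise is
applied after budget closure, multiplicatively on measured saturation,
tension and hemoglobin, so the latent run always conserves oxygen; measured
saturations are capped at 1, which introduces a small downward bias in
arterial content at near-saturation (about 1% at 3% noise) — real analyzers
cap at 100% too. Lactate follows the scenario deterministically (viable:
1.5 + 1.5·e^(−t/90 min); failing: linear 2→8 mmol/L), electrolytes hover
near normal with occasional below-threshold excursions to exercise the
advisory path. A single seed drives all draws; the caller's RNG state is
restored afterwards.

Consequently a green simulation test establishes *internal consistency* —
the pipeline recovers what the generator encoded — not fidelity to real
perfusions: no edema, no temperature dynamics, no metabolic deterioration
coupling lactate to oxygen extraction.

"Noise-free" in the recommendation-recovery checks means measurement noise
*and* arterial PO2 drift both zero: PO2 drift moves CaO2 between baseline
and later samples, so the estimated and measured recommendation pathways
would differ by the drift even with a perfect pipeline.

## Numerical choices

* Normalization is evaluated in closed form with `pmin/pmax` clamping;
  it matches a brute-force piecewise implementation to 1e-12 and inverts to
  1e-9 relative on unclamped values.
* Display rounding is to the nearest 10 ml/min, round-half-even; the raw
  value is retained.
* Negative arteriovenous differences are preserved and flagged, never
  clipped — a swapped pair of syringes should be visible in the report.
* Zero-delivery extraction and zero-flow resistance are reported as missing
  (`NA`), not as infinities.
* CSVs are written with 15 significant digits: write-then-read agrees with
  the in-memory state to ~1e-15 relative, and repeated runs under one seed
  are byte-identical. Session JSON serializes at full precision and is
  self-contained (configuration echoed), so reports are reproducible from
  the file alone.
* The venous-saturation solve (`uniroot` on a monotone function) uses
  tolerance 1e-12, which bounds the noise-free Fick round-trip error below
  1e-6 ml/min.

## Limitations

The heart-weight regressions carry real anatomic scatter; a measured weight
should be preferred when available. The consumption and extraction defaults
are in vivo-derived assumptions applied to an ex situ preparation. PO2 on
the machine is far above physiologic tension, so dissolved oxygen is a
larger content fraction than in vivo; no dissociation-curve or temperature
correction is applied anywhere. The tool advises — it never controls the
pump, and accept/reject decisions for transplantation are out of scope.
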