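# circph

Closed-loop lumped-parameter (0D, electrical-analog) model of the human
systemic and pulmonary circulation, with four time-progressive pulmonary
hypertension (PH) scenarios: distal pulmonary artery stenosis (`dpas`),
left ventricular diastolic dysfunction (`lvdd`), ventricular septal defect
(`vsd`) and mitral stenosis (`ms`).

The package is aimed at computational physiologists and physiologically
minded engineers who want a tested, scriptable simulator of how chronic PH
of different etiologies *develops*: pressure waveforms, pressure-volume
(P-V) loops, systolic/diastolic/mean pressures, stroke volume, cardiac
output and mean pulmonary artery pressure (mPAP), cycle by cycle, as a
disease schedule deforms the circuit.

## The model

Blood pressure maps to voltage, flow to current. The circulation is a
closed network of 25 compartments:

* **Heart chambers** (LV, LA, RV, RA) are time-varying elastance sources
  blending an end-systolic and an end-diastolic P-V relation,

  P(V, t) = e(t) · a·E_es·(V − V_d) + (1 − e(t)) · M_0·|exp(λ(V − V_0)) − 1|,

  with a Gaussian-sum activation e(t): four Gaussians of the form
  exp[−((b·t − C_i)/B_i)²] for the ventricles (the clock stretch b and the
  contractility gain a respond to sympathetic drive F_con), one Gaussian of
  the form exp[−½((t − C_0)/B_0)²] for the atria.
* **Vessels** are Windkessel compartments. Most are linear (P = V/C); the
  systemic veins follow −K_v·log₁₀(V_max/V − 0.99), the vena cava a
  two-branch collapsible law, the proximal systemic artery a
  vasoconstriction-weighted active/passive blend, and the diseased
  pulmonary vessels the saturating law P = −K·ln(1 − V/V_m).
* **Valves** are ideal diodes in series with resistances (the ventricular
  outflow tracts also carry an inertance, so flow is a state clamped
  non-negative by the diode).
* Heart rate comes from the autonomic response surface
  Hr = h₁ + h₂F_Hrs − h₃F²_Hrs − h₄F_Hrv + h₅F²_Hrv − h₆F_Hrv·F_Hrs;
  at the reference operating point (all drives 0.5) Hr = 76.5 bpm and the
  cycle length is T = 0.7845 s.

The resulting ODE system over compartment volumes and inductor flows is
integrated with classical fixed-step RK4 at dt = 0.5 ms (1569 steps per
cardiac cycle). The total blood volume (4711 ml) is conserved exactly by
construction. Disease schedules are deterministic functions of elapsed
simulation time applied once per cycle boundary — parameters are frozen
within a cycle — e.g. distal stenosis multiplies the distal pulmonary
resistance by (1 + g_r·t) while the bed's RC-time decays as τ₀e^(−σt), and
a septal defect opens as R_shunt(t) = R₀/(1 + k_r·t)².

## Worked example

```r
library(circph)
traj <- simulate_circulation("normal", duration = 10)
tail(summarize_cycles(traj)[, c("lv_sys", "aop_sys", "aop_dia",
                                "pap_sys", "pap_dia", "mpap", "co")], 1)
#>    lv_sys aop_sys aop_dia pap_sys pap_dia  mpap     co
#> 12  123.4     122    80.4    20.3    11.2  14.2 5977.3
```

The calibrated normal state pumps 5.98 L/min at 76.5 bpm: left ventricular
systolic pressure 123 mmHg, aortic pressure swinging 80–122 mmHg, pulmonary
artery at 20/11 mmHg (mPAP 14 mmHg — healthy, i.e. below the 25 mmHg PH
threshold). A disease run then shows PH developing:

```r
ph <- simulate_circulation("ms", duration = 700)   # mitral stenosis, ~5 s wall
s <- summarize_cycles(ph)
s[c(1, 892), c("t_start", "rv_sys", "la_sys", "mpap")]
#>     t_start rv_sys la_sys mpap
#> 1       0.0   30.9   17.3 12.0
#> 892   699.1   73.9   45.2 51.0
plot_pv_loop(ph, "la", cycles = c(10, 450, 890))   # the two-lobed LA loop
```

Right ventricular systolic pressure climbs from 31 to 74 mmHg and mPAP
crosses the PH threshold as the stenosing mitral valve backs pressure up
through the left atrium into the lungs.

A shell entry point wraps the same machinery:

```sh
inst/cli/circph-simulate --scenario dpas --duration 700 --out dpas_out --figures
```

writing tidy CSVs (`trajectory.csv`, `flows.csv`, `cycles.csv`,
`snapshots.csv`) and optional figures.

## Acceptance script

`scripts/acceptance.R` recomputes the model's reference quantities from
scratch against the installed package — the autonomic heart rate at the
standard operating point, and the worst-case total blood volume over a
sampled normal run (closed-circuit conservation):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Configuration

All constants live in one JSON document (chambers, vessel laws, edge
R/L/valve table, initial state, scenario coefficient blocks);
`load_config("my.json")` overlays any subset of keys on the shipped
calibrated fixture and validates the result. `data-raw/default_config.R`
regenerates the fixture; the calibration procedure and its targets are
described in the methods vignette (`vignettes/circph-methods.Rmd`).
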