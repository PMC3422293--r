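---
title: "A biophysical model of human jejunal smooth muscle electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biophysical model of human jejunal smooth muscle electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsmc)
```

## The model

Gastrointestinal slow waves are rhythmic depolarisations of smooth muscle
membrane potential, paced by the interstitial cells of Cajal (ICC) and
transmitted to smooth muscle cells (SMC) through gap junctions. `jsmc`
implements a single human jejunal SMC as an equivalent electrical circuit:

$$C_m \frac{dV_m}{dt} = -(I_{ion} - I_{stim}),$$

where $C_m = 50$ pF and the total ionic current is the sum of eight
components: L-type and T-type Ca^2+^ currents, a voltage-dependent K^+^
current (Kv), a large-conductance Ca^2+^- and voltage-activated K^+^ current
(BK), a Nav1.5 Na^+^ current, the Na^+^/K^+^ pump, the Na^+^/Ca^2+^
exchanger (NCX) and a non-selective leak with 0 mV reversal. Each channel
current is ohmic, $I = G \, P_o \, (V_m - E)$, with the open probability
$P_o$ supplied either by Hodgkin–Huxley gates (T-type: $m$, $h$; Kv: $x$,
$y$) or by deterministic continuous-time Markov chains:

* **L-type Ca^2+^** — a 12-state, two-tier topology: a closed chain
  C0–C3 feeding an open state and a voltage-inactivated state, duplicated
  in a Ca^2+^-bound mode whose open state does not conduct. Transitions
  into the Ca^2+^ mode scale with free cytosolic Ca^2+^, producing
  Ca^2+^-dependent inactivation; freezing those edges reproduces an
  EGTA-dialysed pipette (`egta_mode()`).
* **BK** — the 10-state allosteric scheme: five Ca^2+^-occupancy levels in
  a closed and an open tier, cooperative binding to the four α subunits of
  the homotetramer, and voltage-dependent closed–open transitions whose
  allosteric factor preserves detailed balance around every square.
* **Nav1.5** — six states (three closed, open, fast- and slow-inactivated),
  with closed-state inactivation giving the steep availability curve of the
  jejunal channel.

The ICC itself is not modelled biophysically: the SMC sees a prescribed
periodic ICC potential through a constant gap-junction conductance,
$I_{stim} = G_{couple}(V_{ICC} - V_m)$ (positive inward). Intracellular
Na^+^, K^+^ and total Ca^2+^ evolve with the membrane currents (3:2 pump
stoichiometry, 3:1 exchanger, valence 2 for Ca^2+^), and free Ca^2+^
follows from instantaneous equilibrium with the calmodulin and calreticulin
buffers via conservation of mass.

## Numerical scheme

The integrator is a fixed-step operator split, 0.1 ms by default: currents
are evaluated from the beginning-of-step state; Markov occupancies advance
by backward Euler (a dense direct solve of $(I - \Delta t\,Q)p' = p$ —
the BK deactivation rates reach tens per millisecond, which an explicit
step at 0.1 ms cannot handle); the potential, HH gates and concentrations
advance by forward Euler. After each implicit step the occupancy vector is
clamped to non-negative values and renormalised to sum exactly one, which
keeps the accumulated conservation error below $10^{-6}$ over tens of
millions of steps. Buffering equilibrium is solved per step by a
safeguarded Newton iteration warm-started from the previous step. Halving
the step changes the trajectory by well under 0.5 mV over a full
slow-wave cycle; the whole scheme is deterministic, so repeated runs are
bit-identical. The hot loop is compiled (Rcpp/Armadillo); an R reference
stepper (`step()`, `engine = "r"`) implements the identical update and the
test-suite cross-checks the two.

## Parameter provenance and calibration

The whole-cell constants that the source recordings fix directly are used
verbatim: $C_m$, the five maximum conductances (1.44, 0.0425, 1.0217, 80
and 25.1 nS), the at-least-45-fold bound on the leak relative to
$G_{Kv}$, the 0 mV leak reversal, and the ICC waveform anchors (rest
−57 mV, amplitude 23.5 mV, 300 ms upstroke, 9700 ms plateau, 6 cycles per
minute). The remaining constants — rate-coefficient tables, pump and
exchanger scales, buffer totals, cell volume, gap-junction conductance and
waveform shape — are constrained only at the cellular level, and were
calibrated once so that the assembled cell reproduces the recorded
phenotype: resting potential −60 mV, peak amplitude 23 mV, free Ca^2+^
cycling between roughly 94 and 250 nM, quiescence without a stimulus, and
stable ionic content over 30 minutes. The calibrated set ships as the
package default and as a fully commented YAML document
(`inst/extdata/default_params.yaml`).

Two structural facts shaped the calibration and are worth recording:

* **Ion bookkeeping forces the average stimulus current to vanish.** Every
  ionic pathway in the model is assigned to a tracked pool, so at a
  periodic steady state the cycle-averaged gap-junction current must be
  zero; any standing offset between the SMC and ICC potentials would drain
  K^+^ indefinitely. The model therefore spends part of each cycle with
  $V_m$ slightly above the decaying ICC potential, and the −60 mV resting
  value emerges as the per-cycle *minimum*: a brief undershoot carried by
  the slowly deactivating Kv conductance, not a standing offset.
* **The upstroke is coupling-limited.** With a physiological gap-junction
  conductance the membrane time constant filters the 300 ms ICC upstroke;
  the transient T-type and Nav1.5 currents and the early L-type current
  make up the difference, while BK (fast, Ca^2+^- and voltage-gated) caps
  the peak. The voltage-dependent K^+^ current dominates both the resting
  and plateau potentials, and the L-type conductance dominates the Ca^2+^
  transient amplitude — the orderings the sensitivity experiments test.

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `G_couple` | 0.35 | nS | ICC–SMC gap junction; scales stimulus influence |
| `P_NaK` | 4.24 | pA | pump scale; sets Na$_i^*$ and K^+^ recycling |
| `k_NCX`, `alpha_NCX` | 70000, 0.84 | pA, – | exchanger scale and bias; set the diastolic Ca^2+^ floor and extrusion rate |
| `V_c` | 3.5e-12 | L | cytosolic volume; converts current to concentration rate |
| buffers (CaM, CRT) | 0.008/0.027 | mM | Ca^2+^ capacity; scale the free-Ca^2+^ swing |
| `markov$CaL` | — | – | L-type rates; plateau Ca^2+^ entry and upstroke assist |
| `gates$x_Kv` | v½ −13 mV, slope 14.5 mV, τ 1.5 s | – | composite delayed rectifier; rest/plateau repolarisation and the resting undershoot |
| stimulus shape (`s_up`, `plateau_frac`, `tau_plat`, `t_fall`, `w_fall`) | — | – | ICC waveform: upstroke steepness, sustained fraction, early decay, fall onset and width |

The Kv description is deliberately a *composite* whole-cell outward
current: a single activation gate with a shallow voltage dependence and a
slow (1.5 s) time constant, plus an essentially non-inactivating `y` gate,
which matches the recorded behaviour (large outward current, no
significant inactivation over 2 s, steady-state independent of holding
voltage) without resolving individual Kv subtypes.

## Protocols

* `run_free()` — free-running slow waves; `analyze_trace()` extracts
  per-cycle metrics (resting = mean per-cycle minimum; peak; amplitude;
  plateau = mean potential 0.5–2.5 s after each peak; frequency by peak
  detection at 2 mV prominence with a half-period minimum separation;
  Ca^2+^ extrema in nM).
* `run_voltage_clamp()` — forces the potential along a hold/step waveform
  with concentrations frozen (pipette dialysis); `normalize_iv()` produces
  normalized I–V relations; `clamp_protocol(egta = TRUE)` freezes the
  Ca^2+^-dependent transitions for the L-type fitting condition. Because
  the composite Kv activates with a 1.5 s time constant, *steady-state*
  currents are measured at the end of 8 s steps in the holding-voltage
  independence check; 2 s steps (as in the source recordings) show the
  same insignificant inactivation.
* `apply_ca_free()` — sets intra- and extracellular Ca^2+^ to 0.0001 nM so
  that E$_{Ca}$ = 0 mV, replicating the near-Ca^2+^-free bath.
* `variant_2apb()`, `variant_hwang()` — stimulus variants: 4.90 cycles per
  minute with a 19.7 % longer upstroke and 32.9 % smaller amplitude
  (2-APB), and an 8 s period with a −64 mV / 31 mV target phenotype
  (Hwang-matched).
* `sensitivity_sweep()` — ±50 % conductance or ±30 % activation/
  inactivation kinetics variants with tabulated metric deltas. The
  kinetics knobs scale the half-activation voltage and slope of an HH gate
  or the voltage-sensitivity constants of a Markov channel's
  activation/deactivation (or inactivation/recovery) edges.

## Problem sizes used by the shipped tests

The packaged test-suite runs the full protocols at reduced but meaningful
sizes: 180 s free runs (60 s burn-in) for morphology and Ca^2+^ metrics,
240 s for the stimulus variants, 30 simulated minutes for the homeostasis
check, 5 minutes for quiescence, 8 s clamp steps across ten holding
potentials, and ±50 % sensitivity sweeps of 150 s per variant. These match
the published experiment designs except where a quantity is a long-run
average, in which case the shortest window that stabilises the estimate
was chosen.

## What the synthetic data do and do not show

Test fixtures (a reversible three-state chain with a closed-form
stationary distribution, a square-ish synthetic slow wave with prescribed
metrics, random operating points for the transporter formulas) verify the
numerical machinery independently of the biology. Passing them shows the
solvers, metric extraction and current formulas are correct — not that the
cell model matches real tissue. The biological claims rest on the
protocol-level checks above, and those in turn inherit the limits of the
source data: a prescribed (not mechanistic) ICC waveform, BK kinetics
extrapolated from myometrial recordings at sub-micromolar Ca^2+^, pump and
exchanger densities fixed only by the homeostasis requirement, and no
intracellular Ca^2+^ stores, mechanosensitive channels or tissue coupling.

## Known limitations

* The supplementary rate tables of the original description were not
  available to this implementation; the channel kinetics are re-fitted
  against the published topologies and the cell-level phenotype, so
  individual rate constants should not be quoted as the original values.
* The ICC waveform needs one more shape constant than the published
  three-constant form (an explicit fall-onset time) to position the
  terminal repolarisation independently of its width.
* Very long simulations drift slowly in K^+^ (≈1.5 % between minutes 5 and
  30) because the ionic steady state is approached, not imposed.
* The model is a single cell; no conclusions about tissue-level slow-wave
  propagation follow from it.

## A worked example

```{r example, eval = FALSE}
params <- default_parameters()
trace <- run_free(params, duration = 180000)   # 180 s at dt = 0.1 ms
analyze_trace(trace)
#> slow-wave metrics (11 cycles):
#>   resting potential -59.61 mV, peak -36.64 mV, amplitude 22.97 mV
#>   frequency 6.00 cycles/min, time to peak 7641 ms
#>   free Ca2+ 88.7-255.8 nM
```
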