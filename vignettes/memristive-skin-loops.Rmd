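---
title: "Simulating and quantifying memristive V-I loops on human skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying memristive V-I loops on human skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memskin)
```

## The problem

When a low-frequency voltage of a few hundred millivolts to ~1 V is applied
to human skin, the measurement is often *non-linear*: the stimulus itself
changes the electrical state of the tissue. The voltage-current (V-I)
Lissajous figure then shows a *pinched hysteresis loop* — the fingerprint of
a memristor. Two tissue mechanisms produce this behaviour:

* **sweat ducts**: electro-osmosis moves sweat toward the surface during the
  positive half-cycle, filling the ducts and raising the conductance; the
  negative half-cycle drains them. The loop crosses its pinch *transversally*
  (different branch slopes), counter-clockwise in the first quadrant.
* **stratum corneum**: the keratinised outer layer behaves like an NTC
  thermistor. Joule heating is proportional to $v^2$, so its conductance
  peaks twice per period and the loop touches the pinch *tangentially*
  (equal slopes). In parallel with the layer's capacitance this mechanism
  produces loops with **two** pinched points.

`memskin` implements (i) a compact circuit simulator for these mechanisms
that serves as the package's synthetic-data generator, (ii) the per-loop
statistics used to quantify non-linearity, and (iii) the cohort-level
aggregation used to delimit the linear vs non-linear measurement range.

## The circuit model

The simulated element is a parallel combination (driven by
$v_{\mathrm{eff}} = v + e_{dc}$, where $e_{dc}$ lumps endogenous skin and
electrode half-cell potentials as a series EMF):

$$ i = \left[G_D(x) + G_S(T)\right] v_{\mathrm{eff}} + C_S \frac{dv}{dt} + \varepsilon, $$

with duct memductance $G_D(x) = g_{min} + (g_{max} - g_{min})\,x$ and
thermistor conductance
$G_S(T) = g_{ref} \exp\!\left[-B\left(1/T - 1/T_{ref}\right)\right]$.
The two internal states evolve as

$$ \frac{dx}{dt} = a(v_{\mathrm{eff}})\, v_{\mathrm{eff}} - \frac{x - x_0}{\tau_x},
   \qquad
   \frac{dT}{dt} = \frac{G_S(T)\, v_{\mathrm{eff}}^2 - (T - T_{amb})/R_{th}}{C_{th}}, $$

with $x$ clipped to $[0, 1]$ and $a(\cdot)$ switching between a fill gain
$a_+$ ($v_{\mathrm{eff}} > 0$) and a drain gain $a_-$. $\varepsilon$ is
i.i.d. Gaussian current noise (default sd 50 nA, an order below the
smallest cohort exclusion threshold).

Design choices that were genuinely open, and how they were resolved:

* **Voltage- vs current-driven duct state.** Electro-osmosis is driven by
  the electric field, so the filling state responds to the element voltage;
  a current-driven variant would behave similarly at these amplitudes but
  couples the two pathways. Voltage drive keeps the duct equation linear in
  the stimulus when $a_+ = a_-$, which makes the qualitative behaviour
  (loop orientation, frequency roll-off of the lobe area, NL growing with
  amplitude) provable rather than accidental.
* **Separate fill/drain gains** exist solely to reproduce the asymmetric
  phenotype (large first-quadrant, small third-quadrant lobes); symmetric
  subjects use $a_+ = a_-$.
* **Arrhenius NTC law** in $1/T$, the standard thermistor form; the thermal
  parameters are chosen so that currents below ~10 µA cause sub-kelvin
  temperature swings, which is all the two-pinch phenotype requires.
* **DC offset as a series EMF** is the simplest mechanism that shifts the
  pinched point off the origin.
* **Extended-memristor regime.** At high amplitude and frequency real skin
  can enter a regime where conductance depends on the instantaneous voltage
  itself ($i = G(x, v)\,v$). The model deliberately stays generic
  ($G$ depends on state only); the high-NL values such data produce are
  simply reported, not modelled.

### Numerical integration

Fixed-step classical RK4 on the stimulus sample grid with 10 internal
substeps per sample (the waveform is evaluated analytically at half-substep
points; the capacitive term uses the analytic $dv/dt$, so no differencing
noise enters). At 500 samples/period this resolves the fastest default time
constants by 2-3 orders of magnitude; the NL of a default loop changes by
less than 0.5% when re-integrated at 20x denser sampling (tested). Stiff
parameter regimes are rejected rather than integrated: if the temperature
state leaves $(0, T_{amb} + 100\,\mathrm{K}]$ or becomes non-finite, the
simulator raises a `numerical_failure` error naming the thermal parameters.

### What the generator emulates — and what it does not

The cohort generator (`sample_population()`, `simulate_cohort()`) draws
subjects from five phenotype classes (symmetric large-lobe, small-lobe,
asymmetric, shifted-pinch, and two-pinch thermistor-dominated) with mixture
weights 6:10:8:1:3 over 28, matching the observed forehead frequencies.
Per-class parameter medians and log-normal spreads live in a versioned
config (`inst/extdata/phenotype_defaults.json`); they are package choices
tuned to reproduce the qualitative phenotypes, **not** fits to any
subject's data. The generator reproduces: loop orientation and pinch
topology per class, amplitude/frequency dependence of lobe area and NL,
pinched-point drift with frequency, DC offsets and current noise. It does
not emulate: electrode-skin interface chemistry, drift of the baseline
sweat level over a session, inter-channel crosstalk, instrumentation
filtering, or any spatial structure of the ducts. Passing tests therefore
demonstrate correctness of the estimators on data whose generating
mechanism is known — they do not validate the circuit model against real
skin.

## Per-loop statistics

All statistics are computed on the sign-corrected loop (voltage and current
multiplied by the stimulus sign) for the chosen period, conventionally the
third, by which the loop shape has stabilised.

**Non-linearity.** With $v_{max}$ the stimulus amplitude,

$$ NL = \frac{i_{max} - i(0.5\, v_{max})}{i(0.75\, v_{max}) - i(0.5\, v_{max})}, $$

where $i_{max}$ is the *global* current maximum over the period (the
memristive state keeps growing past the voltage peak, so the maximum falls
beyond 90°) and the two reference currents are interpolated on the
ascending-voltage branch in the first quadrant (the descending branch of a
pinched loop would give different values; the ascending branch is the
conventional one). A linear in-phase response gives exactly 2; memristive
loops give more; a capacitive phase lead biases the value below 2 (a 2.1°
lead at 2.5 Hz already gives 1.93). The statistic is exactly invariant to a
DC current offset. Degenerate loops (denominator below 1 pA, configurable)
raise an error rather than returning a huge ratio.

**Lobe area.** The closed curve is split at its two voltage extrema into an
ascending and a descending branch, both are resampled onto a uniform
500-node voltage grid per voltage-sign region, and the absolute trapezoid
area difference is accumulated step by step — taking absolute values
stepwise keeps the contributions on either side of the pinch from
cancelling, so the result is the total lobe area wherever the pinch sits.
The quadrant split uses the sign of the voltage, because the pinch is not
assumed to lie at the origin. An independent geometric route
(`lobe_area_polygon()`: brute-force segment intersection, decomposition
into simple loops, summed absolute shoelace areas) agrees within 0.02% on
simulated loops and serves as the fallback when a branch is non-monotone.

**Pinched points.** Brute-force $O(n^2)$ segment-pair intersection over the
closed polyline; intersections within 1% of the per-axis data range are
merged (noise makes exact intersection ill-posed), and branch directions
are estimated by a local principal axis over ±5 samples in range-normalised
coordinates. A pinch is *tangential* when the branch directions agree
within 15°. A purely tangential touch (thermistor without capacitance)
produces no polyline crossing at all — the tangential flag is exercised via
the two off-origin crossings that appear once the parallel capacitance is
added, which is also the mechanism that yields two pinched points.

**Phase shift and lock-in admittance.** For the linear small-signal regime,
$\alpha = \tan^{-1}(2\pi f C / G)$, its state-dependent generalisation
$\alpha(x, T)$ along a conductance trajectory, and a lock-in demodulator
(`lockin_admittance()`) that separates conductance and susceptance by
averaging $i$ against quadrature references over whole periods — the
standard 100 mV / 20 Hz admittance check before and after a non-linear
protocol.

## Cohort aggregation

`exclusion_filter()` drops loops whose maximum current is below the
amplitude-specific noise threshold (2.1, 1.4, 0.7 µA at 1.2, 0.8, 0.4 V;
rows exactly at the threshold are retained, since only values *below* the
threshold are excluded; other amplitudes scale at 1.75 µA/V).
`summarize_cohort()` reports mean, median and 5%/95% percentiles (linear
interpolation between order statistics, R's type-7 definition — the
convention is a package choice, verified against a brute-force oracle) of
$\log_{10}$ lobe area, $\log_{10} i_{max}$ and NL per site x waveform x
amplitude x frequency group.

`fit_nl_mixed_model()` fits
$NL \sim 1 + |A| + \log_2 f + (1\,|\,\mathrm{subject})$
by REML via `lme4`, with profile-likelihood 95% CIs (Wald available for
speed). The frequency coefficient is reported per unit $\log_2 f$; one
*bisection* of the frequency is $\Delta \log_2 f = -1$, so "NL increases by
0.075 per bisection" corresponds to a coefficient of $-0.075$ here.
P-values are deliberately not reported — denominator degrees of freedom for
mixed models are convention-dependent — so inference uses the CIs.

`boundary_map()` reduces the summaries to the boundary of the non-linear
measurement range: per frequency, the smallest tested amplitude whose group
median NL exceeds 2.05 (or whose lower 5% whisker does, for the
"more than 95% of subjects non-linear" variant).

## Worked example

```{r example, eval = FALSE}
spec <- population_spec(n_subjects = 28, seed = 1)
recs <- simulate_cohort(spec)                  # 28 subjects x 30 stimuli
tbl  <- analyze_recordings(recs, period_index = 3)
kept <- exclusion_filter(tbl)$kept
sinus <- kept[kept$kind == "sinusoidal", ]
summ <- summarize_cohort(sinus)
fit  <- fit_nl_mixed_model(sinus)
boundary_map(summ)
```

Problem sizes used throughout the documentation and tests — 28-subject
cohorts at 500 samples/period, 200-loop oracle comparisons, 50-replicate
parameter-recovery runs — were chosen so that every documented property is
exercised at the scale of the original protocol while remaining quick to
re-run on a laptop.

## Interfaces

Recordings serialise to CSV (`time_s,voltage_V,current_A`, 17 significant
digits for bitwise round-trips) with a JSON metadata sidecar; metrics
tables to CSV with a units sidecar; stimulus grids and population specs to
JSON configs. Externally acquired data enter through `as_recording()`,
which maps arbitrary data-frame columns onto the recording contract —
deposited datasets have no standardised internal layout, so that mapping
is left to the user. The package deliberately exposes no shell entry
point: the pipeline is four function calls (above), and
`scripts/acceptance.R` reproduces the reference values from the command
line.

## Known limitations

* The circuit model is the *minimal* mechanism set reproducing the observed
  phenotypes; it makes no claim of physiological parameter identifiability.
* NL on triangular stimuli is computed with the same voltage-level formula;
  this is an extension beyond its sinusoidal definition and is flagged in
  the metric's documentation.
* Pinch detection on tangentially touching (non-crossing) loops reports no
  pinch; slope equality at the origin must then be assessed directly from
  the branches.
* The mixed model assumes a homoscedastic Gaussian residual; heavy-tailed
  NL distributions at high amplitude are summarised more robustly by the
  percentile summaries.
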