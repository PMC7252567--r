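---
title: "Methods: five-tier individual-level exposure modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five-tier individual-level exposure modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fivetiers` estimates daily individual-level exposure metrics for four
ambient pollutants — PM2.5, elemental carbon (EC), nitrogen oxides (NOx) and
carbon monoxide (CO) — at five nested tiers, each split into background,
on-road and total source components. This vignette documents the model
equations, the assumptions behind them, the tunable parameters, the numerical
choices, what the synthetic-study generator does and does not emulate, and
the package's known limitations.

## The participant-day

All metrics are 24-h summaries over the half-open window [08:00, 08:00 + 24 h)
of local study time, matching a clinical protocol in which participants are
instrumented in the morning and return the next morning. Hourly series carry
24 values per day (the stamp `h` represents `[h, h+1)`); 5-s series carry
17,280 ticks; accelerometer counts come in 1-s epochs (86,400 per day). Each
clinic day is modeled together with its five preceding *lag days*, which have
no logger data of their own: locations, microenvironment labels and activity
counts are copied from the observed day, while concentrations, weather and
air exchange use each lag day's own values. On weekend lag days, time at work
is re-assigned to home (labels *and* geolocations), since the observed day is
a weekday. Lag days are flagged `imputed` in the output, and days shared by
overlapping visits are counted once per visit (multiplicity), with unique
days reported separately by `glance()`.

## Tier 1 — home outdoor concentrations

Tier 1 is a lookup: the hourly concentration field (in applications, the
output of a dispersion model for on-road sources plus an interpolated
background surface, at census-block centroids) is read at the centroid
nearest the home. The package deliberately does not implement dispersion or
kriging; any field in the documented CSV dialect can be ingested. The field
contract is `total = background + onroad` at every centroid-hour, which the
`concentration_field()` constructor enforces.

## Tier 2 — indoor infiltration

Indoor concentrations of *ambient* (outdoor-origin) pollutant follow a
single-compartment mass balance,

$$\frac{dC_{in}}{dt} = \mathrm{AER}\,P\,C_{out} - (\mathrm{AER}+k_r)\,C_{in},$$

with penetration coefficient $P$ (fraction crossing the envelope with
infiltrating air) and first-order indoor removal $k_r$ (deposition/reaction).
The loss term acts on the indoor concentration, as mass conservation
requires. There are no indoor sources by construction: the model quantifies
ambient pollution indoors, not total indoor air quality. Adopted parameter
values (`pollutant_params()`): PM2.5 $P=0.84$, $k_r=0.21\,h^{-1}$; EC 0.98,
0.29; NOx 1.00, 0.5; CO 1.00, 0. CO's $k_r = 0$ is taken literally — no
indoor sink at any temperature — so its equilibrium indoor/outdoor ratio is
exactly 1 at any air exchange rate, and with a constant field every tier
collapses to the outdoor value (a property the acceptance tests exploit).

Numerics: with outdoor concentration and AER piecewise-constant per hour the
balance has an exact solution, so the series is advanced by the exponential
update $C_{ss} + (C_{in}-C_{ss})e^{-(\mathrm{AER}+k_r)\Delta t}$ — unconditionally
stable, no discretisation error at the hourly cadence. The tests cross-check
it against an independent 1-s forward-Euler integration (agreement within
0.1% of the daily mean over 100 random days). The initial condition is the
first hour's steady state rather than zero: an arbitrary zero start would
contaminate the first daily average with a spin-up transient. `indoor_series()`
accepts an explicit `init` where a different convention is wanted. When
$\mathrm{AER}+k_r = 0$ the indoor concentration has no dynamics and holds its
initial value; the steady-state ratio is undefined there and raising an error
is the only honest answer.

## The air exchange rate

Hourly AER comes from the classic Lawrence-Berkeley-Laboratory lineage:
leakage through unintentional envelope openings,

$$Q_{leak} = A_{leak}\sqrt{k_s\,|T_{in}-T_{out}| + k_w U^2},$$

natural ventilation through reported open windows/doors, and mechanical
ventilation from reported window fans, combined in quadrature
($Q_{total} = \sqrt{Q_{leak}^2+Q_{nat}^2+Q_{mech}^2}$, AER $= Q_{total}/V$).
Design choices made here, all configurable via `home_model()`:

- The stack coefficient $k_s$ ((m/s)²/K) defaults by number of stories
  (0.0145 / 0.0290 / 0.0435 for 1–3 stories) and the wind coefficient $k_w$
  (dimensionless) by a 1–5 shielding class (0.1156 down to 0.0121, squared
  shielding factors in the LBL convention). These lookups are documented
  stand-ins in the right magnitude range, not fitted values; studies with
  blower-door or tracer data should override them.
- Natural ventilation is modeled as orifice flow through the reported
  openable area with discharge coefficient 0.6, driven by the same stack and
  wind pressure terms — the simplest defensible physical model given only
  questionnaire-level information ("windows or doors open today").
- Indoor temperature is held at the questionnaire value for the whole day;
  occupant behaviour (windows, doors, fans) reported on a clinic day is
  assumed to persist across that visit's five lag days.

## Tier 3 — personal outdoor concentrations

Every 5-s GPS sample is matched temporally to the enclosing field hour
(piecewise-constant binning, no interpolation between hours — the hourly map
is the finest temporal truth available) and spatially to the nearest centroid
by great-circle (haversine) distance, ties broken deterministically to the
lowest centroid id. At county scale the haversine error versus a projected
distance is far below the centroid spacing. Ticks with a missing or invalid
fix reuse the previous sample's geolocation (receivers drop out indoors); a
leading gap back-fills from the first valid fix, the only defensible choice
when the day starts indoors.

## Tier 4 — microenvironment-weighted exposure

Exposure at each tick weights the two concentration series by the occupied
microenvironment:

$$E = ME_{in\_home}C_{in\_home} + \left[(ME_{in\_work}+ME_{in\_other})
F_{inf\_other\_bldg} + ME_{in\_vehicle}F_{inf\_vehicle} + ME_{out}\right]
C_{out\_personal}.$$

Non-residential buildings and vehicles get equilibrium infiltration factors
rather than a dynamic balance — their envelope parameters are unknowable at
panel-study scale. Adopted values: $F_{inf\_other\_bldg}$ = 0.64, 0.59, 1.00,
1.00 and $F_{inf\_vehicle}$ = 0.44, 0.44, 0.80, 1.00 for PM2.5, EC, NOx, CO.
The hourly indoor series is held piecewise-constant across each hour's 720
ticks — the bridge between the hourly and 5-s cadences. The 5-class
microenvironment set (three outdoor classes merged) is used in the exposure
equation; the dose bookkeeping below retains all seven classes.

### Microenvironment classification

The classifier maps each tick of the GPS track to one of seven
microenvironments with a small decision tree: (1) speed above 10 km/h
sustained for ≥ 30 s ⇒ in vehicle; (2) otherwise the place is home, work or
other by membership in a 40 m radius buffer around the geocoded centres
(nearest wins); (3) indoors versus outdoors by fix quality — an invalid fix
or position dilution of precision (PDOP) above 4 indicates a roof overhead;
(4) missing ticks inherit the previous label; (5) a 60-s centred majority
vote smooths spurious single-tick flips, ties keeping the incumbent label.
Carry-forward is applied *before* smoothing so the vote always sees a
gap-free series — smoothing across unfilled gaps would be ill-defined. All
thresholds are configurable in `place_geometry()`. This tree is a faithful
simplification of GPS-based classifiers in the exposure literature, not a
reproduction of any specific one; buildings are radius-buffered points
(a polygon hook can replace the radius test without touching the rest).
Whether real receivers are better summarised by PDOP or satellite count
indoors varies by device; PDOP-plus-validity is the stand-in here. On
synthetic tracks with default noise the classifier recovers ≥ 95% of
ground-truth tick labels (field evaluations of such classifiers against
diaries report ~99% of daily time).

## Tier 5 — inhaled dose

Each tick's exposure is split over the seven microenvironments
($E_i$ non-zero only for the occupied one) and converted to an inhaled dose
increment $D_i = E_i \cdot MV \cdot \Delta T / BSA$ with $\Delta T$ exactly
$5/60$ min (not the rounded 0.083). Minute ventilation comes from the
accelerometer: counts are summed over the trailing 60 s at each tick
(history before the day start zero-padded, biasing only the first minute
toward sedentary), classified into sedentary/light/moderate/vigorous with
the Actical cut-points 100/1535/3962 cpm (boundaries belong to the upper
class), overridden to sedentary whenever the time-matched microenvironment
is in-vehicle (accelerometers read vehicle vibration as activity), then
mapped to normalised minute ventilation (NMV, L/min/kg) by activity level,
age band and sex, and scaled by body weight. Two METS conventions coexist in
the literature for "sedentary" (< 2.0 for the count thresholds, ≤ 1.5 for
the NMV bands); the count thresholds govern classification and the NMV bands
govern lookup, linked only by the level name. NMV is looked up by age band,
not interpolated within bands. The shipped NMV table is a **synthetic
placeholder** (plausible magnitudes, monotone in activity level, higher
per-kg for children): published NMV medians are not redistributable here, so
studies must supply their own via `read_nmv_table()`; the package tests
inject their own table so no result depends on the defaults. Dose is
normalised by DuBois body surface area. Daily dose is the sum of the 17,280
increments; by construction the per-microenvironment doses sum exactly to
the total and the per-microenvironment minutes to 1440.

## Linearity and component additivity

Every concentration-processing stage — infiltration, spatial lookup, the
exposure equation, the dose increment — is linear in concentration with
coefficients (AER, labels, ventilation) that do not depend on concentration.
Background and on-road components therefore add exactly to the total at
every tier, which `check_tier_records()` verifies to 1e-6 relative on every
record (dose conservation to 1e-9).

## The synthetic study generator

`generate_study()` emulates the data-generating process of the panel design
at its defaults: 15 adult participants (45–80 y), 120 clinic participant-days
in consecutive-weekday pairs spread over ~two years, five lag days each
(720 scheduled participant-days), a ~30 km county-scale domain with a 10×10
centroid grid and two roads. Choices a practitioner would recognise:

- **Fields.** Background = fixed smooth random spatial loadings × diurnal
  cycle × lognormal day factor (means 11, 0.6, 18, 350 µg/m³ for PM2.5, EC,
  NOx, CO); on-road = exponential near-road kernel (250 m e-folding) on top
  of a 25% diffuse urban share, × a rush-hour traffic profile (peak
  strengths 2.5, 4.5, 130, 220 µg/m³). The strengths are set so the on-road
  share rivals or exceeds background for EC and NOx but not for PM2.5 and
  CO, the qualitative ordering such urban dispersion studies report. Totals
  are background + on-road by construction.
- **Days.** Ground-truth plans (home → commute → work → lunch walk → commute
  → home → evening outdoor episode for workers; home/errand templates
  otherwise) are realised as GPS points with 5–9 m location noise, indoor
  fix degradation (PDOP inflated above the classifier threshold, 15%
  invalid fixes, 35% dropout) and commute speeds that traverse the
  home–work distance on time. Accelerometer counts are Poisson draws with
  per-second means 0.7/10/42/80 by planned activity level, placing the
  60-s sums inside the intended cut-point bands.
- **Reproducibility.** Every generated object is deterministic in
  (scenario seed, stream, date, participant), so any single participant-day
  regenerates in isolation; the ground truth is returned alongside the
  observations.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: real dispersion physics and meteorologically
driven field correlation, GPS multipath structure (noise is i.i.d., real
urban error is autocorrelated), device-specific accelerometer spectra,
questionnaire misreporting, and map-matched travel on road networks. Tests
against the generator validate the *pipeline's* correctness and its
contracts, not the field accuracy of the classifiers.

## Problem sizes in the test suite

The shipped tests run the complete pipeline at the design's full scale
(120 clinic participant-days → 720 scheduled participant-days → 8,640
records) once, plus a smaller 3-participant study for the additivity and
conservation audits and single participant-days for the behavioural checks
— sizes chosen to exercise every code path, including weekend lag rules and
overlapping visits, while keeping the default suite comfortably fast.

## Known limitations

- Supplementary engineering tables for the AER model (stack/wind
  coefficients by construction type, exact natural/mechanical flow forms)
  are represented by configurable stand-ins; absolute AER levels should not
  be interpreted without calibration.
- The NMV defaults are placeholders (see above).
- No HVAC/duct modeling, humidity effects, indoor sources, map matching,
  transit-mode inference beyond in-vehicle, or health-outcome modeling.
- The timezone handling assumes a single study clock with no daylight-saving
  discontinuities inside a participant-day window.
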