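# amylokin

Analysis of amyloid aggregation kinetics and aggregation-inhibitor
screens from plate-reader fluorescence data, for groups running
thioflavin-T (ThT) fibrillation assays, fibril-disaggregation
endpoint assays, or bacterial inclusion-body (thioflavin-S) screens
of candidate anti-aggregation compounds.

## The model

A ThT time course is fitted with the minimal autocatalytic
nucleation–elongation scheme. With f(t) the fraction of peptide in
aggregated form, k_n (s⁻¹) the nucleation rate constant, k_e
(M⁻¹s⁻¹) the elongation rate constant and a the initial monomer
concentration,

    df/dt = k (1 − f)(ρ + f),   k = k_e·a,   ρ = k_n / k,

whose closed form under f(0) = 0 is

    f(t) = ρ (e^((1+ρ)kt) − 1) / (1 + ρ e^((1+ρ)kt)).

Nonlinear regression of f against t yields (ρ, k), hence k_n = ρk and
k_e = k/a, plus the characteristic times of the sigmoid: the lag time
t₀ and end time t₁ from the tangent at the inflection point, and the
half-aggregation time t₁/₂ (f = 0.5). Endpoint screens reduce to
two-point control normalizations (percent inhibition, percent
disaggregation, in cellulo percent inhibition) with mean ± SEM over
replicates and an OD620 toxicity flag.

## Worked example

Simulate a triplicate ThT experiment at the uninhibited reference
condition (k_n = 3.09×10⁻⁵ s⁻¹, k_e = 486.9 M⁻¹s⁻¹, 10 μM monomer,
one reading per 5 min, 5% multiplicative noise) and refit it:

```r
library(amylokin)

p <- kinetic_params(k_n = 3.09e-5, k_e = 486.9, a = 1e-5)
cfg <- generator_config(p, t_span = 5000, t_step = 300,
                        noise_cv = 0.05, n_replicates = 3, seed = 20260927)
traces <- generate_timecourse(cfg)
fit <- fit_condition(lapply(traces, normalize_trace), a = 1e-5)
print(fit)
#> Autocatalytic fit ('synthetic', 17 points, 3 replicates)
#>   rho = 0.006082   k = 0.004783 s^-1   RMS = 0.0262
#>   k_n = 2.909e-05 s^-1   k_e = 478.3 M^-1 s^-1 (a = 1e-05 M)
#>   t0 = 650 s   t_half = 1063 s   t1 = 1476 s
```

The fitted nucleation constant (2.91×10⁻⁵ s⁻¹) lands within ~6% of
the generating value and the elongation constant within ~2%, typical
for a single triplicate at this noise level; the lag (t₀ ≈ 650 s),
half (t₁/₂ ≈ 1063 s) and end (t₁ ≈ 1476 s) times are read off the
fitted curve by the tangent construction. Endpoint screens follow the
same pattern:

```r
plate <- generate_endpoint_plate(c(cmp18 = 80), "inhibition_in_cellulo",
                                 noise_cv = 0.02, seed = 1)
screen_plate(plate, "inhibition_in_cellulo")
#>   compound                metric  percent       sem n toxic
#> 1    cmp18 inhibition_in_cellulo 79.95995 0.2313161 3 FALSE
```

The numbered scripts under `analysis/` run the full workflow —
simulate raw CSVs, fit the three kinetic conditions and compare them
against control, screen the endpoint plates, and quantify recovery
error versus noise — writing their tables under `results/`.

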