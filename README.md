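# gaitpolar

Gait-disorder assessment from insole ground-reaction-force (GRF) recordings,
for researchers and engineers working with wearable plantar-pressure
hardware. The package implements a full pipeline from raw five-sensor-per-
foot force traces to a per-subject classification:

1. **COPx extraction** — the signed medial–lateral centre of pressure,
   pooled over both feet so its sign encodes the stance side:
   `COPx = (Σ Fᵢ·xᵢ / Σ Fᵢ) · 100 / x₅ₜₕ₋ₘₑₜₐ` (percent of the
   fifth-metatarsal coordinate).
2. **Continuous gait phase** — a fifth-order adaptive frequency oscillator
   entrains to COPx (`φ̇ᵢ = iω + k_φ e cos φᵢ`, `ω̇ = k_ω e cos φ₁`,
   `α̇ᵢ = k_α e sin φᵢ`, `α̇₀ = k₀ e`, `e = u − û`), yielding a phase
   `φ₁ ∈ [0, 2π)` per sample without event detection.
3. **Polar gaitogram** — samples replotted as `(θ, r) = (φ₁, |COPx|)` form
   an upper (right-stance) and lower (left-stance) closed curve. Their
   areas `∫ ½ r² dθ` give the **area ratio index**
   `ARI = |Arearatio_R − Arearatio_L|`, a weight-bearing-time asymmetry in
   percent, plus the tangent-line angle between the two weight-transfer
   points. With an ARI threshold of 10%, a per-foot share above
   `50 + 10/2 = 55%` flags a gait disorder and marks that foot as the
   unaffected side.
4. **Reference indices** — PPD (normalised per-foot force-sum difference)
   and PCI (stepping-phase deviation + coefficient of variation from heel
   strikes), for comparison with event-based methods.
5. **Group statistics** — exact Mann–Whitney U tests, range-separation
   flags and summary tables for healthy-vs-stroke cohorts, with the
   12-subject reference index table shipped as a fixture.

A seeded synthetic-gait generator with known ground truth (stance-time
duty, load asymmetry, step offset, cadence, noise, shuffling artefacts)
makes the whole pipeline testable without clinical data.

## Worked example

```r
library(gaitpolar)

# a stroke-like synthetic subject: stance time and load shifted to the
# unaffected right foot, delayed left step, shuffling artefacts
tr <- generate_trial(stroke_gait_template(seed = 42))$trial
attr(tr, "group") <- "stroke"          # selects the slow-adaptation gains
rep <- analyze_trial(tr)

round(rep[c("arearatio_R", "arearatio_L", "ARI",
            "ang_tangent_cartesian", "ppd", "pci")], 2)
#>   arearatio_R arearatio_L   ARI ang_tangent_cartesian   ppd   pci
#>         58.18       41.82 16.36                  0.51 54.56 25.33
rep[c("verdict", "affected_side")]
#>   verdict  affected_side
#>   disorder left
```

The right foot carries 58% of the gaitogram area (ARI 16.4% > 10%), so the
subject is classified as having a gait disorder with the left side
affected — which is exactly how the template was constructed. On the
packaged reference cohort:

```r
cmp <- compare_groups(gait_index_table())
glance(cmp)
#>   ari_mean_ratio ari_separated   p_ari   p_ppd   p_pci alpha
#>             7.56 TRUE          0.00404 0.00836 0.00808  0.05
```

ARI separates the groups completely (healthy max 6.9% vs stroke min
12.2%), its group-mean ratio is ≈ 7.6, and the exact Mann–Whitney test
gives p = 2/495 ≈ 0.004. Visualisation: `autoplot()` on a
`polar_gaitogram` or `gait_phase_series`, and `plot_index_comparison()`
for the per-group index dot plots. A command-line front end lives at
`inst/scripts/gaitpolar.R` (`simulate`, `analyze`, `compare`).

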