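# htrpet

Single-scan estimation of blood-brain-barrier (BBB) permeability from
high-temporal-resolution (HTR) dynamic PET.

Quantifying how readily a molecule crosses the BBB — its
permeability-surface-area product, PS (ml/min/cm³) — normally requires
either invasive multi-tracer protocols or stops at the transport rate
K₁ = E·CBF, which confounds permeability with blood flow. With 1–2 s frames
(total-body PET class scanners), the finite time tracer spends traversing a
voxel's vascular tree becomes visible in the time-activity curve, and a
distributed kinetic model — the adiabatic approximation to the
tissue-homogeneity model (AATH) — can estimate cerebral blood flow CBF and
K₁ *jointly* from a single 2-minute scan:

- impulse response R(t) = CBF for 0 ≤ t < T꜀ (vascular transit phase),
  K₁·e^(−k₂(t−T꜀)) for t ≥ T꜀ (tissue washout);
- extraction fraction E = K₁/CBF, and via the Renkin-Crone relation
  **PS = −CBF·ln(1 − E)** (indeterminate at E = 1, i.e. freely diffusible
  tracers);
- blood volume fraction v_b = CBF·T꜀, delay t_d to the arterial sampling
  site.

Fitting uses the basis-function method: exhaustive search over
(t_d, T꜀, k₂) — 65 × 53 × 100 = 344,500 grid nodes for regional fits — with
a closed-form non-negative linear least-squares solve for (CBF, K₁) at each
node, plus the standard one-tissue compartment model (S1TC) and
corrected-AIC comparison to show when HTR framing is actually needed. The
package is aimed at researchers developing or validating PET kinetic
methods: everything runs on synthetic data (bolus input functions,
count-statistics noise, dispersion and metabolite models, digital
phantoms), with Monte-Carlo identifiability and sensitivity machinery and
voxel-wise NIfTI parametric mapping (CBF, K₁, k₂, T꜀, t_d, E, PS, v_b). A
Michaelis-Menten facilitative-transporter model links glucose-analogue PS
to blood glucose.

## Worked example

Simulate a 2-minute grey-matter-like curve (60 × 1 s + 30 × 2 s frames),
add count-statistics noise, and fit it:

```r
library(htrpet)

schedule <- default_htr_schedule()                      # 90 frames, 120 s
aif <- generate_aif(schedule = schedule)                # synthetic aorta input
truth <- aath_params(CBF = 0.5, K1 = 0.165, k2 = 0.33,  # ml/min/cm3, min^-1
                     Tc = 7, td = 2)                    # seconds
tac <- add_noise(generate_aath_tac(truth, aif, schedule),
                 noise_model(seed = 1))

fit <- fit_curve(tac, aif, schedule, regional_grid_spec())
print(fit)
#> AATH fit: wrss=9.77144, AIC=-189.117
#> AATH: CBF=0.4726 K1=0.1659 ml/min/cm3, k2=0.3334 min-1, Tc=7.5 s, td=1.75 s (E=0.351)
#> Derived: E=0.351, PS=0.2043 ml/min/cm3, vb=0.05908 ml/cm3, Ve=0.4976 ml/cm3
```

The fit recovers the generating kinetics to a few percent under noise: CBF
0.47 vs 0.50, K₁ 0.166 vs 0.165 ml/min/cm³, and PS 0.204 vs the true
−0.5·ln(1 − 0.33) = 0.200 ml/min/cm³. Frame-averaging the same curve to
conventional resolution shows why HTR matters — the AATH model is decisively
preferred (ΔAIC < 0) at 1 s frames but loses its advantage at 10 s, where
the vascular phase is averaged away:

```r
compare_models(tac, aif, voxel_grid_spec(), intervals = c(1, 10))
#>   interval  M   aic_aath  aic_s1tc  delta_aic
#> 1        1 90 -189.39549 -57.12688 -132.26861
#> 2       10 12   25.68008  19.40646    6.27362
```

Other entry points: `run_identifiability()` (Monte-Carlo error analysis),
`sensitivity_analysis()`, `fit_voxelwise()` + `write_parametric_maps()`
(NIfTI maps from 4D images), `generate_phantom()`, `fit_mm()`
(PS-glucose transporter kinetics), and the `inst/cli/htrpet` command-line
wrapper (`simulate`, `fit-roi`, `fit-voxel`, `identifiability`, `mm-fit`,
`compare-models`, ...).

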