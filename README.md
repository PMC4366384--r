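# fgf21pkpd

Integrated PK/PD modeling of a long-acting antibody–FGF21 conjugate whose
two FGF21 arms are cleaved at different rates at the C- and N-terminus.
The C-terminus (required for β-klotho binding) is lost within hours while
the N-terminus (required for FGFR1c engagement) persists for days, so the
circulating drug separates into a short-lived, potent **intact** pool and a
long-lived, potency-right-shifted **N-only** pool. The package implements
the full quantitative chain needed to ask which pool drives glucose
lowering (OGTT in ob/ob mice) and body-weight loss (DIO mice):

- **Non-compartmental analysis** — linear-up/log-down trapezoidal AUC,
  terminal t½ = ln 2/λz, CL = dose/AUC(0–∞), Vc, Vss, and ratio-of-means
  subcutaneous bioavailability F = 100·(AUC_sc/dose_sc)/(AUC_iv/dose_iv).
- **Cleavage-network PK (ob/ob)** — every molecule is a bit array
  [C₁ N₁ C₂ N₂]; 16 species, independent first-order clipping per terminus
  (t½ 2.5 h / 13 h), backbone clearance (t½ 12 d), depot absorption
  (t½ 48 h); a 32-state linear ODE system with closed-form and
  per-molecule Monte-Carlo cross-checks.
- **Tissue PK (DIO)** — intact/N-only species in depot, central (2.4 ml)
  and adipose-extracellular (0.8 ml) compartments exchanging at
  0.0167 ml/hr, reproducing the 1.7 h / 26.2 h assay half-lives exactly.
- **Receptor occupancy** — intact and N-only pools competing for a
  4.15 nM KLB/FGFR1c complex (K_D,I = 0.5 nM fixed, K_D,N estimated);
  guaranteed-convergent scalar reduction of the 5-equation equilibrium.
- **OGTT PD** — hyperbolic instantaneous signaling
  S = (I/K_I + N/K_N)/(1 + I/K_I + N/K_N) convolved with an exponential
  persistence kernel of time constant γ; amplitude anchored to the day-3
  10 mg/kg response; (K_N, γ) fitted by multi-start simplex.
- **Body-weight PD** — energy balance with TAT = 0.46·BW − 9.9 g,
  RMR 0.86 kJ/(g FFM·d), overfeeding response (BW_ctrl/BW_trt)^β, adipose
  thermogenesis −ε·P·TAT, and dBW/dt = ΔE/22.274 kJ·g⁻¹, fitted
  simultaneously to five dosing arms.
- **Synthetic-data generators** — seeded emulation of the study designs
  (sampling grids, LLOQ censoring, noise models) with known ground truth,
  so every fit is validated by parameter recovery.

## Worked example

Fit the OGTT model to a synthetic dataset generated at the published
parameter values (K_N = 22 nM, γ = 3 days, 5% noise):

```r
library(fgf21pkpd)
exps  <- list(SC = ogtt_reference_exposure("SC", max_day = 6))
truth <- ogtt_pd_params(K_I = 0.5, K_N = 22, gamma = 3, A = 100)
data  <- gen_ogtt_dataset(generator_spec(seed = 1, noise_cv = 0.05),
                          truth = truth, exposures = exps)
fit   <- fit_ogtt(data, exps)
round(c(K_N = fit$params$K_N, gamma = fit$params$gamma), 2)
#>   K_N gamma
#> 31.32  3.49
ogtt_n_only_fraction(5, 10, "SC", exps, fit$params)
#> [1] 0.9522015
```

One noisy replicate lands near the truth (the acceptance suite shows the
median over 20 replicates recovers K_N within 25% and γ within 20%), and
~95% of the modeled day-5 effect survives with the intact pool removed:
the late glucose-lowering is carried almost entirely by the N-only pool,
the central modeling conclusion.

The numbered scripts under `analysis/` run the complete workflow — NCA
tables, ob/ob pool simulation with stochastic-oracle checks, the OGTT fit,
DIO tissue PK (model bioavailabilities, NT Tmax, fat-to-plasma buildup),
and the five-arm body-weight fit — writing their tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

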