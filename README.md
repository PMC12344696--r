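# specbind

Spectroscopic binding analysis for protein–ligand encapsulation studies.

`specbind` is for biophysical spectroscopists characterizing how a small
hydrophobic ligand (e.g. the heme catabolite bilirubin) binds to and is
encapsulated by a self-assembling protein host (e.g. casein micelles).
It implements the complete analysis chain such a study runs, as tested,
reusable R functions:

| stage | functions | what it yields |
|---|---|---|
| spectral preprocessing | `inner_filter_correct`, `band_descriptor`, `find_isosbestic`, `shift_profile` | corrected intensities, λ_max, FWHM, isosbestic points, red-shift profiles |
| equilibrium binding | `hill1_fit`, `convert_kd_to_molar`, `stern_volmer_fit`, `double_log_hill_fit` | k_D, Hill n, K_b (M⁻¹), K_sv, k_q, K_a |
| thermodynamics | `vant_hoff_fit`, `gibbs`, `classify_forces` | ΔH, ΔS, ΔG(T), Ross–Subramanian force class |
| time-resolved fluorescence | `multiexp_fit`, `average_lifetime`, `lifetime_stern_volmer` | τᵢ, αᵢ, τ_av, χ²_red, dynamic K_D |
| FRET | `efficiency_from_quenching`, `overlap_integral`, `forster_radius`, `distance_from_efficiency`, `energy_transfer_rate`, `radiative_rate`, `decompose_rates`, `fret_chain` | E, J, R₀, r, k_ET, k_r, Σk_nr |
| micellization & morphology | `pyrene_ratio`, `cmc_fit`, `roughness` | CMC (mg/mL), AFM R_a / R_q |
| synthetic data | `gen_absorbance_titration`, `gen_quench_series`, `gen_decay`, `gen_pyrene_ratio`, `gen_height_map`, `simulate_study` | seeded fixtures with known truth |
| orchestration | `pipeline_config`, `run_pipeline`, `write_report` | one auditable report of every value + unit + constant |

The models at the core, in standard notation:

- Hill isotherm `y = start + (end−start)·xⁿ/(k_Dⁿ + xⁿ)`; K_b = MW/k_D.
- Stern–Volmer `(F₀−F)/F = K_sv[Q]`, k_q = K_sv/τ₀.
- van't Hoff `ln K_a = −ΔH/RT + ΔS/R`; ΔG = ΔH − TΔS.
- Multi-exponential TCSPC decay `I(t) = Σ αᵢ e^(−t/τᵢ)` (tail or
  IRF-reconvolution, variable projection + iterated Poisson weights);
  τ_av = Σαᵢτᵢ/Σαᵢ.
- FRET: `J = ∫F_D ε_A λ⁴ dλ / ∫F_D dλ`,
  `R₀ = (8.79×10⁻⁵ κ² n⁻⁴ Q_D J)^(1/6)` Å,
  `r = R₀((1−E)/E)^(1/6)`, `k_ET = τ_D⁻¹(R₀/r)⁶`,
  `E = k_ET/(k_r + k_ET + Σk_nr)`.
- Boltzmann sigmoid for the pyrene I₃₃₅/I₃₃₂ ratio; CMC at the
  inflection.

See `vignettes/methods.Rmd` for the assumptions, conventions, and
numerical choices behind each stage.

## Worked example

```r
library(specbind)

# a seeded two-state encapsulation titration (truth: kd 0.75, n 1.32)
tit  <- gen_absorbance_titration(seed = 1)
resp <- vapply(tit$entries, function(s) max(s$values), numeric(1))
hill1_fit(tit$concentrations, resp)
#> <hill1_fit> k_D = 0.737, n = 1.311, start = 0.8065, end = 0.5003, R2 = 0.9998
round(find_isosbestic(tit), 1)
#> [1] 487.5

convert_kd_to_molar(0.75, 22500)   # mg/mL + Da -> M^-1
#> [1] 30000

vant_hoff_fit(data.frame(T  = c(293.15, 303.15, 313.15),
                         Ka = c(4310, 10100, 116000)))
#> <thermo_result> dH = 124.94 kJ/mol, dS = 493.50 J/(mol K), R2 = 0.9178
#>   force class: hydrophobic
#>   T = 293.15 K: dG = -19.73 kJ/mol (-RT ln Ka: -20.40)
#>   T = 303.15 K: dG = -24.66 kJ/mol (-RT ln Ka: -23.24)
#>   T = 313.15 K: dG = -29.60 kJ/mol (-RT ln Ka: -30.36)

distance_from_efficiency(0.5719, 33.82)   # FRET distance, Angstrom
#> [1] 32.23

average_lifetime(c(0.51, 7.67, 18.86), c(0.39, 0.20, 0.41))  # ns
#> [1] 9.4655
```

The Hill fit recovers the generating parameters from 0.5%-noise spectra;
the isosbestic point sits where the free and bound model bands cross
(≈488.7 nm by construction); the van't Hoff fit on a rounded printed
K_a ladder lands near 125 kJ/mol with a hydrophobic (ΔH > 0, ΔS > 0)
classification; the FRET inversion turns a 57.19% efficiency and a
33.82 Å Förster radius into a 32.23 Å donor–acceptor distance; and the
amplitude-weighted average lifetime of the tri-exponential reference
decay is 9.47 ns.

## Command line

```sh
Rscript inst/cli/specbind.R simulate --dir study --seed 1
Rscript inst/cli/specbind.R run --dir study          # full report
Rscript inst/cli/specbind.R lifetime --decay study/decay.csv \
    --components 3 --mode reconvolution
```

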