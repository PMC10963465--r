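# dissectgr

Growth and remodeling (G&R) of the dissected aortic membrane.

After an aortic dissection, the delaminated part of the wall — the dissected
membrane (intimal flap) — separates the true from the false lumen.
Clinically the membrane thickens as the dissection transitions from the
acute (days 0–15) through the subacute (15–42) to the chronic (42–90)
phase, while the vessel expands. `dissectgr` implements a homogenized
constrained-mixture G&R analysis of an idealized dissected aorta for
researchers in vascular biomechanics: which stress- and
inflammation-mediated turnover parameters, drawn from published ranges,
reproduce those clinical observations?

The wall is a constrained mixture of neo-Hookean elastin and two
Holzapfel–Gasser–Ogden collagen fiber families (tension-only, no
dispersion). Each constituent carries a deposition prestretch (10% fiber
strain for collagen, defining the homeostatic stress σ_h; 10% axial strain
for elastin), and the total deformation decomposes as
F = F_elas F_r F_g with radial growth
F_g = (ρ_tot(s)/ρ_tot(0)) a_g⊗a_g + (I − a_g⊗a_g) and volume-preserving
collagen remodeling F_r = λ_r M⊗M + λ_r^(−1/2)(I − M⊗M). Turnover follows

    ρ̇₊ = ρ/T᷊ (1 + k_Γ₊ Γ + k_σ (σ − σ_h)/σ_h)₊      (collagen production)
    ρ̇₋ = −ρ/T᷊ (1 + k_Γ₋ Γ)                          (collagen degradation)
    ρ̇₋ᵉ = −⅓ ρᵉ k_Γ₋ᵉ Γ                               (elastin degradation)

with T᷊ = 101 days and a transient
(Γ_t = (δs/(β−1))^(β−1) e^(−δs+β−1), peak 1) or permanent
(Γ_p = 1 − e^(−δs)) inflammatory burden applied to the full wall or locally
to the media around the false lumen. A reduced structural surrogate
replaces the 3D finite-element model: the remaining wall and the intact arc
are incompressible thick-walled sectors in radial equilibrium at 80 mmHg,
and the membrane is a detached lamella with zero net transmural load. A
seeded Latin hypercube explores the published parameter ranges and
classifies samples by convergence and by clinically observed thickening
rates (extended ranges [−3.50; 6.09], [−4.13; 5.09], [−3.99; 4.03] mm/year
per phase).

## Worked example

The transient, local-inflammation example case
(k_σ = 0.130, k_Γ₊ = 5.34, k_Γ₋ = 3.67, k_Γ₋ᵉ = 0.0533 step⁻¹,
δ = 0.198 day⁻¹, β = 1.24):

```r
library(dissectgr)
params <- growth_parameters(k_sigma = 0.130, k_gplus_c = 5.34,
                            k_gminus_c = 3.67, k_gminus_e = 0.0533,
                            delta = 0.198, beta = 1.24)
res <- run_simulation(params, inflammation_pattern("transient", "local"))
res
#> G&R simulation (transient/local)
#>   steps completed: 30/30; converged: TRUE
#>   day 90: D_tot 31.63 mm, membrane thickness 1.567 mm

oc <- outcome_record(res)
round(c(acute = oc$R_T_acute_mm_per_year,
        subacute = oc$R_T_subacute_mm_per_year,
        chronic = oc$R_T_chronic_mm_per_year), 2)
#>    acute subacute  chronic
#>     4.36     1.19     0.62
oc$in_clinical_range
#> [1] TRUE
```

The membrane thickens fastest in the acute phase and the rate decays
toward the chronic phase, staying inside the extended clinical ranges for
this parameter set. The annualized lumen trends have the clinically
observed signs — total diameter +4.6 mm/year, true lumen −7.7 mm/year,
false lumen +12.3 mm/year — and at day 90 the membrane retains 39.7% of
its initial volume in elastin and 57.6% in collagen (initial 46% and 54%),
at 97.3% of its initial volume.

A scaled-down parametric study:

```r
study <- run_study(latin_hypercube(100, "transient", seed = 1), "local")
study
#> G&R parametric study: transient/local, n = 100 (seed 1)
#>   converged: 73 (73.0%); within clinical ranges: 22
#>   parameter space reduced to 85.8% (converged), 58.4% (clinical)
```

Transient patterns converge far more often than permanent ones (whose
sustained burden drives the growth factor out of bounds unless the
inflammatory production/degradation gains nearly balance), and restricting
to clinically plausible thickening rates tightens the admissible parameter
space further — the study's central qualitative findings.

A command-line wrapper over the same functions is available:

```sh
Rscript inst/scripts/dissectgr.R study --pattern transient --location local --n 100 --seed 42 --out results/
```

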