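# natzone

Steady-state reaction-transport modelling of the sediment nitrogen cycle and
quantitative mapping of microbial niches onto the **nitrate-ammonium
transition zone (NAT)** — the depth interval in marine sediments where
downward-diffusing nitrate meets upward-diffusing ammonium, and where
anaerobic ammonium oxidation (anammox) is expected to peak.

The package is written for biogeochemists and microbial ecologists who have
porewater concentration profiles (O2, NO3-, NH4+) and depth-resolved
relative-abundance tables (e.g. 16S family-level summaries), and who want to
ask, quantitatively: *where is the transition zone, where does the model put
the anammox rate maximum, and is a given taxon's depth distribution confined
to that zone more than chance would allow?*

## The model

Porewater concentrations C(z) of O2, NO3- and NH4+ (µM; depth z in meters
below the seafloor, positive down) obey a one-dimensional steady-state
diagenetic balance

```
d/dz [ φ Ds dC/dz − φ w C ] + φ S(C, z) = 0
```

with porosity φ, tortuosity-corrected diffusivity `Ds = D0 / (1 − ln φ²)`
(Boudreau's relation), burial velocity w, and net sources S from four
pathways driven by a prescribed organic-carbon mineralization profile
`R_C(z) = R0 exp(−z / z_att)`:

| pathway | rate law | stoichiometry |
|---|---|---|
| aerobic mineralization | `R_C · O2/(O2+K_O2)` | 1 O2 : 1 C, releases r_NC NH4 |
| denitrification | `R_C · (1−monod(O2)) · NO3/(NO3+K_NO3) · Ki/(Ki+O2)` | 0.8 NO3 : 1 C |
| nitrification | `k_nit · NH4 · O2/(O2+K_O2nit)` | 2 O2 : 1 NH4 |
| anammox | `k_amx · NH4 · NO3 · Ki/(Ki+O2)` | 5 NH4 : 3 NO3 → 4 N2 |

Anammox is written lumped on nitrate (nitrite is not part of the state), so
fixed nitrogen consumed equals N2-N produced exactly — a conservation
property the test suite checks to machine precision.

The equations are discretized with a conservative cell-centered finite-volume
scheme (harmonic interface averaging, upwind advection) and solved by damped
projected Newton iteration with a pseudo-transient fallback. The NAT zone is
detected from profiles as the bracket between the NO3- penetration depth and
the NH4+ appearance depth (1 µM thresholds by default), and confinement of a
taxon to the zone is scored as the in-zone fraction of its summed relative
abundance, with a permutation test over depth labels (exact enumeration for
≤ 7 depths, seeded Monte Carlo otherwise).

## Worked example

```r
library(natzone)

# packaged reference scenario: a 4 m column whose steady state mimics the
# canonical deep-sea pattern (O2 gone within decimeters, NO3- penetrating to
# ~2 m, NH4+ rising from below)
setup <- setup_from_config(read_config(reference_config_path()))
sol   <- solve_setup(setup)
glance(sol)
#> # A tibble: 1 × 6
#>   converged residual_norm iterations n_cells extent_m anammox_integrated
#> 1 TRUE           5.77e-12          9     400        4              0.436

# synthetic "measured" profiles (5% noise), transition-zone detection
obs  <- generate_observed(setup, depths = seq(0.05, 3.95, 0.1),
                          noise_sd = c(O2 = 0.05, NO3 = 0.05, NH4 = 0.05),
                          seed = 42, noise_type = "relative")
zone <- detect_nat_zone(obs)
tidy(zone)
#>   z_top z_bottom z_no3 z_nh4 eps_no3 eps_nh4 mode
#> 1  1.99     2.43  2.43  1.99       1       1 overlap

rate_maximum_depth(sol)   # anammox rate peak, inside the zone
#> [1] 2.265

# a synthetic anammox-like taxon niched at the zone center
niches <- taxon_niches("amx_family", A = 0.006, mu = 2.2, sigma = 0.08)
comm   <- generate_community(seq(0.05, 3.95, 0.1), niches,
                             n_reads = 50000, seed = 43)
confinement_test(comm, zone, seed = 7)
#>   taxon       index p_value n_permutations method       seed
#> 1 amx_family 0.993    0.001            999 monte_carlo     7
#> 2 other      0.0997   1                999 monte_carlo     7
```

The depth-integrated anammox rate is 0.436 mmol N m⁻² yr⁻¹; the rate peak at
2.27 m lies inside the detected transition zone (1.99–2.43 m); the niched
taxon keeps 99% of its abundance inside the zone (p = 0.001 against the
label-permutation null) while the residual "other" fraction is indistinguishable
from a uniform distribution (p = 1).

Plots: `autoplot(sol, zone = zone)`, `plot_profiles(obs, sol, zone)`,
`plot_abundance(comm, zone)`, `autoplot(confinement_test(...))`.

A thin command-line wrapper ships in `inst/cli/natzone.R` with subcommands
`simulate`, `natzone`, `confine`, `fit` and `synth`; all outputs are
byte-reproducible from the config file and seeds.

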