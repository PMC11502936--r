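# conecap

Energy-budget carrying capacity for red squirrels (*Sciurus vulgaris*) in
conifer plantations, estimated from ground cone feeding surveys.

Conservation translocations of red squirrels are usually judged on whether a
population persists, but persistence depends on whether the habitat can still
feed it. `conecap` turns the standard field evidence — transect cone counts,
cone measurements, and a per-stand area ledger — into that judgement: how much
seed energy the forest offers, how many squirrels that energy can sustain, how
many appear to be present, and how all of these have changed across survey
years as stands were felled, burned or self-thinned.

## The model

For each species *s* and survey year, the pipeline computes

- seeds per average cone: the mean scale count of a measured subsample for
  Sitka spruce (one seed per scale), or an allometric function of mean cone
  length for lodgepole pine (default: 54/42.8 seeds per mm, linear through the
  origin);
- energy per cone: seeds x seed energy (0.04 kJ/seed spruce, 0.098 kJ/seed
  pine);
- cone density *C_s* (cones/m²): total cones over total transect area;
- energy density *E_s* = *C_s* x energy per cone (kJ/m²);
- forest energy: *E_s* x mature area (ha x 10,000), summed over species —
  using consumed-cone densities and squirrel-*occupied* areas for the
  consumed budget;
- carrying capacity interval: forest energy / (*r* x 365 days) for daily
  requirements *r* = 700 (lower bound) and 400 kJ (upper bound), rounded half
  away from zero; the same division applied to the consumed budget estimates
  the population actually present;
- an independent area-based capacity: mature hectares x 0.32 squirrels/ha.

A habitat module classifies stands (mature at >= 25 years from planting),
builds the per-year area ledger, and transfers known Sitka:lodgepole tree
ratios between stands via relative cone production
(R1 = C_SS1 C_LP2 R2 / (C_LP1 C_SS2)). A comparison module provides
Mann-Whitney rank-sum tests on per-transect densities, fold changes and
cross-paired capacity decline ranges. A synthetic-survey generator
(negative-binomial transect counts, linear scales-on-length cone morphology)
provides ground-truthed data for validation.

## Worked example

The packaged `derryclare_fixture()` encodes a 570-ha west-of-Ireland
plantation surveyed between 2008 and 2021 (33 transects of 50 m x 1 m in
2021; 5599 Sitka spruce cones, 136 consumed; 1032 lodgepole pine cones, 63
consumed), together with its stand ledger and published per-m² densities.

```r
library(conecap)
fx <- derryclare_fixture()
res <- run_pipeline(fx$transects, fx$cones, fx$stands, fx$config,
                    densities = fx$densities, areas = fx$areas)

forest_energy(fx$densities, fx$areas, 2021)
#> Forest energy budget, 2021 (202 ha mature)
#>   available: 20,831,600 kJ
#>   consumed:  569,800 kJ (2.74% of available)

res$capacity
#>  year mature_ha area_capacity fs_capacity_low fs_capacity_high fs_actual_low fs_actual_high
#>  2008       392           125             241              421             9             16
#>  2009       354           113             192              336            17             30
#>  2010       333           107             178              312             7             13
#>  2011       313           100             105              183            12             22
#>  2021       202            65              82              143             2              4
```

Reading the 2021 row: the cone crop held 20.8 million kJ, enough to sustain
between 82 squirrels (if each needs 700 kJ/day for a year) and 143 (at 400
kJ/day); the energy actually consumed corresponds to only 2–4 animals,
against 241–421 sustainable and 9–16 present in 2008 — the signature of a
population collapse driven by habitat loss. `res$changes` quantifies the
drivers: a 53% loss of mature habitat, 42% (spruce) and 60% (pine) coverage
reductions, a 66% fall in available energy, and a 41%–81% decline in carrying
capacity.

A thin command-line wrapper for file-based runs and synthetic-survey
generation is installed at `inst/scripts/conecap.R`.

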