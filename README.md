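# amendr

Analysis tools for *in situ* microbial colonization experiments in deep,
anoxic aquifers that include a pulsed organic-matter amendment. The package is
aimed at geomicrobiologists running down-well incubation series — solid
substrates suspended in a borehole across repeated deployments, profiled by
16S amplicon (OTU) sequencing — who want to (1) quantify how much amended
carbon reached their substrates and what per-cell activity that implies, and
(2) test how substrate type and the perturbation structured the colonizing
community.

## What it computes

**Amendment model.** A pulse of proteinaceous biomass (sea sponges: spongin is
47.44% C, 16.15% N by mass) is converted to a carbon/nitrogen budget, then to
the areal source strength `N = n_C / (π d²/4)` of a one-dimensional plane
source in the well bore. Dispersal follows the thin-film (Gaussian) solution
of Fick's second law,

```
C(x, t) = N / (2 √(π D t)) · exp(−x² / 4Dt)
```

and the carbon delivered to the cartridge window `[x₁, x₂]` is the
single-sided line integral of `C` converted to moles (two labelled
conventions; closed-form erf and trapezoid quadratures both reported).
Community-averaged activity follows as

```
rate = (carbon / duration) / (cell density × water volume)
```

in fmol C cell⁻¹ day⁻¹, with oxidation windows derived from the deployment
calendar.

**Community statistics.** Dataset-wide singleton removal, a 0.01%
relative-abundance threshold, negative-control contaminant removal (≥0.05% in
any control), relative-abundance and fourth-root transforms, Shannon and
Chao1; then from-first-principles Bray-Curtis dissimilarity
`Σ|uᵢ−vᵢ| / Σ(uᵢ+vᵢ)`, NMDS (SMACOF majorization + isotonic regression,
Kruskal stress-1), permutation ANOSIM `R = (r̄_between − r̄_within)/(M/2)`
with automatic exhaustive enumeration, SIMPER decomposition, one-way ANOVA
and the two-sided variance-ratio F-test.

**Synthetic communities.** A seeded Dirichlet-multinomial generator
(`community_spec()`, `simulate_otu_table()`, `succession_fixture()`) emulates
the statistical structure of a low-diversity subsurface survey — a dominant
OTU, substrate-linked fold-changes, a perturbation bloom and recovery across
five incubations, contaminants in sequencing controls, library sizes of
5,000–47,000 reads — so the whole pipeline is testable without any download.

## Worked example

```r
library(amendr)

# --- community half -------------------------------------------------------
fx <- succession_fixture()          # 5 bins x 5 incubations x 2 replicates
filtered <- fx$otu |>
  remove_singletons() |>
  filter_rare_otus() |>             # 0.01% dataset-wide threshold
  filter_contaminants(fx$controls)  # >=0.05% in any negative control
dplyr::count(filter_log(filtered), step)
#>   step                    n
#> 1 filter_contaminants     2      # exactly the two planted contaminants

d   <- bray_curtis_dist(fourth_root(relative_abundance(filtered)))
fit <- nmds(d, seed = 1)
glance(fit)
#>   stress converged n_restarts     k     n  seed
#> 1  0.185 TRUE              20     2    50     1   # below the 0.2 rule

anosim_test(d, fx$metadata$substrate_bin, seed = 1)
#> <amendr_anosim> R = 0.31281, p = 0.001 (999 permutations)

# --- amendment half -------------------------------------------------------
budget <- sponge_budget()           # 5 sponges x 0.37 g
budget
#>   carbon_g nitrogen_g carbon_mol
#> 1    0.878      0.299     0.0731

model <- plane_source_model(areal_source_strength(budget$carbon_mol))
diffusion_report(model, t_days = c(37, 74))
#>   t_days closed_form_mol trapezoid_mol    dx convention
#> 1     37        0.000159      0.000378 0.117 paper_volume
#> 2     74        0.00212       0.00304  0.117 paper_volume

sched <- incubation_schedule()
per_cell_rate(0.160e-3, scenario_duration(sched, "midpoint3_to_midpoint5"))
#> [1] 0.0208    # lower bound, fmol C per cell per day
per_cell_rate(3.01e-3, scenario_duration(sched, "deploy3_to_mid_recovery3_4"))
#> [1] 0.577     # upper bound
```

Reading the numbers: the sponge pulse supplied ~0.88 g C; by 37 days the
closed-form window integral says ~0.16 mmol of it had diffused across the
cartridge window (by 74 days ~2.1 mmol exactly, ~3.0 mmol on the documented
coarse grid — `diffusion_report()` always shows both), and spreading the
bounding amounts over the 177- and 120-day oxidation windows and the measured
4.1×10⁶ cells/ml in 10.6 L gives 0.02–0.58 fmol C per cell per day. On the
community side, the planted contaminants are the only OTUs removed, the
ordination is acceptable (stress < 0.2), and substrate bins explain community
variance (R = 0.31, p = 0.001).

`run_pipeline(pipeline_config(...))` chains all stages (simulate → filter →
transform → statistics → amendment model) and returns a seed-complete,
timestamp-free run report; `autoplot()` methods draw the ordination, the
permutation distribution and SIMPER contributions.

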