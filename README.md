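# quadbind

Trajectory analysis for small planar ligands binding to G-quadruplex
and duplex DNA.

Free-ligand binding simulations of quadruplex stabilizers (the
tri-substituted acridines being the classic case) produce long
trajectories in which the ligand wanders, docks and re-docks.  Turning
those frames into science requires a fixed chain of analyses:

1. **Stable-complex detection** — receptor–ligand atom contacts at a
   3.0 Å cutoff; a frame is a stable complex when the count exceeds 10.
2. **Binding-mode identification** — frames are aligned on the
   receptor backbone (least-squares/Kabsch), ligand poses are clustered
   with the Daura algorithm at a 2 Å pairwise RMSD cutoff (no ligand
   fit), families under 1% population are dropped, and each family
   centroid is classified geometrically as **top** or **bottom**
   end-stacking (beyond the first/last G-tetrad plane, inside the axial
   cylinder) or **groove** binding (lateral surface contact).
3. **Binding-pathway order parameters** — per frame: hydrogen bonds per
   G-tetrad (3.5 Å / 120° criteria), the drug–tetrad plane angle, the
   receptor and ligand RMSD, the center-to-center distance R, the
   channel K⁺–K⁺ distance, plus backbone torsions
   (α, β, γ, δ, ε, ζ, χ) and base-flip event detection.
4. **MM-GBSA energetics** — a from-scratch end-point engine:

   ΔE = ΔE_VDW + ΔE_SUR + ΔE_GBELE + ΔE_conformation

   with 12-6 Lennard-Jones and Coulomb terms (AMBER combination and
   1-4 scaling), Hawkins–Cramer–Truhlar effective Born radii, the
   Still generalized-Born expression with Debye–Hückel salt screening
   (0.15 M default), and a Shrake–Rupley surface term
   (γ = 0.0072 kcal/mol/Å²).  Per-mode means are ranked as
   ΔΔG = ΔE_mode − min(ΔE).

Every input the pipeline needs can be generated with exact ground
truth: an idealized three-tetrad quadruplex whose tetrads register 8
Hoogsteen hydrogen bonds each, a B-form GC duplex with 3 Watson–Crick
bonds per pair, a planar tricyclic +3 cation, and scripted
binding/flip trajectories (`build_quadruplex()`, `build_duplex()`,
`build_ligand()`, `generate_trajectory()`).  The generator is the
validation instrument: planted mode populations, flip intervals and
construction geometry are recovered by the analysis side and asserted
in the test suite.

## Worked example

```r
library(quadbind)

# 1. Idealized systems with known ground truth
quad <- build_quadruplex()          # 3 tetrads, 2 channel K+
lig  <- build_ligand()              # planar tricyclic, +3 e

# 2. A scripted binding run: 10 unbound frames, then a groove episode,
#    then end-stacking on the top tetrad, 0.3 A thermal noise
script <- trajectory_script(
  data.frame(state = c("unbound", "groove", "top"),
             n_frames = c(10, 60, 30), noise = 0.3),
  seed = 7)
run <- generate_trajectory(quad, lig, script)

# 3. Stable complexes, Daura clustering, mode classification
bm <- binding_mode_analysis(run$traj)
round(bm$mode_populations, 3)
#> groove    top
#>  0.671  0.329

# 4. MM-GBSA decomposition of the end-stacked pose
top_frames <- sort(unlist(lapply(
  bm$families[sapply(bm$families, `[[`, "mode") == "top"],
  `[[`, "members")))
e <- mmgbsa_binding(run$traj,
  frame_window = top_frames[seq(1, length(top_frames), 6)])
print(e)
#> MM-GBSA decomposition over 4 frames (kcal/mol)
#>   dvdw      -21.78 +/- 3.40
#>   dsur       -3.32 +/- 0.07
#>   dgbele     15.99 +/- 4.06
#>   dconf       0.00 +/- 0.00
#>   dE         -9.10 +/- 5.40

# 5. Rank the recovered modes
groove_frames <- sort(unlist(lapply(
  bm$families[sapply(bm$families, `[[`, "mode") == "groove"],
  `[[`, "members")))
eg <- mmgbsa_binding(run$traj,
  frame_window = groove_frames[seq(1, length(groove_frames), 12)])
delta_delta_g(c(top = e$dE, groove = eg$dE))
#>     mode         dE      ddG
#> 1    top -9.1049220 0.000000
#> 2 groove  0.6059555 9.710878
```

The recovered populations (67% groove / 33% top of the stable frames)
match the script's plant (60 groove / 30 top bound frames); the van
der Waals term dominates the favorable binding energy, and
end-stacking outranks groove binding on the quadruplex — the ΔΔG
column is each mode's penalty relative to the best one.

## Analysis workflow

The `analysis/` scripts run the full study on the synthetic systems
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_build_systems.R` | builds the systems; audits tetrad/pair H-bonds, ion spacing, ligand charge |
| `02_binding_modes.R` | contact convergence, clustering, mode populations vs planted truth |
| `03_order_parameters.R` | order-parameter series, torsion histograms, flip detection |
| `04_energetics.R` | per-mode MM-GBSA component table |
| `05_ranking.R` | ΔΔG ranking of the recovered modes and of the published per-system best modes |

Run them from the repository root, e.g.
`Rscript analysis/02_binding_modes.R`.

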