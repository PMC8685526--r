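# afpop — population-of-models simulation of atrial fibrillation inducibility

`afpop` is an R package for in-silico pharmacology of atrial fibrillation
(AF). It asks: *which combinations of ionic-channel expression make a human
atrium inducible to reentrant arrhythmia, and how do drugs and tissue
dilation shift that boundary?* The package is aimed at computational
cardiac electrophysiologists who want a tested, end-to-end pipeline — from
a population of calibrated myocyte models to an interpretable classifier of
arrhythmia inducibility — that runs at desk scale on one CPU.

## The pipeline

1. **Population of models.** Nine quantities of a chronic-AF remodeled
   human atrial myocyte model — g<sub>Na</sub>, I<sub>NaK</sub>,
   g<sub>K1</sub>, g<sub>CaL</sub>, g<sub>Kur</sub>, I<sub>KCa</sub>,
   [Na]<sub>o</sub>, [K]<sub>o</sub> and the diffusion coefficient D — are
   varied from −50 % to +100 % by Latin-hypercube sampling. Candidates are
   paced 15 beats at 1 Hz on an 8 × 256 strip and kept only if the
   action-potential biomarkers (APD20/50/90, APA, RMP, V20) at probe cells
   500/620/748 fall inside a constraint box.
2. **Tissue + drugs.** Each accepted profile runs on 2D monodomain sheets
   of a normal (16 cm²) and dilated (20.25 cm²) atrium under basal
   conditions and three drugs, modeled by the pore-block law
   G = G₀ / (1 + [D]/IC₅₀) (flecainide, verapamil) or a saturating
   I<sub>CaL</sub> agonist factor (isoproterenol), with an S1–S2
   cross-field induction protocol.
3. **Rotor analysis.** Hilbert-phase maps, topological-charge phase
   singularity detection and rotor tracking label each simulation
   *induced* (a rotor completing ≥ 1 full rotation after S2) and
   *maintained* (tissue still active in the final 200 ms).
4. **Interpretable classification.** A random forest (80/20 stratified
   split, 5-fold CV) predicts inducibility from the nine effective
   multipliers plus tissue area, and a depth-≤7 CART tree yields
   human-readable decision paths exported as a sunburst structure.

Two cell models sit behind one interface: a detailed 21-state
Courtemanche-family atrial myocyte (with SK current and chronic-AF
remodeling: I<sub>CaL</sub> ×0.45, I<sub>to</sub> ×0.38, I<sub>Kur</sub>
×0.62, I<sub>K1</sub> ×1.62, NCX ×1.50, SERCA ×0.84, PLB ×1.18, SLN ×0.60)
and a fast two-variable surrogate that makes the full pipeline runnable in
minutes. See `vignettes/afpop-methods.Rmd` for the model equations,
parameter choices and limitations.

## Worked example

```r
library(afpop)

## drug factors straight from the pore-block law (conc/IC50 from the
## shipped safety-pharmacology table, in uM)
drug_factors(drug_library()$verapamil)
#>       gNa       gKr      gCaL
#> 0.6666667 0.5833333 0.1666667

## calibrate a small population on the fast surrogate
cfg <- desk_config(n_lhs = 16, n_keep = 2, seed = 3)
pop <- calibrate_population(lhs_sample(16, 9, seed = 3), config = cfg)
sum(pop$accepted)
#> [1] 4

## simulate S1-S2 induction for two of the accepted profiles
acc <- pop[pop$accepted, ]
for (id in c("p0005", "p0006")) {
  m <- unlist(acc[acc$profile_id == id, multiplier_names()])
  sim <- run_s1s2(m, build_geometry("desk_normal"),
                  protocol = cfg$protocol, model = "surrogate", config = cfg)
  print(analyze_reentry(sim)$outcome)
}
#> AF outcome: induced = FALSE | maintained = FALSE | surviving tracks = 0
#> AF outcome: induced = TRUE | maintained = TRUE | surviving tracks = 1
```

Profile p0006's ionic make-up supports reentry: after the premature S2 a
phase singularity persisted beyond one full rotation and the tissue was
still active at the end of the observation window; p0005, calibrated from
the same biomarker box, is non-inducible. The full pipeline
(`run_pipeline(desk_config())`) chains population → simulation grid →
classifier and returns the 160-row labeled design table, the trained
forest and the decision-path sunburst.

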