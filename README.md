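# NMRDynamics

Tools for characterising protein dynamics and interactions by solution NMR,
and for building structural models of proteins whose sequences carry
insertions relative to a homologous template. The package grew out of the
kind of study done on calcium-sensor proteins of the troponin complex —
comparing the backbone dynamics of two isoforms, mapping where peptide
ligands bind, and modelling the assembled complex on a vertebrate template —
but every component is generic.

It implements three connected analyses:

1. **Lipari–Szabo model-free analysis** of backbone ¹⁵N relaxation data
   (T₁, T₂, heteronuclear NOE) under isotropic tumbling. The spectral
   density is

   *J*(ω) = (2/5) [ *S*²τ*c* / (1 + (ωτ*c*)²) + (*S*f² − *S*²) τ / (1 + (ωτ)²) ],
   with τ⁻¹ = τ*c*⁻¹ + τ*i*⁻¹,

   from which the standard ¹⁵N R₁, R₂ and NOE expressions follow (dipolar
   constant *d* from rNH = 1.02 Å, CSA constant *c* from Δσ = −160 ppm).
   Per residue, the five canonical models — (1) *S*²; (2) *S*², τ*i*;
   (3) *S*², R*ex*; (4) *S*², τ*i*, R*ex*; (5) *S*f², *S*s², τ*i* — are fit
   by bounded Levenberg–Marquardt least squares and the simplest adequate
   model is selected. The global correlation time τ*c* is root-solved from
   the trimmed-mean T₁/T₂ ratio of rigid residues (NOE > 0.6, no exchange
   term) and alternated with the per-residue fits until it converges.

2. **HSQC titration analysis**: peak tracking across titration points,
   classification of each residue into slow exchange (free and bound peaks
   co-detected, intensities redistributing), fast exchange (one
   population-averaged peak migrating), or unaffected; composite chemical
   shift perturbations Δδ = √(Δδ*H*² + (0.2 Δδ*N*)²); lobe-level binding
   maps; and a global 1:1 dissociation constant fit from fast-exchange
   trajectories, δobs = δfree + (δbound − δfree)·*f*B(P, L, K*d*), with a
   built-in identifiability check that flags tight (e.g. nanomolar) binding
   as stoichiometric when the protein concentration is far above K*d*.

3. **Iterative gap growing**: threading a target sequence onto a homologous
   template backbone with its insertions left out, then introducing each
   insertion 2–5 residues at a time (C-terminal insertions first), relaxing
   after each addition with a simulated-annealing engine over a coarse
   backbone potential, until the total solvent-accessible surface area
   (Shrake–Rupley) returns to its pre-insertion reference — the signal that
   the fold has re-compacted around the new residues.

A synthetic-data module generates ground-truth-labelled inputs for all
three stages, so the whole pipeline builds and tests without external data.

## Worked example

```r
library(NMRDynamics)
fc <- fieldConstants()                     # 600.13 MHz, rNH 1.02 A, CSA -160 ppm

## --- model-free analysis on a synthetic 150-residue protein --------------
sim <- simulateRelaxationDataset(tauC = 9.4, noise = 0.02, seed = 11)
fit <- runModelFree(sim$table, fc)
fit
#> ModelFreeFit: tauC = 9.39 ns, 150 residues, 2 iterations
#>   model counts: m1=101 m2=30 m3=16 m4=1 m5=2
```

The generating τ*c* was 9.4 ns; the estimate lands at 9.39 ns. Most
residues fit with the simplest model (order parameter only), loop residues
take an internal-motion term, and the exchange-broadened loop residues are
picked up by the R*ex* models. `resultsTable(fit)` gives the per-residue
*S*², τ*i* and R*ex* profiles; `averageWithNoeFilter(sim$table)` reproduces
the NOE > 0.6 filtered T₁/T₂ averages.

```r
## --- titration: regimes and Kd -------------------------------------------
simT  <- simulateTitrationSeries(kd = 3, jitter = 0, seed = 2)  # Kd = 3 uM
trajs <- lapply(trackPeaks(simT$series), classifyExchangeRegime)
table(vapply(trajs, regime, ""))
#>       fast       slow unaffected
#>         10          8         12
fitKdFastExchange(trajs, simT$series)
#> BindingFit: Kd = 3 uM (95% CI 3-3), chisq 3.41e-24
```

All 30 residues classify to their generating regime and the micromolar
K*d* is recovered from the fast-exchange trajectories. Re-running with
`kd = 0.008` (8 nM, far below the 0.8 mM protein concentration) prints
`Kd unidentifiable (stoichiometric/concentration-limited regime)` — the
curve then carries no information about K*d*, and the fitter says so
rather than reporting a number.

```r
## --- gap growing: a 5-residue loop insertion into a toy hairpin ----------
toy <- generateToyTemplateAndTarget(insertionLens = c(5), seed = 3)
res <- runGapGrowing(list(A = toy$targetSeq), toy$template,
                     config = list(engine = engineConfig(seed = 17)))
res$trace
#> SasaTrace: 10 steps, SASA 1787 -> 1821 A^2, 3 event(s)
res$report$conservedCaRmsd    # 0.17 A vs the template
res$report$sasaRatio          # 1.019: back within 2% of the reference
```

The trace records the SASA jump at each residue addition and its decay
during relaxation; the final model contains the full target sequence with
no chain breaks, and the conserved region stays on the template fold.

## Command line

A thin wrapper over the same functions lives in `inst/scripts/`:

```sh
Rscript inst/scripts/nmrdynamics.R all --seed 1 --out rundir
Rscript inst/scripts/nmrdynamics.R relax-fit --table relax.tsv --freq-mhz 600.13 --out rundir
```

Subcommands `simulate`, `relax-fit`, `titrate`, `gapgrow`, `all`; every
output directory gets a checksummed manifest, a JSON report and a log, and
identical seeds reproduce identical checksums.

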