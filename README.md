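# cartwheel

An R package implementing the computational workflow used to discover
small-molecule inhibitors of SAS-6 head-domain dimerization — the
protein–protein interaction that drives assembly of the centriolar
"cartwheel" scaffold. The pipeline spans four stages:

1. **Structure-based pharmacophore screening.** From a dimer interface in
   which a β6-β7 loop inserts into a hydrophobic pocket, the package derives
   a model of typed 3-D interaction features (hydrophobic, aromatic,
   hydrogen-bond donor/acceptor, each with a center, tolerance radius and,
   for hydrogen bonds, a direction vector) plus exclusion spheres on the
   receptor's van der Waals surface. Multi-conformer ligand libraries are
   rigid-body fitted to all feature sub-models of at least five features
   that contain a mandatory core (two hydrophobic/aromatic features and one
   donor), scored by Gaussian overlap
   `score = Σ exp(−d² / (2 (r/2)²))` over matched features, and ranked.
2. **Chemical library preparation.** Property filters (molecular mass
   300–500 Da, ≥1 hydrogen-bond donor, ≥1 aromatic ring), circular
   fingerprints, Tanimoto similarity `T = |A∩B| / |A∪B|`, and greedy
   leader-style diversity picking.
3. **NMR chemical-shift-perturbation analysis.** Combined amide
   perturbations `Δδ = sqrt((δH² + 0.14 δN²) / 2)` from paired HSQC peak
   lists; residues are *notable* when `Δδ > max(2σ, 2σ_exp)` with
   `σ_exp = 0.01 ppm`; titrations are fit with the single-site 1:1
   fast-exchange isotherm
   `Δδ(L) = Δδmax (P + L + Kd − sqrt((P + L + Kd)² − 4 P L)) / (2P)`
   for a global Kd; perturbations map onto structures (B-factor column)
   with a hypergeometric test for enrichment at the dimerization site.
4. **Trajectory contact analysis.** Ligand RMSD series after protein Cα
   superposition (Kabsch), pose-stability classification, hydrogen-bond
   occupancy (3.5 Å / 30° criteria), and ligand-atom × residue contact maps
   normalized so the most frequent contact equals 1.

Seeded synthetic-data generators (`makeToyInterface`, `makeLigandLibrary`,
`makeTitrationPeaks`, `makeTrajectory`) emulate every input — a
loop-into-pocket interface, libraries with planted binders among decoys,
fast-exchange titration peak lists, and trajectories with planted pose
stability — so the entire pipeline is testable offline.

## Worked example

```r
library(cartwheel)

## derive a pharmacophore model from the synthetic dimer interface
iface <- makeToyInterface()
model <- deriveModel(iface, ligandChain = "B", receptorChain = "A")
model@mandatory <- defaultMandatoryCore(model)
model
#> Pharmacophore: 6 features ( acceptor 1, donor 2, hydrophobic 3 ),
#>   14 exclusion spheres, 3 mandatory, minMatch = 5

## screen a library with one planted binder among 20 decoys
lib <- makeLigandLibrary(model, 1L, 20L, syntheticSpec(seed = 1))
head(screenLibrary(lib, model))
#>      id   score submodel conformer nMatched
#> 1 BND01 5.72537        4         1        6

## fit a synthetic fast-exchange titration (planted Kd = 2 mM)
tp  <- makeTitrationPeaks(syntheticSpec(seed = 1))
ts  <- titrationSeries(tp$apo, tp$holo, tp$concentrations, tp$Ptotal)
fit <- fitTitration(ts, residues = tp$site)
sprintf("Kd = %.2f mM (saturated: %s)", fit$Kd * 1e3, fit$saturated)
#> "Kd = 2.45 mM (saturated: FALSE)"
```

The screening hit is the planted binder: it matches all six model features
(score 5.73 of a maximal 6; the deficit reflects the planted coordinate
jitter). The titration recovers the millimolar dissociation constant
without reaching saturation at the top ligand concentration, the signature
of weak, fast-exchange binding.

A command-line front end over the same functions lives at
`inst/scripts/cartwheel-cli.R`:

```sh
Rscript inst/scripts/cartwheel-cli.R simulate --preset library --seed 3 --out sim
Rscript inst/scripts/cartwheel-cli.R screen --receptor sim/interface.pdb \
    --library sim/library.sdf --mw-min 0 --mw-max 100000 \
    --hbd-min 0 --aromatic-min 0 --sim-threshold 1.0 --out screen
```

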