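# etaqsar

Quantitative structure–activity relationship (QSAR) modelling of larvicidal
activity with **Extended Topochemical Atom (ETA) descriptors** — for
cheminformaticians and medicinal chemists who want a fully scripted,
validated pipeline from SMILES to an externally validated PLS model with an
applicability domain, without 3D structure optimisation of any kind.

## What it computes

ETA indices are 2D graph descriptors built from three atomic quantities on
the hydrogen-suppressed molecular graph:

- core count `α = [(Z − Zv)/Zv] · 1/(PN − 1)` (0 for H), where `Z`, `Zv`,
  `PN` are atomic number, valence electron count and period;
- electronegativity measure `ε = −α + 0.3 Zv`;
- valence-electron-mobile (VEM) count `β = β_s + β_ns`, bookkeeping sigma
  contributions (0.5 per bond between atoms of similar electronegativity,
  0.75 for dissimilar), pi contributions (1.0 / 1.5 per pi bond), a flat
  aromatic-ring contribution (2.0) and lone pairs conjugated to a pi
  system (0.5).

Composites are assembled from the molecule, its **reference alkane**
(heteroatoms → C, all bonds single) and its **saturated carbon skeleton**
(C–C multiple bonds single, heteroatoms kept), e.g. the five modelling
descriptors of the larvicide panel this package grew around:

| descriptor | construction | reads as |
|---|---|---|
| `ETA_dEpsilon_D` | `ε₅ − ε₂` | hydrogen-bond donor count |
| `ETA_EtaP_F` | `(η_R − η)/N_v` | functionality (heteroatoms + multiple bonds) relative to size |
| `ETA_dAlpha_B` | `max(0, 0.5 − Σα/N_v)` | polar surface measure |
| `ETA_BetaP_s` | `Σβ_s/N_v` | sigma VEM density / electronegative-atom count |
| `ETA_dEpsilon_C` | `ε₃ − ε₄` | electronegativity (≤ 0; 0 iff no heteroatoms) |

with `η = Σ_{i<j} √(γ_i γ_j / d_ij²)`, `γ = α/β`, `d` the topological
distance, and `ε₁…ε₅` mean-ε variants over the molecule and its derived
graphs.

On top of the descriptor engine the package implements the full modelling
workflow: pretreatment (constant / missing / |r| ≥ 0.95 pruning), k-medoids
train/test division with activity-ranked test selection, genetic-algorithm
descriptor-subset search under double cross-validation (inner 10-fold,
OLS), NIPALS PLS1 (autoscaled X, q-positive sign convention), VIP,
Hotelling T², DModX applicability domain, R²/Q²(LOO)/Q²F1/Q²F2/SEE/F
statistics and Y-randomization — plus a synthetic molecule/activity
generator so every stage is testable without external data.

## Worked example

```r
library(etaqsar)

## descriptors for named panel compounds: camphene (1), resorcinol (49),
## R-limonene (50)
mols <- fixtureCompounds(asMolecules = TRUE)
desc <- etaDescriptors(mols)
round(desc[c("1", "49", "50"), c("ETA_dEpsilon_D", "ETA_EtaP_F",
  "ETA_dAlpha_B", "ETA_BetaP_s", "ETA_dEpsilon_C")], 4)
#>    ETA_dEpsilon_D ETA_EtaP_F ETA_dAlpha_B ETA_BetaP_s ETA_dEpsilon_C
#> 1          0.0000     0.1614       0.0000       1.100         0.0000
#> 49         0.0563     0.7048       0.0417       1.125        -0.1033
#> 50         0.0000     0.2648       0.0000       1.000         0.0000
```

The hydrocarbons camphene and limonene have zero donor (`ETA_dEpsilon_D`),
polarity (`ETA_dAlpha_B`) and electronegativity (`ETA_dEpsilon_C`) terms;
the diol resorcinol is positive on the donor measure and negative on
`ETA_dEpsilon_C`, and carries more functionality per vertex (`ETA_EtaP_F`).

```r
## a synthetic 60-compound panel with activity planted in three
## descriptors, modelled with five descriptors and three latent variables
spec <- syntheticSpec(nCompounds = 60, seed = 1)
smols <- generateMolecules(spec)
act <- generateActivity(smols, spec)
tab <- pretreat(descriptorTable(etaDescriptors(smols), act))$table
sr <- splitTrainTest(kMedoids(tab, k = 5, seed = 1), tab)
fitv <- validateModel(tab[trainIds(sr), ], tab[testIds(sr), ],
                      subset = unique(c(spec@trueSubset, descriptorNames(tab)))[1:5],
                      nLv = 3, nPerm = 100, seed = 1)
fitv$report
#> ValidationReport
#>   R2 = 0.862  Q2(LOO) = 0.818  SEE = 0.626  F = 74.9
#>   external: Q2F1 = 0.912  Q2F2 = 0.912  RMSEP = 0.520
#>   Y-randomization (100 perms): R2 intercept = 0.039, Q2 intercept = -0.270
round(vip(fitv$model), 3)
#> ETA_dEpsilon_D     ETA_EtaP_F    ETA_BetaP_s              N             NR
#>          1.518          0.965          1.211          0.378          0.392
dmodx(fitv$model, confidence = 0.99)
#> AdReport at 0.99 confidence: 0 of 40 compounds outside the applicability domain (D-crit = 2.2165)
```

The three planted descriptors dominate the VIP ranking, the model passes
the Y-randomization thresholds (R² intercept < 0.3, Q² intercept < 0.05),
and no training compound falls outside the DModX domain at 99% confidence.
`runGA()`/`dcvReport()` perform the subset search itself, and
`runPipeline(pipelineConfig(...))` chains every stage and writes all
artifacts plus a manifest. See the vignette in `vignettes/` for the methods
account.

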