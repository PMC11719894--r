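# DomainScape

Conformational-landscape analysis of large multidomain proteins from
molecular dynamics trajectories.

Multidomain enzymes such as the LINE-1 ORF2 protein keep a rigid catalytic
core (fingers–palm–thumb) while terminal domains (the endonuclease EN and
the C-terminal domain CTD) undergo rigid-body excursions of 20–30 Å.
Whole-protein RMSD cannot resolve such landscapes: distinct domain
arrangements give identical values. DomainScape implements the workflow
that can:

* **Distance featurization** — each frame becomes the vector of pairwise
  distances between strided CA atoms (stride 25 on a 1275-residue chain:
  51 atoms, C(51,2) = 1275 features; all CA atoms would give 812,175).
  Distances are rigid-motion invariant, so no superposition biases the
  features.
* **PCA reduction** — the retained dimension *m* is the smallest count
  explaining ≥ 80% of the variance.
* **Gaussian-mixture clustering** — full-covariance EM (compiled inner
  loop, distance-weighted random restarts), with the cluster count scanned
  and assessed by the elbow method on the BIC curve and by silhouette
  analysis; the frame closest to each component mean is the cluster
  representative.
* **Domain geometry** — Kabsch superposition on the rigid core only;
  per-domain RMSD against the initial or the iterated average structure;
  internal (rigid-body-removed) RMSD; minimum interdomain CA–CA
  distances; classification of frames as "closed-contact" when the
  tower–CTD minimum distance is < 8 Å; interdomain salt-bridge and
  hydrophobic-contact detection on all-atom structures.
* **Synthetic ensembles with planted truth** — a generator of miniature
  seven-domain CA trajectories with Markov switching between planted
  conformational basins, used to validate every stage end to end
  (adjusted Rand index, population tables, contact fractions, RMSD
  orderings).

## Worked example

A two-state ensemble in which the CTD docks onto the tower (minimum
CA–CA distance ≈ 5 Å) with stationary occupancy 0.4 and undocks (16 Å)
with occupancy 0.6:

```r
library(DomainScape)

spec <- contactSwitchSpec(seed = 5)
cfg  <- pipelineConfig(ensembleSpec = spec, kRange = c(2, 4), seed = 5,
                       outputDir = "demo_out")
out  <- runPipeline(cfg)

out$chosenK
#> [1] 2
selectionTable(out$selection)
#>   K negLogLik      BIC silhouette
#> 1 2  6493.248 13026.53  0.9410460
#> 2 3  6492.846 13049.74  0.7583333
#> 3 4  6492.795 13073.66  0.5262388
round(out$clusters@weights, 3)
#>     1     2
#> 0.386 0.614
round(out$contactFraction, 4)
#> [1] 0.3863
round(mean(out$groundTruth == 2), 4)   # planted contact occupancy
#> [1] 0.3863
```

The scan chooses K = 2 (the BIC stops improving and the silhouette peaks
there), the recovered cluster weights match the planted occupancies, and
the fraction of frames below the 8 Å contact threshold equals the planted
contact-state occupancy exactly. `demo_out/` receives the assignment and
selection tables, per-domain RMSD summaries, the per-frame contact
distances, one representative PDB per cluster and a JSON run manifest.

Larger preset landscapes are provided by `openLikeSpec()` (five basins,
planted contact mass 0.385) and `closedLikeSpec()` (six basins, contact
mass 0.65); `?runPipeline` walks through the full analysis.

A thin command-line wrapper lives in `inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package = "DomainScape"))')" \
    --config analysis.yaml --out results/
```

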