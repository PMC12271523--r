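# synaxon

Synthesis of brain-wide long-range axonal morphologies and the
connectivity they create.

## The problem

Reconstructed long-range axons (LRAs) — the cables that carry
inter-regional connectivity — exist for only a few thousand neurons,
against tens of millions of cells in a mouse brain. `synaxon` generalizes
from such a sparse sample to whole synthetic populations:

1. **Cluster** the reconstructed axons of each source region by their
   projection patterns. Axon *a* is the vector $t_a \in \mathbb{N}^B$ of
   terminal counts per target region (or $l_a$, path length per region);
   the axons of source $s_a$ are modeled as a Gaussian mixture
   $P(a) = \sum_{k=1}^{C} p_k\, \mathcal{N}(f_a;\, \mu_k, \Sigma_k)$
   fitted by EM (spherical covariances by default), with the component
   count chosen by BIC ($\kappa \ln n - 2\,l(\theta)$, argmin) or
   imposed.
2. **Synthesize** an axon for every new soma: draw a cluster with
   probability $p_c$; draw target regions from the cluster's empirical
   targeting probabilities and tuft counts
   $T_a^{(b)} \sim \mathcal{N}(\bar N_\mathrm{tufts}, \sigma(N_\mathrm{tufts}))$;
   route the trunk as a weighted Steiner tree on an in-brain voxel lattice
   with discounted edges inside fiber tracts; post-process its geometry;
   grow a tuft (terminal arbor) at every target point from the
   persistence barcode of a reconstructed tuft selected by its
   representativity score.
3. **Connect**: detect axo-dendritic touches by segment proximity
   (spatial-hash accelerated, provably identical to all-pairs), filter by
   a minimum inter-bouton interval, prune to a synapse density, and
   aggregate into the single-cell connectome and the region projectome.

Everything runs without external data: the package ships a toy-atlas
builder and a synthetic-axon generator with known ground truth, plus the
statistical comparison machinery (reference normalization, the Maximum
Visible Spread score with its 0.1 / 0.5 significance thresholds,
projection ratios) used to validate synthesized against input
populations. See the methods vignette
(`vignettes/synaxon-methods.Rmd`) for the model details and design
decisions.

## Worked example

Cluster a 59-axon demo population (5 clusters, presubiculum-like source
"PRE"), synthesize 59 new axons, and compare per-region targeting:

```r
library(synaxon)
library(SummarizedExperiment)

atlas <- demoToyAtlas()
atlas
#> BrainAtlas: 32x16x16 voxels @ 100 um, 14 regions, 170 fiber voxels

pop <- generatePopulation(demoPopulationSpec(59), atlas, seed = 42)
features <- lapply(pop$morphologies, computeProjectionFeatures,
                   atlas = atlas, level = 2)
se <- stackPopulation(features)           # regions x axons, assays t and l

X <- t(assay(se, "lengths"))
model <- selectGMM(X, imposedC = 5, seed = 7, sourceRegion = "PRE")
model
#> ProjectionGMM for source 'PRE': C=5 (spherical), B=8 regions,
#>   logLik=-2746.566, BIC=5692.931

clusters <- classifyAxons(model, X)
names(clusters) <- colnames(se)
lib <- buildTuftLibrary(pop$morphologies, atlas, clusters, level = 2)
head(lib$groups[, c("cluster", "region", "n_tufts", "mean_count", "var_count")])
#>   cluster    region n_tufts mean_count  var_count
#> 1       1        RA      53   2.789474 0.16620499
#> 2       1        RB      36   1.894737 0.09418283
#> 3       2        RC      26   2.888889 0.09876543
#> ...

stats <- targetStatistics(se, clusters, lib)
somata <- samplePointInRegion(atlas, "PRE", n = 59, hemisphere = "left",
                              seed = 5)
res <- synthesizePopulation(somata, model, stats, lib, atlas,
                            synthesisConfig(latticeStep = 1L), seed = 11)
res$morphologies[[1]]
#> Morphology 'synth_0001': 83 nodes (soma=1, axon=82, basal=0, apical=0)

synth <- stackPopulation(lapply(res$morphologies, computeProjectionFeatures,
                                atlas = atlas, level = 2))
report <- compareRegionLengths(se, synth)
report[report$n_bio >= 5, c("region", "frac_bio", "frac_synth", "mvs", "flag")]
#>      region  frac_bio frac_synth        mvs flag
#> 1        RA 0.3220339 0.40677966 0.07083198   **
#> 2        RB 0.3220339 0.40677966 0.03397867   **
#> 3 RB_contra 0.1016949 0.05084746 0.39284911    *
#> ...
```

`frac_bio` / `frac_synth` are the fractions of input and synthesized
axons terminating in each region (the projection ratio); `mvs` compares
the in-region axon-length distributions of the two populations (`**` =
strong agreement, MVS < 0.1; `*` = non-random agreement, MVS < 0.5;
`_contra` rows are contralateral targets). Synthesized axons reach the
same regions in matching proportions, with matching in-region cable.

A thin shell entry point wraps the same pipeline
(`inst/scripts/synaxon.R`; subcommands `make-fixtures`, `project`,
`cluster`, `synthesize`, `connect`, `validate`), configured by the YAML
in `inst/extdata/demo-run.yaml`:

```sh
Rscript inst/scripts/synaxon.R make-fixtures --output demo --seed 1
```

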