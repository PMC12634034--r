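# spotvelo

Spatial RNA velocity at spot/cell resolution, inferred by integrating a
reference scRNA-seq dataset with a spatial transcriptomics dataset that
only measures total expression.

RNA velocity estimates a cell's short-term transcriptional future from the
splicing kinetics

$$\frac{du}{dt} = \alpha - \beta u, \qquad \frac{ds}{dt} = \beta u - \gamma s,$$

where $u$ and $s$ are unspliced and spliced transcript abundances. Spatial
platforms (Visium, MERFISH, HybISS, seqFISH) rarely resolve splice status,
so the quantities velocity needs are missing exactly where the tissue
context is. `spotvelo` closes that gap:

1. **Integration** — both modalities, restricted to their shared gene
   panel, are embedded by RBF kernel PCA; gene-space component loadings
   are aligned by SVD of their cross-product, retaining components whose
   cosine similarity exceeds 0.3, and both datasets are projected into the
   reference-side aligned space. With a linear kernel the stage reduces
   exactly to classical PCA + principal-vector alignment.
2. **Transfer** — each spot's $k = 50$ nearest reference cells (cosine
   distance in the aligned space) contribute spliced/unspliced expression
   and cell-type labels through inverse-distance weights
   $a^*_{ij} = \bigl(1 - d_{ij}/\sum_j d_{ij}\bigr)/(k-1)$, which sum to 1
   per spot by construction.
3. **Velocity** — per gene, $\gamma$ is fitted on the extreme spliced
   quantiles (steady-state assumption $u = \gamma s$), velocity is
   $v = U - \gamma S$, and a cosine-softmax transition graph projects
   arrows onto the tissue coordinates. A diffusion-rank pseudotime orders
   spots along the flow.
4. **Analytics** — magnitude-weighted cosine similarity between velocity
   fields; binned distance-variance and percentile trends over pseudotime
   with cubic fits; per-cell-type weights $\omega \in [0,1]$ quantifying
   time- versus space-driven expression via
   $Y' = \omega T + (1 - \omega) D$.

A splicing-ODE simulator (`simulate_paired()`) generates paired datasets
with full ground truth, so every stage is testable without downloads.

## Worked example

```r
library(spotvelo)

sim <- simulate_paired(simulation_config(seed = 7))   # 500 cells, 300 spots,
res <- run_pipeline(sim$ref, sim$spatial,             # 200 genes, 60 shared
                    pipeline_config(seed = 7),
                    reference_velocity = sim$truth$spot_velocity)
res
#> pipeline_result
#>   retained components: 41
#>   valid velocity genes: 200
#>   velocity similarity score: 0.9854
```

41 aligned components pass the 0.3 similarity threshold; all 200 genes get
a valid steady-state fit; and the inferred field agrees with the simulated
ground truth on the shared panel with a weighted cosine score of 0.985
(1 is perfect agreement, −1 perfect opposition). The per-gene fits are a
tibble:

```r
glance(res$velocity_model)
#> # A tibble: 1 × 4
#>   n_genes n_valid median_gamma median_r2
#> 1     200     200        0.920     0.976
```

The median fitted degradation ratio 0.92 sits mid-range of the simulator's
$\gamma \sim U(0.3, 1.5)$. Labels transfer at 97% accuracy
(`mean(res$labels$assigned == sim$truth$spot_labels)`), and the per-type
time-versus-space weights come back as:

```r
res$omega
#> # A tibble: 3 × 5
#>   type   omega  loss     n reason
#> 1 type_1 0.233  18.4   116 <NA>
#> 2 type_2 0.459  12.3    80 <NA>
#> 3 type_3 0      22.5   104 <NA>
```

Plots: `autoplot(res$field, color = res$labels$assigned)` draws the arrow
field on tissue coordinates; `autoplot(res$profile)` the distance-variance
trend with its cubic fit; `autoplot(res$omega)` the per-type weights.

A thin command-line wrapper ships in `inst/cli/spotvelo.R`
(`Rscript spotvelo.R simulate --seed 7 --out fixtures/`, then
`Rscript spotvelo.R run --ref fixtures/ref --spatial fixtures/spatial
--out results/`).

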