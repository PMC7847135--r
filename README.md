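# spotmorph

Quantitative analysis of the dorsal spot pattern of *Triatoma dimidiata*
(Hemiptera: Reduviidae), a principal vector of Chagas disease. The species
comprises three genetically defined haplogroups (H1–H3); spotmorph asks how
well the light spot pattern of the dark dorsal abdomen — two central spots
plus paired spots along the connexivum — discriminates them, and provides
every stage needed to answer that question reproducibly:

1. **Standardization** — grayscale conversion, histogram stretch to the
   central 50% of levels, and alignment/isometric rescaling into a canonical
   frame from three annotated landmarks (thorax–abdomen insertions, abdomen
   tip).
2. **Segmentation** — Minimum-method automatic threshold, minority-class
   spot selection, conditional-median outlier removal (radius 6,
   threshold 50), hole filling, connected-component labeling with QC.
3. **Spot variables** — spots numbered central-1/2, left-odd/right-even
   anterior→posterior; per spot the relative area `Ra = 100·area/Ta`, the
   Feret diameters `MaxFd`, `MinFd` (relative to `sqrt(Ta)`), the Feret
   angle `Fa` folded to 0–90°, and the aspect ratio `Ar = MinFd/MaxFd`;
   per specimen class means, the central/lateral area ratio, and
   central–lateral centroid distances after generalized Procrustes
   alignment of the 14-point configurations.
4. **Heat maps** — per-group per-pixel spot frequency of the aligned masks.
5. **Statistics** — nonparametric descriptives and Kruskal–Wallis tests
   (tie-corrected H, df = k−1) per feature.
6. **Classification** — forward-stepwise linear discriminant analysis
   (partial-F on Wilks' Λ, enter 4.0 / remove 3.9) and a single-hidden-layer
   perceptron (full-batch BFGS; tanh/logistic/sine activations;
   cross-entropy or sum-of-squares loss) with a 60/40 per-group split that
   forces LDA-misclassified specimens into validation, plus
   permutation variable importance.
7. **Synthetic specimens** — a generator that renders the three haplogroup
   archetypes (total relative spot area 15.6% for H2 vs 8.7% for H3, H1
   in between with forward-tilted anterior lateral pairs; shape and
   orientation contrasts to match) with exact ground truth, so the whole
   pipeline is testable with no external data.

See `vignettes/spot-pattern-analysis.Rmd` for the model, parameter and
numerical-precision details.

## Worked example

```r
library(spotmorph)

dir.create("demo")
generate_dataset(n_per_group = c(8, 8, 8), master_seed = 11, dir = "demo/data")
cfg <- pipeline_config(images = "demo/data", rois = "demo/data",
                       labels = "demo/data/labels.csv", out = "demo/out",
                       seed = 5)
res <- run_pipeline(cfg)
res$lda
#> Forward-stepwise LDA
#>   selected: mean_Ar_lateral, mean_Ra_central, mean_Fa_lateral
#>   Wilks lambda = 0.0001, F(6, 38.0) = 736.03, p = 1.01e-37
#>   accuracy: 100.0% resubstitution, 100.0% leave-one-out
res$mlp
#> MLP 11-20-3 (tanh hidden, cross_entropy loss)
#>   accuracy: 100.0% training, 100.0% validation
head(res$stats$tests[, c("feature", "H", "p")], 3)
#>           feature      H        p
#> 1        total_Ra 20.480 3.57e-05
#> 2 mean_Ra_central 20.480 3.57e-05
#> 3 mean_Ra_lateral 15.605 4.09e-04
```

The stepwise LDA picks three variables — lateral spot shape, central spot
area and lateral spot orientation, the axes along which the three archetypes
were built to differ — and separates the groups completely (Wilks' Λ near 0;
on 24 synthetic specimens the separation is far cleaner than real
photographs give). The Kruskal–Wallis rows confirm that total and central
relative spot areas differ strongly across groups. `demo/out/` additionally
holds the standardized images, masks, label grids, per-spot and per-specimen
CSV tables, per-group heat-map PNGs, confusion matrices, canonical scores
and the run manifest.

A thin CLI over the same functions is installed with the package
(`inst/cli/spotmorph.R`):

```sh
Rscript inst/cli/spotmorph.R simulate --n 30,30,30 --seed 7 --out data/
Rscript inst/cli/spotmorph.R run --images data/ --labels data/labels.csv --out results/
```

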