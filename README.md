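# STCellSeg

Segmentation of moving cells in 2D fluorescence time-lapse microscopy,
combining spatio-temporal nonlinear diffusion with a temporally linked
Chan-Vese level-set model.

Region-based active contours segment by intensity statistics alone, so
nuclei whose mean intensity is close to the background are absorbed into
it and lost. Moving cells, however, leave strong *temporal*
discontinuities between consecutive frames. STCellSeg detects those
discontinuities first and then lets a level-set model polish the
boundaries, which recovers low-intensity moving cells that pure region
competition misses. The package is aimed at quantitative microscopy work
(cell counting, morphology, growth and migration assays) on 2D
time-lapse data such as the fluorescently labelled nuclei in the Cell
Tracking Challenge sequences.

## The method

For each sliding three-frame window {t−1, t, t+1}:

1. **Intensity standardization.** A training pass pools all frames and
   learns the empirical CDF `F_AF`; a reference background-threshold
   intensity `I_ref` (background-tail quantile or Otsu split) anchors
   `F_AF(I_ref)`. Each window is histogram-matched so its own intensity
   at that cumulative probability, `I_test`, lands on `I_ref`:

       T1(I) = (I_ref − G_Min)/(I_test − L_Min) · (I − G_Min) + G_Min
       T2(I) = 255 · (I − G_Min)/(G_Max − G_Min)

   after which all windows live on a common 0–255 scale.

2. **Spatio-temporal diffusion.** Three coupled Perona-Malik equations
   are solved by explicit finite differences. Spatially, 4-neighbour
   fluxes are weighted by the edge-stopping diffusivity
   `g(x) = 1/(1 + x²/k²)`; temporally, the centre frame exchanges
   intensity with both neighbours through the forward/backward
   differences `PF = I_{t−1} − I_t`, `NF = I_{t+1} − I_t` weighted by
   `g(|PF|)`, `g(|NF|)`. Background smooths out; spatio-temporal
   discontinuities — moving cells — survive.

3. **Parzen edge map.** For every pixel, the Gaussian-kernel density
   `f_h` of its local window is evaluated at the window mean. A bimodal
   (edge-straddling) window puts the mean in a density valley, so
   `1 − f_h(mean)/max f_h` is an edge-occurrence index in [0, 1].

4. **Watershed delineation.** The inverted edge map is flooded from its
   regional minima; basins are classified as cell or background by
   comparing their mean intensity with the standardized reference
   `T2(I_ref)` (optionally filtered by Gaussian area/intensity
   likelihoods), and adjacent cell basins merge into instances.

5. **Temporally linked Chan-Vese refinement (ST-Diff-TCV).** The motion
   mask initializes the level set `φ`; gradient descent on

       F(φ, c1, c2) = μ·length + ν·area + λ1 ∫_{φ≥0}(I−c1)² + λ2 ∫_{φ<0}(I−c2)²

   refines the boundary, and the converged field seeds the next frame
   (`φ_{n+1}(x, y; 0) = φ_n(x, y; i_final)`). Every k-th frame is
   re-seeded from the motion mask so mitoses and entering cells are
   picked up.

Validation uses the Dice coefficient `2|A∩B|/(|A|+|B|)`; image quality is
summarized by `SNR = 20·log10(ū_C/ū_B)` and `CNR = |ū_C − ū_B|/σ_B`.

## Worked example

A synthetic two-nucleus sequence (the package ships a simulator with
ground-truth masks) segmented by the joint method:

```r
library(STCellSeg)

cfg <- standardFixtures()$clean_two_blob     # 2 cells, 10 frames, SNR 20 dB
sim <- generateSequence(cfg)
sim$sequence
#> FrameSequence: 10 frame(s) of 128x128 (16-bit)
#>   global intensity range: [12.1949, 653.304]

res <- segmentSequence(sim$sequence, method = "stdiff_tcv",
                       config = fixtureSegConfig("clean_two_blob"))
ev <- evaluateSegmentation(res$masks, sim$masks)
cat(sprintf("mean Dice %.3f (sd %.3f)\n", attr(ev, "mean"), attr(ev, "sd")))
#> mean Dice 0.972 (sd 0.016)

cat(sprintf("SNR %.2f dB, CNR %.2f\n",
            snr(frameAt(sim$sequence, 1), sim$masks[[1]]),
            cnr(frameAt(sim$sequence, 1), sim$masks[[1]])))
#> SNR 19.87 dB, CNR 6.96
```

Per-frame Dice sits between 0.95 and 0.99; the motion-only delineation
(`method = "stdiff"`) reaches about 0.89 on the same data and the plain
Chan-Vese baseline about 0.69, so each stage of the joint method earns
its keep. On the `dim_mover` fixture — a dim nucleus displacing 4
px/frame next to a bright one — plain Chan-Vese never finds the dim
cell, while the joint method covers it in every frame.

A command-line front end for shell use lives at
`inst/scripts/stdiff-tcv.R` with `segment`, `evaluate` and `simulate`
subcommands.

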