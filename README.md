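# porediff

Diffusive transport in porous media is controlled by the pore geometry: the
same bulk diffusivity `D0` yields very different effective transport in a
sand-packing-like grain arrangement than in the sheet-and-tunnel channel
networks of tissue extracellular space.  `porediff` is an R package for
studying this numerically, end to end:

* **Geometry generators** for two media families on an `L x L` lattice —
  type A: randomly deposited, overlapping 3x3 solid grains (granular
  media); type B: fluid channels of uniform width grown around the Voronoi
  edges of a random point set tiled into its eight period images
  (extracellular-space-like networks).  Every emitted sample passes a
  left-right percolation test.
* **A lattice Boltzmann solver** (D2Q5, two-relaxation-time) for the steady
  diffusion problem `dc/dt = div(D0 grad c)` with fixed concentrations
  `c_in = 0`, `c_out = 1` on the left/right faces and zero normal flux on
  solids and the top/bottom walls, calibrated to `D0 = 1`; plus an
  independent sparse finite-volume oracle that reproduces the iterated
  steady state to ~1e-11.
* **Transport analysis**: the discrete Fick's-law estimator
  `D = L / (N (c_out - c_in)) * sum_f dc/dx` (pore-averaged or superficial
  normalization), diffusive tortuosity `lambda = D0 / D`, and Archie-law
  fits `D = phi^(n-1)` (equivalently `lambda^2 = phi^(1-n)`).
* **Convolutional surrogates**, implemented in the package itself
  (im2col + GEMM convolutions in compiled code, finite-difference-verified
  backprop): C-Net and U-Net-Half predict `(phi, D)` from the geometry
  image; a U-Net reconstructs the full steady concentration map.  Scalar
  heads optionally carry a self-normalization (SN) module — multiplicative
  output factors `2*sigmoid(.)` in (0,2) with a unit-normalization penalty —
  and all models provide Monte Carlo dropout uncertainties (`M = 20`
  stochastic passes, per-output or per-node 1-sigma bands).

The methods vignette (`vignettes/porediff-methods.Rmd`) documents the
schemes, conventions and numerical choices in detail.

## Worked example

```r
library(porediff)

# a channel-network sample targeting 35% porosity
s <- generate_type_b(128, generator_config_b(0.35), seed = 3)
porosity(s)
#> [1] 0.3904419

# steady concentration field and effective diffusion
f <- solve_steady(s)                        # tolerance 1e-13
f
#> <concentration_field> 128 x 128 (lbm), iterations = 82730, final delta = 9.96e-14, converged: TRUE
effective_diffusion(f, s)                   # pore-averaged: 1/lambda^2
#> [1] 0.4771682
effective_diffusion(f, s, normalization = "total")   # superficial (label convention)
#> [1] 0.1863064
tortuosity(1, effective_diffusion(f, s))
#> [1] 2.095697
```

The pore-averaged value isolates the network tortuosity (`lambda ~ 2`
here); the superficial value additionally counts the lost pore volume and
is the quantity whose porosity dependence follows Archie's law for these
media.  A labeled dataset plus Archie fit:

```r
ds <- make_porous_dataset(40, "B", L = 64, phi_range = c(0.15, 0.7), seed = 1)
fit_archie(ds$records)
#> <archie_fit> n = 2.983 (linear-space RSS 0.02448, 40 records)
```

Training the reduced field surrogate (the scaled configuration used by
the acceptance script; ~8 min on one core):

```r
sp <- split_dataset(make_porous_dataset(150, "B", L = 64, seed = 1, task = "both"),
                    0.7, seed = 2)
m <- build_unet(surrogate_spec("UNET", input_side = 64, containers = 3,
                               blocks_per_container = 2, n_kernels = 32,
                               dropout_where = "bottleneck"), seed = 3)
train_surrogate(m, sp$train, epochs = 8, batch_size = 8, lr = 3e-3, seed = 4)
train_surrogate(m, sp$train, epochs = 0, finetune_epochs = 20,
                finetune_lr = 1e-3, batch_size = 8, seed = 5)
evaluate_field(m, sp$val, M = 20)$mean_abs_error   # mean |true - pred| over all nodes
```

At these desk-scale conditions the held-out mean absolute error lands
around 1.3-1.6% of the concentration scale (the acceptance script below
measures it exactly).  The methods vignette explains why the reduced
configuration floors near the harmonic-baseline error instead of the
sub-1% level a full-depth network reaches at full scale.

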