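# pasvd

Blockwise SVD separation of stationary and flowing blood signals in
interleaved ultrasound/photoacoustic (US/PA) imaging.

## The problem

Single-wavelength photoacoustic imaging of the carotid artery cannot tell
hemoglobin in a stationary intraplaque hemorrhage (IPH) apart from
hemoglobin in flowing luminal blood — both absorb and emit alike. Motion
can: flowing blood decorrelates the speckle pattern from frame to frame,
stationary blood does not. `pasvd` turns that difference into a detector
for stationary PA sources. It is aimed at researchers processing
multiframe beamformed US/PA stacks (10–30 Hz frame rates) who want a
reproducible, scriptable implementation of the whole chain, plus a
synthetic phantom to validate against.

## The method

The multiframe US data of an image block is reshaped into the Casorati
matrix `C` (pixels x frames) and decomposed, `C = U S V'`. Two singular
orders are selected automatically per block:

* `t_low` — the first order `i` where `S_dB(i) / S_dB(i+1)` drops below a
  preset ratio (the tissue/flow boundary);
* `t_high` — the global minimum of the twice-smoothed derivative of the
  singular-value curve (the flow/noise knee).

Orders `1..t_low` reconstruct the stationary-tissue component,
`t_low+1..t_high` the flow component, and the rest the noise component;
the three sum to the input exactly. Per-block threshold fields are
median-filtered across the block grid to remove outliers. The US flow
component then yields a binary perfusion mask (blur, temporal standard
deviation, dynamic-range compression, edge detection, closing, filling),
and PA signal connected to the perfusion region is removed by iteratively
growing the overlap between thresholded PA and the mask — equivalent to
deleting every PA connected component that touches perfusion. Image
quality is quantified with the generalized contrast-to-noise ratio,
`gCNR = 1 - sum_k min(h_sig(x_k), h_bg(x_k))`, which is invariant under
monotone remappings of the gray scale and therefore meaningful for
nonlinear filters.

See `vignettes/methods.Rmd` for the model, parameter defaults with units
and rationale, numerical conventions, and known limitations.

## Worked example

```r
library(pasvd)

# simulate the pulsatile vessel phantom: 3-mm lumen at 1 Hz / 9% strain,
# 0.5-mm arteriole, two 1-mm stationary blood channels; 300 frames, 30 Hz
sim <- simulate_phantom(phantom_config(seed = 1))

components <- blockwise_filter(sim$us, filter_config())
components
#> ComponentSet: 128 x 128 px, 300 frames; grid 1 x 1 blocks
#>   t_low range: 4-4; t_high range: 45-45 (of 300 orders)

detection <- detect_stationary_pa(components, sim$pa, filter_config())

# how well did the perfusion mask recover the true flow region?
tr <- sim$truth
dice <- 2 * sum(detection$perfusion_mask & tr$flow) /
  (sum(detection$perfusion_mask) + sum(tr$flow))
round(dice, 3)
#> [1] 0.869

# PA energy bookkeeping on the linear-amplitude scale
lin <- 10^(detection$pa_image / 20)
lin_masked <- lin * detection$final_mask
round(sum(lin_masked[tr$iph]^2) / sum(lin[tr$iph]^2), 3)    # IPH retained
#> [1] 1
round(sum(lin_masked[tr$flow]^2) / sum(lin[tr$flow]^2), 3)  # flow residual
#> [1] 0.005
```

The filter kept orders 1–4 as stationary tissue (mean image plus wall
pulsation) and orders 5–45 as flow. The perfusion mask overlaps the true
flow region with Dice 0.87; masking removed 99.5 % of the flow-associated
PA energy while retaining all of the stationary (hemorrhage) PA energy.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pasvd.R", package = "pasvd"))')
Rscript "$CLI" simulate --output sim_dir --seed 1
Rscript "$CLI" run --input sim_dir --output out_dir
Rscript "$CLI" gcnr --input out_dir --group components/stationary \
  --signal 44,56,58,70 --background 44,56,3,15
```

Subcommands: `simulate`, `filter`, `detect`, `gcnr`, `run`,
`sweep-blocksize`. Containers are directories with a JSON metadata sidecar
and flat float64 payload per group; configs are flat YAML key–value files
(see `?filter_config`, `?phantom_config`; phantom presets ship under
`inst/extdata/presets/`). Every run writes a provenance record with the
full configuration, defaulted values included.

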