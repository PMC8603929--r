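# crmrept

Conductivity imaging of brain tumours by MR electrical properties
tomography (MREPT), as a tested, fully synthetic-data-driven R pipeline.

At the Larmor frequency, tissue conductivity sigma_H reflects ion
concentration and mobility, and can be estimated from the transceive RF
phase phi_tr of a spin-echo acquisition — no electrodes, no injected
current. This package implements the complete workflow used to study a rat
glioblastoma model at 9.4 T (~400 MHz), for researchers who want a
reproducible desk-scale testbed for high-field phase-based conductivity
imaging:

* **Phantom simulation** — six-region brain-tumour phantoms (contralateral
  cortex, tumour rim, viable tumour, necrotic core, ventricles, edema)
  with literature conductivity/diffusivity values; a divergence-form
  forward solver for the transceive phase; multi-coil multi-echo spin-echo
  and multi-shell DWI simulators with seeded Rician noise.
* **Phase processing** — two-step referenceless channel combination,
  exact-congruence quality-guided unwrapping, squared-magnitude echo
  weighting.
* **Reconstruction** — the phase-based estimate
  `sigma_H = lap(phi_tr) / (2 mu0 omega)` and the stabilized
  convection–reaction solve for u = 1/sigma_H,

  ```
  -c lap(u) + grad(phi_tr) . grad(u) + lap(phi_tr) u = 2 mu0 omega
  ```

  assembled as a sparse finite-difference system per slice with automatic
  artificial-diffusion sizing and Peclet-switched upwinding.
* **Diffusion** — log-linear tensor fit over both shells, mean diffusivity
  MD = (l1 + l2 + l3)/3.
* **Statistics** — per-VOI summaries, Welch two-tailed t-tests across
  regions and imaging days, MD–conductivity Pearson correlation.

## Worked example

Simulate one imaging session over the default tumour phantom, reconstruct
conductivity, fit MD, and summarise the six regions:

```r
library(crmrept)

spec <- default_phantom_spec()
ph   <- build_phantom(spec)                      # ground truth + VOI labels
phi  <- forward_phase(ph$sigma)                  # transceive phase (PDE solve)
raw  <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec,
                             noise_sd = 0.005, seed = 1)
ec   <- combine_echoes(grpc_combine(raw))        # channel + echo combination
rec  <- cr_mrept_solve(smooth_phase(ec$phase, 3),
                       recon_config(laplacian_kernel = "savgol",
                                    savgol_radius_vox = 2))
rec  <- erode_and_mask(rec, ph$vois, 2)          # drop blurred interfaces
md   <- mean_diffusivity(fit_tensor(
          simulate_dwi(ph$md, noise_sd = 0.02, seed = 2)))

round(rbind(sigma = sapply(region_values(rec$sigma, ph$vois), mean),
            md    = sapply(region_values(md, ph$vois), mean)), 3)
```

```
      contralateral_cortex ventricles edema tumor_rim viable_tumor tumor_core
sigma                0.437      0.732 0.743     0.924        0.968      0.936
md                   0.689      1.229 0.890     0.809        0.761      0.888
```

Reading the output: each column is one volume of interest; the first row
is the reconstructed conductivity mean (S/m) over the eroded region, the
second the fitted mean diffusivity (um^2/ms). The ground-truth values are
0.44/0.72/0.77/0.96/0.93/0.84 S/m and 0.69/1.23/0.89/0.81/0.76/0.89
um^2/ms: cortex, ventricles and edema are recovered closely, while the
nested tumour compartments show the expected interface blur of
Laplacian-based reconstruction (the narrow rim pulled toward its
neighbours, the small core biased up toward the surrounding viable
tumour). The tumour/cortex conductivity contrast — the effect of interest
— is recovered robustly.

The full longitudinal study (days 8, 11, 14; tumour conductivity rising,
tumour MD flat, necrotic core absent on day 8) runs as

```r
res <- run_pipeline(pipeline_config(seed = 1), outdir = "out/")
head(res$stats)         # per-region, per-day summaries for both maps
res$pearson             # MD vs conductivity across regions and days
```

and writes NIfTI maps, CSV tables and an md5 manifest (bit-reproducible
for a given seed). A thin CLI wrapping these functions is installed at
`inst/cli/crmrept` (subcommands `simulate`, `unwrap`, `recon`, `dti`,
`stats`, `pipeline`).

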