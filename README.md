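# nvselect

Selective addressing of nitrogen-vacancy (NV) fluorescence in
polarization-modulated wide-field image stacks.

## The problem

Fluorescent nanodiamonds (FNDs) hosting NV centers are photostable probes for
bioimaging and quantum sensing, but in cells and tissue their red emission is
easily buried under autofluorescence, staining dyes or stray light. NV
emission, however, depends on the angle between the linear excitation
polarization and the NV axis: sweeping the polarization with a rotating
half-wave plate imprints a sinusoidal modulation on NV pixels that nothing
else in the scene shares. `nvselect` exploits this physical signature to
classify every pixel of a modulated image stack as NV or non-NV, producing
background-suppressed selective images and background-free ODMR spectra,
without any trained model.

## The model

A stack of `K` frames at equidistant polarization angles `beta_k` is an
`H x W x K` tensor. For an NV center with in-plane axis projection `alpha`
and out-of-plane angle `theta`, the effective excitation is

    I_eff / I_act = 1 - cos^2(theta) * cos^2(beta - alpha)

so an NV pixel trace is a single sine wave

    I_k = c + A * cos(2 * pi * f * k + phi),

with `f` (cycles/frame) fixed by the acquisition and a modulation contrast
`(max - min) / max = cos^2(theta)`. Non-NV pixels carry white noise. Per
pixel, `nvselect` fits the sine basis `{1, cos, sin}` at `f` (or finds `f`
by periodogram search) and extracts amplitude, frequency, phase, offset and
the *fitting accuracy* — the R^2 of the single-sine fit, whose null
distribution on white noise is exactly Beta(1, (K-3)/2). A pixel is NV iff

* accuracy >= 0.8,
* amplitude >= 5 x the robust amplitude noise floor, and
* (free-frequency mode) |f_hat - f_mod| <= 0.02 cycles/frame.

Quantitative outputs: signal-to-background ratio
`SBR = 20 log10(mean_signal / mean_background)` (dB, 1-count floor),
line-profile FWHM, and Lorentzian ODMR dip fits (center, FWHM, contrast);
unmodulated background dilutes measured ODMR contrast by `S / (S + B)`, which
mask gating undoes.

## Worked example

```r
library(nvselect)

# a stained-cell analog: 256 x 256 x 72 stack, 10 FNDs over a textured
# background calibrated so the raw mean-image SBR is 2.61 dB
scene <- scenario_preset("stained_cell", seed = 42)
gen   <- generate_scene(scene)

sbr_db(rowMeans(gen$stack$data, dims = 2), gen$truth$nv_mask)
#> SBR: 2.61 dB (signal mean 18990.9, background mean 14060.84)

feats <- extract_features(gen$stack)      # fixed-frequency fit at f = 0.21
feats
#> feature_maps: 256 x 256 pixels, fixed-frequency fit, noise floor 33.4

mask <- classify_pixels(feats)
sum(mask)                                  # 90 NV pixels (= ground truth)
classification_metrics(mask, gen$truth$nv_mask)[c("precision", "recall")]
#> $precision [1] 1   $recall [1] 1

sbr_db(selective_image(gen$stack, mask), gen$truth$nv_mask)
#> SBR: 85.57 dB (signal mean 18990.9, background mean 0.00)
```

The raw image shows FNDs barely twice as bright as the stained background
(2.61 dB); after classification every background pixel is exactly zero and
the SBR of the selective image is set by the 1-count metric floor.

The same pipeline runs from a shell via the installed `exec/nvselect`
script (`simulate`, `classify`, `metrics`, `odmr` subcommands); every run
writes a `run_record.json` with its config, seed and timings.

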