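# cestpvc

Partial-volume-corrected quantitative CEST (APT) analysis in R.

## The problem

Amide proton transfer (APT) CEST MRI measures the exchange of saturated
amide protons (+3.5 ppm from water) with bulk water, and is used in acute
ischemic stroke because the ischemic core shows a reduced APT effect. But
cerebrospinal fluid (CSF) has essentially no APT effect of its own, so any
voxel at a tissue–CSF boundary shows the *same* signature — reduced APT —
purely through dilution. `cestpvc` is for researchers analyzing z-spectral
CEST data who want quantification that is robust to the CSF content of a
voxel.

## The model

Z-spectra are modeled with a continuous-wave multi-pool Bloch–McConnell
system (water, amide, semisolid MT, NOE for tissue; one free-water pool
for CSF), propagated exactly by matrix exponentials. A voxel with tissue
fraction `[tissue]` (from an independent segmentation-derived
partial-volume estimate, PVE) is fitted as the mixture

    S_total(w) = (1 - [tissue]) * S_CSF(w) + [tissue] * S_tissue(w)

with the CSF magnetization pinned to the tissue water scale by a fixed
proportionality constant (default 0.53, estimable from unsaturated images
with `estimate_csf_tissue_ratio()`). Fitting is voxelwise MAP with
Gaussian priors, a free per-voxel B0 shift, and Laplace posterior
uncertainties. The APT measure is the model-based ratio

    APTR* = (S_w - S_w+a) / S_0    evaluated at +3.5 ppm,

the difference between the fitted spectrum without and with the amide
pool; for partial-volume-corrected (PVC) fits only the tissue compartment
enters, so the measure is undiluted by CSF. Voxels with tissue PVE < 0.5
are fitted CSF-only and excluded from APT analysis. Repeatability
(coefficient of variation), spatial variability, lesion contrast-to-noise
and CSF-fraction profiles are included, as is a digital stroke phantom
with known ground truth that exercises the whole pipeline.

## Worked example

Generate a stroke phantom (30% amide reduction in a 3x3 core, 1% noise),
fit both models over the lesion and its mirrored contralateral ROI, and
compare the lesion contrast-to-noise:

```r
library(cestpvc)

ds <- generate_phantom(default_stroke_spec(seed = 42))
mask <- ds$roi$core | ds$roi$contralateral
opts <- fit_options(compute_sd = FALSE)

for (tag in c("four_pool", "pvc")) {
  fit <- fit_image(ds$data_4d, ds$protocol, pve_map = ds$tissue_pve,
                   mask = mask, model_tag = tag, options = opts,
                   s0_volume = ds$s0_volume)
  aptr <- aptr_star_image(fit)
  cat(sprintf("%-9s core %.5f  contra %.5f  CNR %.2f\n", tag,
              mean(aptr$values[ds$roi$core]),
              mean(aptr$values[ds$roi$contralateral]),
              contrast_to_noise(aptr$values[ds$roi$core],
                                aptr$values[ds$roi$contralateral])))
}
```

prints

```
four_pool core 0.01670  contra 0.02288  CNR -0.79
pvc       core 0.01670  contra 0.02288  CNR -0.79
```

Mean core APTR* sits well below contralateral (the lesion's 30% amide
reduction; the noise-free values are 0.0159 vs 0.0226), the CNR is
negative (core signal is *reduced*) and identical between the models —
partial-volume correction does not cost lesion contrast in clean tissue.
At this noise level the per-voxel APTR* scatter is comparable to the
lesion contrast, so the CNR magnitude (here 0.79) varies noticeably with
the noise seed. The corrective effect appears on mixed voxels:

```r
p <- default_protocol()
cm <- compartment_model()
z <- pvc_spectrum(cm, pve = 0.6, p)          # 60% tissue, 40% CSF, no noise
zz <- zspectrum(z$offsets, z$signal, 1)
aptr_star(fit_voxel(zz, p, "four_pool", options = opts), p)  # 0.0106
aptr_star(fit_voxel(zz, p, "pvc", pve = 0.6, options = opts), p)  # 0.0226
```

The uncorrected 4-pool APTR* of this 60%-tissue voxel is roughly halved by
CSF dilution; the PVC value matches the pure-tissue 0.0226.

A thin command-line interface over the same functions ships in
`inst/cli/cestpvc` (`phantom`, `fit`, `quantify`, `stats`, `ratio`
subcommands).

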