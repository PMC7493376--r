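# Shared phantom fixtures. The "standard" phantom is an 8 mm sphere of
# uptake 6 g/ml on 0.5 g/ml background with 5 mm PSF blur on the clinical
# anisotropic grid.

standard_phantom <- function(radius = 8, peak = 6, fwhm = 5, noise_sd = 0,
                             seed = 1, shape = c(64, 64, 40),
                             center = c(37, 37, 60)) {
  make_pet_phantom(
    shape = shape, spacing = c(1.17, 1.17, 3.27), background_suv = 0.5,
    lesions = list(phantom_lesion(center, radius, peak)),
    psf_fwhm_mm = fwhm,
    noise = if (noise_sd > 0) list(type = "gaussian", sd = noise_sd)
            else list(type = "none"),
    seed = seed)
}

# small unblurred phantom whose lesion is cheap to extract features from
small_lesion_fixture <- function(seed = 5) {
  ph <- make_pet_phantom(
    shape = c(24, 24, 12), spacing = c(1.17, 1.17, 3.27),
    background_suv = 0.5,
    lesions = list(phantom_lesion(c(14, 14, 20), 5, 6)),
    psf_fwhm_mm = 0, noise = list(type = "gaussian", sd = 0.05), seed = seed)
  list(vol = ph$volume, mask = ph$masks[[1]])
}
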