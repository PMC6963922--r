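# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, .fixture_env)) assign(name, make(), .fixture_env)
  get(name, .fixture_env)
}

demo_signatures <- function(seed = 3) {
  fixture(paste0("sig", seed), function() lapply(0:2, make_signature, seed = seed))
}

# one small rendered scene with default noise, 18 fruits (6 per origin)
demo_scene <- function() {
  fixture("scene", function() {
    cfg <- scene_config(n_fruits_per_class = 6L, scene_width = 180L,
                        scene_length_L = 180L, seed = 11)
    render_scene(demo_signatures(), cfg)
  })
}

demo_cube <- function() {
  fixture("cube", function() {
    sc <- demo_scene()
    correct_reflectance(sc$raw, sc$dark, sc$white)
  })
}

# a noiseless scene (all stochastic terms off)
demo_scene_noiseless <- function() {
  fixture("scene0", function() {
    cfg <- scene_config(n_fruits_per_class = 2L, scene_width = 100L,
                        scene_length_L = 100L, noise_sd_additive = 0,
                        illumination_gain_sd = 0, fruit_effect_sd = 0,
                        seed = 12)
    render_scene(demo_signatures(), cfg)
  })
}

# small separable spectrum table sampled directly from the signatures
# (bypasses rendering; for model-level tests). The noise level mimics a
# per-fruit averaged spectrum on the unit-sum scale (mean value ~1/200),
# where residual noise is a few percent of the signal.
demo_table <- function(n_per_class = 20L, seed = 5L, noise_sd = 2e-4) {
  fixture(sprintf("tab_%d_%d", n_per_class, seed), function() {
    sigs <- demo_signatures()
    wl <- crop_bands(sigs[[1]]$wavelength)
    rows <- list(); labs <- integer(0)
    set.seed(seed)
    for (o in 0:2) {
      base <- area_normalize(crop_bands(sigs[[o + 1]]$reflectance))
      for (i in seq_len(n_per_class)) {
        rows[[length(rows) + 1L]] <-
          area_normalize(base + rnorm(length(base), 0, noise_sd))
        labs <- c(labs, o)
      }
    }
    spectrum_table(do.call(rbind, rows), wl, labs)
  })
}
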