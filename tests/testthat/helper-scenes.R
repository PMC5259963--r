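# Default synthetic scenes are expensive enough to build once and share
# across test files.
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(preset = c("intact", "broken")) {
  preset <- match.arg(preset)
  if (is.null(.scene_cache[[preset]])) {
    cfg <- switch(preset,
                  intact = default_intact_config(),
                  broken = default_broken_config())
    lab <- build_labels(cfg)
    stk <- render_intensities(lab, cfg)
    .scene_cache[[preset]] <- list(cfg = cfg, lab = lab, stk = stk)
  }
  .scene_cache[[preset]]
}

# A small scene (fast to build) exercising the same geometry: TM texture,
# one SC-like void, one vein-like void.
small_scene_config <- function(seed = 7L, porosity = c(0.5, 0.7),
                               noise = list(photon_scale = 2000, read_sigma = 5),
                               psf_sigma = c(2, 1),
                               attenuation_length = 180) {
  scene_config(
    stack_shape = c(8, 96, 128),
    lateral_pitch = 2, axial_step = 5, depth_origin = 100,
    tm_roi = roi(rows = c(17, 80), cols = c(41, 80), depths = c(105, 130)),
    porosity_knots = data.frame(depth_um = c(105, 130), porosity = porosity),
    sc_path = data.frame(depth_um = c(110, 130), row = c(48, 48),
                         col = c(104, 104), major_um = c(24, 30),
                         minor_um = c(24, 30)),
    vein_path = NULL, vein_branch = NULL,
    beam_thickness_mean = 8,
    noise = noise, attenuation_length = attenuation_length,
    psf_sigma = psf_sigma, seed = seed
  )
}
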