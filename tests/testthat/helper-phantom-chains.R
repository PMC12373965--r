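# Shared fixtures: all synthetic, built in code at test time.

# circularly shifted copies of one image: a "moving eye" stack whose content
# (and hence any density ground truth) is identical in every frame
shifted_stack <- function(img, n_frames, seed, camera = "mono_global",
                          pitch = 1) {
  set.seed(seed)
  sh <- cbind(sample(30:200, n_frames, replace = TRUE),
              sample(30:200, n_frames, replace = TRUE))
  frames <- lapply(seq_len(n_frames), function(k) {
    m <- img[c((sh[k, 1] + 1):nrow(img), 1:sh[k, 1]), ]
    m[, c((sh[k, 2] + 1):ncol(img), 1:sh[k, 2])]
  })
  image_stack(frames, pitch, camera)
}

# endothelial phantom -> color-camera artifacts -> published chain -> density
recover_mosaic_density <- function(seed, density = 3200) {
  spec <- phantom_spec(fov_mm = 0.5, density = density, modulation = 20,
                       bayer_amplitude = 4, noise_sd = 2, seed = seed)
  ph <- gen_endothelial_mosaic(spec)
  art <- add_camera_artifacts(ph$image, spec)
  img <- highpass(bayer_smooth(art$image, "color_rolling"), 121)
  det <- detect_cells(img, spec$pixel_pitch_um, "bright",
                      scale_um = ph$truth$cell_spacing_um,
                      mask = ph$truth$mask_bright)
  cell_density(det)
}

# nerve phantom -> mono-camera artifacts on a moving stack -> chain -> density
recover_nerve_density <- function(seed, density = 22) {
  spec <- phantom_spec(fov_mm = 1, density = density, modulation = 20,
                       fixed_pattern_rms = 5, noise_sd = 2, seed = seed)
  ph <- gen_nerve_layer(spec)
  st <- shifted_stack(ph$image, 15, seed + 999)
  art <- add_camera_artifacts(st, spec)
  proc <- process_stack(art$stack, highpass_kernel = 121)
  nerve_length_density(trace_nerves(proc$frames[[1]], spec$pixel_pitch_um))
}
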