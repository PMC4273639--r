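# Shared fixtures: small fields keep the image tests fast; the full assay
# geometry is used only where its constants themselves are under test.

assay_geometry <- function() experiment_geometry()

small_geometry <- function(n_fields = 4) {
  experiment_geometry(field_width_um = 200, field_height_um = 160,
                      n_fields = n_fields)
}

# a quiet field: uniform illumination in the ROI, no noise unless asked
simple_truth <- function(transconjugants = empty_colonies(),
                         donors = empty_colonies(),
                         noise_sd = 0, seed = 1,
                         field_width_um = 200, field_height_um = 160, ...) {
  imaging_truth(donors = donors, transconjugants = transconjugants,
                field_width_um = field_width_um,
                field_height_um = field_height_um,
                noise_sd = noise_sd, seed = seed, ...)
}

colony <- function(x, y, r, peak = 1) {
  data.frame(x_um = x, y_um = y, radius_um = r, peak = peak)
}

published_frequencies <- function() {
  mating_frequency_set(conj_comm = 1.16e-4, conj_intra = 1.76e-3,
                       retro_comm = 1.16e-5, retro_intra = 8.34e-4,
                       direct_comm = 3.14e-3)
}
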