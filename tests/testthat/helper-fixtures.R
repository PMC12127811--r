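# Shared fixtures: tiny phantom cohorts and desk-scale model configs built
# in code at test time.

# eight noise-free phantoms with both classes present for every gene and
# rule-consistent triples
tinyOverfitCohort <- function(shape = c(16L, 16L, 16L), noise = 0) {
  labs <- rbind(c(1, 0, 1), c(1, 1, 0), c(0, 0, 0), c(0, 1, 0),
                c(1, 0, 1), c(1, 1, 0), c(0, 0, 0), c(0, 1, 0))
  spec <- cohortSpec(8, volume_shape = shape,
                     lesion_radius_range = c(2.5, 3.5),
                     noise_sd = noise, seed = 11)
  set.seed(42)
  lapply(seq_len(8), function(i)
    renderSubject(labs[i, ], spec, sprintf("sub-%03d", i)))
}

# smallest config the architecture admits (8^3 input, one token)
microConfig <- function(...) {
  modelConfig(input_size = 8L, base_channels = 2L, n_heads = 4L,
              n_layers = 2L, fc_widths = c(16L, 8L, 4L), ...)
}

# a bare transformer-branch config (bypasses full-model width coupling)
vitOnlyConfig <- function(e, input_size = 8L, n_layers = 1L, n_heads = 2L) {
  list(input_size = input_size, base_channels = 2L, embed_dim = as.integer(e),
       n_heads = n_heads, n_layers = n_layers, patch_size = 1L)
}

# one transformer layer's parameters at a given embedding width
mkAccLayerParams <- function(e) {
  set.seed(31)
  gliotyper:::vitParams(vitOnlyConfig(e))$layers[[1]]
}

tinySpec <- function(n = 4, volume_shape = c(16L, 16L, 16L),
                     lesion_radius_range = c(2.5, 3.5), ...) {
  cohortSpec(n, volume_shape = volume_shape,
             lesion_radius_range = lesion_radius_range, ...)
}
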