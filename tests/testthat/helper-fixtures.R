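# shared fixtures: everything is generated in code, nothing on disk

# a tiny network that still exercises every architectural element
tiny_cfg <- function(seed = 1, ...) {
  network_config(depth = 2, base_channels = 4, dense_layers = 2, growth = 2,
                 involution = list(kernel_size = 3, groups = 1, reduction = 2),
                 seed = seed, ...)
}

tiny_unet_cfg <- function(seed = 1) {
  unet_config(depth = 2, base_channels = 4, seed = seed)
}

# small in-memory scenes for trainer tests
tiny_scenes <- function(n = 12, side = 32, seed = 5) {
  make_scenes(n, scene_spec(height = side, width = side,
                            lodging_fraction = 0.25, n_patches = 2),
              seed = seed)
}

# a random involution configuration with valid divisibility
rand_invol_spec <- function() {
  C <- sample(c(2L, 4L, 6L, 8L), 1)
  divs <- which(C %% seq_len(C) == 0L)
  involution_spec(channels = C,
                  kernel_size = sample(c(1L, 3L, 5L), 1),
                  groups = sample(unique(c(1L, 2L[C %% 2L == 0L], C)), 1),
                  reduction = sample(divs, 1))
}

# identity kernel field: one-hot at the center offset for every pixel/group
identity_kernels <- function(h, w, spec) {
  K <- spec$kernel_size
  G <- spec$groups
  ker <- array(0, c(h, w, K * K * G))
  ctr <- (K %/% 2) + K * (K %/% 2)
  for (g in seq_len(G) - 1L) ker[, , ctr + K * K * g + 1L] <- 1
  ker
}
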