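# Shared fixtures, built once per test run. Kept deliberately small: short
# inversion blocks and coarse grids so the full suite stays fast.

# toy timing: 40 readouts/block so a block lasts 0.32 s + 0.1 s delay
toy_timing <- function(n_blocks = 3L, delay_s = 0.1) {
  sequence_timing(tr_s = 0.008, flip_rad = 14 * pi / 180,
                  n_readouts_per_block = 40L, delay_s = delay_s,
                  n_blocks = n_blocks)
}

# protocol timing as acquired in vivo (setting II)
protocol_timing <- function(n_blocks = 5L) sequence_timing(n_blocks = n_blocks)

uniform_coil <- function(n) array(1 + 0i, dim = c(n, n, 1))

# cached small simulated acquisition shared by several tests
tiny_sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (is.null(tiny_sim_cache$sim)) {
    tim <- toy_timing(n_blocks = 3L)
    ph <- make_phantom(grid_size = 16L, seed = 7)
    traj <- make_golden_spiral(n_interleaves = 120, n_samples = 60,
                               grid_size = 16, n_turns = 3)
    maps <- make_coil_maps(16, 2)
    tiny_sim_cache$sim <- simulate_acquisition(ph, tim, traj, maps,
                                               spirals_per_frame = 5L,
                                               noise_sigma = 0, seed = 11)
  }
  tiny_sim_cache$sim
}
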