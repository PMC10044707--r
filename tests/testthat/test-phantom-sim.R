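sig_all <- c(torso = .2, liver = .3, myocardium = .4, blood = .5, vial = .6)

test_that("phantom construction is deterministic and physiologic", {
  p1 <- make_phantom(grid_size = 32, seed = 5)
  p2 <- make_phantom(grid_size = 32, seed = 5)
  expect_identical(p1$phase_offsets, p2$phase_offsets)
  expect_gte(p1$cardiac_freq_hz, 0.8); expect_lte(p1$cardiac_freq_hz, 2)
  expect_gte(p1$resp_freq_hz, 0.1); expect_lte(p1$resp_freq_hz, 0.6)
  # myocardial T1 near the in-vivo scale (~1050 ms)
  expect_equal(p1$tissue_params$myocardium[["t1_s"]], 1.05, tolerance = 0.1)
  expect_gt(p1$tissue_params$blood[["t1_s"]],
            p1$tissue_params$myocardium[["t1_s"]])
})

test_that("a motionless phantom renders identically at any time", {
  ph <- make_phantom(grid_size = 24, seed = 3, cardiac_amp = 0,
                     resp_amp_px = 0)
  base <- render_frame(ph, 0, sig_all)
  set.seed(1)
  for (t in runif(10, 0, 30))
    expect_equal(render_frame(ph, t, sig_all), base, tolerance = 1e-12)
})

test_that("zero signals render a zero image and unknown labels error", {
  ph <- make_phantom(grid_size = 24, seed = 3)
  zero <- sig_all * 0
  expect_equal(max(Mod(render_frame(ph, 1.23, zero))), 0)
  expect_error(render_frame(ph, 0, c(torso = 1)), "unknown label")
})

test_that("pure respiratory translation is shift-equivariant", {
  ph <- make_phantom(grid_size = 32, seed = 3, cardiac_amp = 0,
                     resp_amp_px = 4)
  ph$phase_offsets <- c(0, 0)
  base <- render_frame(ph, 0, sig_all)            # resp shift = 0
  tq <- 1 / (4 * ph$resp_freq_hz)                 # quarter period: shift = +4
  shifted <- render_frame(ph, tq, sig_all)
  expect_gt(max(Mod(shifted - base)), 0.01)       # the heart actually moved
  # oracle: re-render with the moving regions displaced by exactly +4 px
  ph4 <- ph; ph4$resp_amp_px <- 0
  ph4$regions <- lapply(ph4$regions, function(r) {
    if (isTRUE(r$resp)) r$center <- r$center + c(0, 4)
    r
  })
  expect_equal(shifted, render_frame(ph4, 0, sig_all), tolerance = 1e-10)
})

test_that("blood nulls at its ideal inversion time (black-blood contrast)", {
  tim <- sequence_timing(tr_s = 0.002, flip_rad = 1e-6,
                         n_readouts_per_block = 1200L, n_blocks = 1L)
  fp <- simulate_ir_spgr(1.6, 1, tim)
  null_t <- 1.6 * log(2)
  idx <- which.min(abs(fp$readout_times_s - null_t))
  blood_sig <- fp$mz[idx]        # flip -> 0 limit: use Mz itself
  ph <- make_phantom(grid_size = 24, seed = 3)
  img <- render_frame(ph, 0, c(torso = .2, liver = .2, myocardium = .3,
                               blood = blood_sig, vial = .2))
  maps <- phantom_parameter_maps(ph, 0)
  blood_px <- Mod(img)[maps$label == "blood"]
  myo_px <- Mod(img)[maps$label == "myocardium"]
  expect_lt(median(blood_px), 0.05 * median(myo_px))
})

test_that("acquisition produces the documented frame structure", {
  sim <- tiny_sim()
  k <- sim$kframes
  n_frames <- k$timing$n_readouts_per_block * k$timing$n_blocks / 5
  expect_length(k$frames, n_frames)
  expect_equal(sum(k$schedule$discard),
               k$timing$n_readouts_per_block / 5)
  expect_equal(dim(k$frames[[1]]), c(2L, 5L * 60L))
  expect_true(all(diff(k$schedule$t_abs_s) > 0))
})

test_that("default protocol yields 800 frames with block 1 flagged", {
  sched <- frame_schedule(protocol_timing(), 5L)
  expect_equal(nrow(sched), 800L)
  expect_equal(sum(sched$discard), 160L)
  expect_equal(sum(sched$block_index == 1), 160L)
})

# static phantom sampled with full-length (800-readout) blocks: the
# magnetization is periodic from block 2 on, so steady-state blocks repeat
periodic_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tim <- sequence_timing(n_blocks = 3L)
      # a truly static phantom also has no inflow (no motion, no flow)
      ph <- make_phantom(grid_size = 16, seed = 7, cardiac_amp = 0,
                         resp_amp_px = 0, inflow_frac = 0)
      # one block's worth of interleaves: the golden-angle pattern then
      # wraps identically in every block
      traj <- make_golden_spiral(800, 50, 16, 3)
      cache <<- simulate_acquisition(ph, tim, traj, uniform_coil(16), 5L,
                                     0, 1)
    }
    cache
  }
})

test_that("noiseless static frames repeat with the block period", {
  sim <- periodic_sim()
  fpb <- 160L                                  # frames per block
  for (j in c(1, 80, 160)) {
    a <- sim$kframes$frames[[fpb + j]]         # block 2
    b <- sim$kframes$frames[[2 * fpb + j]]     # block 3
    expect_lt(max(Mod(a - b)) / max(Mod(a)), 1e-6)
  }
})

test_that("doubling the noise doubles the residual standard deviation", {
  tim <- sequence_timing(n_blocks = 1L)      # 800 spirals: >= 1e5 samples
  ph <- make_phantom(grid_size = 16, seed = 7)
  traj <- make_golden_spiral(800, 60, 16, 3)
  maps <- make_coil_maps(16, 2)
  s0 <- simulate_acquisition(ph, tim, traj, maps, 5L, 0, seed = 3)
  s1 <- simulate_acquisition(ph, tim, traj, maps, 5L, 0.5, seed = 3)
  s2 <- simulate_acquisition(ph, tim, traj, maps, 5L, 1.0, seed = 3)
  res_of <- function(s) unlist(lapply(seq_along(s0$kframes$frames), function(f)
    c(Re(s$kframes$frames[[f]] - s0$kframes$frames[[f]]),
      Im(s$kframes$frames[[f]] - s0$kframes$frames[[f]]))))
  r1 <- sd(res_of(s1)); r2 <- sd(res_of(s2))
  expect_gt(length(res_of(s1)), 1e5)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("acquisition is deterministic under a fixed seed", {
  tim <- toy_timing(n_blocks = 1L)
  ph <- make_phantom(grid_size = 16, seed = 7)
  traj <- make_golden_spiral(40, 60, 16, 3)
  maps <- make_coil_maps(16, 2)
  a <- simulate_acquisition(ph, tim, traj, maps, 5L, 0.3, seed = 9)
  b <- simulate_acquisition(ph, tim, traj, maps, 5L, 0.3, seed = 9)
  expect_identical(a$kframes$frames, b$kframes$frames)
  expect_identical(a$truth$cardiac_signal, b$truth$cardiac_signal)
})

test_that("navigator of a static phantom is the DC image sum", {
  # n_center_samples = 1, single flat coil, static phantom: the navigator is
  # the k = 0 sample, i.e. the spatial sum of the image at that readout
  tim <- toy_timing(n_blocks = 2L)
  ph <- make_phantom(grid_size = 16, seed = 7, cardiac_amp = 0,
                     resp_amp_px = 0, inflow_frac = 0)
  traj <- make_golden_spiral(80, 50, 16, 3)
  sim <- simulate_acquisition(ph, tim, traj, uniform_coil(16), 5L, 0, 1)
  nav <- extract_navigators(sim$kframes, 1L)
  raw <- attr(nav, "raw")
  # oracle: frame-mean of the rendered image sums over the frame's readouts
  labs <- c("torso", "liver", "myocardium", "blood", "vial")
  fps <- lapply(labs, function(l) {
    pr <- ph$tissue_params[[l]]
    simulate_ir_spgr(pr[["t1_s"]], pr[["m0"]], tim)$signal
  })
  f <- 10L
  sp <- sim$kframes$schedule$spiral_indices[[f]]
  dc <- mean(sapply(sp, function(s) {
    sig <- sapply(fps, `[`, s); names(sig) <- labs
    sum(render_frame(ph, 0, sig))
  }))
  expect_equal(raw[f, 1], dc, tolerance = 1e-10)
})

test_that("static navigators depend only on the within-block position", {
  sim <- periodic_sim()
  raw <- attr(extract_navigators(sim$kframes, 1L), "raw")
  fpb <- 160L
  # steady-state blocks give identical navigator TI profiles
  expect_equal(Mod(raw[(fpb + 1):(2 * fpb), 1]),
               Mod(raw[(2 * fpb + 1):(3 * fpb), 1]), tolerance = 1e-6)
  # and the magnitude dips near the tissue null TIs (low navigator signal
  # when myocardium/blood are nulled)
  prof <- Mod(raw[(fpb + 1):(2 * fpb), 1])
  expect_lt(min(prof), 0.2 * max(prof))
})

test_that("dataset container round-trips", {
  sim <- tiny_sim()
  path <- withr::local_tempdir()
  save_dataset(sim, file.path(path, "ds"))
  ds <- load_dataset(file.path(path, "ds"))
  expect_equal(ds$kframes$frames, sim$kframes$frames)
  expect_equal(ds$truth$cardiac_signal, sim$truth$cardiac_signal)
  expect_equal(ds$kframes$schedule$ti_s, sim$kframes$schedule$ti_s)
})
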