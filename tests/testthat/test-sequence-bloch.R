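test_that("protocol timing reproduces the printed sequence arithmetic", {
  tim <- protocol_timing()
  expect_equal(block_period(tim), 6.9)
  expect_equal(scan_duration(tim), 34)
  sched <- frame_schedule(tim, 5L)
  # 40 ms frame duration: consecutive same-block frames are 40 ms apart
  expect_equal(diff(sched$t_abs_s[1:2]), 0.040)
  fp <- simulate_ir_spgr(1.0, 1, tim)
  # readout times of successive blocks are separated by the 6.9 s period
  expect_equal(fp$readout_times_s[801] - fp$readout_times_s[1], 6.9)
})

test_that("within-block magnetization follows the closed-form geometric recursion", {
  tim <- protocol_timing(n_blocks = 2L)
  for (t1 in c(0.3, 1.0, 2.2)) {
    fp <- simulate_ir_spgr(t1, 1, tim)
    e1 <- exp(-tim$tr_s / t1)
    ca <- cos(tim$flip_rad)
    a_fix <- (1 - e1) / (1 - ca * e1)
    n <- seq_len(tim$n_readouts_per_block)
    mz1 <- 1 + (-1 - 1) * e1                       # readout 1 after inversion
    closed <- a_fix + (ca * e1)^(n - 1) * (mz1 - a_fix)
    expect_lt(max(abs(closed - fp$mz[n])), 1e-10)
  }
})

test_that("zero flip gives zero signal and the ideal inversion null point", {
  tim <- sequence_timing(tr_s = 0.002, flip_rad = 1e-12,
                         n_readouts_per_block = 400L, delay_s = 0.1,
                         n_blocks = 1L)
  fp <- simulate_ir_spgr(1.0, 1, tim)
  expect_lt(max(abs(fp$signal)), 1e-10)
  tr <- ir_mz_trace(1.0, 1, tim, dt_s = 1e-4)
  crossing <- tr$t_s[which(diff(sign(tr$mz)) > 0)[1]]
  expect_equal(crossing, log(2), tolerance = 1e-3)
})

test_that("small-flip dense trace converges to analytic inversion recovery", {
  tim <- sequence_timing(flip_rad = 0.1 * pi / 180, n_blocks = 1L)
  tr <- ir_mz_trace(1.0, 1, tim, dt_s = 1e-3)
  analytic <- 1 - 2 * exp(-tr$t_s / 1.0)
  expect_lt(max(abs(tr$mz - analytic)), 1e-3)
})

test_that("signal never exceeds m0 sin(flip) over random draws", {
  set.seed(42)
  for (i in 1:20) {
    tim <- sequence_timing(flip_rad = runif(1, 0.01, pi / 2),
                           n_readouts_per_block = 50L, n_blocks = 3L,
                           delay_s = runif(1, 0, 1))
    t1 <- runif(1, 0.05, 3)
    m0 <- runif(1, 0.5, 2)
    fp <- simulate_ir_spgr(t1, m0, tim)
    expect_lte(max(abs(fp$signal)), m0 * sin(tim$flip_rad) + 1e-12)
  }
})

test_that("blocks reach a periodic steady state after the first", {
  # 800 excitations saturate Mz to its fixed point within each block, so
  # blocks 2..n are identical to numerical precision
  tim <- sequence_timing(n_blocks = 6L)
  for (t1 in c(0.5, 1.5, 2.5)) {
    fp <- simulate_ir_spgr(t1, 1, tim)
    nr <- tim$n_readouts_per_block
    blocks <- matrix(fp$signal, nrow = nr)
    rel <- max(abs(blocks[, 3:6] - blocks[, 2])) / max(abs(blocks[, 2]))
    expect_lt(rel, 1e-6)
  }
})

test_that("invalid Bloch inputs raise domain errors", {
  tim <- toy_timing()
  expect_error(simulate_ir_spgr(-1, 1, tim), "t1_s")
  expect_error(simulate_ir_spgr(1, 0, tim), "m0")
  expect_error(build_dictionary(c(1, 0.5), tim), "increasing")
  expect_error(build_dictionary(numeric(0), tim), "empty")
})

test_that("frame schedule implements the midpoint TI convention", {
  tim <- protocol_timing()
  sched <- frame_schedule(tim, 5L)
  expect_equal(nrow(sched), 800L)
  expect_equal(sum(sched$discard), 160L)
  expect_equal(sched$ti_s[1], 2.5 * tim$tr_s)         # 20 ms
  # strictly increasing timestamps; block-gap spacing = frame + delay
  expect_true(all(diff(sched$t_abs_s) > 0))
  gaps <- diff(sched$t_abs_s)
  boundary <- which(diff(sched$block_index) == 1)
  expect_equal(unique(round(gaps[boundary], 12)), 0.04 + tim$delay_s)
  expect_equal(unique(round(gaps[-boundary], 12)), 0.04)
  expect_error(frame_schedule(tim, 7L), "divide")
})

test_that("inversion signal is a sawtooth in (0, 1] resetting at blocks", {
  tim <- protocol_timing()
  sched <- frame_schedule(tim, 5L)
  p <- inversion_signal(sched)
  span <- tim$n_readouts_per_block * tim$tr_s
  expect_equal(p[1], 0.020 / span)
  expect_equal(p[160], (span - 0.020) / span)
  expect_true(all(p > 0 & p <= 1))
  within_block <- diff(sched$block_index) == 0
  expect_true(all(diff(p)[within_block] > 0))
  expect_true(all(diff(p)[!within_block] < 0))
})

test_that("dictionary self-match recovers the generating T1 exactly", {
  tim <- toy_timing()
  dict <- build_dictionary(c(0.5, 1.0, 1.5), tim, spirals_per_frame = 5L)
  m <- match_fingerprints(complex(real = dict$atoms[2, ]), dict$atoms,
                          dict$t1_grid_s, dict$timepoint_ti_s)
  expect_equal(m$t1_s[1], 1.0)
  expect_equal(m$match_corr[1], 1, tolerance = 1e-12)
})

test_that("default dictionary covers the reference phantom and blood range", {
  grid <- formals(build_dictionary)$t1_grid_s
  grid <- eval(grid)
  expect_lte(min(grid), 0.022)   # shortest reference sample 21.94 ms
  expect_gte(max(grid), 2.0)     # blood up to ~2 s
})

test_that("early-TI atom values are monotone in T1 over 0.3-2.5 s", {
  tim <- protocol_timing()
  dict <- build_dictionary(seq(0.3, 2.5, by = 0.1), tim)
  # first frame of the steady-state block: shorter T1 recovers further in
  # the delay, is inverted more deeply, and reads more negative; the value
  # increases strictly with T1 (brute-force scan over every atom)
  expect_true(all(diff(dict$atoms[, 1]) > 0))
})

test_that("dictionary construction is bit-reproducible", {
  tim <- toy_timing()
  d1 <- build_dictionary(seq(0.1, 2, by = 0.1), tim)
  d2 <- build_dictionary(seq(0.1, 2, by = 0.1), tim)
  expect_identical(d1$atoms, d2$atoms)
})

test_that("dictionary round-trips through the directory container", {
  tim <- toy_timing()
  dict <- build_dictionary(seq(0.2, 1, by = 0.2), tim)
  path <- withr::local_tempdir()
  save_dictionary(dict, file.path(path, "dict"))
  d2 <- load_dictionary(file.path(path, "dict"))
  expect_equal(d2$atoms, dict$atoms)
  expect_equal(d2$t1_grid_s, dict$t1_grid_s)
  expect_equal(d2$timing$tr_s, tim$tr_s)
})
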