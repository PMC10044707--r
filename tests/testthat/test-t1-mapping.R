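protocol_dict <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_dictionary(seq(0.02, 2.5, by = 0.005),
                                 protocol_timing())
    cache
  }
})

test_that("noiseless atoms identify their own T1 for every grid entry", {
  tim <- toy_timing()
  dict <- build_dictionary(seq(0.1, 2.5, by = 0.1), tim)
  m <- match_fingerprints(dict$atoms + 0i, dict$atoms, dict$t1_grid_s,
                          dict$timepoint_ti_s)
  expect_equal(m$t1_s, dict$t1_grid_s)
  expect_equal(m$match_corr, rep(1, length(dict$t1_grid_s)), tolerance = 1e-12)
})

test_that("matching equals an exhaustive per-pixel scan on noisy data", {
  dict <- protocol_dict()
  set.seed(13)
  n_px <- 100
  idx_true <- sample(length(dict$t1_grid_s), n_px, replace = TRUE)
  S <- dict$atoms[idx_true, ] +
    matrix(rnorm(n_px * ncol(dict$atoms), 0, 0.005), n_px)
  phase <- runif(n_px, -pi, pi)
  Sc <- S * exp(1i * phase)
  m <- match_fingerprints(Sc, dict$atoms, dict$t1_grid_s,
                          dict$timepoint_ti_s)
  # oracle: explicit loop over every atom per pixel
  for (i in seq_len(n_px)) {
    s <- Re(Sc[i, ] * exp(-1i * Arg(Sc[i, which.max(dict$timepoint_ti_s)])))
    scores <- abs(dict$atoms %*% s) /
      (sqrt(sum(s^2)) * sqrt(rowSums(dict$atoms^2)))
    expect_equal(m$t1_s[i], dict$t1_grid_s[which.max(scores)])
  }
})

test_that("14 tissues spanning 0.02-2 s are recovered at 30 dB SNR", {
  dict <- protocol_dict()
  t1_true <- exp(seq(log(0.022), log(2.0), length.out = 14))
  tim <- protocol_timing()
  spf <- 5L
  keep <- !frame_schedule(tim, spf)$discard
  set.seed(14)
  errs <- vapply(t1_true, function(t1) {
    fp <- simulate_ir_spgr(t1, 1, tim)
    fr <- as.numeric(tapply(fp$signal,
                            rep(seq_len(800 * tim$n_blocks / spf), each = spf),
                            mean))
    s <- fr[keep]
    snr_sigma <- sqrt(mean(s^2)) / 10^(30 / 20)
    reps <- 25
    S <- matrix(rep(s, reps), reps, byrow = TRUE) +
      matrix(rnorm(reps * length(s), 0, snr_sigma), reps)
    tis <- rep(dict$timepoint_ti_s, tim$n_blocks - 1L)
    atoms <- dictionary_at_tis(dict, tis)
    m <- match_fingerprints(S + 0i, atoms, dict$t1_grid_s, tis)
    abs(median(m$t1_s) - t1)
  }, 0)
  expect_lte(median(errs), 2 * 0.005)
})

test_that("matching tolerates well-spread TI subsets", {
  # 32 evenly spread TIs out of 160 keep median recovery within 2 grid
  # steps at 30 dB across the physiological range; much smaller subsets
  # are noise-limited at the long-T1 end, where the saturated signal
  # carries little late-TI information
  dict <- protocol_dict()
  set.seed(15)
  t1_true <- c(0.1, 0.3, 0.8, 1.2, 1.8)
  sub <- round(seq(1, length(dict$timepoint_ti_s), length.out = 32))
  tis <- dict$timepoint_ti_s[sub]
  atoms <- dict$atoms[, sub]
  for (t1 in t1_true) {
    row <- which.min(abs(dict$t1_grid_s - t1))
    s <- atoms[row, ]
    sigma <- sqrt(mean(s^2)) / 10^(30 / 20)
    reps <- 51
    S <- matrix(rep(s, reps), reps, byrow = TRUE) +
      matrix(rnorm(reps * length(s), 0, sigma), reps)
    m <- match_fingerprints(S + 0i, atoms, dict$t1_grid_s, tis)
    expect_lte(abs(median(m$t1_s) - t1), 2 * 0.005 + 1e-9)
  }
})

test_that("degenerate matching inputs are handled", {
  dict <- protocol_dict()
  expect_error(match_fingerprints(matrix(0i, 2, 3), dict$atoms[, 1:3],
                                  dict$t1_grid_s, dict$timepoint_ti_s[1:3]),
               "at least 4")
  # all-zero pixel is masked, not an error
  m <- match_fingerprints(matrix(0i, 1, ncol(dict$atoms)), dict$atoms,
                          dict$t1_grid_s, dict$timepoint_ti_s)
  expect_false(m$mask[1])
  expect_true(is.na(m$t1_s[1]))
})

test_that("phase-bin selection widens monotonically and errors when empty", {
  track <- list(z_card = seq(-1, 1, length.out = 50),
                z_resp = rep(c(-0.5, 0.5), 25),
                p = seq(0.02, 1, length.out = 50))
  widths <- seq(0.05, 1.5, length.out = 10)
  counts <- vapply(widths, function(w)
    length(phase_bin(track, 0, 0, c(w, w))$selected), 0L)
  expect_true(all(diff(counts) >= 0))
  empty <- phase_bin(track, 10, 10, c(0, 0))
  expect_length(empty$selected, 0)
  dict <- protocol_dict()
  m <- build_generator(generator_config(grid_size = 16L), seed = 1)
  expect_error(t1_map_binned(m, track, empty, dict), "too narrow")
})

test_that("generative mapping rejects degenerate TI grids", {
  dict <- protocol_dict()
  m <- build_generator(generator_config(grid_size = 16L), seed = 1)
  expect_error(t1_map_generative(m, c(0, 0), ti_grid = 0.5, dictionary = dict),
               "at least 4")
  expect_error(t1_map_generative(m, c(0, 0), ti_grid = numeric(0),
                                 dictionary = dict), "empty")
})

test_that("agreement statistics match hand-computed ANOVA values", {
  x <- c(1, 2, 3)
  expect_equal(agreement_stats(x, x), list(r_squared = 1, icc_a1 = 1))
  # constant offset: perfect correlation, imperfect absolute agreement
  off <- agreement_stats(x + 2, x)
  expect_equal(off$r_squared, 1)
  expect_lt(off$icc_a1, 1)
  # fixed 6-pair toy vs explicit mean-squares computation
  est <- c(21.9, 43.8, 150.2, 400.0, 995.1, 1510.7)
  ref <- c(22.5, 41.0, 155.0, 390.5, 1010.0, 1480.0)
  n <- 6; k <- 2
  dat <- cbind(est, ref)
  rm_ <- rowMeans(dat); cm_ <- colMeans(dat); g <- mean(dat)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm_ - g)^2) / (k - 1)
  mse <- sum((dat - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g)^2) /
    ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  out <- agreement_stats(est, ref)
  expect_equal(out$icc_a1, icc_hand, tolerance = 1e-10)
  expect_equal(out$r_squared, cor(est, ref)^2, tolerance = 1e-10)
  expect_error(agreement_stats(rep(1, 5), 1:5), "variance")
})
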