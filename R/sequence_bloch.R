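#' Sequence timing for the inversion-recovery spoiled-GRE acquisition
#'
#' Describes one slice of the free-breathing protocol: repeated inversion
#' blocks, each consisting of an adiabatic inversion pulse followed by
#' `n_readouts_per_block` spiral GRE readouts at repetition time `tr_s`, and a
#' trailing delay `delay_s` for longitudinal magnetization recovery. Defaults
#' correspond to the 14-degree flip / 500 ms delay protocol variant used for
#' in-vivo imaging (TR 8 ms, 800 interleaves per block, 5 blocks), giving a
#' 6.9 s inversion period and a 34 s single-slice scan.
#'
#' @param tr_s repetition time in seconds.
#' @param flip_rad excitation flip angle in radians (0, pi/2].
#' @param n_readouts_per_block spiral interleaves per inversion block.
#' @param delay_s post-block recovery delay in seconds.
#' @param n_blocks number of inversion blocks.
#' @param inv_efficiency inversion efficiency in [0, 1]; the pulse maps
#'   `Mz -> -inv_efficiency * Mz`.
#' @param readout_dur_s duration of one spiral readout in seconds.
#' @param golden_angle_deg interleave-to-interleave rotation increment.
#' @return an object of class `sequence_timing`.
#' @export
sequence_timing <- function(tr_s = 0.008,
                            flip_rad = 14 * pi / 180,
                            n_readouts_per_block = 800L,
                            delay_s = 0.5,
                            n_blocks = 5L,
                            inv_efficiency = 1.0,
                            readout_dur_s = 0.00274,
                            golden_angle_deg = 137.5) {
  stopifnot(tr_s > 0, flip_rad > 0, flip_rad <= pi / 2,
            n_readouts_per_block >= 1, delay_s >= 0, n_blocks >= 1,
            inv_efficiency >= 0, inv_efficiency <= 1)
  structure(list(
    tr_s = tr_s, flip_rad = flip_rad,
    n_readouts_per_block = as.integer(n_readouts_per_block),
    delay_s = delay_s, n_blocks = as.integer(n_blocks),
    inv_efficiency = inv_efficiency,
    readout_dur_s = readout_dur_s,
    golden_angle_deg = golden_angle_deg
  ), class = "sequence_timing")
}

#' @export
print.sequence_timing <- function(x, ...) {
  cat("IR spoiled-GRE timing:\n")
  cat(sprintf("  TR %.3f ms, flip %.1f deg, %d readouts/block, delay %.0f ms, %d blocks\n",
              x$tr_s * 1000, x$flip_rad * 180 / pi, x$n_readouts_per_block,
              x$delay_s * 1000, x$n_blocks))
  cat(sprintf("  inversion period %.3f s, scan duration %.3f s\n",
              block_period(x), scan_duration(x)))
  invisible(x)
}

#' Inversion-block period (seconds)
#'
#' Time between successive inversion pulses: acquisition span plus delay.
#' @param timing a [sequence_timing()] object.
#' @export
block_period <- function(timing) {
  timing$n_readouts_per_block * timing$tr_s + timing$delay_s
}

#' Single-slice scan duration (seconds)
#'
#' Time from the first inversion pulse to the final readout: the trailing
#' recovery delay of the last block is not part of the scan.
#' @param timing a [sequence_timing()] object.
#' @export
scan_duration <- function(timing) {
  (timing$n_blocks - 1) * block_period(timing) +
    timing$n_readouts_per_block * timing$tr_s
}

#' Simulate the longitudinal magnetization fingerprint for one T1
#'
#' Discrete Bloch recursion for the inversion-recovery spoiled-GRE sequence
#' under perfect spoiling (only Mz is tracked between excitations). At each
#' block start the inversion pulse maps `Mz -> -inv_efficiency * Mz`; the
#' first readout occurs one TR later. For readout n the magnetization relaxes
#' over TR, the signal `Mz * sin(flip)` is recorded, and the excitation
#' leaves `Mz * cos(flip)`. After the block the magnetization relaxes over
#' the recovery delay. Magnetization starts at equilibrium `m0`; all blocks
#' are emitted (callers discard block 1 to avoid the initial transient).
#'
#' @param t1_s longitudinal relaxation time in seconds (> 0).
#' @param m0 equilibrium magnetization (> 0).
#' @param timing a [sequence_timing()] object.
#' @return a `fingerprint` list with `signal` (signed `Mz*sin(flip)` per
#'   readout), `mz` (pre-excitation Mz per readout), `readout_times_s`,
#'   `block_index` per readout, and the inputs.
#' @export
simulate_ir_spgr <- function(t1_s, m0, timing) {
  if (!is.numeric(t1_s) || t1_s <= 0) stop("t1_s must be > 0")
  if (!is.numeric(m0) || m0 <= 0) stop("m0 must be > 0")
  tr <- timing$tr_s
  nr <- timing$n_readouts_per_block
  nb <- timing$n_blocks
  ca <- cos(timing$flip_rad)
  sa <- sin(timing$flip_rad)
  e1 <- exp(-tr / t1_s)
  ed <- exp(-timing$delay_s / t1_s)
  period <- block_period(timing)

  n_tot <- nr * nb
  signal <- numeric(n_tot)
  mzs <- numeric(n_tot)
  times <- numeric(n_tot)
  block <- integer(n_tot)

  mz <- m0
  idx <- 1L
  for (b in seq_len(nb)) {
    mz <- -timing$inv_efficiency * mz
    t0 <- (b - 1) * period
    for (n in seq_len(nr)) {
      mz <- m0 + (mz - m0) * e1      # relaxation over TR before the readout
      mzs[idx] <- mz
      signal[idx] <- mz * sa
      times[idx] <- t0 + n * tr
      block[idx] <- b
      mz <- mz * ca                  # excitation pulse
      idx <- idx + 1L
    }
    mz <- m0 + (mz - m0) * ed        # recovery delay
  }
  structure(list(t1_s = t1_s, m0 = m0, signal = signal, mz = mzs,
                 readout_times_s = times, block_index = block,
                 timing = timing),
            class = "fingerprint")
}

#' Fingerprint of spins that see the inversions but not the excitations
#'
#' Longitudinal magnetization of out-of-slice spins: the adiabatic
#' inversion is non-selective, but the slice-selective excitation does not
#' saturate them, so they follow free inversion recovery between blocks.
#' When such spins flow into the slice (blood inflow) they contribute
#' `Mz * sin(flip)` at the readout. This is the bright-blood mechanism of
#' long-TR spoiled-GRE imaging; the unsaturated curve nulls at
#' `T1 * ln 2` after inversion (for full recovery), giving the black-blood
#' contrast near that TI.
#'
#' @inheritParams simulate_ir_spgr
#' @return a `fingerprint` (same layout as [simulate_ir_spgr()]).
#' @export
simulate_ir_free <- function(t1_s, m0, timing) {
  tim2 <- timing
  tim2$flip_rad <- 1e-12          # evolution without saturation
  fp <- simulate_ir_spgr(t1_s, m0, tim2)
  # readout amplitude still uses the nominal flip of the sequence
  fp$signal <- fp$mz * sin(timing$flip_rad)
  fp$timing <- timing
  fp
}

#' Dense Mz relaxation trace within the first inversion block
#'
#' Evaluates the longitudinal magnetization on a fine time grid after the
#' first inversion, accounting for the excitation pulses at every TR.
#' Mainly a diagnostic for inspecting null points and small-flip limits.
#'
#' @inheritParams simulate_ir_spgr
#' @param dt_s time step of the returned trace.
#' @return data.frame with columns `t_s` (time since inversion) and `mz`.
#' @export
ir_mz_trace <- function(t1_s, m0, timing, dt_s = 1e-3) {
  stopifnot(t1_s > 0, m0 > 0, dt_s > 0)
  tr <- timing$tr_s
  ca <- cos(timing$flip_rad)
  t_end <- timing$n_readouts_per_block * tr
  tt <- seq(0, t_end, by = dt_s)
  mz_pulse <- -timing$inv_efficiency * m0  # Mz right after inversion (t = 0)
  t_pulse <- 0
  out <- numeric(length(tt))
  j <- 1L
  n_pulses <- timing$n_readouts_per_block
  pulse_times <- (1:n_pulses) * tr
  k <- 1L
  for (i in seq_along(tt)) {
    while (k <= n_pulses && pulse_times[k] <= tt[i]) {
      # advance the state through the excitation at pulse_times[k]
      mz_pulse <- m0 + (mz_pulse - m0) * exp(-(pulse_times[k] - t_pulse) / t1_s)
      mz_pulse <- mz_pulse * ca
      t_pulse <- pulse_times[k]
      k <- k + 1L
    }
    out[i] <- m0 + (mz_pulse - m0) * exp(-(tt[i] - t_pulse) / t1_s)
  }
  data.frame(t_s = tt, mz = out)
}

#' Frame binning schedule for the spiral acquisition
#'
#' Groups consecutive spiral readouts into frames of `spirals_per_frame`
#' (default 5, i.e. 40 ms temporal resolution at TR 8 ms). The inversion
#' time `ti_s` of a frame is measured from its block's inversion pulse to
#' the frame's temporal midpoint; frames of block 1 are flagged for
#' discarding so the initial magnetization transient is omitted.
#'
#' @param timing a [sequence_timing()] object.
#' @param spirals_per_frame readouts binned per frame; must divide
#'   `n_readouts_per_block`.
#' @return data.frame with columns `frame_index`, `block_index`, `ti_s`,
#'   `t_abs_s`, `discard`, and list-column `spiral_indices` (1-based global
#'   readout indices).
#' @export
frame_schedule <- function(timing, spirals_per_frame = 5L) {
  spf <- as.integer(spirals_per_frame)
  nr <- timing$n_readouts_per_block
  if (spf < 1L || nr %% spf != 0L)
    stop("spirals_per_frame must divide n_readouts_per_block")
  fpb <- nr %/% spf                       # frames per block
  period <- block_period(timing)
  frame_dur <- spf * timing$tr_s
  n_frames <- fpb * timing$n_blocks

  frame_index <- seq_len(n_frames)
  block_index <- rep(seq_len(timing$n_blocks), each = fpb)
  within <- rep(seq_len(fpb), times = timing$n_blocks)
  ti_s <- (within - 0.5) * frame_dur
  t_abs_s <- (block_index - 1) * period + ti_s
  spiral_indices <- lapply(frame_index, function(f) ((f - 1L) * spf + 1L):(f * spf))
  out <- data.frame(frame_index = frame_index, block_index = block_index,
                    ti_s = ti_s, t_abs_s = t_abs_s,
                    discard = block_index == 1L)
  out$spiral_indices <- spiral_indices
  attr(out, "timing") <- timing
  attr(out, "spirals_per_frame") <- spf
  out
}

#' Inversion conditioning signal p_t
#'
#' Normalized inversion time fed to the networks as the contrast latent:
#' `p = ti / (n_readouts_per_block * tr)`, a sawtooth in (0, 1] that resets
#' at every inversion pulse. It is derived from the (known) pulse timing and
#' is held fixed during all training.
#'
#' @param schedule output of [frame_schedule()].
#' @return numeric vector, one value per frame.
#' @export
inversion_signal <- function(schedule) {
  timing <- attr(schedule, "timing")
  schedule$ti_s / (timing$n_readouts_per_block * timing$tr_s)
}

#' Build a Bloch fingerprint dictionary for T1 matching
#'
#' Simulates the sequence for each T1 on the grid and records, per frame of a
#' periodic steady-state block, the mean signed signal over the frame's
#' readouts (the quantity the reconstructed frame image encodes). The
#' steady-state profile is obtained by running the recursion for several
#' extra blocks and keeping the last, so the dictionary represents the
#' periodic regime rather than the approach to it; measured data retain their
#' small residual transients, as in acquisition. The default grid spans
#' 0.02-2.5 s in 5 ms steps, covering short phantom samples through blood.
#'
#' @param t1_grid_s strictly increasing T1 values (seconds, all > 0).
#' @param timing a [sequence_timing()] object.
#' @param m0 equilibrium magnetization used for simulation.
#' @param spirals_per_frame frame binning, as in [frame_schedule()].
#' @return a `fingerprint_dictionary`: `t1_grid_s`, `atoms` (n_t1 x
#'   n_frames_per_block matrix), `timepoint_ti_s` (frame-midpoint TIs), the
#'   timing and binning used.
#' @export
build_dictionary <- function(t1_grid_s = seq(0.02, 2.5, by = 0.005),
                             timing = sequence_timing(),
                             m0 = 1.0,
                             spirals_per_frame = 5L) {
  if (length(t1_grid_s) == 0) stop("empty T1 grid")
  if (any(t1_grid_s <= 0)) stop("T1 grid values must be > 0")
  if (length(t1_grid_s) > 1 && any(diff(t1_grid_s) <= 0))
    stop("T1 grid must be strictly increasing")
  spf <- as.integer(spirals_per_frame)
  nr <- timing$n_readouts_per_block
  if (nr %% spf != 0L) stop("spirals_per_frame must divide n_readouts_per_block")
  fpb <- nr %/% spf

  # run enough blocks that the kept (last) block is in the periodic regime
  n_settle <- max(timing$n_blocks, 8L)
  tim2 <- timing
  tim2$n_blocks <- n_settle
  keep <- ((n_settle - 1L) * nr + 1L):(n_settle * nr)
  frame_of <- rep(seq_len(fpb), each = spf)

  atoms <- matrix(0, nrow = length(t1_grid_s), ncol = fpb)
  for (i in seq_along(t1_grid_s)) {
    fp <- simulate_ir_spgr(t1_grid_s[i], m0, tim2)
    s <- fp$signal[keep]
    atoms[i, ] <- as.numeric(tapply(s, frame_of, mean))
  }
  ti <- (seq_len(fpb) - 0.5) * spf * timing$tr_s
  structure(list(t1_grid_s = t1_grid_s, atoms = atoms,
                 timepoint_ti_s = ti, timing = timing,
                 spirals_per_frame = spf),
            class = "fingerprint_dictionary")
}

#' Restrict dictionary atoms to a set of inversion times
#'
#' Returns the dictionary signal values at arbitrary TIs inside the block
#' acquisition span by linear interpolation of each atom's steady-state TI
#' profile. Used to form sub-dictionaries for retrospective binning and for
#' generative-mode matching.
#'
#' @param dictionary a [build_dictionary()] result.
#' @param ti_s inversion times (seconds) to sample at.
#' @return matrix n_t1 x length(ti_s).
#' @export
dictionary_at_tis <- function(dictionary, ti_s) {
  rng <- range(dictionary$timepoint_ti_s)
  ti_c <- pmin(pmax(ti_s, rng[1]), rng[2])
  t(apply(dictionary$atoms, 1, function(a)
    stats::approx(dictionary$timepoint_ti_s, a, xout = ti_c, rule = 2)$y))
}

#' Serialize a fingerprint dictionary to a directory container
#'
#' Writes `t1_grid_s`, `atoms` and `timepoint_ti_s` as RDS arrays plus a JSON
#' description of the sequence timing, so a dictionary can be rebuilt or
#' inspected without re-simulation.
#' @param dictionary a [build_dictionary()] result.
#' @param path directory to create.
#' @export
save_dictionary <- function(dictionary, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(dictionary$atoms, file.path(path, "atoms.rds"))
  saveRDS(dictionary$t1_grid_s, file.path(path, "t1_grid_s.rds"))
  saveRDS(dictionary$timepoint_ti_s, file.path(path, "timepoint_ti_s.rds"))
  meta <- unclass(dictionary$timing)
  meta$spirals_per_frame <- dictionary$spirals_per_frame
  jsonlite::write_json(meta, file.path(path, "timing.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "timing.json"), simplifyVector = TRUE)
  timing <- sequence_timing(tr_s = meta$tr_s, flip_rad = meta$flip_rad,
                            n_readouts_per_block = meta$n_readouts_per_block,
                            delay_s = meta$delay_s, n_blocks = meta$n_blocks,
                            inv_efficiency = meta$inv_efficiency,
                            readout_dur_s = meta$readout_dur_s,
                            golden_angle_deg = meta$golden_angle_deg)
  structure(list(t1_grid_s = readRDS(file.path(path, "t1_grid_s.rds")),
                 atoms = readRDS(file.path(path, "atoms.rds")),
                 timepoint_ti_s = readRDS(file.path(path, "timepoint_ti_s.rds")),
                 timing = timing,
                 spirals_per_frame = meta$spirals_per_frame),
            class = "fingerprint_dictionary")
}
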