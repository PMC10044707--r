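#' Beating, breathing numerical phantom
#'
#' A 2D short-axis-like phantom made of anti-aliased ellipses: a static
#' torso, a liver that translates with respiration, a myocardial annulus and
#' blood pool that contract quasi-periodically with the cardiac cycle and
#' translate with respiration, and a static reference vial. Tissue T1 values
#' follow in-vivo 3T scales (myocardium near 1.05 s, blood 1.6 s). Cardiac
#' contraction uses a sharpened raised-cosine waveform to mimic the
#' systole/diastole asymmetry; respiration is a rigid translation.
#'
#' @param grid_size image matrix size.
#' @param cardiac_freq_hz heart rate in Hz (physiological band 0.8-2 Hz).
#' @param resp_freq_hz respiratory rate in Hz (band 0.1-0.6 Hz).
#' @param cardiac_amp fractional contraction of the blood pool at peak
#'   systole (the myocardial outer wall moves with 40% of this amplitude,
#'   so the wall thickens during systole).
#' @param resp_amp_px respiratory translation amplitude in pixels.
#' @param sharpness exponent sharpening the contraction waveform.
#' @param inflow_frac peak fraction of the blood pool replaced by fresh,
#'   unsaturated spins. The slice-selective excitation does not saturate
#'   blood outside the slice, so inflowing blood is much brighter than the
#'   saturated in-slice pool and its supply varies with the cardiac cycle;
#'   this is the dominant cardiac signature in the k-space center for
#'   long-TR spoiled-GRE imaging. Set 0 for a flow-free phantom.
#' @param tissue_params named list of `c(t1_s, m0)` per label; defaults
#'   cover torso, liver, myocardium, blood and a short-T1 vial.
#' @param seed integer seed fixing the motion phase offsets.
#' @return a `dynamic_phantom` object.
#' @export
make_phantom <- function(grid_size = 64L,
                         cardiac_freq_hz = 1.2,
                         resp_freq_hz = 0.25,
                         cardiac_amp = 0.15,
                         resp_amp_px = NULL,
                         sharpness = 2,
                         inflow_frac = 0.6,
                         tissue_params = NULL,
                         seed = 1L) {
  stopifnot(cardiac_freq_hz >= 0, resp_freq_hz >= 0, cardiac_amp >= 0)
  n <- as.integer(grid_size)
  if (is.null(resp_amp_px)) resp_amp_px <- max(2, 0.03 * n)
  if (is.null(tissue_params))
    tissue_params <- list(
      torso      = c(t1_s = 0.50, m0 = 0.85),
      liver      = c(t1_s = 0.80, m0 = 0.95),
      myocardium = c(t1_s = 1.05, m0 = 1.00),
      blood      = c(t1_s = 1.60, m0 = 1.00),
      vial       = c(t1_s = 0.30, m0 = 1.00))
  set.seed(seed)
  phase_offsets <- stats::runif(2, 0, 2 * pi)

  # geometry in units of the grid (centers relative to image center, px)
  u <- n / 64  # scale relative to the reference 64 grid
  regions <- list(
    list(label = "torso", center = c(0, 0), axes = c(28, 24) * u,
         rot = 0, cardiac = FALSE, resp = FALSE),
    list(label = "liver", center = c(-12, -10) * u, axes = c(9, 7) * u,
         rot = 0.4, cardiac = FALSE, resp = TRUE),
    list(label = "vial", center = c(20, -14) * u, axes = c(3, 3) * u,
         rot = 0, cardiac = FALSE, resp = FALSE),
    list(label = "myocardium", center = c(2, 6) * u, axes = c(12, 11) * u,
         rot = 0.2, cardiac = TRUE, resp = TRUE, wall_factor = 0.4),
    list(label = "blood", center = c(2, 6) * u, axes = c(7.5, 6.8) * u,
         rot = 0.2, cardiac = TRUE, resp = TRUE, wall_factor = 1))

  # fixed smooth phase map so simulated data are genuinely complex
  x <- (seq_len(n) - (n / 2 + 1)) / n
  X <- matrix(x, n, n); Y <- t(X)
  phase_map <- exp(1i * pi * (0.5 * X + 0.3 * Y + 0.6 * X * Y))

  structure(list(grid_size = n, regions = regions,
                 tissue_params = tissue_params,
                 cardiac_freq_hz = cardiac_freq_hz,
                 resp_freq_hz = resp_freq_hz,
                 cardiac_amp = cardiac_amp, resp_amp_px = resp_amp_px,
                 sharpness = sharpness, inflow_frac = inflow_frac,
                 phase_offsets = phase_offsets,
                 phase_map = phase_map, seed = seed),
            class = "dynamic_phantom")
}

#' Motion state of the phantom at a time point
#'
#' @param phantom a [make_phantom()] object.
#' @param t_abs_s absolute time in seconds.
#' @return list with `contraction` (0 = diastole, 1 = peak systole),
#'   `resp_shift_px`, and the raw cardiac/respiratory phase angles.
#' @export
phantom_motion_state <- function(phantom, t_abs_s) {
  phc <- 2 * pi * phantom$cardiac_freq_hz * t_abs_s + phantom$phase_offsets[1]
  phr <- 2 * pi * phantom$resp_freq_hz * t_abs_s + phantom$phase_offsets[2]
  contraction <- (0.5 + 0.5 * cos(phc))^phantom$sharpness
  list(contraction = contraction,
       resp_shift_px = phantom$resp_amp_px * sin(phr),
       cardiac_phase = phc, resp_phase = phr)
}

# anti-aliased ellipse coverage over the pixel grid; centers in px relative
# to the image center (first index = x/row, second = y/col)
ellipse_alpha <- function(n, center, axes, rot) {
  g <- seq_len(n) - (n / 2 + 1)
  X <- matrix(g, n, n) - center[1]
  Y <- t(matrix(g, n, n)) - center[2]
  cr <- cos(rot); sr <- sin(rot)
  U <- (X * cr + Y * sr) / axes[1]
  V <- (-X * sr + Y * cr) / axes[2]
  d <- sqrt(U^2 + V^2)
  eps <- 1 / min(axes)               # about one pixel of edge softness
  pmin(1, pmax(0, (1 - d) / eps + 0.5))
}

region_geometry <- function(phantom, region, state) {
  center <- region$center
  axes <- region$axes
  if (isTRUE(region$resp)) center <- center + c(0, state$resp_shift_px)
  if (isTRUE(region$cardiac)) {
    wf <- if (is.null(region$wall_factor)) 1 else region$wall_factor
    axes <- axes * (1 - phantom$cardiac_amp * wf * state$contraction)
  }
  list(center = center, axes = axes)
}

#' Render one complex image frame of the phantom
#'
#' Paints the motion-displaced regions in order (painter's algorithm with
#' anti-aliased edges), assigning each tissue the supplied signed Bloch
#' signal value, and multiplies by the phantom's fixed smooth phase map.
#'
#' @param phantom a [make_phantom()] object.
#' @param t_abs_s absolute time (determines cardiac/respiratory state).
#' @param per_label_signal named numeric vector: signed signal per tissue
#'   label at this readout (typically `Mz * sin(flip)` from
#'   [simulate_ir_spgr()]).
#' @return complex matrix grid_size x grid_size.
#' @export
render_frame <- function(phantom, t_abs_s, per_label_signal) {
  labs <- vapply(phantom$regions, `[[`, "", "label")
  missing <- setdiff(labs, names(per_label_signal))
  if (length(missing)) stop("unknown label(s): ", paste(missing, collapse = ", "))
  n <- phantom$grid_size
  state <- phantom_motion_state(phantom, t_abs_s)
  img <- matrix(0, n, n)
  for (region in phantom$regions) {
    geo <- region_geometry(phantom, region, state)
    a <- ellipse_alpha(n, geo$center, geo$axes, region$rot)
    img <- img * (1 - a) + a * per_label_signal[[region$label]]
  }
  img * phantom$phase_map
}

#' Ground-truth parameter maps of the phantom
#'
#' @param phantom a [make_phantom()] object.
#' @param t_abs_s time at which the geometry is evaluated.
#' @return list of matrices `t1_s`, `m0` and a character matrix `label`
#'   (`"air"` outside the torso).
#' @export
phantom_parameter_maps <- function(phantom, t_abs_s = 0) {
  n <- phantom$grid_size
  state <- phantom_motion_state(phantom, t_abs_s)
  t1 <- matrix(0, n, n); m0 <- matrix(0, n, n)
  label <- matrix("air", n, n)
  for (region in phantom$regions) {
    geo <- region_geometry(phantom, region, state)
    a <- ellipse_alpha(n, geo$center, geo$axes, region$rot)
    sel <- a > 0.5
    pars <- phantom$tissue_params[[region$label]]
    t1[sel] <- pars[["t1_s"]]; m0[sel] <- pars[["m0"]]
    label[sel] <- region$label
  }
  list(t1_s = t1, m0 = m0, label = label)
}

#' Simulate a full free-breathing acquisition of the phantom
#'
#' Renders the phantom at every spiral readout time (so intra-frame motion
#' and contrast evolution are genuinely present), samples each instantaneous
#' image with the multichannel non-uniform Fourier operator on that spiral's
#' rotated interleave, adds i.i.d. complex Gaussian noise, and bins
#' consecutive spirals into frames. Ground truth (per-frame reference
#' images, motion signals, and parameter maps) is returned alongside.
#'
#' @param phantom a [make_phantom()] object.
#' @param timing a [sequence_timing()] object.
#' @param trajectory a [make_golden_spiral()] trajectory (one interleave per
#'   readout, rotated by the golden angle).
#' @param coilmaps complex array grid x grid x n_coils.
#' @param spirals_per_frame frame binning (default 5).
#' @param noise_sigma standard deviation of the complex Gaussian noise per
#'   sample (real and imaginary parts each have sd `noise_sigma/sqrt(2)`).
#' @param seed RNG seed for the noise.
#' @return list with `kframes` (a `kspace_frameset`) and `truth`.
#' @export
simulate_acquisition <- function(phantom, timing, trajectory, coilmaps,
                                 spirals_per_frame = 5L, noise_sigma = 0,
                                 seed = 1L) {
  coilmaps <- as_cx_cube(coilmaps)
  sched <- frame_schedule(timing, spirals_per_frame)
  n_frames <- nrow(sched)
  spf <- as.integer(spirals_per_frame)
  n_coils <- dim(coilmaps)[3]
  ns <- nrow(trajectory$base)

  labs <- vapply(phantom$regions, `[[`, "", "label")
  labs <- unique(labs)
  fps <- lapply(labs, function(l) {
    p <- phantom$tissue_params[[l]]
    simulate_ir_spgr(p[["t1_s"]], p[["m0"]], timing)
  })
  names(fps) <- labs
  readout_times <- fps[[1]]$readout_times_s
  sig_mat <- vapply(fps, `[[`, numeric(length(readout_times)), "signal")
  if ("blood" %in% labs && phantom$inflow_frac > 0) {
    # blood pool = mix of the saturated in-slice pool and fresh unsaturated
    # spins; the fresh fraction tracks the cardiac contraction (peak flow
    # during systole)
    bp <- phantom$tissue_params[["blood"]]
    fresh <- simulate_ir_free(bp[["t1_s"]], bp[["m0"]], timing)$signal
    w <- vapply(readout_times, function(t)
      phantom_motion_state(phantom, t)$contraction, 0)
    frac <- phantom$inflow_frac * (0.3 + 0.7 * w)
    sig_mat[, "blood"] <- (1 - frac) * sig_mat[, "blood"] + frac * fresh
  }

  set.seed(seed)
  frames <- vector("list", n_frames)
  truth_images <- vector("list", n_frames)
  card_sig <- numeric(n_frames); resp_sig <- numeric(n_frames)
  card_phase <- numeric(n_frames); resp_phase <- numeric(n_frames)

  for (f in seq_len(n_frames)) {
    sp_idx <- sched$spiral_indices[[f]]
    samp <- matrix(0i, n_coils, spf * ns)
    for (j in seq_along(sp_idx)) {
      sp <- sp_idx[j]
      sig <- sig_mat[sp, ]
      names(sig) <- labs
      img <- render_frame(phantom, readout_times[sp], sig)
      co <- interleave_coords(trajectory, sp)
      y <- nufft_forward(img, co, coilmaps)
      samp[, ((j - 1) * ns + 1):(j * ns)] <- y
    }
    if (noise_sigma > 0) {
      nr <- length(samp)
      samp <- samp + complex(real = stats::rnorm(nr, 0, noise_sigma / sqrt(2)),
                             imaginary = stats::rnorm(nr, 0, noise_sigma / sqrt(2)))
    }
    frames[[f]] <- samp
    # ground truth at the frame midpoint with frame-averaged tissue signals
    msig <- colMeans(sig_mat[sp_idx, , drop = FALSE])
    names(msig) <- labs
    truth_images[[f]] <- render_frame(phantom, sched$t_abs_s[f], msig)
    st <- phantom_motion_state(phantom, sched$t_abs_s[f])
    card_sig[f] <- st$contraction
    resp_sig[f] <- st$resp_shift_px / max(phantom$resp_amp_px, .Machine$double.eps)
    card_phase[f] <- st$cardiac_phase; resp_phase[f] <- st$resp_phase
  }

  kframes <- structure(list(
    frames = frames, schedule = sched, trajectory = trajectory,
    coilmaps = coilmaps, timing = timing, spirals_per_frame = spf,
    n_samples_per_spiral = ns, noise_sigma = noise_sigma, seed = seed),
    class = "kspace_frameset")
  truth <- list(images = truth_images,
                t1_map = phantom_parameter_maps(phantom, 0),
                cardiac_signal = card_sig, resp_signal = resp_sig,
                cardiac_phase = card_phase, resp_phase = resp_phase,
                schedule = sched, phantom = phantom)
  list(kframes = kframes, truth = truth)
}

#' k-space coordinates of one binned frame
#'
#' @param kframes a `kspace_frameset`.
#' @param f frame index.
#' @return matrix of stacked coordinates for the frame's spirals.
#' @export
frame_coords <- function(kframes, f) {
  interleave_coords(kframes$trajectory, kframes$schedule$spiral_indices[[f]])
}

#' Density-compensation weights for one binned frame
#'
#' The trajectory's annular-area weights are normalized for the full
#' interleave set; a single frame reconstruction uses only
#' `spirals_per_frame` interleaves, so the weights are rescaled accordingly.
#' @param kframes a `kspace_frameset`.
#' @export
frame_dcf <- function(kframes) {
  n_total <- length(kframes$trajectory$angles_deg)
  rep(kframes$trajectory$dcf, kframes$spirals_per_frame) *
    (n_total / kframes$spirals_per_frame)
}

#' Extract k-space self-gating navigators
#'
#' For each frame, takes the first `n_center_samples` points of each of its
#' spirals (spirals start at the k-space center), averages them across the
#' frame's spirals per coil, and concatenates real and imaginary parts over
#' coils into a feature vector. Features are z-scored across frames.
#'
#' @param kframes a `kspace_frameset`.
#' @param n_center_samples central samples per spiral to use (default 1).
#' @return matrix n_frames x (2 * n_coils * n_center_samples), with the raw
#'   (un-normalized) complex navigators in attribute `"raw"`.
#' @export
extract_navigators <- function(kframes, n_center_samples = 1L) {
  ncs <- as.integer(n_center_samples)
  stopifnot(ncs >= 1)
  ns <- kframes$n_samples_per_spiral
  spf <- kframes$spirals_per_frame
  n_coils <- nrow(kframes$frames[[1]])
  n_frames <- length(kframes$frames)
  raw <- matrix(0i, n_frames, n_coils * ncs)
  for (f in seq_len(n_frames)) {
    samp <- kframes$frames[[f]]
    acc <- matrix(0i, n_coils, ncs)
    for (j in seq_len(spf)) {
      cols <- (j - 1) * ns + seq_len(ncs)
      acc <- acc + samp[, cols, drop = FALSE]
    }
    raw[f, ] <- as.vector(acc / spf)
  }
  feat <- cbind(Re(raw), Im(raw))
  mu <- colMeans(feat)
  sdv <- apply(feat, 2, stats::sd)
  sdv[sdv == 0] <- 1
  out <- sweep(sweep(feat, 2, mu), 2, sdv, "/")
  attr(out, "raw") <- raw
  out
}

#' Analytic synthetic navigators with known motion frequencies
#'
#' Generates a navigator matrix of the form
#' `m(t) * (offset_f + a_c * g_c,f * cos(2 pi f_card t) + a_r * g_r,f *
#' cos(2 pi f_resp t))` plus noise, where `m(t)` is the frame-binned signed
#' inversion-recovery modulation of a reference tissue. This isolates the
#' latent-estimation problem from image reconstruction and provides exact
#' ground-truth motion waveforms.
#'
#' @param timing a [sequence_timing()] object.
#' @param spirals_per_frame frame binning.
#' @param n_coils synthetic coil count (2 features per coil).
#' @param cardiac_freq_hz,resp_freq_hz true motion frequencies.
#' @param a_card,a_resp motion modulation amplitudes relative to the offset.
#' @param t1_mod_s T1 of the tissue providing the inversion modulation.
#' @param noise_sd additive Gaussian noise, as a fraction of each clean
#'   feature's standard deviation (0.03 = 3% measurement noise).
#' @param seed RNG seed.
#' @return list: `navigators` (z-scored, retained frames only), `p`,
#'   `t_abs_s`, `cardiac_truth`, `resp_truth`, `schedule`.
#' @export
simulate_navigators <- function(timing = sequence_timing(),
                                spirals_per_frame = 5L,
                                n_coils = 6L,
                                cardiac_freq_hz = 1.2, resp_freq_hz = 0.25,
                                a_card = 0.35, a_resp = 0.45,
                                t1_mod_s = 1.0, noise_sd = 0.03,
                                seed = 1L) {
  sched <- frame_schedule(timing, spirals_per_frame)
  keep <- !sched$discard
  tt <- sched$t_abs_s[keep]
  p <- inversion_signal(sched)[keep]

  fp <- simulate_ir_spgr(t1_mod_s, 1, timing)
  spf <- as.integer(spirals_per_frame)
  frame_of <- rep(seq_len(nrow(sched)), each = spf)
  m_all <- as.numeric(tapply(fp$signal, frame_of, mean))
  m <- m_all[keep]

  set.seed(seed)
  n_feat <- 2L * n_coils
  offset <- stats::runif(n_feat, 0.6, 1.4) * sample(c(-1, 1), n_feat, TRUE)
  g_c <- stats::rnorm(n_feat); g_r <- stats::rnorm(n_feat)
  card <- cos(2 * pi * cardiac_freq_hz * tt)
  resp <- cos(2 * pi * resp_freq_hz * tt)
  nav <- outer(m, offset) + outer(m * card, a_card * g_c) +
    outer(m * resp, a_resp * g_r)
  feat_sd <- apply(nav, 2, stats::sd)
  nav <- nav + matrix(stats::rnorm(length(nav)), nrow(nav)) %*% diag(noise_sd * feat_sd)
  mu <- colMeans(nav); sdv <- apply(nav, 2, stats::sd); sdv[sdv == 0] <- 1
  nav <- sweep(sweep(nav, 2, mu), 2, sdv, "/")
  list(navigators = nav, p = p, t_abs_s = tt,
       cardiac_truth = card, resp_truth = resp,
       modulation = m, schedule = sched)
}

#' Save / load a simulated dataset container
#'
#' Self-describing directory container: JSON metadata plus RDS arrays for
#' the k-space payload, trajectory, coil maps and ground truth.
#' @param sim result of [simulate_acquisition()].
#' @param path directory.
#' @export
save_dataset <- function(sim, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  k <- sim$kframes
  saveRDS(k$frames, file.path(path, "kspace.rds"))
  sched <- k$schedule; sched$spiral_indices <- NULL
  utils::write.csv(sched, file.path(path, "schedule.csv"), row.names = FALSE)
  save_trajectory(k$trajectory, file.path(path, "trajectory"))
  saveRDS(k$coilmaps, file.path(path, "coilmaps.rds"))
  saveRDS(sim$truth, file.path(path, "groundtruth.rds"))
  meta <- unclass(k$timing)
  meta$spirals_per_frame <- k$spirals_per_frame
  meta$n_samples_per_spiral <- k$n_samples_per_spiral
  meta$noise_sigma <- k$noise_sigma
  meta$seed <- k$seed
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  timing <- sequence_timing(tr_s = meta$tr_s, flip_rad = meta$flip_rad,
                            n_readouts_per_block = meta$n_readouts_per_block,
                            delay_s = meta$delay_s, n_blocks = meta$n_blocks,
                            inv_efficiency = meta$inv_efficiency,
                            readout_dur_s = meta$readout_dur_s,
                            golden_angle_deg = meta$golden_angle_deg)
  sched <- frame_schedule(timing, meta$spirals_per_frame)
  kframes <- structure(list(
    frames = readRDS(file.path(path, "kspace.rds")),
    schedule = sched,
    trajectory = load_trajectory(file.path(path, "trajectory")),
    coilmaps = readRDS(file.path(path, "coilmaps.rds")),
    timing = timing, spirals_per_frame = meta$spirals_per_frame,
    n_samples_per_spiral = meta$n_samples_per_spiral,
    noise_sigma = meta$noise_sigma, seed = meta$seed),
    class = "kspace_frameset")
  list(kframes = kframes,
       truth = readRDS(file.path(path, "groundtruth.rds")))
}
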