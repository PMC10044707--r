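#' Fingerprint matching of pixel signal evolutions to a Bloch dictionary
#'
#' For each pixel, the complex time-course is phase-aligned by the phase of
#' its largest-TI sample (where the magnetization is most recovered, so
#' Mz > 0 and the signed polarity of the inversion-recovery curve is
#' restored), the real part is taken, and the dictionary T1 maximizing the
#' normalized inner product `|<s, a>| / (||s|| ||a||)` is returned. Ties
#' break toward the smaller T1.
#'
#' @param pixel_series complex matrix (n_pixels x n_timepoints), one row per
#'   pixel; or a vector for a single pixel.
#' @param atoms real matrix (n_t1 x n_timepoints): dictionary atoms
#'   restricted to the series' TIs (see [dictionary_at_tis()]).
#' @param t1_grid_s the T1 value of each atom row.
#' @param ti_s inversion times of the columns (used for phase alignment).
#' @return a `t1_map` list: `t1_s`, `match_corr`, `scale`, `mask` (FALSE for
#'   all-zero pixels), each a vector over pixels.
#' @export
match_fingerprints <- function(pixel_series, atoms, t1_grid_s, ti_s) {
  if (is.null(dim(pixel_series)) || length(dim(pixel_series)) < 2)
    pixel_series <- matrix(pixel_series, nrow = 1)
  nt <- ncol(pixel_series)
  if (nt < 4) stop("matching needs at least 4 timepoints")
  if (ncol(atoms) != nt) stop("series length does not match dictionary columns")
  if (length(ti_s) != nt) stop("ti_s length mismatch")

  ref <- which.max(ti_s)
  phase <- Arg(pixel_series[, ref])
  S <- Re(pixel_series * exp(-1i * phase))       # polarity-restored real series

  s_norm <- sqrt(rowSums(S^2))
  a_norm <- sqrt(rowSums(atoms^2))
  mask <- s_norm > 0
  dot <- S %*% t(atoms)                          # n_px x n_t1
  corr <- abs(dot) / (pmax(s_norm, .Machine$double.eps) %o% a_norm)
  # which.max returns the first maximum: grid is ascending, so ties break
  # toward the smaller T1
  idx <- apply(corr, 1, which.max)
  t1 <- t1_grid_s[idx]
  best_corr <- corr[cbind(seq_len(nrow(S)), idx)]
  scale <- dot[cbind(seq_len(nrow(S)), idx)] / a_norm[idx]^2
  t1[!mask] <- NA_real_
  structure(list(t1_s = t1, match_corr = best_corr, scale = scale,
                 mask = mask), class = "t1_map")
}

#' Generative-mode T1 mapping
#'
#' Fixes the cardiac and respiratory latents at `z_star` (e.g. diastole at
#' end expiration), sweeps the inversion signal over the TIs of `ti_grid`,
#' generates the corresponding synthetic image series, and matches every
#' pixel time-course against the full Bloch dictionary sampled at those TIs.
#' Phase/contrast combinations never observed during imaging are
#' interpolated by the generative model.
#'
#' @param model a trained `cnn_generator`.
#' @param z_star length-2 vector (z_card, z_resp) held fixed.
#' @param ti_grid inversion times (s) of the sweep; default the
#'   frame-midpoint TIs of one steady-state block.
#' @param dictionary a [build_dictionary()] result.
#' @return a `t1_map` with matrix-shaped fields (`t1_s`, `match_corr`,
#'   `scale`, `mask` as grid matrices).
#' @export
t1_map_generative <- function(model, z_star, ti_grid = NULL, dictionary) {
  if (is.null(ti_grid)) ti_grid <- dictionary$timepoint_ti_s
  if (length(ti_grid) == 0) stop("empty ti_grid")
  if (length(ti_grid) < 4) stop("matching needs at least 4 TIs in ti_grid")
  timing <- dictionary$timing
  p <- ti_grid / (timing$n_readouts_per_block * timing$tr_s)
  series <- generate_frames(model, rep(z_star[1], length(p)),
                            rep(z_star[2], length(p)), p)
  n <- nrow(series$frames[[1]])
  px <- vapply(series$frames, as.vector, complex(n * n))   # (n*n) x nt
  atoms <- dictionary_at_tis(dictionary, ti_grid)
  m <- match_fingerprints(px, atoms, dictionary$t1_grid_s, ti_grid)
  as_grid_map(m, n)
}

as_grid_map <- function(m, n) {
  m$t1_s <- matrix(m$t1_s, n, n)
  m$match_corr <- matrix(m$match_corr, n, n)
  m$scale <- matrix(m$scale, n, n)
  m$mask <- matrix(m$mask, n, n)
  m
}

#' Select frames in a cardiac/respiratory phase bin
#'
#' @param latent_track a `latent_track`.
#' @param z_card_star,z_resp_star bin centers in latent units.
#' @param half_widths length-2 numeric: acceptance half-widths for the
#'   cardiac and respiratory latents.
#' @return a `phase_bin`: selected frame indices (into the retained track)
#'   and the bin definition.
#' @export
phase_bin <- function(latent_track, z_card_star, z_resp_star, half_widths) {
  sel <- which(abs(latent_track$z_card - z_card_star) <= half_widths[1] &
                 abs(latent_track$z_resp - z_resp_star) <= half_widths[2])
  structure(list(target = c(z_card = z_card_star, z_resp = z_resp_star),
                 half_widths = half_widths, selected = sel),
            class = "phase_bin")
}

#' Retrospective-binning T1 mapping
#'
#' Identifies the acquired time instants whose latent vectors fall in the
#' given cardiac/respiratory phase bin, generates the corresponding images
#' at those frames' actual latents and inversion signals (these images enter
#' the training loss, so they are data-consistent), and matches against the
#' sub-dictionary restricted to those frames' TIs.
#'
#' @param model a trained `cnn_generator`.
#' @param latent_track a `latent_track`.
#' @param bin a [phase_bin()] (or the arguments to build one as a list).
#' @param dictionary a [build_dictionary()] result.
#' @return a `t1_map` with matrix-shaped fields.
#' @export
t1_map_binned <- function(model, latent_track, bin, dictionary) {
  sel <- bin$selected
  timing <- dictionary$timing
  span <- timing$n_readouts_per_block * timing$tr_s
  tis <- latent_track$p[sel] * span
  if (length(sel) < 4 || length(unique(round(tis, 9))) < 4)
    stop("phase bin too narrow: fewer than 4 frames with distinct TIs ",
         "selected; widen the half-widths")
  series <- generate_frames(model, latent_track$z_card[sel],
                            latent_track$z_resp[sel], latent_track$p[sel])
  n <- nrow(series$frames[[1]])
  px <- vapply(series$frames, as.vector, complex(n * n))
  atoms <- dictionary_at_tis(dictionary, tis)
  m <- match_fingerprints(px, atoms, dictionary$t1_grid_s, tis)
  as_grid_map(m, n)
}

#' Agreement statistics between estimated and reference values
#'
#' `r_squared` is the squared Pearson correlation. `icc_a1` is the two-way
#' mixed-effects, absolute-agreement, single-measure intraclass correlation
#' ICC(A,1), computed from the paired-measurement ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2 raters.
#'
#' @param estimates,references equal-length paired numeric vectors (n >= 3).
#' @return list `r_squared`, `icc_a1`.
#' @export
agreement_stats <- function(estimates, references) {
  n <- length(estimates)
  if (length(references) != n || n < 3) stop("need >= 3 paired values")
  if (stats::sd(estimates) == 0 || stats::sd(references) == 0)
    stop("zero variance: agreement undefined")
  r2 <- stats::cor(estimates, references)^2

  k <- 2
  dat <- cbind(estimates, references)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(r_squared = r2, icc_a1 = icc)
}

#' Median T1 over a labelled region
#'
#' @param t1map a grid-shaped `t1_map`.
#' @param label_map character matrix of tissue labels (from
#'   [phantom_parameter_maps()]) or a logical mask.
#' @param label region name (ignored when a mask is given).
#' @export
region_median_t1 <- function(t1map, label_map, label = NULL) {
  mask <- if (is.logical(label_map)) label_map else label_map == label
  stats::median(t1map$t1_s[mask & t1map$mask], na.rm = TRUE)
}

#' Export a T1 map to NIfTI (milliseconds) and CSV region summary
#'
#' @param t1map grid-shaped `t1_map`.
#' @param path output NIfTI file (`.nii` / `.nii.gz`).
#' @param label_map optional label matrix for a per-region CSV summary
#'   written next to the NIfTI.
#' @export
save_t1_map <- function(t1map, path, label_map = NULL) {
  img <- t1map$t1_s * 1000
  img[!t1map$mask] <- 0
  RNifti::writeNifti(RNifti::asNifti(img), path)
  if (!is.null(label_map)) {
    labs <- setdiff(unique(as.vector(label_map)), "air")
    summ <- data.frame(
      label = labs,
      median_t1_ms = vapply(labs, function(l)
        1000 * region_median_t1(t1map, label_map, l), 0),
      mean_t1_ms = vapply(labs, function(l) {
        m <- label_map == l & t1map$mask
        1000 * mean(t1map$t1_s[m], na.rm = TRUE)
      }, 0))
    utils::write.csv(summ, sub("\\.nii(\\.gz)?$", "_regions.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
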