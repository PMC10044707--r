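#' Golden-angle spiral trajectory
#'
#' Builds a center-out Archimedean spiral interleave reaching the Nyquist
#' radius of the reconstruction grid (|k| = 0.5 cycles/pixel) in `n_turns`
#' revolutions, then rotates it by successive increments of 137.5 degrees to
#' produce `n_interleaves` golden-angle interleaves. k-space coordinates are
#' in cycles/pixel with DC at the grid center.
#'
#' @param n_interleaves number of interleaves.
#' @param n_samples samples per interleave (sample 1 is exactly k = 0).
#' @param grid_size reconstruction matrix size (>= 8).
#' @param n_turns spiral revolutions from center to edge.
#' @return a `spiral_trajectory`: `base` (n_samples x 2 matrix of the
#'   unrotated interleave), `angles_deg`, `dcf` (annular-area density
#'   compensation weights per sample of one interleave, already divided by
#'   the number of interleaves), `grid_size`, and `coords(i)` accessor via
#'   [interleave_coords()].
#' @export
make_golden_spiral <- function(n_interleaves, n_samples, grid_size, n_turns = 4) {
  stopifnot(n_interleaves >= 1, n_samples >= 1, n_turns >= 1)
  if (grid_size < 8) stop("grid_size must be >= 8")
  tau <- seq(0, 1, length.out = n_samples)
  r <- 0.5 * tau
  th <- 2 * pi * n_turns * tau
  base <- cbind(kx = r * cos(th), ky = r * sin(th))
  angles_deg <- (seq_len(n_interleaves) - 1) * 137.5 %% 360

  # annular-area dcf: sample j owns the ring between radial midpoints,
  # divided over all interleaves at that radius
  rmid <- c(0, (r[-1] + r[-n_samples]) / 2, 0.5)
  area <- pi * (rmid[-1]^2 - rmid[-(n_samples + 1)]^2)
  dcf <- area / n_interleaves

  structure(list(base = base, angles_deg = angles_deg, dcf = dcf,
                 grid_size = as.integer(grid_size), n_turns = n_turns),
            class = "spiral_trajectory")
}

#' k-space coordinates of selected interleaves
#'
#' @param trajectory a [make_golden_spiral()] result.
#' @param interleaves integer indices of interleaves (1-based).
#' @return matrix (length(interleaves) * n_samples) x 2 of stacked coords.
#' @export
interleave_coords <- function(trajectory, interleaves) {
  out <- lapply(interleaves, function(i) {
    a <- trajectory$angles_deg[(i - 1L) %% length(trajectory$angles_deg) + 1L] * pi / 180
    ca <- cos(a); sa <- sin(a)
    cbind(trajectory$base[, 1] * ca - trajectory$base[, 2] * sa,
          trajectory$base[, 1] * sa + trajectory$base[, 2] * ca)
  })
  do.call(rbind, out)
}

#' Synthetic smooth coil sensitivity maps
#'
#' Gaussian-bump sensitivities centered on a ring around the FOV with a
#' smooth linear phase per coil, as a stand-in for measured (e.g. ESPIRiT)
#' maps, which the reconstruction accepts as input in the same format.
#'
#' @param grid_size image matrix size.
#' @param n_coils number of coils.
#' @param width bump standard deviation as a fraction of the FOV.
#' @return complex array grid_size x grid_size x n_coils.
#' @export
make_coil_maps <- function(grid_size, n_coils = 6L, width = 0.45) {
  n <- grid_size
  x <- (seq_len(n) - (n / 2 + 1)) / n
  X <- matrix(x, n, n)
  Y <- t(X)
  maps <- array(0i, dim = c(n, n, n_coils))
  for (c in seq_len(n_coils)) {
    a <- 2 * pi * (c - 1) / n_coils
    cx <- 0.45 * cos(a); cy <- 0.45 * sin(a)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * width^2))
    ph <- 2 * pi * (0.15 * cos(a) * X + 0.15 * sin(a) * Y)
    maps[, , c] <- mag * exp(1i * ph)
  }
  sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / sos
  maps
}

as_cx_cube <- function(maps) {
  if (length(dim(maps)) == 2) dim(maps) <- c(dim(maps), 1L)
  maps
}

#' Multichannel non-uniform Fourier forward operator
#'
#' Evaluates `y[c, s] = sum_r S_c(r) x(r) exp(-i 2 pi k_s . r)` exactly, with
#' image coordinates `r` in grid units centered on the image center (DC at
#' index n/2 + 1). This is the per-frame encoding operator of the
#' acquisition model `b_t = A_t(x_t) + n_t`.
#'
#' @param image complex matrix (nx x ny).
#' @param coords k-space sample locations, n_samples x 2, cycles/pixel.
#' @param coilmaps complex array nx x ny x n_coils (or a matrix for 1 coil).
#' @return complex matrix n_coils x n_samples.
#' @export
nufft_forward <- function(image, coords, coilmaps) {
  coilmaps <- as_cx_cube(coilmaps)
  if (!all(dim(image) == dim(coilmaps)[1:2]))
    stop("image and coil-map grids do not match")
  storage.mode(image) <- "complex"
  storage.mode(coilmaps) <- "complex"
  nudft_forward_cpp(image, coilmaps, as.numeric(coords[, 1]),
                    as.numeric(coords[, 2]))
}

#' Multichannel non-uniform Fourier adjoint operator
#'
#' Exact adjoint of [nufft_forward()] when `dcf` is omitted; with `dcf`, a
#' density-compensated gridding reconstruction.
#'
#' @param samples complex matrix n_coils x n_samples.
#' @param coords k-space sample locations, n_samples x 2.
#' @param coilmaps complex array nx x ny x n_coils.
#' @param dcf optional nonnegative weights per sample.
#' @return complex image matrix.
#' @export
nufft_adjoint <- function(samples, coords, coilmaps, dcf = NULL) {
  coilmaps <- as_cx_cube(coilmaps)
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  if (ncol(samples) != nrow(coords)) stop("sample count does not match coords")
  if (nrow(samples) != dim(coilmaps)[3]) stop("coil count mismatch")
  w <- if (is.null(dcf)) rep(1, nrow(coords)) else as.numeric(dcf)
  if (length(w) != nrow(coords)) stop("dcf length mismatch")
  storage.mode(samples) <- "complex"
  storage.mode(coilmaps) <- "complex"
  nudft_adjoint_cpp(samples, coilmaps, as.numeric(coords[, 1]),
                    as.numeric(coords[, 2]), w)
}

#' Estimate the operator norm of A^H A by power iteration
#'
#' @param coords,coilmaps as in [nufft_forward()].
#' @param n_iter power iterations.
#' @param seed RNG seed for the start vector.
#' @return estimated largest eigenvalue of A^H A.
#' @export
nufft_operator_norm <- function(coords, coilmaps, n_iter = 30, seed = 1) {
  coilmaps <- as_cx_cube(coilmaps)
  n <- dim(coilmaps)[1:2]
  set.seed(seed)
  x <- matrix(complex(real = stats::rnorm(prod(n)),
                      imaginary = stats::rnorm(prod(n))), n[1], n[2])
  lam <- 0
  for (i in seq_len(n_iter)) {
    y <- nufft_adjoint(nufft_forward(x, coords, coilmaps), coords, coilmaps)
    lam <- sqrt(sum(Mod(y)^2)) / sqrt(sum(Mod(x)^2))
    x <- y / sqrt(sum(Mod(y)^2))
  }
  lam
}

#' Save / load spiral trajectories
#'
#' Directory container (RDS arrays + JSON metadata); `load_trajectory` also
#' accepts externally supplied coordinates stored in the same layout.
#' @param trajectory a `spiral_trajectory`.
#' @param path directory.
#' @export
save_trajectory <- function(trajectory, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(trajectory$base, file.path(path, "base.rds"))
  saveRDS(trajectory$angles_deg, file.path(path, "angles_deg.rds"))
  saveRDS(trajectory$dcf, file.path(path, "dcf.rds"))
  jsonlite::write_json(list(grid_size = trajectory$grid_size,
                            n_turns = trajectory$n_turns),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  structure(list(base = readRDS(file.path(path, "base.rds")),
                 angles_deg = readRDS(file.path(path, "angles_deg.rds")),
                 dcf = readRDS(file.path(path, "dcf.rds")),
                 grid_size = meta$grid_size, n_turns = meta$n_turns),
            class = "spiral_trajectory")
}
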