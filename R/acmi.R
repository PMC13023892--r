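# Adaptive confocal microwave imaging: background transfer functions from
# simulated field distributions, two-way kernels carrying the source spectrum,
# whitened differential spectra, and the 100 x 100 energy image.
#
# The image value at pixel r is the magnitude of
#   sum_{i,j} sum_{omega in band} dX_ij(omega) K*_ij(r,omega) / (N_ij(omega)+eps),
# with K_ij(r,omega) = S(omega) H_i(r,omega) H_j(r,omega) and
# H_i(r,omega) = E_i(r,omega) / (S(omega)+gamma).  All spectra come from real
# time series, so the negative-frequency half of the sum is the conjugate of
# the positive half; the band is therefore kept on positive frequencies and
# the full two-sided sum recovered as twice the real part.

#' Imaging grid
#'
#' A square pixel grid covering the square circumscribing the antenna circle
#' (default 100 x 100 pixels over \eqn{[-0.1, 0.1]^2} m); pixel centers are
#' used for field sampling.
#'
#' @param n Pixels per side.
#' @param half Half-extent (m).
#' @return List with `n`, `half`, `dx`, center coordinates `xc`, `yc` and
#'   center matrices `X`, `Y` (x varies along rows).
#' @export
imaging_grid <- function(n = 100L, half = 0.10) {
  dx <- 2 * half / n
  xc <- -half + (seq_len(n) - 0.5) * dx
  list(n = as.integer(n), half = half, dx = dx, xc = xc, yc = xc,
       X = matrix(xc, n, n), Y = matrix(xc, n, n, byrow = TRUE))
}

#' Discrete source spectrum
#'
#' DFT of the excitation waveform with its frequency grid.
#'
#' @param s Real waveform.
#' @param dt Sample interval (s).
#' @return List with complex `S`, `freq` (Hz), `omega` (rad/s), `dt`, `n`.
#' @export
source_spectrum <- function(s, dt) {
  if (length(s) < 1) stop("empty waveform")
  n <- length(s)
  freq <- (seq_len(n) - 1) / (n * dt)
  list(S = fft(s), freq = freq, omega = 2 * pi * freq, dt = dt, n = n)
}

#' Effective-bandwidth frequency bins
#'
#' Positive-frequency bins where the source magnitude reaches at least
#' `threshold` of its peak; this realizes the restriction of the imaging sum
#' to the effective antenna bandwidth.
#'
#' @param spec A [source_spectrum()].
#' @param threshold Fraction of the peak magnitude (default 0.1).
#' @return Integer bin indices (1-based, within `2 .. floor(n/2)+1`).
#' @export
effective_band <- function(spec, threshold = 0.1) {
  n <- spec$n
  pos <- 2:(floor(n / 2) + 1)
  mag <- Mod(spec$S)
  band <- pos[mag[pos] >= threshold * max(mag)]
  if (length(band) == 0) stop("empty effective band")
  band
}

#' Background transfer functions
#'
#' Per transmitter and pixel, `H_i(r, omega) = E_i(r, omega) / (S(omega) +
#' gamma)` where `gamma` is a small Tikhonov stabilizer guarding spectral
#' notches of the source.
#'
#' @param E List (per transmitter) of complex `n_bins x n_pixels` spectra, as
#'   produced by [field_spectra()].
#' @param S_spec Complex source spectrum vector on the same frequency grid.
#' @param gamma Nonnegative stabilizer; with `gamma = 0` the function raises
#'   if any retained bin of `S_spec` is zero.
#' @param band Optional bin subset over which the zero check applies.
#' @return List (per transmitter) of complex `n_bins x n_pixels` matrices.
#' @export
background_transfer <- function(E, S_spec, gamma, band = NULL) {
  if (gamma < 0) stop("gamma must be nonnegative")
  check <- if (is.null(band)) seq_along(S_spec) else band
  if (gamma == 0 && any(S_spec[check] == 0))
    stop("gamma = 0 with a zero source bin in the retained band")
  denom <- S_spec + gamma
  lapply(E, function(e) e / denom)
}

# DFT of background field time histories, per transmitter
#' Field spectra of background field histories
#'
#' @param fields A `background_fields` object from [simulate_background()].
#' @return List per transmitter of complex `n_bins x n_pixels` matrices.
#' @export
field_spectra <- function(fields) lapply(fields$e, stats::mvfft)

#' Two-way imaging kernel set
#'
#' Holds the source spectrum, the per-transmitter transfer functions and the
#' retained band; the kernel `K_ij(r, omega) = S(omega) H_i(r, omega)
#' H_j(r, omega)` is evaluated lazily through [kernel_at()] (and materialized
#' as a full array only on request, for small grids).
#'
#' @param S_spec Complex source spectrum vector.
#' @param H Transfer-function list from [background_transfer()].
#' @param band Retained bin indices.
#' @param gamma Stabilizer used to build `H`.
#' @param materialize If `TRUE`, also store the dense array
#'   `K[i, j, r, w]` (use only for small pixel counts).
#' @param banded If `TRUE`, the matrices in `H` hold only the `band` rows
#'   (in band order) rather than the full frequency grid; [acmi_operator()]
#'   stores its transfer functions this way to bound memory.
#' @return Object of class `kernel_set`.
#' @export
build_kernels <- function(S_spec, H, band, gamma = 0, materialize = FALSE,
                          banded = FALSE) {
  ks <- structure(list(S_spec = S_spec, H = H, band = band, gamma = gamma,
                       K = NULL, banded = banded), class = "kernel_set")
  if (materialize) {
    na <- length(H); npix <- ncol(H[[1]]); nb <- length(band)
    K <- array(complex(real = 0), c(na, na, npix, nb))
    for (w in seq_len(nb)) {
      b <- if (banded) w else band[w]
      Hw <- t(vapply(H, function(h) h[b, ], complex(npix)))
      for (i in seq_len(na)) for (j in seq_len(na))
        K[i, j, , w] <- S_spec[band[w]] * Hw[i, ] * Hw[j, ]
    }
    ks$K <- K
  }
  ks
}

# row of the stored H matrices corresponding to full-grid bin b
h_row <- function(ks, b) if (isTRUE(ks$banded)) match(b, ks$band) else b

#' Evaluate kernel entries
#'
#' @param ks A [build_kernels()] kernel set.
#' @param i,j Transmitter / receiver indices.
#' @param bin Frequency-bin index (into the full DFT grid).
#' @return Complex vector over pixels, `K_ij(., bin)`.
#' @export
kernel_at <- function(ks, i, j, bin) {
  r <- h_row(ks, bin)
  ks$S_spec[bin] * ks$H[[i]][r, ] * ks$H[[j]][r, ]
}

#' Differential record
#'
#' Elementwise subtraction `x - x_bg`, suppressing static system and
#' interface responses; self-channels remain zero.
#'
#' @param x,x_bg Matching [multistatic_record()]s.
#' @return A `multistatic_record` holding the differential signals.
#' @export
differential <- function(x, x_bg) {
  if (!all(dim(x$S) == dim(x_bg$S)) || x$dt != x_bg$dt)
    stop("record shapes or sample intervals differ")
  out <- x
  out$S <- x$S - x_bg$S
  out$noise_snr_db <- x$noise_snr_db
  out
}

# per-channel DFT of a multistatic record: complex array (na, na, n_bins)
record_spectra <- function(rec) {
  d <- dim(rec$S)
  Sm <- matrix(rec$S, d[1] * d[2], d[3])
  array(t(stats::mvfft(t(Sm))), d)
}

#' Noise power spectral density from background recordings
#'
#' Per-channel averaged periodogram `mean |X(omega)|^2 dt / n` over the
#' provided records; for white noise of variance `v` the expected level is
#' `v dt`.
#'
#' @param recs List of [multistatic_record()]s holding noise (e.g. noisy
#'   background minus clean background).
#' @return Nonnegative array `(n_antennas, n_antennas, n_bins)`.
#' @export
estimate_noise_psd <- function(recs) {
  if (length(recs) == 0) stop("need at least one record")
  d <- dim(recs[[1]]$S)
  acc <- array(0, d)
  for (r in recs) {
    X <- record_spectra(r)
    acc <- acc + Mod(X)^2 * recs[[1]]$dt / d[3]
  }
  acc / length(recs)
}

#' Confocal image container
#'
#' @param I Real image matrix.
#' @param extent Physical half-extent (m).
#' @param normalization Normalization tag (`"minmax"` or `"none"`).
#' @return Object of class `confocal_image`.
#' @export
confocal_image <- function(I, extent, normalization = "none") {
  stopifnot(is.matrix(I), all(is.finite(I)))
  structure(list(I = I, extent = extent, normalization = normalization),
            class = "confocal_image")
}

#' @export
print.confocal_image <- function(x, ...) {
  cat(sprintf("<confocal_image> %d x %d, extent +/- %.3g m, normalization: %s\n",
              nrow(x$I), ncol(x$I), x$extent, x$normalization))
  invisible(x)
}

# min-max normalize to [0, 1]; a constant image maps to all zeros
minmax_norm <- function(I) {
  rng <- range(I)
  if (rng[2] > rng[1]) (I - rng[1]) / (rng[2] - rng[1]) else I * 0
}

#' Whitened confocal reconstruction
#'
#' Forms the complex imaging sum over channel pairs and the retained band,
#' whitened by the noise PSD, and returns its magnitude min-max normalized to
#' \eqn{[0, 1]}.  `raw = TRUE` skips the magnitude/normalization steps and
#' returns the complex per-pixel sum (used by the linearity checks).
#'
#' @param dX Complex differential spectra, array `(na, na, n_bins)`.
#' @param ks A [build_kernels()] kernel set.
#' @param N Noise PSD array `(na, na, n_bins)`, or `NULL` for none.
#' @param epsilon Positive whitening floor; default `1e-6 * max(N)` (or
#'   `1e-12` when `N` is null/zero).
#' @param img_grid The [imaging_grid()] pixels refer to.
#' @param gain Per-pixel gain handling: `"matched"` (default) divides the
#'   coherent sum by the whitened kernel energy
#'   \eqn{\sum_{ij,\omega} |K_{ij}(r,\omega)|^2 / (N_{ij}(\omega)+\epsilon)},
#'   giving a unit-gain (adaptive) focusing map whose peak tracks the
#'   scatterer amplitude; `"sum"` keeps the plain coherent sum, whose
#'   magnitude is biased toward antenna-proximal pixels by the two-way kernel
#'   amplitude.  Both are linear in `dX` prior to the magnitude step.
#' @param raw Return the complex per-pixel sum (after gain handling, before
#'   magnitude/normalization) instead of the normalized image.
#' @param normalization `"minmax"` rescales each image to `[0, 1]` on its own
#'   range; `"fixed"` divides by the data-independent reference `scale_ref`
#'   and clips to `[0, 1]`, preserving amplitude cues across a dataset (no
#'   per-sample normalization); `"none"` returns raw magnitudes.
#' @param scale_ref Reference magnitude for `normalization = "fixed"`.
#' @return A [confocal_image()] (or complex vector when `raw = TRUE`).
#' @export
reconstruct <- function(dX, ks, N = NULL, epsilon = NULL,
                        img_grid = imaging_grid(),
                        gain = c("matched", "sum"), raw = FALSE,
                        normalization = c("minmax", "fixed", "none"),
                        scale_ref = NULL) {
  gain <- match.arg(gain)
  normalization <- match.arg(normalization)
  band <- ks$band
  if (length(band) == 0) stop("empty band")
  na <- dim(dX)[1]
  npix <- ncol(ks$H[[1]])
  if (is.null(N)) N <- array(0, dim(dX))
  if (any(N < 0)) stop("noise PSD must be nonnegative")
  if (is.null(epsilon)) {
    mN <- max(N)
    epsilon <- if (mN > 0) 1e-6 * mN else 1e-12
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  acc <- complex(npix)
  energy <- numeric(npix)
  diag_idx <- cbind(seq_len(na), seq_len(na))
  s2 <- Mod(ks$S_spec)^2
  for (b in band) {
    r <- h_row(ks, b)
    Winv <- 1 / (N[, , b] + epsilon)
    W <- dX[, , b] * Winv
    W[diag_idx] <- 0
    Hc <- Conj(t(vapply(ks$H, function(h) h[r, ], complex(npix))))
    acc <- acc + Conj(ks$S_spec[b]) * colSums(Hc * (W %*% Hc))
    if (gain == "matched") {
      Winv[diag_idx] <- 0
      E <- Mod(Hc)^2
      energy <- energy + s2[b] * colSums(E * (Winv %*% E))
    }
  }
  acc <- acc + Conj(acc)  # negative-frequency half of the two-sided sum
  if (gain == "matched")
    acc <- acc / (2 * energy + 1e-12 * max(2 * energy))
  if (raw) return(acc)
  I <- matrix(Mod(acc), img_grid$n, img_grid$n)
  I <- switch(normalization,
              minmax = minmax_norm(I),
              fixed = {
                if (is.null(scale_ref) || scale_ref <= 0)
                  stop("normalization = 'fixed' needs a positive scale_ref")
                pmin(I / scale_ref, 1)
              },
              none = I)
  img <- confocal_image(I, img_grid$half, normalization)
  img$gain <- gain
  img
}

#' ACMI configuration
#'
#' @param gamma Tikhonov stabilizer; `NULL` means `1e-3 * max |S(omega)|`.
#' @param epsilon Whitening floor; `NULL` means scale-aware default.
#' @param band_threshold Effective-bandwidth fraction of the source peak.
#' @param img_grid An [imaging_grid()].
#' @param gain Gain handling passed to [reconstruct()].
#' @return Object of class `acmi_config`.
#' @export
acmi_config <- function(gamma = NULL, epsilon = NULL, band_threshold = 0.1,
                        img_grid = imaging_grid(), gain = "matched") {
  structure(list(gamma = gamma, epsilon = epsilon,
                 band_threshold = band_threshold, img_grid = img_grid,
                 gain = gain),
            class = "acmi_config")
}

#' Precompute the imaging operator for one geometry
#'
#' Computes the source spectrum, effective band, field spectra and transfer
#' functions once so that many samples sharing the background can be imaged
#' cheaply.
#'
#' @param fields `background_fields` from [simulate_background()].
#' @param p The [pulse_spec()] used for the acquisition.
#' @param cfg An [acmi_config()].
#' @return A [build_kernels()] kernel set with the resolved `gamma` attached.
#' @export
acmi_operator <- function(fields, p, cfg = acmi_config()) {
  spec <- source_spectrum(excitation_pulse(p), p$dt)
  band <- effective_band(spec, cfg$band_threshold)
  gamma <- if (is.null(cfg$gamma)) 1e-3 * max(Mod(spec$S)) else cfg$gamma
  E <- field_spectra(fields)
  H <- background_transfer(E, spec$S, gamma, band)
  H <- lapply(H, function(h) h[band, , drop = FALSE])  # bound memory
  build_kernels(spec$S, H, band, gamma = gamma, banded = TRUE)
}

#' End-to-end imaging pipeline for one acquisition
#'
#' Composes differential -> spectra -> whitening -> reconstruction.
#'
#' @param phantom_record Head-present [multistatic_record()].
#' @param bg_record Background [multistatic_record()] to subtract.
#' @param operator Either a precomputed [acmi_operator()] kernel set, or the
#'   `background_fields` object (the operator is then built on the fly).
#' @param p The [pulse_spec()] (required when `operator` is raw fields).
#' @param cfg An [acmi_config()].
#' @param noise_psd Optional noise PSD array for whitening.
#' @param scale_ref Optional fixed normalization reference (see
#'   [reconstruct()]); when given, images share one amplitude scale instead
#'   of being min-max normalized per sample.
#' @return A [confocal_image()].
#' @export
imaging_pipeline <- function(phantom_record, bg_record, operator, p = NULL,
                             cfg = acmi_config(), noise_psd = NULL,
                             scale_ref = NULL) {
  if (inherits(operator, "background_fields")) {
    if (is.null(p)) stop("pulse_spec required to build the operator from fields")
    operator <- acmi_operator(operator, p, cfg)
  }
  drec <- differential(phantom_record, bg_record)
  dX <- record_spectra(drec)
  reconstruct(dX, operator, N = noise_psd, epsilon = cfg$epsilon,
              img_grid = cfg$img_grid, gain = cfg$gain %||% "matched",
              normalization = if (is.null(scale_ref)) "minmax" else "fixed",
              scale_ref = scale_ref)
}

#' Pixel nearest to a physical point
#'
#' @param pt Length-2 numeric (m).
#' @param img_grid An [imaging_grid()].
#' @return Integer `(row, col)` pixel index.
#' @export
nearest_pixel <- function(pt, img_grid) {
  c(which.min(abs(img_grid$xc - pt[1])), which.min(abs(img_grid$yc - pt[2])))
}
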