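# Time-domain electromagnetic forward model: differentiated-Gaussian
# excitation, 12-element circular array, and a 2-D transverse-magnetic FDTD
# solver on the array plane (graded-conductivity sponge boundary).  Produces
# the multistatic signal matrix S, head-absent background recordings, and
# background field histories on the imaging grid.

#' Differentiated-Gaussian excitation pulse specification
#'
#' Defaults reproduce the acquisition protocol: tau = 0.4 ns, t0 = 1.2 ns,
#' 300 samples at 0.03 ns (9 ns window).
#'
#' @param tau Pulse width (s).
#' @param t0 Pulse delay (s).
#' @param dt Output sample interval (s).
#' @param n_samples Output length.
#' @return Object of class `pulse_spec`.
#' @export
pulse_spec <- function(tau = 0.4e-9, t0 = 1.2e-9, dt = 0.03e-9, n_samples = 300L) {
  if (tau <= 0 || t0 <= 0 || dt <= 0 || n_samples < 1)
    stop("pulse parameters must be positive")
  structure(list(tau = tau, t0 = t0, dt = dt, n_samples = as.integer(n_samples)),
            class = "pulse_spec")
}

#' Evaluate the excitation pulse
#'
#' The second-derivative-of-Gaussian (Ricker-type) waveform
#' \deqn{s(t_n) = [1 - 4\pi((t_n-t_0)/\tau)^2] \, e^{-2\pi((t_n-t_0)/\tau)^2}}
#' evaluated at `t_n = n dt`, `n = 0 .. n_samples-1` (or at arbitrary times
#' `t`).  The pulse peaks at 1 at `t = t0` and is zero-mean.
#'
#' @param p A [pulse_spec()].
#' @param t Optional explicit time vector (s); overrides the sample grid.
#' @return Numeric waveform.
#' @export
excitation_pulse <- function(p, t = NULL) {
  stopifnot(inherits(p, "pulse_spec"))
  if (is.null(t)) t <- (seq_len(p$n_samples) - 1) * p$dt
  u <- (t - p$t0) / p$tau
  (1 - 4 * pi * u^2) * exp(-2 * pi * u^2)
}

#' Circular antenna array
#'
#' @param n_antennas Element count (default 12).
#' @param radius Array radius (m), default 0.10.
#' @return Object of class `antenna_array` with uniformly spaced positions
#'   starting on the +x axis.
#' @export
antenna_array <- function(n_antennas = 12L, radius = 0.10) {
  th <- 2 * pi * (seq_len(n_antennas) - 1) / n_antennas
  structure(list(n_antennas = as.integer(n_antennas), radius = radius,
                 positions = cbind(x = radius * cos(th), y = radius * sin(th))),
            class = "antenna_array")
}

#' Solver configuration
#'
#' The internal timestep is set from the CFL bound of the fastest medium
#' present (`dt = cfl * dx / (v_max * sqrt(2))`) and the outputs are linearly
#' resampled onto the pulse's 0.03 ns grid; `dt_internal` may override it (the
#' solver raises if the override violates the stability bound).
#'
#' @param sponge_cells Absorbing-layer width in cells.
#' @param cfl Safety fraction of the CFL limit.
#' @param dt_internal Optional explicit internal timestep (s).
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(sponge_cells = 16L, cfl = 0.95, dt_internal = NULL) {
  structure(list(sponge_cells = as.integer(sponge_cells), cfl = cfl,
                 dt_internal = dt_internal), class = "solver_config")
}

#' Multistatic record container
#'
#' @param S Array `(n_antennas, n_antennas, n_samples)`; `S[i, j, ]` is the
#'   waveform received at antenna `j` when `i` transmits; `S[i, i, ]` is zero.
#' @param dt Sample interval (s).
#' @param noise_snr_db Applied SNR in dB, or `NULL` for a noiseless record.
#' @return Object of class `multistatic_record`.
#' @export
multistatic_record <- function(S, dt, noise_snr_db = NULL) {
  stopifnot(length(dim(S)) == 3, dim(S)[1] == dim(S)[2])
  for (i in seq_len(dim(S)[1]))
    if (any(S[i, i, ] != 0)) stop("diagonal (self-transmission) entries must be zero")
  structure(list(S = S, dt = dt, noise_snr_db = noise_snr_db),
            class = "multistatic_record")
}

#' @export
print.multistatic_record <- function(x, ...) {
  d <- dim(x$S)
  cat(sprintf("<multistatic_record> %d x %d channels, %d samples at %.3g ns%s\n",
              d[1], d[2], d[3], x$dt * 1e9,
              if (is.null(x$noise_snr_db)) " (noiseless)"
              else sprintf(" (SNR %.1f dB)", x$noise_snr_db)))
  invisible(x)
}

# map physical positions to 0-based node indices of the padded solver grid
node_index <- function(pos, grid, sponge) {
  i <- round((pos[, 1] - grid$origin[1]) / grid$dx)
  j <- round((pos[, 2] - grid$origin[2]) / grid$dx)
  n <- grid$n
  if (any(i < 0 | i >= n | j < 0 | j >= n))
    stop("positions fall outside the solver domain")
  cbind(i + sponge, j + sponge)
}

# pad the dielectric map with sponge cells filled with the coupling medium
pad_map <- function(map, sponge) {
  cm <- coupling_medium()
  n <- nrow(map$eps_r); np <- n + 2 * sponge
  eps <- matrix(cm[["eps_r"]], np, np); sig <- matrix(cm[["sigma"]], np, np)
  idx <- sponge + seq_len(n)
  eps[idx, idx] <- map$eps_r; sig[idx, idx] <- map$sigma
  list(eps = eps, sig = sig)
}

# one FDTD run: transmitter at node src, record Ez at rec nodes on p's grid
run_fdtd <- function(padded, grid, p, src, rec_nodes, cfg, energy_trace = FALSE) {
  v_max <- .c0 / sqrt(min(padded$eps))
  dt_b <- grid$dx / (v_max * sqrt(2))
  dt_i <- if (is.null(cfg$dt_internal)) cfg$cfl * dt_b else cfg$dt_internal
  t_out <- (seq_len(p$n_samples) - 1) * p$dt
  n_steps <- ceiling(max(t_out) / dt_i) + 2L
  src_wave <- excitation_pulse(p, t = seq_len(n_steps) * dt_i)
  .fdtd_run_cpp(padded$eps, padded$sig, grid$dx, dt_i, n_steps,
                src[1], src[2], src_wave, rec_nodes, t_out,
                cfg$sponge_cells, coupling_medium()[["eps_r"]], energy_trace)
}

#' Simulate a full multistatic acquisition
#'
#' Excites the antennas sequentially (one transmitter, remaining elements
#' receiving) and assembles the noiseless signal matrix
#' `S (n_antennas x n_antennas x n_samples)` with zero diagonal.
#'
#' @param map Phantom [dielectric_map()] on `grid`.
#' @param array An [antenna_array()].
#' @param p A [pulse_spec()].
#' @param grid The [grid_spec()] the map was rasterized on.
#' @param cfg A [solver_config()].
#' @param energy_trace If `TRUE`, attach the per-step total field energy of
#'   the first transmitter run as attribute `energy`.
#' @return A [multistatic_record()].
#' @export
simulate_multistatic <- function(map, array, p, grid, cfg = solver_config(),
                                 energy_trace = FALSE) {
  padded <- pad_map(map, cfg$sponge_cells)
  nodes <- node_index(array$positions, grid, cfg$sponge_cells)
  na <- array$n_antennas
  S <- array(0, c(na, na, p$n_samples))
  energy <- NULL
  for (i in seq_len(na)) {
    out <- run_fdtd(padded, grid, p, nodes[i, ], nodes, cfg,
                    energy_trace = energy_trace && i == 1L)
    if (i == 1L && energy_trace) energy <- out$energy
    for (j in seq_len(na)) if (j != i) S[i, j, ] <- out$rec[, j]
  }
  rec <- multistatic_record(S, p$dt)
  if (!is.null(energy)) attr(rec, "energy") <- energy
  rec
}

#' Background (lesion-free) simulation with field recording
#'
#' Runs the array in a lesion-free background medium -- by default the bare
#' homogeneous coupling medium, or any supplied [dielectric_map()] such as
#' the canonical lesion-free head -- returning both the background
#' multistatic record and, per transmitter, the time-domain electric-field
#' history sampled at every imaging-grid pixel center.  These field histories
#' define the background transfer functions of the adaptive confocal imaging
#' kernel.
#'
#' @param array An [antenna_array()].
#' @param p A [pulse_spec()].
#' @param grid Solver [grid_spec()].
#' @param img_grid Imaging grid from [imaging_grid()].
#' @param cfg A [solver_config()].
#' @param map Optional background [dielectric_map()]; `NULL` means the
#'   homogeneous coupling medium.
#' @return List with `record` (a [multistatic_record()]) and `fields`
#'   (class `background_fields`: list `e` of `n_samples x n_pixels` matrices,
#'   one per transmitter, plus `grid`, `dt`).
#' @export
simulate_background <- function(array, p, grid, img_grid = imaging_grid(),
                                cfg = solver_config(), map = NULL) {
  if (is.null(map)) {
    cm <- coupling_medium()
    n <- grid$n
    map <- dielectric_map(matrix(cm[["eps_r"]], n, n), matrix(cm[["sigma"]], n, n),
                          grid$dx, grid$origin, matrix(FALSE, n, n))
  }
  padded <- pad_map(map, cfg$sponge_cells)
  ant_nodes <- node_index(array$positions, grid, cfg$sponge_cells)
  na <- array$n_antennas

  # Record on the solver-node grid covering the imaging extent and sample the
  # exact pixel centers by bilinear interpolation of the four surrounding
  # nodes (pixel centers do not coincide with solver nodes in general).
  px <- as.vector(img_grid$X); py <- as.vector(img_grid$Y)
  fx <- (px - grid$origin[1]) / grid$dx   # fractional node coordinates
  fy <- (py - grid$origin[2]) / grid$dx
  i0 <- pmin(pmax(floor(fx), 0), grid$n - 2L)
  j0 <- pmin(pmax(floor(fy), 0), grid$n - 2L)
  wx <- pmin(pmax(fx - i0, 0), 1); wy <- pmin(pmax(fy - j0, 0), 1)
  irng <- range(i0); jrng <- range(j0)
  is <- irng[1]:(irng[2] + 1L); js <- jrng[1]:(jrng[2] + 1L)
  node_grid <- cbind(rep(is, times = length(js)) + cfg$sponge_cells,
                     rep(js, each = length(is)) + cfg$sponge_cells)
  col00 <- (i0 - irng[1] + 1L) + length(is) * (j0 - jrng[1])
  col10 <- col00 + 1L
  col01 <- col00 + length(is)
  col11 <- col01 + 1L
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy;       w11 <- wx * wy

  rec_nodes <- rbind(ant_nodes, node_grid)
  S <- array(0, c(na, na, p$n_samples))
  e <- vector("list", na)
  for (i in seq_len(na)) {
    out <- run_fdtd(padded, grid, p, ant_nodes[i, ], rec_nodes, cfg)
    for (j in seq_len(na)) if (j != i) S[i, j, ] <- out$rec[, j]
    En <- out$rec[, -seq_len(na), drop = FALSE]
    e[[i]] <- En[, col00, drop = FALSE] * rep(w00, each = nrow(En)) +
      En[, col10, drop = FALSE] * rep(w10, each = nrow(En)) +
      En[, col01, drop = FALSE] * rep(w01, each = nrow(En)) +
      En[, col11, drop = FALSE] * rep(w11, each = nrow(En))
  }
  fields <- structure(list(e = e, grid = img_grid, dt = p$dt),
                      class = "background_fields")
  list(record = multistatic_record(S, p$dt), fields = fields)
}

#' Add channel noise at a target SNR
#'
#' Adds white Gaussian noise to every off-diagonal channel.  The SNR is
#' defined as mean signal power over all off-diagonal channels divided by the
#' noise variance; the realized noise sample variance is rescaled to the
#' target exactly, so the realized SNR matches the request.  The diagonal
#' stays exactly zero.  `snr_db = Inf` returns the record unchanged.
#'
#' @param rec A [multistatic_record()].
#' @param snr_db Target signal-to-noise ratio (dB).
#' @param seed Integer seed; equal seeds give identical noisy records.
#' @param signal_power Optional reference signal power defining the SNR.  By
#'   default the record's own mean off-diagonal power is used; the dataset
#'   generator instead passes the scattered power of a canonical reference
#'   lesion, so that the stated SNR is a target (hemorrhage-echo) SNR and the
#'   absolute noise variance is identical across all samples.
#' @return A noisy [multistatic_record()].
#' @export
add_noise <- function(rec, snr_db, seed = 1L, signal_power = NULL) {
  stopifnot(inherits(rec, "multistatic_record"))
  if (all(rec$S == 0)) stop("cannot set an SNR on an identically zero record")
  if (is.infinite(snr_db)) return(rec)
  na <- dim(rec$S)[1]; nt <- dim(rec$S)[3]
  off <- which(outer(seq_len(na), seq_len(na), "!="))
  Sm <- matrix(rec$S, na * na, nt)  # rows are (i,j) channels
  p_sig <- if (is.null(signal_power)) mean(Sm[off, ]^2) else signal_power
  v_target <- p_sig / 10^(snr_db / 10)
  with_seed(seed, {
    noise <- matrix(rnorm(length(off) * nt), length(off), nt)
    noise <- noise * sqrt(v_target / mean(noise^2))
    Sm[off, ] <- Sm[off, ] + noise
  })
  out <- rec
  out$S <- array(Sm, dim(rec$S))
  out$noise_snr_db <- snr_db
  out
}

#' Realized SNR of a noisy record against its noiseless original
#'
#' @param noisy,clean Matching [multistatic_record()]s.
#' @return SNR in dB under the off-diagonal mean-power definition.
#' @export
realized_snr_db <- function(noisy, clean) {
  na <- dim(clean$S)[1]
  off <- which(outer(seq_len(na), seq_len(na), "!="))
  nt <- dim(clean$S)[3]
  Sm <- matrix(clean$S, na * na, nt); Nm <- matrix(noisy$S - clean$S, na * na, nt)
  10 * log10(mean(Sm[off, ]^2) / mean(Nm[off, ]^2))
}
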