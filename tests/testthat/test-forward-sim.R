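test_that("excitation pulse matches its closed form", {
  p <- pulse_spec()
  expect_equal(excitation_pulse(p, t = p$t0), 1.0)
  expect_equal(excitation_pulse(p, t = p$t0 + p$tau), (1 - 4 * pi) * exp(-2 * pi),
               tolerance = 1e-12)
  # even symmetry about t0 on-grid
  dlt <- 7 * p$dt
  expect_equal(excitation_pulse(p, t = p$t0 + dlt),
               excitation_pulse(p, t = p$t0 - dlt), tolerance = 1e-12)
  # zero mean over the 9 ns window (second derivative of a Gaussian)
  s <- excitation_pulse(p)
  expect_lt(abs(sum(s) * p$dt), 1e-6 * max(abs(s)) * p$dt * length(s))
  expect_error(pulse_spec(tau = -1), "positive")
  expect_error(pulse_spec(dt = 0), "positive")
})

test_that("antenna positions lie uniformly on the stated circle", {
  arr <- antenna_array()
  expect_equal(arr$n_antennas, 12L)
  r <- sqrt(rowSums(arr$positions^2))
  expect_equal(r, rep(0.10, 12), tolerance = 1e-12)
  ang <- atan2(arr$positions[, 2], arr$positions[, 1])
  expect_equal(sort(diff(sort(ang))), rep(pi / 6, 11), tolerance = 1e-9)
})

test_that("additive noise hits the requested SNR and preserves structure", {
  rec <- synthetic_record(na = 6L, nt = 128L, seed = 2)
  noisy <- add_noise(rec, 5, seed = 10)
  expect_lt(abs(realized_snr_db(noisy, rec) - 5), 0.1)
  # diagonal stays exactly zero
  for (i in 1:6) expect_identical(noisy$S[i, i, ], rep(0, 128))
  # unit-power record at 5 dB: noise variance ~ 10^(-1/2)
  off <- which(outer(1:6, 1:6, "!="))
  Sm <- matrix(rec$S, 36, 128)
  p_sig <- mean(Sm[off, ]^2)
  v_real <- mean((matrix(noisy$S - rec$S, 36, 128)[off, ])^2)
  expect_equal(v_real / p_sig, 10^(-0.5), tolerance = 1e-6)
  # determinism and the no-noise sentinel
  expect_identical(add_noise(rec, 5, seed = 10)$S, noisy$S)
  expect_identical(add_noise(rec, Inf, seed = 10)$S, rec$S)
  zero <- multistatic_record(array(0, c(3, 3, 8)), 0.03e-9)
  expect_error(add_noise(zero, 5), "zero record")
  # explicit reference power defines the variance directly
  ref <- add_noise(rec, 0, seed = 3, signal_power = 1)
  v <- mean((matrix(ref$S - rec$S, 36, 128)[off, ])^2)
  expect_equal(v, 1, tolerance = 1e-6)
})

test_that("solver obeys reciprocity and background equivalence", {
  gen <- test_gen()
  pr <- test_phantom_record()
  S <- pr$rec$S
  num <- 0; den <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    num <- num + sum((S[i, j, ] - S[j, i, ])^2)
    den <- den + sum(S[i, j, ]^2)
  }
  expect_lt(sqrt(num / den), 0.01)

  # a phantom identical to the coupling medium reproduces the head-absent
  # background record within solver round-off
  n <- gen$grid$n; cm <- coupling_medium()
  hom <- dielectric_map(matrix(cm[1], n, n), matrix(cm[2], n, n),
                        gen$grid$dx, gen$grid$origin, matrix(FALSE, n, n))
  rec_hom <- simulate_multistatic(hom, gen$array, gen$pulse, gen$grid, gen$solver)
  bg_hom <- test_background_hom()
  expect_lt(max(abs(rec_hom$S - bg_hom$record$S)), 1e-12 * max(abs(bg_hom$record$S)) + 1e-300)

  # diagonal of any record is zero
  for (i in 1:12) expect_identical(pr$rec$S[i, i, ], rep(0, dim(S)[3]))
})

test_that("solver is linear in the source and dissipates energy", {
  gen <- test_gen()
  # linearity: doubling the source waveform doubles every received sample
  n <- gen$grid$n; cm <- coupling_medium()
  padded <- mwstroke:::pad_map(
    dielectric_map(matrix(cm[1], n, n), matrix(cm[2], n, n),
                   gen$grid$dx, gen$grid$origin, matrix(FALSE, n, n)),
    gen$solver$sponge_cells)
  nodes <- mwstroke:::node_index(gen$array$positions, gen$grid,
                                 gen$solver$sponge_cells)
  v_max <- mwstroke:::.c0 / sqrt(min(padded$eps))
  dt_i <- 0.9 * gen$grid$dx / (v_max * sqrt(2))
  n_steps <- 150L
  t_out <- seq(0, (n_steps - 1) * dt_i, by = dt_i)[1:100]
  w <- excitation_pulse(gen$pulse, t = seq_len(n_steps) * dt_i)
  r1 <- mwstroke:::.fdtd_run_cpp(padded$eps, padded$sig, gen$grid$dx, dt_i,
                                 n_steps, nodes[1, 1], nodes[1, 2], w,
                                 nodes, t_out, gen$solver$sponge_cells,
                                 cm[1], FALSE)
  r2 <- mwstroke:::.fdtd_run_cpp(padded$eps, padded$sig, gen$grid$dx, dt_i,
                                 n_steps, nodes[1, 1], nodes[1, 2], 2 * w,
                                 nodes, t_out, gen$solver$sponge_cells,
                                 cm[1], FALSE)
  expect_equal(r2$rec, 2 * r1$rec, tolerance = 1e-12)

  # energy decay after the source turns off (lossy medium)
  pr <- test_phantom_record()
  en <- attr(pr$rec, "energy")
  src_off <- ceiling(length(en) * 4 / 9)  # pulse support ends well before 4 ns
  late <- en[src_off:length(en)]
  expect_true(all(diff(late) <= 1e-12 * max(en)))

  # CFL violation raises
  bad <- solver_config(dt_internal = 1e-10)
  expect_error(simulate_multistatic(test_phantom_record()$phantom$map,
                                    gen$array, gen$pulse, gen$grid, bad),
               "CFL")
})

test_that("halving the grid spacing converges the received waveforms", {
  # Node-registered convergence study: source, receiver and a circular
  # scatterer sit on identical physical coordinates at every resolution
  # (0.1/dx integer), the sponge keeps a fixed physical width, and the
  # injected amplitude is scaled by the internal timestep so the source rate
  # is resolution-independent.  Grid dispersion at the coarse steps prevents
  # tight L2 agreement, but each refinement must move the (amplitude-
  # normalized) waveform monotonically toward the fine-grid solution.
  p <- pulse_spec()
  cm <- coupling_medium()
  rec_at <- function(dx) {
    sponge <- as.integer(round(0.06 / dx))
    n_half <- as.integer(round(0.115 / dx))
    n <- 2L * n_half + 1L + 2L * sponge
    ctr <- n_half + sponge          # 0-based index of x = 0
    coord <- ((0:(n - 1)) - ctr) * dx
    eps <- matrix(cm[1], n, n); sig <- matrix(cm[2], n, n)
    X <- matrix(coord, n, n); Y <- matrix(coord, n, n, byrow = TRUE)
    inside <- (X - 0.03)^2 + Y^2 <= 0.015^2
    eps[inside] <- 61; sig[inside] <- 1.6
    v_max <- mwstroke:::.c0 / sqrt(min(eps))
    dt_i <- 0.95 * dx / (v_max * sqrt(2))
    t_out <- (seq_len(p$n_samples) - 1) * p$dt
    n_steps <- as.integer(ceiling(max(t_out) / dt_i) + 2)
    w <- excitation_pulse(p, t = seq_len(n_steps) * dt_i) * (dt_i / 1e-12)
    src <- c(ctr - as.integer(round(0.1 / dx)), ctr)
    rx <- matrix(c(ctr + as.integer(round(0.1 / dx)), ctr), 1)
    out <- mwstroke:::.fdtd_run_cpp(eps, sig, dx, dt_i, n_steps,
                                    src[1], src[2], w, rx, t_out,
                                    sponge, cm[1], FALSE)
    out$rec[, 1]
  }
  w10 <- rec_at(10e-3); w5 <- rec_at(5e-3); w25 <- rec_at(2.5e-3)
  w_ref <- rec_at(1.25e-3)
  rel <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
  nrm <- function(w) w / max(abs(w))
  errs <- c(rel(nrm(w10), nrm(w_ref)), rel(nrm(w5), nrm(w_ref)),
            rel(nrm(w25), nrm(w_ref)))
  expect_true(all(diff(errs) < 0))  # strictly decreasing with refinement
  xc <- vapply(list(w10, w5, w25), function(w)
    max(ccf(w, w_ref, lag.max = 40, plot = FALSE)$acf), numeric(1))
  expect_true(all(diff(xc) > 0))    # waveform similarity increases
  expect_gt(xc[3], 0.5)             # bounded error at the default resolution
})

test_that("background fields respect causality and lossy attenuation", {
  gen <- test_gen()
  bg <- test_background_hom()
  e1 <- bg$fields$e[[1]]  # transmitter 1 at (0.1, 0)
  gridi <- gen$acmi$img_grid
  pix_near <- (which.min(abs(gridi$yc - 0)) - 1) * gridi$n +
    which.min(abs(gridi$xc - 0.095))
  pix_mid <- (which.min(abs(gridi$yc - 0)) - 1) * gridi$n +
    which.min(abs(gridi$xc - 0.05))
  pix_far <- (which.min(abs(gridi$yc - 0)) - 1) * gridi$n +
    which.min(abs(gridi$xc - 0.0))
  t_near <- which.max(abs(e1[, pix_near]))
  t_far <- which.max(abs(e1[, pix_far]))
  expect_lt(t_near, t_far)  # peak arrives earlier close to the source
  # amplitude at twice the distance is smaller (spreading + sigma > 0)
  a_mid <- max(abs(e1[, pix_mid]))   # ~5 cm from source
  a_far <- max(abs(e1[, pix_far]))   # ~10 cm from source
  expect_gt(a_mid, a_far)
})
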