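test_that("source spectrum obeys DFT identities", {
  p <- pulse_spec()
  s <- excitation_pulse(p)
  sp <- source_spectrum(s, p$dt)
  expect_equal(length(sp$S), length(s))
  # zero waveform
  expect_true(all(source_spectrum(rep(0, 64), p$dt)$S == 0))
  # Parseval under the unnormalized-DFT convention
  lhs <- sum(s^2) * p$dt
  rhs <- sum(Mod(sp$S)^2) * p$dt / length(s)
  expect_lt(abs(lhs - rhs) / lhs, 1e-10)
  # shift theorem: delay by k samples is a unit-modulus phase per bin
  k <- 11
  s2 <- c(rep(0, k), s[1:(length(s) - k)])
  sp2 <- source_spectrum(s2, p$dt)
  n <- length(s)
  phase <- exp(-2i * pi * (0:(n - 1)) * k / n)
  # compare on bins carrying energy
  keep <- Mod(sp$S) > 1e-6 * max(Mod(sp$S))
  expect_lt(max(Mod(sp2$S[keep] - sp$S[keep] * phase[keep])) / max(Mod(sp$S)), 1e-6)
  expect_error(source_spectrum(numeric(0), p$dt), "empty")
})

test_that("background transfer functions follow the stabilized division", {
  set.seed(4)
  nb <- 32; npix <- 10
  S <- complex(real = rnorm(nb), imaginary = rnorm(nb))
  G <- matrix(complex(real = rnorm(nb * npix), imaginary = rnorm(nb * npix)),
              nb, npix)
  E <- list(G * S)  # E = S * G elementwise per bin
  H <- background_transfer(E, S, gamma = 0)
  expect_equal(H[[1]], G, tolerance = 1e-12)
  # rearranged definition |H| |S + gamma| = |E|
  gma <- 0.3
  H2 <- background_transfer(E, S, gamma = gma)
  expect_equal(Mod(H2[[1]]) * abs(Mod(S + gma)), Mod(E[[1]]), tolerance = 1e-10)
  # monotonicity in gamma for real-positive spectra
  Spos <- runif(nb, 0.5, 2)
  Ha <- background_transfer(E, Spos, gamma = 0.1)
  Hb <- background_transfer(E, Spos, gamma = 0.2)
  expect_true(all(Mod(Hb[[1]]) <= Mod(Ha[[1]]) + 1e-12))
  # gamma = 0 with a zero retained bin raises
  Szero <- S; Szero[5] <- 0
  expect_error(background_transfer(E, Szero, gamma = 0), "zero source bin")
})

test_that("kernels satisfy the product identity and symmetry", {
  set.seed(5)
  na <- 3; nb_full <- 16; npix <- 7
  S <- complex(real = rnorm(nb_full), imaginary = rnorm(nb_full))
  H <- lapply(1:na, function(i)
    matrix(complex(real = rnorm(nb_full * npix), imaginary = rnorm(nb_full * npix)),
           nb_full, npix))
  band <- c(2L, 5L, 9L)
  ks <- build_kernels(S, H, band, materialize = TRUE)
  for (w in seq_along(band)) {
    b <- band[w]
    for (i in 1:na) for (j in 1:na) {
      expect_identical(ks$K[i, j, , w], S[b] * H[[i]][b, ] * H[[j]][b, ])
      # symmetric up to the float non-associativity of the triple product
      expect_equal(ks$K[i, j, , w], ks$K[j, i, , w], tolerance = 1e-12)
      expect_identical(kernel_at(ks, i, j, b), S[b] * H[[i]][b, ] * H[[j]][b, ])
    }
  }
  # H == 1 collapses the kernel to the source spectrum
  H1 <- lapply(1:na, function(i) matrix(complex(real = 1), nb_full, npix))
  ks1 <- build_kernels(S, H1, band)
  expect_equal(kernel_at(ks1, 1, 3, 5), rep(S[5], npix))
})

test_that("differential subtraction is exact and shape-checked", {
  x <- synthetic_record(na = 4, seed = 1)
  bg <- synthetic_record(na = 4, seed = 2)
  d <- differential(x, bg)
  expect_equal(d$S, x$S - bg$S)
  expect_true(all(differential(x, x)$S == 0))
  # linear arithmetic: diff against c * bg
  cc <- 2.5
  xb <- x; xb$S <- x$S + cc * bg$S
  expect_equal(differential(xb, bg)$S, x$S + (cc - 1) * bg$S, tolerance = 1e-12)
  small <- synthetic_record(na = 3, seed = 3)
  expect_error(differential(x, small), "differ")
})

test_that("noise PSD estimator matches the periodogram expectation", {
  v <- 0.7; dt <- 0.03e-9; na <- 4; nt <- 64
  recs <- lapply(1:100, function(k) {
    S <- array(0, c(na, na, nt))
    set.seed(k)
    for (i in 1:na) for (j in 1:na)
      if (i != j) S[i, j, ] <- rnorm(nt, sd = sqrt(v))
    multistatic_record(S, dt)
  })
  N <- estimate_noise_psd(recs)
  off_levels <- sapply(1:na, function(i) sapply(1:na, function(j)
    if (i != j) mean(N[i, j, ]) else NA))
  expect_equal(mean(off_levels, na.rm = TRUE), v * dt, tolerance = 0.05)
  expect_true(all(N >= 0))
  # zero records give a zero PSD; averaging identical records is the identity
  zero <- multistatic_record(array(0, c(na, na, nt)), dt)
  expect_true(all(estimate_noise_psd(list(zero))== 0))
  one <- recs[[1]]
  expect_equal(estimate_noise_psd(list(one, one)), estimate_noise_psd(list(one)))
  expect_error(estimate_noise_psd(list()), "at least one")
})

test_that("reconstruction is linear and zero-preserving before the magnitude", {
  set.seed(6)
  na <- 4; nb_full <- 32; npix <- 25
  S <- complex(real = rnorm(nb_full), imaginary = rnorm(nb_full))
  H <- lapply(1:na, function(i)
    matrix(complex(real = rnorm(nb_full * npix), imaginary = rnorm(nb_full * npix)),
           nb_full, npix))
  ks <- build_kernels(S, H, band = c(3L, 7L, 11L))
  ig <- imaging_grid(n = 5, half = 0.1)
  dX <- array(complex(real = rnorm(na * na * nb_full),
                      imaginary = rnorm(na * na * nb_full)), c(na, na, nb_full))
  for (i in 1:na) dX[i, i, ] <- 0

  z <- reconstruct(array(complex(real = 0), c(na, na, nb_full)), ks,
                   img_grid = ig, raw = TRUE)
  expect_true(all(Mod(z) == 0))

  a1 <- reconstruct(dX, ks, img_grid = ig, raw = TRUE)
  a2 <- reconstruct(2.5 * dX, ks, img_grid = ig, raw = TRUE)
  expect_lt(max(Mod(a2 - 2.5 * a1)) / max(Mod(a1)), 1e-10)

  # whitening with a constant PSD is proportional to the plain matched filter
  Nc <- array(0.4, c(na, na, nb_full))
  aw <- reconstruct(dX, ks, N = Nc, epsilon = 1e-9, img_grid = ig, raw = TRUE)
  expect_gt(abs(cor(Mod(aw), Mod(a1))), 1 - 1e-8)

  expect_error(reconstruct(dX, build_kernels(S, H, integer(0)), img_grid = ig),
               "empty band")
  # normalized image lies in [0, 1]
  img <- reconstruct(dX, ks, img_grid = ig)
  expect_true(all(img$I >= 0 & img$I <= 1))
  expect_s3_class(img, "confocal_image")
})

test_that("a noiseless point scatterer is localized by the full pipeline", {
  gen <- test_gen()
  bg <- test_background_hom()
  grid <- gen$grid; n <- grid$n; cm <- coupling_medium()
  hom <- dielectric_map(matrix(cm[1], n, n), matrix(cm[2], n, n),
                        grid$dx, grid$origin, matrix(FALSE, n, n))
  les <- lesion_spec(c(0.03, -0.02), c(0.008, 0.008), 0)
  sc <- rasterize_ellipse(hom, les, grid)
  rec <- simulate_multistatic(sc, gen$array, gen$pulse, grid, gen$solver)
  img <- imaging_pipeline(rec, bg$record, bg$operator, p = gen$pulse,
                          cfg = gen$acmi)
  am <- which(img$I == max(img$I), arr.ind = TRUE)[1, ]
  tp <- nearest_pixel(les$center, gen$acmi$img_grid)
  expect_lte(sqrt(sum((am - tp)^2)), 5)

  # identical inputs give identical images; a lesion-free head still yields a
  # nonzero image against the head-absent background (interface mismatch)
  img2 <- imaging_pipeline(rec, bg$record, bg$operator, p = gen$pulse,
                           cfg = gen$acmi)
  expect_identical(img$I, img2$I)
  ph0 <- make_phantom(phantom_config(0, seed = 11, grid = grid))
  rec0 <- simulate_multistatic(ph0$map, gen$array, gen$pulse, grid, gen$solver)
  img0 <- imaging_pipeline(rec0, bg$record, bg$operator, p = gen$pulse,
                           cfg = gen$acmi, scale_ref = 1)
  expect_gt(max(img0$I), 0)
})
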