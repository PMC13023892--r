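# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code; the expensive pieces (background simulation with field
# recording) are cached in this environment.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_gen <- function() gen_config_reduced()

# canonical-head background (record + operator + noise PSD + scale) at the
# reduced solver resolution
test_background <- function() memo("background", build_background(test_gen(), seed = 1))

# background in the bare coupling medium (for the homogeneous-scatterer checks)
test_background_hom <- function() memo("background_hom", {
  gen <- test_gen()
  bg <- simulate_background(gen$array, gen$pulse, gen$grid,
                            gen$acmi$img_grid, gen$solver)
  list(record = bg$record, fields = bg$fields,
       operator = acmi_operator(bg$fields, gen$pulse, gen$acmi))
})

# nine-sample dataset built against the cached background (three per class,
# the minimum the stratified split accepts)
test_tiny_ds <- function() memo("tiny_ds", {
  build_dataset(dataset_manifest(c(3L, 3L, 3L), seed = 21), test_gen(),
                background = test_background())
})

# one single-lesion phantom + its record, reused by several tests
test_phantom_record <- function() memo("phantom_record", {
  gen <- test_gen()
  ph <- make_phantom(phantom_config(1, seed = 42, grid = gen$grid))
  rec <- simulate_multistatic(ph$map, gen$array, gen$pulse, gen$grid,
                              gen$solver, energy_trace = TRUE)
  list(phantom = ph, rec = rec)
})

# small synthetic multistatic record (no physics) for signal-level tests
synthetic_record <- function(na = 4L, nt = 64L, seed = 1, dt = 0.03e-9) {
  S <- array(0, c(na, na, nt))
  set.seed(seed)
  for (i in seq_len(na)) for (j in seq_len(na))
    if (i != j) S[i, j, ] <- rnorm(nt)
  multistatic_record(S, dt)
}

# synthetic paired samples with a controllable class signal, for model tests
synthetic_samples <- function(n, sep = 0.5, seed = 3, img_n = 100L) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    lab <- k %% 2L
    img <- matrix(pmin(pmax(rnorm(img_n^2, mean = lab * sep, sd = 0.3), 0), 1),
                  img_n, img_n)
    wav <- matrix(rnorm(64 * 144, mean = lab * sep, sd = 0.3), 64, 144)
    sample_record(confocal_image(img, 0.1, "none"), wav,
                  label3 = lab, sample_id = k)
  })
}

# finite-difference gradient of f at x (dense; keep x small)
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_relerr <- function(a, b) max(abs(a - b)) / (max(abs(b)) + 1e-12)
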