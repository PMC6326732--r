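# Core lead-matrix math: path closing, signed-area quadrature against the
# closed form, antisymmetry/invariance properties, and spectral phase
# recovery.

test_that("center_and_close removes ramps, is idempotent, and recovers a trended sinusoid", {
  # a pure ramp closes to exactly zero
  ramp <- matrix(0:3, 1, dimnames = list("r", NULL))
  expect_equal(unname(center_and_close(ramp)), matrix(0, 1, 4))

  # already-closed zero-mean signal passes through unchanged
  t <- seq(0, 4 * pi, length.out = 201)  # exactly 2 periods, endpoints equal
  x <- rbind(s = sin(t))
  expect_equal(center_and_close(x), x - rowMeans(x), tolerance = 1e-12)
  # idempotence
  expect_equal(center_and_close(center_and_close(x)), center_and_close(x),
               tolerance = 1e-12)

  # sin(t) + linear trend 0.5*u: endpoints sit at the same phase, so the
  # linear closing removes the trend exactly
  u <- (seq_along(t) - 1) / (length(t) - 1)
  trended <- rbind(s = sin(t) + 0.5 * u)
  rec <- center_and_close(trended)
  target <- sin(t) - mean(sin(t))
  expect_lt(max(abs(rec - target)), 1e-8)

  expect_error(center_and_close(rbind(c(1, NA, 3))), "non-finite")
})

test_that("lead matrix matches the closed-form ellipse area over an (a, b, delta, n) grid", {
  n_samples <- 10000
  for (a in c(1, 2)) for (b in c(1, 3)) for (delta in c(pi / 6, pi / 2, 2)) {
    for (n_per in c(1, 2)) {
      t <- seq(0, 2 * pi * n_per, length.out = n_samples + 1)[seq_len(n_samples)]
      x <- rbind(p = a * sin(t), q = b * sin(t + delta))
      A <- lead_matrix(x)
      expected <- n_per * pi * a * b * sin(-delta)  # sin(phi_i - phi_j)
      expect_lt(abs(A["p", "q"] - expected), 1e-3 * abs(expected))
    }
  }
})

test_that("identical channels enclose zero area and 2x2 eigenvalues equal the single entry", {
  t <- seq(0, 2 * pi, length.out = 500)[-500]
  x <- rbind(a = sin(t), b = sin(t))
  A <- lead_matrix(x)
  expect_identical(A["a", "b"], 0)

  y <- rbind(a = sin(t), b = sin(t + pi / 2))
  B <- lead_matrix(y)
  ss <- spectral_decomposition(B)
  expect_equal(ss$eigen_magnitudes[1], abs(B["a", "b"]), tolerance = 1e-10)
})

test_that("lead matrices satisfy antisymmetry, translation and reparameterization invariance", {
  spec <- sinusoid_spec(n_channels = 8, n_periods = 3, n_samples = 2000,
                        snr = Inf)
  x <- gen_phase_shifted_sinusoids(spec, seed = 7)
  A <- lead_matrix(x)
  expect_equal(max(abs(A + t(A))), 0)

  # translation invariance
  shifted <- x + matrix(seq_len(nrow(x)), nrow(x), ncol(x))
  expect_equal(lead_matrix(shifted), A, tolerance = 1e-10)

  # reparameterization invariance under monotone warps
  for (w in list(function(u) u^2, function(u) u^3,
                 function(u) (exp(u) - 1) / (exp(1) - 1))) {
    xw <- gen_cyclic_aperiodic(spec, warp = w, seed = 7)
    Aw <- lead_matrix(xw)
    expect_lt(max(abs(Aw - A)), 0.01 * max(abs(A)))
  }

  # eigenvalues purely imaginary
  ev <- eigen(A, only.values = TRUE)$values
  expect_lt(max(abs(Re(ev))), 1e-10 * max(abs(A)))

  expect_error(lead_matrix(x[, 1:2]), "3 samples")
})

test_that("spectral decomposition handles the zero matrix and a hand-built phase matrix", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sz <- spectral_decomposition(z)
  expect_false(sz$defined)
  expect_equal(sz$eigen_magnitudes, c(0, 0))
  expect_true(all(is.na(sz$strengths)))
  expect_error(recover_phase_offsets(sz), "undefined")

  # A[i, j] = sin(phi_j - phi_i), phi = (0, pi/2, pi, 3pi/2): rank 2,
  # equal strengths, gaps recovered up to rotation and sign
  phi <- c(0, pi / 2, pi, 3 * pi / 2)
  A <- outer(phi, phi, function(a, b) sin(b - a))
  dimnames(A) <- list(letters[1:4], letters[1:4])
  # independent oracle: direct eigendecomposition
  ev <- eigen(A)$values
  expect_equal(sort(Im(ev), decreasing = TRUE)[1], 2, tolerance = 1e-10)
  ss <- spectral_decomposition(A)
  expect_equal(ss$eigen_magnitudes, c(2, 0), tolerance = 1e-10)
  expect_equal(unname(ss$strengths[, 1]), rep(0.5, 4), tolerance = 1e-10)
  offs <- recover_phase_offsets(ss, "a")
  expect_identical(unname(offs["a"]), 0)
  expect_lt(circular_rmse(offs, phi), 1e-8)

  expect_error(spectral_decomposition(matrix(1:4, 2)), "antisymmetric")
})

test_that("phase offsets of 8 shifted sinusoids are recovered, noiseless and at SNR 20", {
  spec <- sinusoid_spec(n_channels = 8, n_periods = 4, n_samples = 300,
                        snr = Inf)
  x <- gen_phase_shifted_sinusoids(spec, seed = 1)
  offs <- recover_phase_offsets(spectral_decomposition(lead_matrix(x)), 1)
  expect_lt(circular_rmse(offs, spec$phases), 0.05)

  noisy_spec <- sinusoid_spec(n_channels = 8, n_periods = 4, n_samples = 300,
                              snr = 20)
  rmses <- vapply(1:5, function(s) {
    xn <- gen_phase_shifted_sinusoids(noisy_spec, seed = s)
    on <- recover_phase_offsets(spectral_decomposition(lead_matrix(xn)), 1)
    circular_rmse(on, noisy_spec$phases)
  }, 0)
  expect_true(all(rmses < 0.15))
})
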