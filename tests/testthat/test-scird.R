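test_that("kernels are zero-mean, unit-norm and symmetric at k = 0", {
  for (p in list(c(3, 1, 0, 0), c(4, 1.5, 0.05, 0.7), c(2, 1, -0.1, 2.1))) {
    ker <- scird_kernel(p[1], p[2], p[3], p[4], halfsize = 12)
    expect_lt(abs(sum(ker)), 1e-9)
    expect_lt(abs(sum(ker^2) - 1), 1e-9)
  }
  ker <- scird_kernel(3, 1, 0, 0, halfsize = 10)
  expect_lt(max(abs(ker - ker[nrow(ker):1, ])), 1e-9)   # x2 -> -x2
  expect_lt(max(abs(ker - ker[, ncol(ker):1])), 1e-9)   # x1 -> -x1
  expect_error(scird_kernel(5, 1, 0, 0, halfsize = 8), "3-sigma")
})

test_that("k = 0 kernel equals the separable oriented ridge closed form", {
  sigma1 <- 3; sigma2 <- 1.2; h <- 10
  for (theta in c(0, 0.6, pi / 2)) {
    ker <- scird_kernel(sigma1, sigma2, 0, theta, h)
    # oracle: separable product g(x1) * (-g''(x2)), built independently
    s <- seq(-h, h)
    X <- matrix(rep(s, each = length(s)), length(s), length(s))
    Y <- matrix(rep(s, times = length(s)), length(s), length(s))
    x1 <- X * cos(theta) + Y * sin(theta)
    x2 <- -X * sin(theta) + Y * cos(theta)
    g1 <- exp(-x1^2 / (2 * sigma1^2))
    neg_g2pp <- (1 / sigma2^2 - x2^2 / sigma2^4) * exp(-x2^2 / (2 * sigma2^2))
    ref <- g1 * neg_g2pp
    ref <- ref - mean(ref)
    ref <- ref / sqrt(sum(ref^2))
    expect_lt(max(abs(ker - ref)), 1e-9)
  }
})

test_that("bank construction enforces its invariants", {
  expect_error(scird_bank(k = c(-0.1, 0.1)), "contain 0")
  expect_error(scird_bank(sigma1 = c(2, -1)), "> 0")
  expect_error(scird_bank(sigma1 = 4, halfsize = 5), "halfsize")
  b <- scird_bank(sigma1 = 2, sigma2 = 1, k = 0, n_theta = 6)
  expect_true(all(b$theta >= 0 & b$theta < pi))
  expect_equal(nrow(b$params), 6)
})

test_that("FFT response equals direct spatial correlation", {
  set.seed(14)
  img <- matrix(runif(40 * 40), 40, 40)
  bank <- scird_bank(sigma1 = 2, sigma2 = c(1, 1.5), k = c(-0.05, 0, 0.05),
                     n_theta = 4, halfsize = 7)
  r_fft <- scird_response(img, bank, backend = "fft")
  r_sp <- scird_response(img, bank, backend = "spatial")
  rel <- max(abs(r_fft$values - r_sp$values)) / max(abs(r_sp$values))
  expect_lt(rel, 1e-6)

  # single-kernel spot check against an explicit windowed sum
  bank1 <- scird_bank(sigma1 = 2, sigma2 = 1, k = 0, n_theta = 1,
                      halfsize = 6)
  r1 <- scird_response(img, bank1)
  ker <- scird_kernel(2, 1, 0, 0, 6)
  for (px in list(c(20, 20), c(1, 1), c(40, 3))) {
    expect_equal(r1$values[px[1], px[2]],
                 correlate_at_oracle(img, ker, px[1], px[2]),
                 tolerance = 1e-9)
  }
})

test_that("response is zero on a zero image and errors on bad input", {
  bank <- scird_bank(sigma1 = 2, sigma2 = 1, k = 0, n_theta = 2,
                     halfsize = 6)
  r <- scird_response(matrix(0, 30, 30), bank)
  expect_lt(max(abs(r$values)), 1e-12)
  expect_error(scird_response(matrix(NA_real_, 8, 8), bank), "finite")
  expect_error(scird_response(matrix(0, 30, 30), structure(list(),
    class = "scird_bank")))
})

test_that("centerline response dominates background on a straight ridge", {
  ph <- straight_vessel_phantom(grid = 90, width = 2)
  bank <- scird_bank(sigma1 = 4, sigma2 = c(1, 2), k = 0, n_theta = 4,
                     halfsize = 12)
  r <- scird_response(ph$intensity, bank)
  center <- mean(r$values[46, 15:75])     # y = 45 centerline (1-based row 46)
  far <- mean(r$values[66, 15:75])        # >= 6 px away
  expect_gt(center, far)
})

test_that("curvature kernels only add response on curved ridges", {
  cfg <- phantom_config(grid_size = 80, n_vessels = 0,
                        background_noise_sd = 0, seed = 2)
  ves <- data.frame(x0 = 10, y0 = 55, phi = -0.3, k = 0.05, width = 2,
                    length = 65)
  ph <- generate_vessel_network(cfg, vessels = ves)
  full <- scird_bank(sigma1 = 4, sigma2 = 1, k = c(-0.05, 0, 0.05),
                     n_theta = 6, halfsize = 12)
  k0 <- scird_bank(sigma1 = 4, sigma2 = 1, k = 0, n_theta = 6,
                   halfsize = 12)
  r_full <- scird_response(ph$intensity, full)$values
  r_k0 <- scird_response(ph$intensity, k0)$values
  expect_true(all(r_full - r_k0 >= -1e-12))  # max over a superset
  expect_gt(max(r_full - r_k0), 0)           # and strictly helps somewhere
})

test_that("responses are consistent under 90-degree rotation", {
  set.seed(19)
  ph <- straight_vessel_phantom(grid = 60, width = 2, noise = 0.02)
  bank <- scird_bank(sigma1 = 3, sigma2 = 1, k = c(-0.05, 0, 0.05),
                     n_theta = 4, halfsize = 9)  # theta closed under 90 deg
  r <- scird_response(ph$intensity, bank)$values
  r_rot <- scird_response(rot90(ph$intensity), bank)$values
  inner <- 15:45
  a <- rot90(r)[inner, inner]; b <- r_rot[inner, inner]
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-6)
})

test_that("centerline response is stable across vessel widths", {
  bank <- scird_bank(sigma1 = 4, sigma2 = c(1, 1.5, 2, 3), k = 0,
                     n_theta = 4, halfsize = 12)
  peak <- vapply(c(2, 3, 4), function(w) {
    ph <- straight_vessel_phantom(grid = 90, width = w)
    r <- scird_response(ph$intensity, bank)
    mean(r$values[46, 20:70])
  }, numeric(1))
  expect_lt((max(peak) - min(peak)) / max(peak), 0.25)
})

test_that("binarization honours thresholds and the row-major tie rule", {
  vals <- matrix(seq(0.01, 1, length.out = 100), 10, 10)
  expect_false(any(binarize_vessels(vals, "fixed", 2)))
  expect_identical(sum(binarize_vessels(vals, "percentile", 0.1)), 10L)
  expect_error(binarize_vessels(vals, "percentile", 1.2), "in \\(0, 1\\)")

  # ties straddling the cutoff: all values equal; keep ceil(0.1 * N)
  # pixels in row-major order (first row filled first)
  tied <- matrix(1, 10, 10)
  m <- binarize_vessels(tied, "percentile", 0.1)
  expect_identical(sum(m), 10L)
  # oracle: stable sort on (-value, row-major index)
  expect_true(all(m[1, ]))
  expect_false(any(m[-1, ]))
})
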