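# Grayscale conversion, bilinear resize, and the kurtosis-stopped
# anisotropic diffusion filter.

test_that("grayscale conversion uses BT.601 luma", {
  rgb <- array(100, c(4, 4, 3))
  expect_equal(to_grayscale(rgb), matrix(100, 4, 4))

  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(red), matrix(0.299 * 255, 2, 2))  # 76.245

  g <- matrix(runif(9, 0, 255), 3, 3)
  expect_identical(to_grayscale(g), g)

  expect_error(to_grayscale(array(0, c(2, 2, 2))), "channel")
})

test_that("bilinear resize matches the closed form and fixes degenerate cases", {
  img <- matrix(runif(224 * 224, 0, 255), 224, 224)
  expect_identical(resize_image(img, 224, 224), img)

  const <- matrix(7, 5, 9)
  expect_equal(resize_image(const, 13, 4), matrix(7, 13, 4))

  # 2x2 checkerboard {0,255} to 4x4: source coords (i-0.5)/2 + 0.5 clamped
  # to [1,2] give fractional offsets 0, .25, .75, 1 along each axis
  cb <- matrix(c(0, 255, 255, 0), 2, 2)
  out <- resize_image(cb, 4, 4)
  f <- c(0, 0.25, 0.75, 1)
  expected <- outer(f, f, function(a, b) {
    (1 - a) * (1 - b) * 0 + a * (1 - b) * 255 + (1 - a) * b * 255 + a * b * 0
  })
  expect_equal(out, expected)

  expect_error(resize_image(cb, 0, 4), "positive")
})

test_that("diffusion step matches a brute-force evaluation and conserves intensity", {
  const <- matrix(42, 6, 6)
  expect_equal(diffusion_step(const), const)

  # 3x3 single hot center pixel: hand-evaluated flux update
  img <- matrix(0, 3, 3); img[2, 2] <- 255
  out <- diffusion_step(img, kappa = 30, lam = 0.2)
  g255 <- exp(-(255 / 30)^2)
  expect_equal(out[2, 2], 255 + 0.2 * 4 * g255 * (-255))
  expect_equal(out[1, 2], 0 + 0.2 * g255 * 255)  # one hot neighbour (below)
  expect_equal(out[1, 1], 0)                     # reflecting corner, flat

  set.seed(31)
  for (rep in 1:5) {
    r <- matrix(runif(25, 0, 255), 5, 5)
    expect_equal(diffusion_step(r, 27, 0.17), naive_diffusion_step(r, 27, 0.17),
                 tolerance = 1e-12)
    # flux-form conservation under reflecting borders
    expect_equal(sum(diffusion_step(r)), sum(r), tolerance = 1e-6 * sum(r))
  }

  # kappa -> Inf limit: converges to the linear heat step (g = 1)
  r <- matrix(runif(25, 0, 255), 5, 5)
  heat <- r + 0.2 * ((dermfuse:::shift_up(r) - r) + (dermfuse:::shift_down(r) - r) +
                     (dermfuse:::shift_left(r) - r) + (dermfuse:::shift_right(r) - r))
  expect_equal(diffusion_step(r, kappa = 1e9, lam = 0.2), heat, tolerance = 1e-8)
})

test_that("noise component is the multiplicative residual", {
  A <- matrix(100, 4, 4)
  expect_equal(noise_component(A, A), matrix(0, 4, 4))
  expect_equal(noise_component(2 * A, A), matrix(1, 4, 4))

  set.seed(8)
  A0 <- matrix(runif(16, 10, 255), 4, 4)
  A <- matrix(runif(16, 10, 255), 4, 4)
  expect_equal(noise_component(A0, A), (A0 - A) / pmax(A, 1))

  expect_error(noise_component(A0, matrix(0, 2, 2)), "shape")
})

test_that("excess kurtosis matches closed forms", {
  set.seed(42)
  expect_lt(abs(excess_kurtosis(rnorm(1e6))), 0.02)
  expect_lt(abs(excess_kurtosis(runif(1e6)) - (-1.2)), 0.02)
  expect_equal(excess_kurtosis(rep(c(-1, 1), 50)), -2)
  expect_true(isTRUE(attr(excess_kurtosis(rep(5, 10)), "degenerate")))
  expect_error(excess_kurtosis(1:3), "at least 4")
})

test_that("intensity correlation is Pearson's r", {
  x <- matrix(rnorm(100), 10, 10)
  expect_equal(intensity_correlation(x, x), 1)
  expect_equal(intensity_correlation(x, -x), -1)
  set.seed(2)
  a <- matrix(rnorm(1e5), 250, 400); b <- matrix(rnorm(1e5), 250, 400)
  expect_lt(abs(intensity_correlation(a, b)), 0.02)
  expect_error(intensity_correlation(x, matrix(1, 10, 10)), "constant")
})

test_that("madf denoises speckled regions while keeping the edge, and records traces", {
  const <- matrix(50, 8, 8)
  res <- madf(const)
  expect_identical(res$stop_reason, "degenerate")
  expect_identical(res$filtered, const)

  fx <- two_region_fixture(64, 64, 100, 200, variance = 0.05, seed = 7)
  res <- madf(fx$noisy, diffusion_params())
  left <- 5:(fx$edge_col - 6); right <- (fx$edge_col + 7):60
  var_in <- c(stats::var(as.numeric(fx$noisy[, left])),
              stats::var(as.numeric(fx$noisy[, right])))
  var_out <- c(stats::var(as.numeric(res$filtered[, left])),
               stats::var(as.numeric(res$filtered[, right])))
  expect_true(all(var_out < 0.25 * var_in))
  step <- mean(abs(res$filtered[, fx$edge_col + 1] - res$filtered[, fx$edge_col]))
  expect_gte(step, 0.8 * 100)

  # trace contract
  expect_length(res$k_trace, res$iterations_run)
  expect_length(res$rho_image, res$iterations_run)
  expect_true(all(is.finite(res$k_trace)))
  if (res$stop_reason == "tolerance") {
    expect_lte(abs(res$k_trace[res$iterations_run]), 0.001)
  }
  expect_lte(res$iterations_run, diffusion_params()$max_iter)
})

test_that("flat-region variance is non-increasing over early diffusion iterations", {
  fx <- two_region_fixture(48, 48, 100, 200, variance = 0.05, seed = 12)
  A <- fx$noisy
  v_prev <- stats::var(as.numeric(A[, 5:18]))
  for (t in 1:10) {
    A <- diffusion_step(A)
    v <- stats::var(as.numeric(A[, 5:18]))
    expect_lte(v, v_prev + 1e-9)
    v_prev <- v
  }
})

test_that("reflecting borders behave as an exact mirror extension", {
  # with Neumann (replicate-ghost) borders, diffusing the mirror-doubled
  # image must equal the mirror-doubling of the diffused image, exactly
  fx <- two_region_fixture(24, 24, 100, 200, variance = 0.05, seed = 3)
  img <- fx$noisy
  ext <- img[c(24:1, 1:24), c(24:1, 1:24)]
  a <- img; b <- ext
  for (t in 1:5) {
    a <- diffusion_step(a)
    b <- diffusion_step(b)
  }
  expect_equal(b[25:48, 25:48], a, tolerance = 1e-12)
  expect_equal(b[24:1, 25:48], a, tolerance = 1e-12)  # symmetry preserved
})
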