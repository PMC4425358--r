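test_that("bars data matches its stated generative regime", {
  d <- generate_bars(seed = 1)
  expect_equal(dim(d$Y), c(2000, 25))
  expect_equal(dim(d$W_true), c(25, 10))
  expect_equal(colSums(d$W_true), rep(25, 10), tolerance = 1e-9)
  # on average two active bars per patch (binomial standard error)
  se <- sqrt(10 * 0.2 * 0.8 / 2000)
  expect_lt(abs(mean(d$k_true) - 2), 3 * se)
  # clean patches reproduce exactly from the stored latents
  expect_equal(d$Y_clean, render(d$S_true, d$W_true), tolerance = 1e-12)
  # determinism
  d2 <- generate_bars(seed = 1)
  expect_identical(d$Y, d2$Y)
  expect_error(generate_bars(H = 9))
  expect_error(generate_bars(H = 14, grid = 5))
})

test_that("pi = 0 bars are pure noise and sigma = 0 bars are exact renders", {
  d0 <- generate_bars(pi = 0, N = 500, seed = 2)
  expect_true(all(d0$k_true == 0))
  expect_lt(abs(mean(abs(d0$Y)) - 2 * sqrt(2 / pi)), 0.05)  # half-normal mean
  dn <- generate_bars(sigma = 1e-12, N = 200, seed = 3)
  one <- which(dn$k_true == 1)[1]
  h <- which(dn$S_true[one, ] != 0)
  expect_equal(dn$Y[one, ], dn$S_true[one, h] * dn$W_true[, h],
               tolerance = 1e-6)
})

test_that("stroke rasterization is opaque overwrite, not superposition", {
  d <- generate_strokes(canvas = 64, n_strokes = 30, patch = 9,
                        noise_sigma = 0, seed = 4)
  vals <- unique(as.vector(d$Y_clean))
  allowed <- c(0, d$meta$stroke_intensities)
  expect_true(all(vals %in% allowed))  # never sums of intensities
  expect_true(all(d$k_true <= d$meta$max_k))
  # determinism
  d2 <- generate_strokes(canvas = 64, n_strokes = 30, patch = 9,
                         noise_sigma = 0, seed = 4)
  expect_identical(d$Y, d2$Y)
})

test_that("stroke-free canvases give pure noise with zero labels", {
  d <- generate_strokes(canvas = 32, n_strokes = 0, patch = 9,
                        noise_sigma = 3, seed = 5)
  expect_true(all(d$k_true == 0))
  expect_equal(nrow(d$Y), (32 - 9 + 1)^2)
  expect_lt(abs(sd(as.vector(d$Y)) - 3), 0.1)
})

test_that("a single visible stroke yields its intensity and a count of one", {
  d <- generate_strokes(canvas = 48, n_strokes = 1, patch = 9,
                        noise_sigma = 0, seed = 6)
  hit <- which(apply(d$Y_clean, 1, max) > 0)
  expect_true(length(hit) > 0)
  expect_true(all(d$k_true[hit] == 1))
  expect_equal(max(d$Y_clean), d$meta$stroke_intensities[1])
})

test_that("defaults put window complexity in the 0..5 regime with a small discard tail", {
  d <- generate_strokes(seed = 7)
  n_total <- (256 - 9 + 1)^2
  expect_equal(nrow(d$Y) + d$meta$n_discarded, n_total)
  # retained count lands near the full window count (sub-2% discard tail)
  expect_gt(nrow(d$Y), 0.98 * n_total)
  expect_gt(mean(d$k_true), 0.5)
  expect_lt(mean(d$k_true), 3)
})

test_that("patch dataset extraction counts windows and noise correctly", {
  img <- matrix(7, 10, 10)
  d <- generate_patch_dataset(img, patch = 9, noise_sigma = 1e-12, seed = 8)
  expect_equal(nrow(d$Y), 4)  # (10-9+1)^2
  expect_true(all(abs(d$Y - 7) < 1e-9))
  expect_error(generate_patch_dataset(matrix(0, 5, 5), patch = 9))
  img2 <- matrix(runif(150 * 150, 0, 255), 150, 150)
  d2 <- generate_patch_dataset(img2, patch = 9, noise_sigma = 5, seed = 9)
  res <- d2$Y - d2$Y_clean
  expect_lt(abs(sd(as.vector(res)) - 5) / 5, 0.02)
})

test_that("ON/OFF channel split is nonnegative, disjoint and invertible", {
  expect_equal(split_channels(c(1, -2)), c(1, 0, 0, 2))
  x <- c(3, 0, 2)
  expect_equal(split_channels(x), c(x, 0, 0, 0))
  set.seed(10)
  for (i in 1:100) {
    v <- rnorm(7)
    out <- split_channels(v)
    expect_true(all(out >= 0))
    expect_true(all(out[1:7] * out[8:14] == 0))
    expect_equal(out[1:7] - out[8:14], v)
  }
})

test_that("contrast normalization scales to max 10 and keeps zero patches", {
  expect_equal(normalize_contrast(c(0, 5, 2.5)), c(0, 10, 5))
  expect_equal(normalize_contrast(rep(0, 4)), rep(0, 4))
  expect_error(normalize_contrast(c(-1, 2)))
  set.seed(11)
  out <- normalize_contrast(runif(50, 0, 3))
  expect_true(all(out >= 0 & out <= 10))
  expect_equal(max(out), 10)
})

test_that("pseudo-whitening shapes the spectrum like the ramp filter and kills DC", {
  set.seed(12)
  n <- 64
  img <- matrix(rnorm(n * n), n, n)
  out <- pseudo_whiten(img)
  expect_lt(abs(mean(out)), 1e-9)
  # white-noise input: output amplitude spectrum tracks the filter profile
  fr <- c(0:(n / 2), -(n / 2 - 1):-1)
  rho <- sqrt(outer(fr^2, fr^2, "+"))
  filt <- rho * exp(-(rho / (200 * n / 512))^4)
  amp <- Mod(fft(out))
  mid <- rho > 2 & rho < n / 2 & filt > 1e-3
  # per-bin white-noise amplitudes are noisy (Rayleigh), but the expected
  # amplitude is proportional to the filter profile
  expect_gt(cor(as.vector(amp[mid]), as.vector(filt[mid])), 0.45)
  # and binned means track the profile closely
  bins <- cut(rho[mid], 8)
  ratio <- tapply(amp[mid] / filt[mid], bins, mean)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.35)
  # not a projection: filtering twice differs from filtering once
  expect_gt(max(abs(pseudo_whiten(out) - out)), 1e-6)
  expect_error(pseudo_whiten(matrix(0, 4, 5)))
})
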