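make_dset <- function(s0, weighted, b = 1000, d = c(2, 2, 2)) {
  nv <- 1L + length(weighted)
  sig <- array(0, c(d, nv))
  sig[, , , 1] <- s0
  for (k in seq_along(weighted)) sig[, , , k + 1] <- weighted[[k]]
  diffusion_set(sig, c(0, rep(b, length(weighted))),
                rbind(NA, diag(3)[rep(1:3, length.out = length(weighted)), ]))
}

test_that("three-direction ADC inverts the geometric-mean attenuation", {
  d1 <- make_dset(1000, rep(list(vol(1000 * exp(-0.8), c(2, 2, 2))), 3))
  expect_equal(unique(as.vector(compute_adc_3dir(d1)$adc)), 0.8, tolerance = 1e-12)

  d2 <- make_dset(1000, rep(list(vol(1000, c(2, 2, 2))), 3))
  expect_equal(unique(as.vector(compute_adc_3dir(d2)$adc)), 0)

  # unequal per-direction attenuation averages arithmetically
  d3 <- make_dset(1000, lapply(c(0.3, 0.8, 1.3), function(e) vol(1000 * exp(-e), c(2, 2, 2))))
  expect_equal(unique(round(as.vector(compute_adc_3dir(d3)$adc), 12)), 0.8)

  # a fourth direction is not a valid input for the closed form
  sig4 <- array(1000, c(2, 2, 2, 5))
  d4 <- diffusion_set(sig4, c(0, rep(1000, 4)),
                      rbind(NA, diag(3), c(1, 1, 0) / sqrt(2)))
  expect_error(compute_adc_3dir(d4), class = "strokeclock_bad_acquisition")

  # non-positive signals are flagged invalid, not propagated
  w <- vol(1000 * exp(-0.8), c(2, 2, 2)); w[1, 1, 1] <- 0
  d5 <- make_dset(1000, list(w, w, w))
  r <- compute_adc_3dir(d5)
  expect_false(r$valid[1, 1, 1])
  expect_true(is.na(r$adc[1, 1, 1]))
})

test_that("tensor mean diffusivity recovers isotropic and anisotropic truth", {
  p <- make_phantom(small_spec(), 300, acquisition_preset("glasgow"))
  dset <- simulate_diffusion(p, sigma = 0)
  md <- compute_mean_diffusivity(dset)
  inb <- p$brain_mask
  expect_lt(max(abs(md$adc[inb] - p$maps$adc[inb]) / p$maps$adc[inb]), 1e-6)

  # diagonal tensor diag(1.2, 0.6, 0.6) um^2/ms -> MD = 0.8
  g <- diffusion_directions(20)
  dd <- c(1.2, 0.6, 0.6)
  sig <- array(0, c(2, 2, 2, 21))
  sig[, , , 1] <- 1000
  for (k in 1:20) sig[, , , k + 1] <- 1000 * exp(-1000 * sum(dd * g[k, ]^2) * 1e-3)
  dset2 <- diffusion_set(sig, c(0, rep(1000, 20)), rbind(NA, g))
  md2 <- compute_mean_diffusivity(dset2)
  expect_equal(unique(round(as.vector(md2$adc), 10)), 0.8)

  # five directions cannot determine six tensor components
  sig5 <- array(1000, c(2, 2, 2, 6))
  d5 <- diffusion_set(sig5, c(0, rep(1000, 5)), rbind(NA, diffusion_directions(5)))
  expect_error(compute_mean_diffusivity(d5), class = "strokeclock_bad_acquisition")
})

test_that("effective DWI reproduces the b = 1000 attenuation", {
  expect_equal(unique(as.vector(effective_dwi(vol(1000), vol(0.5)))),
               1000 * exp(-0.5))  # ~606.53
  expect_equal(effective_dwi(vol(1000), vol(0)), vol(1000))
})

test_that("effective DWI of the 3-direction ADC equals the geometric mean", {
  set.seed(7)
  d3 <- c(3, 3, 2)
  s0 <- array(stats::runif(prod(d3), 500, 1500), d3)
  ws <- lapply(1:3, function(i) s0 * exp(-array(stats::runif(prod(d3), 0.2, 1.2), d3)))
  dset <- make_dset(s0, ws, d = d3)
  lhs <- effective_dwi(s0, compute_adc_3dir(dset)$adc)
  gm <- (ws[[1]] * ws[[2]] * ws[[3]])^(1 / 3)
  expect_lt(max(abs(lhs - gm) / gm), 1e-10)
})

test_that("echo summation adds the TE series voxelwise", {
  e1 <- echo_series(vol(7, c(2, 2, 2)), te = 50)
  expect_equal(echo_sum_t2w(e1), vol(7, c(2, 2, 2)))

  sig <- array(3, c(2, 2, 2, 5))
  e5 <- echo_series(sig, te = c(20, 40, 60, 80, 100))
  expect_equal(echo_sum_t2w(e5), vol(15, c(2, 2, 2)))

  # closed form: PD 100, T2 80 over the 5-echo train
  te <- c(20, 40, 60, 80, 100)
  sig2 <- array(0, c(2, 2, 2, 5))
  for (k in 1:5) sig2[, , , k] <- 100 * exp(-te[k] / 80)
  expect_equal(unique(round(as.vector(echo_sum_t2w(echo_series(sig2, te))), 4)),
               round(100 * sum(exp(-te / 80)), 4))  # 255.2064
})

test_that("mono-exponential T2 fitting recovers noiseless decays exactly", {
  # two-point log-linear solution
  sig <- array(0, c(2, 2, 2, 2))
  sig[, , , 1] <- 100 * exp(-20 / 80); sig[, , , 2] <- 100 * exp(-100 / 80)
  f <- fit_t2_map(echo_series(sig, c(20, 100)))
  expect_equal(unique(round(as.vector(f$t2), 9)), 80)
  expect_equal(unique(round(as.vector(f$s0), 9)), 100)

  # flat series has no finite decay constant
  flat <- echo_series(array(50, c(2, 2, 2, 3)), c(10, 50, 90))
  ff <- fit_t2_map(flat)
  expect_true(all(!ff$valid))
  expect_true(all(is.na(ff$t2)))

  # three-echo TSE-style train
  te <- c(9.5, 66, 123)
  sig3 <- array(0, c(2, 2, 2, 3))
  for (k in 1:3) sig3[, , , k] <- 1000 * exp(-te[k] / 150)
  f3 <- fit_t2_map(echo_series(sig3, te))
  expect_equal(unique(round(as.vector(f3$t2), 8)), 150)

  expect_error(fit_t2_map(flat, method = "bogus"), class = "strokeclock_bad_method")
})

test_that("log-linear and nonlinear T2 fits agree on noiseless data", {
  skip_if_not_installed("minpack.lm")
  sp <- phantom_spec(grid_dim = c(16, 16, 8), lesion_center = c(5, 9, 4),
                     lesion_semiaxes = c(2, 2, 2), noise_model = "none")
  p <- make_phantom(sp, 300, acquisition_preset("glasgow"))
  e <- simulate_echo_series(p, sigma = 0)
  a <- fit_t2_map(e, "loglin")
  b <- fit_t2_map(e, "nonlinear")
  inb <- p$brain_mask
  expect_lt(max(abs(a$t2[inb] - b$t2[inb]) / a$t2[inb]), 1e-3)
})

test_that("quantitative maps are invariant to global intensity scaling", {
  p <- make_phantom(tiny_spec(), 300, acquisition_preset("bristol"))
  p <- simulate_signals(p, sigma = 0)
  m1 <- quant_maps(p)
  p2 <- p
  p2$signals$echo$signals <- p$signals$echo$signals * 3.7
  p2$signals$diffusion$signals <- p$signals$diffusion$signals * 3.7
  m2 <- quant_maps(p2)
  inb <- p$brain_mask
  expect_equal(m1$t2[inb], m2$t2[inb], tolerance = 1e-12)
  expect_equal(m1$adc[inb], m2$adc[inb], tolerance = 1e-12)
})

test_that("raising weighted signals at fixed S0 strictly lowers ADC", {
  set.seed(3)
  d3 <- c(3, 3, 2)
  s0 <- array(stats::runif(prod(d3), 500, 1500), d3)
  ws <- lapply(1:3, function(i) s0 * exp(-array(stats::runif(prod(d3), 0.3, 1), d3)))
  base <- compute_adc_3dir(make_dset(s0, ws, d = d3))$adc
  up <- compute_adc_3dir(make_dset(s0, lapply(ws, function(w) w * 1.25), d = d3))$adc
  expect_true(all(up < base))
})
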