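test_that("acquisition parameter invariants are enforced", {
  expect_error(acquisition_params(echo_times = c(40, 20)), "strictly increasing")
  expect_error(acquisition_params(echo_times = c(20, 40), b_values = c(1000, 1000)),
               "include 0")
  expect_error(acquisition_params(echo_times = 20, flair_TI = 3000, flair_TR = 2500,
                                  flair_TE = 90), "TI < TR")
  # site-style FLAIR timings are accepted
  ox <- acquisition_preset("oxford")
  expect_equal(ox$flair_TR, 9000)
  expect_equal(ox$flair_TE, 96)
  expect_equal(ox$flair_TI, 2500)
  expect_equal(acquisition_preset("bristol")$echo_times, c(20, 40, 60, 80, 100))
})

test_that("lesion T2 follows the linear growth model", {
  sp0 <- small_spec(t2_slope_per_min = 0)
  p0 <- make_phantom(sp0, 400)
  expect_equal(unique(p0$maps$t2[p0$lesion_mask]), 80)

  sp <- small_spec(t2_slope_per_min = 6.0e-4)
  p <- make_phantom(sp, 270)
  expect_equal(unique(p$maps$t2[p$lesion_mask]), 80 * 1.162, tolerance = 1e-12)
})

test_that("phantoms with equal spec differ only in lesion T2 across onsets", {
  sp <- small_spec()
  a <- make_phantom(sp, 180)
  b <- make_phantom(sp, 480)
  expect_identical(a$lesion_mask, b$lesion_mask)
  expect_identical(a$brain_mask, b$brain_mask)
  expect_identical(a$maps$adc, b$maps$adc)
  same <- a$maps$t2 == b$maps$t2
  expect_true(all(same[a$brain_mask & !a$lesion_mask]))
  expect_true(all(!same[a$lesion_mask]))
})

test_that("invalid lesion geometry is rejected", {
  expect_error(phantom_spec(lesion_center = c(3, 36, 12), lesion_semiaxes = c(5, 6, 4)),
               class = "strokeclock_lesion_out_of_grid")
  expect_error(phantom_spec(lesion_center = c(32, 36, 12), lesion_semiaxes = c(5, 6, 4)),
               class = "strokeclock_lesion_bilateral")
  expect_error(make_phantom(small_spec(), -5), class = "strokeclock_bad_onset")
})

test_that("echo series follows the mono-exponential forward model", {
  sp <- small_spec()  # non-ischemic tissue: PD 100, T2 80 ms
  p <- make_phantom(sp, 300, acquisition_preset("bristol"))
  e <- simulate_echo_series(p, sigma = 0)
  expect_equal(dim(e$signals)[4], 5L)  # one volume per echo of the 5-TE train
  bg <- p$brain_mask & !p$lesion_mask & !p$csf_mask
  s_te80 <- e$signals[, , , 4][bg]
  expect_equal(unique(round(s_te80, 6)), round(100 * exp(-1), 6))
  expect_error(simulate_echo_series(p, sigma = -0.1), class = "strokeclock_bad_sigma")
})

test_that("diffusion forward model attenuates isotropically", {
  sp <- small_spec(tissues = list(
    nonischemic = list(adc = 0.8, t2 = 80, pd = 1000, t1 = 1200),
    csf = list(adc = 3.0, t2 = 2000, pd = 1000, t1 = 4000),
    lesion = list(adc = 0.5, t2_baseline = 80, pd = 1000, t1 = 1400)
  ))
  p <- make_phantom(sp, 300, acquisition_preset("bristol"))
  d <- simulate_diffusion(p, sigma = 0)
  bg <- p$brain_mask & !p$lesion_mask & !p$csf_mask
  expect_equal(unique(round(d$signals[, , , 1][bg], 6)), 1000)  # b = 0 volume is S0
  s1 <- d$signals[, , , 2][bg]
  expect_equal(unique(round(s1, 4)), round(1000 * exp(-0.8), 4))  # 449.3290
  # isotropic: all three direction volumes identical
  expect_identical(d$signals[, , , 2], d$signals[, , , 3])
  expect_identical(d$signals[, , , 2], d$signals[, , , 4])
})

test_that("FLAIR nulls a compartment at TI = T1 ln 2 and suppresses CSF", {
  # null point: inversion factor vanishes when TI = T1 ln 2 and TR >> T1
  acq_null <- acquisition_params(echo_times = c(20, 60), b_values = c(0, 1000, 1000, 1000),
                                 flair_TI = 1200 * log(2), flair_TR = 5e5, flair_TE = 90)
  p <- make_phantom(small_spec(), 300, acq_null)
  fl <- simulate_flair(p, sigma = 0)
  bg <- p$brain_mask & !p$lesion_mask & !p$csf_mask  # tissue T1 = 1200 ms
  expect_lt(max(abs(fl[bg])), 1e-3)

  # default glasgow-style timings: CSF well below 10% of tissue signal
  p2 <- make_phantom(small_spec(), 300, acquisition_preset("glasgow"))
  fl2 <- simulate_flair(p2, sigma = 0)
  bg2 <- p2$brain_mask & !p2$lesion_mask & !p2$csf_mask
  expect_lt(mean(fl2[p2$csf_mask]) / mean(fl2[bg2]), 0.10)

  # missing T1 values make the inversion model unusable
  sp_no_t1 <- small_spec(tissues = list(
    nonischemic = list(adc = 0.77, t2 = 80, pd = 100),
    csf = list(adc = 3.0, t2 = 2000, pd = 120),
    lesion = list(adc = 0.5, t2_baseline = 80, pd = 100)
  ))
  p3 <- make_phantom(sp_no_t1, 300, acquisition_preset("glasgow"))
  expect_error(simulate_flair(p3, sigma = 0), class = "strokeclock_missing_t1")
})

test_that("cohort sampler reproduces the clinical class balance", {
  co <- make_cohort(n = 35, spec = tiny_spec(), seed = 11)
  expect_equal(nrow(co$truth), 35L)
  expect_equal(sum(co$truth$label), 16L)
  expect_equal(sum(1 - co$truth$label), 19L)
  expect_equal(sum(co$truth$flair), 17L)
  expect_equal(sum(co$truth$label[co$truth$flair]), 5L)

  sub <- make_cohort(n = 17, preset = "flair_subcohort", spec = tiny_spec(), seed = 11)
  expect_equal(sum(sub$truth$label), 5L)
  expect_equal(sum(1 - sub$truth$label), 12L)

  expect_error(make_cohort(n = 1), class = "strokeclock_bad_cohort")
})

test_that("identical seeds give identical cohorts", {
  a <- make_cohort(n = 4, spec = tiny_spec(noise_model = "rician"), seed = 5)
  b <- make_cohort(n = 4, spec = tiny_spec(noise_model = "rician"), seed = 5)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients[[2]]$signals$echo$signals,
                   b$patients[[2]]$signals$echo$signals)
  expect_identical(a$patients[[3]]$signals$diffusion$signals,
                   b$patients[[3]]$signals$diffusion$signals)
})

test_that("Rician noise biases fitted T2 upward, less so at higher signal", {
  te <- c(20, 40, 60, 80, 100)
  d <- c(12, 12, 8)
  sigma_abs <- 2
  pd_grid <- c(6, 12, 30, 100)
  set.seed(42)
  bias <- vapply(pd_grid, function(pd) {
    sig <- array(0, c(d, length(te)))
    for (k in seq_along(te))
      sig[, , , k] <- add_rician_noise(array(pd * exp(-te[k] / 80), d), sigma_abs)
    fit <- fit_t2_map(echo_series(sig, te))
    mean(fit$t2, na.rm = TRUE) - 80
  }, numeric(1))
  expect_gt(bias[1], 0)                      # low SNR: positive T2 bias
  expect_true(all(diff(bias) < 0))           # bias shrinks as PD grows
  expect_lt(abs(bias[length(bias)]), 2)      # nearly unbiased at high SNR
})
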