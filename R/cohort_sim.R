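#' Simulate a hyperacute stroke cohort
#'
#' Generates `n` virtual patients with simulated signal volumes and a ground
#' truth table. The default (`preset = "full"`) emulates a 35-patient
#' hyperacute cohort scanned 2.4--9.5 h from onset with 16 patients within and
#' 19 beyond the 270-minute thrombolysis window, of whom 17 also received a
#' FLAIR scan (5 within / 12 beyond). `preset = "flair_subcohort"` emulates
#' the 17-patient FLAIR subcohort on its own. Within/beyond counts are fixed
#' by the preset proportions (rounded for non-default `n`); onset times are
#' drawn uniformly inside the group-specific ranges observed clinically.
#'
#' Every patient is simulated with one common protocol (glasgow-style by
#' default); FLAIR is simulated only for the subcohort patients. Keeping the
#' diffusion/echo protocol identical across the cohort matters: the two
#' subgroups have different within/beyond class balances, so any
#' protocol-dependent measurement bias (e.g. ADC estimator noise differing
#' between 3- and 20-direction schemes interacting with the ADC-window
#' selection) would masquerade as timing information in a parameter that is
#' constructed to carry none.
#'
#' Per-patient biological variability: the lesion centre, semi-axes and
#' hemisphere are jittered, and the lesion T2 response is scaled by a
#' patient-specific factor ~ N(1, lesion_t2_sd^2) so T2 ratios overlap across
#' the window boundary as they do in real cohorts. The lesion ADC is held at
#' the spec value, so ADC carries no timing information by construction.
#'
#' @param n number of patients (>= 2).
#' @param preset `"full"` or `"flair_subcohort"`.
#' @param spec a [phantom_spec()] shared by the cohort.
#' @param onset_sampler optional `function(n)` returning onset minutes; when
#'   supplied, labels follow the sampled onsets instead of preset counts.
#' @param lesion_t2_sd standard deviation of the patient-specific lesion T2
#'   scaling factor (default 0.03).
#' @param acquisition the common [acquisition_params()] protocol (default
#'   glasgow-style preset, the only one with FLAIR timings that strongly
#'   suppress CSF).
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return object of class `stroke_cohort`: list with `patients` (list of
#'   `virtual_patient` with signals), `truth` (data.frame: id, onset_min,
#'   label, flair, site), `spec`, `seed`.
#' @export
make_cohort <- function(n = 35L, preset = c("full", "flair_subcohort"),
                        spec = phantom_spec(), onset_sampler = NULL,
                        lesion_t2_sd = 0.03,
                        acquisition = acquisition_preset("glasgow"), seed = 1L) {
  preset <- match.arg(preset)
  n <- as.integer(n)
  if (n < 2L) stop_strokeclock("bad_cohort", "a cohort needs at least 2 patients")
  set.seed(as.integer(seed))

  if (preset == "full") {
    n_flair <- round(n * 17 / 35)
    w_flair <- round(n_flair * 5 / 17)
    w_noflair <- round(n * 16 / 35) - w_flair
    groups <- data.frame(
      flair = c(rep(FALSE, n - n_flair), rep(TRUE, n_flair)),
      within = c(rep(TRUE, w_noflair), rep(FALSE, n - n_flair - w_noflair),
                 rep(TRUE, w_flair), rep(FALSE, n_flair - w_flair))
    )
    rng <- list(
      noflair_within = c(145, 265), noflair_beyond = c(308, 569),
      flair_within = c(148, 190),   flair_beyond = c(334, 569)
    )
  } else {
    w <- round(n * 5 / 17)
    groups <- data.frame(
      flair = rep(TRUE, n),
      within = c(rep(TRUE, w), rep(FALSE, n - w))
    )
    rng <- list(flair_within = c(148, 190), flair_beyond = c(334, 569))
  }

  if (is.null(onset_sampler)) {
    onset <- numeric(n)
    for (i in seq_len(n)) {
      key <- paste0(if (groups$flair[i]) "flair" else "noflair",
                    if (groups$within[i]) "_within" else "_beyond")
      r <- rng[[key]] %||% rng[[sub("noflair", "flair", key)]]
      onset[i] <- stats::runif(1, r[1], r[2])
    }
  } else {
    onset <- onset_sampler(n)
    if (length(onset) != n || any(onset <= 0))
      stop_strokeclock("bad_cohort", "onset_sampler must return n positive onset minutes")
    groups$within <- onset <= 270
  }

  d <- spec$grid_dim
  mid <- (d[1] + 1) / 2
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    # jitter lesion geometry within the hemisphere
    jc <- spec$lesion_center + round(stats::runif(3, -2, 2) * d / c(64, 64, 24))
    js <- pmax(2, spec$lesion_semiaxes + round(stats::runif(3, -1, 1)))
    side_right <- stats::runif(1) < 19 / 35
    if (side_right) jc[1] <- d[1] + 1 - jc[1]
    u <- 1 + stats::rnorm(1, 0, lesion_t2_sd)
    ts <- spec$tissues
    ts$lesion$t2_baseline <- ts$lesion$t2_baseline * max(u, 0.5)
    pspec <- phantom_spec(
      grid_dim = spec$grid_dim, voxel_mm = spec$voxel_mm, tissues = ts,
      lesion_center = jc, lesion_semiaxes = js,
      t2_slope_per_min = spec$t2_slope_per_min,
      noise_sigma = spec$noise_sigma, noise_model = spec$noise_model,
      seed = spec$seed
    )
    p <- make_phantom(pspec, onset[i], acquisition = acquisition)
    patients[[i]] <- simulate_signals(p, with_flair = groups$flair[i])
  }

  truth <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    onset_min = onset,
    label = as.integer(onset <= 270),
    flair = groups$flair,
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, truth = truth, spec = spec, seed = seed),
            class = "stroke_cohort")
}
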