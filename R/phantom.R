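#' Specification of a synthetic stroke phantom
#'
#' Defines the geometry, tissue parameters and noise model of a three-
#' compartment digital brain phantom (non-ischemic tissue, CSF, one unilateral
#' ischemic lesion) on a pre-registered axial grid. The first array axis is
#' left/right; the mid-sagittal midline sits between the two central sagittal
#' planes at x = (nx + 1) / 2 voxel units.
#'
#' The ischemic lesion is an ellipsoid confined to one hemisphere (bilateral
#' lesions are rejected, mirroring the usual bilateral-stroke exclusion). Its
#' T2 grows linearly with time from onset, T2(t) = T2_baseline * (1 + slope * t),
#' while its ADC is depressed and constant in time.
#'
#' @param grid_dim grid size in voxels, length 3 (default 64 x 64 x 24).
#' @param voxel_mm voxel edge lengths in mm (default 2 mm isotropic).
#' @param tissues named list with elements `nonischemic`, `csf`, `lesion`;
#'   each a list with `adc` (um^2/ms), `t2` (ms; for the lesion `t2_baseline`),
#'   `pd` (proton density, arbitrary units) and `t1` (ms, used only by FLAIR).
#' @param lesion_center ellipsoid centre in voxel coordinates (1-based).
#' @param lesion_semiaxes ellipsoid semi-axes in voxels.
#' @param t2_slope_per_min fractional lesion T2 growth per minute (>= 0);
#'   default 6.0e-4 /min.
#' @param noise_sigma Rician channel noise, expressed as a fraction of the
#'   non-ischemic tissue proton density (default 0.03).
#' @param noise_model `"rician"` (magnitude MR data), `"gaussian"` (debugging),
#'   or `"none"`.
#' @param seed integer seed recorded with the spec; [make_cohort()] uses it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(64L, 64L, 24L),
                         voxel_mm = c(2, 2, 2),
                         tissues = list(
                           nonischemic = list(adc = 0.77, t2 = 80,  pd = 100, t1 = 1200),
                           csf         = list(adc = 3.00, t2 = 2000, pd = 120, t1 = 4000),
                           lesion      = list(adc = 0.50, t2_baseline = 80, pd = 100, t1 = 1400)
                         ),
                         lesion_center = c(18, 36, 12),
                         lesion_semiaxes = c(5, 6, 4),
                         t2_slope_per_min = 6.0e-4,
                         noise_sigma = 0.03,
                         noise_model = c("rician", "gaussian", "none"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L || any(grid_dim < 8L))
    stop_strokeclock("bad_spec", "grid_dim must be three dimensions of at least 8 voxels")
  if (t2_slope_per_min < 0)
    stop_strokeclock("bad_spec", "t2_slope_per_min must be >= 0")
  if (noise_sigma < 0)
    stop_strokeclock("bad_sigma", "noise_sigma must be >= 0")
  for (cls in c("nonischemic", "csf", "lesion")) {
    p <- tissues[[cls]]
    if (is.null(p)) stop_strokeclock("bad_spec", "missing tissue class '%s'", cls)
    t2v <- if (cls == "lesion") p$t2_baseline else p$t2
    if (is.null(t2v) || t2v <= 0 || is.null(p$adc) || p$adc <= 0)
      stop_strokeclock("bad_spec", "tissue class '%s' needs positive ADC and T2", cls)
  }
  # lesion inside the grid
  lo <- lesion_center - lesion_semiaxes
  hi <- lesion_center + lesion_semiaxes
  if (any(lo < 1) || any(hi > grid_dim))
    stop_strokeclock("lesion_out_of_grid", "lesion ellipsoid extends outside the grid")
  # lesion confined to one hemisphere (strictly off the midline)
  mid <- (grid_dim[1] + 1) / 2
  if (lo[1] < mid && hi[1] > mid)
    stop_strokeclock("lesion_bilateral", "lesion crosses the mid-sagittal plane")
  structure(
    list(
      grid_dim = grid_dim, voxel_mm = as.numeric(voxel_mm), tissues = tissues,
      lesion_center = as.numeric(lesion_center),
      lesion_semiaxes = as.numeric(lesion_semiaxes),
      t2_slope_per_min = t2_slope_per_min,
      noise_sigma = noise_sigma, noise_model = noise_model,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Logical ellipsoid mask on an integer voxel grid (voxel-centre based).
ellipsoid_mask <- function(grid_dim, center, semiaxes) {
  x <- ((seq_len(grid_dim[1]) - center[1]) / semiaxes[1])^2
  y <- ((seq_len(grid_dim[2]) - center[2]) / semiaxes[2])^2
  z <- ((seq_len(grid_dim[3]) - center[3]) / semiaxes[3])^2
  outer(outer(x, y, "+"), z, "+") <= 1
}

# Fixed symmetric anatomy: a brain ellipsoid and two mirrored ventricles,
# proportional to the grid so small test grids keep the same layout.
phantom_anatomy <- function(spec) {
  d <- spec$grid_dim
  ctr <- (d + 1) / 2
  brain <- ellipsoid_mask(d, ctr, c(0.44 * d[1], 0.44 * d[2], 0.42 * d[3]))
  voff <- 0.086 * d[1]
  vsemi <- c(0.047 * d[1], 0.094 * d[2], 0.125 * d[3])
  csf <- ellipsoid_mask(d, c(ctr[1] - voff, ctr[2], ctr[3]), vsemi) |
    ellipsoid_mask(d, c(ctr[1] + voff, ctr[2], ctr[3]), vsemi)
  csf <- csf & brain
  list(brain = brain, csf = csf)
}

#' Build a virtual patient (ground truth only)
#'
#' Lays tissue classes onto the grid and fills the ground-truth parameter maps
#' (ADC, T2, proton density, T1). The lesion T2 is
#' `t2_baseline * (1 + slope * onset_minutes)`; lesion voxels take precedence
#' over CSF where the ellipsoids would overlap. The result is fully
#' deterministic: all randomness lives in the signal simulators and the
#' cohort sampler.
#'
#' @param spec a [phantom_spec()].
#' @param onset_minutes time from symptom onset (minutes, > 0).
#' @param acquisition optional [acquisition_params()] attached to the patient.
#' @return object of class `virtual_patient` with elements `maps` (adc, t2,
#'   pd, t1 arrays; NA outside the brain, pd 0 outside), `brain_mask`,
#'   `lesion_mask`, `csf_mask`, `onset_minutes`, `spec`, `acquisition` and an
#'   initially empty `signals` list.
#' @export
make_phantom <- function(spec, onset_minutes, acquisition = NULL) {
  if (!inherits(spec, "phantom_spec")) stop_strokeclock("bad_spec", "spec must be a phantom_spec")
  if (!is.numeric(onset_minutes) || onset_minutes <= 0)
    stop_strokeclock("bad_onset", "onset_minutes must be > 0")
  anat <- phantom_anatomy(spec)
  d <- spec$grid_dim
  lesion <- ellipsoid_mask(d, spec$lesion_center, spec$lesion_semiaxes)
  lesion <- lesion & anat$brain  # ischemia is confined to brain tissue
  if (!any(lesion))
    stop_strokeclock("lesion_out_of_grid", "lesion ellipsoid misses the brain compartment")

  ts <- spec$tissues
  lesion_t2 <- ts$lesion$t2_baseline * (1 + spec$t2_slope_per_min * onset_minutes)

  adc <- array(NA_real_, d); t2 <- array(NA_real_, d)
  pd <- array(0, d);         t1 <- array(NA_real_, d)
  fill <- function(map, mask, val) { map[mask] <- val; map }
  adc <- fill(adc, anat$brain, ts$nonischemic$adc)
  t2  <- fill(t2,  anat$brain, ts$nonischemic$t2)
  pd  <- fill(pd,  anat$brain, ts$nonischemic$pd)
  t1  <- fill(t1,  anat$brain, ts$nonischemic$t1 %||% NA_real_)
  adc <- fill(adc, anat$csf, ts$csf$adc)
  t2  <- fill(t2,  anat$csf, ts$csf$t2)
  pd  <- fill(pd,  anat$csf, ts$csf$pd)
  t1  <- fill(t1,  anat$csf, ts$csf$t1 %||% NA_real_)
  adc <- fill(adc, lesion, ts$lesion$adc)
  t2  <- fill(t2,  lesion, lesion_t2)
  pd  <- fill(pd,  lesion, ts$lesion$pd)
  t1  <- fill(t1,  lesion, ts$lesion$t1 %||% NA_real_)

  structure(
    list(
      onset_minutes = onset_minutes,
      maps = list(adc = adc, t2 = t2, pd = pd, t1 = t1),
      brain_mask = anat$brain, lesion_mask = lesion, csf_mask = anat$csf & !lesion,
      spec = spec, acquisition = acquisition, signals = list()
    ),
    class = "virtual_patient"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_sigma <- function(patient, sigma) {
  if (is.null(sigma)) sigma <- patient$spec$noise_sigma
  if (!is.numeric(sigma) || sigma < 0)
    stop_strokeclock("bad_sigma", "noise sigma must be >= 0")
  sigma * patient$spec$tissues$nonischemic$pd
}

#' Simulate a multi-echo T2 signal series
#'
#' Forward model of the mono-exponential decay fitted by [fit_t2_map()]:
#' noiseless signal `PD * exp(-TE / T2)` per voxel, one volume per echo time,
#' optionally corrupted with Rician noise.
#'
#' @param patient a [make_phantom()] result.
#' @param params an [acquisition_params()]; defaults to the patient's.
#' @param sigma noise level as a fraction of non-ischemic tissue proton
#'   density; default taken from the phantom spec. Must be >= 0.
#' @param noise_model overrides the spec's noise model.
#' @return an `echo_series`: list with `signals` (4D array, echo index last)
#'   and `te` (ms).
#' @export
simulate_echo_series <- function(patient, params = patient$acquisition,
                                 sigma = NULL, noise_model = NULL) {
  if (is.null(params)) stop_strokeclock("bad_acquisition", "no acquisition parameters supplied")
  sig_abs <- resolve_sigma(patient, sigma)
  model <- noise_model %||% patient$spec$noise_model
  te <- params$echo_times
  d <- patient$spec$grid_dim
  pd <- patient$maps$pd
  t2 <- patient$maps$t2
  out <- array(0, c(d, length(te)))
  decay <- array(0, d)
  inb <- patient$brain_mask
  for (k in seq_along(te)) {
    decay[inb] <- pd[inb] * exp(-te[k] / t2[inb])
    out[, , , k] <- apply_noise(decay, sig_abs, model)
  }
  echo_series(out, te)
}

#' Construct an echo series container
#'
#' @param signals 4D array with the echo index on the fourth dimension (a 3D
#'   array is treated as a single echo).
#' @param te echo times in ms, strictly increasing, one per volume.
#' @return object of class `echo_series`.
#' @export
echo_series <- function(signals, te) {
  if (length(dim(signals)) == 3L) dim(signals) <- c(dim(signals), 1L)
  if (dim(signals)[4] != length(te))
    stop_strokeclock("bad_acquisition", "one volume per echo time required")
  if (is.unsorted(te, strictly = TRUE))
    stop_strokeclock("bad_acquisition", "echo times must be strictly increasing")
  structure(list(signals = signals, te = as.numeric(te)), class = "echo_series")
}

#' Construct a diffusion set container
#'
#' One signal volume per acquired b value; b = 0 volumes carry no direction.
#'
#' @param signals 4D array, volume index last.
#' @param b numeric vector of b values (s/mm^2), one per volume, including 0.
#' @param directions matrix with one row per volume (rows for b = 0 volumes
#'   are ignored and may be NA).
#' @return object of class `diffusion_set`.
#' @export
diffusion_set <- function(signals, b, directions) {
  if (length(dim(signals)) == 3L) dim(signals) <- c(dim(signals), 1L)
  if (dim(signals)[4] != length(b))
    stop_strokeclock("bad_acquisition", "one volume per b value required")
  if (!any(b == 0)) stop_strokeclock("bad_acquisition", "b values must include 0")
  if (min(signals, na.rm = TRUE) < 0)
    stop_strokeclock("bad_signal", "diffusion signals must be non-negative")
  directions <- as.matrix(directions)
  if (nrow(directions) != length(b))
    stop_strokeclock("bad_acquisition", "one direction row per volume required")
  structure(
    list(signals = signals, b = as.numeric(b), directions = directions,
         n_directions = nrow(unique(round(directions[b > 0, , drop = FALSE], 10)))),
    class = "diffusion_set"
  )
}

#' Simulate a multi-b-value diffusion series
#'
#' Isotropic forward model `S = S0 * exp(-b * ADC * 1e-3)` with ADC in
#' um^2/ms and b in s/mm^2; identical across gradient directions unless an
#' `anisotropy` vector is given, in which case the effective diffusivity along
#' unit direction g is `ADC * sum(anisotropy * g^2)` (a diagonal tensor whose
#' axis multipliers average to the stated ADC when `mean(anisotropy) == 1`).
#'
#' @inheritParams simulate_echo_series
#' @param anisotropy optional length-3 axis multipliers; `NULL` = isotropic.
#' @return a [diffusion_set()].
#' @export
simulate_diffusion <- function(patient, params = patient$acquisition,
                               sigma = NULL, noise_model = NULL, anisotropy = NULL) {
  if (is.null(params)) stop_strokeclock("bad_acquisition", "no acquisition parameters supplied")
  sig_abs <- resolve_sigma(patient, sigma)
  model <- noise_model %||% patient$spec$noise_model
  b <- params$b_values
  dirs <- diffusion_directions(params$n_directions)
  d <- patient$spec$grid_dim
  s0 <- patient$maps$pd
  adc <- patient$maps$adc
  nvol <- length(b)
  out <- array(0, c(d, nvol))
  dir_rows <- matrix(NA_real_, nvol, 3)
  inb <- patient$brain_mask
  wi <- 0L
  vol <- array(0, d)
  for (k in seq_len(nvol)) {
    if (b[k] == 0) {
      vol[] <- s0
    } else {
      wi <- wi + 1L
      g <- dirs[(wi - 1L) %% nrow(dirs) + 1L, ]
      dir_rows[k, ] <- g
      eff <- if (is.null(anisotropy)) 1 else sum(anisotropy * g^2)
      vol[] <- 0
      vol[inb] <- s0[inb] * exp(-b[k] * adc[inb] * eff * 1e-3)
    }
    out[, , , k] <- apply_noise(vol, sig_abs, model)
  }
  diffusion_set(out, b, dir_rows)
}

#' Simulate a T2w FLAIR volume
#'
#' Inversion-recovery-attenuated T2-weighted signal,
#' `PD * |1 - 2 exp(-TI/T1) + exp(-TR/T1)| * exp(-TE/T2)`,
#' with per-compartment T1 from the phantom spec. With the default timings
#' (TI 2500 ms, TR 10000 ms) CSF (T1 ~ 4000 ms at 3T) is strongly suppressed
#' relative to parenchyma.
#'
#' @inheritParams simulate_echo_series
#' @return 3D signal array.
#' @export
simulate_flair <- function(patient, params = patient$acquisition,
                           sigma = NULL, noise_model = NULL) {
  if (is.null(params) || !isTRUE(params$has_flair))
    stop_strokeclock("bad_acquisition", "acquisition has no FLAIR settings")
  if (anyNA(patient$maps$t1[patient$brain_mask]))
    stop_strokeclock("missing_t1", "FLAIR simulation needs T1 values for every tissue class")
  sig_abs <- resolve_sigma(patient, sigma)
  model <- noise_model %||% patient$spec$noise_model
  ti <- params$flair_TI; tr <- params$flair_TR; te <- params$flair_TE
  d <- patient$spec$grid_dim
  out <- array(0, d)
  inb <- patient$brain_mask
  t1 <- patient$maps$t1[inb]; t2 <- patient$maps$t2[inb]; pd <- patient$maps$pd[inb]
  out[inb] <- pd * abs(1 - 2 * exp(-ti / t1) + exp(-tr / t1)) * exp(-te / t2)
  apply_noise(out, sig_abs, model)
}

#' Simulate every signal volume of a patient's protocol
#'
#' @inheritParams simulate_echo_series
#' @param with_flair simulate the FLAIR volume where the protocol has one
#'   (set FALSE for patients outside the FLAIR subcohort).
#' @return the patient with its `signals` list populated (`echo`, `diffusion`
#'   and, where the protocol has one, `flair`).
#' @export
simulate_signals <- function(patient, params = patient$acquisition,
                             sigma = NULL, noise_model = NULL, with_flair = TRUE) {
  patient$acquisition <- params
  patient$signals$echo <- simulate_echo_series(patient, params, sigma, noise_model)
  patient$signals$diffusion <- simulate_diffusion(patient, params, sigma, noise_model)
  if (isTRUE(params$has_flair) && isTRUE(with_flair))
    patient$signals$flair <- simulate_flair(patient, params, sigma, noise_model)
  patient
}
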