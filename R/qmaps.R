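#' ADC map from a three-direction diffusion set
#'
#' Orientation-independent apparent diffusion coefficient from a single b > 0
#' shell acquired along three orthogonal directions:
#' `ADC = -ln(S1*S2*S3 / S0^3) / (3b)`, converted to um^2/ms (exponent
#' convention `b * ADC * 1e-3` with b in s/mm^2). Multiple b = 0 volumes are
#' averaged into S0. Voxels with any non-positive signal are flagged invalid.
#'
#' @param d a [diffusion_set()] with exactly 3 weighted volumes / directions.
#' @return list with `adc` (um^2/ms; NA where invalid) and logical `valid`.
#' @export
compute_adc_3dir <- function(d) {
  if (!inherits(d, "diffusion_set")) stop_strokeclock("bad_input", "need a diffusion_set")
  w <- which(d$b > 0)
  if (length(w) != 3L || d$n_directions != 3L)
    stop_strokeclock("bad_acquisition", "compute_adc_3dir requires exactly 3 weighted directions")
  b <- unique(d$b[w])
  if (length(b) != 1L)
    stop_strokeclock("bad_acquisition", "weighted volumes must share one b value")
  d3 <- dim(d$signals)[1:3]
  z <- which(d$b == 0)
  s0 <- apply(d$signals[, , , z, drop = FALSE], 1:3, mean)
  s1 <- d$signals[, , , w[1]]; s2 <- d$signals[, , , w[2]]; s3 <- d$signals[, , , w[3]]
  valid <- s0 > 0 & s1 > 0 & s2 > 0 & s3 > 0
  valid <- na_false(valid)
  adc <- array(NA_real_, d3)
  adc[valid] <- -1000 * log(s1[valid] * s2[valid] * s3[valid] / s0[valid]^3) / (3 * b)
  list(adc = adc, valid = valid)
}

#' Mean diffusivity from a multi-direction diffusion set
#'
#' Ordinary log-linear least-squares tensor fit per voxel over >= 6
#' non-collinear gradient directions; mean diffusivity is trace/3 in um^2/ms.
#' On isotropic input MD equals the scalar ADC.
#'
#' @param d a [diffusion_set()] with at least 6 distinct directions.
#' @return list with `adc` (MD, um^2/ms) and logical `valid`.
#' @export
compute_mean_diffusivity <- function(d) {
  if (!inherits(d, "diffusion_set")) stop_strokeclock("bad_input", "need a diffusion_set")
  w <- which(d$b > 0)
  if (d$n_directions < 6L)
    stop_strokeclock("bad_acquisition", "tensor fit requires at least 6 directions (got %d)",
                     d$n_directions)
  G <- d$directions[w, , drop = FALSE]
  bvec <- d$b[w]
  X <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
             2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3]) * bvec * 1e-3
  if (qr(X)$rank < 6L)
    stop_strokeclock("bad_acquisition", "direction set is rank deficient for a tensor fit")
  d3 <- dim(d$signals)[1:3]
  z <- which(d$b == 0)
  s0 <- apply(d$signals[, , , z, drop = FALSE], 1:3, mean)
  nw <- length(w)
  V <- matrix(d$signals[, , , w], ncol = nw)
  valid <- s0 > 0 & array(matrixStats_all_pos(V), d3)
  valid <- na_false(valid)
  idx <- which(valid)
  adc <- array(NA_real_, d3)
  if (length(idx)) {
    Y <- -log(V[idx, , drop = FALSE] / s0[idx])     # idx x nw
    D <- qr.solve(X, t(Y))                          # 6 x n
    adc[idx] <- (D[1, ] + D[2, ] + D[3, ]) / 3
  }
  list(adc = adc, valid = valid)
}

matrixStats_all_pos <- function(V) {
  out <- rep(TRUE, nrow(V))
  for (j in seq_len(ncol(V))) out <- out & V[, j] > 0
  out
}

#' Effective diffusion-weighted image
#'
#' Synthesizes a b = 1000 s/mm^2 DWI from the unweighted signal and the ADC
#' map: `DWI = S0 * exp(-1000 * ADC * 1e-3)` with ADC in um^2/ms. Invalid
#' (NA) ADC voxels propagate NA.
#'
#' @param s0 unweighted signal volume.
#' @param adc ADC volume in um^2/ms.
#' @return DWI signal volume.
#' @export
effective_dwi <- function(s0, adc) {
  check_same_grid(s0, adc)
  s0 * exp(-adc)
}

#' Echo-summed T2-weighted image
#'
#' Voxelwise sum of all echoes of the TE series (no bias-field handling:
#' synthetic volumes are bias-free; a pre-corrected volume can be substituted
#' upstream).
#'
#' @param e an [echo_series()].
#' @return T2w signal volume.
#' @export
echo_sum_t2w <- function(e) {
  if (!inherits(e, "echo_series")) stop_strokeclock("bad_input", "need an echo_series")
  ne <- dim(e$signals)[4]
  out <- e$signals[, , , 1]
  if (ne > 1) for (k in 2:ne) out <- out + e$signals[, , , k]
  out
}

#' Voxelwise mono-exponential T2 map
#'
#' Fits `S(TE) = S0 * exp(-TE / T2)` per voxel. The default `"loglin"` method
#' is weighted least squares on the log-signal with weights proportional to
#' the squared signal (the first-order variance weighting that makes the
#' log-domain fit match the signal-domain objective); `"nonlinear"` refines
#' the log-linear start with Levenberg-Marquardt (minpack.lm) per voxel and is
#' intended for small volumes. Voxels with any non-positive signal, a
#' non-decaying series, or T2 outside (0, 5000] ms are flagged invalid.
#'
#' @param e an [echo_series()] with >= 2 echoes.
#' @param method `"loglin"` (default) or `"nonlinear"`.
#' @return list with `t2` (ms), `s0`, `residual` (per-voxel RMS of the signal
#'   domain residuals) and logical `valid`.
#' @export
fit_t2_map <- function(e, method = c("loglin", "nonlinear")) {
  if (!inherits(e, "echo_series")) stop_strokeclock("bad_input", "need an echo_series")
  if (!is.character(method)) stop_strokeclock("bad_method", "unknown T2 fitting method")
  method <- tryCatch(match.arg(method),
                     error = function(e) stop_strokeclock("bad_method", "unknown T2 fitting method"))
  te <- e$te
  if (length(te) < 2L)
    stop_strokeclock("bad_acquisition", "T2 fitting needs at least 2 echoes")
  d3 <- dim(e$signals)[1:3]
  ne <- length(te)
  V <- matrix(e$signals, ncol = ne)
  pos <- matrixStats_all_pos(V)
  pos <- pos & !is.na(pos)

  t2 <- array(NA_real_, d3); s0 <- array(NA_real_, d3); res <- array(NA_real_, d3)
  idx <- which(pos)
  if (length(idx)) {
    Vp <- V[idx, , drop = FALSE]
    W <- Vp^2
    Y <- log(Vp)
    sw <- rowSums(W)
    swx <- as.vector(W %*% te)
    swxx <- as.vector(W %*% te^2)
    swy <- rowSums(W * Y)
    swxy <- as.vector(rowSums(W * Y * rep(te, each = nrow(W))))
    den <- sw * swxx - swx^2
    slope <- (sw * swxy - swx * swy) / den
    inter <- (swy - slope * swx) / sw
    t2v <- -1 / slope
    s0v <- exp(inter)
    ok <- is.finite(t2v) & t2v > 0 & t2v <= 5000
    if (method == "nonlinear") {
      if (!requireNamespace("minpack.lm", quietly = TRUE))
        stop_strokeclock("bad_method", "nonlinear refinement needs the minpack.lm package")
      for (j in which(ok)) {
        fitj <- tryCatch(
          minpack.lm::nlsLM(y ~ a * exp(-te / b),
                            data = list(y = Vp[j, ], te = te),
                            start = list(a = s0v[j], b = t2v[j]),
                            control = minpack.lm::nls.lm.control(maxiter = 50)),
          error = function(e) NULL)
        if (!is.null(fitj)) {
          cf <- stats::coef(fitj)
          s0v[j] <- cf[["a"]]; t2v[j] <- cf[["b"]]
        }
      }
      ok <- ok & is.finite(t2v) & t2v > 0 & t2v <= 5000
    }
    fitted <- s0v * exp(-outer(1 / t2v, te))  # s0 * exp(-te / t2), voxels x echoes
    resv <- sqrt(rowMeans((Vp - fitted)^2))
    sel <- idx[ok]
    t2[sel] <- t2v[ok]; s0[sel] <- s0v[ok]; res[sel] <- resv[ok]
  }
  valid <- array(FALSE, d3)
  valid[idx] <- TRUE
  valid <- valid & !is.na(t2)
  list(t2 = t2, s0 = s0, residual = res, valid = valid)
}

#' Compute the full quantitative map set for one patient
#'
#' Runs the T2 fit, the echo sum, the ADC route matching the protocol
#' (three-direction closed form, or the tensor mean-diffusivity fit for
#' >= 6 directions) and the effective DWI; passes FLAIR through unchanged.
#'
#' @param patient a `virtual_patient` with populated `signals`.
#' @param t2_method passed to [fit_t2_map()].
#' @return object of class `quant_map_set`: list with `adc`, `dwi`, `t2w`,
#'   `t2`, `s0_fit`, `residual`, optional `flair`, logical `valid`, and
#'   `voxel_mm`.
#' @export
quant_maps <- function(patient, t2_method = "loglin") {
  sig <- patient$signals
  if (is.null(sig$echo) || is.null(sig$diffusion))
    stop_strokeclock("bad_input", "patient signals not simulated; see simulate_signals()")
  fit <- fit_t2_map(sig$echo, method = t2_method)
  t2w <- echo_sum_t2w(sig$echo)
  dset <- sig$diffusion
  adc <- if (dset$n_directions >= 6L) compute_mean_diffusivity(dset) else compute_adc_3dir(dset)
  z <- which(dset$b == 0)
  s0 <- apply(dset$signals[, , , z, drop = FALSE], 1:3, mean)
  dwi <- effective_dwi(s0, adc$adc)
  structure(
    list(adc = adc$adc, dwi = dwi, t2w = t2w, t2 = fit$t2, s0_fit = fit$s0,
         residual = fit$residual, flair = sig$flair,
         valid = adc$valid & fit$valid, voxel_mm = patient$spec$voxel_mm),
    class = "quant_map_set"
  )
}
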