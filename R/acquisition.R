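#' Acquisition parameters for a multiparametric stroke MRI protocol
#'
#' Bundles the sequence timings needed to simulate and fit the three signal
#' sources used throughout the package: a multi-echo T2 train (echo times),
#' a multi-b-value diffusion series (b values with multiplicities and the
#' number of distinct gradient directions) and, optionally, a T2w FLAIR
#' acquisition (inversion time, repetition time, echo time).
#'
#' @param echo_times echo times TE in ms, strictly increasing, all > 0.
#' @param t2w_TR repetition time of the multi-echo sequence (ms), metadata only.
#' @param b_values vector of b values in s/mm^2, one entry per acquired
#'   diffusion volume (so multiplicities are expressed by repetition);
#'   must include at least one b = 0 entry.
#' @param n_directions number of independent diffusion gradient directions
#'   used for the b > 0 volumes.
#' @param flair_TI,flair_TR,flair_TE FLAIR inversion/repetition/echo times in
#'   ms, or `NULL` if the protocol has no FLAIR. `flair_TI < flair_TR` required.
#' @return an object of class `acq_params`.
#' @seealso [acquisition_preset()] for ready-made site-style protocols.
#' @export
acquisition_params <- function(echo_times, t2w_TR = NA_real_,
                               b_values = c(0, 1000, 1000, 1000),
                               n_directions = 3L,
                               flair_TI = NULL, flair_TR = NULL, flair_TE = NULL) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1L || any(echo_times <= 0))
    stop_strokeclock("bad_acquisition", "echo times must be positive")
  if (is.unsorted(echo_times, strictly = TRUE))
    stop_strokeclock("bad_acquisition", "echo times must be strictly increasing")
  b_values <- as.numeric(b_values)
  if (!any(b_values == 0))
    stop_strokeclock("bad_acquisition", "b values must include 0")
  if (any(b_values < 0))
    stop_strokeclock("bad_acquisition", "b values must be non-negative")
  has_flair <- !is.null(flair_TI)
  if (has_flair) {
    if (is.null(flair_TR) || is.null(flair_TE))
      stop_strokeclock("bad_acquisition", "FLAIR needs TI, TR and TE")
    if (flair_TI >= flair_TR)
      stop_strokeclock("bad_acquisition", "FLAIR requires TI < TR")
  }
  structure(
    list(
      echo_times = echo_times, t2w_TR = t2w_TR,
      b_values = b_values, n_directions = as.integer(n_directions),
      flair_TI = flair_TI, flair_TR = flair_TR, flair_TE = flair_TE,
      has_flair = has_flair
    ),
    class = "acq_params"
  )
}

#' Site-style acquisition presets
#'
#' Three presets styled after typical 3T hyperacute-stroke protocols:
#' \describe{
#'   \item{bristol}{5-echo GRASE-style T2 train (20--100 ms), 3-direction
#'     diffusion at b = 1000 s/mm^2, no FLAIR.}
#'   \item{glasgow}{3-echo TSE T2 train (9.5, 66, 123 ms), 20-direction
#'     diffusion with 3 b = 0 volumes, FLAIR with TI 2500 / TR 10000 / TE 93 ms.}
#'   \item{oxford}{3-echo TSE T2 train (7.7, 77, 177 ms), 3-direction
#'     diffusion, FLAIR with TI 2500 / TR 9000 / TE 96 ms.}
#' }
#'
#' @param site one of `"glasgow"` (default), `"bristol"`, `"oxford"`.
#' @return an [acquisition_params()] object.
#' @export
acquisition_preset <- function(site = c("glasgow", "bristol", "oxford")) {
  site <- match.arg(site)
  switch(site,
    bristol = acquisition_params(
      echo_times = c(20, 40, 60, 80, 100), t2w_TR = 3000,
      b_values = c(0, 1000, 1000, 1000), n_directions = 3L
    ),
    glasgow = acquisition_params(
      echo_times = c(9.5, 66, 123), t2w_TR = 12500,
      b_values = c(rep(0, 3), rep(1000, 20)), n_directions = 20L,
      flair_TI = 2500, flair_TR = 10000, flair_TE = 93
    ),
    oxford = acquisition_params(
      echo_times = c(7.7, 77, 177), t2w_TR = 12000,
      b_values = c(0, 1000, 1000, 1000), n_directions = 3L,
      flair_TI = 2500, flair_TR = 9000, flair_TE = 96
    )
  )
}

#' Evenly spread unit gradient directions
#'
#' Identity axes for n = 3, otherwise a Fibonacci-sphere arrangement, which is
#' well conditioned for the log-linear tensor fit at n >= 6.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
diffusion_directions <- function(n) {
  n <- as.integer(n)
  if (n == 3L) return(diag(3))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
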