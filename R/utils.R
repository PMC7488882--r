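# Internal helpers shared across modules.

stop_strokeclock <- function(subclass, msg, ...) {
  cond <- structure(
    class = c(paste0("strokeclock_", subclass), "strokeclock_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  stop(cond)
}

check_same_grid <- function(...) {
  dims <- lapply(list(...), function(v) dim(v)[1:3])
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) identical(as.integer(d), as.integer(ref)), logical(1))
  if (!all(ok)) stop_strokeclock("grid_mismatch", "volumes do not share one grid")
  invisible(ref)
}

# Replace NA with FALSE in a logical array (threshold tests on invalid voxels fail).
na_false <- function(x) {
  x[is.na(x)] <- FALSE
  x
}

#' Add Rician noise to a magnitude signal array
#'
#' Magnitude MR data are Rician distributed: the noiseless signal is corrupted
#' by independent Gaussian noise in two quadrature channels and the magnitude
#' is taken. At low signal-to-noise this biases intensities upward.
#'
#' @param x numeric array of noiseless signal intensities.
#' @param sigma Gaussian channel noise standard deviation (same units as `x`);
#'   must be non-negative.
#' @return array of the same shape with Rician-corrupted values (all >= 0).
#' @export
add_rician_noise <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop_strokeclock("bad_sigma", "noise sigma must be a single non-negative number")
  if (sigma == 0) return(x)
  n <- length(x)
  out <- sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  array(out, dim = dim(x))
}

add_gaussian_noise <- function(x, sigma) {
  if (sigma < 0) stop_strokeclock("bad_sigma", "noise sigma must be non-negative")
  if (sigma == 0) return(x)
  x + array(stats::rnorm(length(x), 0, sigma), dim = dim(x))
}

apply_noise <- function(x, sigma, model = c("rician", "gaussian", "none")) {
  model <- match.arg(model)
  switch(model,
    rician = add_rician_noise(x, sigma),
    gaussian = add_gaussian_noise(x, sigma),
    none = x
  )
}

#' Write a volume as NIfTI-1
#'
#' Thin wrapper around [RNifti::writeNifti()]; writes uncompressed `.nii` so
#' that repeated runs of the pipeline produce byte-identical files.
#'
#' @param x 3D or 4D numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_mm voxel edge lengths in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_mm = c(2, 2, 2)) {
  img <- RNifti::asNifti(x)
  nd <- length(dim(x))
  RNifti::pixdim(img) <- c(voxel_mm, rep(1, nd - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return numeric array with a `voxel_mm` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_mm") <- vox
  out
}
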