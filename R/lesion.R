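#' Segmentation configuration
#'
#' Threshold rules used to identify ischemic voxels on quantitative maps.
#' A voxel is ischemic iff `adc_low < ADC < adc_high`, ADC is more than one
#' half-width-half-maximum below the median non-ischemic ADC, and
#' `t2_low < T2 < t2_high` (the T2 window suppresses CSF).
#'
#' @param adc_low,adc_high ADC window in um^2/ms (defaults 0.30 / 0.55; the
#'   clinically reported plausible ranges are 0.2--0.4 and 0.55--0.6).
#' @param t2_low,t2_high T2 window in ms (defaults 30 / 200).
#' @param hwhm_rule enable the adaptive median-minus-HWHM rule (default TRUE).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param secondary_cluster_fraction keep secondary clusters at least this
#'   fraction of the largest cluster's volume (default 0.5).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(adc_low = 0.30, adc_high = 0.55,
                                t2_low = 30, t2_high = 200,
                                hwhm_rule = TRUE,
                                connectivity = 26L,
                                secondary_cluster_fraction = 0.5) {
  if (adc_low >= adc_high) stop_strokeclock("bad_config", "adc_low must be < adc_high")
  if (t2_low >= t2_high) stop_strokeclock("bad_config", "t2_low must be < t2_high")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_strokeclock("bad_config", "connectivity must be 6, 18 or 26")
  if (secondary_cluster_fraction < 0 || secondary_cluster_fraction > 1)
    stop_strokeclock("bad_config", "secondary_cluster_fraction must be in [0,1]")
  structure(
    list(adc_low = adc_low, adc_high = adc_high, t2_low = t2_low, t2_high = t2_high,
         hwhm_rule = isTRUE(hwhm_rule), connectivity = as.integer(connectivity),
         secondary_cluster_fraction = secondary_cluster_fraction),
    class = "segmentation_config"
  )
}

#' Median and HWHM of non-ischemic ADC
#'
#' Median ADC over non-ischemic brain voxels (brain minus the candidate
#' lesion) and the half-width at half-maximum of their kernel-smoothed ADC
#' histogram (Gaussian kernel, Silverman's rule bandwidth). For a Gaussian
#' ADC distribution HWHM ~ 1.177 * sigma. A degenerate (constant) histogram
#' returns a vanishing HWHM flagged with attribute `degenerate`.
#'
#' @param adc ADC volume (um^2/ms).
#' @param brain_mask logical brain mask.
#' @param candidate_mask logical candidate lesion mask (excluded voxels).
#' @return list with `median` and `hwhm` (um^2/ms).
#' @export
nonischemic_adc_stats <- function(adc, brain_mask, candidate_mask = NULL) {
  if (is.null(candidate_mask)) candidate_mask <- array(FALSE, dim(adc))
  check_same_grid(adc, brain_mask, candidate_mask)
  vals <- adc[brain_mask & !candidate_mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop_strokeclock("empty_nonischemic", "no non-ischemic voxels to estimate ADC statistics")
  med <- stats::median(vals)
  if (length(unique(vals)) < 2L || stats::sd(vals) == 0) {
    hwhm <- structure(1e-6, degenerate = TRUE)
  } else {
    den <- stats::density(vals, bw = "nrd0", n = 1024)
    imax <- which.max(den$y)
    half <- den$y[imax] / 2
    left <- half_crossing(den$x, den$y, imax, half, side = "left")
    right <- half_crossing(den$x, den$y, imax, half, side = "right")
    hwhm <- (right - left) / 2
  }
  list(median = med, hwhm = as.numeric(hwhm))
}

# Linear interpolation of the half-maximum crossing of a density curve.
half_crossing <- function(x, y, imax, half, side) {
  if (side == "left") {
    below <- which(y[seq_len(imax)] < half)
    if (!length(below)) return(x[1])
    i <- max(below)
    x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
  } else {
    below <- which(y[imax:length(y)] < half)
    if (!length(below)) return(x[length(x)])
    i <- imax + min(below) - 1L
    x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
  }
}

#' Segment candidate ischemic voxels
#'
#' Applies the ADC window, the adaptive median-minus-HWHM rule and the T2
#' window of the [segmentation_config()]. The HWHM rule is circular (the
#' non-ischemic statistics need a lesion estimate), resolved with one
#' bootstrap pass: the initial non-ischemic set is the brain minus the
#' ADC-window pass, after which all thresholds are applied once.
#'
#' @param adc,t2 quantitative maps on one grid (NA = invalid voxel, never
#'   selected).
#' @param brain_mask logical brain mask.
#' @param cfg a [segmentation_config()].
#' @return list with `mask` (logical candidate mask) and `stats`
#'   (non-ischemic median/HWHM used). Signals a classed `strokeclock_no_lesion`
#'   error if no voxel survives (the phantom analogue of "no evident lesion").
#' @export
segment_ischemic <- function(adc, t2, brain_mask, cfg = segmentation_config()) {
  check_same_grid(adc, t2, brain_mask)
  window <- na_false(adc > cfg$adc_low & adc < cfg$adc_high) & brain_mask
  st <- nonischemic_adc_stats(adc, brain_mask, candidate_mask = window)
  mask <- window
  if (cfg$hwhm_rule) mask <- mask & na_false(adc < st$median - st$hwhm)
  mask <- mask & na_false(t2 > cfg$t2_low & t2 < cfg$t2_high)
  if (!any(mask))
    stop_strokeclock("no_lesion", "no voxel satisfies the ischemic criteria")
  list(mask = mask, stats = st)
}

# Half-set of neighbor offsets for the requested connectivity.
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- switch(as.character(connectivity),
    "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
    "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
    "26" = g
  )
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) | (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

#' Label connected components of a voxel mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[r, ], nrow(coord), 3, byrow = TRUE)
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
    j <- match(lin, idx)
    sel <- inside & !is.na(j)
    from <- c(from, which(sel)); to <- c(to, j[sel])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Refine a candidate mask to the principal cluster(s)
#'
#' Keeps the largest connected component plus any component whose volume is at
#' least `secondary_cluster_fraction` of the largest (allowing multiple
#' lesions); reports the lesion volume in mL.
#'
#' @param mask logical candidate mask (non-empty).
#' @param cfg a [segmentation_config()].
#' @param voxel_mm voxel edge lengths in mm.
#' @return list with `mask`, `n_clusters` kept, `volume_ml`.
#' @export
refine_clusters <- function(mask, cfg = segmentation_config(), voxel_mm = c(2, 2, 2)) {
  if (!any(mask)) stop_strokeclock("no_lesion", "empty mask has no clusters")
  lab <- label_components(mask, cfg$connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= cfg$secondary_cluster_fraction * max(sizes))
  out <- array(lab %in% keep, dim(mask))
  list(mask = out, n_clusters = length(keep),
       volume_ml = sum(out) * prod(voxel_mm) / 1000)
}

# Reflect a mask about the mid-sagittal plane within each axial slice.
reflect_mask <- function(mask) {
  mask[rev(seq_len(dim(mask)[1])), , , drop = FALSE]
}

#' Mirrored non-ischemic reference VOI
#'
#' Reflects the ischemic VOI about the midline of each axial slice (the
#' central sagittal plane of the registered frame) and removes reflected
#' voxels whose T2 falls outside the CSF-exclusion window — the automated
#' stand-in for manually editing visible CSF out of the reference region.
#'
#' @param voi_mask logical ischemic VOI, entirely within one hemisphere.
#' @param t2 T2 map (ms).
#' @param cfg a [segmentation_config()] providing the T2 window.
#' @return logical reference mask.
#' @export
mirror_reference <- function(voi_mask, t2, cfg = segmentation_config()) {
  check_same_grid(voi_mask, t2)
  ref <- reflect_mask(voi_mask)
  if (any(ref & voi_mask))
    stop_strokeclock("lesion_bilateral",
                     "VOI touches the midline; reflected reference overlaps the lesion")
  ref <- ref & na_false(t2 > cfg$t2_low & t2 < cfg$t2_high)
  if (!any(ref))
    stop_strokeclock("empty_reference", "T2 limits removed every reference voxel")
  ref
}

#' Identify the ischemic VOI and its mirrored reference
#'
#' Convenience wrapper running [segment_ischemic()], [refine_clusters()] and
#' [mirror_reference()] in sequence.
#'
#' @inheritParams segment_ischemic
#' @param voxel_mm voxel edge lengths in mm.
#' @return object of class `voi_pair`: list with `ischemic`, `reference`
#'   (disjoint logical masks), `nonischemic_stats` (median/HWHM of
#'   non-ischemic ADC), `volume_ml` and `n_clusters`.
#' @export
find_voi <- function(adc, t2, brain_mask, cfg = segmentation_config(),
                     voxel_mm = c(2, 2, 2)) {
  seg <- segment_ischemic(adc, t2, brain_mask, cfg)
  ref1 <- refine_clusters(seg$mask, cfg, voxel_mm)
  ref <- mirror_reference(ref1$mask, t2, cfg)
  structure(
    list(ischemic = ref1$mask, reference = ref,
         nonischemic_stats = seg$stats,
         volume_ml = ref1$volume_ml, n_clusters = ref1$n_clusters),
    class = "voi_pair"
  )
}
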