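#' Ischemic-to-reference image intensity ratio
#'
#' The timing biomarker: mean map value over the ischemic VOI divided by the
#' mean over the mirrored non-ischemic reference VOI, computed on each map's
#' native units (ms for T2, um^2/ms for ADC, arbitrary units for weighted
#' images). Invalid (NA) voxels are dropped from the means.
#'
#' @param map a quantitative or weighted volume.
#' @param voi a `voi_pair` (see [find_voi()]), or any list with logical
#'   `ischemic` and `reference` masks.
#' @return the ratio (dimensionless scalar).
#' @export
intensity_ratio <- function(map, voi) {
  check_same_grid(map, voi$ischemic, voi$reference)
  if (!any(voi$ischemic) || !any(voi$reference))
    stop_strokeclock("empty_voi", "both VOI masks must be non-empty")
  mi <- mean(map[voi$ischemic], na.rm = TRUE)
  mr <- mean(map[voi$reference], na.rm = TRUE)
  if (!is.finite(mr) || mr == 0)
    stop_strokeclock("empty_voi", "reference VOI mean is zero or undefined")
  mi / mr
}

#' Assemble the cohort analysis table
#'
#' One row per patient with onset time, the within-window label and one
#' intensity ratio per available map type. Maps missing for a patient (e.g.
#' FLAIR outside the subcohort) are recorded as NA, not errors.
#'
#' @param patients list of `virtual_patient` (or any objects with
#'   `onset_minutes`), or a data.frame with `id` and `onset_min` columns.
#' @param map_sets list of `quant_map_set`, one per patient.
#' @param vois list of `voi_pair`, one per patient.
#' @param window_min treatment window in minutes (default 270).
#' @param strict_boundary if TRUE the label rule is `onset < window_min`;
#'   default FALSE uses `onset <= window_min` (the boundary patient counts as
#'   within; no clinical cohort sits exactly on the boundary).
#' @return data.frame (`cohort_table`) with columns id, onset_min, label,
#'   ratio_adc, ratio_dwi, ratio_t2w, ratio_t2, ratio_flair, lesion_ml.
#' @export
build_cohort_table <- function(patients, map_sets, vois, window_min = 270,
                               strict_boundary = FALSE) {
  n <- length(map_sets)
  if (length(vois) != n)
    stop_strokeclock("bad_input", "one map set and VOI pair per patient required")
  if (is.data.frame(patients)) {
    ids <- patients$id; onset <- patients$onset_min
  } else {
    onset <- vapply(patients, function(p) p$onset_minutes, numeric(1))
    ids <- sprintf("P%03d", seq_len(n))
  }
  ratio_or_na <- function(map, voi) {
    if (is.null(map)) return(NA_real_)
    intensity_ratio(map, voi)
  }
  rows <- lapply(seq_len(n), function(i) {
    m <- map_sets[[i]]; v <- vois[[i]]
    data.frame(
      id = ids[i], onset_min = onset[i],
      label = if (strict_boundary) as.integer(onset[i] < window_min)
              else as.integer(onset[i] <= window_min),
      ratio_adc = ratio_or_na(m$adc, v),
      ratio_dwi = ratio_or_na(m$dwi, v),
      ratio_t2w = ratio_or_na(m$t2w, v),
      ratio_t2 = ratio_or_na(m$t2, v),
      ratio_flair = ratio_or_na(m$flair, v),
      lesion_ml = v$volume_ml,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Run maps, VOI and ratios over a simulated cohort
#'
#' Per-patient pipeline: quantitative maps, lesion VOI with mirrored
#' reference, intensity ratios; assembles the cohort table. Patients in whom
#' no lesion is found are excluded (recorded in the `excluded` attribute),
#' mirroring the usual no-evident-lesion exclusion.
#'
#' @param cohort a [make_cohort()] result.
#' @param cfg a [segmentation_config()].
#' @param window_min treatment window in minutes.
#' @return a `cohort_table` data.frame (see [build_cohort_table()]) with the
#'   cohort's truth `flair`/`site` columns joined.
#' @export
analyze_cohort <- function(cohort, cfg = segmentation_config(), window_min = 270) {
  n <- length(cohort$patients)
  maps <- vector("list", n); vois <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    m <- quant_maps(p)
    v <- tryCatch(find_voi(m$adc, m$t2, p$brain_mask, cfg, p$spec$voxel_mm),
                  strokeclock_no_lesion = function(e) NULL)
    if (!is.null(v)) {
      maps[[i]] <- m; vois[[i]] <- v; keep[i] <- TRUE
    }
  }
  truth <- cohort$truth
  tab <- build_cohort_table(truth[keep, , drop = FALSE], maps[keep], vois[keep],
                            window_min = window_min)
  tab$flair <- truth$flair[keep][match(tab$id, truth$id[keep])]
  attr(tab, "excluded") <- truth$id[!keep]
  tab
}
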