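# End-to-end orchestration: simulate -> maps -> voi -> ratios -> evaluate,
# with a file manifest so a run is fully reproducible from its config.

#' Pipeline run configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param n cohort size.
#' @param preset cohort preset, see [make_cohort()].
#' @param seed integer seed controlling the whole run.
#' @param window_min treatment window in minutes (> 0).
#' @param flair simulate/evaluate FLAIR and the mismatch reading (default TRUE;
#'   when FALSE every patient uses the non-FLAIR protocol).
#' @param spec a [phantom_spec()].
#' @param segmentation a [segmentation_config()].
#' @param t2_method T2 fitting method, see [fit_t2_map()].
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, n = 35L, preset = "full", seed = 7L,
                       window_min = 270, flair = TRUE,
                       spec = phantom_spec(), segmentation = segmentation_config(),
                       t2_method = "loglin") {
  if (!is.numeric(window_min) || window_min <= 0)
    stop_strokeclock("config_error", "window_min must be > 0")
  if (!is.numeric(n) || n < 2)
    stop_strokeclock("config_error", "cohort size must be >= 2")
  structure(
    list(out_dir = out_dir, n = as.integer(n), preset = preset,
         seed = as.integer(seed), window_min = window_min, flair = isTRUE(flair),
         spec = spec, segmentation = segmentation, t2_method = t2_method),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: out_dir, n_patients, preset, seed, window_min, flair,
#' t2_method, and nested `segmentation` / `phantom` blocks passed to
#' [segmentation_config()] and [phantom_spec()]. (The cohort size is spelled
#' `n_patients` because a bare `n` is a YAML 1.1 boolean.)
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_config, y$segmentation %||% list())
  spec <- do.call(phantom_spec, y$phantom %||% list())
  run_config(
    out_dir = y$out_dir %||% ".", n = y$n_patients %||% 35L,
    preset = y$preset %||% "full",
    seed = y$seed %||% 7L, window_min = y$window_min %||% 270,
    flair = y$flair %||% TRUE, spec = spec, segmentation = seg,
    t2_method = y$t2_method %||% "loglin"
  )
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

cohort_for_config <- function(cfg) {
  preset <- cfg$preset
  cohort <- make_cohort(n = cfg$n, preset = preset, spec = cfg$spec, seed = cfg$seed)
  if (!cfg$flair) {
    # drop FLAIR from the protocol entirely
    for (i in seq_along(cohort$patients)) {
      cohort$patients[[i]]$signals$flair <- NULL
      cohort$patients[[i]]$acquisition$has_flair <- FALSE
    }
    cohort$truth$flair <- FALSE
  }
  cohort
}

#' Pipeline stage: simulate the cohort
#'
#' Writes per-patient signal volumes (NIfTI-1, echo/direction index in the
#' 4th dimension), ground-truth masks, an acquisition metadata JSON, the
#' cohort truth table, and (when FLAIR is enabled) a synthetic mismatch
#' ratings table.
#'
#' @param cfg a [run_config()].
#' @return character vector of files written, invisibly.
#' @export
stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "sim")
  cohort <- cohort_for_config(cfg)
  vox <- cfg$spec$voxel_mm
  files <- character(0)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    pd <- file.path(d, cohort$truth$id[i])
    dir.create(pd, showWarnings = FALSE)
    w <- function(x, nm) {
      path <- file.path(pd, nm)
      write_volume(x, path, vox)
      files <<- c(files, path)
    }
    w(p$signals$echo$signals, "echo.nii")
    w(p$signals$diffusion$signals, "diffusion.nii")
    if (!is.null(p$signals$flair)) w(p$signals$flair, "flair.nii")
    w(p$brain_mask + 0, "brain_mask.nii")
    w(p$lesion_mask + 0, "lesion_mask.nii")
    meta <- list(
      te = p$signals$echo$te,
      b = p$signals$diffusion$b,
      directions = p$signals$diffusion$directions,
      n_directions = p$signals$diffusion$n_directions,
      onset_minutes = p$onset_minutes
    )
    mpath <- file.path(pd, "acquisition.json")
    jsonlite::write_json(meta, mpath, digits = NA, auto_unbox = TRUE)
    files <- c(files, mpath)
  }
  tpath <- file.path(d, "truth.csv")
  utils::write.csv(cohort$truth, tpath, row.names = FALSE)
  files <- c(files, tpath)
  if (any(cohort$truth$flair)) {
    sub <- cohort$truth[cohort$truth$flair, ]
    rr <- simulate_mismatch_ratings(sub$onset_min)
    rdf <- data.frame(item_id = sub$id, rr$ratings, arbitrator = rr$arbitrator,
                      stringsAsFactors = FALSE)
    rpath <- file.path(d, "ratings.csv")
    utils::write.csv(rdf, rpath, row.names = FALSE)
    files <- c(files, rpath)
  }
  invisible(files)
}

read_patient_signals <- function(sim_pd) {
  meta <- jsonlite::read_json(file.path(sim_pd, "acquisition.json"), simplifyVector = TRUE)
  echo <- echo_series(read_volume(file.path(sim_pd, "echo.nii")), meta$te)
  diff <- diffusion_set(read_volume(file.path(sim_pd, "diffusion.nii")),
                        meta$b, meta$directions)
  fl <- NULL
  fpath <- file.path(sim_pd, "flair.nii")
  if (file.exists(fpath)) fl <- read_volume(fpath)
  list(echo = echo, diffusion = diff, flair = fl,
       brain = read_volume(file.path(sim_pd, "brain_mask.nii")) > 0.5,
       lesion = read_volume(file.path(sim_pd, "lesion_mask.nii")) > 0.5)
}

#' Pipeline stage: quantitative maps
#'
#' @param cfg a [run_config()].
#' @return files written, invisibly.
#' @export
stage_maps <- function(cfg) {
  simd <- file.path(cfg$out_dir, "sim")
  d <- stage_dir(cfg, "maps")
  truth <- utils::read.csv(file.path(simd, "truth.csv"), stringsAsFactors = FALSE)
  vox <- cfg$spec$voxel_mm
  files <- character(0)
  for (id in truth$id) {
    sig <- read_patient_signals(file.path(simd, id))
    fake_patient <- list(signals = sig, spec = cfg$spec)
    m <- quant_maps(fake_patient, t2_method = cfg$t2_method)
    pd <- file.path(d, id)
    dir.create(pd, showWarnings = FALSE)
    for (nm in c("adc", "dwi", "t2w", "t2", "s0_fit")) {
      path <- file.path(pd, paste0(nm, ".nii"))
      vol <- m[[nm]]
      vol[is.na(vol)] <- 0
      write_volume(vol, path, vox)
      files <- c(files, path)
    }
    path <- file.path(pd, "valid.nii")
    write_volume(m$valid + 0, path, vox)
    files <- c(files, path)
    if (!is.null(m$flair)) {
      path <- file.path(pd, "flair.nii")
      write_volume(m$flair, path, vox)
      files <- c(files, path)
    }
    manifest <- list(units = list(adc = "um^2/ms", t2 = "ms",
                                  dwi = "a.u.", t2w = "a.u.", flair = "a.u."),
                     t2_method = cfg$t2_method)
    jpath <- file.path(pd, "maps.json")
    jsonlite::write_json(manifest, jpath, auto_unbox = TRUE)
    files <- c(files, jpath)
  }
  invisible(files)
}

read_patient_maps <- function(maps_pd) {
  rd <- function(nm) {
    x <- read_volume(file.path(maps_pd, paste0(nm, ".nii")))
    x[x == 0] <- NA  # zeros encode invalid voxels on disk
    x
  }
  valid <- read_volume(file.path(maps_pd, "valid.nii")) > 0.5
  fl <- NULL
  if (file.exists(file.path(maps_pd, "flair.nii")))
    fl <- read_volume(file.path(maps_pd, "flair.nii"))
  structure(list(adc = rd("adc"), dwi = rd("dwi"), t2w = rd("t2w"), t2 = rd("t2"),
                 s0_fit = rd("s0_fit"), flair = fl, valid = valid),
            class = "quant_map_set")
}

#' Pipeline stage: lesion and reference VOIs
#'
#' @param cfg a [run_config()].
#' @return files written, invisibly.
#' @export
stage_voi <- function(cfg) {
  simd <- file.path(cfg$out_dir, "sim")
  mapsd <- file.path(cfg$out_dir, "maps")
  d <- stage_dir(cfg, "voi")
  truth <- utils::read.csv(file.path(simd, "truth.csv"), stringsAsFactors = FALSE)
  vox <- cfg$spec$voxel_mm
  files <- character(0)
  for (id in truth$id) {
    m <- read_patient_maps(file.path(mapsd, id))
    brain <- read_volume(file.path(simd, id, "brain_mask.nii")) > 0.5
    pd <- file.path(d, id)
    dir.create(pd, showWarnings = FALSE)
    voi <- tryCatch(find_voi(m$adc, m$t2, brain, cfg$segmentation, vox),
                    strokeclock_no_lesion = function(e) NULL)
    if (is.null(voi)) {
      jsonlite::write_json(list(status = "no_lesion"),
                           file.path(pd, "voi.json"), auto_unbox = TRUE)
      files <- c(files, file.path(pd, "voi.json"))
      next
    }
    write_volume(voi$ischemic + 0, file.path(pd, "ischemic.nii"), vox)
    write_volume(voi$reference + 0, file.path(pd, "reference.nii"), vox)
    jsonlite::write_json(
      list(status = "ok", volume_ml = voi$volume_ml, n_clusters = voi$n_clusters,
           nonischemic_median = voi$nonischemic_stats$median,
           nonischemic_hwhm = voi$nonischemic_stats$hwhm),
      file.path(pd, "voi.json"), digits = NA, auto_unbox = TRUE)
    files <- c(files, file.path(pd, c("ischemic.nii", "reference.nii", "voi.json")))
  }
  invisible(files)
}

#' Pipeline stage: cohort intensity-ratio table
#'
#' @param cfg a [run_config()].
#' @return files written, invisibly.
#' @export
stage_ratios <- function(cfg) {
  simd <- file.path(cfg$out_dir, "sim")
  truth <- utils::read.csv(file.path(simd, "truth.csv"), stringsAsFactors = FALSE)
  maps <- list(); vois <- list(); keep <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    id <- truth$id[i]
    vj <- jsonlite::read_json(file.path(cfg$out_dir, "voi", id, "voi.json"),
                              simplifyVector = TRUE)
    if (!identical(vj$status, "ok")) next
    keep[i] <- TRUE
    maps[[id]] <- read_patient_maps(file.path(cfg$out_dir, "maps", id))
    vois[[id]] <- list(
      ischemic = read_volume(file.path(cfg$out_dir, "voi", id, "ischemic.nii")) > 0.5,
      reference = read_volume(file.path(cfg$out_dir, "voi", id, "reference.nii")) > 0.5,
      volume_ml = vj$volume_ml
    )
  }
  tab <- build_cohort_table(truth[keep, , drop = FALSE], maps[truth$id[keep]],
                            vois[truth$id[keep]], window_min = cfg$window_min)
  tab$flair <- truth$flair[keep]
  path <- file.path(cfg$out_dir, "cohort.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate a cohort table of intensity ratios
#'
#' The full statistical comparison of the timing classifiers: correlations of
#' every ratio with onset time, ROC/AUC with CIs and pairwise DeLong
#' comparisons, Youden cutoffs with diagnostic metrics, single-ratio and
#' combined logistic models ranked by AICc, and — on the FLAIR subcohort —
#' PRG curves/AUPRG, F1 at the Youden cutoff, plus mismatch-rating agreement
#' (free-marginal kappa) and adjudicated-mismatch F1 when ratings are given.
#'
#' Classification directions follow the biology: within-window means a ratio
#' at or below the cutoff for T2, T2w, DWI and FLAIR (T2-driven intensities
#' rise with time) but at or above it for ADC.
#'
#' @param tab a `cohort_table` (needs `label` and ratio columns; `flair`
#'   column marks subcohort membership).
#' @param ratings optional data.frame (item_id, rater columns, arbitrator)
#'   for the mismatch analysis.
#' @param conf_level confidence level for intervals.
#' @return nested list of results, JSON-serializable.
#' @export
evaluate_cohort <- function(tab, ratings = NULL, conf_level = 0.95) {
  dirs <- c(ratio_adc = "above", ratio_dwi = "below", ratio_t2w = "below",
            ratio_t2 = "below", ratio_flair = "below")
  usable <- function(nm) {
    if (!nm %in% names(tab)) return(FALSE)
    ok <- !is.na(tab[[nm]])
    sum(ok) >= 3 && length(unique(tab$label[ok])) == 2
  }
  present <- names(dirs)[vapply(names(dirs), usable, logical(1))]
  res <- list(n = nrow(tab), n_within = sum(tab$label == 1))

  res$correlations <- lapply(stats::setNames(present, present), function(nm) {
    ok <- !is.na(tab[[nm]])
    lapply(stats::setNames(c("pearson", "spearman", "kendall"),
                           c("pearson", "spearman", "kendall")),
           function(m) {
             ct <- correlate(tab[[nm]][ok], tab$onset_min[ok], method = m)
             list(estimate = ct$estimate, p = ct$p_value)
           })
  })

  roc_one <- function(nm, sub) {
    ok <- !is.na(sub[[nm]])
    r <- roc_auc(sub[[nm]][ok], sub$label[ok], direction = dirs[[nm]],
                 conf_level = conf_level)
    y <- youden_cutoff(sub[[nm]][ok], sub$label[ok], direction = dirs[[nm]])
    list(auc = r$auc, auc_ci = as.list(r$ci), auc_p = r$p_value,
         direction = dirs[[nm]], cutoff = y$cutoff, youden_j = y$j,
         confusion = unclass(y$confusion),
         metrics = y$metrics)
  }
  res$roc <- lapply(stats::setNames(present, present), roc_one, sub = tab)

  full_cols <- present[vapply(present, function(nm) !anyNA(tab[[nm]]), logical(1))]
  if (length(full_cols) >= 2) {
    res$auc_comparison <- compare_aucs(
      stats::setNames(lapply(full_cols, function(nm) tab[[nm]]), full_cols),
      tab$label, directions = dirs[full_cols])
  }

  logit_one <- function(preds) {
    tryCatch({
      f <- fit_logistic(tab[stats::complete.cases(tab[, c("label", preds), drop = FALSE]), ],
                        preds)
      list(status = "ok", coefficients = f$coefficients, chisq = f$chisq,
           df = f$df, p = f$p_model, aicc = f$aicc)
    },
    strokeclock_separation = function(e) list(status = "separated"),
    strokeclock_error = function(e) list(status = "not_fitted",
                                         message = conditionMessage(e)))
  }
  models <- c(lapply(stats::setNames(present, present), function(nm) logit_one(nm)),
              list(combined = logit_one(setdiff(present, "ratio_flair"))))
  res$logistic <- models

  sub <- tab[!is.na(tab$flair) & tab$flair, , drop = FALSE]
  if (nrow(sub) >= 4 && length(unique(sub$label)) == 2) {
    subres <- list(n = nrow(sub), n_within = sum(sub$label == 1))
    subres$prg <- lapply(stats::setNames(present, present), function(nm) {
      ok <- !is.na(sub[[nm]])
      if (length(unique(sub$label[ok])) < 2) return(NULL)
      p <- prg_curve(sub[[nm]][ok], sub$label[ok], direction = dirs[[nm]])
      list(auprg = p$auprg, prevalence = p$prevalence)
    })
    subres$f1 <- lapply(stats::setNames(present, present), function(nm) {
      ok <- !is.na(sub[[nm]])
      if (length(unique(sub$label[ok])) < 2) return(NULL)
      y <- youden_cutoff(sub[[nm]][ok], sub$label[ok], direction = dirs[[nm]])
      f <- f1_score(y$confusion)
      list(f1 = f$f1, ci = as.list(f$ci), cutoff = y$cutoff)
    })
    if (!is.null(ratings)) {
      rater_cols <- grep("^rater", names(ratings), value = TRUE)
      rmat <- as.matrix(ratings[, rater_cols, drop = FALSE])
      kap <- free_marginal_kappa(rmat, k = 3)
      subres$kappa <- list(po = kap$po, kappa = kap$kappa, ci = as.list(kap$ci))
      final <- majority_adjudicate(rmat, ratings$arbitrator)
      idx <- match(ratings$item_id, sub$id)
      ok <- !is.na(idx)
      pred_within <- final[ok] == "mismatch"
      lbl <- sub$label[idx[ok]]
      ctm <- confusion_table(tp = sum(pred_within & lbl == 1),
                             fp = sum(pred_within & lbl == 0),
                             fn = sum(!pred_within & lbl == 1),
                             tn = sum(!pred_within & lbl == 0))
      fm <- f1_score(ctm)
      subres$mismatch <- list(final = final, f1 = fm$f1, ci = as.list(fm$ci),
                              confusion = unclass(ctm))
    }
    res$subcohort <- subres
  }
  res
}

#' Pipeline stage: statistical evaluation
#'
#' @param cfg a [run_config()].
#' @return path of the evaluation JSON, invisibly.
#' @export
stage_evaluate <- function(cfg) {
  tab <- utils::read.csv(file.path(cfg$out_dir, "cohort.csv"), stringsAsFactors = FALSE)
  rpath <- file.path(cfg$out_dir, "sim", "ratings.csv")
  ratings <- if (cfg$flair && file.exists(rpath))
    utils::read.csv(rpath, stringsAsFactors = FALSE) else NULL
  res <- evaluate_cohort(tab, ratings)
  path <- file.path(cfg$out_dir, "evaluation.json")
  jsonlite::write_json(res, path, digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate, maps, voi, ratios and evaluate in order and writes a
#' manifest listing every produced file with its MD5 checksum. Rerunning with
#' the same configuration reproduces identical results (volumes are written
#' as uncompressed NIfTI so checksums are stable). A failing stage raises its
#' typed error annotated with the stage name; artifacts of completed stages
#' are retained.
#'
#' @param cfg a [run_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop_strokeclock("config_error", "need a run_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(simulate = stage_simulate, maps = stage_maps, voi = stage_voi,
                 ratios = stage_ratios, evaluate = stage_evaluate)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](cfg), error = function(e) {
      cond <- structure(
        class = class(e),
        list(message = sprintf("stage '%s': %s", nm, conditionMessage(e)),
             call = conditionCall(e))
      )
      stop(cond)
    })
  }
  files <- sort(list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = list(n = cfg$n, preset = cfg$preset, seed = cfg$seed,
                  window_min = cfg$window_min, flair = cfg$flair,
                  t2_method = cfg$t2_method),
    files = data.frame(
      path = sub(paste0("^", cfg$out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
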