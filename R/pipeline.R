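pipeline_defaults <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    out_dir = "physari_out",
    n_subjects = 50L,
    age_range = c(10, 26),
    noise_sd = 10,
    plate_jitter_sd = 0.25,
    dicom_dir = NULL,
    masks_manifest = NULL,
    observers = list(n = 3L, perturbation = 2),
    segmentation = list(
      roi_box = NULL,
      threshold = list(mode = "auto", tmin = NULL, tmax = NULL, otsu_fraction = 0.6),
      refine = list(median = FALSE, close_radius = 0L, min_component = 20L,
                    keep_largest = FALSE),
      visibility_min_pixels = 20L
    ),
    volume_mode = "as-printed",
    overlay_subjects = 2L,
    log_level = "info"
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop_physari("unknown config key", if (nzchar(path)) paste0(" under '", path, "'"),
                 ": ", paste(unknown, collapse = ", "),
                 class = "physari_config_error")
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_config(defaults[[k]], user[[k]],
                   path = if (nzchar(path)) paste0(path, ".", k) else k)
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys by name, and checks cross-field constraints (input mode, threshold
#' range, subject count).
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` list with all defaults applied.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_physari("no such config file: ", config, class = "physari_io_error")
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (!cfg$mode %in% c("simulate", "dicom_dir"))
    stop_physari("mode must be 'simulate' or 'dicom_dir'",
                 class = "physari_config_error")
  if (cfg$mode == "simulate" && cfg$n_subjects < 2)
    stop_physari("n_subjects must be >= 2 in simulate mode",
                 class = "physari_config_error")
  if (cfg$mode == "dicom_dir" && is.null(cfg$dicom_dir))
    stop_physari("dicom_dir mode requires the dicom_dir key",
                 class = "physari_config_error")
  th <- cfg$segmentation$threshold
  if (!th$mode %in% c("auto", "fixed"))
    stop_physari("segmentation.threshold.mode must be 'auto' or 'fixed'",
                 class = "physari_config_error")
  if (th$mode == "fixed") {
    if (is.null(th$tmin) || is.null(th$tmax))
      stop_physari("fixed threshold mode requires tmin and tmax",
                   class = "physari_config_error")
    if (th$tmin > th$tmax)
      stop_physari("segmentation.threshold: tmin > tmax",
                   class = "physari_config_error")
  }
  if (!cfg$volume_mode %in% c("as-printed", "slab"))
    stop_physari("volume_mode must be 'as-printed' or 'slab'",
                 class = "physari_config_error")
  if (!is.null(cfg$segmentation$roi_box) && length(cfg$segmentation$roi_box) != 4)
    stop_physari("segmentation.roi_box must be [top, left, height, width]",
                 class = "physari_config_error")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[physARI] ", ...)
  invisible(NULL)
}

load_dicom_cohort <- function(cfg) {
  meta_path <- file.path(cfg$dicom_dir, "metadata.csv")
  if (!file.exists(meta_path))
    stop_physari("metadata.csv not found in ", cfg$dicom_dir,
                 class = "physari_io_error")
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  manifest <- if (!is.null(cfg$masks_manifest))
    jsonlite::read_json(cfg$masks_manifest, simplifyVector = FALSE) else NULL
  lapply(seq_len(nrow(meta)), function(i) {
    rec <- meta[i, , drop = FALSE]
    study <- load_subject(file.path(cfg$dicom_dir, rec$subject_id), rec)
    observers <- NULL
    if (!is.null(manifest)) {
      subj_masks <- manifest[[rec$subject_id]]
      observers <- lapply(names(subj_masks), function(obs) {
        paths <- unlist(subj_masks[[obs]])
        masks <- lapply(seq_along(paths), function(s)
          load_femur_mask(paths[s], study$slices[[s]]))
        segmentation_result(obs, femur_masks = masks)
      })
    }
    list(study = study, truth = NULL, observers = observers)
  })
}

#' Run the full morphometry pipeline
#'
#' Orchestrates an end-to-end run: simulate a phantom cohort (or ingest a
#' DICOM directory plus manual femur masks), segment the growth plate on
#' every slice, measure per-observer morphometry, and write the report
#' files: per-subject morphometry, pairwise observer kappas, age--ARI
#' correlations by sex and in total, the device-influence regression,
#' cohort descriptives, sex comparisons (Mann-Whitney) with normality
#' checks, and outline-overlay PNGs. Identical config and seed give
#' identical outputs.
#'
#' @param config Path to a YAML config, or a (possibly partial) named list;
#'   see [validate_config()].
#' @return Invisibly, a list with the validated `config`, the in-memory
#'   result tables (`morphometry`, `per_subject`, `kappa`, `correlation`,
#'   `regression`, `descriptives`, `sex_comparison`) and the written
#'   `files`. In simulate mode `per_subject` additionally carries the
#'   generator's `nominal_ARI` (ground-truth masks), so parameter recovery
#'   can be assessed against it.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)

  seg_cfg <- cfg$segmentation
  box_for <- function(slice) {
    if (is.null(seg_cfg$roi_box)) default_roi_box(slice) else
      do.call(bounding_box, as.list(seg_cfg$roi_box))
  }
  spec_fixed <- if (seg_cfg$threshold$mode == "fixed")
    threshold_spec(seg_cfg$threshold$tmin, seg_cfg$threshold$tmax) else NULL
  ref <- refine_params(median = seg_cfg$refine$median,
                       close_radius = seg_cfg$refine$close_radius,
                       min_component = seg_cfg$refine$min_component,
                       keep_largest = seg_cfg$refine$keep_largest)

  result <- with_seed(cfg$seed, {
    if (cfg$mode == "simulate") {
      pipeline_log(cfg, "simulating cohort of ", cfg$n_subjects, " subjects")
      cohort <- generate_cohort(cfg$n_subjects, age_range = cfg$age_range,
                                seed = sample.int(.Machine$integer.max - 1L, 1),
                                plate_jitter_sd = cfg$plate_jitter_sd,
                                noise_sd = cfg$noise_sd)
      cohort <- lapply(cohort, function(subj) {
        subj$observers <- simulate_observer_masks(
          subj$truth, perturbation = cfg$observers$perturbation,
          seed = sample.int(.Machine$integer.max - 1L, 1),
          n_observers = cfg$observers$n)
        subj
      })
    } else {
      pipeline_log(cfg, "loading DICOM cohort from ", cfg$dicom_dir)
      cohort <- load_dicom_cohort(cfg)
    }

    pipeline_log(cfg, "segmenting growth plates")
    cohort <- lapply(cohort, function(subj) {
      subj$plate_masks <- lapply(subj$study$slices, function(sl)
        segment_growth_plate(sl, box = box_for(sl), spec = spec_fixed,
                             refine = ref,
                             otsu_fraction = seg_cfg$threshold$otsu_fraction))
      subj
    })

    pipeline_log(cfg, "measuring morphometry")
    morphs <- list()
    for (subj in cohort) {
      if (is.null(subj$observers))
        stop_physari("no observer femur masks available for subject ",
                     subj$study$subject_id, class = "physari_validation_error")
      for (obs in subj$observers) {
        seg <- segmentation_result(obs$observer_id, obs$femur_masks,
                                   plate_masks = subj$plate_masks)
        morphs[[length(morphs) + 1L]] <- measure_subject(
          subj$study, seg, visibility_min = seg_cfg$visibility_min_pixels,
          volume_mode = cfg$volume_mode)
      }
    }
    morph_df <- morphometry_table(morphs)
    per_subject <- average_over_observers(morph_df)
    if (cfg$mode == "simulate") {
      ids <- vapply(cohort, function(s) s$study$subject_id, character(1))
      noms <- vapply(cohort, function(s) s$truth$nominal_ARI, numeric(1))
      per_subject$nominal_ARI <- noms[match(per_subject$subject_id, ids)]
    }

    pipeline_log(cfg, "computing statistics")
    obs_ids <- unique(morph_df$observer_id)
    kappa_df <- NULL
    if (length(obs_ids) >= 2) {
      pairs <- utils::combn(obs_ids, 2, simplify = FALSE)
      kappa_df <- do.call(rbind, lapply(pairs, function(pr) {
        counts <- c(a = 0, b = 0, c = 0, d = 0)
        for (subj in cohort) {
          oa <- Filter(function(o) o$observer_id == pr[1], subj$observers)[[1]]
          ob <- Filter(function(o) o$observer_id == pr[2], subj$observers)[[1]]
          kr <- cohen_kappa(oa$femur_masks, ob$femur_masks,
                            domain = box_for(subj$study$slices[[1]]))
          counts <- counts + kr$counts
        }
        kr <- kappa_from_table(counts["a"], counts["b"], counts["c"], counts["d"])
        data.frame(observer_pair = paste(pr[1], "vs", pr[2]),
                   kappa = kr$kappa, ci_low = kr$ci_low, ci_high = kr$ci_high,
                   n_pixels = kr$n, stringsAsFactors = FALSE)
      }))
    }

    corr_df <- do.call(rbind, lapply(
      list(c("Female", "F"), c("Male", "M"), c("Total", NA)), function(g) {
        sel <- if (is.na(g[2])) rep(TRUE, nrow(per_subject)) else per_subject$sex == g[2]
        if (sum(sel) < 3) return(NULL)
        cr <- pearson_r_ci(per_subject$age[sel], per_subject$ARI[sel])
        data.frame(group = g[1], n = cr$n, r = cr$r, ci_low = cr$ci_low,
                   ci_high = cr$ci_high, p = cr$p, stringsAsFactors = FALSE)
      }))

    X <- data.frame(
      age = per_subject$age,
      sex = as.integer(per_subject$sex == "M"),
      field_strength = per_subject$field_strength,
      pixel_size_mm2 = per_subject$pixel_size_mm2,
      matrix_area_mm2 = per_subject$matrix_area_mm2,
      n_pixels = per_subject$n_pixels,
      slice_thickness = per_subject$Ts,
      n_slices = per_subject$Ns,
      total_width = per_subject$total_width
    )
    reg <- multiple_regression(per_subject$ARI, X)

    desc_df <- rbind(
      cohort_summary(per_subject$age[per_subject$sex == "F"], "Age, female (y)"),
      cohort_summary(per_subject$age[per_subject$sex == "M"], "Age, male (y)"),
      cohort_summary(per_subject$age, "Age, total (y)"),
      cohort_summary(per_subject$ARI, "ARI, total"),
      cohort_summary(per_subject$field_strength, "Magnetic field strength (T)"),
      cohort_summary(per_subject$pixel_size_mm2, "Pixel size (mm2)"),
      cohort_summary(per_subject$n_pixels, "Total number of pixels on the image"),
      cohort_summary(per_subject$matrix_area_mm2, "Image matrix area (mm2)"),
      cohort_summary(per_subject$Ts, "Slice thickness (mm)"),
      cohort_summary(per_subject$Ns, "Total slices of the study area"),
      cohort_summary(per_subject$total_width, "Total width of the study area (mm)")
    )

    sexcmp <- rbind(
      data.frame(variable = "age",
                 U = mann_whitney_u(per_subject$age[per_subject$sex == "F"],
                                    per_subject$age[per_subject$sex == "M"])$U,
                 p = mann_whitney_u(per_subject$age[per_subject$sex == "F"],
                                    per_subject$age[per_subject$sex == "M"])$p,
                 ks_normality_p = ks_normality(per_subject$age)$p),
      data.frame(variable = "ARI",
                 U = mann_whitney_u(per_subject$ARI[per_subject$sex == "F"],
                                    per_subject$ARI[per_subject$sex == "M"])$U,
                 p = mann_whitney_u(per_subject$ARI[per_subject$sex == "F"],
                                    per_subject$ARI[per_subject$sex == "M"])$p,
                 ks_normality_p = ks_normality(per_subject$ARI)$p)
    )

    list(cohort = cohort, morphometry = morph_df, per_subject = per_subject,
         kappa = kappa_df, correlation = corr_df, regression = reg,
         descriptives = desc_df, sex_comparison = sexcmp)
  })

  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    morphometry = file.path(out, "morphometry.csv"),
    per_subject = file.path(out, "per_subject_ari.csv"),
    kappa = file.path(out, "kappa.csv"),
    correlation = file.path(out, "correlation.csv"),
    regression = file.path(out, "regression.csv"),
    regression_model = file.path(out, "regression_model.json"),
    descriptives = file.path(out, "descriptives.csv"),
    sex_comparison = file.path(out, "sex_comparison.csv"),
    run_metadata = file.path(out, "run_metadata.json")
  )
  write.csv(result$morphometry, files["morphometry"], row.names = FALSE)
  write.csv(result$per_subject, files["per_subject"], row.names = FALSE)
  if (!is.null(result$kappa)) write.csv(result$kappa, files["kappa"], row.names = FALSE)
  write.csv(result$correlation, files["correlation"], row.names = FALSE)
  write.csv(result$regression$table, files["regression"], row.names = FALSE)
  jsonlite::write_json(
    list(r_squared = result$regression$r_squared, f = result$regression$f,
         df1 = result$regression$df1, df2 = result$regression$df2,
         model_p = result$regression$model_p, n = result$regression$n),
    files["regression_model"], auto_unbox = TRUE, digits = NA)
  write.csv(result$descriptives, files["descriptives"], row.names = FALSE)
  write.csv(result$sex_comparison, files["sex_comparison"], row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, mode = cfg$mode, n_subjects = length(result$cohort),
         observers = cfg$observers, volume_mode = cfg$volume_mode),
    files["run_metadata"], auto_unbox = TRUE, digits = NA)

  if (cfg$overlay_subjects > 0) {
    ovdir <- file.path(out, "overlays")
    dir.create(ovdir, showWarnings = FALSE)
    for (subj in head(result$cohort, cfg$overlay_subjects)) {
      for (s in seq_along(subj$study$slices)) {
        ov <- outline_overlay(subj$study$slices[[s]], subj$plate_masks[[s]])
        png::writePNG(ov / max(ov, 1),
                      file.path(ovdir, sprintf("%s_%02d.png",
                                               subj$study$subject_id, s - 1L)))
      }
    }
    files <- c(files, overlays = ovdir)
  }
  pipeline_log(cfg, "wrote reports to ", out)
  result$cohort <- NULL
  invisible(c(list(config = cfg, files = files), result))
}
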