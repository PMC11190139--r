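#' Default run configuration
#'
#' The nested configuration consumed by [runCaseControl()]. Blocks mirror
#' the pipeline stages: `acquisition` (sequence timing), `phantom` (slab
#' geometry), `cohort` (design and demographics), `effects` (simulated
#' disease effect), `laminar` (depth sampling), `simulation` (tier and
#' noise), `stats` (inference settings), plus `master_seed` and every block
#' is overridable from a YAML file via [readRunConfig()].
#'
#' The default `simulation$tier = "profile"` draws depth profiles directly
#' (fast, for statistical work); `tier = "voxel"` renders full phantom
#' volumes per subject and runs map estimation and laminar extraction.
#'
#' @return a named list of configuration blocks.
#' @export
defaultRunConfig <- function() {
  list(
    acquisition = list(
      ti1 = 670, ti2 = 3675.4, tr_seq = 6778, tr_gre1 = 6.2, tr_gre2 = 31,
      fa1 = 4, fa2 = 4, tes = c(3, 11.5, 19, 28.5), n_exc = 150,
      inv_eff = 0.96),
    phantom = list(
      grid_shape = c(32, 32, 24), voxel_size = 0.7,
      ribbon_thickness_mm = 3.5, undulation_amp_mm = 1.4,
      undulation_period_mm = 16),
    cohort = list(
      n_mdd = 48, n_hc = 10, baseline_sd = 70, p_female = 0.7,
      n_ids_missing = 1),
    effects = list(
      affected_roi = "lOFC", group_shift_d = 0.6, severity_corr = 0.27,
      between_subject_sd = 40, noise_sd = 0.01, depth_weighted = FALSE),
    laminar = list(dilation = 2, n_depths = 10, min_voxels = 10),
    simulation = list(
      tier = "profile", profile_noise_sd = 15,
      rois = c("rACC", "mOFC", "lOFC", "S1"), contrasts = c("T1", "T2star")),
    stats = list(alpha = 0.05, bootstrap_reps = 2000),
    master_seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Loads a YAML file whose blocks mirror [defaultRunConfig()] and merges it
#' over the defaults (file values win, block by block).
#'
#' @param path YAML file path.
#' @return a configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (blk in names(user)) {
    if (is.list(user[[blk]]) && is.list(cfg[[blk]])) {
      for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  cfg
}

.cfgAcquisition <- function(cfg) {
  a <- cfg$acquisition
  acquisitionParams(ti1 = a$ti1, ti2 = a$ti2, trSeq = a$tr_seq,
                    trGre1 = a$tr_gre1, trGre2 = a$tr_gre2, fa1 = a$fa1,
                    fa2 = a$fa2, tes = a$tes, nExc = a$n_exc,
                    invEff = a$inv_eff)
}

.cfgEffects <- function(cfg) {
  e <- cfg$effects
  effectConfig(affectedRoi = e$affected_roi, groupShiftD = e$group_shift_d,
               severityCorr = e$severity_corr,
               betweenSubjectSd = e$between_subject_sd,
               noiseSd = e$noise_sd, depthWeighted = isTRUE(e$depth_weighted))
}

#' Extract all depth profiles for one rendered subject
#'
#' The voxel-tier per-subject chain: build the subject's phantom, render the
#' acquisition, estimate T1/T2* maps, compute the depth field from the
#' tissue labels, refine each ROI mask against gray matter, and extract
#' 10-depth profiles per ROI x hemisphere x contrast.
#'
#' @param subject one cohort row.
#' @param cfg a configuration list (see [defaultRunConfig()]).
#' @param lut optionally a prebuilt [LookupTable-class] (rebuilt otherwise).
#' @return a long data.frame of profile rows (`subject_id`, `roi`,
#'   `hemisphere`, `contrast`, `depth`, `value`).
#' @export
extractSubjectProfiles <- function(subject, cfg = defaultRunConfig(),
                                   lut = NULL) {
  params <- .cfgAcquisition(cfg)
  effects <- .cfgEffects(cfg)
  ph <- cfg$phantom
  truth <- makeCorticalPhantom(
    gridShape = ph$grid_shape, voxelSize = ph$voxel_size,
    ribbonThicknessMm = ph$ribbon_thickness_mm, subject = subject,
    effects = effects, undulationAmpMm = ph$undulation_amp_mm,
    undulationPeriodMm = ph$undulation_period_mm)
  img <- renderSubjectImages(truth, params, noiseSd = effects@noiseSd,
                             seed = subject$rng_seed)
  if (is.null(lut)) lut <- buildT1Lookup(params)
  maps <- list(
    T1 = estimateT1Map(img$uni, lut, voxelSize(truth)),
    T2star = estimateT2starMap(img$echoes, params@tes, voxelSize(truth)))
  depth <- computeDepthField(tissueLabels(truth), voxelSize(truth))
  gm <- tissueLabels(truth) == tissueCodes()[["GM"]]

  rows <- list()
  for (roi in cfg$simulation$rois) {
    for (hemi in c("left", "right")) {
      rawMask <- roiLabels(truth) == roiCode(roi, hemi)
      if (!any(rawMask)) next
      mask <- refineRoiMask(rawMask, gm, cfg$laminar$dilation)
      for (ct in cfg$simulation$contrasts) {
        prof <- extractDepthProfile(
          maps[[ct]], mask, depth, nDepths = cfg$laminar$n_depths,
          minVoxels = cfg$laminar$min_voxels,
          subjectId = subject$subject_id, roi = roi, hemisphere = hemi)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject$subject_id, roi = roi, hemisphere = hemi,
          contrast = ct, depth = profileDepths(prof),
          value = profileValues(prof), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.writeResults <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(x, file.path(dir, paste0(name, ".json")),
                       dataframe = "rows", digits = NA, na = "null")
}

#' Run the case-control pipeline
#'
#' Executes the full chain on a generated cohort: simulate (profile or voxel
#' tier), reduce to metrics, test lateralization, run the case-control
#' ANCOVA on every (ROI, contrast, metric), and — for ROIs with significant
#' group differences — the within-patient analyses. Writes `subjects.csv`,
#' `profiles.csv`, `metrics.csv`, `lateralization.csv`,
#' `stats_case_control.(csv|json)`, `stats_within_patient.(csv|json)`, a
#' config snapshot (`config.yaml`) and a stage log (`log.txt`) into
#' `outDir`. Two runs from the same config are identical.
#'
#' @param cfg a configuration list (see [defaultRunConfig()],
#'   [readRunConfig()]).
#' @param outDir output directory, created if needed; `NULL` skips writing.
#' @return a list with `cohort`, `profiles`, `metrics`,
#'   `lateralization`, `stage1` (case-control results) and `stage2`
#'   (within-patient results).
#' @export
runCaseControl <- function(cfg = defaultRunConfig(), outDir = NULL) {
  logLines <- character()
  say <- function(fmt, ...) {
    logLines[[length(logLines) + 1L]] <<- sprintf(fmt, ...)
  }
  effects <- .cfgEffects(cfg)
  co <- cfg$cohort
  cohort <- generateCohort(nMdd = co$n_mdd, nHc = co$n_hc,
                           effects = effects,
                           masterSeed = cfg$master_seed,
                           baselineSd = co$baseline_sd,
                           pFemale = co$p_female,
                           nIdsMissing = co$n_ids_missing)
  say("cohort: %d MDD + %d HC subjects (master seed %d)",
      co$n_mdd, co$n_hc, cfg$master_seed)

  if (identical(cfg$simulation$tier, "voxel")) {
    params <- .cfgAcquisition(cfg)
    lut <- buildT1Lookup(params)
    profs <- lapply(seq_len(nrow(cohort)), function(i) {
      extractSubjectProfiles(cohort[i, ], cfg, lut)
    })
    profiles <- do.call(rbind, profs)
    say("voxel tier: rendered %d subjects on a %s grid",
        nrow(cohort), paste(cfg$phantom$grid_shape, collapse = "x"))
  } else {
    profiles <- simulateProfileCohort(
      cohort, effects, rois = cfg$simulation$rois,
      contrasts = cfg$simulation$contrasts,
      nDepths = cfg$laminar$n_depths,
      profileNoiseSd = cfg$simulation$profile_noise_sd,
      seed = cfg$master_seed + 1L)
    say("profile tier: drew %d profile rows", nrow(profiles))
  }

  metricsLR <- computeMetricsTable(profiles, averageHemis = FALSE)
  later <- lateralizationTest(metricsLR)
  say("lateralization: %d/%d tests with p < %.2f",
      sum(later$p < cfg$stats$alpha), nrow(later), cfg$stats$alpha)

  metrics <- computeMetricsTable(profiles, averageHemis = TRUE)
  combos <- expand.grid(roi = cfg$simulation$rois,
                        contrast = cfg$simulation$contrasts,
                        metric = c("mean", "auc", "offset"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stage1 <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    ancovaGroupTest(metrics, cohort, roi = combos$roi[i],
                    contrast = combos$contrast[i],
                    metric = combos$metric[i])
  }))
  say("case-control: %d/%d tests with p < %.2f",
      sum(stage1$p < cfg$stats$alpha), nrow(stage1), cfg$stats$alpha)

  stage2 <- withinPatientAnalyses(
    metrics, cohort, stage1, alpha = cfg$stats$alpha,
    nBoot = cfg$stats$bootstrap_reps, seed = cfg$master_seed + 2L)
  if (nrow(stage2)) {
    say("within-patient: %d analyses in gated regions", nrow(stage2))
  } else {
    say("within-patient: no region passed the case-control gate; empty table")
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(outDir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(profiles, file.path(outDir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(metricsLR, file.path(outDir, "metrics_by_hemisphere.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(later, file.path(outDir, "lateralization.csv"),
                     row.names = FALSE)
    .writeResults(stage1, outDir, "stats_case_control")
    .writeResults(stage2, outDir, "stats_within_patient")
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
    writeLines(logLines, file.path(outDir, "log.txt"))
  }

  list(cohort = cohort, profiles = profiles, metrics = metrics,
       metricsByHemisphere = metricsLR, lateralization = later,
       stage1 = stage1, stage2 = stage2, log = logLines)
}

#' Run only the within-patient stage from existing results
#'
#' Re-runs the gated within-patient analyses from a completed
#' [runCaseControl()] result bundle (or equivalent tables).
#'
#' @param cfg configuration list.
#' @param results a [runCaseControl()] result list (needs `metrics`,
#'   `cohort`, `stage1`).
#' @param outDir optional output directory.
#' @return the within-patient results data.frame.
#' @export
runWithinPatients <- function(cfg, results, outDir = NULL) {
  stage2 <- withinPatientAnalyses(
    results$metrics, results$cohort, results$stage1,
    alpha = cfg$stats$alpha, nBoot = cfg$stats$bootstrap_reps,
    seed = cfg$master_seed + 2L)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeResults(stage2, outDir, "stats_within_patient")
  }
  stage2
}
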