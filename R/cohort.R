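## Evaluate 'code' under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic case-control cohort
#'
#' Draws one row per subject for a patient/control design: demographics (age
#' truncated to the 20-55 year inclusion window, about 70% female), symptom
#' severity (IDS, 0-84) and childhood trauma (CTQ) scores with
#' group-appropriate distributions, antidepressant use and comorbid anxiety
#' flags among patients, and each subject's true quantitative effect: a
#' subject-level baseline offset common to all ROIs, and — for patients — an
#' additive T1 shift in the affected ROI.
#'
#' The shift is calibrated analytically. With `z` the standardized IDS score
#' among patients, `shift = mu + sigma_s * (rho * z + sqrt(1 - rho^2) * eps)`
#' so that the shift-severity correlation is exactly
#' `rho = severityCorr`, and `mu = groupShiftD * s_pool` where `s_pool` is
#' the pooled SD implied by the group variances
#' (`baselineSd^2 + betweenSubjectSd^2` among patients, `baselineSd^2` among
#' controls), so the population standardized group difference on any
#' mean-like T1 metric equals `groupShiftD`.
#'
#' By default one patient's IDS/CTQ scores are recorded as missing
#' (questionnaire non-completion); the underlying severity still drives that
#' subject's simulated shift.
#'
#' @param nMdd,nHc group sizes.
#' @param effects an [EffectConfig-class].
#' @param masterSeed integer; all randomness flows from it.
#' @param baselineSd SD (ms) of the subject-level baseline offset.
#' @param pFemale probability of female sex.
#' @param nIdsMissing number of patients with unrecorded IDS/CTQ.
#' @return a data.frame with one row per subject: `subject_id`, `group`
#'   (`"MDD"`/`"HC"`), `age`, `sex` (`"F"`/`"M"`), `ids_score`, `ctq_score`,
#'   `on_antidepressants`, `comorbid_anxiety`, `baseline_offset`,
#'   `t1_profile_shift`, `rng_seed`.
#' @examples
#' head(generateCohort(masterSeed = 7))
#' @export
generateCohort <- function(nMdd = 48, nHc = 10, effects = effectConfig(),
                           masterSeed = 1L, baselineSd = 70,
                           pFemale = 0.7, nIdsMissing = 1L) {
  stopifnot(nMdd >= 1, nHc >= 1, baselineSd > 0)
  validObject(effects)
  rho <- effects@severityCorr
  sigS <- effects@betweenSubjectSd
  n <- nMdd + nHc

  .withSeed(masterSeed, {
    grp <- rep(c("MDD", "HC"), c(nMdd, nHc))
    age <- .rtruncnorm(n, 37, 10, 20, 55)
    sex <- ifelse(stats::runif(n) < pFemale, "F", "M")
    ids <- numeric(n)
    ids[grp == "MDD"] <- pmin(.rtruncnorm(nMdd, 33.5, 13.5, 9, Inf), 84)
    ids[grp == "HC"] <- pmin(.rtruncnorm(nHc, 4, 3, 0, Inf), 84)
    ctq <- numeric(n)
    ctq[grp == "MDD"] <- pmin(.rtruncnorm(nMdd, 46.8, 19.2, 25, Inf), 125)
    ctq[grp == "HC"] <- pmin(.rtruncnorm(nHc, 39.9, 9.2, 25, Inf), 125)
    meds <- grp == "MDD" & stats::runif(n) < 0.5
    anx <- grp == "MDD" & stats::runif(n) < 0.44

    base <- stats::rnorm(n, 0, baselineSd)

    ## calibrated patient shift (population algebra, see Details)
    sPool <- sqrt(((nMdd - 1) * (baselineSd^2 + sigS^2) +
                     (nHc - 1) * baselineSd^2) / (n - 2))
    mu <- effects@groupShiftD * sPool
    shift <- numeric(n)
    zIds <- scale(ids[grp == "MDD"])[, 1]
    if (stats::sd(ids[grp == "MDD"]) == 0 && rho != 0)
      stop("calibration error: severityCorr != 0 needs varying IDS scores")
    if (any(!is.finite(zIds))) zIds <- rep(0, nMdd)
    eps <- stats::rnorm(nMdd)
    shift[grp == "MDD"] <-
      mu + sigS * (rho * zIds + sqrt(1 - rho^2) * eps)

    idsRec <- ids; ctqRec <- ctq
    if (nIdsMissing > 0 && nIdsMissing < nMdd) {
      drop <- sample(which(grp == "MDD"), nIdsMissing)
      idsRec[drop] <- NA_real_
      ctqRec[drop] <- NA_real_
    }

    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = grp, age = age, sex = sex,
      ids_score = idsRec, ctq_score = ctqRec,
      on_antidepressants = meds, comorbid_anxiety = anx,
      baseline_offset = base, t1_profile_shift = shift,
      rng_seed = sample.int(.Machine$integer.max, n),
      stringsAsFactors = FALSE
    )
  })
}

#' Draw 10-depth profiles directly for a cohort
#'
#' The fast simulation tier: instead of rendering voxel volumes, draws each
#' subject's depth profiles directly as
#' `baseline(depth) + baseline_offset + shift * weight(depth) + noise`, with
#' independent measurement noise per hemisphere and depth point. The shift
#' applies only to patients in the affected ROI (T1 contrast). Used for
#' statistical calibration loops where imaging physics is not under test.
#'
#' @param cohort a [generateCohort()] data.frame.
#' @param effects the [EffectConfig-class] used to generate the cohort.
#' @param rois ROIs to simulate.
#' @param contrasts contrasts to simulate.
#' @param nDepths depth points per profile.
#' @param profileNoiseSd SD (ms) of the per-depth measurement noise for T1;
#'   scaled by the T2*/T1 baseline ratio for T2*.
#' @param seed integer seed.
#' @return a data.frame of profile rows: `subject_id`, `roi`, `hemisphere`,
#'   `contrast`, `depth`, `value`.
#' @export
simulateProfileCohort <- function(cohort, effects = effectConfig(),
                                  rois = "lOFC", contrasts = "T1",
                                  nDepths = 10L, profileNoiseSd = 15,
                                  seed = 1L) {
  stopifnot(nrow(cohort) >= 1, nDepths >= 1)
  validObject(effects)
  x <- (seq_len(nDepths) - 0.5) / nDepths
  hemis <- c("left", "right")
  grid <- expand.grid(
    depthIdx = seq_len(nDepths), hemisphere = hemis, contrast = contrasts,
    roi = rois, subject_id = cohort$subject_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sub <- cohort[match(grid$subject_id, cohort$subject_id), ]
  w <- .shiftWeight(x, effects@depthWeighted)

  .withSeed(seed, {
    val <- numeric(nrow(grid))
    for (ct in unique(grid$contrast)) {
      i <- grid$contrast == ct
      base <- baselineProfile(x[grid$depthIdx[i]], ct)
      scaleF <- baselineCoeffs(ct)[1] / baselineCoeffs("T1")[1]
      eff <- ifelse(ct == "T1" & grid$roi[i] == effects@affectedRoi,
                    sub$t1_profile_shift[i] * w[grid$depthIdx[i]], 0)
      val[i] <- base + sub$baseline_offset[i] * scaleF + eff +
        stats::rnorm(sum(i), 0, profileNoiseSd * scaleF)
    }
    data.frame(
      subject_id = grid$subject_id, roi = grid$roi,
      hemisphere = grid$hemisphere, contrast = grid$contrast,
      depth = x[grid$depthIdx], value = val,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a cohort table as CSV
#'
#' @param cohort a [generateCohort()] data.frame.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeCohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE)
  invisible(file)
}
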