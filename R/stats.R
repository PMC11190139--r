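#' Reduce a table of depth profiles to per-subject metrics
#'
#' Computes the three scalar metrics (mean, AUC, offset) for every
#' (subject, ROI, hemisphere, contrast) profile in a long profile table,
#' averaging hemispheres first when requested.
#'
#' @param profiles long data.frame with columns `subject_id`, `roi`,
#'   `hemisphere`, `contrast`, `depth`, `value` (as produced by
#'   [simulateProfileCohort()] or the pipeline's extraction stage).
#' @param averageHemis if `TRUE` (default), left/right profiles are averaged
#'   depthwise before metric computation and reported as
#'   `hemisphere = "averaged"`.
#' @return long data.frame: `subject_id`, `roi`, `hemisphere`, `contrast`,
#'   `metric` (`"mean"`, `"auc"`, `"offset"`), `value`.
#' @export
computeMetricsTable <- function(profiles, averageHemis = TRUE) {
  need <- c("subject_id", "roi", "hemisphere", "contrast", "depth", "value")
  stopifnot(all(need %in% names(profiles)))
  if (averageHemis && all(profiles$hemisphere %in% c("left", "right"))) {
    agg <- stats::aggregate(
      value ~ subject_id + roi + contrast + depth, data = profiles,
      FUN = mean)
    agg$hemisphere <- "averaged"
    profiles <- agg
  }
  key <- interaction(profiles$subject_id, profiles$roi, profiles$hemisphere,
                     profiles$contrast, drop = TRUE)
  out <- lapply(split(profiles, key), function(df) {
    df <- df[order(df$depth), ]
    prof <- new("DepthProfile",
                subjectId = df$subject_id[1], roi = df$roi[1],
                hemisphere = df$hemisphere[1], contrast = df$contrast[1],
                depths = df$depth, values = df$value,
                nVoxels = rep(1L, nrow(df)))
    m <- profileMetrics(prof)
    data.frame(subject_id = df$subject_id[1], roi = df$roi[1],
               hemisphere = df$hemisphere[1], contrast = df$contrast[1],
               metric = c("mean", "auc", "offset"),
               value = c(m@meanValue, m@auc, m@offset),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Core ANCOVA on a prepared data.frame with columns value, group (factor
## MDD/HC), age, sex. Returns the partial F for the group term, the
## covariate-adjusted HC - MDD difference with its t-based CI, and both
## Cohen's d variants (signed MDD - HC).
.ancovaCore <- function(df, ciLevel = 0.95) {
  n <- nrow(df)
  n1 <- sum(df$group == "MDD"); n2 <- sum(df$group == "HC")
  if (n1 < 3 || n2 < 3)
    stop("need at least 3 subjects per group")
  if (anyNA(df$value) || anyNA(df$age) || anyNA(df$sex))
    stop("missing covariates or metric values")
  if (length(unique(df$sex)) < 2L)
    stop("design error: single-sex sample makes the sex covariate singular")
  df$group <- factor(df$group, levels = c("MDD", "HC"))
  df$sex <- factor(df$sex)

  full <- stats::lm(value ~ group + age + sex, data = df)
  red <- stats::lm(value ~ age + sex, data = df)
  dfDen <- n - 4L
  sseF <- sum(stats::residuals(full)^2)
  sseR <- sum(stats::residuals(red)^2)
  if (sseF <= 1e-12 * max(1, mean(df$value)^2)) {
    ## degenerate: residual variance (numerically) zero
    if (sseR - sseF <= 1e-12 * max(1, mean(df$value)^2)) {
      Fv <- 0; p <- 1
    } else {
      Fv <- Inf; p <- 0
    }
    est <- unname(stats::coef(full)["groupHC"])
    ci <- c(est, est)
    tv <- 0
  } else {
    Fv <- (sseR - sseF) / (sseF / dfDen)
    p <- stats::pf(Fv, 1, dfDen, lower.tail = FALSE)
    est <- unname(stats::coef(full)["groupHC"])
    se <- sqrt(diag(stats::vcov(full)))[["groupHC"]]
    tcrit <- stats::qt(1 - (1 - ciLevel) / 2, dfDen)
    ci <- est + c(-1, 1) * tcrit * se
    tv <- est / se
  }
  m1 <- mean(df$value[df$group == "MDD"])
  m2 <- mean(df$value[df$group == "HC"])
  sPool <- sqrt(((n1 - 1) * stats::var(df$value[df$group == "MDD"]) +
                   (n2 - 1) * stats::var(df$value[df$group == "HC"])) /
                  (n - 2))
  dPooled <- if (sPool > 0) (m1 - m2) / sPool else 0
  dAdj <- -tv * sqrt(1 / n1 + 1 / n2) # signed MDD - HC
  list(F = Fv, df1 = 1L, df2 = dfDen, p = p,
       dPooled = dPooled, dAdjusted = dAdj,
       ciLo = ci[1], ciHi = ci[2], n = n)
}

#' Case-control ANCOVA on one profile metric
#'
#' Ordinary-least-squares ANCOVA `metric ~ group + age + sex` comparing
#' patients and controls on one (ROI, contrast, metric) while adjusting for
#' age and sex. Reports the partial F and p for the group term (denominator
#' df `N - 4`), the covariate-adjusted group difference (HC - MDD, ms) with
#' its t-based confidence interval, and two Cohen's d variants, both signed
#' MDD - HC: `effect_pooled` from raw group means over the pooled SD, and
#' `effect_adjusted = t * sqrt(1/n1 + 1/n2)` from the ANCOVA t statistic.
#'
#' @param metrics metrics table from [computeMetricsTable()].
#' @param cohort cohort table from [generateCohort()] (or any table with
#'   `subject_id`, `group`, `age`, `sex`).
#' @param roi,contrast,metric which metric to test.
#' @param hemisphere hemisphere level to use (default `"averaged"`).
#' @param ciLevel confidence level for the adjusted-difference CI.
#' @return one-row data.frame: `stage`, `roi`, `contrast`, `metric`, `term`,
#'   `statistic` (F), `df1`, `df2`, `p`, `effect_pooled`, `effect_adjusted`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
ancovaGroupTest <- function(metrics, cohort, roi = "lOFC", contrast = "T1",
                            metric = "mean", hemisphere = "averaged",
                            ciLevel = 0.95) {
  sel <- metrics$roi == roi & metrics$contrast == contrast &
    metrics$metric == metric & metrics$hemisphere == hemisphere
  if (!any(sel))
    stop(sprintf("no metric rows for %s/%s/%s/%s", roi, contrast, metric,
                 hemisphere))
  df <- merge(metrics[sel, c("subject_id", "value")],
              cohort[, c("subject_id", "group", "age", "sex")],
              by = "subject_id")
  r <- .ancovaCore(df, ciLevel)
  data.frame(stage = "case-control", roi = roi, contrast = contrast,
             metric = metric, term = "group",
             statistic = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
             effect_pooled = r$dPooled, effect_adjusted = r$dAdjusted,
             ci_lo = r$ciLo, ci_hi = r$ciHi, n = r$n,
             stringsAsFactors = FALSE)
}

#' Kendall rank correlation with bootstrap confidence interval
#'
#' Kendall's tau-b with tie correction; the p-value uses the tie-adjusted
#' normal approximation. The confidence interval is a subject-level
#' percentile bootstrap (pairs resampled with replacement), seeded.
#'
#' @param x,y numeric vectors; pairwise-complete observations are used.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param ciLevel confidence level.
#' @return one-row data.frame: `tau`, `p`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' kendallCorrelation(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
kendallCorrelation <- function(x, y, nBoot = 2000L, seed = 1L,
                               ciLevel = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 pairwise-complete observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: input is all tied")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  taus <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[i])) < 2L || length(unique(y[i])) < 2L)
        return(NA_real_)
      stats::cor(x[i], y[i], method = "kendall")
    }, numeric(1))
  })
  qs <- stats::quantile(taus, c((1 - ciLevel) / 2, 1 - (1 - ciLevel) / 2),
                        na.rm = TRUE, names = FALSE)
  data.frame(tau = unname(ct$estimate), p = ct$p.value,
             ci_lo = qs[1], ci_hi = qs[2], n = n)
}

#' Hemisphere lateralization test
#'
#' Paired t-test of left vs right metric values per (ROI, contrast). When no
#' ROI/contrast shows a significant asymmetry, downstream analysis may use
#' hemisphere-averaged profiles. Subjects missing either hemisphere are
#' excluded and counted.
#'
#' @param metrics metrics table from
#'   [computeMetricsTable()]`(averageHemis = FALSE)`.
#' @param metric which metric to test (default `"mean"`).
#' @return data.frame with one row per (roi, contrast): `roi`, `contrast`,
#'   `metric`, `statistic` (t), `df`, `p`, `mean_diff` (left - right), `n`,
#'   `n_excluded`.
#' @export
lateralizationTest <- function(metrics, metric = "mean") {
  sel <- metrics$metric == metric &
    metrics$hemisphere %in% c("left", "right")
  m <- metrics[sel, ]
  if (!nrow(m)) stop("no left/right metric rows present")
  combos <- unique(m[, c("roi", "contrast")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    mi <- m[m$roi == combos$roi[i] & m$contrast == combos$contrast[i], ]
    w <- stats::reshape(mi[, c("subject_id", "hemisphere", "value")],
                        idvar = "subject_id", timevar = "hemisphere",
                        direction = "wide")
    lv <- w$value.left; rv <- w$value.right
    ok <- !is.na(lv) & !is.na(rv)
    nExcl <- sum(!ok)
    d <- lv[ok] - rv[ok]
    if (length(d) < 2) stop("need at least 2 complete left/right pairs")
    if (stats::sd(d) == 0) {
      tv <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(d)
      tv <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(roi = combos$roi[i], contrast = combos$contrast[i],
               metric = metric, statistic = tv, df = length(d) - 1L, p = p,
               mean_diff = mean(d), n = length(d), n_excluded = nExcl,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-patient analyses, gated on case-control results
#'
#' For every (ROI, contrast) with at least one metric significant in the
#' case-control stage, probes — among patients only — whether symptom
#' severity (IDS) and childhood trauma (CTQ) correlate with each metric
#' (Kendall tau with bootstrap CI), and whether antidepressant use and
#' comorbid anxiety relate to the metrics (age/sex-adjusted two-group OLS,
#' same form as the case-control ANCOVA). An empty gating set yields an
#' empty table, not an error.
#'
#' @param metrics metrics table from [computeMetricsTable()].
#' @param cohort cohort table from [generateCohort()].
#' @param stage1 case-control results (rows from [ancovaGroupTest()]).
#' @param alpha gating significance level (default 0.05).
#' @param metricsTested which metrics to analyse in gated pairs.
#' @param nBoot,seed bootstrap settings for the correlations.
#' @return data.frame in the same long schema as [ancovaGroupTest()], with
#'   `stage = "within-patient"`, `term` naming the clinical variable, and
#'   `statistic` holding tau (correlations) or F (group terms).
#' @export
withinPatientAnalyses <- function(metrics, cohort, stage1, alpha = 0.05,
                                  metricsTested = c("mean", "auc", "offset"),
                                  nBoot = 2000L, seed = 1L) {
  gate <- unique(stage1[stage1$p < alpha, c("roi", "contrast")])
  empty <- data.frame(
    stage = character(), roi = character(), contrast = character(),
    metric = character(), term = character(), statistic = numeric(),
    df1 = integer(), df2 = integer(), p = numeric(),
    effect_pooled = numeric(), effect_adjusted = numeric(),
    ci_lo = numeric(), ci_hi = numeric(), n = integer(),
    stringsAsFactors = FALSE)
  if (!nrow(gate)) return(empty)
  pat <- cohort[cohort$group == "MDD", ]

  rows <- list()
  for (g in seq_len(nrow(gate))) {
    for (met in metricsTested) {
      sel <- metrics$roi == gate$roi[g] & metrics$contrast == gate$contrast[g] &
        metrics$metric == met & metrics$hemisphere == "averaged" &
        metrics$subject_id %in% pat$subject_id
      mv <- metrics[sel, c("subject_id", "value")]
      df <- merge(mv, pat, by = "subject_id")
      for (v in c("ids_score", "ctq_score")) {
        kc <- kendallCorrelation(df[[v]], df$value, nBoot = nBoot,
                                 seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = "within-patient", roi = gate$roi[g],
          contrast = gate$contrast[g], metric = met, term = v,
          statistic = kc$tau, df1 = NA_integer_, df2 = NA_integer_,
          p = kc$p, effect_pooled = NA_real_, effect_adjusted = NA_real_,
          ci_lo = kc$ci_lo, ci_hi = kc$ci_hi, n = kc$n,
          stringsAsFactors = FALSE)
      }
      for (v in c("on_antidepressants", "comorbid_anxiety")) {
        sub <- data.frame(value = df$value,
                          group = ifelse(df[[v]], "MDD", "HC"),
                          age = df$age, sex = df$sex)
        rows[[length(rows) + 1L]] <- tryCatch({
          r <- .ancovaCore(sub)
          data.frame(
            stage = "within-patient", roi = gate$roi[g],
            contrast = gate$contrast[g], metric = met, term = v,
            statistic = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
            effect_pooled = r$dPooled, effect_adjusted = r$dAdjusted,
            ci_lo = r$ciLo, ci_hi = r$ciHi, n = r$n,
            stringsAsFactors = FALSE)
        }, error = function(e) data.frame(
          stage = "within-patient", roi = gate$roi[g],
          contrast = gate$contrast[g], metric = met, term = v,
          statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
          p = NA_real_, effect_pooled = NA_real_,
          effect_adjusted = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          n = nrow(sub), stringsAsFactors = FALSE))
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
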