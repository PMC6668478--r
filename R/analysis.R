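#' Mean arterial pressure
#'
#' `MAP = (2 * DBP + SBP) / 3`, in mmHg. Vectorized; the exact value is
#' returned (print/CSV output rounds to 2 decimals). Equal pressures are a
#' precondition violation and draw a warning, but the analytic value is
#' still returned.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @return MAP in mmHg.
#' @export
compute_map <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("pressures must be positive")
  if (any(sbp < dbp)) stop("systolic pressure must be >= diastolic")
  if (any(sbp == dbp)) warning("equal systolic and diastolic pressure")
  (2 * dbp + sbp) / 3
}

#' Segmentation agreement metrics
#'
#' Voxel-level agreement between a segmentation S and a gold standard G:
#' Dice similarity coefficient `DSC = 2 TP / (2 TP + FP + FN)`, sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)` (all in percent), and the
#' absolute vessels volume difference `AVVD = | |G| - |S| | / |G|` in
#' percent, where `|.|` counts foreground voxels.
#'
#' @param S segmented [vessel_mask()] or logical array.
#' @param G gold-standard mask on the same grid.
#' @return An object of class `seg_eval` with `TP, TN, FP, FN, dsc,
#'   sensitivity, specificity, avvd` (percent).
#' @export
evaluate_segmentation <- function(S, G) {
  s <- if (inherits(S, "vessel_mask")) S$mask else S
  g <- if (inherits(G, "vessel_mask")) G$mask else G
  stopifnot(identical(dim(s), dim(g)))
  tp <- sum(s & g)
  fp <- sum(s & !g)
  fn <- sum(!s & g)
  tn <- sum(!s & !g)
  if (sum(g) == 0) stop("empty gold standard: AVVD undefined")
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 dsc = 200 * tp / (2 * tp + fp + fn),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 avvd = 100 * abs(sum(g) - sum(s)) / sum(g)),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("<seg_eval> DSC %.2f%%  Sens %.2f%%  Spec %.2f%%  AVVD %.2f%%\n",
              x$dsc, x$sensitivity, x$specificity, x$avvd))
  invisible(x)
}

#' Simulate a repeated-measures blood-pressure cohort
#'
#' Synthetic stand-in for a small longitudinal cohort (defaults: 15
#' subjects, two timepoints ~2 years apart). A vascular feature is drawn
#' per observation, and MAP is generated from the random-intercept model
#' the association test fits:
#' `MAP = map_mean + effect * z + b_subject + e`, with `z` the standardized
#' feature, `b_subject ~ N(0, subject_sd^2)` shared across timepoints and
#' `e ~ N(0, residual_sd^2)`. `effect` is in mmHg per feature SD and carries
#' the association sign (negative for vessel radius, positive for curvature
#' summaries). Systolic/diastolic readings are reconstructed from MAP via a
#' plausible pulse pressure so `MAP = (2 DBP + SBP)/3` holds exactly. At
#' the defaults MAP spans roughly 75-110 mmHg.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_timepoints observations per subject.
#' @param feature_name feature column name in the output.
#' @param effect association strength, mmHg per feature SD (0 = null).
#' @param feature_mean,feature_sd feature location/scale in its own units
#'   (`feature_sd = 0` makes the feature, and hence the association,
#'   degenerate-constant).
#' @param residual_sd within-subject MAP residual SD, mmHg.
#' @param subject_sd between-subject random-intercept SD, mmHg.
#' @param map_mean grand mean MAP, mmHg.
#' @param seed RNG seed.
#' @return data frame with `subject_id, timepoint, sbp_mmHg, dbp_mmHg,
#'   map_mmHg` and the feature column.
#' @export
simulate_cohort <- function(n_subjects = 15, n_timepoints = 2,
                            feature_name = "median_radius_mm",
                            effect = -5, feature_mean = 2.5,
                            feature_sd = 0.4, residual_sd = 3,
                            subject_sd = 5, map_mean = 92.5, seed = 1) {
  stopifnot(n_subjects >= 2, n_timepoints >= 1)
  with_seed(seed, {
    n <- n_subjects * n_timepoints
    subject <- rep(seq_len(n_subjects), each = n_timepoints)
    tp <- rep(paste0("t", seq_len(n_timepoints) - 1), n_subjects)
    z <- rnorm(n)
    b <- rnorm(n_subjects, 0, subject_sd)[subject]
    map <- map_mean + effect * z + b + rnorm(n, 0, residual_sd)
    pp <- pmax(rnorm(n, 45, 8), 20) # pulse pressure
    dbp <- map - pp / 3
    sbp <- dbp + pp
    out <- data.frame(subject_id = subject, timepoint = tp,
                      sbp_mmHg = sbp, dbp_mmHg = dbp,
                      map_mmHg = compute_map(sbp, dbp))
    out[[feature_name]] <- feature_mean + feature_sd * z
    out
  })
}

#' Mixed-model association between MAP and a vascular feature
#'
#' Fits `MAP ~ feature + (1 | subject)` by full maximum likelihood (not
#' REML, so the fixed-effect structures are comparable) and tests the
#' feature by a likelihood-ratio test against the intercept-only model with
#' the same random intercept: chi-squared with 1 degree of freedom. A
#' singular random-effect fit is flagged and the test falls back to
#' ordinary least-squares regression (never silently).
#'
#' @param table data frame with `map_mmHg`, `subject_id` and the feature.
#' @param feature_name column to test.
#' @return An object of class `association_result`: `feature, chisq, df,
#'   p_value, coefficient, sign, singular, method`.
#' @export
fit_map_association <- function(table, feature_name) {
  stopifnot(feature_name %in% names(table),
            all(c("map_mmHg", "subject_id") %in% names(table)))
  tab <- table[complete.cases(table[, c("map_mmHg", "subject_id",
                                        feature_name)]), ]
  tab$..feat <- tab[[feature_name]]
  fit_lmm <- function(formula) {
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = tab, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  }
  full <- tryCatch(fit_lmm(map_mmHg ~ ..feat + (1 | subject_id)),
                   error = function(e) NULL)
  null <- tryCatch(fit_lmm(map_mmHg ~ 1 + (1 | subject_id)),
                   error = function(e) NULL)
  singular <- is.null(full) || is.null(null) ||
    lme4::isSingular(full, tol = 1e-4)
  if (!singular) {
    chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
    coefficient <- lme4::fixef(full)[["..feat"]]
    method <- "lmm_lrt"
  } else {
    f1 <- lm(map_mmHg ~ ..feat, data = tab)
    f0 <- lm(map_mmHg ~ 1, data = tab)
    chisq <- max(0, 2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0))))
    coefficient <- coef(f1)[["..feat"]]
    method <- "ols_lrt_fallback"
  }
  structure(list(feature = feature_name, chisq = chisq, df = 1L,
                 p_value = pchisq(chisq, 1, lower.tail = FALSE),
                 coefficient = coefficient, sign = sign(coefficient),
                 singular = singular, method = method),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association> %s: chi^2(%d) = %.4f, p = %.4g, coef %s%s\n",
              x$feature, x$df, x$chisq, x$p_value,
              if (x$sign >= 0) "+" else "-",
              if (x$singular) " [singular fit: OLS fallback]" else ""))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param bias_correct run bias-field correction.
#' @param ggmrf [ggmrf_params()] for homogeneity enhancement (`NULL` skips).
#' @param skull_strip run skull stripping (`--no-skull-strip` equivalent:
#'   `FALSE`).
#' @param refine [refine_config()] for the local adaptive stage.
#' @param z_fraction axial lower/upper split fraction of the brain mask.
#' @param mesh_sigma indicator smoothing for surface extraction, voxels.
#' @param max_subordinate LCDG subordinate component cap per sign.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bias_correct = TRUE, ggmrf = ggmrf_params(),
                            skull_strip = TRUE, refine = refine_config(),
                            z_fraction = 0.5, mesh_sigma = 0.5,
                            max_subordinate = 4) {
  structure(list(bias_correct = bias_correct, ggmrf = ggmrf,
                 skull_strip = skull_strip, refine = refine,
                 z_fraction = z_fraction, mesh_sigma = mesh_sigma,
                 max_subordinate = max_subordinate),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full per-subject pipeline
#'
#' Preprocessing (bias correction, GGMRF smoothing, skull stripping), the
#' two-stage segmentation (global LCDG Bayesian classification, then local
#' adaptive refinement), vascular feature extraction (median radius via the
#' distance-map CDF; curvature-based tortuosity globally and per axial
#' section), and MAP. Fully deterministic for fixed inputs and
#' configuration.
#'
#' @param volume the subject's [volume3d()].
#' @param sbp,dbp blood-pressure readings, mmHg.
#' @param config a [pipeline_config()].
#' @param subject_id,timepoint identifiers carried into the record.
#' @return list with `record` (data frame: one row per section with the
#'   feature vector and pressures), `mask_initial`, `mask_final`, `model`
#'   (the fitted `lcdg_model`), `brain_mask`, `radius_cdf` and `mesh`.
#' @export
run_subject_pipeline <- function(volume, sbp, dbp,
                                 config = pipeline_config(),
                                 subject_id = "subject", timepoint = "t0") {
  vol <- volume
  if (config$bias_correct)
    vol <- stage("bias_correction", correct_bias(vol)$volume)
  if (!is.null(config$ggmrf))
    vol <- stage("ggmrf", ggmrf_smooth(vol, config$ggmrf))
  brain <- if (config$skull_strip) stage("skull_strip", strip_skull(vol))
           else array(TRUE, dim(vol$data))
  model <- stage("lcdg", {
    h <- empirical_density(vol, mask = brain)
    fit_lcdg(h, Q = vol$Q, max_subordinate = config$max_subordinate)
  })
  initial <- stage("classify", classify_initial(vol, model, mask = brain))
  lut <- lcdg_decision(model)
  global_thr <- if (any(lut)) min(which(lut)) - 1 else Inf
  final <- stage("refine", refine_segmentation(vol, initial, config$refine,
                                               global_threshold = global_thr,
                                               mask = brain))
  feats <- stage("features", {
    dmap <- distance_transform(final)
    cdf <- radius_cdf(vessel_radii(final, dmap))
    mesh <- extract_mesh(final, smooth_sigma = config$mesh_sigma)
    curv <- estimate_principal_curvatures(mesh)
    sec <- split_sections(brain, config$z_fraction)
    z_cut_mm <- (sec$z_cut - 1) * vol$spacing[3]
    lower_v <- curv$vertices[, 3] <= z_cut_mm
    sk <- skeletonize(final$mask, dmap)
    zidx <- slice.index(final$mask, 3)
    rows <- list()
    for (s in c("global", "lower", "upper")) {
      vs <- switch(s, global = NULL, lower = which(lower_v),
                   upper = which(!lower_v))
      radii <- switch(s,
        global = dmap[sk],
        lower = dmap[sk & zidx <= sec$z_cut],
        upper = dmap[sk & zidx > sec$z_cut])
      cs <- tryCatch(curvature_summaries(curv, vs, section = s),
                     error = function(e) NULL)
      if (is.null(cs) || length(radii) == 0) next
      cs$median_radius_mm <- median(radii)
      rows[[s]] <- cs
    }
    list(rows = do.call(rbind, rows), cdf = cdf, mesh = mesh, curv = curv)
  })
  map <- compute_map(sbp, dbp)
  rec <- cbind(data.frame(subject_id = subject_id, timepoint = timepoint,
                          sbp_mmHg = sbp, dbp_mmHg = dbp, map_mmHg = map),
               feats$rows, row.names = NULL)
  rec <- rec[, c("subject_id", "timepoint", "sbp_mmHg", "dbp_mmHg",
                 "map_mmHg", "section", "median_radius_mm", "median_H",
                 "median_K", "mean_H", "mean_K", "integral_absK")]
  list(record = rec, mask_initial = initial, mask_final = final,
       model = model, brain_mask = brain, radius_cdf = feats$cdf,
       mesh = feats$mesh, curvatures = feats$curv)
}
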