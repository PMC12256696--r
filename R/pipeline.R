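# End-to-end orchestration: phantom cohort -> preprocessing -> deformation
# model -> similarity metrics -> sphere placement -> synthetic lattice dose
# -> DVH evaluation on placed vs. isodose-fitted contours -> paired
# comparison, with a reproducible JSON report.

#' Pipeline configuration
#'
#' Defaults describe a small reproducible in-silico study: a cohort of
#' thorax phantoms, a toy-scale deformation model, the clinical placement
#' constraints, a 2000 cGy single-fraction prescription with a 0.3 valley
#' ratio, and the protocol OAR limits (600 cGy D0.03cc, skin D1cc 600 cGy;
#' lung MVS 740 cGy / 1000 cc, liver MVS 910 cGy / 700 cc).
#'
#' @param region phantom region preset.
#' @param n_cases number of phantom cases (also the training pairs).
#' @param seed master seed; all stages derive from it.
#' @param target_shape preprocessing output grid for the model stage.
#' @param model a [model_spec()].
#' @param placement a [placement_params()].
#' @param prescription_cGy,valley_ratio,peak_factor synthetic dose painter
#'   settings.
#' @param oar_limits list of dose limits applied in the report.
#' @param gtv_semiaxes_mm,oars phantom tumour/OAR geometry passed to
#'   [phantom_spec()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(region = "thorax", n_cases = 5L, seed = 7L,
                            target_shape = c(48, 48, 24),
                            model = model_spec(levels = 2L, start_channels = 4L,
                                               epochs = 8L, lr = 0.02),
                            placement = placement_params(),
                            prescription_cGy = 2000, valley_ratio = 0.3,
                            peak_factor = 1.3,
                            oar_limits = list(D003cc_cGy = 600, skin_D1cc_cGy = 600,
                                              lung_mvs = c(level_cGy = 740, min_cc = 1000),
                                              liver_mvs = c(level_cGy = 910, min_cc = 700)),
                            gtv_semiaxes_mm = c(70, 55, 50),
                            oars = list(cord = list(type = "cylinder",
                                                    center = c(0, 67, 0),
                                                    radius = 7))) {
  stopifnot(n_cases >= 1, prescription_cGy > 0,
            valley_ratio > 0, valley_ratio < 1)
  structure(list(region = region, n_cases = as.integer(n_cases),
                 seed = as.integer(seed), target_shape = as.integer(target_shape),
                 model = model, placement = placement,
                 prescription_cGy = prescription_cGy,
                 valley_ratio = valley_ratio, peak_factor = peak_factor,
                 oar_limits = oar_limits,
                 gtv_semiaxes_mm = gtv_semiaxes_mm, oars = oars),
            class = "pipeline_config")
}

sim_as_list <- function(s) {
  list(mae_HU = s$mae_HU, ncc = s$ncc, ssim = s$ssim, gmsd = s$gmsd,
       n_voxels = s$n_voxels, mask_used = s$mask_used)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

# carry a mask through a predicted deformation field (trilinear + 0.5 cut)
warp_mask <- function(mask, dvf) {
  w <- warp(image_volume(array(as.double(mask$voxels), grid_shape(mask)),
                         mask$spacing, mask$origin), dvf, fill = 0)
  binary_mask(array(as.integer(w$voxels >= 0.5), grid_shape(mask)),
              mask$spacing, mask$origin)
}

case_structures <- function(dose, gtv, spheres, oars, config) {
  ras <- rasterize_spheres(spheres, gtv)
  out <- list(
    gtv = dvh_metrics(dose, gtv, config$prescription_cGy, dv_cc = 0.03),
    spheres = dvh_metrics(dose, ras$union, config$prescription_cGy, dv_cc = 0.03))
  for (nm in names(oars)) {
    o <- oars[[nm]]
    mvs <- NULL
    if (grepl("lung", nm)) mvs <- config$oar_limits$lung_mvs[["level_cGy"]]
    if (grepl("liver", nm)) mvs <- config$oar_limits$liver_mvs[["level_cGy"]]
    vcc <- if (grepl("skin", nm)) c(0.03, 1) else 0.03
    out[[nm]] <- dvh_metrics(dose, o, config$prescription_cGy,
                             mvs_level_cGy = mvs, dv_cc = vcc,
                             structure_name = nm)
  }
  out
}

#' Run the full in-silico LRT workflow
#'
#' Generates the phantom cohort, preprocesses every dCT/pCT pair, trains the
#' deformation model on all pairs, predicts each sCT and scores similarity,
#' places lattice spheres per case, paints the synthetic lattice dose,
#' evaluates DVH metrics on the placed contours and on contours re-fitted
#' from the 50% isodose (the "recalculated" plan), checks the configured OAR
#' limits, and compares the two metric sets across cases with the Wilcoxon
#' signed-rank test. Bit-reproducible from the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, `report.json` and the
#'   rendered summary are written there.
#' @return The report as a nested list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundles <- run_stage("phantom", lapply(seq_len(config$n_cases), function(i) {
    make_phantom(phantom_spec(region = config$region,
                              gtv_center_mm = c(0, 0, 0),
                              gtv_semiaxes_mm = config$gtv_semiaxes_mm,
                              oars = config$oars,
                              seed = config$seed + i))
  }))
  pre <- run_stage("preprocess", lapply(bundles, function(b)
    preprocess_pair(b$dct, b$pct, target_shape = config$target_shape)))

  mspec <- config$model
  mspec$seed <- config$seed
  model <- run_stage("train", train_sct_model(
    lapply(pre, function(p) list(dct = p$dct_ready, pct = p$pct_ready)), mspec))

  cases <- vector("list", config$n_cases)
  metrics_a <- metrics_b <- vector("list", config$n_cases)
  all_ok <- TRUE
  for (i in seq_len(config$n_cases)) {
    b <- bundles[[i]]; p <- pre[[i]]
    pred <- run_stage("predict", predict_sct(model, p$dct_ready))
    sim_dct <- similarity_report(p$dct_ready, p$pct_ready, p$pct_mask)
    sim_sct <- similarity_report(pred$sct, p$pct_ready, p$pct_mask)

    # the planning target as the model predicts it: diagnostic-frame GTV
    # carried through the predicted deformation, then back onto the native
    # grid; plans are made on this target and recalculated on the truth
    gtv_pred <- run_stage("predict", {
      gp <- warp_mask(resample_to_grid(b$dct_gtv, p$dct_ready), pred$dvf)
      gp <- resample_to_grid(gp, b$gtv)
      if (sum(gp$voxels) == 0L) stop("predicted GTV is empty")
      gp
    })
    spheres <- run_stage("plan", place_spheres(gtv_pred, b$oars, config$placement))
    aud <- audit_placement(spheres, gtv_pred, b$oars, config$placement)
    dose_a <- run_stage("dose", synth_lattice_dose(
      spheres, gtv_pred, config$prescription_cGy, config$valley_ratio,
      config$peak_factor))
    dose_b <- run_stage("dose", synth_lattice_dose(
      spheres, b$gtv, config$prescription_cGy, config$valley_ratio,
      config$peak_factor))
    fitted <- run_stage("fit", fit_spheres_from_isodose(
      dose_b, config$prescription_cGy, 0.5, config$placement$sphere_diameter_mm))
    ma <- run_stage("dose_eval", case_structures(dose_a, gtv_pred, spheres,
                                                 b$oars, config))
    mb <- run_stage("dose_eval", case_structures(dose_b, b$gtv, fitted,
                                                 b$oars, config))
    metrics_a[[i]] <- ma; metrics_b[[i]] <- mb

    limits <- character(0)
    for (nm in names(b$oars)) {
      lim <- if (grepl("skin", nm)) config$oar_limits$skin_D1cc_cGy
             else config$oar_limits$D003cc_cGy
      val <- if (grepl("skin", nm)) mb[[nm]][["D1cc"]] else mb[[nm]][["D0.03cc"]]
      if (!is.null(val) && val > lim)
        limits <- c(limits, sprintf("%s exceeds %g cGy (%.1f)", nm, lim, val))
      if (grepl("lung", nm) && !is.na(mb[[nm]]$MVS_cc) &&
          mb[[nm]]$MVS_cc < config$oar_limits$lung_mvs[["min_cc"]])
        limits <- c(limits, sprintf("lung MVS %.0f cc below %g cc",
                                    mb[[nm]]$MVS_cc, config$oar_limits$lung_mvs[["min_cc"]]))
      if (grepl("liver", nm) && !is.na(mb[[nm]]$MVS_cc) &&
          mb[[nm]]$MVS_cc < config$oar_limits$liver_mvs[["min_cc"]])
        limits <- c(limits, sprintf("liver MVS %.0f cc below %g cc",
                                    mb[[nm]]$MVS_cc, config$oar_limits$liver_mvs[["min_cc"]]))
    }
    ok <- length(aud$violations) == 0 && length(limits) == 0
    all_ok <- all_ok && ok
    cases[[i]] <- list(
      seed = config$seed + i,
      similarity = list(dct_vs_pct = sim_as_list(sim_dct),
                        sct_vs_pct = sim_as_list(sim_sct)),
      n_spheres = aud$n_spheres,
      audit = unclass(aud),
      n_fitted = nrow(sphere_centers(fitted)),
      dvh_planned = lapply(ma, unclass),
      dvh_recalc = lapply(mb, unclass),
      limit_violations = limits,
      pass = ok)
  }
  comparison <- run_stage("compare", if (config$n_cases >= 2)
    as.data.frame(compare_plans(metrics_a, metrics_b)) else NULL)
  report <- list(
    config = list(region = config$region, n_cases = config$n_cases,
                  seed = config$seed, target_shape = config$target_shape,
                  prescription_cGy = config$prescription_cGy,
                  valley_ratio = config$valley_ratio,
                  peak_factor = config$peak_factor,
                  model = unclass(mspec), placement = unclass(config$placement),
                  oar_limits = config$oar_limits),
    training = list(epochs = mspec$epochs, loss_trace = model$trace),
    cases = cases,
    comparison = comparison,
    pass = all_ok)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(render_report(report), file.path(out_dir, "report.txt"))
    return(invisible(report))
  }
  report
}

fmt_quartiles <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.3f [%.3f, %.3f]", q[2], q[1], q[3])
}

#' Render a pipeline report as readable text
#'
#' Formats the similarity block (median and quartiles per metric), the
#' placement audits, the per-metric deviation listing, and flags any limit
#' or constraint violation. No new numbers are computed.
#'
#' @param report output of [run_pipeline()].
#' @return Character vector of lines (also printed invisibly usable with
#'   `writeLines`).
#' @export
render_report <- function(report) {
  out <- c(sprintf("LRT in-silico workflow report (seed %d, %d case(s))",
                   report$config$seed, length(report$cases)),
           sprintf("prescription %g cGy, valley ratio %.2f",
                   report$config$prescription_cGy, report$config$valley_ratio), "")
  if (length(report$cases) == 0) return(c(out, "no paired cases"))
  out <- c(out, "Image similarity (median [IQR] across cases):")
  for (mt in c("mae_HU", "ncc", "ssim", "gmsd")) {
    vd <- vapply(report$cases, function(cs) cs$similarity$dct_vs_pct[[mt]], numeric(1))
    vs <- vapply(report$cases, function(cs) cs$similarity$sct_vs_pct[[mt]], numeric(1))
    out <- c(out, sprintf("  %-7s dCT vs pCT %s | sCT vs pCT %s",
                          mt, fmt_quartiles(vd), fmt_quartiles(vs)))
  }
  out <- c(out, "", "Sphere placement:")
  for (i in seq_along(report$cases)) {
    cs <- report$cases[[i]]
    flag <- if (length(cs$audit$violations)) "VIOLATIONS" else "ok"
    out <- c(out, sprintf("  case %d: %d sphere(s), %d fitted, audit %s",
                          i, cs$n_spheres, cs$n_fitted, flag))
    for (v in cs$audit$violations) out <- c(out, sprintf("    !! %s", v))
    for (v in cs$limit_violations) out <- c(out, sprintf("    !! limit: %s", v))
  }
  cmp <- report$comparison
  if (is.null(cmp) || nrow(cmp) == 0) {
    out <- c(out, "", "Plan comparison: no paired cases")
  } else {
    out <- c(out, "", "Planned vs recalculated DVH deviations:")
    for (r in seq_len(nrow(cmp))) {
      out <- c(out, sprintf("  %-10s %-12s mean dev %9.3f  median %9.3f  p %s",
                            cmp$structure[r], cmp$metric[r], cmp$mean_dev[r],
                            cmp$median_dev[r],
                            ifelse(is.na(cmp$p_value[r]), "-",
                                   sprintf("%.4f", cmp$p_value[r]))))
    }
  }
  out <- c(out, "", sprintf("Overall: %s", if (isTRUE(report$pass)) "PASS" else "FAIL"))
  out
}
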