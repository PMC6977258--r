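#' Configuration of an end-to-end study emulation
#'
#' Bundles every knob of the pipeline — cohort sizes, phantom spec, observer
#' model, fit configuration, seed and output directory — so that a run is
#' reproducible from the configuration alone.
#'
#' @param n_benign,n_malignant Cohort group sizes.
#' @param spec A [nodule_phantom_spec()].
#' @param observer An [observer_model()].
#' @param fit A [fit_config()].
#' @param groups Benign/malignant [group_distribution()]s.
#' @param fit_mode `"fit_then_average"` (voxelwise maps averaged over the
#'   ROI, the pixel-by-pixel reading) or `"average_then_fit"`.
#' @param seed Integer master seed.
#' @param out_dir Output directory for report tables (`NULL` = don't write).
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_benign = 24, n_malignant = 22,
                         spec = nodule_phantom_spec(),
                         observer = observer_model(),
                         fit = fit_config(),
                         groups = thyroid_group_defaults(),
                         fit_mode = c("fit_then_average", "average_then_fit"),
                         seed = 1, out_dir = NULL, verbose = FALSE) {
  fit_mode <- match.arg(fit_mode)
  structure(list(n_benign = n_benign, n_malignant = n_malignant, spec = spec,
                 observer = observer, fit = fit, groups = groups,
                 fit_mode = fit_mode, seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "study_config")
}

# The three delineations mirrored from the study design: reader 1 session 1,
# reader 2 sessions 1 and 2 (intraobserver = reader 2's two sessions,
# interobserver = readers 1 vs 2, first sessions).
study_delineations <- function() {
  data.frame(observer = c(1L, 2L, 2L), session = c(1L, 1L, 2L))
}

measurement_columns <- function() {
  c("nodule_id", "group", "method", "observer", "session",
    "D", "f", "Dstar", "ADC600", "ADC990")
}

#' Measure every nodule of a cohort with both ROI methods
#'
#' Simulates the two-reader/two-session delineations of each phantom, fits
#' voxelwise IVIM and two-point ADC maps over the union of all its ROIs, and
#' aggregates to one measurement row per (nodule, method, observer,
#' session). ADC600/ADC990 are recorded for W-L rows only, matching the
#' study protocol. All parameter columns are on the reporting scale
#' (x10^-3 mm^2/s for D, D*, ADC; % for f).
#'
#' @param cohort A `nodule_cohort` from [generate_cohort()].
#' @param observer An [observer_model()].
#' @param fit A [fit_config()].
#' @param fit_mode See [study_config()].
#' @param seed Integer seed for the delineation simulation.
#' @param verbose Progress messages.
#' @return Data frame with columns
#'   `r paste(measurement_columns(), collapse = ", ")`.
#' @export
measure_cohort <- function(cohort, observer = observer_model(),
                           fit = fit_config(),
                           fit_mode = "fit_then_average", seed = 1,
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  deli <- study_delineations()
  rows <- list()
  for (i in seq_along(cohort$nodules)) {
    nod <- cohort$nodules[[i]]
    masks <- simulate_observer_masks(nod, observer, n_observers = 2,
                                     n_sessions = 2,
                                     seed = sub_seed(cohort$seed, 2000 + i))
    used <- Filter(function(m) {
      any(m$observer == deli$observer & m$session == deli$session)
    }, masks)

    vol <- nod$volume
    maps <- NULL; adc600 <- NULL; adc990 <- NULL
    if (fit_mode == "fit_then_average") {
      union <- Reduce(`|`, lapply(used, `[[`, "mask"), nod$true_mask)
      maps <- fit_ivim_map(vol, union, fit)
      adc600 <- fit_adc_map(vol, union, 600)
      adc990 <- fit_adc_map(vol, union, 990)
    }

    for (d in seq_len(nrow(deli))) {
      obs <- deli$observer[d]; ses <- deli$session[d]
      pick <- function(method) {
        Filter(function(m) m$method == method & m$observer == obs &
                 m$session == ses, used)
      }
      wl <- pick("W-L")[[1]]
      ss <- pick("S-S")

      if (fit_mode == "fit_then_average") {
        mw <- summarize_roi(maps, wl)
        a6 <- mean(adc600[wl$mask], na.rm = TRUE)
        a9 <- mean(adc990[wl$mask], na.rm = TRUE)
        s1 <- summarize_roi(maps, ss[[1]]); s2 <- summarize_roi(maps, ss[[2]])
      } else {
        mw <- roi_fit_mode(vol, wl, fit, "average_then_fit")
        mean_decay <- roi_mean_decay(vol, wl$mask)
        a6 <- fit_adc_two_point(mean_decay, 600)$adc
        a9 <- fit_adc_two_point(mean_decay, 990)$adc
        s1 <- roi_fit_mode(vol, ss[[1]], fit, "average_then_fit")
        s2 <- roi_fit_mode(vol, ss[[2]], fit, "average_then_fit")
        s1$n_voxels <- ss[[1]]$n_voxels; s2$n_voxels <- ss[[2]]$n_voxels
      }
      sa <- aggregate_ss(s1[c("D", "f", "D_star", "n_voxels")],
                         s2[c("D", "f", "D_star", "n_voxels")])
      rows[[length(rows) + 1]] <- data.frame(
        nodule_id = i, group = as.character(cohort$labels[i]),
        method = c("W-L", "S-S"), observer = obs, session = ses,
        D = c(mw$D, sa$D) * 1e3, f = c(mw$f, sa$f) * 1e2,
        Dstar = c(mw$D_star, sa$D_star) * 1e3,
        ADC600 = c(a6 * 1e3, NA), ADC990 = c(a9 * 1e3, NA))
    }
    if (verbose && (i %% 10 == 0)) {
      message("  measured ", i, "/", length(cohort$nodules), " nodules")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, measurement_columns()]
}

roi_mean_decay <- function(volume, mask) {
  nb <- length(volume$b)
  sig <- matrix(volume$data, ncol = nb)[which(mask), , drop = FALSE]
  signal_decay(volume$b, colMeans(sig))
}

# Extract one delineation's values for a parameter/method as a vector
# ordered by nodule id.
deli_values <- function(measurements, param, method, observer, session) {
  m <- measurements[measurements$method == method &
                      measurements$observer == observer &
                      measurements$session == session, ]
  m[order(m$nodule_id), param]
}

#' Reproducibility report: ICC and Bland-Altman tables
#'
#' For each IVIM parameter and ROI method, computes intraobserver agreement
#' (reader 2, session 1 vs session 2) and interobserver agreement (reader 1
#' vs reader 2, first sessions) as ICC(2,1) with 95% CI and band, and as
#' Bland-Altman mean difference and 95% limits of agreement.
#'
#' @param measurements Measurement table from [measure_cohort()].
#' @return List with data.frames `icc` (parameter, method, comparison, icc,
#'   ci_low, ci_high, band) and `loa` (parameter, method, comparison,
#'   mean_diff, sd_diff, loa_low, loa_high, loa_span).
#' @export
agreement_report <- function(measurements) {
  params <- c("D", "f", "Dstar")
  methods <- c("W-L", "S-S")
  icc_rows <- list(); loa_rows <- list()
  for (p in params) for (met in methods) {
    pairs <- list(
      intraobserver = list(deli_values(measurements, p, met, 2, 1),
                           deli_values(measurements, p, met, 2, 2)),
      interobserver = list(deli_values(measurements, p, met, 1, 1),
                           deli_values(measurements, p, met, 2, 1)))
    for (cmp in names(pairs)) {
      x <- pairs[[cmp]][[1]]; y <- pairs[[cmp]][[2]]
      ic <- icc21(x, y)
      ba <- bland_altman(x, y)
      icc_rows[[length(icc_rows) + 1]] <- data.frame(
        parameter = p, method = met, comparison = cmp,
        icc = round(ic$icc, 3), ci_low = round(ic$ci95[1], 3),
        ci_high = round(ic$ci95[2], 3), band = ic$band)
      loa_rows[[length(loa_rows) + 1]] <- data.frame(
        parameter = p, method = met, comparison = cmp,
        mean_diff = round(ba$mean_diff, 3), sd_diff = round(ba$sd_diff, 3),
        loa_low = round(ba$loa[1], 2), loa_high = round(ba$loa[2], 2),
        loa_span = format_loa(ba))
    }
  }
  list(icc = do.call(rbind, icc_rows), loa = do.call(rbind, loa_rows))
}

#' Distribution report across delineations
#'
#' Mean +/- SD of each parameter/method for reader 1, reader 2's two
#' sessions and all delineations pooled, with the one-way ANOVA F and p
#' across the three repeated delineations, Levene homogeneity p, and the
#' smallest per-column Shapiro-Wilk p.
#'
#' @param measurements Measurement table from [measure_cohort()].
#' @return Data frame, one row per parameter x method.
#' @export
distribution_report <- function(measurements) {
  params <- c("D", "f", "Dstar")
  methods <- c("W-L", "S-S")
  rows <- list()
  for (p in params) for (met in methods) {
    cols <- list(reader1 = deli_values(measurements, p, met, 1, 1),
                 reader2_s1 = deli_values(measurements, p, met, 2, 1),
                 reader2_s2 = deli_values(measurements, p, met, 2, 2))
    tests <- repeated_measure_tests(cols)
    pooled <- unlist(cols, use.names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = p, method = met,
      mean_r1 = mean(cols$reader1), sd_r1 = stats::sd(cols$reader1),
      mean_r2s1 = mean(cols$reader2_s1), sd_r2s1 = stats::sd(cols$reader2_s1),
      mean_r2s2 = mean(cols$reader2_s2), sd_r2s2 = stats::sd(cols$reader2_s2),
      mean_total = mean(pooled), sd_total = stats::sd(pooled),
      anova_F = tests$anova$statistic, anova_p = tests$anova$p_value,
      levene_p = tests$levene$p_value,
      shapiro_min_p = min(tests$shapiro$p_value))
  }
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, 4)
  out
}

# The marker set of the diagnostic analysis (reader 1, first session):
# IVIM from both ROI methods plus the two W-L ADC pairs. Low values
# indicate malignancy for every marker.
marker_table <- function(measurements) {
  r1 <- measurements[measurements$observer == 1 & measurements$session == 1, ]
  wl <- r1[r1$method == "W-L", ]; wl <- wl[order(wl$nodule_id), ]
  ss <- r1[r1$method == "S-S", ]; ss <- ss[order(ss$nodule_id), ]
  stopifnot(identical(wl$nodule_id, ss$nodule_id))
  data.frame(nodule_id = wl$nodule_id, group = wl$group,
             D_SS = ss$D, f_SS = ss$f, Dstar_SS = ss$Dstar,
             D_WL = wl$D, f_WL = wl$f, Dstar_WL = wl$Dstar,
             ADC600 = wl$ADC600, ADC990 = wl$ADC990)
}

diagnostic_marker_names <- function() {
  c("D_SS", "f_SS", "D_WL", "f_WL", "ADC600", "ADC990")
}

#' Benign-versus-malignant group comparison report
#'
#' Group means +/- SD and independent-sample t-test p-values for every
#' marker (IVIM by both ROI methods, ADC600/ADC990 from W-L ROIs), using
#' reader 1's first-session measurements.
#'
#' @param measurements Measurement table from [measure_cohort()].
#' @return Data frame, one row per marker.
#' @export
group_report <- function(measurements) {
  mk <- marker_table(measurements)
  markers <- c(diagnostic_marker_names(), "Dstar_SS", "Dstar_WL")
  rows <- lapply(markers, function(m) {
    b <- mk[mk$group == "benign", m]; g <- mk[mk$group == "malignant", m]
    t <- independent_group_test(b, g)
    data.frame(marker = m,
               benign_mean = round(mean(b), 2), benign_sd = round(stats::sd(b), 2),
               malignant_mean = round(mean(g), 2),
               malignant_sd = round(stats::sd(g), 2),
               t = round(t$statistic, 3), p_value = signif(t$p_value, 4))
  })
  do.call(rbind, rows)
}

#' Method comparison report (paired t-tests W-L vs S-S)
#'
#' @param measurements Measurement table from [measure_cohort()].
#' @return Data frame, one row per IVIM parameter.
#' @export
method_comparison_report <- function(measurements) {
  rows <- lapply(c("D", "f", "Dstar"), function(p) {
    wl <- deli_values(measurements, p, "W-L", 1, 1)
    ss <- deli_values(measurements, p, "S-S", 1, 1)
    t <- paired_method_test(wl, ss)
    data.frame(parameter = p, mean_WL = round(t$mean_x, 3),
               mean_SS = round(t$mean_y, 3), t = round(t$statistic, 3),
               p_value = signif(t$p_value, 4))
  })
  do.call(rbind, rows)
}

#' Diagnostic performance report
#'
#' ROC/AUC with DeLong 95% CI, Youden-optimal cutoff and the derived
#' sensitivity, specificity, accuracy, PPV and NPV for the six diagnostic
#' markers; DeLong pairwise AUC comparisons (raw and Bonferroni-adjusted p)
#' among the leading markers; and the logistic combination of W-L D and f.
#'
#' @param measurements Measurement table from [measure_cohort()].
#' @return List with data.frames `table` (per-marker diagnostics),
#'   `auc_all` (AUC of all markers including D*), `comparisons` (DeLong
#'   tests), and the `logistic` combination result.
#' @export
diagnostic_report <- function(measurements) {
  mk <- marker_table(measurements)
  labels <- mk$group

  diag_one <- function(m) youden_optimal(labeled_scores(mk[[m]], labels))
  diags <- lapply(diagnostic_marker_names(), diag_one)
  names(diags) <- diagnostic_marker_names()
  tab <- do.call(rbind, lapply(diagnostic_marker_names(), function(m) {
    d <- diags[[m]]
    data.frame(marker = m, auc = round(d$auc, 3),
               ci_low = round(d$ci95[1], 3), ci_high = round(d$ci95[2], 3),
               youden = round(d$youden_j, 3), cutoff = round(d$cutoff, 3),
               sens = round(d$sens, 2), spec = round(d$spec, 2),
               accuracy = round(d$accuracy, 2), ppv = round(d$ppv, 2),
               npv = round(d$npv, 2))
  }))

  all_markers <- c(diagnostic_marker_names(), "Dstar_SS", "Dstar_WL")
  auc_all <- do.call(rbind, lapply(all_markers, function(m) {
    r <- roc_auc(labeled_scores(mk[[m]], labels))
    data.frame(marker = m, auc = round(r$auc, 3),
               ci_low = round(r$ci95[1], 3), ci_high = round(r$ci95[2], 3))
  }))

  logit <- logistic_combine(mk[c("D_WL", "f_WL")], labels)

  cmp_pairs <- list(c("D_WL", "ADC600"), c("D_WL", "ADC990"),
                    c("D_WL", "f_WL"), c("D_WL", "D_SS"),
                    c("ADC600", "ADC990"))
  cmp_rows <- lapply(cmp_pairs, function(pr) {
    dt <- delong_test(labeled_scores(mk[[pr[1]]], labels),
                      labeled_scores(mk[[pr[2]]], labels))
    data.frame(marker1 = pr[1], marker2 = pr[2],
               auc1 = round(dt$auc1, 3), auc2 = round(dt$auc2, 3),
               z = round(dt$z, 3), p_value = signif(dt$p_value, 4))
  })
  dt_comb <- delong_test(logit$scores, labeled_scores(mk$D_WL, labels))
  cmp_rows[[length(cmp_rows) + 1]] <- data.frame(
    marker1 = "D_WL+f_WL", marker2 = "D_WL",
    auc1 = round(dt_comb$auc1, 3), auc2 = round(dt_comb$auc2, 3),
    z = round(dt_comb$z, 3), p_value = signif(dt_comb$p_value, 4))
  comparisons <- do.call(rbind, cmp_rows)
  comparisons$p_bonferroni <- signif(
    pmin(comparisons$p_value * nrow(comparisons), 1), 4)

  list(table = tab, auc_all = auc_all, comparisons = comparisons,
       logistic = logit)
}

#' Run the full study emulation
#'
#' Simulate cohort -> delineate -> fit -> aggregate -> reproducibility and
#' diagnostic statistics, optionally writing every report table as CSV plus
#' a provenance JSON. Identical configuration and seed give byte-identical
#' CSV output.
#'
#' @param config A [study_config()].
#' @return List of class `study_result`: `manifest`, `measurements`,
#'   `distribution`, `agreement` (icc + loa), `method_comparison`, `groups`,
#'   `diagnostics`, `config`, and `paths` of any files written.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (config$verbose) message("[", ..., "]")

  say("simulate: generating ", config$n_benign, "+", config$n_malignant,
      " nodule phantoms, seed ", config$seed)
  cohort <- generate_cohort(config$n_benign, config$n_malignant, config$spec,
                            seed = config$seed, groups = config$groups)

  say("fit: measuring cohort (", config$fit_mode, ")")
  measurements <- measure_cohort(cohort, config$observer, config$fit,
                                 config$fit_mode, seed = config$seed,
                                 verbose = config$verbose)

  say("analyze: reproducibility and group statistics")
  agreement <- agreement_report(measurements)
  distribution <- distribution_report(measurements)
  method_cmp <- method_comparison_report(measurements)
  groups <- group_report(measurements)

  say("analyze: diagnostics")
  diagnostics <- diagnostic_report(measurements)

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    paths <- write_study_reports(config$out_dir, cohort, measurements,
                                 distribution, agreement, method_cmp,
                                 groups, diagnostics, config)
    say("report: ", length(paths), " files written to ", config$out_dir)
  }
  structure(list(manifest = cohort$manifest, measurements = measurements,
                 distribution = distribution, agreement = agreement,
                 method_comparison = method_cmp, groups = groups,
                 diagnostics = diagnostics, config = config, paths = paths),
            class = "study_result")
}

write_study_reports <- function(out_dir, cohort, measurements, distribution,
                                agreement, method_cmp, groups, diagnostics,
                                config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    wcsv(cohort$manifest, "cohort_manifest.csv"),
    wcsv(measurements, "measurements.csv"),
    wcsv(distribution, "distribution_table.csv"),
    wcsv(agreement$icc, "icc_table.csv"),
    wcsv(agreement$loa, "bland_altman_table.csv"),
    wcsv(method_cmp, "method_comparison_table.csv"),
    wcsv(groups, "group_comparison_table.csv"),
    wcsv(diagnostics$table, "diagnostic_table.csv"),
    wcsv(diagnostics$auc_all, "auc_all_markers.csv"),
    wcsv(diagnostics$comparisons, "auc_comparisons.csv"))

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("ivimroi")),
               r_version = R.version.string,
               written = format(Sys.time(), tz = "UTC"))
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
  c(paths, cfg_path, prov_path)
}

serialize_config <- function(config) {
  list(n_benign = config$n_benign, n_malignant = config$n_malignant,
       seed = config$seed, fit_mode = config$fit_mode,
       spec = lapply(unclass(config$spec), function(x) {
         if (inherits(x, "ivim_params")) unclass(x) else x
       }),
       observer = unclass(config$observer),
       fit = unclass(config$fit),
       groups = lapply(config$groups, unclass))
}

#' Fit IVIM and ADC from files on disk
#'
#' Reads a 4D NIfTI volume, its b-values (FSL bval dialect) and one or more
#' 3D NIfTI ROI masks, fits voxelwise parameter maps over the union of the
#' masks, and returns (and optionally writes) per-ROI mean measurements.
#' b-values in the file may be in any order; volumes are canonically
#' reordered by ascending b.
#'
#' @param volume_path Path to the 4D `.nii`/`.nii.gz` volume.
#' @param mask_paths Named character vector of mask NIfTI paths; names are
#'   used as ROI labels (defaults to file names).
#' @param bval_path Path to the whitespace-separated b-value file.
#' @param fit A [fit_config()].
#' @param out_dir If non-`NULL`, parameter maps (NIfTI + JSON sidecar) and
#'   the measurement CSV are written here.
#' @return List with `maps` (an `ivim_maps`), `measurements` (data.frame:
#'   roi, n_voxels, D, f, Dstar, ADC600, ADC990 on the reporting scale;
#'   ADC columns present when the scheme contains those b-values), `paths`.
#' @export
fit_only <- function(volume_path, mask_paths, bval_path,
                     fit = fit_config(), out_dir = NULL) {
  if (!file.exists(volume_path)) stop("volume file not found: ", volume_path)
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  # keep acquisition order: dwi_volume() sorts data and b-values together
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  img <- RNifti::readNifti(volume_path)
  if (length(dim(img)) != 4) stop("volume must be 4D (x, y, z, b)")
  vol <- dwi_volume(array(as.numeric(img), dim(img)), bvals,
                    voxel_size = RNifti::pixdim(img)[1:3])
  if (is.null(names(mask_paths))) names(mask_paths) <- basename(mask_paths)
  masks <- lapply(mask_paths, read_mask_nifti)
  for (m in masks) as_mask_array(m, dim(vol$data)[1:3])
  union <- Reduce(`|`, masks)
  maps <- fit_ivim_map(vol, union, fit)
  has6 <- 600 %in% as.numeric(vol$b); has9 <- 990 %in% as.numeric(vol$b)
  adc600 <- if (has6) fit_adc_map(vol, union, 600)
  adc990 <- if (has9) fit_adc_map(vol, union, 990)

  rows <- lapply(names(masks), function(nm) {
    s <- summarize_roi(maps, masks[[nm]])
    df <- data.frame(roi = nm, n_voxels = s$n_voxels, D = s$D * 1e3,
                     f = s$f * 1e2, Dstar = s$D_star * 1e3)
    df$ADC600 <- if (has6) mean(adc600[masks[[nm]]], na.rm = TRUE) * 1e3 else NA
    df$ADC990 <- if (has9) mean(adc990[masks[[nm]]], na.rm = TRUE) * 1e3 else NA
    df
  })
  measurements <- do.call(rbind, rows)

  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_param_maps(maps, file.path(out_dir, "ivim"),
                              voxel_size = vol$voxel_size)
    csv <- file.path(out_dir, "roi_measurements.csv")
    utils::write.csv(measurements, csv, row.names = FALSE)
    paths <- c(paths, csv)
  }
  list(maps = maps, measurements = measurements, paths = paths)
}
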