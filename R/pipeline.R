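#' Run the full synthetic inter-/intrarater reliability experiment
#'
#' End-to-end seeded pipeline: generate the patient cohort, simulate all
#' rater sessions, then compute the synthetic analogues of a reliability
#' study's report tables -- interclass median differences and equivalence
#' decision,
#' interrater ICC with bootstrap CI, per-rater test-retest ICC(2,1),
#' intrarater pairwise summaries (angles and drawn-line RMSE/SD), and the
#' validation correlation of rated against reference angles.
#'
#' @param config a [cohort_config()].
#' @param curvatures curvature types to rate (default all three).
#' @param out_dir optional directory; when given, every table is written as
#'   CSV alongside a JSON run manifest, and paths are recorded in the
#'   manifest.
#' @param n_boot bootstrap draws for the interrater ICC CI (default 500).
#' @param equivalence_bounds equivalence band (degrees, default `c(-5, 5)`).
#' @param rater_args list of overrides for [make_rater_profiles()] (e.g.
#'   `bias_sd`, `annotation_noise_sd`).
#' @return list with `records`, `interclass`, `interrater`, `intrarater`,
#'   `intrarater_lines`, `validation`, `equivalence`, `manifest`.
#' @export
run_iir_experiment <- function(config = cohort_config(),
                               curvatures = c("coronal", "kyphotic", "lordotic"),
                               out_dir = NULL, n_boot = 500,
                               equivalence_bounds = c(-5, 5),
                               rater_args = list()) {
  spines <- generate_cohort(config)
  profiles <- do.call(make_rater_profiles,
                      c(list(n_clinicians = config$n_clinicians,
                             n_students = config$n_students,
                             seed = config$seed), rater_args))
  records <- simulate_raters(config, spines, profiles,
                             curvatures = curvatures, keep_lines = TRUE)
  drawn <- attr(records, "lines")
  attr(records, "lines") <- NULL
  cor_rec <- records[records$curvature == "coronal", ]

  # interclass: median difference between class means per patient, plus the
  # mixed-model equivalence CI on the coronal error
  med_diff <- do.call(rbind, lapply(split(records, records$curvature), function(g) {
    pm <- tapply(g$angle_deg, list(g$patient_id, g$is_clinician), mean)
    d <- pm[, "1"] - pm[, "0"]
    data.frame(curvature = g$curvature[1], median_diff = stats::median(d),
               iqr_diff = iqr_of(d), row.names = NULL)
  }))
  rownames(med_diff) <- NULL
  err <- cor_rec
  err$error <- err$angle_deg - err$reference_deg
  eq_fit <- fit_lmm(err, "error", "is_clinician", "rater_id")
  equivalence <- interclass_equivalence(eq_fit, ci_level = 0.90,
                                        bounds = equivalence_bounds)

  interrater <- icc_crossed(cor_rec, n_boot = n_boot,
                            seed = derive_seed(config$seed, 5))

  # intrarater: per-rater ICC(2,1) on the patients x repetitions matrix
  icc2 <- vapply(split(cor_rec, cor_rec$rater_id), function(g) {
    m <- tapply(g$angle_deg, list(g$patient_id, g$repetition), mean)
    icc2_per_rater(m)$icc
  }, 0)
  intrarater <- list(
    angle = intrarater_summaries(records),
    icc2 = data.frame(rater_id = names(icc2), icc2 = unname(icc2)),
    icc2_median = stats::median(icc2), icc2_iqr = iqr_of(icc2))

  # line-based intrarater agreement: pairwise RMSE/SD between the three
  # drawn repetitions of each rater x patient, pooled as median (IQR)
  key <- do.call(rbind, strsplit(names(drawn), "|", fixed = TRUE))
  cell_stats <- do.call(rbind, lapply(
    split(seq_along(drawn), paste(key[, 1], key[, 2], sep = "|")),
    function(ix) {
      st <- line_repetition_stats(drawn[ix])
      data.frame(patient_id = key[ix[1], 1], rater_id = key[ix[1], 2],
                 rmse = stats::median(st$rmse), sd = stats::median(st$sd))
    }))
  cell_stats$is_clinician <-
    profiles$is_clinician[match(cell_stats$rater_id, profiles$rater_id)]
  pool_lines <- function(d, label) data.frame(
    group = label,
    median_rmse = stats::median(d$rmse), iqr_rmse = iqr_of(d$rmse),
    median_sd = stats::median(d$sd), iqr_sd = iqr_of(d$sd))
  intrarater_lines <- rbind(
    pool_lines(cell_stats[cell_stats$is_clinician == 1, ], "clinicians"),
    pool_lines(cell_stats[cell_stats$is_clinician == 0, ], "students"))
  rownames(intrarater_lines) <- NULL

  validation <- do.call(rbind, lapply(split(records, interaction(
    records$curvature, records$is_clinician)), function(g) {
      v <- validation_correlation(g$angle_deg, g$reference_deg)
      data.frame(curvature = g$curvature[1],
                 group = if (g$is_clinician[1] == 1) "clinicians" else "students",
                 pcc = v$pcc, ci_low = v$ci_low, ci_high = v$ci_high,
                 median_diff = v$median_diff, iqr_diff = v$iqr_diff,
                 row.names = NULL)
    }))
  rownames(validation) <- NULL

  res <- list(records = records, interclass = med_diff,
              interrater = data.frame(icc = interrater$icc,
                                      ci_low = interrater$ci_low,
                                      ci_high = interrater$ci_high),
              intrarater = intrarater, intrarater_lines = intrarater_lines,
              validation = validation, equivalence = equivalence)
  res$manifest <- write_stage_outputs(res, config, out_dir, "iir")
  res
}

#' Compare acquisition protocols on posture alignment and SPL-ISL coupling
#'
#' Each protocol specifies whether registration markers are available and
#' how strongly the standing posture differs between the radiographic and
#' surface-scan acquisitions. Per patient, the scan-side curves are
#' posture-perturbed; with markers they are rigidly registered back onto
#' the radiograph frame via the skin markers before comparison. Reported
#' per protocol: median RMSE (median SD) of the lateral-outline alignment
#' error and median (IQR) SPL-ISL Pearson correlation per plane for both
#' correlation options (direct, and Procrustes rotation + translation).
#'
#' @param protocols named list; each element a list with fields `markers`
#'   (logical), `lean_sd` (degrees), `flexion_sd` (mm) and optionally
#'   `coronal_lean_sd` (degrees; defaults to half the sagittal lean SD,
#'   since lateral sway between acquisitions is typically smaller than the
#'   sagittal posture change). At least 2 protocols.
#' @param n_patients cohort size per protocol (default 30).
#' @param seed root integer seed (the same cohort is reused across
#'   protocols so differences are attributable to the protocol).
#' @param axial_rotation_gain rotation coupling of the cohort (default 0.5).
#' @param marker_noise_sd digitization noise on marker positions (mm).
#' @param out_dir optional output directory for CSV tables + manifest.
#' @return list with `alignment` and `correlation` data frames and
#'   `manifest`.
#' @export
run_protocol_comparison <- function(protocols = default_protocols(),
                                    n_patients = 30, seed = 1,
                                    axial_rotation_gain = 0.5,
                                    marker_noise_sd = 1,
                                    out_dir = NULL) {
  if (length(protocols) < 2) stop("need at least 2 protocol configs", call. = FALSE)
  if (is.null(names(protocols)))
    names(protocols) <- sprintf("protocol%d", seq_along(protocols))
  sev <- rep(c("normal", "mild", "moderate", "severe"),
             length.out = n_patients)
  spines <- lapply(seq_len(n_patients), function(i)
    generate_spine(sev[i], seed = derive_seed(seed, 300 + i),
                   patient_id = sprintf("P%d", i),
                   axial_rotation_gain = axial_rotation_gain))
  align_rows <- list(); cor_rows <- list()
  for (pn in names(protocols)) {
    pr <- protocols[[pn]]
    stopifnot(is.logical(pr$markers), pr$lean_sd >= 0, pr$flexion_sd >= 0)
    for (i in seq_len(n_patients)) {
      ps <- derive_seed(seed, 7000 + i)
      crv <- sample_curves(spines[[i]], 200)
      mk <- make_markers(spines[[i]])
      clean_sd <- if (is.null(pr$coronal_lean_sd)) pr$lean_sd / 2
                  else pr$coronal_lean_sd
      pert <- with_seed(derive_seed(ps, match(pn, names(protocols))), {
        lean <- max(-29, min(29, stats::rnorm(1, 0, pr$lean_sd)))
        flex <- stats::rnorm(1, 0, pr$flexion_sd)
        sway <- max(-29, min(29, stats::rnorm(1, 0, clean_sd)))
        scan <- perturb_posture(c(crv, list(markers = mk)), lean, flex, sway)
        scan$markers <- polyline3d(
          scan$markers$x + stats::rnorm(nrow(mk), 0, marker_noise_sd),
          scan$markers$y + stats::rnorm(nrow(mk), 0, marker_noise_sd),
          scan$markers$z + stats::rnorm(nrow(mk), 0, marker_noise_sd),
          label = "markers")
        scan
      })
      if (pr$markers) {
        reg <- rigid_register(pert$markers, mk)
        scan_outline <- apply_transform(pert$outline, reg$transform)
        scan_spl <- apply_transform(pert$SPL, reg$transform)
      } else {
        scan_outline <- pert$outline
        scan_spl <- pert$SPL
      }
      yg <- seq(max(min(scan_outline$y), min(crv$outline$y)),
                min(max(scan_outline$y), max(crv$outline$y)), length.out = 100)
      ae <- alignment_error(lateral_outline(scan_outline, yg),
                            lateral_outline(crv$outline, yg))
      align_rows[[length(align_rows) + 1]] <-
        data.frame(protocol = pn, patient_id = spines[[i]]$patient_id,
                   rmse = ae$rmse, sd = ae$sd)
      for (pl in c("coronal", "sagittal")) for (opt in 1:2)
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          protocol = pn, patient_id = spines[[i]]$patient_id, plane = pl,
          option = opt,
          pcc = line_correlation(scan_spl, crv$ISL, pl, procrustes = opt == 2))
    }
  }
  align <- do.call(rbind, align_rows)
  cors <- do.call(rbind, cor_rows)
  alignment <- do.call(rbind, lapply(split(align, align$protocol), function(g)
    data.frame(protocol = g$protocol[1],
               median_rmse = stats::median(g$rmse),
               median_sd = stats::median(g$sd), row.names = NULL)))
  correlation <- do.call(rbind, lapply(
    split(cors, list(cors$protocol, cors$plane, cors$option)), function(g)
      data.frame(protocol = g$protocol[1], plane = g$plane[1],
                 option = g$option[1], median_pcc = stats::median(g$pcc),
                 iqr_pcc = iqr_of(g$pcc), row.names = NULL)))
  rownames(alignment) <- rownames(correlation) <- NULL
  res <- list(alignment = alignment, correlation = correlation,
              per_patient = list(alignment = align, correlation = cors))
  res$manifest <- write_stage_outputs(res, list(seed = seed,
                                                protocols = protocols),
                                      out_dir, "protocols")
  res
}

#' Default three-protocol comparison
#'
#' Protocol 1: no registration markers, large posture perturbation;
#' protocol 2: markers, large perturbation; protocol 3: markers, small
#' perturbation (the highest-quality acquisition setup).
#'
#' @return named list of protocol configurations for
#'   [run_protocol_comparison()].
#' @export
default_protocols <- function() {
  list(study1 = list(markers = FALSE, lean_sd = 4, flexion_sd = 6),
       study2 = list(markers = TRUE, lean_sd = 4, flexion_sd = 6),
       study3 = list(markers = TRUE, lean_sd = 1.5, flexion_sd = 2))
}

# Serialize result tables + a manifest with a config hash; returns the
# manifest (invisible no-op when out_dir is NULL).
write_stage_outputs <- function(res, config, out_dir, stage) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- list(config_hash = hash,
                   seed = if (!is.null(config$seed)) config$seed else NA,
                   stage = stage,
                   versions = paste("spinalign",
                                    as.character(utils::packageVersion("spinalign"))),
                   stage_outputs = list())
  if (is.null(out_dir)) return(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- res[vapply(res, is.data.frame, TRUE)]
  for (nm in names(flat)) {
    p <- file.path(out_dir, paste0(stage, "_", nm, ".csv"))
    utils::write.csv(flat[[nm]], p, row.names = FALSE)
    manifest$stage_outputs[[nm]] <- p
  }
  mp <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest$stage_outputs$manifest <- mp
  manifest
}
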