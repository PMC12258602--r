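#' Cohort configuration for a synthetic reliability study
#'
#' Defaults reproduce the inter-/intrarater study design: 7 patients
#' (1 normal, 2 mild, 3 moderate, 1 severe), 6 clinician and 10 student
#' raters, 3 repetitions per patient image.
#'
#' @param n_patients number of patients.
#' @param severity_counts named counts over
#'   `c("normal", "mild", "moderate", "severe")`; must sum to `n_patients`.
#' @param n_clinicians,n_students rater counts.
#' @param n_repetitions repetitions per patient image per rater.
#' @param seed root integer seed for the whole cohort.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 7,
                          severity_counts = c(normal = 1, mild = 2,
                                              moderate = 3, severe = 1),
                          n_clinicians = 6, n_students = 10,
                          n_repetitions = 3, seed = 1) {
  stopifnot(all(c("normal", "mild", "moderate", "severe") %in% names(severity_counts)),
            all(severity_counts >= 0), n_clinicians >= 0, n_students >= 0,
            n_repetitions >= 0)
  if (sum(severity_counts) != n_patients)
    stop("severity counts must sum to n_patients", call. = FALSE)
  structure(list(n_patients = n_patients, severity_counts = severity_counts,
                 n_clinicians = n_clinicians, n_students = n_students,
                 n_repetitions = n_repetitions, seed = seed),
            class = "cohort_config")
}

#' Generate the spine models of a cohort
#'
#' @param config a [cohort_config()].
#' @param axial_rotation_gain coupling passed to [generate_spine()].
#' @return list of [spine_model()], one per patient, ids `"P1"`, `"P2"`, ...
#' @export
generate_cohort <- function(config, axial_rotation_gain = 0.5) {
  sev <- rep(names(config$severity_counts), times = config$severity_counts)
  lapply(seq_along(sev), function(i)
    generate_spine(sev[i], seed = derive_seed(config$seed, i),
                   patient_id = sprintf("P%d", i),
                   axial_rotation_gain = axial_rotation_gain))
}

#' Rater profiles with systematic bias and annotation noise
#'
#' Each rater carries a systematic angle offset (drawn from
#' `N(0, bias_sd^2)`) and a control-point jitter level applied to the drawn
#' ISL; reliability studies find students and clinicians comparable, so both classes
#' default to the same noise level.
#'
#' @param n_clinicians,n_students rater counts.
#' @param bias_sd between-rater SD of the systematic angle offset (degrees).
#' @param annotation_noise_sd control-point jitter SD (mm).
#' @param seed integer seed.
#' @return data frame with columns `rater_id`, `is_clinician`, `bias`,
#'   `annotation_noise_sd`.
#' @export
make_rater_profiles <- function(n_clinicians = 6, n_students = 10,
                                bias_sd = 1.4, annotation_noise_sd = 1.5,
                                seed = 1) {
  n <- n_clinicians + n_students
  with_seed(derive_seed(seed, 901), {
    data.frame(
      rater_id = sprintf("R%02d", seq_len(n)),
      is_clinician = rep(c(1L, 0L), c(n_clinicians, n_students)),
      bias = stats::rnorm(n, 0, bias_sd),
      annotation_noise_sd = rep(annotation_noise_sd, n))
  })
}

#' Parallel biplanar projection of curves and markers
#'
#' Emulates slot-scanning biplanar radiography with an orthographic model:
#' the frontal view drops the antero-posterior coordinate (`(x, y)` pairs),
#' the lateral view drops the lateral coordinate (`(z, y)` pairs); point
#' labels are preserved in both views.
#'
#' @param curves named list of [polyline3d()] (may be empty).
#' @param markers a [polyline3d()] with label `"markers"`; required.
#' @return list with data frames `frontal` (`x`, `y`, `label`) and
#'   `lateral` (`z`, `y`, `label`).
#' @export
project_biplanar <- function(curves = list(), markers) {
  if (missing(markers) || is.null(markers) || nrow(markers) == 0)
    stop("markers must be non-empty", call. = FALSE)
  items <- c(curves, list(markers = markers))
  lab <- unlist(lapply(names(items), function(nm) {
    lev <- attr(items[[nm]], "level")
    if (!is.null(lev)) paste0(nm, ":", lev) else
      sprintf("%s:%d", nm, seq_len(nrow(items[[nm]])))
  }))
  all_pts <- do.call(rbind, lapply(items, as_matrix3))
  list(frontal = data.frame(x = all_pts[, 1], y = all_pts[, 2], label = lab),
       lateral = data.frame(z = all_pts[, 3], y = all_pts[, 2], label = lab))
}

#' Perturb the standing posture between acquisitions
#'
#' Models imperfect posture replication between the radiographic and the
#' surface-scan acquisitions: a global lean (rotation about the lateral
#' axis, through the lumbosacral point at the caudal end of the spine) plus
#' a quadratic sagittal bow of peak amplitude `flexion_coeff` at
#' mid-height, and optionally a lateral sway (rotation about the
#' antero-posterior axis) since standing posture is never replicated
#' exactly in the coronal plane either. Craniocaudal monotonicity is
#' re-established by resampling each curve onto a uniform height grid.
#'
#' @param curves a [polyline3d()] or a (possibly named) list of them.
#' @param sagittal_lean global lean angle (degrees, `|lean| < 30`).
#' @param flexion_coeff peak antero-posterior bow amplitude (mm).
#' @param coronal_lean lateral sway angle (degrees, `|lean| < 30`,
#'   default 0).
#' @return perturbed curves, same shape as the input.
#' @export
perturb_posture <- function(curves, sagittal_lean = 0, flexion_coeff = 0,
                            coronal_lean = 0) {
  if (abs(sagittal_lean) >= 30 || abs(coronal_lean) >= 30)
    stop("lean out of range (|lean| < 30 degrees)", call. = FALSE)
  single <- inherits(curves, "polyline3d")
  lst <- if (single) list(curves) else curves
  y_all <- range(unlist(lapply(lst, function(l) range(l$y))))
  rot <- rigid_transform(rotation_about(3, coronal_lean) %*%
                           rotation_about(1, sagittal_lean))
  out <- lapply(lst, function(l) {
    lab <- attr(l, "label"); lev <- attr(l, "level")
    p <- as_matrix3(l)
    p[, 2] <- p[, 2] - y_all[1]            # pivot at the caudal end
    p <- p %*% t(rot$rotation)
    p[, 2] <- p[, 2] + y_all[1]
    u <- (p[, 2] - y_all[1]) / diff(y_all)
    p[, 3] <- p[, 3] + flexion_coeff * 4 * u * (1 - u)
    if (lab == "markers") {
      r <- polyline3d(p[, 1], p[, 2], p[, 3], label = "markers")
    } else {
      o <- order(p[, 2])
      yg <- seq(min(p[, 2]), max(p[, 2]), length.out = nrow(p))
      r <- polyline3d(interp_at(p[o, 2], p[o, 1], yg), yg,
                      interp_at(p[o, 2], p[o, 3], yg), label = lab)
    }
    attr(r, "level") <- lev
    r
  })
  if (single) out[[1]] else out
}

#' Simulate rater annotation sessions
#'
#' For every patient x rater x repetition (x curvature type) the rater
#' "draws" the ISL as a small set of control points sampled along the true
#' curve, each jittered in the two transverse directions by the rater's
#' control-point noise; the drawn line is spline-smoothed and the angles
#' extracted exactly as in the analysis pipeline, then offset by the
#' rater's systematic bias. The 21 patient-repetition images of each rater
#' session are presented in an independently shuffled order recorded in
#' `presentation_order`. Reference angles are the generator's ground truth.
#'
#' @param config a [cohort_config()].
#' @param spines list of [spine_model()] from [generate_cohort()].
#' @param rater_profiles data frame from [make_rater_profiles()].
#' @param curvatures subset of `c("coronal", "kyphotic", "lordotic")`.
#' @param n_control_points control points per drawn line (default 9).
#' @param keep_lines also return every smoothed drawn line (for line-based
#'   intrarater summaries); stored in the `"lines"` attribute as a list
#'   keyed `"<patient>|<rater>|<repetition>"`.
#' @return a data frame of rating records with columns `patient_id`,
#'   `rater_id`, `is_clinician`, `repetition`, `curvature`, `angle_deg`,
#'   `reference_deg`, `presentation_order`.
#' @export
simulate_raters <- function(config, spines, rater_profiles,
                            curvatures = "coronal", n_control_points = 9,
                            keep_lines = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(rater_profiles) != config$n_clinicians + config$n_students)
    stop("rater profile count must equal n_clinicians + n_students", call. = FALSE)
  if (length(spines) == 0 || config$n_repetitions == 0)
    stop("empty cohort", call. = FALSE)
  curvatures <- match.arg(curvatures,
                          c("coronal", "kyphotic", "lordotic"), several.ok = TRUE)
  refs <- lapply(spines, function(m)
    c(coronal = implied_cobb(m), kyphotic = m$kyphosis_angle,
      lordotic = m$lordosis_angle))
  curves <- lapply(spines, sample_curves, n_samples = 200)
  rows <- vector("list", nrow(rater_profiles))
  lines_out <- if (keep_lines) list() else NULL
  for (r in seq_len(nrow(rater_profiles))) {
    prof <- rater_profiles[r, ]
    combos <- expand.grid(pat = seq_along(spines),
                          rep = seq_len(config$n_repetitions))
    rseed <- derive_seed(config$seed, 1000 + r)
    rec <- with_seed(rseed, {
      ord <- sample.int(nrow(combos))     # shuffled presentation
      out <- vector("list", nrow(combos))
      lns <- list()
      for (k in seq_len(nrow(combos))) {
        i <- combos$pat[ord[k]]; rep_i <- combos$rep[ord[k]]
        isl <- curves[[i]]$ISL
        ctrl <- resample_polyline(isl, n_control_points)
        noisy <- polyline3d(
          ctrl$x + stats::rnorm(n_control_points, 0, prof$annotation_noise_sd),
          ctrl$y,
          ctrl$z + stats::rnorm(n_control_points, 0, prof$annotation_noise_sd),
          label = "ISL")
        sm <- smooth_line(noisy)
        if (keep_lines)
          lns[[sprintf("%s|%s|%d", spines[[i]]$patient_id,
                       prof$rater_id, rep_i)]] <- sm
        angs <- drawn_angles(sm, spines[[i]], curvatures)
        out[[k]] <- data.frame(
          patient_id = spines[[i]]$patient_id,
          rater_id = prof$rater_id,
          is_clinician = prof$is_clinician,
          repetition = rep_i,
          curvature = curvatures,
          angle_deg = angs[curvatures] + prof$bias,
          reference_deg = refs[[i]][curvatures],
          presentation_order = k)
      }
      list(rec = do.call(rbind, out), lns = lns)
    })
    rows[[r]] <- rec$rec
    if (keep_lines) lines_out <- c(lines_out, rec$lns)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (keep_lines) attr(res, "lines") <- lines_out
  res
}

# angles of a drawn + smoothed ISL, by the same extraction used downstream
drawn_angles <- function(smoothed, model, curvatures) {
  angs <- c(coronal = NA_real_, kyphotic = NA_real_, lordotic = NA_real_)
  if ("coronal" %in% curvatures)
    angs["coronal"] <- cobb_coronal(project_plane(smoothed, "coronal"))$angle
  if (any(c("kyphotic", "lordotic") %in% curvatures)) {
    sa <- sagittal_angles(project_plane(smoothed, "sagittal"), spine_levels(model))
    angs["kyphotic"] <- sa$kyphotic
    angs["lordotic"] <- sa$lordotic
  }
  angs
}

#' Write / read rating records as CSV
#'
#' Column layout: `patient_id,rater_id,is_clinician,repetition,curvature,`
#' `angle_deg,reference_deg,presentation_order`.
#'
#' @param records data frame from [simulate_raters()].
#' @param path file path.
#' @return `read_records_csv` returns the records data frame.
#' @export
write_records_csv <- function(records, path) {
  cols <- c("patient_id", "rater_id", "is_clinician", "repetition",
            "curvature", "angle_deg", "reference_deg", "presentation_order")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
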