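#' Configuration for a packaged study run
#'
#' Validated bundle of everything a study run needs, fully serialized into
#' the output directory for provenance so that any artifact directory is
#' reproducible from its config and seed alone.
#'
#' @param experiment `"volunteer"` or `"patient"`.
#' @param profiles Named list of [scanner_profile()]; default all three
#'   packaged profiles.
#' @param phantom A [phantom_spec()].
#' @param quant Optional [quant_params()] template; `t1_blood` is always
#'   taken from each profile.
#' @param n_subjects Volunteer-study cohort size.
#' @param between_subject_cv Volunteer-study between-subject CV.
#' @param patients Patient-study scenario list; each element
#'   `list(lesion = list(center, radius, cbf) | NULL, resected_fraction)`
#'   where `resected_fraction` is the fraction of the lesion radius removed
#'   by the simulated surgery (1 = complete resection).
#' @param rating List of rating constants: `shell_mm`, `z`, `min_cluster`.
#' @param seed Integer master seed.
#' @return A `run_config` object.
#' @export
run_config <- function(experiment = c("volunteer", "patient"),
                       profiles = asl_profiles(),
                       phantom = phantom_spec(), quant = quant_params(),
                       n_subjects = 10, between_subject_cv = 0.18,
                       patients = NULL,
                       rating = list(shell_mm = 10, z = 2, min_cluster = 5),
                       seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(phantom, "phantom_spec"), inherits(quant, "quant_params"),
            length(profiles) >= 1, n_subjects >= 2, between_subject_cv >= 0)
  if (!all(vapply(profiles, inherits, logical(1), "scanner_profile")))
    stop("run_config: profiles must be scanner_profile objects")
  if (experiment == "volunteer" && length(profiles) < 2)
    stop("run_config: volunteer experiment needs >= 2 profiles")
  for (nm in c("shell_mm", "z", "min_cluster"))
    if (is.null(rating[[nm]]) || rating[[nm]] <= 0)
      stop("run_config: rating$", nm, " must be positive")
  structure(list(experiment = experiment, profiles = profiles,
                 phantom = phantom, quant = quant,
                 n_subjects = as.integer(n_subjects),
                 between_subject_cv = between_subject_cv,
                 patients = patients, rating = rating,
                 seed = as.integer(seed)),
            class = "run_config")
}

.serialize_config <- function(cfg, out_dir) {
  ser <- list(experiment = cfg$experiment,
              profiles = lapply(cfg$profiles, unclass),
              phantom = unclass(cfg$phantom), quant = unclass(cfg$quant),
              n_subjects = cfg$n_subjects,
              between_subject_cv = cfg$between_subject_cv,
              patients = cfg$patients, rating = cfg$rating, seed = cfg$seed)
  jsonlite::write_json(ser, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the volunteer reproducibility experiment
#'
#' Simulates `n_subjects` volunteers scanned on every profile, quantifies
#' gray-matter mean CBF per scan, and computes cross-scanner agreement. If
#' `out_dir` is given, writes the cohort table (CSV), the agreement report
#' (JSON) and the serialized config.
#'
#' @param cfg A [run_config()] with `experiment = "volunteer"`.
#' @param out_dir Optional output directory (created if missing).
#' @return List with `table` (a [cohort_table()]), `agreement`
#'   (a [cohort_agreement()]), `truth` (per-subject true mean GM CBF) and
#'   `seed`.
#' @export
run_volunteer_study <- function(cfg = run_config("volunteer"),
                                out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$experiment != "volunteer")
    stop("run_volunteer_study: config is for experiment '", cfg$experiment, "'")
  coh <- make_cohort(cfg$n_subjects, base_spec = cfg$phantom,
                     between_subject_cv = cfg$between_subject_cv,
                     profiles = cfg$profiles, seed = cfg$seed)
  agr <- cohort_agreement(coh$table)
  res <- list(table = coh$table, agreement = agr, truth = coh$truth,
              seed = cfg$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .serialize_config(cfg, out_dir)
    write_cohort_table(coh$table, file.path(out_dir, "cohort_table.csv"))
    jsonlite::write_json(list(pairwise = agr$pairwise,
                              profile_mean = as.list(agr$profile_mean),
                              profile_sd = as.list(agr$profile_sd),
                              n_subjects = agr$n_subjects),
                         file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}

#' Run the patient resection-control experiment
#'
#' Simulates each patient at three timepoints on the given profile
#' (preoperative: lesion present; intraoperative and postoperative: a
#' resection cavity replaces the resected part of the lesion, any remainder
#' staying hyperperfused), quantifies each scan, and rates residual tumor
#' from elevated perfusion in a shell around the cavity. Patients whose
#' `resected_fraction` is 1 have no residual lesion; a fraction below 1
#' leaves a residual rind at the cavity margin. The intraoperative scan
#' uses the first profile named `"1p5t_or"` if present (surface-coil OR
#' scanner), otherwise the first profile.
#'
#' @param cfg A [run_config()] with `experiment = "patient"` and a
#'   `patients` scenario list.
#' @param out_dir Optional output directory.
#' @return List with `calls` (data frame: patient, intraop/postop rating
#'   plus cluster details), `summary` (the [table2_summary()]-style counts)
#'   and `seed`.
#' @export
run_patient_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$experiment != "patient")
    stop("run_patient_study: config is for experiment '", cfg$experiment, "'")
  if (is.null(cfg$patients) || !length(cfg$patients))
    stop("run_patient_study: cfg$patients scenarios required")

  profs <- cfg$profiles
  intra_prof <- if ("1p5t_or" %in% names(profs)) profs[["1p5t_or"]] else
    profs[[1]]
  post_prof <- profs[[1]]
  set.seed(cfg$seed)
  pat_seeds <- matrix(sample.int(2^30, 3L * length(cfg$patients)), ncol = 3)

  # preoperative scan: intact lesion, no cavity; records whether the tumor
  # shows as supra-threshold perfusion against contralateral gray matter
  preop_visible <- function(scen, prof, seed) {
    lesion <- scen$lesion
    spec <- cfg$phantom
    spec$grid <- prof$grid
    spec$voxel_size <- prof$voxel_size
    spec$lesions <- list(lesion)
    spec$cavity <- NULL
    ph <- generate_phantom(spec, seed = seed)
    p <- quant_params(lambda_bbp = cfg$quant$lambda_bbp, pld = cfg$quant$pld,
                      tau = cfg$quant$tau, t1_blood = prof$t1_blood,
                      alpha = cfg$quant$alpha)
    cmap <- quantify_series(simulate_acquisition(ph, prof, p, seed = seed))
    les_mask <- ph$true_cbf >= lesion$cbf - 1e-9 & ph$head_mask
    gmm <- gm_mask_from_phantom(ph)
    ref <- contralateral_reference(gmm & !les_mask, les_mask)
    rv <- cmap$values[ref]
    rv <- rv[is.finite(rv)]
    thr <- mean(rv) + cfg$rating$z * stats::sd(rv)
    as.integer(mean(cmap$values[les_mask], na.rm = TRUE) > thr)
  }

  one_timepoint <- function(scen, prof, seed) {
    lesion <- scen$lesion
    if (is.null(lesion))
      stop("run_patient_study: each patient scenario needs a lesion")
    resid_radius <- lesion$radius * (1 - scen$resected_fraction)^(1 / 3)
    lesions <- list()
    if (resid_radius > 0) {
      # residual rind kept at the cavity margin, offset outward in x
      lesions <- list(list(center = lesion$center +
                             c(lesion$radius * 0.8, 0, 0),
                           radius = max(resid_radius, 1e-3),
                           cbf = lesion$cbf))
    }
    spec <- cfg$phantom
    spec$grid <- prof$grid
    spec$voxel_size <- prof$voxel_size
    spec$lesions <- lesions
    spec$cavity <- list(center = lesion$center, radius = lesion$radius)
    ph <- generate_phantom(spec, seed = seed)
    p <- quant_params(lambda_bbp = cfg$quant$lambda_bbp, pld = cfg$quant$pld,
                      tau = cfg$quant$tau, t1_blood = prof$t1_blood,
                      alpha = cfg$quant$alpha)
    ser <- simulate_acquisition(ph, prof, p, seed = seed)
    cmap <- quantify_series(ser)
    gmm <- gm_mask_from_phantom(ph)
    shell <- cavity_shell(ph$cavity_mask, shell_mm = cfg$rating$shell_mm,
                          voxel_size = prof$voxel_size,
                          head_mask = ph$head_mask)
    ref <- contralateral_reference(gmm, shell)
    rate_residual(cmap, shell, ref, z = cfg$rating$z,
                  min_cluster = cfg$rating$min_cluster)
  }

  rows <- lapply(seq_along(cfg$patients), function(i) {
    scen <- cfg$patients[[i]]
    pre <- preop_visible(scen, post_prof, pat_seeds[i, 3])
    intra <- one_timepoint(scen, intra_prof, pat_seeds[i, 1])
    post <- one_timepoint(scen, post_prof, pat_seeds[i, 2])
    data.frame(patient = i,
               truth_residual = as.integer(scen$resected_fraction < 1),
               asl_preop_visible = pre,
               asl_intraop = intra$rating, asl_postop = post$rating,
               intraop_cluster = intra$largest_cluster_voxels,
               postop_cluster = post$largest_cluster_voxels,
               intraop_threshold = intra$threshold_used,
               postop_threshold = post$threshold_used)
  })
  calls <- do.call(rbind, rows)
  summ <- list(intraop_residual = sum(calls$asl_intraop),
               postop_residual = sum(calls$asl_postop),
               complete_at_surgery = nrow(calls) - sum(calls$asl_intraop),
               n_patients = nrow(calls))
  res <- list(calls = calls, summary = summ, seed = cfg$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .serialize_config(cfg, out_dir)
    utils::write.csv(calls, file.path(out_dir, "residual_calls.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
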