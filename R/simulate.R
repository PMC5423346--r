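# Smooth low-order multiplicative coil-sensitivity field for surface coils.
# Two circular coils anterior and posterior of the head make sensitivity
# highest near the +/- y faces and lowest mid-volume; modelled as
# 1 + amplitude * g(y, z) with g a separable cosine surface normalized to
# peak magnitude 1. Strictly positive for amplitude < 1.
.bias_field <- function(grid, voxel_size, amplitude) {
  if (amplitude == 0) return(array(1, dim = grid))
  co <- .voxel_coords(grid, voxel_size)
  ext <- grid * voxel_size / 2
  g <- -cos(pi * co$y / ext[2]) * (0.8 + 0.2 * cos(pi * co$z / (2 * ext[3])))
  g <- g / max(abs(g))
  array(1 + amplitude * g, dim = grid)
}

#' Simulate a pCASL acquisition of a phantom
#'
#' Produces an interleaved control/label series with the signal model the
#' quantification stage assumes:
#' \itemize{
#'   \item M0 = proton-density template x multiplicative coil bias field;
#'   \item control_i = M0 + noise; label_i = M0 - dM + noise, with dM the
#'     exact forward difference signal for the phantom's true CBF
#'     ([forward_delta_m()]);
#'   \item noise i.i.d. zero-mean Gaussian with sd `profile$noise_sd`,
#'     drawn independently for every voxel of every volume.
#' }
#' The interleave order is control-first and is recorded in the series
#' metadata so downstream subtraction can never silently flip sign. The
#' output is bit-reproducible given `(phantom, profile, seed)`.
#'
#' @param phantom An [generate_phantom()] result on the profile's grid.
#' @param profile A [scanner_profile()].
#' @param p A [quant_params()]; its `t1_blood` must match the profile's.
#' @param seed Integer RNG seed.
#' @return An object of class `asl_series`: list with `volumes`
#'   (4-D array, 2 x n_pairs volumes), `m0`, `profile`, `params`, `order`
#'   (`"control_first"`), `seed`.
#' @export
simulate_acquisition <- function(phantom, profile, p = NULL, seed = 1L) {
  stopifnot(inherits(phantom, "asl_phantom"),
            inherits(profile, "scanner_profile"))
  if (is.null(p))
    p <- quant_params(t1_blood = profile$t1_blood)
  stopifnot(inherits(p, "quant_params"))
  if (!isTRUE(all.equal(p$t1_blood, profile$t1_blood)))
    stop("simulate_acquisition: quant_params t1_blood (", p$t1_blood,
         " ms) does not match profile t1_blood (", profile$t1_blood, " ms)")
  g <- profile$grid
  if (!identical(dim(phantom$true_cbf), as.integer(g)))
    stop("simulate_acquisition: phantom grid does not match profile grid")

  bias <- .bias_field(g, profile$voxel_size, profile$bias_field_amplitude)
  m0 <- phantom$m0 * bias
  dm <- forward_delta_m(phantom$true_cbf, m0, p)

  n_vol <- 2L * profile$n_pairs
  nvox <- prod(g)
  set.seed(seed)
  vols <- matrix(stats::rnorm(nvox * n_vol, sd = profile$noise_sd),
                 nrow = nvox, ncol = n_vol)
  ctl <- seq(1L, n_vol, by = 2L)
  vols[, ctl] <- vols[, ctl] + as.vector(m0)
  vols[, -ctl] <- vols[, -ctl] + as.vector(m0) - as.vector(dm)

  structure(list(volumes = array(vols, dim = c(g, n_vol)), m0 = m0,
                 profile = profile, params = p, order = "control_first",
                 seed = as.integer(seed)),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("pCASL series: %d volumes (%d pairs, %s) on %dx%dx%d grid\n",
              d[4], d[4] / 2, x$order, d[1], d[2], d[3]))
  cat(sprintf("  profile '%s' (%.1fT), noise sd %g, seed %d\n",
              x$profile$name, x$profile$field_strength,
              x$profile$noise_sd, x$seed))
  invisible(x)
}

#' Simulate a multi-scanner volunteer cohort
#'
#' Emulates a reproducibility experiment in which each subject is scanned on
#' every profile within a short interval, so the underlying physiology is
#' shared across scanners: each subject draws a single global CBF scale from
#' a lognormal distribution with mean 1 and coefficient of variation
#' `between_subject_cv`, applied identically to all profiles; acquisitions
#' are then simulated independently per profile.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base_spec A [phantom_spec()] shared by all subjects.
#' @param between_subject_cv Between-subject CV of true CBF (default 0.18,
#'   the "rather high inter-individual spread" regime typical of healthy
#'   cohorts).
#' @param profiles Named list of [scanner_profile()] (default all three
#'   packaged profiles).
#' @param seed Integer seed governing both the subject scales and every
#'   acquisition.
#' @param keep_series Keep the simulated series in the result? Default
#'   FALSE: a full cohort is large, and downstream agreement statistics
#'   need only per-subject summaries, so by default each series is
#'   quantified on the fly and discarded.
#' @param quant_fn Function applied to each `asl_series` when
#'   `keep_series = FALSE`; defaults to gray-matter mean CBF extraction via
#'   the standard pipeline. Receives `(series, phantom)`.
#' @return An object of class `asl_cohort`: list with `subject_scale`
#'   (length `n_subjects`), `truth` (per-subject true mean GM CBF), and
#'   either `series` (subject x profile list of `asl_series`) or `table`
#'   (a subject x profile [cohort_table()] of mean GM CBF).
#' @export
make_cohort <- function(n_subjects, base_spec = phantom_spec(),
                        between_subject_cv = 0.18,
                        profiles = asl_profiles(), seed = 1L,
                        keep_series = FALSE, quant_fn = NULL) {
  stopifnot(n_subjects >= 2, between_subject_cv >= 0,
            inherits(base_spec, "phantom_spec"), length(profiles) >= 1)
  set.seed(seed)
  if (between_subject_cv > 0) {
    sdlog <- sqrt(log(1 + between_subject_cv^2))
    scales <- stats::rlnorm(n_subjects, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    scales <- rep(1, n_subjects)
  }
  # independent sub-seeds per (subject, profile), kept well below 2^31
  sub_seeds <- matrix(sample.int(2^30, n_subjects * length(profiles)),
                      nrow = n_subjects)

  if (is.null(quant_fn))
    quant_fn <- function(series, phantom) {
      cmap <- quantify_series(series)
      mask <- gm_mask_from_phantom(phantom)
      mean_roi_cbf(cmap, mask)$mean
    }

  truth <- numeric(n_subjects)
  series <- if (keep_series) vector("list", n_subjects) else NULL
  tab <- matrix(NA_real_, nrow = n_subjects, ncol = length(profiles),
                dimnames = list(NULL, names(profiles)))
  for (s in seq_len(n_subjects)) {
    spec_s <- base_spec
    spec_s$subject_scale <- base_spec$subject_scale * scales[s]
    if (keep_series) series[[s]] <- vector("list", length(profiles))
    for (j in seq_along(profiles)) {
      prof <- profiles[[j]]
      spec_sj <- spec_s
      spec_sj$grid <- prof$grid
      spec_sj$voxel_size <- prof$voxel_size
      ph <- generate_phantom(spec_sj, seed = sub_seeds[s, j])
      if (j == 1L) {
        gmm <- ph$tissue_probs$gm > 0.5
        truth[s] <- mean(ph$true_cbf[gmm])
      }
      p <- quant_params(t1_blood = prof$t1_blood)
      ser <- simulate_acquisition(ph, prof, p, seed = sub_seeds[s, j])
      if (keep_series) {
        series[[s]][[j]] <- ser
      } else {
        tab[s, j] <- quant_fn(ser, ph)
      }
    }
    if (keep_series) names(series[[s]]) <- names(profiles)
  }

  out <- list(subject_scale = scales, truth = truth, profiles = profiles,
              seed = as.integer(seed))
  if (keep_series) out$series <- series else out$table <- cohort_table(tab)
  structure(out, class = "asl_cohort")
}

#' @export
print.asl_cohort <- function(x, ...) {
  cat(sprintf("Simulated ASL cohort: %d subjects x %d profiles (seed %d)\n",
              length(x$subject_scale), length(x$profiles), x$seed))
  cat(sprintf("  true mean GM CBF %.1f .. %.1f ml/100 g/min\n",
              min(x$truth), max(x$truth)))
  if (!is.null(x$table)) {
    cat("  mean GM CBF table:\n")
    print(round(unclass(x$table), 2))
  }
  invisible(x)
}
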