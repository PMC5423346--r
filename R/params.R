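#' Quantification parameters for single-delay pCASL
#'
#' Bundles the physical constants entering the consensus single
#' post-labeling-delay CBF quantification equation. All times are stored in
#' milliseconds, matching how acquisition protocols print them; the
#' quantification code converts to seconds internally so that the 6000
#' pre-factor yields ml/100 g/min.
#'
#' @param lambda_bbp Blood-brain partition coefficient, ml/g. Default 0.9.
#' @param pld Post-labeling delay, ms. Default 1800.
#' @param tau Labeling duration, ms. Default 1800.
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms.
#'   Default 1650 (typical at 3T; use 1350 at 1.5T, or see
#'   [t1_blood_for_field()]).
#' @param alpha Labeling efficiency, dimensionless fraction in (0, 1].
#'   Default 0.85, the value recommended for pCASL by the consensus
#'   literature; it is deliberately configurable because protocols differ.
#'
#' @return An object of class `quant_params`.
#' @examples
#' quant_params()
#' quant_params(t1_blood = 1350) # 1.5T blood T1
#' @export
quant_params <- function(lambda_bbp = 0.9, pld = 1800, tau = 1800,
                         t1_blood = 1650, alpha = 0.85) {
  p <- list(lambda_bbp = as.numeric(lambda_bbp), pld = as.numeric(pld),
            tau = as.numeric(tau), t1_blood = as.numeric(t1_blood),
            alpha = as.numeric(alpha))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("quant_params: '", nm, "' must be a single finite positive number")
  }
  if (p$alpha > 1)
    stop("quant_params: 'alpha' must lie in (0, 1]")
  structure(p, class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat("pCASL quantification parameters\n")
  cat(sprintf("  lambda = %.3g ml/g, PLD = %g ms, tau = %g ms\n",
              x$lambda_bbp, x$pld, x$tau))
  cat(sprintf("  T1_blood = %g ms, alpha = %.3g\n", x$t1_blood, x$alpha))
  invisible(x)
}

#' Blood T1 for a given main field strength
#'
#' @param field_strength Main magnetic field in tesla (1.5 or 3.0).
#' @return Blood T1 in ms: 1650 at 3T, 1350 at 1.5T.
#' @export
t1_blood_for_field <- function(field_strength) {
  if (isTRUE(all.equal(field_strength, 3.0))) return(1650)
  if (isTRUE(all.equal(field_strength, 1.5))) return(1350)
  stop("no packaged blood T1 for field strength ", field_strength, " T")
}

#' Scanner acquisition profile
#'
#' Describes one scanner setup: geometry, number of label/control pairs,
#' blood T1 at its field strength, and the noise/coil characteristics used
#' by the acquisition simulator. The three packaged profiles (see
#' [asl_profiles()]) mirror a 3T scanner with a volume head coil (20 pairs),
#' a 1.5T radiology scanner (30 pairs), and a 1.5T intraoperative scanner
#' with two circular surface coils (40 pairs); lower field strength and
#' poorer coils are compensated by more signal averages.
#'
#' @param name Identifier string.
#' @param field_strength Tesla; packaged profiles use 1.5 or 3.0.
#' @param n_pairs Number of label/control pairs (>= 1).
#' @param t1_blood Blood T1 in ms; defaults from the field strength.
#' @param grid Integer vector (nx, ny, nz) of voxel counts.
#' @param voxel_size Numeric (dx, dy, dz) voxel spacing in mm.
#' @param noise_sd Additive Gaussian noise standard deviation, in the same
#'   arbitrary signal units as M0.
#' @param bias_field_amplitude Peak fractional deviation of the smooth
#'   multiplicative coil-sensitivity field (0 for volume coils, > 0 for
#'   surface coils).
#'
#' @return An object of class `scanner_profile`.
#' @export
scanner_profile <- function(name, field_strength, n_pairs,
                            t1_blood = t1_blood_for_field(field_strength),
                            grid = c(67L, 69L, 16L),
                            voxel_size = c(3.6, 3.5, 5.9375),
                            noise_sd = 5, bias_field_amplitude = 0) {
  grid <- as.integer(grid)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(grid) == 3L, length(voxel_size) == 3L)
  if (any(grid < 1L) || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("scanner_profile: grid and voxel_size must be strictly positive")
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L)
    stop("scanner_profile: n_pairs must be >= 1")
  if (!is.finite(t1_blood) || t1_blood <= 0)
    stop("scanner_profile: t1_blood must be positive and finite")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("scanner_profile: noise_sd must be >= 0")
  if (!is.finite(bias_field_amplitude) || bias_field_amplitude < 0 ||
      bias_field_amplitude >= 1)
    stop("scanner_profile: bias_field_amplitude must lie in [0, 1)")
  structure(list(name = as.character(name),
                 field_strength = as.numeric(field_strength),
                 n_pairs = n_pairs, t1_blood = as.numeric(t1_blood),
                 grid = grid, voxel_size = voxel_size,
                 noise_sd = as.numeric(noise_sd),
                 bias_field_amplitude = as.numeric(bias_field_amplitude)),
            class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("Scanner profile '%s' (%.1fT)\n", x$name, x$field_strength))
  cat(sprintf("  %d label/control pairs, T1_blood %g ms\n",
              x$n_pairs, x$t1_blood))
  cat(sprintf("  grid %dx%dx%d, voxel %.4gx%.4gx%.4g mm\n",
              x$grid[1], x$grid[2], x$grid[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  noise sd %g, bias amplitude %g\n",
              x$noise_sd, x$bias_field_amplitude))
  invisible(x)
}

#' The three packaged scanner profiles
#'
#' Packaged acquisition profiles on a shared grid covering a
#' 240 x 240 x 95 mm field of view with 3.6 x 3.5 mm in-plane resolution
#' and 16 slices (5 mm thickness at 5.94 mm spacing):
#' \describe{
#'   \item{`3t`}{3T, 32-channel head coil, 20 pairs, blood T1 1650 ms.}
#'   \item{`1p5t_rad`}{1.5T radiology scanner, 6-channel head coil,
#'     30 pairs, blood T1 1350 ms.}
#'   \item{`1p5t_or`}{1.5T intraoperative scanner, two circular surface
#'     coils, 40 pairs, blood T1 1350 ms, nonzero coil bias field.}
#' }
#' Noise standard deviations (5 / 6 / 8 signal units against a gray-matter
#' M0 of roughly 1000) are simulator defaults chosen so that single-pair SNR
#' is lowest for the operating-room surface-coil profile, the deficit the
#' larger number of averages is there to compensate.
#'
#' @param which Optional profile name; omit for the full named list.
#' @return A `scanner_profile`, or a named list of all three.
#' @examples
#' asl_profiles("3t")
#' names(asl_profiles())
#' @export
asl_profiles <- function(which = NULL) {
  profs <- list(
    `3t` = scanner_profile("3t", 3.0, 20L, noise_sd = 5,
                           bias_field_amplitude = 0),
    `1p5t_rad` = scanner_profile("1p5t_rad", 1.5, 30L, noise_sd = 6,
                                 bias_field_amplitude = 0),
    `1p5t_or` = scanner_profile("1p5t_or", 1.5, 40L, noise_sd = 8,
                                bias_field_amplitude = 0.3))
  if (is.null(which)) return(profs)
  if (!which %in% names(profs))
    stop("unknown profile '", which, "'; available: ",
         paste(names(profs), collapse = ", "))
  profs[[which]]
}

#' Read quantification parameters and scanner profiles from a config file
#'
#' The config is YAML (or JSON, a YAML subset) with optional top-level keys
#' `quant_params` and `profiles`; times in ms. Fields omitted fall back to
#' the packaged defaults.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A list with elements `quant_params` (a [quant_params()] object or
#'   NULL) and `profiles` (named list of [scanner_profile()] or NULL).
#' @export
read_asl_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(quant_params = NULL, profiles = NULL)
  if (!is.null(cfg$quant_params))
    out$quant_params <- do.call(quant_params, cfg$quant_params)
  if (!is.null(cfg$profiles)) {
    out$profiles <- lapply(names(cfg$profiles), function(nm) {
      args <- cfg$profiles[[nm]]
      args$name <- nm
      do.call(scanner_profile, args)
    })
    names(out$profiles) <- names(cfg$profiles)
  }
  out
}

#' Write quantification parameters and profiles to a YAML config file
#'
#' @param path Output path.
#' @param quant_params Optional [quant_params()] object.
#' @param profiles Optional named list of [scanner_profile()] objects.
#' @return `path`, invisibly.
#' @export
write_asl_config <- function(path, quant_params = NULL, profiles = NULL) {
  cfg <- list()
  if (!is.null(quant_params))
    cfg$quant_params <- unclass(quant_params)
  if (!is.null(profiles)) {
    cfg$profiles <- lapply(profiles, function(p) {
      p <- unclass(p)
      p$name <- NULL
      p
    })
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
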