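#' Quantify CBF from a subtracted pCASL signal
#'
#' Evaluates the single post-labeling-delay quantification equation
#' recommended by the ISMRM perfusion study group and the ASL-in-dementia
#' consortium:
#' \deqn{CBF = \frac{6000 \, \lambda \, \Delta M \, e^{PLD/T_{1,blood}}}
#'   {2 \, \alpha \, T_{1,blood} \, M_0 \, (1 - e^{-\tau/T_{1,blood}})}}
#' with \eqn{T_{1,blood}}, PLD and \eqn{\tau} in seconds inside the
#' exponentials and the leading \eqn{T_{1,blood}} factor, so that the 6000
#' pre-factor converts ml/g/s to ml/100 g/min. Parameters are stored in ms
#' (as protocols print them) and converted here.
#'
#' The result is linear in `delta_m` and invariant under joint rescaling of
#' `delta_m` and `m0`: only the ratio \eqn{\Delta M / M_0} matters, which is
#' what makes the quantification insensitive to smooth multiplicative coil
#' sensitivity.
#'
#' @param delta_m Mean control-minus-label difference signal (scalar or
#'   vector), arbitrary signal units.
#' @param m0 Equilibrium magnetization signal, same units; must be > 0.
#' @param p A [quant_params()] object.
#' @return CBF in ml/100 g/min, same shape as `delta_m`.
#' @examples
#' quantify_voxel(10, 1000, quant_params()) # 0.01 difference ratio
#' @export
quantify_voxel <- function(delta_m, m0, p) {
  stopifnot(inherits(p, "quant_params"))
  if (length(m0) != 1L && length(m0) != length(delta_m))
    stop("m0 must be scalar or match delta_m in length")
  if (any(!is.finite(delta_m)) || any(!is.finite(m0)))
    stop("quantify_voxel: non-finite input")
  if (any(m0 <= 0))
    stop("quantify_voxel: m0 must be strictly positive")
  .cbf_factor(p) * delta_m / m0
}

# CBF per unit (delta_m / m0): the whole equation except the signal ratio.
.cbf_factor <- function(p) {
  t1b <- p$t1_blood / 1000
  pld <- p$pld / 1000
  tau <- p$tau / 1000
  6000 * p$lambda_bbp * exp(pld / t1b) /
    (2 * p$alpha * t1b * (1 - exp(-tau / t1b)))
}

#' Quantify a whole CBF map from difference and M0 volumes
#'
#' Applies [quantify_voxel()] voxel-wise. Voxels whose M0 falls at or below
#' a small positive floor (a fraction of the robust M0 maximum, by default
#' `1e-6` of its 99th percentile) are flagged invalid and carry the `NA`
#' sentinel rather than a fabricated value; everything else is quantified.
#' Non-finite inputs are likewise flagged, never propagated silently.
#'
#' @param diff 3-D array of mean control-minus-label differences.
#' @param m0_vol 3-D array of M0 signal on the same grid.
#' @param p A [quant_params()] object.
#' @param voxel_size Numeric length-3 voxel spacing in mm (metadata).
#' @param source_scanner Identifier recorded in the map's provenance.
#' @param m0_floor_frac M0 validity floor as a fraction of the robust
#'   (99th-percentile) M0 maximum.
#' @return A `cbf_map`: list with `values` (3-D array, ml/100 g/min, `NA`
#'   at invalid voxels), `n_invalid`, `params_used`, `voxel_size`,
#'   `source_scanner`.
#' @export
quantify_map <- function(diff, m0_vol, p, voxel_size = c(1, 1, 1),
                         source_scanner = "unknown", m0_floor_frac = 1e-6) {
  stopifnot(inherits(p, "quant_params"))
  if (!identical(dim(diff), dim(m0_vol)))
    stop("quantify_map: diff and m0_vol grids differ")
  if (length(dim(diff)) != 3L)
    stop("quantify_map: expected 3-D volumes")
  robust_max <- stats::quantile(m0_vol[is.finite(m0_vol)], 0.99,
                                names = FALSE)
  floor_val <- m0_floor_frac * max(robust_max, 0)
  invalid <- !is.finite(m0_vol) | !is.finite(diff) | m0_vol <= floor_val
  values <- array(NA_real_, dim = dim(diff))
  k <- .cbf_factor(p)
  values[!invalid] <- k * diff[!invalid] / m0_vol[!invalid]
  structure(list(values = values, n_invalid = sum(invalid),
                 params_used = p, voxel_size = as.numeric(voxel_size),
                 source_scanner = source_scanner),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("CBF map %dx%dx%d from '%s'\n", d[1], d[2], d[3],
              x$source_scanner))
  v <- x$values[is.finite(x$values)]
  cat(sprintf("  valid voxels: %d (%d invalid)\n", length(v), x$n_invalid))
  if (length(v))
    cat(sprintf("  range %.2f .. %.2f ml/100 g/min, median %.2f\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

#' @export
summary.cbf_map <- function(object, ...) {
  v <- object$values[is.finite(object$values)]
  out <- list(n_valid = length(v), n_invalid = object$n_invalid,
              mean = mean(v), sd = stats::sd(v),
              quartiles = stats::quantile(v, c(0.25, 0.5, 0.75)),
              source_scanner = object$source_scanner)
  class(out) <- "summary.cbf_map"
  out
}

#' @export
print.summary.cbf_map <- function(x, ...) {
  cat(sprintf("CBF map from '%s': %d valid / %d invalid voxels\n",
              x$source_scanner, x$n_valid, x$n_invalid))
  cat(sprintf("  mean %.2f (sd %.2f) ml/100 g/min; quartiles %.2f / %.2f / %.2f\n",
              x$mean, x$sd, x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  invisible(x)
}

#' Forward model: difference signal expected from a true CBF field
#'
#' Algebraic inverse of [quantify_voxel()]: given true CBF and M0, returns
#' the control-minus-label difference \eqn{\Delta M} that quantification
#' would map back to exactly that CBF. This is the generative core of the
#' acquisition simulator; using the exact inverse makes noiseless
#' simulate-then-quantify an identity, so parameter recovery is a sharp
#' self-consistency test.
#'
#' @param true_cbf 3-D array (or scalar/vector) of CBF in ml/100 g/min.
#' @param m0 M0 signal, same shape (or scalar).
#' @param p A [quant_params()] object.
#' @return Difference signal with the shape of `true_cbf`.
#' @export
forward_delta_m <- function(true_cbf, m0, p) {
  stopifnot(inherits(p, "quant_params"))
  if (!is.null(dim(true_cbf)) && !is.null(dim(m0)) &&
      !identical(dim(true_cbf), dim(m0)))
    stop("forward_delta_m: grids differ")
  true_cbf * m0 / .cbf_factor(p)
}
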