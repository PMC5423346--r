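#' Average pairwise control-minus-label subtraction
#'
#' Collapses an interleaved pCASL series to the mean over pairs of
#' (control - label), the perfusion-weighted difference signal. The series
#' must carry its interleave-order metadata; with the packaged
#' control-first convention the difference is positive in perfused tissue.
#' Averaging is done before quantification; since the quantification
#' equation is linear in the difference signal the two orders are
#' mathematically identical, and averaging first keeps invalid-voxel
#' bookkeeping in one place.
#'
#' @param series An `asl_series` (from [simulate_acquisition()] or
#'   [read_asl_series()]).
#' @return A `difference_map`: list with `values` (3-D array),
#'   `n_pairs_used`, `voxel_size`, `source_scanner`.
#' @export
pairwise_subtract <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  d <- dim(series$volumes)
  if (length(d) != 4L || d[4] %% 2L != 0L)
    stop("pairwise_subtract: series must hold an even number of volumes")
  if (is.null(series$order) ||
      !series$order %in% c("control_first", "label_first"))
    stop("pairwise_subtract: missing or unknown interleave-order metadata")
  n_pairs <- d[4] %/% 2L
  v <- matrix(series$volumes, nrow = prod(d[1:3]), ncol = d[4])
  odd <- seq(1L, d[4], by = 2L)
  diffs <- v[, odd, drop = FALSE] - v[, -odd, drop = FALSE]
  if (series$order == "label_first") diffs <- -diffs
  structure(list(values = array(rowMeans(diffs), dim = d[1:3]),
                 n_pairs_used = n_pairs,
                 voxel_size = series$profile$voxel_size,
                 source_scanner = series$profile$name),
            class = "difference_map")
}

#' Quantify an acquisition series to a CBF map
#'
#' Convenience wrapper: [pairwise_subtract()] then [quantify_map()] against
#' the series' own M0 volume and quantification parameters.
#'
#' @param series An `asl_series`.
#' @param p Optional [quant_params()] override; defaults to the parameters
#'   stored with the series.
#' @return A `cbf_map`.
#' @export
quantify_series <- function(series, p = NULL) {
  stopifnot(inherits(series, "asl_series"))
  if (is.null(p)) p <- series$params
  dm <- pairwise_subtract(series)
  quantify_map(dm$values, series$m0, p,
               voxel_size = series$profile$voxel_size,
               source_scanner = series$profile$name)
}

#' Gray-matter mask from phantom ground truth
#'
#' Thresholds the phantom's gray-matter probability map, standing in for
#' anatomical segmentation when the ground truth is known.
#'
#' @param phantom An `asl_phantom`.
#' @param prob_threshold Probability threshold in (0, 1); default 0.5.
#' @return A `gm_mask`: logical 3-D array with attribute
#'   `provenance = "phantom-truth"`.
#' @export
gm_mask_from_phantom <- function(phantom, prob_threshold = 0.5) {
  stopifnot(inherits(phantom, "asl_phantom"))
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("gm_mask_from_phantom: prob_threshold must lie in (0, 1)")
  m <- phantom$tissue_probs$gm > prob_threshold
  if (!any(m))
    stop("gm_mask_from_phantom: empty gray-matter mask")
  structure(m, class = "gm_mask", provenance = "phantom-truth")
}

#' Gray-matter mask by M0 intensity threshold
#'
#' Fallback for acquired data without a ground-truth segmentation: keeps
#' voxels whose M0 lies in a band around typical parenchymal intensity,
#' between the `lower` and `upper` quantiles of the positive M0 signal.
#' A crude stand-in for anatomical segmentation, adequate for ROI means.
#'
#' @param m0 3-D M0 array.
#' @param lower,upper Quantiles of positive M0 bounding the band.
#' @return A `gm_mask` with attribute `provenance = "threshold"`.
#' @export
gm_mask_from_m0 <- function(m0, lower = 0.5, upper = 0.95) {
  stopifnot(lower < upper)
  pos <- m0[m0 > 0 & is.finite(m0)]
  if (!length(pos)) stop("gm_mask_from_m0: no positive M0 signal")
  q <- stats::quantile(pos, c(lower, upper), names = FALSE)
  m <- m0 >= q[1] & m0 <= q[2]
  if (!any(m)) stop("gm_mask_from_m0: empty mask")
  structure(m, class = "gm_mask", provenance = "threshold")
}

#' Mean CBF over a region of interest
#'
#' Arithmetic mean and standard deviation of a CBF map over a mask,
#' excluding (and counting) invalid voxels.
#'
#' @param map A `cbf_map`.
#' @param mask Logical 3-D array (e.g. a `gm_mask`) on the map's grid.
#' @return List with `mean`, `sd`, `n` (valid voxels used) and `n_excluded`
#'   (masked voxels dropped as invalid).
#' @export
mean_roi_cbf <- function(map, mask) {
  stopifnot(inherits(map, "cbf_map"))
  if (!identical(dim(map$values), dim(mask)))
    stop("mean_roi_cbf: mask grid does not match map grid")
  if (!any(mask)) stop("mean_roi_cbf: empty mask")
  v <- map$values[mask]
  ok <- is.finite(v)
  if (!any(ok))
    stop("mean_roi_cbf: no valid voxels inside mask")
  list(mean = mean(v[ok]), sd = stats::sd(v[ok]), n = sum(ok),
       n_excluded = sum(!ok))
}
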