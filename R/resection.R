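# Integer voxel offsets within a Euclidean radius (mm), for anisotropic
# voxels. Used for mm-accurate morphological dilation.
.ball_offsets <- function(radius_mm, voxel_size) {
  r <- floor(radius_mm / voxel_size)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (off$dx * voxel_size[1])^2 + (off$dy * voxel_size[2])^2 +
    (off$dz * voxel_size[3])^2
  as.matrix(off[d2 <= radius_mm^2, , drop = FALSE])
}

# Binary dilation of a 3-D mask by a Euclidean radius in mm.
.dilate_mm <- function(mask, radius_mm, voxel_size) {
  g <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask)
  out <- array(FALSE, dim = g)
  off <- .ball_offsets(radius_mm, voxel_size)
  for (k in seq_len(nrow(off))) {
    sh <- idx
    sh[, 1] <- sh[, 1] + off[k, 1]
    sh[, 2] <- sh[, 2] + off[k, 2]
    sh[, 3] <- sh[, 3] + off[k, 3]
    keep <- sh[, 1] >= 1L & sh[, 1] <= g[1] & sh[, 2] >= 1L &
      sh[, 2] <= g[2] & sh[, 3] >= 1L & sh[, 3] <= g[3]
    out[sh[keep, , drop = FALSE]] <- TRUE
  }
  out
}

#' Shell around a resection cavity
#'
#' The search region for residual tumor: the cavity mask dilated by a
#' Euclidean distance (mm-accurate under anisotropic voxels), minus the
#' cavity itself, optionally intersected with a head mask. Residual tumor
#' after resection, if present, sits at the cavity rim, which is also where
#' surgically induced enhancement confounds anatomical reading - hence a
#' rim shell rather than the whole brain.
#'
#' @param cavity_mask Logical 3-D array; must be nonempty.
#' @param shell_mm Shell thickness in mm (> 0); default 10.
#' @param voxel_size Numeric (dx, dy, dz) mm.
#' @param head_mask Optional logical array restricting the shell to tissue.
#' @return Logical 3-D array. May be empty when `shell_mm` is smaller than
#'   any voxel dimension (the zero-thickness limit).
#' @export
cavity_shell <- function(cavity_mask, shell_mm = 10,
                         voxel_size = c(1, 1, 1), head_mask = NULL) {
  if (!any(cavity_mask))
    stop("cavity_shell: empty cavity mask")
  if (!is.numeric(shell_mm) || shell_mm <= 0)
    stop("cavity_shell: shell_mm must be > 0")
  shell <- .dilate_mm(cavity_mask, shell_mm, voxel_size) & !cavity_mask
  if (!is.null(head_mask)) shell <- shell & head_mask
  shell
}

# Sizes of 26-connected components among TRUE voxels of a 3-D mask.
# Returns integer(0) for an empty mask. Component adjacency is built as a
# graph over the (typically few) foreground voxels.
.cluster_sizes_26 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  g <- dim(mask)
  # linear index lookup for foreground voxels
  lin <- (idx[, 3] - 1L) * g[1] * g[2] + (idx[, 2] - 1L) * g[1] + idx[, 1]
  pos <- integer(prod(g))
  pos[lin] <- seq_len(n)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  half <- off[seq_len(nrow(off) / 2), , drop = FALSE]  # undirected: half
  edges <- NULL
  for (k in seq_len(nrow(half))) {
    sh <- idx
    sh[, 1] <- sh[, 1] + half[k, 1]
    sh[, 2] <- sh[, 2] + half[k, 2]
    sh[, 3] <- sh[, 3] + half[k, 3]
    keep <- sh[, 1] >= 1L & sh[, 1] <= g[1] & sh[, 2] >= 1L &
      sh[, 2] <= g[2] & sh[, 3] >= 1L & sh[, 3] <= g[3]
    if (!any(keep)) next
    lin2 <- (sh[keep, 3] - 1L) * g[1] * g[2] + (sh[keep, 2] - 1L) * g[1] +
      sh[keep, 1]
    nb <- pos[lin2]
    hit <- nb > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(keep)[hit], nb[hit]))
  }
  if (is.null(edges)) return(rep(1L, n))  # all foreground voxels isolated
  gr <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  if (igraph::vcount(gr) < n)
    gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  comp <- igraph::components(gr)
  as.integer(comp$csize)
}

#' Rate residual tumor from elevated perfusion around a cavity
#'
#' Operationalizes the visual "elevated CBF at the resection rim means
#' residual tumor" reading as a reproducible rule: the CBF threshold is
#' `mean + z * sd` over a reference gray-matter region (which must be
#' disjoint from the shell); supra-threshold shell voxels are grouped into
#' 26-connected clusters; the rating is 1 exactly when the largest cluster
#' reaches `min_cluster` voxels. All constants are explicit arguments - the
#' defaults (z = 2, 5 voxels) are this package's operational choice, not a
#' clinically validated threshold, and no equivalence to human readers is
#' claimed.
#'
#' @param cbf A `cbf_map`.
#' @param shell Logical 3-D array, the [cavity_shell()] search region.
#' @param gm_reference Logical 3-D array of reference gray matter (e.g. a
#'   [contralateral_reference()]); voxels overlapping the shell are dropped.
#' @param z Threshold multiplier on the reference SD (default 2).
#' @param min_cluster Minimum 26-connected cluster size in voxels
#'   (default 5).
#' @return An object of class `residual_call`: list with `rating` (0/1),
#'   `largest_cluster_voxels`, `cluster_peak_cbf`, `threshold_used`,
#'   `reference_mean`, `reference_sd`, `n_shell_voxels`, `z`, `min_cluster`.
#' @export
rate_residual <- function(cbf, shell, gm_reference, z = 2, min_cluster = 5) {
  stopifnot(inherits(cbf, "cbf_map"))
  if (!identical(dim(cbf$values), dim(shell)) ||
      !identical(dim(cbf$values), dim(gm_reference)))
    stop("rate_residual: grids differ")
  ref <- gm_reference & !shell
  ref_v <- cbf$values[ref]
  ref_v <- ref_v[is.finite(ref_v)]
  if (length(ref_v) < 2)
    stop("rate_residual: empty or degenerate reference region")
  thr <- mean(ref_v) + z * stats::sd(ref_v)
  shell_v <- cbf$values[shell]
  supra <- array(FALSE, dim = dim(shell))
  supra[shell] <- is.finite(shell_v) & shell_v > thr
  sizes <- .cluster_sizes_26(supra)
  largest <- if (length(sizes)) max(sizes) else 0L
  peak <- if (any(supra)) max(cbf$values[supra], na.rm = TRUE) else NA_real_
  structure(list(rating = as.integer(largest >= min_cluster),
                 largest_cluster_voxels = largest, cluster_peak_cbf = peak,
                 threshold_used = thr, reference_mean = mean(ref_v),
                 reference_sd = stats::sd(ref_v),
                 n_shell_voxels = sum(shell), z = z,
                 min_cluster = as.integer(min_cluster)),
            class = "residual_call")
}

#' @export
print.residual_call <- function(x, ...) {
  cat(sprintf("Residual-tumor call: %d (%s)\n", x$rating,
              if (x$rating == 1) "elevated perfusion at cavity rim"
              else "no supra-threshold cluster"))
  cat(sprintf("  threshold %.1f ml/100 g/min (ref %.1f +/- %.1f, z = %g)\n",
              x$threshold_used, x$reference_mean, x$reference_sd, x$z))
  cat(sprintf("  largest cluster %d voxels (min %d); peak CBF %s\n",
              x$largest_cluster_voxels, x$min_cluster,
              ifelse(is.na(x$cluster_peak_cbf), "-",
                     sprintf("%.1f", x$cluster_peak_cbf))))
  invisible(x)
}

#' Contralateral gray-matter reference region
#'
#' Reflects the gray-matter mask through the midsagittal plane (the x
#' midline of the grid) and keeps reflected-GM voxels that are themselves
#' GM, excluding the shell. Falls back to whole GM minus shell when the
#' reflection leaves too few voxels (e.g. midline pathology).
#'
#' @param gm_mask Logical 3-D GM array.
#' @param shell Logical 3-D search-region array.
#' @param min_voxels Fallback trigger: minimum reference size.
#' @return Logical 3-D array.
#' @export
contralateral_reference <- function(gm_mask, shell, min_voxels = 50) {
  stopifnot(identical(dim(gm_mask), dim(shell)))
  # hemisphere containing the shell, reflected in x
  g <- dim(gm_mask)
  idx <- which(shell, arr.ind = TRUE)
  if (nrow(idx)) {
    mid <- (g[1] + 1) / 2
    lesion_side_right <- mean(idx[, 1]) > mid
    xs <- seq_len(g[1])
    side <- if (lesion_side_right) xs < mid else xs > mid
    ref <- gm_mask & array(rep(side, times = g[2] * g[3]), dim = g)
  } else {
    ref <- gm_mask
  }
  ref <- ref & !shell
  if (sum(ref) < min_voxels) ref <- gm_mask & !shell
  ref
}

#' Patient rating table (binary residual-tumor calls)
#'
#' Validates a per-patient table of binary residual-tumor ratings by
#' modality (ASL vs anatomical) and timepoint (intra- vs postoperative).
#'
#' @param df Data frame with columns `patient`, `asl_intraop`,
#'   `asl_postop`, `anat_intraop`, `anat_postop` (cells 0/1); further
#'   columns (diagnosis, initial readings) are carried through.
#' @return A `rating_table` data frame.
#' @export
rating_table <- function(df) {
  need <- c("patient", "asl_intraop", "asl_postop", "anat_intraop",
            "anat_postop")
  if (!all(need %in% names(df)))
    stop("rating_table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$patient))
    stop("rating_table: duplicate patient labels")
  for (col in setdiff(need, "patient"))
    if (!all(df[[col]] %in% c(0, 1)))
      stop("rating_table: non-binary cells in '", col, "'")
  structure(df, class = c("rating_table", "data.frame"))
}

#' Read a rating table from CSV
#'
#' @param path CSV with a header row; see [rating_table()] for the schema.
#'   Defaults to the packaged table of eight glioblastoma resections
#'   (blinded intra-/postoperative ASL and anatomical readings, including
#'   patient 1's anatomical postoperative call both as initially read and
#'   as later amended to an adjacent-artery partial-volume effect).
#' @return A `rating_table`.
#' @export
read_rating_table <- function(path = system.file("extdata",
                                                 "table2_ratings.csv",
                                                 package = "pcasl")) {
  rating_table(utils::read.csv(path))
}

#' Resection bookkeeping from a rating table
#'
#' Counts, from the ASL columns: patients with residual tumor
#' intraoperatively, with residual tumor postoperatively, and with complete
#' resection already at surgery (`n - intraop_residual`).
#'
#' @param table A [rating_table()].
#' @return Named list `intraop_residual`, `postop_residual`,
#'   `complete_at_surgery`, `n_patients`.
#' @export
table2_summary <- function(table) {
  if (!inherits(table, "rating_table")) table <- rating_table(table)
  n <- nrow(table)
  intra <- sum(table$asl_intraop)
  post <- sum(table$asl_postop)
  list(intraop_residual = intra, postop_residual = post,
       complete_at_surgery = n - intra, n_patients = n)
}
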