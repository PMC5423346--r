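# NIfTI affine for a RAS-oriented volume centered on the grid origin.
.ras_affine <- function(grid, voxel_size) {
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- -(grid - 1) / 2 * voxel_size
  structure(aff, code = 2L)
}

#' Write an ASL series to NIfTI plus a JSON sidecar
#'
#' Writes the interleaved 4-D series as `<prefix>_asl.nii`, the M0 volume
#' as `<prefix>_m0.nii` (RAS orientation, voxel spacing in the header), and
#' the acquisition metadata (scanner profile, quantification parameters,
#' interleave order, seed) as `<prefix>.json`, so an acquisition can be
#' reconstituted losslessly.
#'
#' @param series An `asl_series`.
#' @param prefix Output path prefix (directories must exist).
#' @param compress Write `.nii.gz` instead of `.nii`? Default FALSE.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_asl_series <- function(series, prefix, compress = FALSE) {
  stopifnot(inherits(series, "asl_series"))
  ext <- if (compress) ".nii.gz" else ".nii"
  g <- series$profile$grid
  vs <- series$profile$voxel_size
  aff <- .ras_affine(g, vs)
  paths <- c(asl = paste0(prefix, "_asl", ext),
             m0 = paste0(prefix, "_m0", ext),
             meta = paste0(prefix, ".json"))
  img4 <- RNifti::asNifti(series$volumes)
  img4 <- RNifti::`pixdim<-`(img4, c(vs, 1))
  img4 <- RNifti::`sform<-`(img4, aff)
  RNifti::writeNifti(img4, paths["asl"])
  img3 <- RNifti::asNifti(series$m0)
  img3 <- RNifti::`pixdim<-`(img3, vs)
  img3 <- RNifti::`sform<-`(img3, aff)
  RNifti::writeNifti(img3, paths["m0"])
  meta <- list(profile = unclass(series$profile),
               params = unclass(series$params),
               order = series$order, seed = series$seed)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an ASL series written by [write_asl_series()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `asl_series`.
#' @export
read_asl_series <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path))
    stop("read_asl_series: sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ext <- if (file.exists(paste0(prefix, "_asl.nii"))) ".nii" else ".nii.gz"
  vols <- RNifti::readNifti(paste0(prefix, "_asl", ext))
  m0 <- RNifti::readNifti(paste0(prefix, "_m0", ext))
  prof <- scanner_profile(name = meta$profile$name,
                          field_strength = meta$profile$field_strength,
                          n_pairs = meta$profile$n_pairs,
                          t1_blood = meta$profile$t1_blood,
                          grid = meta$profile$grid,
                          voxel_size = meta$profile$voxel_size,
                          noise_sd = meta$profile$noise_sd,
                          bias_field_amplitude =
                            meta$profile$bias_field_amplitude)
  p <- do.call(quant_params, meta$params)
  vols <- array(as.numeric(vols), dim = dim(vols))
  m0 <- array(as.numeric(m0), dim = dim(m0))
  if (dim(vols)[4] != 2L * prof$n_pairs)
    stop("read_asl_series: volume count does not match profile n_pairs")
  structure(list(volumes = vols, m0 = m0, profile = prof, params = p,
                 order = meta$order, seed = as.integer(meta$seed)),
            class = "asl_series")
}

#' Write a CBF map as NIfTI with a JSON provenance sidecar
#'
#' The sidecar records the quantification parameters actually used
#' (including the labeling efficiency), units, the source scanner and the
#' invalid-voxel count, so every map carries its own provenance.
#'
#' @param map A `cbf_map`.
#' @param prefix Output path prefix.
#' @param compress Write `.nii.gz`? Default FALSE.
#' @return Named character vector of paths, invisibly.
#' @export
write_cbf_map <- function(map, prefix, compress = FALSE) {
  stopifnot(inherits(map, "cbf_map"))
  ext <- if (compress) ".nii.gz" else ".nii"
  aff <- .ras_affine(dim(map$values), map$voxel_size)
  paths <- c(cbf = paste0(prefix, "_cbf", ext),
             meta = paste0(prefix, "_cbf.json"))
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`pixdim<-`(img, map$voxel_size)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, paths["cbf"])
  jsonlite::write_json(list(units = "ml/100g/min",
                            params_used = unclass(map$params_used),
                            source_scanner = map$source_scanner,
                            n_invalid = map$n_invalid),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
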