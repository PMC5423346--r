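#' Specification of a digital head phantom
#'
#' Describes a simple anatomical ground truth: an ellipsoidal head with a
#' gray-matter (GM) shell, a white-matter (WM) core and CSF-filled
#' ventricles, on the acquisition grid. Optional hyperperfused spherical
#' lesions stand in for tumor tissue and an optional spherical cavity for a
#' resection void. Default tissue perfusion is GM 50, WM 20, CSF 0
#' ml/100 g/min - GM calibrated to healthy-volunteer gray matter means near
#' 49 ml/100 g/min.
#'
#' Coordinates are in mm with the origin at the grid center; lesions and the
#' cavity are specified as `(center, radius)` in that frame.
#'
#' @param grid Integer (nx, ny, nz) voxel counts.
#' @param voxel_size Numeric (dx, dy, dz) mm.
#' @param head_semiaxes Ellipsoid semi-axes (mm) of the head/brain outline.
#' @param gm_thickness Cortical GM shell thickness, mm.
#' @param cbf Named numeric: true perfusion per tissue class, ml/100 g/min.
#' @param m0_pd Named numeric: proton-density M0 per tissue class, signal
#'   units (CSF brightest, as on a long-TR reference).
#' @param lesions List of lesions, each `list(center = c(x, y, z), radius,
#'   cbf)`; lesion CBF overrides the background inside its radius.
#' @param cavity Optional `list(center = c(x, y, z), radius)`: a resection
#'   void with zero tissue and zero signal.
#' @param subject_scale Global multiplicative CBF factor (one subject's
#'   physiology relative to the cohort mean).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(67L, 69L, 16L),
                         voxel_size = c(3.6, 3.5, 5.9375),
                         head_semiaxes = c(78, 95, 60),
                         gm_thickness = 9,
                         cbf = c(gm = 50, wm = 20, csf = 0),
                         m0_pd = c(gm = 1000, wm = 820, csf = 1250),
                         lesions = list(), cavity = NULL,
                         subject_scale = 1) {
  grid <- as.integer(grid)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(grid) == 3L, all(grid >= 4L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(head_semiaxes) == 3L, all(head_semiaxes > 0),
            gm_thickness > 0, subject_scale > 0)
  need <- c("gm", "wm", "csf")
  if (!all(need %in% names(cbf)) || !all(need %in% names(m0_pd)))
    stop("phantom_spec: cbf and m0_pd need entries gm, wm, csf")
  if (any(cbf < 0)) stop("phantom_spec: tissue CBF must be >= 0")
  fov <- grid * voxel_size
  check_sphere <- function(s, what) {
    if (!is.list(s) || is.null(s$center) || is.null(s$radius) ||
        length(s$center) != 3L || s$radius <= 0)
      stop("phantom_spec: malformed ", what)
    if (any(abs(s$center) + s$radius > fov / 2))
      stop("phantom_spec: ", what, " extends outside the grid")
  }
  for (l in lesions) {
    check_sphere(l, "lesion")
    if (is.null(l$cbf) || l$cbf < 0)
      stop("phantom_spec: lesion cbf must be >= 0")
  }
  if (!is.null(cavity)) check_sphere(cavity, "cavity")
  structure(list(grid = grid, voxel_size = voxel_size,
                 head_semiaxes = as.numeric(head_semiaxes),
                 gm_thickness = as.numeric(gm_thickness),
                 cbf = cbf, m0_pd = m0_pd, lesions = lesions,
                 cavity = cavity, subject_scale = as.numeric(subject_scale)),
            class = "phantom_spec")
}

# mm coordinates of every voxel center, origin at grid center.
# Returns a list of three arrays (x, y, z) with the grid's dims.
.voxel_coords <- function(grid, voxel_size) {
  ax <- lapply(1:3, function(i) {
    (seq_len(grid[i]) - (grid[i] + 1) / 2) * voxel_size[i]
  })
  list(x = array(rep(ax[[1]], times = grid[2] * grid[3]), dim = grid),
       y = array(rep(rep(ax[[2]], each = grid[1]), times = grid[3]),
                 dim = grid),
       z = array(rep(ax[[3]], each = grid[1] * grid[2]), dim = grid))
}

#' Generate a ground-truth phantom volume set
#'
#' Rasterizes a [phantom_spec()] into tissue-class maps, a true CBF field
#' and an M0 (proton-density) template. Tissue labels are crisp (class
#' probabilities 0/1) and the true CBF field is exactly the
#' probability-weighted sum of class CBF values, with lesions overriding the
#' background inside their radius and the cavity zeroing both tissue and
#' signal. The construction is fully deterministic; `seed` is accepted for
#' interface symmetry with the stochastic stages and recorded in the output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer, recorded in the result.
#' @return An object of class `asl_phantom`: list with 3-D arrays
#'   `true_cbf`, `m0`, `tissue_probs` (named list gm/wm/csf), `head_mask`,
#'   `cavity_mask`, plus `spec` and `seed`.
#' @export
generate_phantom <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  co <- .voxel_coords(g, spec$voxel_size)
  semi <- spec$head_semiaxes

  in_ellipsoid <- function(semiaxes, center = c(0, 0, 0)) {
    ((co$x - center[1]) / semiaxes[1])^2 +
      ((co$y - center[2]) / semiaxes[2])^2 +
      ((co$z - center[3]) / semiaxes[3])^2 <= 1
  }
  in_sphere <- function(center, radius) {
    (co$x - center[1])^2 + (co$y - center[2])^2 +
      (co$z - center[3])^2 <= radius^2
  }

  head <- in_ellipsoid(semi)
  inner <- in_ellipsoid(pmax(semi - spec$gm_thickness, 1e-6))
  # ventricles: paired CSF ellipsoids either side of the midline,
  # scaled with the head so small test phantoms keep all three tissues
  vsemi <- c(0.17, 0.32, 0.23) * semi
  voff <- c(0.25 * semi[1], 0.08 * semi[2], 0.08 * semi[3])
  vent <- in_ellipsoid(vsemi, center = c(-voff[1], voff[2], voff[3])) |
    in_ellipsoid(vsemi, center = c(voff[1], voff[2], voff[3]))
  vent <- vent & inner

  gm <- head & !inner
  csf <- vent
  wm <- inner & !vent

  cavity <- array(FALSE, dim = g)
  if (!is.null(spec$cavity))
    cavity <- in_sphere(spec$cavity$center, spec$cavity$radius) & head

  gm[cavity] <- FALSE
  wm[cavity] <- FALSE
  csf[cavity] <- FALSE

  probs <- list(gm = array(as.numeric(gm), dim = g),
                wm = array(as.numeric(wm), dim = g),
                csf = array(as.numeric(csf), dim = g))

  true_cbf <- probs$gm * spec$cbf[["gm"]] + probs$wm * spec$cbf[["wm"]] +
    probs$csf * spec$cbf[["csf"]]
  m0 <- probs$gm * spec$m0_pd[["gm"]] + probs$wm * spec$m0_pd[["wm"]] +
    probs$csf * spec$m0_pd[["csf"]]

  for (l in spec$lesions) {
    les <- in_sphere(l$center, l$radius) & (gm | wm | csf)
    true_cbf[les] <- l$cbf
  }
  true_cbf <- true_cbf * spec$subject_scale
  true_cbf[cavity] <- 0
  m0[cavity] <- 0

  structure(list(true_cbf = true_cbf, m0 = m0, tissue_probs = probs,
                 head_mask = head & !cavity, cavity_mask = cavity,
                 spec = spec, seed = as.integer(seed)),
            class = "asl_phantom")
}

#' @export
print.asl_phantom <- function(x, ...) {
  g <- x$spec$grid
  cat(sprintf("ASL head phantom %dx%dx%d (voxel %.4gx%.4gx%.4g mm)\n",
              g[1], g[2], g[3], x$spec$voxel_size[1], x$spec$voxel_size[2],
              x$spec$voxel_size[3]))
  cat(sprintf("  head %d voxels: GM %d, WM %d, CSF %d; cavity %d\n",
              sum(x$head_mask), sum(x$tissue_probs$gm > 0),
              sum(x$tissue_probs$wm > 0), sum(x$tissue_probs$csf > 0),
              sum(x$cavity_mask)))
  if (length(x$spec$lesions))
    cat(sprintf("  %d lesion(s), max true CBF %.1f ml/100 g/min\n",
                length(x$spec$lesions), max(x$true_cbf)))
  invisible(x)
}
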