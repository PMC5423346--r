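test_that("cavity shell matches the brute-force distance band", {
  ph <- generate_phantom(small_spec(cavity = list(center = c(30, 25, 0),
                                                  radius = 12)), seed = 1)
  vs <- c(8, 8, 8)
  shell <- cavity_shell(ph$cavity_mask, shell_mm = 10, voxel_size = vs)
  # oracle: voxels within 10 mm (center-to-center) of any cavity voxel
  d <- brute_min_dist(ph$cavity_mask, vs)
  want <- d <= 10 & !ph$cavity_mask
  expect_identical(shell, want)
  expect_gt(sum(shell), 0)
  # anisotropic voxels: the mm radius must respect each axis spacing
  vs2 <- c(4, 8, 16)
  shell2 <- cavity_shell(ph$cavity_mask, shell_mm = 10, voxel_size = vs2)
  d2 <- brute_min_dist(ph$cavity_mask, vs2)
  expect_identical(shell2, d2 <= 10 & !ph$cavity_mask)

  # the shell never contains cavity voxels
  expect_false(any(shell & ph$cavity_mask))
  # head-mask restriction is honored
  shell_h <- cavity_shell(ph$cavity_mask, 10, vs, head_mask = ph$head_mask)
  expect_true(all(ph$head_mask[shell_h]))
  # sub-voxel shell thickness collapses to the empty set
  expect_equal(sum(cavity_shell(ph$cavity_mask, 1e-6, vs)), 0)
  expect_error(cavity_shell(array(FALSE, dim(ph$cavity_mask)), 10, vs),
               "empty cavity")
  expect_error(cavity_shell(ph$cavity_mask, 0, vs), "> 0")
})

test_that("26-connected clustering governs the residual rating", {
  g <- c(12L, 12L, 6L)
  p <- quant_params()
  vals <- array(50, g)
  shell <- array(FALSE, g); shell[4:9, 4:9, 2:5] <- TRUE
  ref <- array(FALSE, g); ref[1:3, , ] <- TRUE
  mk_map <- function(v) quantify_map(forward_delta_m(v, 1000, p),
                                     array(1000, g), p)

  # ref is constant 50 -> sd 0 -> threshold 50: any higher voxel is supra.
  # a 5-voxel diagonal chain touches only at corners: one 26-cluster
  diag_map <- vals
  for (i in 0:4) diag_map[4 + i, 4 + i, 2 + i %/% 2] <- 150
  call <- rate_residual(mk_map(diag_map), shell, ref, z = 2, min_cluster = 5)
  expect_equal(call$rating, 1L)
  expect_equal(call$largest_cluster_voxels, 5L)
  expect_equal(call$cluster_peak_cbf, 150, tolerance = 1e-9)

  # four isolated voxels never reach min_cluster = 5
  iso <- vals
  iso[4, 4, 2] <- iso[4, 8, 4] <- iso[8, 4, 4] <- iso[8, 8, 2] <- 150
  call2 <- rate_residual(mk_map(iso), shell, ref, z = 2, min_cluster = 5)
  expect_equal(call2$rating, 0L)
  expect_equal(call2$largest_cluster_voxels, 1L)

  # hyperperfusion outside the search shell is invisible to the rating
  outside <- vals
  outside[10:12, 10:12, 1] <- 150
  call3 <- rate_residual(mk_map(outside), shell, ref)
  expect_equal(call3$rating, 0L)
  expect_equal(call3$largest_cluster_voxels, 0L)

  expect_error(rate_residual(mk_map(vals), shell, array(FALSE, g)),
               "reference")
})

test_that("the rating threshold tracks the reference distribution", {
  g <- c(12L, 12L, 6L)
  p <- quant_params()
  shell <- array(FALSE, g); shell[5:8, 5:8, 3:4] <- TRUE
  ref <- array(FALSE, g); ref[1:3, , ] <- TRUE
  set.seed(81)
  vals <- array(50 + rnorm(prod(g), 0, 10), g)
  cm <- quantify_map(forward_delta_m(vals, 1000, p), array(1000, g), p)
  call <- rate_residual(cm, shell, ref, z = 2)
  rv <- vals[ref & !shell]
  expect_equal(call$threshold_used, mean(rv) + 2 * stats::sd(rv),
               tolerance = 1e-9)
  expect_equal(call$n_shell_voxels, sum(shell))
})

test_that("raising lesion contrast never flips a detection off", {
  g <- c(14L, 14L, 6L)
  p <- quant_params()
  shell <- array(FALSE, g); shell[5:10, 5:10, 3:5] <- TRUE
  ref <- array(FALSE, g); ref[1:3, , ] <- TRUE
  les <- array(FALSE, g); les[6:8, 6:8, 3:4] <- TRUE
  set.seed(91)
  noise <- array(rnorm(prod(g), 0, 15), g) # one fixed realization
  prev <- 0L
  for (contrast in c(0, 20, 40, 60, 90, 130, 180)) {
    vals <- array(50, g) + noise
    vals[les] <- vals[les] + contrast
    cm <- quantify_map(forward_delta_m(vals, 1000, p), array(1000, g), p)
    r <- rate_residual(cm, shell, ref)$rating
    expect_gte(r, prev) # monotone: once detected, stays detected
    prev <- r
  }
  expect_equal(prev, 1L)
})

test_that("detection power grows with the number of averages", {
  prof20 <- small_profile(n_pairs = 20L, noise_sd = 8, name = "n20")
  prof40 <- small_profile(n_pairs = 40L, noise_sd = 8, name = "n40")
  spec <- small_spec(lesions = list(list(center = c(38, 25, 0), radius = 11,
                                         cbf = 110)),
                     cavity = list(center = c(24, 25, 0), radius = 12))
  p <- small_params()
  rate_once <- function(prof, seed) {
    ph <- generate_phantom(spec, seed = seed)
    cm <- quantify_series(simulate_acquisition(ph, prof, p, seed = seed))
    shell <- cavity_shell(ph$cavity_mask, 10, prof$voxel_size,
                          head_mask = ph$head_mask)
    ref <- contralateral_reference(gm_mask_from_phantom(ph), shell)
    rate_residual(cm, shell, ref)$rating
  }
  seeds <- 1:100
  p20 <- mean(vapply(seeds, rate_once, numeric(1), prof = prof20))
  p40 <- mean(vapply(seeds, rate_once, numeric(1), prof = prof40))
  expect_gte(p40, p20)
  expect_gt(p40, 0) # the 40-average arm does detect at this contrast
})

test_that("rating-table bookkeeping reproduces the packaged patient counts", {
  tab <- read_rating_table()
  expect_s3_class(tab, "rating_table")
  expect_equal(nrow(tab), 8)
  s <- table2_summary(tab)
  expect_equal(s$intraop_residual, 5)
  expect_equal(s$postop_residual, 4)
  expect_equal(s$complete_at_surgery, 3)
  # brute-force column sums as oracle
  expect_equal(s$intraop_residual, sum(tab$asl_intraop))
  expect_equal(s$postop_residual, sum(tab$asl_postop))
  # the footnoted amendment is encoded both ways for patient 1
  expect_equal(tab$anat_postop_initial[tab$patient == 1], 1)
  expect_equal(tab$anat_postop[tab$patient == 1], 0)

  z <- tab; z$asl_intraop <- 0; z$asl_postop <- 0
  sz <- table2_summary(rating_table(z))
  expect_equal(sz$intraop_residual, 0)
  expect_equal(sz$complete_at_surgery, 8)

  bad <- tab; bad$asl_intraop[2] <- 2
  expect_error(rating_table(bad), "non-binary")
})
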