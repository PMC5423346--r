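test_that("noiseless acquisition quantifies back to phantom truth", {
  prof <- small_profile(noise_sd = 0)
  ph <- generate_phantom(small_spec(), seed = 3)
  p <- small_params()
  ser <- simulate_acquisition(ph, prof, p, seed = 3)
  expect_equal(dim(ser$volumes)[4], 2L * prof$n_pairs)
  expect_identical(ser$order, "control_first")

  dm <- pairwise_subtract(ser)
  expect_equal(dm$values, forward_delta_m(ph$true_cbf, ph$m0, p),
               tolerance = 1e-12)
  cm <- quantify_series(ser)
  err <- abs(cm$values[ph$head_mask] - ph$true_cbf[ph$head_mask])
  expect_lt(max(err), 1e-8)
})

test_that("acquisitions are bit-reproducible given (phantom, profile, seed)", {
  prof <- small_profile(noise_sd = 4)
  ph <- generate_phantom(small_spec(), seed = 9)
  s1 <- simulate_acquisition(ph, prof, seed = 77)
  s2 <- simulate_acquisition(ph, prof, seed = 77)
  expect_identical(s1, s2)
  s3 <- simulate_acquisition(ph, prof, seed = 78)
  expect_false(identical(s1$volumes, s3$volumes))
})

test_that("blood T1 mismatch between params and profile is refused", {
  prof <- small_profile()
  ph <- generate_phantom(small_spec(), seed = 1)
  expect_error(simulate_acquisition(ph, prof, quant_params(t1_blood = 1650),
                                    seed = 1),
               "t1_blood")
})

test_that("averaged-difference noise follows the sd * sqrt(2/n) law", {
  prof <- small_profile(n_pairs = 4L, noise_sd = 6)
  ph <- generate_phantom(small_spec(), seed = 2)
  p <- small_params()
  truth <- forward_delta_m(ph$true_cbf, ph$m0, p)
  mask <- ph$head_mask
  sq <- 0
  n_seeds <- 120
  for (s in seq_len(n_seeds)) {
    dm <- pairwise_subtract(simulate_acquisition(ph, prof, p, seed = s))
    sq <- sq + (dm$values[mask] - truth[mask])^2
  }
  emp_sd <- sqrt(mean(sq / n_seeds))
  want <- prof$noise_sd * sqrt(2 / prof$n_pairs)
  expect_lt(abs(emp_sd - want) / want, 0.10)
})

test_that("a multiplicative coil bias field cancels out of quantified CBF", {
  ph <- generate_phantom(small_spec(), seed = 4)
  p <- small_params()
  prof_b <- small_profile(noise_sd = 0, bias = 0.4)
  prof_0 <- small_profile(noise_sd = 0, bias = 0)
  cb <- quantify_series(simulate_acquisition(ph, prof_b, p, seed = 1))
  c0 <- quantify_series(simulate_acquisition(ph, prof_0, p, seed = 1))
  m <- ph$head_mask & ph$true_cbf > 0
  expect_lt(max(abs(cb$values[m] - c0$values[m]) / c0$values[m]), 1e-6)
  # but the bias visibly modulates the raw M0 signal itself
  sb <- simulate_acquisition(ph, prof_b, p, seed = 1)
  expect_gt(max(abs(sb$m0[m] / ph$m0[m] - 1)), 0.2)
})

test_that("cohorts share physiology across profiles and calibrate their CV", {
  profs <- list(a = small_profile(n_pairs = 2L, noise_sd = 0),
                b = small_profile(n_pairs = 3L, noise_sd = 0, name = "b"))
  coh <- make_cohort(4, base_spec = small_spec(), between_subject_cv = 0,
                     profiles = profs, seed = 1)
  # cv = 0: every subject carries the same true GM CBF
  expect_equal(coh$truth, rep(50, 4))
  expect_equal(dim(coh$table), c(4L, 2L))
  # noiseless: measured means equal subject truth on both scanners exactly
  expect_equal(unname(coh$table[, "a"]), coh$truth, tolerance = 1e-10)
  expect_equal(unname(coh$table[, "b"]), coh$truth, tolerance = 1e-10)

  # lognormal subject scale: sample CV of truth lands near the target
  prof1 <- list(a = small_profile(n_pairs = 1L, noise_sd = 0))
  cvs <- vapply(1:20, function(s) {
    coh <- make_cohort(10, base_spec = small_spec(),
                       between_subject_cv = 0.18, profiles = prof1, seed = s)
    stats::sd(coh$truth) / mean(coh$truth)
  }, numeric(1))
  expect_gte(mean(cvs >= 0.09 & cvs <= 0.27), 0.9)

  # subject scale identical within subject across profiles
  coh2 <- make_cohort(3, base_spec = small_spec(), between_subject_cv = 0.3,
                      profiles = profs, seed = 5)
  expect_equal(unname(coh2$table[, "a"]), unname(coh2$table[, "b"]),
               tolerance = 1e-10)
  expect_equal(unname(coh2$table[, "a"]), coh2$truth, tolerance = 1e-10)
})

test_that("cohorts can retain full series for downstream processing", {
  profs <- list(a = small_profile(n_pairs = 2L, noise_sd = 1))
  coh <- make_cohort(2, base_spec = small_spec(), between_subject_cv = 0.1,
                     profiles = profs, seed = 2, keep_series = TRUE)
  expect_length(coh$series, 2)
  expect_s3_class(coh$series[[1]]$a, "asl_series")
  expect_equal(dim(coh$series[[2]]$a$volumes)[4], 4L)
})
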