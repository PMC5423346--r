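small_vol_cfg <- function(noise = c(0, 0), seed = 1L, n = 4) {
  run_config("volunteer",
             profiles = list(a = small_profile(2L, noise_sd = noise[1]),
                             b = small_profile(3L, noise_sd = noise[2],
                                               name = "b")),
             phantom = small_spec(), n_subjects = n,
             between_subject_cv = 0.18, seed = seed)
}

test_that("noiseless volunteer study gives perfect cross-scanner agreement", {
  res <- run_volunteer_study(small_vol_cfg(seed = 2))
  expect_equal(nrow(res$table), 4)
  expect_equal(res$agreement$pairwise$r, 1, tolerance = 1e-9)
  # per-profile means identical when only physiology varies
  expect_equal(unname(res$agreement$profile_mean["a"]),
               unname(res$agreement$profile_mean["b"]), tolerance = 1e-9)
  expect_equal(unname(res$table[, "a"]), res$truth, tolerance = 1e-9)
})

test_that("volunteer study artifacts are reproducible from config + seed", {
  d1 <- file.path(tempdir(), "vol1"); d2 <- file.path(tempdir(), "vol2")
  res1 <- run_volunteer_study(small_vol_cfg(noise = c(2, 2), seed = 9), d1)
  res2 <- run_volunteer_study(small_vol_cfg(noise = c(2, 2), seed = 9), d2)
  expect_identical(res1$table, res2$table)
  for (f in c("run_config.json", "cohort_table.csv", "agreement.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the serialized config is complete enough to re-drive the run
  cfgj <- jsonlite::read_json(file.path(d1, "run_config.json"),
                              simplifyVector = TRUE)
  expect_equal(cfgj$seed, 9)
  expect_equal(cfgj$n_subjects, 4)
  expect_equal(cfgj$profiles$a$noise_sd, 2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("config validation precedes any compute", {
  expect_error(run_config("volunteer", profiles = asl_profiles()["3t"]),
               ">= 2 profiles")
  expect_error(run_config("volunteer", rating = list(shell_mm = 0, z = 2,
                                                     min_cluster = 5)),
               "shell_mm")
  expect_error(run_volunteer_study(run_config("patient",
                                              patients = list(list()))),
               "experiment 'patient'")
  cfgp <- run_config("patient", patients = NULL)
  expect_error(run_patient_study(cfgp), "scenarios required")
})

test_that("patient study counts residuals per scenario construction", {
  lesion <- list(center = c(28, 22, 0), radius = 13, cbf = 150)
  patients <- list(
    list(lesion = lesion, resected_fraction = 0.4),
    list(lesion = lesion, resected_fraction = 1),
    list(lesion = lesion, resected_fraction = 0.5))
  # 8 mm test voxels: a residual rind spans only a handful of voxels, so
  # the cluster minimum is scaled down with the resolution (it is config)
  cfg <- run_config("patient",
                    profiles = list(`1p5t_or` = small_profile(4L,
                                                              noise_sd = 2,
                                                              name = "1p5t_or"),
                                    post = small_profile(3L, noise_sd = 2,
                                                         name = "post")),
                    phantom = small_spec(), patients = patients,
                    rating = list(shell_mm = 10, z = 2, min_cluster = 3),
                    seed = 11)
  out <- file.path(tempdir(), "pat")
  res <- run_patient_study(cfg, out)
  expect_equal(nrow(res$calls), 3)
  expect_equal(res$calls$truth_residual, c(1L, 0L, 1L))
  # residual scenarios are detected, the complete resection is not
  expect_equal(res$calls$asl_intraop, c(1L, 0L, 1L))
  expect_equal(res$calls$asl_postop, c(1L, 0L, 1L))
  expect_true(all(res$calls$asl_preop_visible == 1L))
  expect_equal(res$summary$intraop_residual, 2)
  expect_equal(res$summary$postop_residual, 2)
  expect_equal(res$summary$complete_at_surgery, 1)
  expect_true(file.exists(file.path(out, "residual_calls.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  unlink(out, recursive = TRUE)
})
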