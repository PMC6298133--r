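test_that("MSE scoring follows its definition", {
  t <- seq(0, 2160, by = 30)
  base <- concentration_profile(t, 50 + 10 * sin(t / 300))
  expect_equal(mse_score(base, base), 0)
  shifted <- concentration_profile(t, base$conc_pmol_per_L + 3)
  expect_equal(mse_score(shifted, base), 9)             # delta^2
  # +1, -1 at the first two of the seven scoring times -> MSE = 2/7
  tp <- c(6, 8, 12, 16, 20, 24, 28)
  bump <- base$conc_pmol_per_L
  bump[match(6 * 60, t)] <- bump[match(6 * 60, t)] + 1
  bump[match(8 * 60, t)] <- bump[match(8 * 60, t)] - 1
  expect_equal(mse_score(concentration_profile(t, bump), base, tp), 2 / 7)
  short <- concentration_profile(seq(0, 600, 30), rep(1, 21))
  expect_error(mse_score(short, base, tp), "outside")
})

test_that("MSE is invariant to the profile grid resolution", {
  p <- default_parameters()
  fine <- simulate_single_dose(std_event(), std_subject(), p,
                               t_end_min = 1800)
  coarse <- concentration_profile(seq(0, 1800, by = 120),
                                  profile_conc_at(fine,
                                                  seq(0, 1800, by = 120)))
  obs <- fix_truth()
  tp <- c(6, 12, 24)
  expect_equal(mse_score(fine, obs, tp), mse_score(coarse, obs, tp),
               tolerance = 1e-10)
})

test_that("noiseless single-parameter fits recover the truth within 1%", {
  obs <- fix_truth()
  for (free in c("k_pre", "k_HD")) {
    fit <- fit_profile(fit_spec(free, n_starts = 2, seed = 11), obs,
                       default_parameters(), std_event(), std_subject())
    truth <- default_parameters()[[free]]
    expect_lt(abs(fit$estimates[[free]] - truth) / truth, 0.01)
  }
})

test_that("noiseless joint fit recovers all three parameters within 5%", {
  obs <- fix_truth()
  spec <- fit_spec(c("k_pre", "k_HD", "k_DM"), n_starts = 3, seed = 5)
  fit <- fit_profile(spec, obs, default_parameters(), std_event(),
                     std_subject())
  expect_lt(fit$mse, 1e-4)   # the truth is attainable
  truth <- unlist(unclass(default_parameters())[spec$free])
  expect_true(all(abs(unlist(fit$estimates) - truth) / truth < 0.05))
  expect_equal(nrow(fit$trace), 3)
  expect_equal(fit$mse, min(fit$trace$mse))
})

test_that("fits are deterministic given the seed", {
  obs <- fix_truth()
  run <- function() fit_profile(fit_spec("k_pre", n_starts = 3, seed = 99),
                                obs, default_parameters(), std_event(),
                                std_subject())
  f1 <- run(); f2 <- run()
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$trace$mse, f2$trace$mse)
})

test_that("fits under multiplicative noise recover k_pre within 10%", {
  for (seed in 1:5) {
    obs <- generate_clamp_profile(
      synthetic_study_spec("Gla-100", 0.4, cv = 0.1, seed = seed,
                           times_h = seq(2, 30, by = 2)))
    fit <- fit_profile(fit_spec("k_pre", n_starts = 2, seed = seed,
                                timepoints_h = c(6, 8, 12, 16, 20, 24, 28)),
                       obs, default_parameters(), std_event(),
                       std_subject())
    expect_lt(abs(fit$estimates[["k_pre"]] - 0.28) / 0.28, 0.10)
  }
})

test_that("validation scores one profile per condition and orders fits", {
  p <- default_parameters()
  profs <- lapply(c(0.4, 0.6, 0.9), function(d)
    generate_clamp_profile(synthetic_study_spec("Gla-300", d, cv = 0), p))
  tab <- validate_profiles(p, profs)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$mse < 1e-8))          # self-generated data
  worse <- validate_profiles(default_parameters(k_pre = 0.42), profs)
  expect_true(all(worse$mse > tab$mse))
  bad <- concentration_profile(c(0, 60), c(0, 1))
  expect_error(validate_profiles(p, list(bad)), "metadata")
})

test_that("fit results serialize to JSON with the full trace", {
  obs <- fix_truth()
  fit <- fit_profile(fit_spec("k_pre", n_starts = 2, seed = 1), obs,
                     default_parameters(), std_event(), std_subject())
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$estimates$k_pre, fit$estimates[["k_pre"]])
  expect_equal(length(x$trace$mse), 2)
})

test_that("fit specs validate their inputs", {
  expect_error(fit_spec("alpha"), "not fittable")
  expect_error(fit_spec("k_pre", lower = c(k_pre = 2), upper = c(k_pre = 1)),
               "ordered")
})
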