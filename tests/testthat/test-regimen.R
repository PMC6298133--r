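test_that("windowed AUC handles rectangle, triangle and additivity", {
  t <- seq(0, 2880, by = 10)
  flat <- concentration_profile(t, rep(50, length(t)))
  expect_equal(auc_window(flat, 0, 1440), 24 * 50)
  zero <- concentration_profile(t, rep(0, length(t)))
  expect_equal(auc_window(zero, 0, 1440), 0)
  ramp <- concentration_profile(t, 50 * pmin(t / 1440, 1))
  expect_equal(auc_window(ramp, 0, 1440), 12 * 50)   # triangle
  # additive over adjacent windows, interpolated endpoints
  expect_equal(auc_window(ramp, 0, 700) + auc_window(ramp, 700, 1440),
               auc_window(ramp, 0, 1440))
  expect_error(auc_window(flat, -10, 100), "outside")
  expect_error(trailing_auc(flat, 1000), "before the profile")
})

test_that("time_to_steady_state follows the 5%-of-final-day rule", {
  expect_equal(time_to_steady_state(rep(7, 6)), 1L)
  # geometric approach, per-day residual halving: day 5 is the first within
  # 5% of the day-10 reference (residual 2^-5 ~ 0.031)
  days <- 1:10
  series <- 100 * (1 - 2^-days)
  ref <- series[10]
  brute <- min(which(abs(series - ref) / ref <= 0.05))
  expect_equal(brute, 5L)
  expect_equal(time_to_steady_state(series), 5L)
  expect_true(is.na(time_to_steady_state(c(0, 0))))
})

test_that("a single-event schedule reproduces the single-dose profile", {
  ev <- std_event()
  sch <- glargine_schedule(list(ev), std_subject(), horizon_min = 1440)
  reg <- simulate_regimen(sch)
  single <- simulate_single_dose(ev, std_subject(), t_end_min = 1440)
  expect_equal(reg$conc_pmol_per_L, single$conc_pmol_per_L,
               tolerance = 1e-10)
})

test_that("schedule validation rejects disorder and late events", {
  e1 <- std_event(); e2 <- dose_event(1440, "Gla-100", dose_pmol = 1000)
  expect_error(glargine_schedule(list(e2, e1)), "non-decreasing")
  expect_error(glargine_schedule(list(e1, e2), horizon_min = 1440),
               "horizon")
})

test_that("superposition and full mode agree", {
  s <- std_subject()
  run <- function(mode, alpha) {
    p <- default_parameters(alpha = alpha)
    simulate_regimen(uniform_schedule(4, "Gla-100", 0.4, s, mode = mode),
                     p, dt_min = 5)
  }
  a0 <- run("superposition", 0); b0 <- run("full", 0)
  expect_lt(max(abs(a0$conc_pmol_per_L - b0$conc_pmol_per_L)) /
              max(a0$conc_pmol_per_L), 1e-3)    # linear: identical in theory
  al <- default_parameters()$alpha
  a1 <- run("superposition", al); b1 <- run("full", al)
  expect_lt(max(abs(a1$conc_pmol_per_L - b1$conc_pmol_per_L)) /
              max(a1$conc_pmol_per_L), 0.01)    # weak clearance saturation
})

test_that("uniform dosing reaches a flat trailing-AUC plateau", {
  for (prod in c("Gla-100", "Gla-300")) {
    auc <- daily_trailing_auc(fix_regimen(prod), 6)$auc_pmolh_per_L
    expect_lt(diff(range(auc[4:6])) / auc[6], 0.005)
  }
})

test_that("flexible scenarios emit the published injection intervals", {
  times_h <- function(sch)
    vapply(sch$events, `[[`, numeric(1), "time_min") / 60
  # scenario 1: one dose 3 h early -> intervals 21, 27 h
  s1 <- build_flexible_scenario(flex_preset("flex1"))
  expect_equal(diff(times_h(s1))[6:7], c(21, 27))
  # scenario 2: intervals 27, 18, 27 h
  s2 <- build_flexible_scenario(flex_preset("flex2"))
  expect_equal(diff(times_h(s2))[6:8], c(27, 18, 27))
  # scenario 3: intervals 21, 30, 21 h then back to 24
  s3 <- build_flexible_scenario(flex_preset("flex3"))
  expect_equal(diff(times_h(s3))[6:9], c(21, 30, 21, 24))
  # no deviations -> uniform 24 h raster
  s0 <- build_flexible_scenario(numeric())
  expect_true(all(diff(times_h(s0)) == 24))
  expect_error(build_flexible_scenario(c(-25)), "interval")
  expect_error(flex_preset("flex9"), "unknown preset")
})

test_that("Gla-300 trailing exposure fluctuates less in every scenario", {
  s <- std_subject(); p <- default_parameters()
  for (sc in c("flex1", "flex2", "flex3")) {
    ratio <- vapply(c("Gla-100", "Gla-300"), function(prod) {
      dose <- if (prod == "Gla-100") 0.4 else 0.432
      sch <- build_flexible_scenario(flex_preset(sc), product = prod,
                                     dose_U_per_kg = dose, subject = s)
      prof <- simulate_regimen(sch, p)
      w <- attr(sch, "perturbed_window_min")
      tt <- seq(w[1], min(w[2] + 1440, sch$horizon_min), by = 60)
      a <- trailing_auc(prof, tt)$auc_pmolh_per_L
      max(a) / min(a)
    }, numeric(1))
    expect_lt(ratio[["Gla-300"]], ratio[["Gla-100"]])
  }
})

test_that("switch schedules mark the switch and shift exposure as expected", {
  s <- std_subject(); p <- default_parameters()
  expect_warning(build_switch_scenario("Gla-100", "Gla-100", s),
                 "same product")
  sch <- build_switch_scenario("Gla-100", "Gla-300", s)
  expect_equal(attr(sch, "switch_time_min"), 6 * 1440)
  prof <- simulate_regimen(sch, p)
  auc <- daily_trailing_auc(prof, 12)$auc_pmolh_per_L
  expect_lt(auc[7], auc[6])   # 100 -> 300: exposure drops after the switch
  sch2 <- build_switch_scenario("Gla-300", "Gla-100", s)
  prof2 <- simulate_regimen(sch2, p)
  auc2 <- daily_trailing_auc(prof2, 12)$auc_pmolh_per_L
  expect_gt(auc2[7], auc2[6]) # 300 -> 100: stacking raises exposure
})
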