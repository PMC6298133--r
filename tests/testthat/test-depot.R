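test_that("surface area is the f_vol-scaled sphere surface", {
  # unit sphere: V = 4*pi/3 mm^3 has surface 4*pi mm^2
  P_unit <- (4 * pi / 3) * 600          # pmol giving that volume at Gla-100
  expect_equal(surface_area(P_unit, "Gla-100", f_vol = 1), 4 * pi)
  # 32 U Gla-100 depot (V = 320 mm^3), independent arithmetic
  expect_equal(surface_area(192000, "Gla-100", f_vol = 3.6),
               3.6 * (36 * pi)^(1 / 3) * 320^(2 / 3))
  expect_equal(surface_area(192000, "Gla-100", f_vol = 3.6), 814.49,
               tolerance = 1e-4)
  expect_equal(surface_area(0, "Gla-100"), 0)
  expect_error(surface_area(-1, "Gla-100"), ">= 0")
})

test_that("equal-mass area and flux ratio Gla-300:Gla-100 is (1/3)^(2/3)", {
  masses <- c(1e3, 1e4, 192000, 4e5)
  for (P in masses) {
    expect_equal(surface_area(P, "Gla-300") / surface_area(P, "Gla-100"),
                 (1 / 3)^(2 / 3))
    expect_equal(release_flux(P, "Gla-300") / release_flux(P, "Gla-100"),
                 (1 / 3)^(2 / 3))
  }
})

test_that("release flux mixes k_pre and k_sol by pw and is concave in P", {
  p0 <- default_parameters(pw = 0)
  expect_equal(release_flux(0, "Gla-100", p0), 0)
  expect_equal(release_flux(192000, "Gla-100", p0),
               0.28 * surface_area(192000, "Gla-100"))  # ~228 pmol/min
  expect_equal(release_flux(192000, "Gla-100", p0) /
                 surface_area(192000, "Gla-100"), 0.28)
  p1 <- default_parameters(pw = 1)
  expect_equal(release_flux(192000, "Gla-100", p1) /
                 surface_area(192000, "Gla-100"), 0.34)
  # monotone increasing, concave (P^(2/3))
  P <- seq(0, 2e5, length.out = 50)
  J <- release_flux(P, "Gla-100", default_parameters())
  expect_true(all(diff(J) > 0))
  expect_true(all(diff(diff(J)) < 0))
})

test_that("depot derivatives conserve mass against the outflows", {
  p <- default_parameters()
  d0 <- depot_rhs(0, 0, "Gla-100", p)
  expect_equal(unlist(d0), c(dS = 0, dP = 0, J_release = 0, J_bypass = 0))
  dose <- 192000
  d1 <- depot_rhs(dose, 0, "Gla-100", p)
  expect_equal(d1$dP, p$k_FP * (1 - p$pw) * dose)  # no release at P = 0
  expect_equal(d1$J_bypass, p$k_FP * p$pw * dose)
  for (S in c(0, 1e4)) for (P in c(0, 5e4, 192000)) {
    d <- depot_rhs(S, P, "Gla-300", p)
    expect_equal(d$dS + d$dP + d$J_release + d$J_bypass, 0)
  }
})

test_that("closed-form depletion time matches its formula and scaling", {
  p <- default_parameters()
  a100 <- p$f_vol * (36 * pi)^(1 / 3) / 600^(2 / 3)
  expect_equal(depletion_time_closed_form(192000, "Gla-100", p),
               3 * 192000^(1 / 3) / (p$k_pre * a100))
  expect_equal(depletion_time_closed_form(192000, "Gla-100", p) / 60,
               42.09, tolerance = 1e-3)   # ~ 42 h
  expect_equal(depletion_time_closed_form(192000, "Gla-300", p) / 60,
               87.56, tolerance = 1e-3)   # ~ 87 h
  # cube-root scaling: 8x the mass doubles the depletion time
  expect_equal(depletion_time_closed_form(8 * 192000, "Gla-100", p) /
                 depletion_time_closed_form(192000, "Gla-100", p), 2)
  expect_error(depletion_time_closed_form(0, "Gla-100"), "> 0")
})

test_that("numeric depot depletion matches the closed form within 0.5%", {
  # pure-precipitate conditions: pw = 0, instantaneous precipitation
  p <- default_parameters(pw = 0, k_FP = 1e3)
  for (prod in c("Gla-100", "Gla-300")) {
    t_full <- depletion_time_closed_form(192000, prod, p)
    # closed form for the time at which P falls to the threshold P_thr:
    # P^(1/3) decreases linearly, so t = t_full * (1 - (P_thr/P0)^(1/3))
    P_thr <- 1e-4 * 192000
    t_pred <- t_full * (1 - (P_thr / 192000)^(1 / 3))
    prof <- simulate_single_dose(std_event(prod), std_subject(), p,
                                 t_end_min = 1.05 * t_full,
                                 output_grid_min = seq(0, 1.05 * t_full,
                                                       length.out = 4000),
                                 keep_states = TRUE)
    P <- prof$states[, "P"]
    past_peak <- seq_along(P) > which.max(P)
    t_num <- prof$time_min[which(past_peak & P < P_thr)[1]]
    expect_equal(t_num, t_pred, tolerance = 5e-3)
  }
})

test_that("the fraction of the dose entering the precipitate is 1 - pw", {
  # disable release so the two-state subsystem can be read off at the end
  p <- default_parameters(k_pre = 0, k_sol = 0, pw = 0.1)
  prof <- simulate_single_dose(std_event(), std_subject(), p,
                               t_end_min = 120,
                               output_grid_min = c(0, 60, 120),
                               keep_states = TRUE)
  expect_equal(unname(prof$states[3, "P"]) / 192000, 1 - p$pw,
               tolerance = 5e-3)
})
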