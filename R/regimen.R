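# Multi-dose machinery. The canonical steady-state construction sums
# time-shifted single-dose profiles (superposition); a "full" mode integrates
# one independent depot per injection feeding a single plasma compartment,
# which differs from superposition only through the (weak) clearance
# saturation and is used to bound that nonlinearity.

#' A dosing schedule
#'
#' @param events list of [dose_event()]s, times non-decreasing.
#' @param subject a [subject_spec()].
#' @param horizon_min simulation horizon, minutes; must lie beyond the last
#'   event.
#' @param mode \code{"superposition"} (default; the canonical construction)
#'   or \code{"full"} (independent depots, shared plasma).
#' @return object of class \code{glargine_schedule}.
#' @export
glargine_schedule <- function(events, subject = subject_spec(),
                              horizon_min = NULL,
                              mode = c("superposition", "full")) {
  mode <- match.arg(mode)
  stopifnot(length(events) >= 1,
            all(vapply(events, inherits, logical(1), "glargine_dose_event")))
  times <- vapply(events, `[[`, numeric(1), "time_min")
  if (any(diff(times) < 0))
    stop("event times must be non-decreasing", call. = FALSE)
  horizon_min <- horizon_min %||% (max(times) + 2 * 1440)
  if (horizon_min <= max(times))
    stop("events at or after the horizon", call. = FALSE)
  structure(list(events = events, subject = subject,
                 horizon_min = horizon_min, mode = mode),
            class = "glargine_schedule")
}

#' @export
print.glargine_schedule <- function(x, ...) {
  times <- vapply(x$events, `[[`, numeric(1), "time_min")
  prods <- vapply(x$events, function(e) e$product$name, character(1))
  cat(sprintf("<glargine_schedule> %d doses over %.1f days (%s mode)\n",
              length(x$events), x$horizon_min / 1440, x$mode))
  cat("  products:", paste(unique(prods), collapse = ", "),
      "| dose times (h):", paste(round(times / 60, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Build a uniform once-daily schedule
#'
#' @param n_days number of once-daily doses.
#' @param product formulation name or object.
#' @param dose_U_per_kg daily dose, U/kg.
#' @param subject a [subject_spec()].
#' @param interval_h injection interval, hours (default 24).
#' @param extra_horizon_h horizon margin after the last dose, hours.
#' @inheritParams glargine_schedule
#' @return a [glargine_schedule()].
#' @export
uniform_schedule <- function(n_days = 6, product = "Gla-100",
                             dose_U_per_kg = 0.4,
                             subject = subject_spec(),
                             interval_h = 24, extra_horizon_h = 24,
                             mode = "superposition") {
  ev <- lapply(seq_len(n_days) - 1, function(d)
    dose_event(d * interval_h * 60, product,
               dose_U_per_kg = dose_U_per_kg,
               body_mass_kg = subject$body_mass_kg))
  glargine_schedule(ev, subject,
                    horizon_min = ((n_days - 1) * interval_h +
                                     extra_horizon_h) * 60,
                    mode = mode)
}

#' Simulate a dosing regimen
#'
#' Superposition mode simulates each distinct (product, dose) combination
#' once and sums the time-shifted copies; full mode integrates every
#' injection's depot explicitly against one shared, saturably cleared plasma
#' compartment. With linear clearance (\code{alpha = 0}) the two are
#' equivalent up to solver error.
#'
#' @param schedule a [glargine_schedule()].
#' @param params model parameters.
#' @param dt_min output grid spacing, minutes (default 1; AUCs use this grid).
#' @return a [concentration_profile()] over \code{[0, horizon]}.
#' @export
simulate_regimen <- function(schedule, params = default_parameters(),
                             dt_min = 1) {
  stopifnot(inherits(schedule, "glargine_schedule"))
  grid <- seq(0, schedule$horizon_min, by = dt_min)
  meta <- list(mode = schedule$mode,
               body_mass_kg = schedule$subject$body_mass_kg,
               dose_times_min = vapply(schedule$events, `[[`, numeric(1),
                                       "time_min"))
  if (schedule$mode == "superposition") {
    conc <- superpose_profiles(schedule, params, grid)
  } else {
    conc <- simulate_full_regimen(schedule, params, grid)
  }
  concentration_profile(grid, conc, metadata = meta)
}

superpose_profiles <- function(schedule, params, grid) {
  keys <- vapply(schedule$events, function(e)
    paste(e$product$name, format(e$dose_pmol, digits = 15)), character(1))
  cache <- new.env(parent = emptyenv())
  conc <- numeric(length(grid))
  horizon <- schedule$horizon_min
  for (i in seq_along(schedule$events)) {
    e <- schedule$events[[i]]
    if (e$dose_pmol == 0) next
    if (is.null(cache[[keys[i]]])) {
      cache[[keys[i]]] <- simulate_single_dose(
        e, schedule$subject, params, t_end_min = horizon)
    }
    prof <- cache[[keys[i]]]
    idx <- grid >= e$time_min
    conc[idx] <- conc[idx] +
      stats::approx(prof$time_min, prof$conc_pmol_per_L,
                    xout = grid[idx] - e$time_min, rule = 2)$y
  }
  conc
}

# Full mode: piecewise integration, appending a fresh depot block
# (S, P, H, D, M with its own volume-dependent loss rates) at each event.
simulate_full_regimen <- function(schedule, params, grid) {
  ev <- schedule$events
  ev_times <- vapply(ev, `[[`, numeric(1), "time_min")
  Vp <- schedule$subject$plasma_volume_L
  p <- params
  k_eff <- (1 - p$pw) * p$k_pre + p$pw * p$k_sol

  blocks <- list()   # per-block constants
  y <- c(A = 0, L_deg = 0, L_cl = 0)  # plasma + sinks first, blocks appended

  block_consts <- function(e) {
    lam <- derived_loss_rates(p, e$injection_volume_mm3)
    list(a_rel = k_eff * p$f_vol * SPHERE_COEF /
           e$product$conc_pmol_per_mm3^(2 / 3),
         lambda_H = lam$lambda_H, lambda_D = lam$lambda_D,
         lambda_M = lam$lambda_M)
  }

  rhs <- function(t, y, parms) {
    k <- (length(y) - 3) / 5
    A <- y[1]
    CL <- p$k_Clearance / (1 + p$alpha * A / Vp)
    dy <- numeric(length(y))
    dA <- -CL * A; dLd <- 0; dLc <- CL * A
    for (j in seq_len(k)) {
      o <- 3 + 5 * (j - 1)
      b <- parms[[j]]
      S <- y[o + 1]; P <- max(y[o + 2], 0)
      H <- y[o + 3]; D <- y[o + 4]; M <- y[o + 5]
      J_rel <- b$a_rel * P^(2 / 3)
      dy[o + 1] <- -p$k_FP * S
      dy[o + 2] <- p$k_FP * (1 - p$pw) * S - J_rel
      dy[o + 3] <- J_rel + p$k_FP * p$pw * S -
        (p$k_HD + b$lambda_H) * H + p$k_DH * D
      dy[o + 4] <- p$k_HD * H - (p$k_DH + p$k_DM + b$lambda_D) * D
      dy[o + 5] <- p$k_DM * D - (p$k_abs + b$lambda_M) * M
      dA <- dA + p$k_abs * M
      dLd <- dLd + b$lambda_H * H + b$lambda_D * D + b$lambda_M * M
    }
    dy[1] <- dA; dy[2] <- dLd; dy[3] <- dLc
    list(dy)
  }

  conc <- numeric(length(grid))
  # unique event times define the integration segments
  seg_bounds <- unique(c(ev_times, schedule$horizon_min))
  t_cur <- seg_bounds[1]
  conc[grid <= t_cur] <- 0
  for (s in seq_along(seg_bounds)) {
    t_seg <- seg_bounds[s]
    if (s > 1) {
      # integrate previous segment [t_cur, t_seg]
      seg_grid <- sort(unique(c(t_cur, grid[grid > t_cur & grid < t_seg],
                                t_seg)))
      out <- deSolve::lsoda(y, seg_grid, rhs, parms = blocks,
                            rtol = p$rtol, atol = p$atol)
      if (attr(out, "istate")[1] < 0)
        stop("ODE solver failed in full-regimen mode", call. = FALSE)
      keep <- out[, 1] %in% grid
      conc[match(out[keep, 1], grid)] <- pmax(out[keep, "A"], 0) / Vp
      y <- out[nrow(out), -1]
      t_cur <- t_seg
    }
    # add the doses injected at t_seg
    for (i in which(ev_times == t_seg)) {
      if (ev[[i]]$dose_pmol == 0) next
      blocks[[length(blocks) + 1]] <- block_consts(ev[[i]])
      y <- c(y, ev[[i]]$dose_pmol, 0, 0, 0, 0)
    }
  }
  conc
}

#' Windowed AUC of a concentration profile
#'
#' Trapezoidal rule on the profile's own grid, with linear interpolation at
#' the window endpoints. Additive over adjacent windows.
#'
#' @param profile a [concentration_profile()].
#' @param t_start_min,t_end_min window bounds, minutes, within the profile
#'   support.
#' @return AUC in pmol h / L.
#' @export
auc_window <- function(profile, t_start_min, t_end_min) {
  stopifnot(inherits(profile, "glargine_profile"))
  if (t_end_min < t_start_min) stop("empty window", call. = FALSE)
  rng <- range(profile$time_min)
  if (t_start_min < rng[1] - 1e-9 || t_end_min > rng[2] + 1e-9)
    stop("AUC window outside the profile grid", call. = FALSE)
  t <- profile$time_min; c_ <- profile$conc_pmol_per_L
  inside <- t > t_start_min & t < t_end_min
  tt <- c(t_start_min, t[inside], t_end_min)
  cc <- c(profile_conc_at(profile, t_start_min), c_[inside],
          profile_conc_at(profile, t_end_min))
  sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2) / 60
}

#' Trailing 24-hour exposure series
#'
#' The exposure metric of the flexible-dosing and switching analyses:
#' AUC over the 24 h preceding each requested time point.
#'
#' @param profile a [concentration_profile()].
#' @param times_min evaluation times (minutes), each at least 24 h after the
#'   start of the profile grid.
#' @param window_min width of the trailing window (default 24 h).
#' @return data.frame with \code{time_min} and \code{auc_pmolh_per_L}.
#' @export
trailing_auc <- function(profile, times_min, window_min = 1440) {
  stopifnot(inherits(profile, "glargine_profile"))
  if (any(times_min - window_min < profile$time_min[1] - 1e-9))
    stop("trailing window starts before the profile", call. = FALSE)
  auc <- vapply(times_min, function(t)
    auc_window(profile, t - window_min, t), numeric(1))
  data.frame(time_min = times_min, auc_pmolh_per_L = auc)
}

#' Daily trailing AUC of a once-daily regimen
#'
#' Day \code{d} is scored by the AUC over its own 24 h,
#' \eqn{[(d-1)\cdot 24, d\cdot 24]} hours.
#'
#' @param profile regimen profile starting at the first dose.
#' @param n_days number of days to score.
#' @return data.frame with \code{day} and \code{auc_pmolh_per_L}.
#' @export
daily_trailing_auc <- function(profile, n_days) {
  trail <- trailing_auc(profile, (seq_len(n_days)) * 1440)
  data.frame(day = seq_len(n_days), auc_pmolh_per_L = trail$auc_pmolh_per_L)
}

#' First day at steady state
#'
#' Smallest day whose trailing 24-h AUC is within \code{rel_tol} of the
#' final day's value (the reference for "steady state" under a finite
#' horizon).
#'
#' @param daily_aucs numeric vector of daily trailing AUCs (day 1, 2, ...),
#'   length >= 2.
#' @param rel_tol relative tolerance (default 0.05).
#' @return integer day index, or \code{NA_integer_} if the reference is zero.
#' @export
time_to_steady_state <- function(daily_aucs, rel_tol = 0.05) {
  stopifnot(is.numeric(daily_aucs), length(daily_aucs) >= 2)
  ref <- daily_aucs[length(daily_aucs)]
  if (ref <= 0) return(NA_integer_)
  ok <- abs(daily_aucs - ref) / ref <= rel_tol
  which(ok)[1]
}

#' Flexible-dosing deviation presets
#'
#' Per-dose time shifts (hours, relative to the nominal 24-h raster) of the
#' three studied scenarios: one injection 3 h early (intervals 21, 27 h);
#' one 3 h late then 3 h early (27, 18, 27 h); one early then late
#' (21, 30, 21 h).
#'
#' @param name \code{"flex1"}, \code{"flex2"} or \code{"flex3"}.
#' @return numeric vector of shifts in hours.
#' @export
flex_preset <- function(name) {
  switch(name,
    flex1 = c(-3),
    flex2 = c(3, -3),
    flex3 = c(-3, 3),
    stop("unknown preset: '", name, "'", call. = FALSE))
}

#' Build a flexible-interval once-daily schedule
#'
#' Six lead-in doses at the base interval establish steady state; the
#' following doses are shifted by \code{deviations_h} from their nominal
#' times; trailing doses return to the nominal raster.
#'
#' @param deviations_h per-dose shifts in hours (may be empty).
#' @param base_interval_h nominal interval (default 24 h).
#' @param n_lead lead-in doses before the first deviation (default 6).
#' @param n_tail doses back on the raster afterwards (default 3).
#' @param product,dose_U_per_kg,subject dosing as in [uniform_schedule()].
#' @inheritParams glargine_schedule
#' @return a [glargine_schedule()]; the attribute \code{perturbed_window_min}
#'   spans the perturbed dosing days.
#' @export
build_flexible_scenario <- function(deviations_h = numeric(),
                                    base_interval_h = 24, n_lead = 6,
                                    n_tail = 3, product = "Gla-100",
                                    dose_U_per_kg = 0.4,
                                    subject = subject_spec(),
                                    mode = "superposition") {
  if (base_interval_h <= 0) stop("interval must be > 0", call. = FALSE)
  n_dev <- length(deviations_h)
  nominal <- (seq_len(n_lead + n_dev + n_tail) - 1) * base_interval_h
  shift <- c(rep(0, n_lead), deviations_h, rep(0, n_tail))
  times_h <- nominal + shift
  if (any(diff(times_h) <= 0))
    stop("deviations produce a non-positive interval", call. = FALSE)
  ev <- lapply(times_h * 60, dose_event, product = product,
               dose_U_per_kg = dose_U_per_kg,
               body_mass_kg = subject$body_mass_kg)
  sch <- glargine_schedule(ev, subject,
                           horizon_min = (max(times_h) + 48) * 60,
                           mode = mode)
  attr(sch, "perturbed_window_min") <-
    c(n_lead, n_lead + n_dev + 1) * base_interval_h * 60
  sch
}

#' Build a product-switch schedule
#'
#' Once-daily dosing of one product to steady state, then once-daily dosing
#' of the other. Default doses follow the exposure-harmonized pairing:
#' Gla-100 at 0.4 U/kg and Gla-300 at 0.432 U/kg.
#'
#' @param from_product,to_product formulation names or objects.
#' @param subject a [subject_spec()].
#' @param n_pre,n_post daily doses before / after the switch (default 6 / 6).
#' @param doses_U_per_kg named vector of default daily doses per product.
#' @inheritParams glargine_schedule
#' @return a [glargine_schedule()] with attribute \code{switch_time_min}.
#' @export
build_switch_scenario <- function(from_product, to_product,
                                  subject = subject_spec(),
                                  n_pre = 6, n_post = 6,
                                  doses_U_per_kg = c("Gla-100" = 0.4,
                                                     "Gla-300" = 0.432),
                                  mode = "superposition") {
  from <- glargine_formulation(from_product)
  to <- glargine_formulation(to_product)
  if (identical(from$name, to$name))
    warning("switching to the same product", call. = FALSE)
  dose_of <- function(f) {
    d <- doses_U_per_kg[[f$name]]
    if (is.null(d)) stop("no default dose for ", f$name, call. = FALSE)
    d
  }
  ev <- c(
    lapply((seq_len(n_pre) - 1) * 1440, dose_event, product = from,
           dose_U_per_kg = dose_of(from),
           body_mass_kg = subject$body_mass_kg),
    lapply((n_pre + seq_len(n_post) - 1) * 1440, dose_event, product = to,
           dose_U_per_kg = dose_of(to),
           body_mass_kg = subject$body_mass_kg))
  sch <- glargine_schedule(ev, subject,
                           horizon_min = (n_pre + n_post) * 1440,
                           mode = mode)
  attr(sch, "switch_time_min") <- n_pre * 1440
  sch
}

# Steady-state daily exposure of a once-daily regimen: day-n trailing AUC of
# an n-day uniform schedule (superposition).
steady_daily_auc <- function(product, dose_U_per_kg,
                             subject = subject_spec(),
                             params = default_parameters(), n_days = 6) {
  sch <- uniform_schedule(n_days, product, dose_U_per_kg, subject,
                          extra_horizon_h = 24)
  prof <- simulate_regimen(sch, params)
  daily_trailing_auc(prof, n_days)$auc_pmolh_per_L[n_days]
}

#' Gla-300 dose increase harmonizing steady-state exposure with Gla-100
#'
#' Bisects on a Gla-300 dose scale until the steady-state trailing 24-h AUC
#' equals that of Gla-100 at the reference dose. The model predicts a
#' positive increase because the smaller Gla-300 injection volume raises the
#' volume-dependent subcutaneous loss rates and so lowers bioavailability.
#'
#' @param subject a [subject_spec()].
#' @param params model parameters.
#' @param base_dose_U_per_kg Gla-100 reference dose (default 0.4 U/kg).
#' @param rel_tol relative AUC matching tolerance (default 1e-4).
#' @param bracket search interval for the scale (default \code{c(1, 1.5)},
#'   i.e. 0--50 percent increase).
#' @return percent increase, \code{(scale - 1) * 100}.
#' @export
harmonizing_dose_scale <- function(subject = subject_spec(),
                                   params = default_parameters(),
                                   base_dose_U_per_kg = 0.4,
                                   rel_tol = 1e-4,
                                   bracket = c(1, 1.5)) {
  target <- steady_daily_auc("Gla-100", base_dose_U_per_kg, subject, params)
  fval <- function(s)
    steady_daily_auc("Gla-300", s * base_dose_U_per_kg, subject, params) -
      target
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- fval(lo); f_hi <- fval(hi)
  if (abs(f_lo) / target <= rel_tol) return((lo - 1) * 100)
  if (sign(f_lo) == sign(f_hi))
    stop("no harmonizing scale within [", (lo - 1) * 100, "%, ",
         (hi - 1) * 100, "%]", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- fval(mid)
    if (abs(f_mid) / target <= rel_tol) return((mid - 1) * 100)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else hi <- mid
  }
  ((lo + hi) / 2 - 1) * 100
}
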