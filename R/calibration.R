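# Calibration: seeded multi-start bounded least squares of a chosen
# parameter subset against an observed mean concentration profile, scored by
# the mean squared error at fixed clock times (default 6, 8, 12, 16, 20, 24
# and 28 h post dose).

FITTABLE <- c("k_FP", "k_pre", "k_sol", "k_HD", "k_DM",
              "lambda_H_numerator")

#' Specification of a calibration run
#'
#' @param free character vector of parameters to estimate; any of
#'   \code{k_FP, k_pre, k_sol, k_HD, k_DM, lambda_H_numerator}.
#' @param lower,upper optional named bounds; default one decade either side
#'   of the parameter's default value.
#' @param n_starts number of multi-start initial points (default 5).
#' @param seed integer seed controlling the starts (runs are reproducible).
#' @param timepoints_h scoring times in hours post dose.
#' @return object of class \code{glargine_fit_spec}.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL, n_starts = 5,
                     seed = 1, timepoints_h = c(6, 8, 12, 16, 20, 24, 28)) {
  stopifnot(is.character(free), length(free) >= 1)
  bad <- setdiff(free, FITTABLE)
  if (length(bad))
    stop("not fittable: ", paste(bad, collapse = ", "), call. = FALSE)
  defaults <- unlist(unclass(default_parameters())[free])
  lo <- defaults / 10; hi <- defaults * 10
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo <= 0) ||
      any(hi <= lo))
    stop("bounds must be finite, positive and ordered", call. = FALSE)
  stopifnot(all(timepoints_h > 0), n_starts >= 1)
  structure(list(free = free, lower = lo, upper = hi,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 timepoints_h = timepoints_h),
            class = "glargine_fit_spec")
}

#' Mean squared error between two profiles at fixed time points
#'
#' Both profiles are linearly interpolated onto the scoring times; points
#' outside either profile's support are an error.
#'
#' @param predicted,observed [concentration_profile()]s.
#' @param timepoints_h scoring times, hours.
#' @return MSE in (pmol/L)^2.
#' @export
mse_score <- function(predicted, observed,
                      timepoints_h = c(6, 8, 12, 16, 20, 24, 28)) {
  t_min <- timepoints_h * 60
  mean((profile_conc_at(predicted, t_min) -
          profile_conc_at(observed, t_min))^2)
}

sim_at_timepoints <- function(params, event, subject, t_min) {
  grid <- sort(unique(c(0, t_min, max(t_min))))
  simulate_single_dose(event, subject, params, t_end_min = max(t_min),
                       output_grid_min = grid)
}

#' Fit free parameters to an observed profile
#'
#' Bounded Levenberg-Marquardt least squares
#' (\code{\link[minpack.lm]{nls.lm}}) on the residuals at the scoring times,
#' restarted from \code{n_starts} seeded initial points drawn log-uniformly
#' within the bounds (the first start is the default parameter set, clipped
#' to the bounds). Identical spec + data + seed give identical results.
#'
#' @param spec a [fit_spec()].
#' @param observed observed mean single-dose profile (its metadata may carry
#'   product/dose/body mass; otherwise supply \code{event} and
#'   \code{subject}).
#' @param fixed parameter set holding everything not being fitted.
#' @param event the [dose_event()] that produced the observed profile.
#' @param subject the [subject_spec()] of the observed profile.
#' @return object of class \code{glargine_fit}: \code{params} (full set with
#'   fitted values), \code{estimates}, \code{mse}, per-start \code{trace}
#'   data.frame, \code{spec}.
#' @export
fit_profile <- function(spec, observed, fixed = default_parameters(),
                        event, subject) {
  stopifnot(inherits(spec, "glargine_fit_spec"),
            inherits(observed, "glargine_profile"),
            inherits(event, "glargine_dose_event"))
  t_min <- spec$timepoints_h * 60
  obs <- profile_conc_at(observed, t_min)
  k <- length(spec$free)

  resid_fun <- function(theta) {
    p <- fixed
    p[spec$free] <- as.list(pmin(pmax(theta, spec$lower), spec$upper))
    pred <- sim_at_timepoints(validate_parameters(p), event, subject, t_min)
    profile_conc_at(pred, t_min) - obs
  }

  defaults <- pmin(pmax(unlist(unclass(fixed)[spec$free]), spec$lower),
                   spec$upper)
  starts <- matrix(NA_real_, spec$n_starts, k,
                   dimnames = list(NULL, spec$free))
  starts[1, ] <- defaults
  if (spec$n_starts > 1) {
    draws <- with_seed(spec$seed, matrix(
      stats::runif((spec$n_starts - 1) * k), spec$n_starts - 1, k))
    starts[-1, ] <- exp(log(spec$lower)[col(draws)] +
                          draws * (log(spec$upper) -
                                     log(spec$lower))[col(draws)])
  }

  runs <- lapply(seq_len(spec$n_starts), function(i) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = spec$lower, upper = spec$upper,
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res))
      return(list(final = rep(NA_real_, k), mse = Inf, converged = FALSE))
    list(final = stats::setNames(unname(res$par), spec$free),
         mse = mean(res$fvec^2),
         converged = res$info %in% 1:4)
  })
  mses <- vapply(runs, `[[`, numeric(1), "mse")
  if (all(!is.finite(mses)))
    stop("all optimization starts failed", call. = FALSE)
  best <- which.min(mses)
  finals <- do.call(rbind, lapply(runs, `[[`, "final"))
  trace <- data.frame(start = seq_len(spec$n_starts),
                      initial = I(asplit(starts, 1)),
                      final = I(asplit(finals, 1)),
                      mse = mses,
                      converged = vapply(runs, `[[`, logical(1),
                                         "converged"))
  best_params <- fixed
  best_params[spec$free] <- as.list(runs[[best]]$final)
  structure(list(params = validate_parameters(best_params),
                 estimates = runs[[best]]$final,
                 mse = mses[best], trace = trace, spec = spec),
            class = "glargine_fit")
}

#' @export
print.glargine_fit <- function(x, ...) {
  cat("<glargine_fit>", length(x$spec$free), "free parameter(s),",
      x$spec$n_starts, "start(s)\n")
  cat(sprintf("  best MSE %.6g (pmol/L)^2\n", x$mse))
  for (nm in names(x$estimates))
    cat(sprintf("  %-20s %g\n", nm, x$estimates[[nm]]))
  invisible(x)
}

#' Validate a parameter set against observed profiles
#'
#' Simulates each observed condition (taken from profile metadata:
#' \code{product}, \code{dose_pmol}, \code{body_mass_kg}) with the given
#' parameters and reports one MSE per profile.
#'
#' @param params parameter set to score.
#' @param observed_profiles list of [concentration_profile()]s with
#'   complete metadata.
#' @param timepoints_h scoring times, hours; defaults to every profile time
#'   point at or after 6 h if \code{NULL}.
#' @return data.frame with product, dose, and MSE per profile.
#' @export
validate_profiles <- function(params, observed_profiles,
                              timepoints_h = c(6, 8, 12, 16, 20, 24, 28)) {
  stopifnot(is.list(observed_profiles))
  rows <- lapply(observed_profiles, function(obs) {
    m <- obs$metadata
    if (is.null(m$product) || is.null(m$dose_pmol) ||
        is.null(m$body_mass_kg))
      stop("observed profile lacks product/dose/body-mass metadata",
           call. = FALSE)
    subject <- subject_spec(m$body_mass_kg, V_D = params$V_D)
    ev <- dose_event(0, m$product, dose_pmol = m$dose_pmol)
    tp <- timepoints_h[timepoints_h * 60 <= max(obs$time_min)]
    pred <- sim_at_timepoints(params, ev, subject, tp * 60)
    data.frame(product = m$product, dose_pmol = m$dose_pmol,
               body_mass_kg = m$body_mass_kg,
               n_timepoints = length(tp),
               mse = mse_score(pred, obs, tp))
  })
  do.call(rbind, rows)
}

#' Serialize a fit result to JSON
#'
#' @param fit a \code{glargine_fit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "glargine_fit"))
  x <- list(
    free = fit$spec$free,
    estimates = as.list(fit$estimates),
    mse = fit$mse,
    seed = fit$spec$seed,
    timepoints_h = fit$spec$timepoints_h,
    trace = lapply(seq_len(nrow(fit$trace)), function(i) list(
      start = i,
      initial = as.list(fit$trace$initial[[i]]),
      final = as.list(fit$trace$final[[i]]),
      mse = fit$trace$mse[i],
      converged = fit$trace$converged[i])))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
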