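#' Concentration-time profile
#'
#' The unit of exchange between the simulator, the AUC/exposure machinery,
#' CSV I/O and the calibration module: a strictly increasing time grid with
#' the plasma glargine concentration at each point, optionally the full state
#' trajectory, and metadata describing how it was produced.
#'
#' @param time_min numeric vector, minutes, strictly increasing.
#' @param conc_pmol_per_L plasma concentration, pmol/L, same length,
#'   non-negative (tiny solver undershoots below \code{-1e-9 * max} are
#'   clipped to zero).
#' @param states optional matrix of state trajectories (rows = time points).
#' @param metadata named list (product, dose, body mass, ...).
#' @return object of class \code{glargine_profile}.
#' @export
concentration_profile <- function(time_min, conc_pmol_per_L, states = NULL,
                                  metadata = list()) {
  stopifnot(is.numeric(time_min), is.numeric(conc_pmol_per_L))
  if (length(time_min) != length(conc_pmol_per_L))
    stop("time and concentration must have equal length", call. = FALSE)
  if (length(time_min) < 2 || any(diff(time_min) <= 0))
    stop("time grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  tol <- 1e-9 * max(abs(conc_pmol_per_L), 1)
  if (any(conc_pmol_per_L < -tol))
    stop("negative concentration in profile", call. = FALSE)
  conc_pmol_per_L <- pmax(conc_pmol_per_L, 0)
  structure(list(time_min = as.numeric(time_min),
                 conc_pmol_per_L = as.numeric(conc_pmol_per_L),
                 states = states,
                 metadata = metadata),
            class = "glargine_profile")
}

#' @export
print.glargine_profile <- function(x, ...) {
  n <- length(x$time_min)
  cat(sprintf(
    "<glargine_profile> %d points, t = %.2f..%.2f h, Cmax = %.2f pmol/L\n",
    n, x$time_min[1] / 60, x$time_min[n] / 60, max(x$conc_pmol_per_L)))
  if (!is.null(x$metadata$product))
    cat(sprintf("  %s, dose %.0f pmol, BM %.0f kg\n", x$metadata$product,
                x$metadata$dose_pmol %||% NA,
                x$metadata$body_mass_kg %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.glargine_profile <- function(x, ...) {
  df <- data.frame(time_h = x$time_min / 60,
                   conc_pmol_per_L = x$conc_pmol_per_L)
  if (!is.null(x$states)) df <- cbind(df, as.data.frame(x$states))
  df
}

#' Interpolate a profile at arbitrary times
#'
#' Linear interpolation on the stored grid; times outside the support are an
#' error (no extrapolation).
#'
#' @param profile a [concentration_profile()].
#' @param time_min times to evaluate, minutes.
#' @return concentrations in pmol/L.
#' @export
profile_conc_at <- function(profile, time_min) {
  stopifnot(inherits(profile, "glargine_profile"))
  rng <- range(profile$time_min)
  if (any(time_min < rng[1] - 1e-9) || any(time_min > rng[2] + 1e-9))
    stop(sprintf("time outside profile support [%.3f, %.3f] min",
                 rng[1], rng[2]), call. = FALSE)
  stats::approx(profile$time_min, profile$conc_pmol_per_L,
                xout = pmin(pmax(time_min, rng[1]), rng[2]))$y
}
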