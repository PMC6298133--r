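# Synthetic clamp-study profiles and CSV exchange. The observed mean
# concentration curves of the original euglycemic clamp studies are not
# published as tables, so calibration and validation are exercised against
# synthetic mean profiles: the model's own output at a stated parameter set,
# sampled at clamp-like times, with seeded multiplicative log-normal noise.

#' Specification of a synthetic clamp study arm
#'
#' @param product formulation name or object.
#' @param dose_U_per_kg single dose, U/kg.
#' @param body_mass_kg subject body mass (default 80 kg).
#' @param times_h sampling times, hours post dose (default hourly over a
#'   36-h clamp).
#' @param cv multiplicative noise coefficient of variation (>= 0; 0 gives
#'   the noiseless mean curve).
#' @param seed integer seed for the noise draws.
#' @return object of class \code{glargine_synth_spec}.
#' @export
synthetic_study_spec <- function(product, dose_U_per_kg,
                                 body_mass_kg = 80,
                                 times_h = seq(0.5, 36, by = 0.5),
                                 cv = 0, seed = 1) {
  stopifnot(cv >= 0, all(times_h >= 0), length(times_h) >= 2)
  structure(list(product = glargine_formulation(product),
                 dose_U_per_kg = dose_U_per_kg,
                 body_mass_kg = body_mass_kg,
                 times_h = sort(unique(times_h)),
                 cv = cv, seed = as.integer(seed)),
            class = "glargine_synth_spec")
}

#' Generate a synthetic observed mean profile
#'
#' Simulates the ground truth with \code{params} and applies one seeded
#' multiplicative log-normal factor per sampling time, mean-corrected so the
#' expected factor is 1. With \code{cv = 0} the output equals the simulated
#' truth exactly; identical seeds give identical output.
#'
#' @param spec a [synthetic_study_spec()].
#' @param params parameter set used as ground truth.
#' @return a [concentration_profile()] on the sampling grid, metadata
#'   flagged \code{synthetic = TRUE}.
#' @export
generate_clamp_profile <- function(spec, params = default_parameters()) {
  stopifnot(inherits(spec, "glargine_synth_spec"))
  subject <- subject_spec(spec$body_mass_kg, V_D = params$V_D)
  ev <- dose_event(0, spec$product, dose_U_per_kg = spec$dose_U_per_kg,
                   body_mass_kg = spec$body_mass_kg)
  t_min <- spec$times_h * 60
  truth <- sim_at_timepoints(params, ev, subject, pmax(t_min, 1e-6))
  conc <- profile_conc_at(truth, t_min)
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    fac <- with_seed(spec$seed,
                     exp(stats::rnorm(length(conc), -sdlog^2 / 2, sdlog)))
    conc <- conc * fac
  }
  concentration_profile(t_min, conc, metadata = list(
    product = spec$product$name,
    dose_pmol = ev$dose_pmol,
    body_mass_kg = spec$body_mass_kg,
    cv = spec$cv, seed = spec$seed, synthetic = TRUE))
}

#' Read / write a concentration profile CSV
#'
#' Canonical columns are \code{time_h} and \code{conc_pmol_per_L}; the
#' aliases \code{time} and \code{conc} are accepted on read (a normalization
#' message is emitted). Times must be strictly increasing and concentrations
#' non-negative; violations are reported with the offending row number.
#'
#' @param path CSV file path.
#' @return \code{read_profile_csv}: a [concentration_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  aliases <- c(time = "time_h", conc = "conc_pmol_per_L")
  for (a in names(aliases)) {
    if (!(aliases[[a]] %in% nm) && a %in% nm) {
      message("read_profile_csv: normalizing column '", a, "' to '",
              aliases[[a]], "'")
      names(df)[nm == a] <- aliases[[a]]
      nm <- names(df)
    }
  }
  missing <- setdiff(c("time_h", "conc_pmol_per_L"), names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  t_h <- df$time_h; conc <- df$conc_pmol_per_L
  bad <- which(diff(t_h) <= 0)
  if (length(bad))
    stop("time not strictly increasing at row ", bad[1] + 1, call. = FALSE)
  neg <- which(conc < 0)
  if (length(neg))
    stop("negative concentration at row ", neg[1], call. = FALSE)
  meta <- list()
  for (key in c("product", "dose_pmol", "body_mass_kg"))
    if (key %in% names(df)) meta[[key]] <- df[[key]][1]
  concentration_profile(t_h * 60, conc, metadata = meta)
}

#' @rdname read_profile_csv
#' @param profile a [concentration_profile()].
#' @param states if \code{TRUE} and the profile carries state trajectories,
#'   write them as additional columns (wide format).
#' @export
write_profile_csv <- function(profile, path, states = FALSE) {
  stopifnot(inherits(profile, "glargine_profile"))
  df <- data.frame(time_h = profile$time_min / 60,
                   conc_pmol_per_L = profile$conc_pmol_per_L)
  if (states && !is.null(profile$states))
    df <- cbind(df, as.data.frame(profile$states))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
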