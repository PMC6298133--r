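# Internal unit system: amounts in monomer-equivalent pmol, time in minutes,
# volumes in mm^3, areas in mm^2, plasma concentration in pmol/L.
# 1 U insulin glargine = 6 nmol = 6000 pmol (molar mass ~6063 g/mol,
# 100 U/mL ~ 3.64 mg/mL).
PMOL_PER_U <- 6000

#' Built-in insulin glargine formulations
#'
#' Returns the specification of one of the two marketed insulin glargine
#' products: Gla-100 (100 U/mL, Lantus-type) or Gla-300 (300 U/mL,
#' Toujeo-type). Both deliver the same molecule and the same units per dose;
#' Gla-300 does so in one third of the injection volume, which is the root of
#' every pharmacokinetic difference the model produces.
#'
#' @param name one of \code{"Gla-100"}, \code{"Gla-300"} (case-insensitive;
#'   \code{"gla100"}/\code{"gla300"} also accepted).
#' @return an object of class \code{glargine_formulation} with fields
#'   \code{name}, \code{conc_U_per_mL} and \code{conc_pmol_per_mm3} (molar
#'   concentration; exactly 3x higher for Gla-300).
#' @export
#' @examples
#' glargine_formulation("Gla-300")$conc_pmol_per_mm3 /
#'   glargine_formulation("Gla-100")$conc_pmol_per_mm3  # exactly 3
glargine_formulation <- function(name) {
  if (inherits(name, "glargine_formulation")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  key <- gsub("[^a-z0-9]", "", tolower(name))
  conc <- switch(key,
    "gla100" = 100,
    "gla300" = 300,
    stop("unknown formulation: '", name,
         "' (built-ins are Gla-100 and Gla-300)", call. = FALSE)
  )
  structure(list(
    name = if (conc == 100) "Gla-100" else "Gla-300",
    conc_U_per_mL = conc,
    # U/mL -> pmol/mm^3: x U/mL * 6000 pmol/U / 1000 mm^3/mL
    conc_pmol_per_mm3 = conc * PMOL_PER_U / 1000
  ), class = "glargine_formulation")
}

#' @export
print.glargine_formulation <- function(x, ...) {
  cat(sprintf("<glargine_formulation> %s: %g U/mL = %g pmol/mm^3\n",
              x$name, x$conc_U_per_mL, x$conc_pmol_per_mm3))
  invisible(x)
}

#' Subject specification
#'
#' Only body mass enters the model: it scales the injected dose (doses are
#' prescribed per kg) and the plasma distribution volume
#' \eqn{V_{Plasma} = V_D \times BM}.
#'
#' @param body_mass_kg body mass in kg (> 0).
#' @param V_D distribution volume per kg (L/kg), default 0.1421.
#' @return object of class \code{glargine_subject} with \code{body_mass_kg}
#'   and \code{plasma_volume_L}.
#' @export
subject_spec <- function(body_mass_kg = 80, V_D = 0.1421) {
  stopifnot(is.numeric(body_mass_kg), length(body_mass_kg) == 1)
  if (!is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("body_mass_kg must be positive", call. = FALSE)
  structure(list(
    body_mass_kg = body_mass_kg,
    V_D = V_D,
    plasma_volume_L = V_D * body_mass_kg
  ), class = "glargine_subject")
}

#' Convert a weight-based dose to monomer-equivalent pmol
#'
#' Uses the fixed equivalence 1 U = 6 nmol insulin glargine, consistent with
#' the clinically quoted pairs (0.4 U/kg = 2.4 nmol/kg, 0.6 U/kg = 3.6
#' nmol/kg, 0.9 U/kg = 5.4 nmol/kg).
#'
#' @param dose_U_per_kg dose in U/kg (>= 0).
#' @param body_mass_kg body mass in kg (> 0).
#' @return dose in pmol.
#' @seealso [pmol_to_dose()] for the inverse.
#' @export
#' @examples
#' dose_to_pmol(0.4, 80)  # 192000 pmol = 2.4 nmol/kg x 80 kg
dose_to_pmol <- function(dose_U_per_kg, body_mass_kg) {
  stopifnot(is.numeric(dose_U_per_kg), is.numeric(body_mass_kg))
  if (any(dose_U_per_kg < 0)) stop("dose must be >= 0", call. = FALSE)
  if (any(body_mass_kg <= 0)) stop("body mass must be > 0", call. = FALSE)
  dose_U_per_kg * PMOL_PER_U * body_mass_kg
}

#' @rdname dose_to_pmol
#' @param dose_pmol dose in pmol.
#' @export
pmol_to_dose <- function(dose_pmol, body_mass_kg) {
  stopifnot(is.numeric(dose_pmol), is.numeric(body_mass_kg))
  if (any(body_mass_kg <= 0)) stop("body mass must be > 0", call. = FALSE)
  dose_pmol / (PMOL_PER_U * body_mass_kg)
}

#' Injection volume of a dose
#'
#' The formulation concentration fixes the injected volume for a given molar
#' dose; at equal dose the Gla-300 volume is exactly one third of Gla-100's.
#'
#' @param dose_pmol dose in monomer-equivalent pmol (>= 0).
#' @param formulation a [glargine_formulation()] or its name.
#' @return injection volume in mm^3.
#' @export
#' @examples
#' injection_volume(192000, "Gla-100")  # 320 mm^3 = 0.32 mL (32 U)
injection_volume <- function(dose_pmol, formulation) {
  if (any(dose_pmol < 0)) stop("dose must be >= 0", call. = FALSE)
  f <- glargine_formulation(formulation)
  dose_pmol / f$conc_pmol_per_mm3
}

#' Default model parameters
#'
#' Constructs the full parameter set of the depot/dissociation/disposition
#' model. Defaults are the calibrated literature set; any field may be
#' overridden by name. Rates are per minute, the dissolution rate constants
#' \code{k_pre}/\code{k_sol} are pmol/(min mm^2), diffusion constants are
#' cm^2/min (used only by the spatial variant), \code{alpha} is L/pmol.
#'
#' Fields:
#' \describe{
#'   \item{k_FP}{rate of precipitate formation from the injected solution,
#'     1/min (2.82).}
#'   \item{k_pre, k_sol}{per-area redissolution rate of precipitated and
#'     soluble glargine at the depot surface, pmol/(min mm^2) (0.28, 0.34).}
#'   \item{f_vol}{form factor correcting the spherical surface area for the
#'     depot's spread along septal spaces (3.6, dimensionless).}
#'   \item{D_H, D_D}{diffusion constants of hexamer and dimer, cm^2/min;
#'     spatial variant only.}
#'   \item{lambda_H_numerator}{numerator of the hexamer loss rate; divided by
#'     the injection volume in mL to give 1/min (1.948e-5).}
#'   \item{lambda_D_factor}{dimer loss rate as a multiple of the hexamer one
#'     (4.57).}
#'   \item{lambda_M}{monomer loss rate, 1/min (2.9e-3), volume independent.}
#'   \item{k_HD, k_DH, k_DM}{hexamer->dimer, dimer->hexamer and
#'     dimer->monomer dissociation rates, 1/min.}
#'   \item{k_abs}{monomer absorption rate into plasma, 1/min (6.18e-2).}
#'   \item{V_SC_factor}{subcutaneous distribution volume as a multiple of the
#'     injection volume (2.5); spatial variant only.}
#'   \item{V_D}{plasma distribution volume per kg body mass, L/kg (0.1421).}
#'   \item{k_Clearance}{plasma clearance rate, 1/min (0.1234).}
#'   \item{alpha}{saturation coefficient of clearance, L/pmol (1.58e-4);
#'     clearance is \eqn{k_{Clearance}/(1+\alpha C)}.}
#'   \item{pw}{fraction of the injected/surface material that stays in
#'     solution rather than precipitating (default 0.1); the downstream
#'     exposure is insensitive to it because k_pre and k_sol are similar.}
#'   \item{rtol, atol}{ODE solver tolerances (1e-8 relative, 1e-6 pmol
#'     absolute).}
#' }
#'
#' @param ... named overrides of any field.
#' @return object of class \code{glargine_params}.
#' @export
default_parameters <- function(...) {
  p <- list(
    k_FP = 2.82,
    k_pre = 0.28,
    k_sol = 0.34,
    f_vol = 3.6,
    D_H = 4.6860e-5,
    D_D = 1.7926 * 4.6860e-5,
    lambda_H_numerator = 1.948e-5,
    lambda_D_factor = 4.57,
    lambda_M = 2.9e-3,
    k_HD = 0.72,
    k_DH = 1.5e-5,
    k_DM = 5.81e-3,
    k_abs = 6.18e-2,
    V_SC_factor = 2.5,
    V_D = 0.1421,
    k_Clearance = 0.1234,
    alpha = 1.58e-4,
    pw = 0.1,
    rtol = 1e-8,
    atol = 1e-6
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  validate_parameters(structure(p, class = "glargine_params"))
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "glargine_params"))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))
  if (!all(num))
    stop("non-numeric parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  rates <- c("k_FP", "k_pre", "k_sol", "lambda_H_numerator",
             "lambda_D_factor", "lambda_M", "k_HD", "k_DH", "k_DM",
             "k_abs", "k_Clearance", "alpha")
  bad <- rates[vapply(rates, function(n) p[[n]] < 0, logical(1))]
  if (length(bad))
    stop("negative rate parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$pw < 0 || p$pw > 1) stop("pw must lie in [0, 1]", call. = FALSE)
  if (p$f_vol <= 0 || p$V_D <= 0 || p$V_SC_factor <= 0)
    stop("f_vol, V_D and V_SC_factor must be positive", call. = FALSE)
  p
}

#' @export
print.glargine_params <- function(x, ...) {
  cat("<glargine_params>\n")
  nm <- names(x)
  for (i in seq_along(x)) cat(sprintf("  %-20s %g\n", nm[i], x[[i]]))
  invisible(x)
}

#' Volume-dependent non-specific loss rates
#'
#' In subcutaneous tissue all three association states are degraded
#' non-specifically. The hexamer loss rate scales inversely with the injection
#' volume (so the more concentrated Gla-300, with a third of the volume, loses
#' hexamers three times faster per minute); the dimer rate is a fixed multiple
#' of it; the monomer rate is volume independent. This is the mechanism behind
#' the lower bioavailability of Gla-300.
#'
#' @param params a [default_parameters()] object.
#' @param injection_volume_mm3 injection volume in mm^3 (> 0).
#' @return list with \code{lambda_H}, \code{lambda_D}, \code{lambda_M}
#'   (1/min).
#' @export
#' @examples
#' derived_loss_rates(default_parameters(), 320)$lambda_H  # 6.0875e-5 /min
derived_loss_rates <- function(params, injection_volume_mm3) {
  stopifnot(inherits(params, "glargine_params"))
  if (!is.numeric(injection_volume_mm3) || injection_volume_mm3 <= 0)
    stop("injection volume must be > 0 (loss rate divides by it)",
         call. = FALSE)
  v_mL <- injection_volume_mm3 / 1000
  lambda_H <- params$lambda_H_numerator / v_mL
  list(lambda_H = lambda_H,
       lambda_D = params$lambda_D_factor * lambda_H,
       lambda_M = params$lambda_M)
}

#' A single injection event
#'
#' @param time_min time of the injection, minutes from scenario start.
#' @param product formulation (object or name).
#' @param dose_pmol monomer-equivalent dose in pmol (>= 0). Alternatively give
#'   \code{dose_U_per_kg} together with \code{body_mass_kg}.
#' @param dose_U_per_kg,body_mass_kg weight-based dose specification.
#' @return object of class \code{glargine_dose_event} with the derived
#'   \code{injection_volume_mm3}.
#' @export
dose_event <- function(time_min = 0, product, dose_pmol = NULL,
                       dose_U_per_kg = NULL, body_mass_kg = NULL) {
  f <- glargine_formulation(product)
  if (is.null(dose_pmol)) {
    if (is.null(dose_U_per_kg) || is.null(body_mass_kg))
      stop("give dose_pmol, or dose_U_per_kg with body_mass_kg",
           call. = FALSE)
    dose_pmol <- dose_to_pmol(dose_U_per_kg, body_mass_kg)
  }
  if (dose_pmol < 0) stop("dose must be >= 0", call. = FALSE)
  structure(list(
    time_min = time_min,
    product = f,
    dose_pmol = dose_pmol,
    injection_volume_mm3 = if (dose_pmol > 0)
      injection_volume(dose_pmol, f) else 0
  ), class = "glargine_dose_event")
}

#' Read / write a parameter configuration file
#'
#' Flat JSON or YAML mapping of parameter names to values (format chosen by
#' file extension). Omitted keys take their defaults; unknown keys are an
#' error. The round trip is lossless.
#'
#' @param path file path ending in \code{.json}, \code{.yaml} or \code{.yml}.
#' @return \code{read_params_config} returns a \code{glargine_params};
#'   \code{write_params_config} returns \code{path} invisibly.
#' @export
read_params_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    "yaml" = ,
    "yml"  = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  do.call(default_parameters, as.list(vals))
}

#' @rdname read_params_config
#' @param params a \code{glargine_params} object.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "glargine_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    "yaml" = ,
    "yml"  = yaml::write_yaml(x, path, precision = 17L),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  invisible(path)
}
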