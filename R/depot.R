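# Depot formation and surface-area-limited redissolution.
#
# The injected acidic solution (amount S) precipitates at physiological pH
# with first-order rate k_FP into a single amorphous body (amount P); a
# fraction pw stays soluble and bypasses the depot. Redissolution is
# Nernst-Brunner: a flux proportional to the depot surface area, which for a
# single body of volume V = P / C_formulation is f_vol * (36*pi)^(1/3) *
# V^(2/3). The formulation concentration is the only product-specific input,
# so at equal dose the Gla-300 depot has 1/3 the volume and (1/3)^(2/3) ~
# 0.48 the surface area — the "approximately half" redissolution rate.

SPHERE_COEF <- (36 * pi)^(1 / 3)  # surface of a sphere = coef * V^(2/3)

#' Depot surface area
#'
#' Surface area of a single-bodied depot holding \code{P} pmol of
#' precipitated glargine, as the sphere surface for volume
#' \eqn{V = P / C_{formulation}} scaled by the form factor \code{f_vol}
#' (depots spread along septal spaces and are not spherical).
#'
#' @param P precipitated amount, pmol (>= 0).
#' @param formulation a [glargine_formulation()] or name.
#' @param f_vol form factor (default from [default_parameters()]).
#' @return surface area in mm^2; 0 when \code{P = 0}.
#' @export
#' @examples
#' surface_area(192000, "Gla-100", f_vol = 3.6)  # ~ 813 mm^2 for a 32 U depot
surface_area <- function(P, formulation, f_vol = default_parameters()$f_vol) {
  if (any(P < 0)) stop("P must be >= 0", call. = FALSE)
  f <- glargine_formulation(formulation)
  f_vol * SPHERE_COEF * (P / f$conc_pmol_per_mm3)^(2 / 3)
}

#' Redissolution flux from the depot
#'
#' Per-area release mixes the precipitate redissolution rate \code{k_pre}
#' and the soluble-glargine rate \code{k_sol} by the surface solution
#' fraction \code{pw}:
#' \deqn{J = [(1-pw) k_{pre} + pw\, k_{sol}] \times SA(P).}
#' Monotone increasing and concave in \code{P}; at equal depot mass the
#' Gla-300 flux is \eqn{(1/3)^{2/3} \approx 0.481} times the Gla-100 flux.
#'
#' @param P precipitated amount, pmol.
#' @inheritParams surface_area
#' @param params model parameters.
#' @return release flux, pmol/min.
#' @export
release_flux <- function(P, formulation, params = default_parameters()) {
  k_eff <- (1 - params$pw) * params$k_pre + params$pw * params$k_sol
  k_eff * surface_area(P, formulation, params$f_vol)
}

#' Time derivatives of the isolated depot subsystem
#'
#' @param S soluble injected amount at the site, pmol.
#' @param P precipitated amount, pmol.
#' @inheritParams release_flux
#' @return list with \code{dS}, \code{dP} (pmol/min), the redissolution flux
#'   \code{J_release} and the bypass flux \code{J_bypass} (the fraction
#'   \code{pw} of precipitating material that stays soluble and feeds the
#'   hexamer pool directly). \code{dS + dP + J_release + J_bypass = 0}: the
#'   depot conserves mass against its outflows.
#' @export
depot_rhs <- function(S, P, formulation, params = default_parameters()) {
  if (S < 0 || P < 0) stop("state must be non-negative", call. = FALSE)
  J_rel <- release_flux(max(P, 0), formulation, params)
  J_byp <- params$k_FP * params$pw * S
  list(dS = -params$k_FP * S,
       dP = params$k_FP * (1 - params$pw) * S - J_rel,
       J_release = J_rel,
       J_bypass = J_byp)
}

#' Closed-form depot depletion time
#'
#' For a pure precipitate (\code{pw = 0}, no formation term) the depot obeys
#' \eqn{dP/dt = -k_{pre} a P^{2/3}} with
#' \eqn{a = f_{vol} (36\pi)^{1/3} / C^{2/3}}, which depletes in finite time
#' \deqn{t = 3 P_0^{1/3} / (k_{pre} a).}
#' Serves as an analytic oracle for the numerical integrator; note the
#' cube-root scaling (8x the dose takes only 2x as long).
#'
#' @param P0 initial precipitated amount, pmol (> 0).
#' @inheritParams release_flux
#' @return depletion time in minutes.
#' @export
#' @examples
#' depletion_time_closed_form(192000, "Gla-100") / 60  # ~ 42 h
#' depletion_time_closed_form(192000, "Gla-300") / 60  # ~ 87 h
depletion_time_closed_form <- function(P0, formulation,
                                       params = default_parameters()) {
  if (!is.numeric(P0) || any(P0 <= 0)) stop("P0 must be > 0", call. = FALSE)
  f <- glargine_formulation(formulation)
  a <- params$f_vol * SPHERE_COEF / f$conc_pmol_per_mm3^(2 / 3)
  3 * P0^(1 / 3) / (params$k_pre * a)
}
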