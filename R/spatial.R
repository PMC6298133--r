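# Radial-diffusion variant of the subcutaneous stage. Hexamers and dimers
# released from the depot diffuse through a spherical SC domain of volume
# V_SC = V_SC_factor * V_Injection discretised into concentric shells
# (finite volumes); release enters the innermost shell, the outer boundary
# is zero-flux, monomers do not diffuse (no constant is given for them) and
# every reaction, loss and absorption acts locally. Because all of those
# local processes are first order, the spatially integrated totals obey
# exactly the compartmental equations: the variant exists to represent the
# diffusion terms explicitly and to verify that equivalence.

#' Simulate a single dose with explicit radial diffusion in SC tissue
#'
#' @inheritParams simulate_single_dose
#' @param n_shells number of concentric shells (1 reproduces the
#'   compartmental model exactly).
#' @return a [concentration_profile()]; metadata records \code{n_shells}.
#'   The attached states (if requested) are the per-species totals.
#' @export
simulate_single_dose_spatial <- function(event, subject = subject_spec(),
                                         params = default_parameters(),
                                         n_shells = 20,
                                         t_end_min = 72 * 60,
                                         output_grid_min = NULL,
                                         keep_states = FALSE) {
  stopifnot(inherits(event, "glargine_dose_event"),
            n_shells >= 1, n_shells == round(n_shells))
  grid <- output_grid_min %||% seq(0, t_end_min, by = 1)
  meta <- list(product = event$product$name, dose_pmol = event$dose_pmol,
               body_mass_kg = subject$body_mass_kg, n_shells = n_shells)
  if (event$dose_pmol == 0)
    return(concentration_profile(grid, numeric(length(grid)),
                                 metadata = meta))

  f <- event$product
  V_inj <- event$injection_volume_mm3
  V_SC <- params$V_SC_factor * V_inj                       # mm^3
  R <- (3 * V_SC / (4 * pi))^(1 / 3)                       # mm
  r <- seq(0, R, length.out = n_shells + 1)
  shell_vol <- 4 * pi / 3 * diff(r^3)                      # mm^3
  iface_area <- 4 * pi * r[2:n_shells]^2                   # mm^2 (internal)
  dr <- R / n_shells
  # diffusion constants: cm^2/min -> mm^2/min
  DH <- params$D_H * 100
  DD <- params$D_D * 100

  lam <- derived_loss_rates(params, V_inj)
  k_eff <- (1 - params$pw) * params$k_pre + params$pw * params$k_sol
  a_rel <- k_eff * params$f_vol * SPHERE_COEF / f$conc_pmol_per_mm3^(2 / 3)
  Vp <- subject$plasma_volume_L
  p <- params
  n <- n_shells
  iH <- 2 + seq_len(n); iD <- 2 + n + seq_len(n); iM <- 2 + 2 * n + seq_len(n)
  iA <- 3 * n + 3; iLd <- iA + 1; iLc <- iA + 2

  diffuse <- function(x, Dc) {
    # net diffusive gain per shell for amounts x (first-order exchange
    # between adjacent shells through shared interfaces)
    if (n == 1) return(0)
    conc <- x / shell_vol
    flux <- Dc * iface_area * diff(conc) / dr   # pmol/min, inward-positive
    c(flux, 0) - c(0, flux)
  }

  rhs <- function(t, y, parms) {
    S <- y[1]; P <- max(y[2], 0)
    H <- y[iH]; D <- y[iD]; M <- y[iM]; A <- y[iA]
    J_rel <- a_rel * P^(2 / 3)
    J_byp <- p$k_FP * p$pw * S
    src <- numeric(n); src[1] <- J_rel + J_byp
    CL <- p$k_Clearance / (1 + p$alpha * A / Vp)
    dH <- src + diffuse(H, DH) - (p$k_HD + lam$lambda_H) * H + p$k_DH * D
    dD <- diffuse(D, DD) + p$k_HD * H - (p$k_DH + p$k_DM + lam$lambda_D) * D
    dM <- p$k_DM * D - (p$k_abs + lam$lambda_M) * M
    list(c(-p$k_FP * S,
           p$k_FP * (1 - p$pw) * S - J_rel,
           dH, dD, dM,
           p$k_abs * sum(M) - CL * A,
           lam$lambda_H * sum(H) + lam$lambda_D * sum(D) +
             lam$lambda_M * sum(M),
           CL * A))
  }

  y0 <- numeric(3 * n + 5)
  y0[1] <- event$dose_pmol
  out <- deSolve::lsoda(y0, grid, rhs, parms = NULL,
                        rtol = params$rtol, atol = params$atol)
  if (attr(out, "istate")[1] < 0)
    stop("spatial ODE solver failed", call. = FALSE)
  y <- out[, -1, drop = FALSE]
  conc <- pmax(y[, iA], 0) / Vp
  states <- NULL
  if (keep_states) {
    states <- cbind(S = y[, 1], P = y[, 2],
                    H = rowSums(y[, iH, drop = FALSE]),
                    D = rowSums(y[, iD, drop = FALSE]),
                    M = rowSums(y[, iM, drop = FALSE]),
                    A = y[, iA], L_deg = y[, iLd], L_cl = y[, iLc])
  }
  concentration_profile(grid, conc, states = states, metadata = meta)
}
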