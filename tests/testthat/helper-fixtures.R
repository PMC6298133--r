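# Shared fixtures; heavy simulations are memoised for the whole test run.
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

std_subject <- function() subject_spec(80)

std_event <- function(product = "Gla-100", dose = 0.4)
  dose_event(0, product, dose_U_per_kg = dose, body_mass_kg = 80)

# 6-day once-daily regimen profile at 0.4 U/kg, superposition mode.
fix_regimen <- function(product) {
  memo(paste0("reg_", product), {
    sch <- uniform_schedule(6, product, 0.4, std_subject())
    simulate_regimen(sch, default_parameters())
  })
}

# Single 0.4 U/kg dose with states, 6-day horizon.
fix_single <- function(product) {
  memo(paste0("single_", product),
       simulate_single_dose(std_event(product), std_subject(),
                            default_parameters(), t_end_min = 8640,
                            keep_states = TRUE))
}

# Noiseless synthetic clamp profile (half-hourly, 36 h) per product.
fix_truth <- function(product = "Gla-100", dose = 0.4) {
  memo(paste0("truth_", product, "_", dose),
       generate_clamp_profile(
         synthetic_study_spec(product, dose, cv = 0),
         default_parameters()))
}
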