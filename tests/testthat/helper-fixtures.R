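# Shared fixtures: one default schedule and synthetic aorta input per run.
fix_schedule <- default_htr_schedule()
fix_aif <- generate_aif(schedule = fix_schedule)

# Glucose-analogue-like regional kinetics (moderate extraction).
fdg_like <- function() aath_params(CBF = 0.5, K1 = 0.165, k2 = 0.33, Tc = 7, td = 2)

# A parameter set whose nonlinear components sit exactly on grid nodes.
on_grid_params <- function(spec = voxel_grid_spec(), E = 0.3, CBF = 0.5,
                           td_i = 5L, Tc_i = 9L, k2_i = 60L) {
  aath_params(CBF = CBF, K1 = E * CBF, k2 = spec$k2[k2_i],
              Tc = spec$Tc[Tc_i], td = spec$td[td_i])
}

# Tiny grid for brute-force comparisons.
tiny_grid <- function() grid_spec(td_range = c(1, 3), td_step = 1,
                                  Tc_range = c(4, 8), Tc_step = 2,
                                  k2_range = c(0.05, 1), k2_n = 4)

# Step input at amplitude `a` from t = 0 (exactly representable on the fine grid).
step_input <- function(a = 10, schedule = fix_schedule, fine_dt = 0.05) {
  tfine <- seq(0, schedule_end(schedule), by = fine_dt)
  step <- rep(a, length(tfine))
  input_function(schedule, whole_blood = rep(a, schedule$M),
                 fine = list(t = tfine, whole_blood = step, plasma = step))
}
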