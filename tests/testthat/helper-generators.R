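# Shared builders for synthetic truths used across tests.
# The slow-binding truth mirrors the studied compound: k3 = 0.0041 /s,
# k4 = 0.0004 /s, Kiapp = 35.8 uM, assayed at S = 375 uM with Km = 200 uM.

tyr_mm <- function() mm_params(Vmax = 1.5e-4, Km = 200)

slow_truth <- function() two_step_params(k3 = 0.0041, k4 = 0.0004, Kiapp = 35.8)

# first-step Ki consistent with Kiapp at the default assay substrate
slow_mechanism <- function(mm = tyr_mm(), ts = slow_truth(), S = 375) {
  mechanism_spec(mm, inhibition_model("competitive", ts$Kiapp / (1 + S / mm$Km)),
                 two_step = ts)
}

inhibitor_series <- function() c(6.2, 12.5, 25, 50, 100)

# 4-substrate x 4-inhibitor steady-state design (2-fold dilutions of the
# 375 uM assay substrate; inhibitor series includes the uninhibited control)
velocity_design <- function(noise_sd = 0, replicates = 1, seed = NULL) {
  assay_design(inhibitor_concs = c(0, 12.5, 25, 50),
               substrate_concs = 375 / c(8, 4, 2, 1),
               noise_sd = noise_sd, replicates = replicates, seed = seed)
}

noiseless_grid <- function(Ki, mode = "competitive", mm = tyr_mm(), alpha = 1,
                           design = velocity_design()) {
  simulate_steady_state(design, mechanism_spec(mm,
    inhibition_model(mode, Ki, alpha)))
}

# closed-form slow-binding curves for a given mechanism truth
slow_curves <- function(noise_sd = 0, replicates = 1, seed = NULL,
                        ts = slow_truth(), mm = tyr_mm(), S = 375,
                        inhibitors = inhibitor_series(),
                        t_grid = seq(0, 1200, by = 10)) {
  des <- assay_design(inhibitor_concs = inhibitors, substrate_concs = S,
                      t_grid = t_grid, noise_sd = noise_sd,
                      replicates = replicates, seed = seed)
  params <- lapply(inhibitors, function(I)
    slow_binding_params_for(I, S, mm, ts))
  simulate_progress_closed_form(des, params)
}

# one-step slow-binding curves: kobs strictly linear in I, sharing the
# intercept and low-I slope of slow_truth()
one_step_curves <- function(noise_sd = 0, replicates = 1, seed = NULL,
                            mm = tyr_mm(), S = 375,
                            inhibitors = inhibitor_series()) {
  ts <- slow_truth()
  kon <- ts$k3 / ts$Kiapp; koff <- ts$k4; Ki_one <- koff / kon
  v0 <- velocity(S, 0, mm)
  des <- assay_design(inhibitor_concs = inhibitors, substrate_concs = S,
                      noise_sd = noise_sd, replicates = replicates, seed = seed)
  params <- lapply(inhibitors, function(I)
    slow_binding_params(vi = v0, vs = v0 / (1 + I / Ki_one),
                        kobs = koff + kon * I))
  simulate_progress_closed_form(des, params)
}

# kobs series generated directly from a rate model with multiplicative noise
direct_kobs_series <- function(gen, noise = 0.02, replicates = 3, seed = 1,
                               inhibitors = inhibitor_series()) {
  set.seed(seed)
  d <- expand.grid(inhibitor_um = inhibitors, replicate = seq_len(replicates))
  k <- gen(d$inhibitor_um)
  d$kobs <- k * (1 + rnorm(length(k), 0, noise))
  d[, c("inhibitor_um", "kobs")]
}
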