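test_that("closed-form generator is exact at zero noise and seed-stable", {
  curves <- slow_curves(noise_sd = 0, replicates = 2, seed = 11)
  meta <- attr(curves, "metadata")
  expect_equal(nrow(curves), 121 * 5 * 2)
  for (I in unique(curves$inhibitor_um)) {
    sub <- curves[curves$inhibitor_um == I & curves$replicate == 1, ]
    truth <- meta$params[[match(I, meta$design$inhibitor_concs)]]
    expect_identical(sub$signal_au, progress_value(sub$time_s, truth))
  }
  # determinism: same seed reproduces bit-identical data
  again <- slow_curves(noise_sd = 0.01, replicates = 2, seed = 11)
  third <- slow_curves(noise_sd = 0.01, replicates = 2, seed = 11)
  expect_identical(again$signal_au, third$signal_au)
  other <- slow_curves(noise_sd = 0.01, replicates = 2, seed = 12)
  expect_false(identical(again$signal_au, other$signal_au))
})

test_that("closed-form generator matches the model oracle pointwise", {
  des <- assay_design(inhibitor_concs = 50, substrate_concs = 375,
                      t_grid = c(0, 50, 100), noise_sd = 0, replicates = 1)
  p <- slow_binding_params(vi = 1, vs = 0.5, kobs = 0.01)
  out <- simulate_progress_closed_form(des, list(p))
  expect_equal(out$signal_au[out$time_s == 100], 81.606, tolerance = 1e-5)
})

test_that("generator rejects mismatched parameter lists", {
  des <- assay_design(inhibitor_concs = c(10, 20), noise_sd = 0)
  expect_error(simulate_progress_closed_form(
    des, list(slow_binding_params(1, 0.5, 0.01))), "one slow_binding_params")
})

test_that("mass-action and closed-form simulators agree for a rapid first step", {
  des <- assay_design(inhibitor_concs = inhibitor_series(), noise_sd = 0,
                      replicates = 1)
  mech <- slow_mechanism()
  mc <- simulate_progress_mechanistic(des, mech)
  cf <- slow_curves(noise_sd = 0, replicates = 1)
  for (I in inhibitor_series()) {
    a <- mc$signal_au[mc$inhibitor_um == I]
    b <- cf$signal_au[cf$inhibitor_um == I]
    expect_lt(max(abs(a - b)), 0.01 * max(b))
  }
})

test_that("noiseless mechanistic curves return the hyperbolic-law kobs", {
  des <- assay_design(inhibitor_concs = inhibitor_series(), noise_sd = 0,
                      replicates = 1)
  mc <- simulate_progress_mechanistic(des, slow_mechanism())
  ts <- slow_truth()
  for (I in inhibitor_series()) {
    sub <- mc[mc$inhibitor_um == I, c("time_s", "signal_au")]
    f <- fit_progress_curve(sub)
    expect_true(f$converged)
    expect_equal(f$params[["kobs"]], kobs_of_I(I, ts), tolerance = 0.05)
  }
})

test_that("degenerate mechanisms give straight lines at the rate-law slope", {
  mm <- tyr_mm()
  des <- assay_design(inhibitor_concs = c(0, 25), noise_sd = 0, replicates = 1)
  mech <- mechanism_spec(mm, inhibition_model("competitive", 12))
  out <- simulate_progress_mechanistic(des, mech)
  for (I in c(0, 25)) {
    sub <- out[out$inhibitor_um == I, ]
    expect_equal(sub$signal_au,
                 velocity(375, I, mm, mech$inh) * sub$time_s)
  }
  # uninhibited slope is the Michaelis-Menten velocity
  sub0 <- out[out$inhibitor_um == 0, ]
  expect_equal(sub0$signal_au, mm$Vmax * 375 / (mm$Km + 375) * sub0$time_s)
})

test_that("mechanistic simulator flags substrate depletion and slow EI steps", {
  mm_hot <- mm_params(Vmax = 5e-3, Km = 200)   # burns >10% of substrate
  des <- assay_design(inhibitor_concs = 25, noise_sd = 0, replicates = 1)
  mech <- mechanism_spec(mm_hot, inhibition_model("competitive", 12.45),
                         two_step = slow_truth())
  expect_warning(out <- simulate_progress_mechanistic(des, mech), "depletion")
  expect_true(length(attr(out, "metadata")$warnings) > 0)
  # a sluggish first step violates the rapid-equilibrium premise
  mech_slow <- mechanism_spec(tyr_mm(), inhibition_model("competitive", 12.45),
                              two_step = slow_truth(), fast_step_kon = 1e-5)
  expect_error(simulate_progress_mechanistic(des, mech_slow), "fast_step_kon")
})

test_that("steady-state grid obeys the competitive rate law exactly at zero noise", {
  mm <- mm_params(Vmax = 1, Km = 100)
  des <- assay_design(inhibitor_concs = c(0, 5, 10.3, 20),
                      substrate_concs = c(50, 100, 200, 400),
                      noise_sd = 0, replicates = 1)
  g <- simulate_steady_state(des, mechanism_spec(mm,
    inhibition_model("competitive", 10.3)))
  # hand evaluation: S = Km, I = Ki gives Vmax/3
  expect_equal(g$v_au_per_s[g$substrate_um == 100 & g$inhibitor_um == 10.3],
               1 / 3)
  # I = 0 rows follow Michaelis-Menten
  r0 <- g[g$inhibitor_um == 0, ]
  expect_equal(r0$v_au_per_s, 1 * r0$substrate_um / (100 + r0$substrate_um))
  # double-reciprocal lines share the 1/Vmax intercept across I
  for (I in unique(g$inhibitor_um)) {
    sub <- g[g$inhibitor_um == I, ]
    fit <- lm(I(1 / v_au_per_s) ~ I(1 / substrate_um), sub)
    expect_equal(unname(coef(fit)[1]), 1, tolerance = 1e-9)
  }
})

test_that("dose-response generator is exact at zero noise and seed-dependent", {
  des <- assay_design(inhibitor_concs = c(6.2, 12.5, 25, 39.7, 50, 100),
                      replicates = 1, seed = 3)
  p <- dose_response_params(ic50 = 39.7)
  out <- simulate_dose_response(des, p, noise_pp = 0)
  expect_equal(out$inhibition_pct[out$inhibitor_um == 39.7], 50)
  expect_equal(out$inhibition_pct[out$inhibitor_um == 100], 71.6,
               tolerance = 1e-3)
  expect_identical(out$inhibition_pct, dose_response(out$inhibitor_um, p))
  a <- simulate_dose_response(assay_design(seed = 1), p)
  b <- simulate_dose_response(assay_design(seed = 2), p)
  expect_false(identical(a$inhibition_pct, b$inhibition_pct))
})

test_that("all generators attach reproducibility metadata", {
  curves <- slow_curves(seed = 5)
  g <- simulate_steady_state(velocity_design(seed = 5), slow_mechanism())
  dr <- simulate_dose_response(assay_design(seed = 5),
                               dose_response_params(39.7))
  for (x in list(curves, g, dr)) {
    meta <- attr(x, "metadata")
    expect_false(is.null(meta$design))
    expect_equal(meta$seed, 5L)
  }
})
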