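test_that("rate law reproduces hand-computed velocities and limits", {
  mm <- mm_params(Vmax = 1, Km = 100)
  # half-saturation identity holds in every mode at I = 0
  for (mode in c("competitive", "uncompetitive", "noncompetitive", "mixed")) {
    inh <- inhibition_model(mode, Ki = 10, alpha = 2)
    expect_equal(velocity(100, 0, mm, inh), 0.5)
  }
  # competitive, S = Km, I = Ki: Vmax*S/(2Km + S) = 1/3
  expect_equal(velocity(100, 10.3, mm, inhibition_model("competitive", 10.3)),
               1 / 3)
  # competitive velocity vanishes as I grows
  expect_lt(velocity(100, 1e9, mm, inhibition_model("competitive", 10)), 1e-6)
  # noncompetitive at saturating S with I = Ki halves Vmax
  expect_equal(velocity(1e12, 10, mm, inhibition_model("noncompetitive", 10)),
               0.5, tolerance = 1e-6)
})

test_that("every inhibition mode reduces to Michaelis-Menten at I = 0", {
  set.seed(42)
  for (i in 1:20) {
    mm <- mm_params(Vmax = runif(1, 0.1, 10), Km = runif(1, 10, 500))
    S <- runif(5, 1, 1000)
    for (mode in c("competitive", "uncompetitive", "noncompetitive", "mixed")) {
      inh <- inhibition_model(mode, Ki = runif(1, 1, 100),
                              alpha = runif(1, 0.2, 5))
      expect_equal(velocity(S, 0, mm, inh), mm$Vmax * S / (mm$Km + S))
    }
  }
})

test_that("parameter containers reject invalid values", {
  expect_error(mm_params(-1, 100), "Vmax")
  expect_error(mm_params(1, 0), "Km")
  expect_error(inhibition_model("competitive", -5), "Ki")
  expect_error(slow_binding_params(1, 0.5, 0), "kobs")
  expect_error(two_step_params(0, 0.0004, 35.8), "k3")
  expect_error(two_step_params(0.004, -1, 35.8), "k4")
  expect_error(dose_response_params(10, top = 0, bottom = 100), "top")
  expect_error(assay_deltas(0, 0.1), "delta_control")
  expect_error(velocity(-1, 0, mm_params(1, 100)), "nonnegative")
  expect_error(progress_value(-1, slow_binding_params(1, 0.5, 0.01)), "t must")
})

test_that("progress curve matches its closed form and boundary behaviour", {
  p <- slow_binding_params(vi = 1, vs = 0.5, kobs = 0.01)
  expect_identical(progress_value(0, p), 0)
  # independent evaluation: 50 + 50*(1 - exp(-1))
  expect_equal(progress_value(100, p), 50 + 50 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(progress_value(100, p), 81.606, tolerance = 1e-5)
  # vi = vs collapses to a straight line exactly
  pl <- slow_binding_params(vi = 0.3, vs = 0.3, kobs = 0.02)
  tt <- seq(0, 500, 25)
  expect_identical(progress_value(tt, pl), 0.3 * tt)
})

test_that("progress curve slope is vi at t -> 0 and vs at late times", {
  set.seed(7)
  for (i in 1:10) {
    p <- slow_binding_params(vi = runif(1, 0.1, 2), vs = runif(1, 0, 0.1),
                             kobs = 10^runif(1, -3, -1))
    h <- 1e-3 / p$kobs
    d0 <- (progress_value(h, p) - progress_value(0, p)) / h
    expect_equal(d0, p$vi, tolerance = 1e-3)
    t_late <- 25 / p$kobs
    slope <- (progress_value(t_late + 10, p) - progress_value(t_late, p)) / 10
    expect_equal(slope, p$vs, tolerance = 1e-6)
    # nonnegative and continuous on a dense grid
    tt <- seq(0, t_late, length.out = 200)
    vals <- progress_value(tt, p)
    expect_true(all(vals >= 0))
    expect_true(all(abs(diff(vals)) < p$vi * diff(tt)[1] * 1.01))
  }
})

test_that("kobs hyperbola has exact intercept, monotonicity and asymptote", {
  ts <- two_step_params(k3 = 0.0041, k4 = 0.0004, Kiapp = 35.8)
  expect_identical(kobs_of_I(0, ts), 0.0004)
  # half-saturation: k4 + k3/2
  expect_equal(kobs_of_I(35.8, ts), 0.00245, tolerance = 1e-12)
  I <- seq(0, 5000, length.out = 400)
  k <- kobs_of_I(I, ts)
  expect_true(all(diff(k) > 0))
  expect_true(all(k <= ts$k3 + ts$k4))
  expect_equal(kobs_of_I(1e12, ts), ts$k3 + ts$k4, tolerance = 1e-9)
})

test_that("percent inhibition is the control-normalized signal drop", {
  expect_identical(percent_inhibition(0.5, 0.5), 0)
  expect_identical(percent_inhibition(0.5, 0), 100)
  expect_equal(percent_inhibition(assay_deltas(0.5, 0.2)), 60)
  # affine in delta_inhibitor: slope -100/delta_control
  dc <- 0.8
  di <- seq(0, 0.8, 0.1)
  y <- vapply(di, function(x) percent_inhibition(dc, x), 0)
  expect_equal(diff(y) / diff(di), rep(-100 / dc, length(di) - 1))
  expect_error(percent_inhibition(0, 0.1), "delta_control")
})

test_that("log-logistic dose-response hits its midpoint and plateaus", {
  p <- dose_response_params(ic50 = 39.7)
  expect_equal(dose_response(39.7, p), 50)
  expect_identical(dose_response(0, p), 0)
  expect_equal(dose_response(3 * 39.7, p), 75)
  # independent evaluation at 100 uM: 100/(1 + 39.7/100)
  expect_equal(dose_response(100, p), 100 / 1.397, tolerance = 1e-12)
  p2 <- dose_response_params(10, hill = 2, top = 90, bottom = 10)
  expect_equal(dose_response(10, p2), 50)
  expect_identical(dose_response(0, p2), 10)
})

test_that("overall Ki* composes the two binding steps", {
  ts <- two_step_params(0.0041, 0.0004, 35.8)
  expect_equal(overall_ki_star(ts), 35.8 * 0.0004 / 0.0045, tolerance = 1e-12)
  expect_equal(overall_ki_star(ts), 3.18, tolerance = 1e-2)
  # irreversible second step drives the overall constant to zero
  expect_identical(overall_ki_star(two_step_params(0.01, 0, 20)), 0)
  # vanishing isomerization leaves the first-step constant
  expect_equal(overall_ki_star(two_step_params(1e-12, 0.01, 20)), 20,
               tolerance = 1e-6)
})

test_that("apparent Ki scales with substrate competition", {
  expect_equal(kiapp_from_ki(10, 0, 200), 10)
  expect_equal(kiapp_from_ki(12.45, 375, 200), 12.45 * 2.875)
  # consistency with the curve-parameter mapping at I = 0: linear curve
  mm <- mm_params(1, 200)
  p0 <- slow_binding_params_for(0, 375, mm, two_step_params(0.004, 4e-4, 35.8))
  expect_equal(p0$vi, p0$vs)
  expect_equal(p0$vi, velocity(375, 0, mm))
})
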