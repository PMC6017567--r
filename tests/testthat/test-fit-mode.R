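test_that("noiseless grids are classified and Ki recovered to precision", {
  g <- noiseless_grid(10.3)
  mc <- classify_mode(g)
  expect_equal(mc$mode, "competitive")
  expect_equal(mc$Ki, 10.3, tolerance = 1e-6)
  gn <- noiseless_grid(20, mode = "noncompetitive")
  expect_equal(classify_mode(gn)$mode, "noncompetitive")
  gu <- noiseless_grid(15, mode = "uncompetitive")
  expect_equal(classify_mode(gu)$mode, "uncompetitive")
  gm <- noiseless_grid(15, mode = "mixed", alpha = 4)
  mcm <- classify_mode(gm)
  expect_equal(mcm$mode, "mixed")
  expect_equal(mcm$alpha, 4, tolerance = 1e-4)
})

test_that("classification needs a non-singular design", {
  des <- assay_design(inhibitor_concs = c(0, 10, 20), substrate_concs = 100,
                      noise_sd = 0, replicates = 1)
  g <- simulate_steady_state(des, mechanism_spec(tyr_mm(),
    inhibition_model("competitive", 10)))
  expect_error(classify_mode(g), "singular")
})

test_that("mode call is invariant to velocity rescaling and unit changes", {
  g <- noiseless_grid(10.3)
  ref <- classify_mode(g)
  g2 <- g; g2$v_au_per_s <- g2$v_au_per_s * 7.3
  sc <- classify_mode(g2)
  expect_equal(sc$mode, ref$mode)
  expect_equal(sc$Ki, ref$Ki, tolerance = 1e-6)
  # concentrations expressed in nM scale Ki by the same factor
  g3 <- g; g3$substrate_um <- g3$substrate_um * 1000
  g3$inhibitor_um <- g3$inhibitor_um * 1000
  un <- classify_mode(g3)
  expect_equal(un$mode, ref$mode)
  expect_equal(un$Ki, ref$Ki * 1000, tolerance = 1e-6)
})

test_that("Lineweaver-Burk diagnostics report a common intercept when competitive", {
  g <- noiseless_grid(10.3)
  mc <- classify_mode(g)
  lb <- mc$lineweaver_burk$per_inhibitor
  # all double-reciprocal intercepts equal 1/Vmax
  expect_equal(lb$intercept, rep(1 / tyr_mm()$Vmax, nrow(lb)), tolerance = 1e-9)
  # slopes increase with inhibitor (Km apparent grows)
  expect_true(all(diff(lb$slope[order(lb$inhibitor_um)]) > 0))
})

test_that("competitive mode survives 2% noise in most runs", {
  calls <- vapply(1:100, function(s) {
    g <- simulate_steady_state(
      velocity_design(noise_sd = 0.02, replicates = 3, seed = s),
      mechanism_spec(tyr_mm(), inhibition_model("competitive", 10.3)))
    classify_mode(g)$mode
  }, "")
  expect_gte(mean(calls == "competitive"), 0.9)
})

test_that("Dixon analysis finds the intersection at -Ki", {
  g <- noiseless_grid(10.3)
  d <- dixon_ki(g)
  expect_equal(d$Ki, 10.3, tolerance = 1e-6)
  expect_true(all(abs(d$intersections - 10.3) < 1e-5))
  # algebraic equivalence with the global competitive fit at zero noise
  expect_equal(d$Ki, d$global_Ki, tolerance = 1e-6)
  g8 <- noiseless_grid(44.2)
  expect_equal(dixon_ki(g8)$Ki, 44.2, tolerance = 1e-6)
})

test_that("Dixon estimate ignores the velocity scale", {
  g <- noiseless_grid(10.3)
  g$v_au_per_s <- g$v_au_per_s * 123.4
  expect_equal(dixon_ki(g)$Ki, 10.3, tolerance = 1e-6)
})

test_that("parallel Dixon lines (uncompetitive pattern) are an error", {
  gu <- noiseless_grid(15, mode = "uncompetitive")
  expect_error(dixon_ki(gu), "parallel|undefined")
  g <- noiseless_grid(10.3)
  expect_error(dixon_ki(g[g$inhibitor_um %in% c(0, 12.5), ]), "3 distinct")
})
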