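test_that("conv_exp reproduces closed-form convolutions", {
  dt <- 1 / 120
  tt <- seq(0, 5, by = dt)
  # ramp input against exp(-beta t): t/b - (1 - e^{-bt})/b^2
  for (beta in c(0.05, 0.7, 12)) {
    y <- petkin:::conv_exp(tt, dt, beta)
    ya <- tt / beta - (1 - exp(-beta * tt)) / beta^2
    # roundoff accumulates over the 600-step recursion; values reach ~1e2
    expect_lt(max(abs(y - ya)), 1e-10)
  }
  # beta = 0 limit is the running integral
  y0 <- petkin:::conv_exp(tt, dt, 0)
  expect_equal(y0, tt^2 / 2, tolerance = 1e-10)
})

test_that("macro parameters follow the distribution-volume algebra", {
  # fixed rates of the simulation grid
  p <- micro_params(0.8, 2.25, 0.20, 0.17, 0.15, 0.08)
  m <- macro_from_micro(p)
  expect_equal(signif(m$VT, 3), 1.44)
  p2 <- micro_params(0.8, 2.25, 1.70, 0.17, 0.15, 0.08)
  expect_equal(signif(macro_from_micro(p2)$BPND, 3), 10.0)
  # 1T reduction: no binding branches
  p1 <- micro_params(0.8, 2.25)
  expect_equal(macro_from_micro(p1)$VT, 0.8 / 2.25)
  expect_null(macro_from_micro(p1)$BPND)
  expect_error(macro_from_micro(micro_params(0.8, 2.25, 0.2, 0)), "k4")
})

test_that("dvr_minus_one matches the published reference ratios", {
  expect_equal(dvr_minus_one(1.44, 1.44), 0)
  expect_equal(round(dvr_minus_one(2.06, 1.44), 2), 0.43)
  expect_equal(round(dvr_minus_one(6.46, 1.44), 2), 3.49, tolerance = 0.01)
  expect_error(dvr_minus_one(2, 0), "positive")
})

test_that("VT is strictly increasing in k3 over the grid", {
  expect_true(all(diff(fx$grid$theory$VT) > 0))
  expect_true(all(diff(fx$grid$theory$BPND) > 0))
})

test_that("model_tac is linear in the input and handles edge configurations", {
  sch <- fx$schedule
  p <- micro_params(0.8, 2.25, 0.5, 0.17, vB = 0.05)
  zero <- sampled_curve(c(0, 30, 60), c(0, 0, 0), "plasma_parent")
  expect_equal(model_tac(p, zero, zero, sch)$values, rep(0, 21))
  # vB = 1, K1 = 0: pure blood voxel equals frame-averaged whole blood
  pb <- micro_params(0, 1, vB = 1)
  tac_b <- model_tac(pb, fx$input$plasma_parent, fx$input$whole_blood, sch)
  W <- petkin:::frame_average_matrix(sch)
  cb <- evaluate_curve(fx$input$whole_blood, petkin:::fine_grid(sch))
  expect_equal(tac_b$values, as.numeric(W %*% cb), tolerance = 1e-12)
  # linearity: scaling both inputs scales the TAC
  inp2 <- lapply(fx$input[c("plasma_parent", "whole_blood")], function(cv) {
    sampled_curve(cv$times, 3 * cv$values, cv$kind)
  })
  t1 <- model_tac(p, fx$input$plasma_parent, fx$input$whole_blood, sch)
  t3 <- model_tac(p, inp2$plasma_parent, inp2$whole_blood, sch)
  expect_equal(t3$values, 3 * t1$values, tolerance = 1e-12)
})

test_that("a 2T model with k3 = 0 collapses to the 1T model", {
  sch <- fx$schedule
  p1 <- micro_params(0.8, 2.25, vB = 0.05)
  p2 <- micro_params(0.8, 2.25, 0, 0.17, vB = 0.05)
  t1 <- model_tac(p1, fx$input$plasma_parent, fx$input$whole_blood, sch)
  t2 <- model_tac(p2, fx$input$plasma_parent, fx$input$whole_blood, sch)
  expect_lt(max(abs(t1$values - t2$values)), 1e-10)
})

test_that("the 3T forward model matches a stiff ODE integration", {
  skip_if_not_installed("deSolve")
  p <- fx$grid$configs[[6]]              # k3 = 0.95
  sch <- fx$schedule
  tac <- fx_tac(6)
  cpf <- approxfun(fx$input$plasma_parent$times,
                   fx$input$plasma_parent$values, yleft = 0, rule = 2)
  rhs <- function(t, y, parms) {
    list(c(p$K1 * cpf(t) - (p$k2 + p$k3 + p$k5) * y[1] +
             p$k4 * y[2] + p$k6 * y[3],
           p$k3 * y[1] - p$k4 * y[2],
           p$k5 * y[1] - p$k6 * y[3]))
  }
  t_fine <- petkin:::fine_grid(sch)
  sol <- deSolve::ode(c(0, 0, 0), t_fine, rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  ct <- rowSums(sol[, 2:4])
  cb <- evaluate_curve(fx$input$whole_blood, t_fine)
  pet <- (1 - p$vB) * ct + p$vB * cb
  W <- petkin:::frame_average_matrix(sch)
  frames_ode <- as.numeric(W %*% pet)
  expect_lt(max(abs(tac$values[-1] - frames_ode[-1]) / frames_ode[-1]),
            1e-6)
})

test_that("impulse-response integral reproduces VT for every grid row (equilibrium check)", {
  for (i in seq_along(fx$grid$configs)) {
    h <- petkin:::tissue_impulse(fx$grid$configs[[i]])
    # integral_0^inf h = sum phi/theta equals VT
    expect_equal(sum(h$phi / h$theta), fx$grid$theory$VT[i],
                 tolerance = 1e-3)
  }
})

test_that("degenerate eigenvalues are handled by the limit path, not failure", {
  # k3 = 0, k2 = k4 makes the 2T system defective
  p <- micro_params(0.5, 0.3, 0, 0.3, vB = 0)
  tac <- model_tac(p, fx$input$plasma_parent, NULL, fx$schedule)
  p1 <- micro_params(0.5, 0.3, vB = 0)
  tac1 <- model_tac(p1, fx$input$plasma_parent, NULL, fx$schedule)
  expect_equal(tac$values, tac1$values, tolerance = 1e-6)
})
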