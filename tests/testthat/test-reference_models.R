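# Reference-model fits are exercised against TACs generated with the
# packaged plasma input; the k3 = 0.20 grid configuration plays the
# pseudo-reference region throughout.

test_that("all three reference models return BPND ~ 0 for target == reference", {
  ref <- fx_tac(1)
  fs <- fit_srtm(ref, ref, fx$schedule, fx$config)
  expect_lt(abs(fs$BPND), 1e-6)
  expect_equal(fs$R1, 1, tolerance = 1e-6)
  ff <- fit_frtm(ref, ref, fx$schedule, fx$config)
  expect_lt(abs(ff$BPND), 0.01)
  expect_equal(ff$R1, 1, tolerance = 0.01)
  f2 <- fit_srtm_2c(ref, ref, fx$schedule, fx$config)
  expect_lt(abs(f2$BPND), 0.01)
  expect_equal(f2$R1, 1, tolerance = 0.01)
})

test_that("SRTM recovers BPND generatively when its assumptions hold", {
  # target and reference both 1T, sharing K1/k2; true BPND = 2 by k2a
  # construction (target k2a = k2_target / (1 + BPND))
  pref <- micro_params(0.8, 0.4, vB = 0)
  ptgt <- micro_params(0.96, 0.16, vB = 0)   # R1 = 1.2, k2 = 0.48, BP = 2
  cr <- model_tac(pref, fx$input$plasma_parent, NULL, fx$schedule)
  ct <- model_tac(ptgt, fx$input$plasma_parent, NULL, fx$schedule)
  f <- fit_srtm(ct, cr, fx$schedule, fx$config)
  expect_lt(abs(f$BPND / 2 - 1), 0.02)
  expect_lt(abs(f$R1 / 1.2 - 1), 0.01)
})

test_that("SRTM basis solution matches direct nonlinear optimization", {
  set.seed(31)
  for (rep in 1:4) {
    pref <- micro_params(runif(1, 0.4, 1), runif(1, 0.2, 0.8), vB = 0)
    cr <- model_tac(pref, fx$input$plasma_parent, NULL, fx$schedule)
    R1 <- runif(1, 0.7, 1.3)
    BP <- runif(1, 0.5, 4)
    k2 <- R1 * pref$k2
    ptgt <- micro_params(R1 * pref$K1, k2 / (1 + BP), vB = 0)
    ct <- model_tac(ptgt, fx$input$plasma_parent, NULL, fx$schedule)
    f <- fit_srtm(ct, cr, fx$schedule, fx$config)
    # independent route: direct 3-parameter NLS of the same objective
    ctx <- petkin:::ref_context(ct, cr, fx$schedule)
    obj <- function(p) {
      b <- petkin:::frame_average(
        petkin:::conv_exp(ctx$cr_fine, ctx$dt, p[3]), ctx$W)
      sum((p[1] * ctx$cr + (p[2] - p[1] * p[3]) * b - ctx$y)^2)
    }
    direct <- optim(c(1, 0.3, 0.2), obj, method = "L-BFGS-B",
                    lower = c(0.1, 1e-3, 1e-3), upper = c(5, 5, 5),
                    control = list(factr = 1e4, maxit = 500))
    bp_direct <- direct$par[2] / direct$par[3] - 1
    expect_lt(abs(f$BPND - bp_direct) / max(abs(bp_direct), 1), 0.005)
  }
})

test_that("FRTM recovers its own forward parameters noiselessly", {
  ref <- fx_tac(1)
  ctx <- petkin:::ref_context(ref, ref, fx$schedule)
  truth <- c(R1 = 0.9, k2 = 0.3, k3 = 0.2, BPND = 2.0)
  y <- petkin:::frtm_curve(truth, ctx)
  tgt <- sampled_curve(fx$schedule$mid_min, y, "tissue")
  f <- fit_frtm(tgt, ref, fx$schedule, fx$config)
  expect_lt(max(abs(f$pars / truth - 1)), 0.02)
})

test_that("the FRTM forward curve agrees with plasma-driven generation", {
  # dual route: generate reference (1T) and target (2T) from the same
  # plasma with K1/k2_ND matched, then check the reference-only closed form
  # reproduces the target TAC
  R1 <- 0.85
  k2 <- 0.6; k3 <- 0.25; k4 <- 0.12
  pref <- micro_params(0.5, k2 / R1, vB = 0)
  ptgt <- micro_params(0.5 * R1, k2, k3, k4, vB = 0)
  cr <- model_tac(pref, fx$input$plasma_parent, NULL, fx$schedule)
  ct <- model_tac(ptgt, fx$input$plasma_parent, NULL, fx$schedule)
  ctx <- petkin:::ref_context(ct, cr, fx$schedule)
  y_frtm <- petkin:::frtm_curve(c(R1, k2, k3, k3 / k4), ctx)
  # the residual reflects reconstructing the reference curve from its 21
  # frame averages, not the algebra
  expect_lt(max(abs(y_frtm - ct$values)) / max(ct$values), 0.005)
})

test_that("SRTM-2C collapses to SRTM when the reference is truly one-tissue", {
  pref <- micro_params(0.8, 0.4, vB = 0)
  ptgt <- micro_params(0.96, 0.16, vB = 0)
  cr <- model_tac(pref, fx$input$plasma_parent, NULL, fx$schedule)
  ct <- model_tac(ptgt, fx$input$plasma_parent, NULL, fx$schedule)
  fs <- fit_srtm(ct, cr, fx$schedule, fx$config)
  f2 <- fit_srtm_2c(ct, cr, fx$schedule, fx$config)
  expect_lt(abs(f2$BPND / fs$BPND - 1), 0.02)
})

test_that("reference models underestimate BPND against a binding-contaminated reference", {
  ref <- fx_tac(1)
  for (i in c(6, 17)) {
    truth <- fx$grid$theory$DVR_minus_1[i]
    tgt <- fx_tac(i)
    expect_lt(fit_srtm(tgt, ref, fx$schedule, fx$config)$BPND, truth)
    expect_lt(fit_frtm(tgt, ref, fx$schedule, fx$config)$BPND, truth)
    expect_lt(fit_srtm_2c(tgt, ref, fx$schedule, fx$config)$BPND, truth)
  }
})

test_that("SRTM-2C improves on SRTM for the high-binding target", {
  ref <- fx_tac(1)
  tgt <- fx_tac(17)
  truth <- fx$grid$theory$DVR_minus_1[17]
  fs <- fit_srtm(tgt, ref, fx$schedule, fx$config)
  f2 <- fit_srtm_2c(tgt, ref, fx$schedule, fx$config)
  expect_lt(abs(f2$BPND - truth), abs(fs$BPND - truth))
})
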