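test_that("AIC follows the least-squares formula", {
  expect_equal(aic_rss(21, 21, 2), 4)                     # log term vanishes
  expect_equal(aic_rss(0.42, 21, 4), 21 * log(0.42 / 21) + 2 * 4,
               tolerance = 1e-12)
  expect_identical(aic_rss(1, 10, 2), aic_rss(1, 10, 2))
  perfect <- aic_rss(0, 21, 2)
  expect_identical(unclass(perfect)[1], -Inf)
  expect_true(attr(perfect, "perfect_fit"))
  expect_error(aic_rss(1, 4, 4), "n_free")
})

test_that("noiseless 1T TAC is recovered exactly by the 1T fit", {
  p <- micro_params(0.8, 2.25, vB = 0.05)
  tac <- model_tac(p, fx$input$plasma_parent, fx$input$whole_blood,
                   fx$schedule)
  f <- fit_compartment_model(tac, fx$input$plasma_parent,
                             fx$input$whole_blood, fx$schedule, "1T",
                             fx$config)
  expect_lt(abs(f$params$K1 / 0.8 - 1), 1e-3)
  expect_lt(abs(f$params$k2 / 2.25 - 1), 1e-3)
  expect_lt(f$rss, 1e-10)
})

test_that("randomized noiseless self-recovery holds across parameter draws", {
  set.seed(20)
  for (rep in 1:6) {
    K1 <- runif(1, 0.2, 1.5)
    k2 <- runif(1, 0.3, 3)
    k3 <- runif(1, 0.05, 1.5)
    k4 <- runif(1, 0.05, 0.5)
    p <- micro_params(K1, k2, k3, k4, vB = 0.05)
    tac <- model_tac(p, fx$input$plasma_parent, fx$input$whole_blood,
                     fx$schedule)
    f <- fit_compartment_model(tac, fx$input$plasma_parent,
                               fx$input$whole_blood, fx$schedule, "2T",
                               fx$config)
    expect_lt(f$rss, 1e-8)
    expect_lt(abs(f$macro$VT / macro_from_micro(p)$VT - 1), 0.005)
  }
})

test_that("adding a compartment never increases noiseless RSS (nested models)", {
  for (i in c(1, 9, 17)) {
    tac <- fx_tac(i)
    f1 <- fit_compartment_model(tac, fx$input$plasma_parent,
                                fx$input$whole_blood, fx$schedule, "1T",
                                fx$config)
    f2 <- fit_compartment_model(tac, fx$input$plasma_parent,
                                fx$input$whole_blood, fx$schedule, "2T",
                                fx$config)
    expect_lte(f2$rss, f1$rss * (1 + 1e-9))
    # 2T is preferred by AIC on every 3T-generated noiseless TAC
    expect_lt(f2$aic, f1$aic)
  }
})

test_that("1T underestimates VT on low-binding 3T TACs", {
  tac <- fx_tac(1)                       # k3 = 0.20, the pseudo-reference
  f1 <- fit_compartment_model(tac, fx$input$plasma_parent,
                              fx$input$whole_blood, fx$schedule, "1T",
                              fx$config)
  f2 <- fit_compartment_model(tac, fx$input$plasma_parent,
                              fx$input$whole_blood, fx$schedule, "2T",
                              fx$config)
  expect_lt(f1$macro$VT, f2$macro$VT)
  expect_lt(f1$macro$VT, fx$grid$theory$VT[1])
})

test_that("blood delay is recovered from a known input shift", {
  p <- micro_params(0.8, 2.25, 0.5, 0.17, vB = 0.05)
  cfg <- fx$config_fast
  tac0 <- model_tac(p, fx$input$plasma_parent, fx$input$whole_blood,
                    fx$schedule)
  d0 <- estimate_blood_delay(tac0, fx$input$plasma_parent,
                             fx$input$whole_blood, fx$schedule, cfg)
  expect_lt(abs(d0), 0.01)
  tac <- model_tac(p, fx$input$plasma_parent, fx$input$whole_blood,
                   fx$schedule, delay = 0.1)
  d <- estimate_blood_delay(tac, fx$input$plasma_parent,
                            fx$input$whole_blood, fx$schedule, cfg)
  expect_lt(abs(d - 0.1), 0.01)
  expect_false(attr(d, "at_bound"))
})

test_that("model_preference tallies AIC winners per region", {
  fits <- data.frame(
    region = rep(c("pons", "cortex"), each = 20),
    subject = rep(rep(1:10, each = 2), 2),
    model = rep(c("1TCM", "2TCM"), 20),
    aic = c(rbind(rep(5, 10), rep(3, 10)),          # pons: all favor 2T
            rbind(c(rep(1, 7), rep(9, 3)), rep(4, 10))), # cortex: 7/10 1T
    n_free = rep(c(2, 4), 20))
  pref <- model_preference(fits)
  pons <- pref[pref$region == "pons", ]
  cortex <- pref[pref$region == "cortex", ]
  expect_equal(pons$pct_2TCM, 100)
  expect_equal(cortex$pct_1TCM, 70)
  # independent tally oracle
  oracle <- with(fits[fits$region == "cortex", ], {
    a <- aic[model == "1TCM"]; b <- aic[model == "2TCM"]
    100 * mean(a < b)
  })
  expect_equal(cortex$pct_1TCM, oracle)
  # exact ties go to the simpler model
  tie <- data.frame(region = "r", subject = rep(1:2, each = 2),
                    model = rep(c("1TCM", "2TCM"), 2), aic = rep(7, 4),
                    n_free = rep(c(2, 4), 2))
  expect_equal(model_preference(tie)$pct_1TCM, 100)
  # mismatched pairs are rejected
  bad <- fits[-1, ]
  expect_error(model_preference(bad), "mismatched")
})

test_that("regional fits share the fixed whole-brain delay", {
  # the fixed-delay contract: the delay passed in is stored untouched
  p <- micro_params(0.8, 2.25, vB = 0.05)
  tac <- model_tac(p, fx$input$plasma_parent, fx$input$whole_blood,
                   fx$schedule, delay = 0.07)
  f_a <- fit_compartment_model(tac, fx$input$plasma_parent,
                               fx$input$whole_blood, fx$schedule, "1T",
                               fx$config_fast, delay = 0.07)
  f_b <- fit_compartment_model(fx_tac(3), fx$input$plasma_parent,
                               fx$input$whole_blood, fx$schedule, "2T",
                               fx$config_fast, delay = 0.07)
  expect_identical(f_a$delay, f_b$delay)
})
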