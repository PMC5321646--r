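test_that("sampled_curve validates its invariants", {
  expect_error(sampled_curve(numeric(0), numeric(0)), "empty")
  expect_error(sampled_curve(c(1, 1), c(0, 0)), "increasing")
  expect_error(sampled_curve(c(1, 2), c(0, Inf)), "finite")
  expect_error(sampled_curve(c(1, 2), c(0.5, 1.5), kind = "fraction"),
               "fraction")
  cv <- sampled_curve(c(0, 1, 2), c(0, 5, 3))
  expect_s3_class(cv, "sampled_curve")
})

test_that("evaluate_curve follows the interpolation contract", {
  cv <- sampled_curve(c(1, 2, 4), c(10, 20, 0))
  # zero before the first sample, exact at samples, hold after the last
  expect_equal(evaluate_curve(cv, 0.5), 0)
  expect_equal(evaluate_curve(cv, c(1, 2, 4)), c(10, 20, 0))
  expect_equal(evaluate_curve(cv, 3), 10)      # linear between 2 and 4
  expect_equal(evaluate_curve(cv, 100), 0)     # hold last value
  # shift-equivariance in delay
  tq <- seq(0, 6, by = 0.25)
  expect_equal(evaluate_curve(cv, tq, delay = 0.7),
               evaluate_curve(cv, tq - 0.7, delay = 0))
  expect_error(evaluate_curve(cv, 1, delay = NaN), "finite")
})

test_that("evaluate_curve matches an analytic input within the interpolation bound", {
  # curve sampled from a smooth analytic bolus at 1-s spacing; linear
  # interpolation error is bounded by max|f''| h^2 / 8
  f <- function(t) t * exp(-1.5 * t)
  h <- 1 / 60
  tt <- seq(0, 10, by = h)
  cv <- sampled_curve(tt, f(tt))
  set.seed(11)
  tq <- runif(10001, 0, 10)
  err <- abs(evaluate_curve(cv, tq) - f(tq))
  # |f''| = |(2.25 t - 3) e^{-1.5t}| <= 3
  expect_lt(max(err), 3 * h^2 / 8)
})

test_that("parent-fraction fit recovers a noiseless single exponential", {
  tt <- c(5, 10, 15, 30, 45, 60)
  f <- function(t) 0.2 + 0.8 * exp(-0.05 * t)
  m <- fit_parent_fraction(sampled_curve(tt, f(tt), kind = "fraction"))
  expect_equal(m$offset, 0.2, tolerance = 1e-6)
  expect_equal(m$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(m$rate, 0.05, tolerance = 1e-6)
  expect_equal(predict_parent_fraction(m, tt), f(tt), tolerance = 1e-6)
})

test_that("constant parent fraction of 1 fits as no metabolism", {
  m <- fit_parent_fraction(sampled_curve(c(5, 30, 60), c(1, 1, 1),
                                         kind = "fraction"))
  expect_equal(predict_parent_fraction(m, c(1, 30, 59)), c(1, 1, 1),
               tolerance = 1e-8)
})

test_that("parent-fraction fit beats a brute-force grid search", {
  samples <- sampled_curve(c(5, 30, 60), c(0.9, 0.5, 0.3),
                           kind = "fraction")
  m <- fit_parent_fraction(samples)
  # independent oracle: exhaustive 50^3 grid over (offset, amplitude, rate)
  offs <- seq(0, 1, length.out = 50)
  amps <- seq(0, 1, length.out = 50)
  rates <- seq(0, 0.2, length.out = 50)
  gr <- expand.grid(off = offs, amp = amps, rate = rates)
  E <- exp(-outer(gr$rate, samples$times))          # 125000 x 3
  pred <- gr$off + gr$amp * E
  rss_grid <- rowSums((pred - rep(samples$values, each = nrow(gr)))^2)
  expect_lte(m$rss, min(rss_grid) + 1e-12)
})

test_that("parent-fraction fit rejects insufficient data", {
  expect_error(fit_parent_fraction(sampled_curve(c(5, 30), c(0.9, 0.5),
                                                 kind = "fraction")),
               "insufficient")
})

test_that("metabolite correction is a pointwise product and never increases plasma", {
  inp <- fx$input
  m <- inp$parent_fraction
  corrected <- apply_metabolite_correction(inp$plasma_total, m)
  expect_identical(corrected$kind, "plasma_parent")
  expect_equal(corrected$times, inp$plasma_total$times)
  f <- predict_parent_fraction(m, inp$plasma_total$times)
  expect_equal(corrected$values, inp$plasma_total$values * f,
               tolerance = 1e-12)
  expect_true(all(corrected$values <= inp$plasma_total$values + 1e-12))
  # identity fraction leaves the curve unchanged
  one <- structure(list(offset = 1, amplitude = 0, rate = 0, rss = 0),
                   class = "parent_fraction_model")
  same <- apply_metabolite_correction(inp$plasma_total, one)
  expect_equal(same$values, inp$plasma_total$values)
  # kind mismatch is a type error
  expect_error(apply_metabolite_correction(inp$whole_blood, m), "kind")
})

test_that("curve CSV/TSV and PMOD-style .tac round-trips work", {
  cv <- sampled_curve(c(0, 1, 2.5), c(0, 4.2, 1.1), kind = "plasma_total")
  p <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, p)
  back <- read_curve(p)
  expect_equal(back$times, cv$times)
  expect_equal(back$values, cv$values)
  expect_identical(back$kind, "plasma_total")

  tacfile <- withr::local_tempfile(fileext = ".tac")
  writeLines(c("time frontal pons",
               "0.25 1.2 0.8",
               "1.0 5.5 2.2",
               "2.0 4.1 2.0"), tacfile)
  tl <- read_tac_table(tacfile)
  expect_named(tl, c("frontal", "pons"))
  expect_equal(tl$pons$values, c(0.8, 2.2, 2.0))
})
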