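test_that("an exponential sample recovers shape 1 within its CI", {
  set.seed(60)
  fit <- fit_weibull(rexp(2000, rate = 1 / 20))
  expect_gt(1, fit$shape_ci[1])
  expect_lt(1, fit$shape_ci[2])
  expect_equal(fit$scale, 20, tolerance = 0.1)
  expect_equal(fit$failure_type, "random")
})

test_that("the MLE beats every point on a surrounding parameter grid", {
  set.seed(61)
  d <- rweibull(300, shape = 0.7, scale = 24)
  fit <- fit_weibull(d)
  ll <- function(sh, sc) sum(dweibull(d, sh, sc, log = TRUE))
  grid <- expand.grid(sh = fit$shape * seq(0.8, 1.2, length.out = 50),
                      sc = fit$scale * seq(0.8, 1.2, length.out = 50))
  grid_ll <- mapply(ll, grid$sh, grid$sc)
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
})

test_that("the fit agrees with an independent distribution fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(62)
  d <- rweibull(500, shape = 0.8, scale = 18)
  fit <- fit_weibull(d)
  ref <- fitdistrplus::fitdist(d, "weibull")
  expect_equal(unname(coef(fit)["shape"]), unname(ref$estimate["shape"]),
               tolerance = 1e-4)
  expect_equal(unname(coef(fit)["scale"]), unname(ref$estimate["scale"]),
               tolerance = 1e-4)
})

test_that("zero-day onsets are shifted for the likelihood only", {
  set.seed(63)
  d <- c(rep(0, 40), round(rweibull(200, 0.7, 24)))
  d <- d[d >= 0]
  fit <- fit_weibull(d)
  expect_s3_class(fit, "weibull_tto")
  expect_gt(fit$scale, 0)
  # binning and summaries see the raw zeros
  expect_gte(unname(bin_tto(d)["0-30"]), 40)
  # interval-censored alternative also fits
  fit2 <- fit_weibull(d, zero_handling = "interval")
  expect_equal(fit2$shape, fit$shape, tolerance = 0.15)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_weibull(c(1, 2, 3)), "at least 10")
  expect_error(fit_weibull(rep(5, 50)), "identical")
})

test_that("failure classification follows the shape-CI rule", {
  expect_equal(classify_failure(0.70, ci = c(0.64, 0.76)), "early")
  expect_equal(classify_failure(1.0, ci = c(0.9, 1.1)), "random")
  expect_equal(classify_failure(1.8, ci = c(1.5, 2.2)), "wear_out")
  expect_message(ind <- classify_failure(1.4, ci = c(0.9, 2.2)), "indeterminate")
  expect_equal(ind, "indeterminate")
  expect_error(classify_failure(0.7), "CI")
})

test_that("model-object methods are coherent", {
  set.seed(64)
  fit <- fit_weibull(rweibull(200, 0.9, 15))
  expect_named(coef(fit), c("scale", "shape"))
  ci <- confint(fit)
  expect_true(ci["scale", "lower"] < fit$scale &&
                fit$scale < ci["scale", "upper"])
  expect_true(ci["shape", "lower"] < fit$shape &&
                fit$shape < ci["shape", "upper"])
  expect_equal(attr(logLik(fit), "nobs"), fit$n)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_length(sims[[1]], fit$n)
  expect_output(print(fit), "failure type")
})

test_that("parameter recovery at the published design size is nearly unbiased", {
  # 100 seeded replicates at n = 394 from shape 0.70, scale 23.88
  shapes <- scales <- numeric(100)
  for (i in 1:100) {
    set.seed(1000 + i)
    f <- fit_weibull(rweibull(394, shape = 0.70, scale = 23.88))
    shapes[i] <- f$shape; scales[i] <- f$scale
  }
  expect_lt(abs(median(shapes) - 0.70) / 0.70, 0.05)
  expect_lt(abs(median(scales) - 23.88) / 23.88, 0.05)
})
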