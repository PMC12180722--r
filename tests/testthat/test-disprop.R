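t_ref <- contingency_table(10, 90, 100, 9900)

test_that("ROR point estimate and Wald interval match the closed form", {
  r <- ror_estimate(t_ref)
  expect_equal(r$ror, 11.0)
  # frozen from an independent evaluation of the log-variance formula:
  # exp(log(11) -/+ 1.96*sqrt(1/10 + 1/90 + 1/100 + 1/9900))
  expect_equal(r$ror_lo, 5.559515, tolerance = 1e-6)
  expect_equal(r$ror_hi, 21.764486, tolerance = 1e-6)
  expect_false(r$corrected)
  sym <- ror_estimate(contingency_table(25, 25, 25, 25))
  expect_equal(sym$ror, 1.0)
  expect_lt(sym$ror_lo, 1); expect_gt(sym$ror_hi, 1)
})

test_that("PRR matches its definition and sits below ROR when ROR > 1", {
  p <- prr_estimate(t_ref)
  expect_equal(p$prr, 10.0)
  expect_equal(prr_estimate(contingency_table(25, 25, 25, 25))$prr, 1.0)
  set.seed(77)
  tabs <- random_tables(500)
  r <- ror_estimate(tabs); p <- prr_estimate(tabs)
  up <- r$ror > 1
  expect_true(all(p$prr[up] <= r$ror[up] + 1e-12))
})

test_that("zero cells trigger the Haldane correction with a flag", {
  z <- contingency_table(0, 10, 5, 100)
  r <- ror_estimate(z)
  expect_true(r$corrected)
  expect_equal(r$ror, (0.5 * 100.5) / (10.5 * 5.5))
  expect_true(prr_estimate(z)$corrected)
  # a corrected estimate converges to the uncorrected one as all cells grow
  base <- c(a = 2, b = 7, c = 5, d = 30)
  rel_err <- vapply(c(1, 10, 100, 1000), function(k) {
    cells <- base * k
    corrected <- ((cells["a"] + 0.5) * (cells["d"] + 0.5)) /
      ((cells["b"] + 0.5) * (cells["c"] + 0.5))
    uncorrected <- ror_estimate(as.list(cells))$ror
    abs(corrected / uncorrected - 1)
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[4], 1e-3)
})

test_that("Yates chi-square equals the cellwise continuity-corrected sum", {
  expect_equal(chi_square_yates(t_ref), 66.32694, tolerance = 1e-6)
  expect_equal(chi_square_yates(contingency_table(25, 25, 25, 25)), 0)
  expect_error(chi_square_yates(contingency_table(0, 0, 5, 5)), "marginal")
  set.seed(78)
  tabs <- random_tables(200, max_cell = 400)
  cellwise <- vapply(seq_len(nrow(tabs)), function(i) {
    o <- unlist(tabs[i, ]); n <- sum(o)
    e <- c((o[1] + o[2]) * (o[1] + o[3]), (o[1] + o[2]) * (o[2] + o[4]),
           (o[3] + o[4]) * (o[1] + o[3]), (o[3] + o[4]) * (o[2] + o[4])) / n
    sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  }, numeric(1))
  expect_equal(chi_square_yates(tabs), cellwise, tolerance = 1e-10)
})

test_that("information component applies 0.5 shrinkage with the closed-form IC025", {
  ic <- information_component(t_ref)
  expect_equal(ic$ic, 2.724099, tolerance = 1e-6)   # log2(10.5/(E+0.5)), E=1.0891
  expect_equal(ic$ic025, 1.617302, tolerance = 1e-6)
  # a == E exactly gives IC = 0
  k <- list(a = 4, b = 16, c = 16, d = 64)  # E = 20*20/100 = 4 = a
  expect_equal(information_component(k)$ic, 0)
  # a = 0: shrunk IC finite, IC025 sentinel -Inf
  z <- information_component(list(a = 0, b = 10, c = 5, d = 100))
  expect_true(is.finite(z$ic))
  expect_identical(z$ic025, -Inf)
})

test_that("shrinkage pulls |IC| below |log2(a/E)|", {
  set.seed(79)
  tabs <- random_tables(500)
  keep <- tabs$a >= 1
  tabs <- tabs[keep, ]
  e <- with(tabs, (a + b) * (a + c) / (a + b + c + d))
  ic <- information_component(tabs)$ic
  expect_true(all(abs(ic) <= abs(log2(tabs$a / e)) + 1e-12))
})

test_that("the Bate variant gives an interval no wider than its expectation allows", {
  b <- information_component(t_ref, variant = "bate")
  expect_lt(b$ic025, b$ic)
  expect_gt(b$ic, 0)
})

test_that("joint criteria gate on a >= 3 and combine per mode", {
  m <- signal_metrics(contingency_table(2, 8, 10, 980))
  expect_false(evaluate_signal(m, "all")$is_signal)
  expect_false(evaluate_signal(m, "any")$is_signal)   # a = 2 fails the gate

  strong <- signal_metrics(contingency_table(30, 70, 50, 9850))
  expect_true(all(evaluate_signal(strong, "all")$flags))
  expect_true(evaluate_signal(strong, "all")$is_signal)
  expect_true(evaluate_signal(strong, "any")$is_signal)

  # exactly one sub-criterion true -> any yes, all no
  fake <- list(n_cases = 5, ror_lo = 2, prr = 1, chi2 = 1, ic025 = -1,
               ebgm05 = 0.5)
  expect_true(evaluate_signal(fake, "any")$is_signal)
  expect_false(evaluate_signal(fake, "all")$is_signal)
})

test_that("mode=all signals are a subset of mode=any signals", {
  set.seed(80)
  tabs <- random_tables(200, max_cell = 300)
  implied <- vapply(sample.int(nrow(tabs), 40), function(i) {
    m <- signal_metrics(contingency_table(tabs$a[i], tabs$b[i], tabs$c[i],
                                          tabs$d[i]))
    !evaluate_signal(m, "all")$is_signal || evaluate_signal(m, "any")$is_signal
  }, logical(1))
  expect_true(all(implied))
})

test_that("ranking is a stable descending sort with documented tie-breaks", {
  res <- data.frame(term = c("b", "a", "c"), ror = c(5, 50, 11),
                    n_cases = c(1, 2, 3))
  expect_equal(rank_signals(res, "ror")$ror, c(50, 11, 5))
  tie <- data.frame(term = c("z", "y"), ror = c(3, 8), n_cases = c(10, 10))
  expect_equal(rank_signals(tie, "n_cases")$term, c("y", "z"))
  empty <- res[0, ]
  expect_equal(nrow(rank_signals(empty, "ror")), 0L)
})
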