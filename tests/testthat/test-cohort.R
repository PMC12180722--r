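# build a case_reports frame directly for summary tests
make_reports <- function(n, sex = "F", reporter = "pharmacist",
                         serious = TRUE, outcomes = list(character(0)),
                         age = NA_real_, weight = NA_real_,
                         year = "2024") {
  out <- data.frame(primaryid = as.character(seq_len(n)),
                    caseid = as.character(seq_len(n)),
                    fda_dt = paste0(year, "0315"),
                    sex = sex, age_years = age, weight_kg = weight,
                    reporter = reporter, country = "CN",
                    stringsAsFactors = FALSE)
  out$serious <- rep_len(serious, n)
  out$outcomes <- rep_len(outcomes, n)
  class(out) <- c("case_reports", "data.frame")
  out
}

test_that("single-membership percentages sum to 100 and round half-up", {
  rep10 <- make_reports(10, sex = "F")
  cs <- describe_cohort(rep10)
  expect_equal(cs$sex$pct[cs$sex$level == "F"], 100)
  expect_equal(sum(cs$sex$pct), 100)
  expect_equal(sum(cs$reporter$pct), 100)
  # half-up at 2 decimals: 1/3 of 3 -> 33.33, 2/3 -> 66.67
  cs3 <- describe_cohort(make_reports(3, sex = c("F", "M", "M")))
  expect_equal(cs3$sex$pct[cs3$sex$level == "F"], 33.33)
  expect_equal(cs3$sex$pct[cs3$sex$level == "M"], 66.67)
})

test_that("outcome percentages are multi-membership and may exceed 100 in total", {
  outc <- c(rep(list(c("hospitalization", "life_threatening")), 6),
            rep(list("hospitalization"), 3),
            list(character(0)))
  cs <- describe_cohort(make_reports(10, outcomes = outc,
                                     serious = lengths(outc) > 0))
  o <- cs$outcomes
  expect_equal(o$n[o$level == "hospitalization"], 9L)
  expect_equal(o$n[o$level == "life_threatening"], 6L)
  expect_gt(sum(o$pct), 100)
  expect_equal(cs$seriousness$n[cs$seriousness$level == "serious"], 9L)
})

test_that("published cohort counts reproduce the printed percentages", {
  n <- 441
  serious <- c(rep(TRUE, 440), FALSE)
  reporter <- c(rep("pharmacist", 395), rep("physician", 40),
                rep("consumer", 6))
  outc <- c(rep(list("hospitalization"), 274), rep(list("life_threatening"), 57),
            rep(list("other"), 110))
  outc <- rep_len(outc, n)
  reps <- make_reports(n, reporter = reporter, serious = serious,
                       outcomes = outc)
  cs <- describe_cohort(reps)
  expect_equal(cs$seriousness$pct[cs$seriousness$level == "serious"], 99.77)
  expect_equal(cs$reporter$pct[cs$reporter$level == "pharmacist"], 89.57)
  expect_equal(cs$outcomes$pct[cs$outcomes$level == "hospitalization"], 62.13)
  expect_equal(cs$outcomes$pct[cs$outcomes$level == "life_threatening"], 12.93)
})

test_that("TTO blocks report both denominators", {
  reps <- make_reports(20)
  days <- c(rep(10, 15), rep(40, 3), NA, NA)
  tto <- data.frame(caseid = as.character(1:20), days = days,
                    status = ifelse(is.na(days), "missing", "valid"))
  class(tto) <- c("tto_records", "data.frame")
  cs <- describe_cohort(reps, tto = tto)
  expect_equal(cs$tto_bins$pct[cs$tto_bins$level == "0-30"],
               round_half_up(100 * 15 / 20, 2))
  expect_equal(cs$tto_bins_valid$pct[cs$tto_bins_valid$level == "0-30"],
               round_half_up(100 * 15 / 18, 2))
  expect_equal(cs$tto$value[cs$tto$statistic == "n"], 18)
})

test_that("an empty cohort is an error", {
  expect_error(describe_cohort(make_reports(1)[0, ]), "empty")
})

test_that("case_reports decodes demographics and outcome codes", {
  demo <- data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                     fda_dt = c("20240101", "20240202"),
                     event_dt = c("", ""), sex = c("F", "UNK"),
                     age = c("63", "730"), age_cod = c("YR", "DY"),
                     wt = c("110", "55"), wt_cod = c("LBS", "KG"),
                     occp_cod = c("PH", "XX"), reporter_country = c("CN", ""),
                     stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = c("1", "1"), caseid = c("1", "1"),
                     outc_cod = c("HO", "LT"), stringsAsFactors = FALSE)
  reps <- case_reports(demo, outc)
  expect_equal(reps$age_years, c(63, 730 / 365.25))
  expect_equal(reps$weight_kg[1], 110 * 0.45359237)
  expect_equal(reps$reporter, c("pharmacist", "unknown"))
  expect_equal(reps$sex[2], "unknown")
  expect_equal(reps$serious, c(TRUE, FALSE))
  expect_setequal(reps$outcomes[[1]], c("hospitalization", "life_threatening"))
})
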