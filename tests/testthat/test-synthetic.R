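test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_cases = 120, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_packets(cfg, d1)
  generate_packets(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("no duplicates and no deletions make dedup the identity", {
  cfg <- generator_config(n_cases = 150, seed = 98, duplicate_fraction = 0,
                          deletion_fraction = 0)
  d <- withr::local_tempdir()
  led <- generate_packets(cfg, d)
  demo <- do.call(rbind, lapply(
    list.files(d, pattern = "^DEMO_", full.names = TRUE),
    read_ascii_table, table_name = "DEMO"))
  expect_equal(nrow(demo), 150L)
  dd <- deduplicate_reports(demo)
  expect_equal(nrow(dd), 150L)
  expect_setequal(dd$primaryid, led$cases$canonical_primaryid)
  expect_length(list.files(d, pattern = "^deleted_cases_"), 0L)
})

test_that("dedup plus deletions reproduce the ledger's canonical case set", {
  for (seed in c(1, 7, 23)) {
    cfg <- generator_config(n_cases = 150, seed = seed,
                            duplicate_fraction = 0.2,
                            deletion_fraction = 0.1)
    d <- withr::local_tempdir()
    led <- generate_packets(cfg, d)
    demo <- do.call(rbind, lapply(
      list.files(d, pattern = "^DEMO_", full.names = TRUE),
      read_ascii_table, table_name = "DEMO"))
    deleted <- unique(unlist(lapply(
      list.files(d, pattern = "^deleted_cases_", full.names = TRUE),
      read_deleted_list)))
    got <- suppressMessages(apply_deletions(deduplicate_reports(demo),
                                            deleted))
    want <- led$cases[!led$cases$deleted, ]
    expect_setequal(got$primaryid, want$canonical_primaryid)
    expect_setequal(got$caseid, want$caseid)
    # ledger also equals the brute-force group-by oracle on the raw table
    oracle <- dedup_oracle(demo)
    oracle <- oracle[!(oracle$caseid %in% deleted), ]
    expect_setequal(got$primaryid, oracle$primaryid)
  }
})

test_that("duplicate versions strictly increase fda_dt and primaryid", {
  cfg <- generator_config(n_cases = 100, seed = 97, duplicate_fraction = 0.3)
  sim <- simulate_cohort(cfg)
  dup <- sim$ledger$cases[nzchar(sim$ledger$cases$duplicate_primaryids), ]
  expect_gt(nrow(dup), 0L)
  demo <- sim$tables$DEMO
  for (i in seq_len(nrow(dup))) {
    versions <- demo[demo$caseid == dup$caseid[i], ]
    o <- order(as.numeric(versions$primaryid))
    expect_true(all(diff(as.numeric(versions$primaryid[o])) > 0))
    expect_true(all(diff(as.Date(versions$fda_dt[o], "%Y%m%d")) > 0))
    expect_equal(versions$primaryid[o][nrow(versions)],
                 dup$canonical_primaryid[i])
  }
})

test_that("pre-rounding onset times follow the generating Weibull", {
  cfg <- generator_config(n_cases = 50000, seed = 96, duplicate_fraction = 0,
                          deletion_fraction = 0, missing_date_fraction = 0,
                          tto_scale = 23.88, tto_shape = 0.70)
  sim <- simulate_cohort(cfg)
  ks <- suppressWarnings(
    ks.test(sim$ledger$cases$tto_exact, "pweibull", 0.70, 23.88))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted relative rates surface as signals; background stays quiet", {
  cfg <- generator_config(
    n_cases = 5000, seed = 95, target_fraction = 0.1,
    planted_associations = data.frame(pt = "PT_007", rate = 10))
  sim <- simulate_cohort(cfg)
  led <- sim$ledger$pairs
  planted <- led[led$pt == "PT_007", ]
  # around 20+ expected co-reports at rate 10
  expect_gte(planted$a, 20)
  r <- ror_estimate(contingency_table(planted$a, planted$b, planted$c,
                                      planted$d))
  expect_gt(r$ror, 5); expect_lt(r$ror, 20)
})

test_that("the profile matches the published marginal mixes", {
  cfg <- toripalimab_profile(seed = 1)
  expect_equal(cfg$n_cases, 441)
  expect_equal(unname(cfg$reporter_mix["PH"]), 0.8957, tolerance = 1e-4)
  expect_equal(cfg$tto_shape, 0.70)
  expect_equal(cfg$tto_scale, 23.88)
  expect_equal(cfg$serious_prob, 440 / 441)

  sim <- simulate_cohort(cfg)
  demo <- suppressWarnings(deduplicate_reports(sim$tables$DEMO))
  reps <- case_reports(demo, sim$tables$OUTC)
  cs <- describe_cohort(reps)
  expect_equal(cs$n_reports, 441)
  # binomial sampling tolerance at n = 441: ~3 x sqrt(p(1-p)/n) margins
  phat <- cs$reporter$pct[cs$reporter$level == "pharmacist"] / 100
  expect_lt(abs(phat - 0.8957), 3 * sqrt(0.8957 * (1 - 0.8957) / 441) + 1e-9)
  shat <- cs$seriousness$pct[cs$seriousness$level == "serious"] / 100
  expect_gt(shat, 0.98)
  ohat <- cs$outcomes$pct[cs$outcomes$level == "hospitalization"] / 100
  expect_lt(abs(ohat - 274 / 441), 3 * sqrt(0.62 * 0.38 / 441) + 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(duplicate_fraction = 1.5), "fractions")
  expect_error(generator_config(tto_scale = -1), "Weibull")
  expect_error(generator_config(
    n_events = 2,
    planted_associations = data.frame(pt = c("PT_001", "PT_002", "PT_003"),
                                      rate = c(2, 2, 2))),
    "vocabulary")
  expect_error(generator_config(year_mix = c(`2023` = 0.5)), "sum to 1")
})
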