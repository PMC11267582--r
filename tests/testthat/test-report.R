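# Descriptive reporting, sex stratification, overlap counts, and the
# end-to-end pipeline contract.

table1_fixture <- function() {
  # a case set carrying the canonical published demographic counts
  n <- 1177L
  sex <- c(rep("F", 470), rep("M", 519), rep("", 188))
  occp <- c(rep("CN", 614), rep("HP", 299), rep("MD", 193), rep("PH", 36),
            rep("OT", 9), rep("", 26))
  country <- c(rep("US", 801), rep("DE", 98), rep("ES", 60), rep("GB", 48),
               rep("AU", 42), rep("FR", 128))
  demo <- make_demo(as.character(seq_len(n)), sex = sex, occp = occp,
                    country = country)
  outc <- data.table::data.table(PRIMARYID = as.character(1:40),
                                 CASEID = as.character(1:40),
                                 OUTC_COD = "DE")
  make_case_set(demo = demo, outc = outc)
}

test_that("demographic percentages reproduce published worked examples", {
  s <- summarize_demographics(table1_fixture())
  expect_equal(s$total, 1177L)
  g <- function(tab, cat) tab$percent[tab$category == cat]
  expect_equal(g(s$tables$sex, "Male"), 44.1)        # 519/1177
  expect_equal(g(s$tables$sex, "Female"), 39.9)      # 470/1177
  expect_equal(g(s$tables$sex, "Unknown"), 16.0)
  expect_equal(g(s$tables$reporter, "Consumer"), 52.2)   # 614/1177
  expect_equal(g(s$tables$country, "US"), 68.1)          # 801/1177
  expect_equal(g(s$tables$outcome, "Death"), 3.4)        # 40/1177
})

test_that("counts sum to the total and percents recompute from counts", {
  s <- summarize_demographics(table1_fixture())
  for (nm in c("sex", "age", "weight", "reporter", "country")) {
    tab <- s$tables[[nm]]
    expect_equal(sum(tab$count), s$total, label = nm)
    expect_true(all(abs(tab$percent - 100 * tab$count / s$total) <= 0.05),
                label = nm)
    expect_lte(abs(sum(tab$percent) - 100), 0.2)
  }
})

test_that("an all-unknown case set reports 100% unknown", {
  cs <- make_case_set(demo = make_demo(c("1", "2", "3")))
  s <- summarize_demographics(cs)
  expect_equal(s$tables$sex$category, "Unknown")
  expect_equal(s$tables$sex$percent, 100.0)
  empty <- summarize_demographics(make_case_set(demo = make_demo(character())))
  expect_equal(empty$total, 0L)
})

test_that("age unit codes convert to years", {
  expect_equal(age_years(c("40", "4", "24", "730"),
                         c("YR", "DEC", "MON", "DY")),
               c(40, 40, 2, 730 / 365.25))
  expect_true(is.na(age_years("abc", "YR")))
  expect_equal(age_years("55", ""), 55)  # missing unit taken as years
})

test_that("identical strata give z = 0 and p = 1", {
  ids <- as.character(1:40)
  sex <- rep(c("F", "M"), 20)  # mirrored composition
  demo <- make_demo(ids, sex = sex)
  reac <- data.table::data.table(PRIMARYID = ids, CASEID = ids,
                                 PT = rep(c("Rash", "Rash", "Headache",
                                            "Headache"), 10))
  target <- make_case_set(demo = demo, reac = reac)
  bids <- as.character(101:300)
  bsex <- rep(c("F", "M"), 100)
  bdemo <- make_demo(bids, sex = bsex)
  breac <- data.table::data.table(PRIMARYID = bids, CASEID = bids,
                                  PT = rep(c("Rash", "Rash", "Headache",
                                             "Headache"), 50))
  background <- make_case_set(demo = bdemo, reac = breac)
  out <- stratify_by_sex(target, background, terms = "Rash")
  expect_equal(out$z, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$N_f, out$N_m)
})

test_that("a sex-specific signal appears only in the carrying stratum", {
  cfg <- faers_config(n_reports = 20000, target_fraction = 0.15, seed = 91,
                      missingness = list(sex = 0, age = 0.5, weight = 0.7,
                                         event_dt = 0.4, start_dt = 0.3),
                      injected_signals = data.frame(pt = "Bronchitis",
                                                    rr = 8))
  ds <- generate_dataset(cfg)
  # make the signal female-only: strip Bronchitis from male target reports
  led <- ds$ledger$cases
  male_t <- led$caseid[led$is_target & led$sex == "M"]
  reac <- ds$tables$reac
  drop <- reac$CASEID %in% male_t & reac$PT == "Bronchitis"
  ds$tables$reac <- reac[!drop]
  cl <- clean_cases(ds$tables)
  out <- stratify_by_sex(cl$target, cl$background, terms = "Bronchitis")
  expect_true(out$ror_low_f > 1)
  # male stratum: no case left, so the term is reported one-sided
  expect_true(is.na(out$ror_low_m) || out$ror_low_m <= 1)
})

test_that("overlap counts partition terms by criteria met", {
  ds <- generate_dataset(small_config(
    injected_signals = data.frame(pt = c("Cellulitis", "Psoriasis"),
                                  rr = c(12, 6))))
  cl <- clean_cases(ds$tables)
  tabs <- build_all(cl$target, cl$background, level = "PT")
  sig <- signal_table(tabs[tabs$a > 0 & tabs$c > 0])
  ov <- criteria_overlap(sig)
  expect_equal(sum(ov$by_n_criteria), nrow(sig))
  expect_equal(unname(ov$at_least["0"]), nrow(sig))
  # terms meeting all four criteria are a subset of those meeting two
  expect_lte(ov$at_least[["4"]], ov$at_least[["2"]])
  expect_equal(sum(ov$by_subset$count), nrow(sig))
})

test_that("the pipeline writes its declared outputs and is deterministic", {
  cfg <- faers_config(n_reports = 2500, target_fraction = 0.12, seed = 5,
                      injected_signals = data.frame(pt = "Cellulitis",
                                                    rr = 10))
  data_dir <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = data_dir)
  out1 <- withr::local_tempdir()
  res <- run_pipeline(data_dir, out1)
  for (f in c("cleaning_report.json", "signals_pt.tsv", "signals_soc.tsv",
              "contingency_pt.tsv", "tto.tsv", "tto_exclusions.tsv",
              "criteria_overlap.json", "demographics_sex.tsv",
              "run_log.json")) {
    expect_true(file.exists(file.path(out1, f)), label = f)
  }
  # outputs parse and the run log is internally consistent
  log <- jsonlite::read_json(file.path(out1, "run_log.json"))
  expect_equal(log$stages$after_pt_exclusion, log$n_target)
  expect_equal(log$n_tto + log$n_tto_excluded, log$n_target)
  sig <- data.table::fread(file.path(out1, "signals_pt.tsv"))
  expect_true("Cellulitis" %in% sig$term)
  expect_equal(sig$classification[sig$term == "Cellulitis"], "significant")
  # determinism: a second run over the same files gives identical signals
  out2 <- withr::local_tempdir()
  run_pipeline(data_dir, out2)
  expect_identical(readLines(file.path(out1, "signals_pt.tsv")),
                   readLines(file.path(out2, "signals_pt.tsv")))
  expect_identical(readLines(file.path(out1, "signals_soc.tsv")),
                   readLines(file.path(out2, "signals_soc.tsv")))
})

test_that("injected signals are recovered and null terms stay quiet", {
  hits <- 0L
  null_pos <- 0L
  null_tot <- 0L
  for (s in 1:50) {
    cfg <- faers_config(n_reports = 3000, target_fraction = 0.1,
                        seed = 2000 + s,
                        injected_signals = data.frame(pt = "Cellulitis",
                                                      rr = 10))
    ds <- generate_dataset(cfg)
    cl <- clean_cases(ds$tables)
    tabs <- build_all(cl$target, cl$background, level = "PT")
    sig <- signal_table(tabs[tabs$a > 0 & tabs$c > 0])
    hits <- hits +
      (sig$classification[sig$term == "Cellulitis"] == "significant")
    nulls <- sig[sig$term != "Cellulitis"]
    null_pos <- null_pos + sum(nulls$flag_ror)
    null_tot <- null_tot + nrow(nulls)
  }
  expect_gte(hits / 50, 0.95)
  expect_lte(null_pos / null_tot, 0.10)
})
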