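# Time-to-onset: calendar arithmetic and exclusions, summaries, binning,
# growth rates, Weibull ML fitting, KS goodness of fit, Kruskal-Wallis.

tto_case <- function(event_dt, start_dt, pid = "1") {
  make_case_set(
    demo = make_demo(pid, event_dt = event_dt),
    drug = data.table::data.table(PRIMARYID = pid, CASEID = pid,
                                  DRUG_SEQ = "1",
                                  DRUGNAME = "TILDRAKIZUMAB",
                                  ROLE_COD = "PS"),
    reac = data.table::data.table(PRIMARYID = pid, CASEID = pid,
                                  PT = "Psoriasis"),
    ther = data.table::data.table(PRIMARYID = pid, CASEID = pid,
                                  DSG_DRUG_SEQ = "1", START_DT = start_dt,
                                  END_DT = ""))
}

test_that("TTO is calendar days from therapy start to event", {
  out <- compute_tto(tto_case("20200711", "20200101"))
  expect_equal(out$tto$tto_days, 192L)
  expect_equal(nrow(out$exclusions), 0L)
})

test_that("input errors and partial dates are excluded with reasons", {
  neg <- compute_tto(tto_case("20200101", "20200301"))
  expect_equal(nrow(neg$tto), 0L)
  expect_equal(neg$exclusions$reason, "negative")
  part <- compute_tto(tto_case("20200711", "202001"))
  expect_equal(part$exclusions$reason, "start partial")
  miss <- compute_tto(tto_case("", "20200101"))
  expect_equal(miss$exclusions$reason, "event missing")
  # included + excluded partitions the case set, also at scale
  ds <- generate_dataset(small_config())
  cl <- clean_cases(ds$tables)
  out <- compute_tto(cl$target)
  expect_equal(nrow(out$tto) + nrow(out$exclusions), n_cases(cl$target))
  expect_true(all(out$tto$tto_days >= 0))
})

test_that("TTO agrees with the generator's ground truth", {
  ds <- generate_dataset(small_config(negative_tto_rate = 0))
  cl <- clean_cases(ds$tables)
  out <- compute_tto(cl$target)
  led <- ds$ledger$cases
  usable <- led[led$tto_usable == TRUE]
  expect_setequal(out$tto$PRIMARYID, usable$final_primaryid)
  idx <- match(out$tto$PRIMARYID, usable$final_primaryid)
  expect_equal(out$tto$tto_days, usable$tto_true[idx])
})

test_that("summaries use linear-interpolation quartiles", {
  s1 <- summarize_tto(10)
  expect_equal(s1$median, 10)
  expect_equal(c(s1$q1, s1$q3), c(10, 10))
  expect_equal(summarize_tto(c(1, 2, 3, 4))$median, 2.5)
  expect_equal(summarize_tto(numeric())$n, 0L)
  x <- sample_tto(1e5, 0.89, 269.56, seed = 8)
  med_theory <- 269.56 * log(2)^(1 / 0.89)
  expect_lt(abs(summarize_tto(x)$median - med_theory) / med_theory, 0.02)
})

test_that("bins partition the axis and counts sum to n", {
  b <- bin_counts(c(5, 35, 400))
  expect_equal(b$month[1], 1L)
  expect_equal(b$month[2], 1L)
  expect_equal(b$over_year, 1L)
  expect_equal(sum(b$month) + b$over_year, 3L)
  empty <- bin_counts(numeric())
  expect_equal(sum(empty$month), 0L)
  expect_equal(empty$over_year, 0L)
  set.seed(5)
  x <- c(rweibull(500, 0.9, 250), 0, 365, 366)
  b2 <- bin_counts(x)
  expect_equal(sum(b2$month) + b2$over_year, length(x))
  expect_equal(sum(b2$quarter), sum(b2$month))
  expect_error(bin_counts(c(-1, 5)), "negative")
  expect_error(bin_counts(1:10, month_days = 40), "bin scheme")
})

test_that("growth rates are percent changes at one decimal", {
  expect_equal(growth_rate(c(89, 72, 64, 32)), c(-19.1, -11.1, -50.0))
  expect_equal(growth_rate(c(7, 7)), 0)
  expect_true(is.na(growth_rate(c(0, 5))))
  expect_error(growth_rate(5), "two bins")
})

test_that("Weibull MLE recovers known parameters", {
  x <- sample_tto(1e5, shape = 1, scale = 100, seed = 12)
  f <- fit_weibull(x)
  expect_gt(f$shape, 0.98)
  expect_lt(f$shape, 1.02)
  expect_lt(abs(f$scale - 100) / 100, 0.02)
  # CDF at the fitted scale is 1 - exp(-1) by construction
  expect_equal(pweibull(f$scale, f$shape, f$scale), 1 - exp(-1))
  expect_equal(f$onset_type, if (f$shape < 1) "early" else "late")
  expect_error(fit_weibull(1:5), "at least 10")
  expect_error(fit_weibull(c(-1, 1:20)), "negative")
})

test_that("Weibull fit agrees with an independent ML implementation", {
  x <- sample_tto(2000, 0.89, 269.56, seed = 77)
  x[x == 0] <- 0.5
  f <- fit_weibull(x)
  m <- MASS::fitdistr(x, "weibull")
  expect_equal(f$shape, unname(m$estimate["shape"]), tolerance = 5e-3)
  expect_equal(f$scale, unname(m$estimate["scale"]), tolerance = 5e-3)
  # our optimum is at least as good as the independent fit's
  expect_gte(f$loglik + 1e-6, m$loglik)
})

test_that("shape CIs attain near-nominal coverage at the study size", {
  cov <- vapply(1:200, function(i) {
    x <- sample_tto(335, 0.89, 269.56, seed = 1000 + i)
    ci <- fit_weibull(x)$shape_ci
    ci[1] <= 0.89 && 0.89 <= ci[2]
  }, logical(1))
  expect_gte(mean(cov), 0.90)
  expect_lte(mean(cov), 0.99)
})

test_that("a sub-unity shape implies a strictly decreasing hazard", {
  x <- sample_tto(5000, 0.89, 269.56, seed = 21)
  f <- fit_weibull(x)
  expect_lt(f$shape, 1)
  grid <- seq(1, 1000, length.out = 100)
  h <- weibull_hazard(f, grid)
  expect_true(all(diff(h) < 0))
})

test_that("KS statistic matches a brute-force sup-distance", {
  x <- sample_tto(50, 0.89, 269.56, seed = 33)
  x[x == 0] <- 0.5
  x <- x + runif(50, -0.1, 0.1)  # break whole-day ties for the oracle
  f <- fit_weibull(x)
  ks <- weibull_ks_test(x, f)
  xs <- sort(x)
  Fx <- pweibull(xs, f$shape, f$scale)
  n <- length(xs)
  d_oracle <- max(pmax(abs(seq_len(n) / n - Fx),
                       abs((seq_len(n) - 1) / n - Fx)))
  expect_equal(ks$statistic, d_oracle, tolerance = 1e-12)
})

test_that("KS p-values behave under the null and a gross misfit", {
  x <- sample_tto(2000, 0.89, 269.56, seed = 44)
  f <- fit_weibull(x)
  expect_gt(weibull_ks_test(x, f)$p_value, 0.05)
  u <- runif(2000) * 10
  expect_lt(weibull_ks_test(u, f)$p_value, 1e-6)
})

test_that("Kruskal-Wallis matches a hand computation and rank invariance", {
  out <- tto_kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(out$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(out$df, 1)
  same <- tto_kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  shifted <- tto_kruskal_wallis(list(c(1, 2, 3) + 100, c(4, 5, 6) + 100))
  expect_equal(shifted$H, out$H)
  expect_error(tto_kruskal_wallis(list(1:3)), "two")
  expect_error(tto_kruskal_wallis(list(1:3, numeric())), "non-empty")
})

test_that("report-level TTO propagates to PT and SOC groups", {
  cs <- make_case_set(
    demo = make_demo(c("1", "2"), event_dt = c("20200301", "20200501")),
    drug = data.table::data.table(PRIMARYID = c("1", "2"),
                                  CASEID = c("1", "2"), DRUG_SEQ = "1",
                                  DRUGNAME = "TILDRAKIZUMAB",
                                  ROLE_COD = "PS"),
    reac = data.table::data.table(PRIMARYID = c("1", "1", "2"),
                                  CASEID = c("1", "1", "2"),
                                  PT = c("Pneumonia", "Bronchitis", "Rash")),
    ther = data.table::data.table(PRIMARYID = c("1", "2"),
                                  CASEID = c("1", "2"), DSG_DRUG_SEQ = "1",
                                  START_DT = c("20200101", "20200401"),
                                  END_DT = ""))
  tt <- compute_tto(cs)
  g_pt <- tto_groups(tt$tto, cs, level = "PT")
  expect_equal(sort(names(g_pt)), c("Bronchitis", "Pneumonia", "Rash"))
  expect_equal(g_pt$Pneumonia, g_pt$Bronchitis)  # same report, same TTO
  map <- default_pt_vocabulary()[, c("pt", "soc"), with = FALSE]
  g_soc <- tto_groups(tt$tto, cs, level = "SOC", map = map)
  expect_equal(length(g_soc$`Infections and infestations`), 1L)
})
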