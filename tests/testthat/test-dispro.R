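# The four disproportionality estimators, their closed forms, algebraic
# identities, and the signal-classification rule.

test_that("estimators match plain-arithmetic oracles on a reference table", {
  tab <- tab_row(10, 90, 100, 9900)
  o <- oracle_stats(10, 90, 100, 9900)
  r <- ror(tab)
  expect_equal(r$ror, 11.0)
  expect_equal(r$low, o$ror_low, tolerance = 1e-12)
  expect_equal(r$high, o$ror_high, tolerance = 1e-12)
  p <- prr(tab)
  expect_equal(p$prr, 10.0)
  expect_equal(p$chi2, o$chi2, tolerance = 1e-12)
  expect_equal(rrr(tab), 101000 / 11000, tolerance = 1e-12)
  ic <- information_component(tab)
  expect_equal(ic$ic, log2(101000 / 11000), tolerance = 1e-12)
  e <- ebgm_simple(tab)
  expect_equal(e$ebgm, 101000 / 11000, tolerance = 1e-12)
  expect_equal(e$ebgm05, o$ebgm05, tolerance = 1e-12)
})

test_that("balanced tables give the null value for every estimator", {
  for (k in c(1, 5, 40)) {
    tab <- tab_row(k, k, k, k)
    expect_equal(ror(tab)$ror, 1)
    expect_equal(prr(tab)$prr, 1)
    expect_equal(prr(tab)$chi2, 0)
    expect_equal(rrr(tab), 1)
    expect_equal(information_component(tab)$ic, 0)
    expect_equal(ebgm_simple(tab)$ebgm, 1)
  }
  # any table with ad = bc has chi2 = 0
  expect_equal(prr(tab_row(2, 4, 3, 6))$chi2, 0)
})

test_that("closed forms match brute-force evaluation on all small tables", {
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; c <- grid$c[i]; d <- grid$d[i]
    tab <- tab_row(a, b, c, d)
    o <- oracle_stats(a, b, c, d)
    expect_equal(ror(tab)$ror, o$ror, tolerance = 1e-12)
    expect_equal(prr(tab)$prr, o$prr, tolerance = 1e-12)
    expect_equal(prr(tab)$chi2, o$chi2, tolerance = 1e-12)
    expect_equal(rrr(tab), o$rrr, tolerance = 1e-12)
    expect_equal(information_component(tab)$ic, o$ic, tolerance = 1e-12)
    # ordering: ad > bc implies ROR > PRR > RRR; ad < bc reverses it
    if (a * d > b * c) {
      expect_true(o$ror > o$prr && o$prr > o$rrr)
    } else if (a * d < b * c) {
      expect_true(o$ror < o$prr && o$prr < o$rrr)
    }
  }
})

test_that("IC is exactly log2 of the relative reporting ratio", {
  set.seed(31)
  for (i in 1:50) {
    tab <- tab_row(sample(1:50, 1), sample(1:500, 1), sample(1:500, 1),
                   sample(100:100000, 1))
    expect_equal(information_component(tab)$ic, log2(rrr(tab)),
                 tolerance = 1e-14)
  }
})

test_that("printed IC equals log2 of printed EBGM on published-style rows", {
  # rows where the 2-decimal identity holds exactly
  pairs <- list(c(3.32, 1.73), c(2.17, 1.12), c(1.06, 0.08), c(1.03, 0.04),
                c(0.77, -0.38), c(0.80, -0.32), c(0.48, -1.06),
                c(0.21, -2.25))
  for (p in pairs) {
    expect_equal(round(log2(p[1]), 2), p[2], tolerance = 1e-9)
  }
})

test_that("doubling all cells preserves ratios and doubles chi-squared", {
  tab <- tab_row(7, 35, 60, 4000)
  tab2 <- tab_row(14, 70, 120, 8000)
  expect_equal(ror(tab2)$ror, ror(tab)$ror)
  expect_equal(prr(tab2)$prr, prr(tab)$prr)
  expect_equal(rrr(tab2), rrr(tab))
  expect_equal(prr(tab2)$chi2, 2 * prr(tab)$chi2, tolerance = 1e-12)
})

test_that("zero cells error unless the continuity correction is enabled", {
  tab <- tab_row(3, 0, 10, 500)
  expect_error(ror(tab), "zero cell")
  expect_error(prr(tab), "zero cell")
  r <- ror(tab, correction = TRUE)
  o <- oracle_stats(3.5, 0.5, 10.5, 500.5)
  expect_equal(r$ror, o$ror, tolerance = 1e-12)
})

test_that("interval bounds bracket the point estimates", {
  set.seed(17)
  for (i in 1:30) {
    tab <- tab_row(sample(3:40, 1), sample(1:300, 1), sample(1:300, 1),
                   sample(500:50000, 1))
    r <- ror(tab)
    expect_true(r$low < r$ror && r$ror < r$high)
    ic <- information_component(tab)
    expect_lt(ic$ic025, ic$ic)
    e <- ebgm_simple(tab)
    expect_lt(e$ebgm05, e$ebgm)
  }
})

test_that("fixed-width IC025 mode subtracts the configured constant", {
  tab <- tab_row(10, 90, 100, 9900)
  ic <- information_component(tab, ic025_mode = "fixed", fixed_width = 1.66)
  expect_equal(ic$ic - ic$ic025, 1.66)
})

test_that("classification follows the positive/significant rule", {
  crit <- signal_criteria()
  # published vulvovaginal-candidiasis-style row: all four criteria met
  res <- classify_signal(list(N = 5, ror_low = 50.39, prr = 121.42,
                              chi2 = 591.50, ic025 = 5.24, ebgm05 = 57.52),
                         crit)
  expect_true(all(res$flags))
  expect_equal(res$classification, "significant")
  # N = 2 gates out ROR and PRR regardless of magnitude
  res2 <- classify_signal(list(N = 2, ror_low = 100, prr = 100, chi2 = 1000,
                               ic025 = -1, ebgm05 = 1), crit)
  expect_equal(res2$classification, "none")
  # ROR criterion alone: positive but not significant
  res3 <- classify_signal(list(N = 3, ror_low = 1.2, prr = 1.5, chi2 = 10,
                               ic025 = -0.5, ebgm05 = 1.5), crit)
  expect_equal(res3$classification, "positive")
  expect_equal(res3$n_met, 1L)
  # two non-ROR criteria: significant under the default any-two rule,
  # not when ROR membership is required
  st <- list(N = 5, ror_low = 0.9, prr = 3, chi2 = 10, ic025 = 0.4,
             ebgm05 = 1)
  expect_equal(classify_signal(st, crit)$classification, "significant")
  expect_equal(classify_signal(st, signal_criteria(require_ror = TRUE))$
                 classification, "none")
})

test_that("relaxing any threshold never removes a flag", {
  set.seed(47)
  strict <- signal_criteria()
  relaxed <- signal_criteria(ror_n = 2L, ror_low = 0.8, prr_min = 1.5,
                             chi2_min = 2, prr_n = 2L, ic025_min = -0.5,
                             ebgm05_min = 1.5)
  for (i in 1:40) {
    st <- list(N = sample(1:10, 1), ror_low = runif(1, 0.5, 3),
               prr = runif(1, 0.5, 4), chi2 = runif(1, 0, 10),
               ic025 = runif(1, -1, 1), ebgm05 = runif(1, 0.5, 3))
    f1 <- classify_signal(st, strict)$flags
    f2 <- classify_signal(st, relaxed)$flags
    expect_true(all(f2[f1]))
  }
})

test_that("signal_table is a faithful vectorization of the estimators", {
  tabs <- data.table::rbindlist(list(tab_row(10, 90, 100, 9900),
                                     tab_row(5, 5, 10, 9980)))
  tabs$term <- c("A", "B")
  sig <- signal_table(tabs)
  expect_equal(sig$N, c(10L, 5L))
  expect_equal(sig$ror[1], 11.0)
  expect_equal(sig$ebgm[2], rrr(tabs[2]))
  expect_equal(nrow(signal_table(tabs[0])), 0L)
})

test_that("full MGPS recovers a known gamma-mixture prior", {
  set.seed(42)
  N <- 10000
  E <- runif(N, 0.5, 50)
  w_true <- 0.4
  comp <- runif(N) < w_true
  lam <- ifelse(comp, rgamma(N, 1.5, rate = 1.5), rgamma(N, 3, rate = 1))
  a <- rpois(N, lam * E)
  Ttot <- 1000; ntot <- 1e7
  ac <- round(E * ntot / Ttot)
  tabs <- data.table::data.table(a = a, b = Ttot - a, c = ac - a,
                                 d = ntot - Ttot - (ac - a), n = ntot)
  fit <- mgps_full(tabs)
  hp <- fit$hyperparams
  mean_fit <- hp[["w"]] * hp[["alpha1"]] / hp[["beta1"]] +
    (1 - hp[["w"]]) * hp[["alpha2"]] / hp[["beta2"]]
  mean_true <- w_true * 1 + (1 - w_true) * 3
  expect_lt(abs(mean_fit - mean_true) / mean_true, 0.1)
  expect_gte(fit$loglik, fit$loglik_init)
  expect_true(all(fit$results$eb05 < fit$results$ebgm))
})

test_that("MGPS limits: point-mass prior shrinks to 1, data dominate", {
  tabs <- data.table::data.table(a = c(5, 20, 3), b = c(95, 980, 47),
                                 c = c(50, 100, 10),
                                 d = c(9850, 98900, 940))
  tabs$n <- tabs$a + tabs$b + tabs$c + tabs$d
  pm <- mgps_full(tabs, theta = c(1e4, 1e4, 1e4, 1e4, 0.5))
  expect_true(all(abs(pm$results$ebgm - 1) < 0.05))
  # huge observed count with E = 100: EBGM approaches observed/expected
  big <- data.table::data.table(a = 1e4, b = 9e4, c = 9e4,
                                d = 1e8 - 1e4 - 9e4 - 9e4, n = 1e8)
  lik <- mgps_full(big, theta = c(0.2, 0.1, 2, 4, 1 / 3))
  expect_equal(lik$results$E, 100, tolerance = 1e-6)
  expect_equal(lik$results$ebgm, 100, tolerance = 0.05)
})
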