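# Time-to-onset (TTO) analysis: days from the start of therapy with the
# primary-suspect target drug to the event date, summarized, binned with
# growth rates, and modelled with a Weibull law (shape < 1 indicates an
# early-failure onset profile: hazard highest soon after starting therapy,
# then decreasing).

#' Compute time to onset per report
#'
#' For each report in a cleaned target case set, TTO = event date minus the
#' earliest fully specified therapy start date among the primary-suspect
#' target-drug entries, in days. Reports with a missing or partial date on
#' either side, or with the event dated before therapy start (input
#' errors), are excluded with a reason; exclusions are data, not errors.
#'
#' @param cs Target `case_set` (from [clean_cases()]).
#' @param synonyms Target-drug synonym list.
#' @return List with `tto` (`data.table`: `PRIMARYID`, `tto_days`) and
#'   `exclusions` (`data.table`: `PRIMARYID`, `reason` in
#'   `event missing/event partial/start missing/start partial/negative`).
#'   Row counts add up to `n_cases(cs)`.
#' @export
compute_tto <- function(cs, synonyms = default_synonyms()) {
  demo <- cs$demo
  n <- nrow(demo)
  event_stat <- date_status(demo$EVENT_DT)
  event_date <- parse_full_date(demo$EVENT_DT)

  # earliest full START_DT among PS target-drug therapy entries
  drug <- cs$drug
  ther <- cs$ther
  start_date <- rep(as.Date(NA), n)
  start_stat <- rep("missing", n)
  if (!is.null(ther) && nrow(ther)) {
    ps <- drug[match_drug(drug$DRUGNAME, synonyms) & drug$ROLE_COD == "PS"]
    seq_col <- intersect(c("DSG_DRUG_SEQ", "DRUG_SEQ"), names(ther))[1]
    if (!is.na(seq_col) && "DRUG_SEQ" %in% names(ps)) {
      key_t <- paste(ther$PRIMARYID, ther[[seq_col]])
      key_d <- paste(ps$PRIMARYID, ps$DRUG_SEQ)
      ther_ps <- ther[key_t %in% key_d]
    } else {
      ther_ps <- ther[ther$PRIMARYID %in% unique(ps$PRIMARYID)]
    }
    if (nrow(ther_ps)) {
      st <- date_status(ther_ps$START_DT)
      sd <- parse_full_date(ther_ps$START_DT)
      agg <- data.table::data.table(PRIMARYID = ther_ps$PRIMARYID,
                                    stat = st, date = sd)
      # best available status per report: full > partial > missing
      rank <- c(full = 1L, partial = 2L, missing = 3L)
      agg <- agg[order(agg$PRIMARYID, rank[agg$stat], agg$date)]
      first <- agg[!duplicated(agg$PRIMARYID)]
      idx <- match(demo$PRIMARYID, first$PRIMARYID)
      hit <- !is.na(idx)
      start_stat[hit] <- first$stat[idx[hit]]
      start_date[hit] <- first$date[idx[hit]]
    }
  }

  reason <- rep(NA_character_, n)
  reason[event_stat == "partial"] <- "event partial"
  reason[event_stat == "missing"] <- "event missing"
  need_start <- is.na(reason)
  reason[need_start & start_stat == "partial"] <- "start partial"
  reason[need_start & start_stat == "missing"] <- "start missing"
  ok <- is.na(reason)
  tto_days <- rep(NA_integer_, n)
  tto_days[ok] <- as.integer(event_date[ok] - start_date[ok])
  neg <- ok & tto_days < 0
  reason[neg] <- "negative"
  keep <- ok & !neg
  list(
    tto = data.table::data.table(PRIMARYID = demo$PRIMARYID[keep],
                                 tto_days = tto_days[keep]),
    exclusions = data.table::data.table(PRIMARYID = demo$PRIMARYID[!keep],
                                        reason = reason[!keep])
  )
}

#' Group report-level TTO values by PT or SOC
#'
#' Each report contributes its single TTO to every PT (or mapped SOC) it
#' reports, for group comparisons across terms.
#'
#' @param tto `data.table` from [compute_tto()]`$tto`.
#' @param cs The same target `case_set`.
#' @param level `"PT"` or `"SOC"`.
#' @param map PT->SOC map, required at SOC level.
#' @return Named list of numeric TTO vectors, one per term.
#' @export
tto_groups <- function(tto, cs, level = c("PT", "SOC"), map = NULL) {
  level <- match.arg(level)
  terms <- normalize_terms(cs$reac, level, map)
  merged <- merge(terms, tto, by = "PRIMARYID")
  split(merged$tto_days, merged$term)
}

#' Median and interquartile range of TTO
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7).
#'
#' @param ttos Numeric vector of day counts.
#' @return List `median`, `q1`, `q3`, `n`; all `NA` with `n = 0` for empty
#'   input.
#' @export
summarize_tto <- function(ttos) {
  if (!length(ttos)) {
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0L))
  }
  q <- stats::quantile(ttos, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(ttos))
}

#' Bin TTO values into months, quarters and an over-one-year tail
#'
#' Months are 30-day windows (`[0,30), [30,60), ...`), with the twelfth
#' month extended to the year cutoff so that the bins partition
#' `[0, year_cutoff]`; quarters aggregate three months; values beyond the
#' cutoff land in `over_year`. Counts always sum to the input length.
#'
#' @param ttos Numeric vector of non-negative day counts.
#' @param month_days Month length in days (default 30).
#' @param year_cutoff One-year cutoff in days (default 365); must be at
#'   least `12 * month_days`.
#' @return List: `month` (12 counts), `quarter` (4 counts), `over_year`,
#'   `n`, plus the scheme used.
#' @export
bin_counts <- function(ttos, month_days = 30, year_cutoff = 365) {
  if (month_days <= 0 || year_cutoff < 12 * month_days) {
    stop("invalid bin scheme: need month_days > 0 and year_cutoff >= ",
         "12 * month_days", call. = FALSE)
  }
  ttos <- as.numeric(ttos)
  if (any(ttos < 0, na.rm = TRUE)) {
    stop("negative TTO values must be excluded upstream", call. = FALSE)
  }
  month <- integer(12L)
  for (m in 1:12) {
    lo <- (m - 1) * month_days
    hi <- if (m < 12) m * month_days else year_cutoff + 1e-9
    month[m] <- sum(ttos >= lo & ttos < hi)
  }
  quarter <- vapply(1:4, function(q) sum(month[(3 * q - 2):(3 * q)]),
                    integer(1))
  over_year <- sum(ttos > year_cutoff)
  list(month = month, quarter = quarter, over_year = over_year,
       n = length(ttos), month_days = month_days, year_cutoff = year_cutoff)
}

#' Step-over-step growth rates of binned counts
#'
#' `rate_t = (N_t - N_{t-1}) / N_{t-1}` as a percentage rounded to one
#' decimal; steps with a zero previous count yield `NA`.
#'
#' @param counts Ordered numeric vector of at least two bin counts.
#' @return Numeric vector of length `length(counts) - 1`.
#' @export
growth_rate <- function(counts) {
  if (length(counts) < 2L) stop("need at least two bins", call. = FALSE)
  prev <- counts[-length(counts)]
  cur <- counts[-1L]
  out <- ifelse(prev > 0, round(100 * (cur - prev) / prev, 1), NA_real_)
  as.numeric(out)
}

#' @noRd
weibull_negloglik <- function(logpar, x) {
  shape <- exp(logpar[1]); scale <- exp(logpar[2])
  -(length(x) * (log(shape) - shape * log(scale)) +
      (shape - 1) * sum(log(x)) - sum((x / scale)^shape))
}

#' Maximum-likelihood Weibull fit for time-to-onset data
#'
#' Fits shape (beta) and scale (eta, days) by maximum likelihood, with 95%
#' confidence intervals from the normal approximation on the log-parameters
#' using the observed information. Zero-day values are shifted by +0.5 day
#' (events on the day therapy started) and the shift is recorded. A fitted
#' shape below 1 marks the early-failure onset type: the hazard decreases
#' with time on therapy; the scale is the time by which about 63.2% of
#' events have occurred.
#'
#' @param ttos Numeric vector of day counts, `n >= 10`.
#' @return Object of class `weibull_fit`: `shape`, `shape_ci`, `scale`,
#'   `scale_ci`, `loglik`, `n`, `n_shifted_zeros`, `onset_type`.
#' @export
fit_weibull <- function(ttos) {
  x <- as.numeric(ttos)
  x <- x[!is.na(x)]
  if (length(x) < 10L) stop("need at least 10 TTO values", call. = FALSE)
  if (any(x < 0)) stop("negative TTO values must be excluded upstream",
                       call. = FALSE)
  n_zero <- sum(x == 0)
  x[x == 0] <- 0.5
  m <- mean(log(x)); s <- stats::sd(log(x))
  shape0 <- if (s > 0) 1.2826 / s else 1
  scale0 <- exp(m + 0.5772 / shape0)
  opt <- stats::optim(c(log(shape0), log(scale0)), weibull_negloglik, x = x,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0L) {
    stop("Weibull fit did not converge (code ", opt$convergence, ")",
         call. = FALSE)
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    stop("Weibull fit: singular observed information", call. = FALSE)
  })
  se <- sqrt(pmax(diag(vc), 0))
  est <- exp(opt$par)
  ci <- function(i) unname(exp(opt$par[i] + c(-1.96, 1.96) * se[i]))
  shape <- est[1]
  structure(list(shape = unname(shape), shape_ci = ci(1),
                 scale = unname(est[2]), scale_ci = ci(2),
                 loglik = -opt$value, n = length(x),
                 n_shifted_zeros = n_zero,
                 onset_type = if (shape < 1) "early"
                              else if (shape > 1) "late" else "random"),
            class = "weibull_fit")
}

#' Hazard function of a fitted Weibull
#' @param fit A `weibull_fit`.
#' @param t Time points (days, > 0).
#' @return Hazard values `(shape/scale) * (t/scale)^(shape-1)`.
#' @export
weibull_hazard <- function(fit, t) {
  (fit$shape / fit$scale) * (t / fit$scale)^(fit$shape - 1)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull TTO fit (n = %d%s)\n", x$n,
              if (x$n_shifted_zeros)
                sprintf(", %d zero-day values shifted by +0.5",
                        x$n_shifted_zeros) else ""))
  cat(sprintf("  shape beta = %.3f (95%% CI %.3f-%.3f)  [%s onset type]\n",
              x$shape, x$shape_ci[1], x$shape_ci[2], x$onset_type))
  cat(sprintf("  scale eta  = %.2f days (95%% CI %.2f-%.2f)\n",
              x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  ~63.2%% of events occur within %.1f days\n", x$scale))
  invisible(x)
}

#' Kolmogorov-Smirnov goodness of fit against a fitted Weibull
#'
#' One-sample KS test of the data against the fitted Weibull CDF with the
#' asymptotic p-value (no correction for estimated parameters, the common
#' practice in TTO analyses); `p > 0.05` is read as compatibility with the
#' Weibull model. Ties from whole-day resolution are tolerated.
#'
#' @param ttos Numeric vector of day counts (zeros shifted as in
#'   [fit_weibull()]).
#' @param fit A `weibull_fit`.
#' @return List: `statistic`, `p_value`, `complies`.
#' @export
weibull_ks_test <- function(ttos, fit) {
  x <- as.numeric(ttos)
  x[x == 0] <- 0.5
  kt <- suppressWarnings(stats::ks.test(x, "pweibull", shape = fit$shape,
                                        scale = fit$scale, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       complies = kt$p.value > 0.05)
}

#' Kruskal-Wallis comparison of TTO across groups
#'
#' Rank-based test (with tie correction) of whether median TTO differs
#' across terms; chi-squared reference on k-1 degrees of freedom.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List: `H`, `df`, `p_value`, `group_sizes`.
#' @export
tto_kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(!vapply(groups, length, integer(1)))) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value,
       group_sizes = vapply(groups, length, integer(1)))
}
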