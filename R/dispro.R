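# The four disproportionality estimators on 2x2 tables and the signal
# classification rule.
#
# For a (drug, term) 2x2 table with cells a, b, c, d (n = a+b+c+d):
#   ROR = (a*d)/(b*c), 95% CI = exp(ln ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))
#   PRR = [a/(a+b)] / [c/(c+d)],
#     chi^2 = n(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]   (Pearson, no Yates)
#   RRR = a*n / [(a+b)(a+c)]  -- observed over expected, E = (a+b)(a+c)/n
#   IC  = log2(RRR); IC025 by the Noren approximation
#   EBGM (simplified) = RRR; EB05 = exp(ln RRR - 1.645*sqrt(1/a+1/b+1/c+1/d))
# The full empirical-Bayes gamma-Poisson shrinker lives in mgps_full().

#' @noRd
table_cells <- function(tab, correction = FALSE) {
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  if (length(cells) != 4L || any(is.na(cells)) || any(cells < 0)) {
    stop("a contingency table needs non-negative cells a, b, c, d",
         call. = FALSE)
  }
  if (any(cells == 0)) {
    if (!correction) {
      stop("degenerate table: zero cell; enable the Haldane-Anscombe ",
           "correction (correction = TRUE) or drop the term", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  names(cells) <- c("a", "b", "c", "d")
  cells
}

#' Reporting odds ratio with 95% confidence interval
#'
#' @param tab A one-row contingency table (list/data.frame with `a, b, c,
#'   d`).
#' @param correction Apply the Haldane-Anscombe 0.5 continuity correction
#'   to zero cells (default: a zero cell is an error).
#' @return Named list: `ror`, `low`, `high`.
#' @export
ror <- function(tab, correction = FALSE) {
  x <- table_cells(tab, correction)
  est <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  list(ror = unname(est),
       low = unname(exp(log(est) - 1.96 * se)),
       high = unname(exp(log(est) + 1.96 * se)))
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' @inheritParams ror
#' @param yates Apply Yates continuity correction to the chi-squared
#'   statistic (default off, the convention in FAERS disproportionality
#'   work).
#' @return Named list: `prr`, `chi2`.
#' @export
prr <- function(tab, correction = FALSE, yates = FALSE) {
  x <- table_cells(tab, correction)
  a <- x["a"]; b <- x["b"]; c_ <- x["c"]; d <- x["d"]
  n <- a + b + c_ + d
  est <- (a / (a + b)) / (c_ / (c_ + d))
  dev <- abs(a * d - b * c_)
  if (yates) dev <- max(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(prr = unname(est), chi2 = unname(chi2))
}

#' Relative reporting ratio (observed over expected)
#'
#' `RRR = a*n / [(a+b)(a+c)]`, the observed count over its
#' independence-model expectation; the quantity underlying both the
#' information component and the gamma-Poisson shrinker.
#'
#' @inheritParams ror
#' @return Numeric scalar.
#' @export
rrr <- function(tab, correction = FALSE) {
  x <- table_cells(tab, correction)
  n <- sum(x)
  unname(x["a"] * n / ((x["a"] + x["b"]) * (x["a"] + x["c"])))
}

#' BCPNN information component with lower 95% bound
#'
#' `IC = log2(RRR)` in bits. The default lower bound `IC025` uses the Noren
#' closed-form approximation
#' `IC - 3.3*(a+0.5)^(-1/2) - 2.0*(a+0.5)^(-3/2)`; `ic025_mode = "fixed"`
#' subtracts a constant width instead (a non-standard compatibility mode
#' for outputs that print a near-constant IC-IC025 gap).
#'
#' @inheritParams ror
#' @param ic025_mode `"noren"` (default) or `"fixed"`.
#' @param fixed_width Width used when `ic025_mode = "fixed"`.
#' @return Named list: `ic`, `ic025`.
#' @export
information_component <- function(tab, correction = FALSE,
                                  ic025_mode = c("noren", "fixed"),
                                  fixed_width = 1.66) {
  ic025_mode <- match.arg(ic025_mode)
  x <- table_cells(tab, correction)
  ic <- log2(rrr(tab, correction))
  if (ic025_mode == "noren") {
    a <- x["a"]
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2.0 * (a + 0.5)^(-1.5)
  } else {
    ic025 <- ic - fixed_width
  }
  list(ic = unname(ic), ic025 = unname(ic025))
}

#' Simplified gamma-Poisson shrinker point estimate and lower bound
#'
#' Point estimate equal to the relative reporting ratio (the
#' observed/expected ratio that the empirical-Bayes geometric mean shrinks
#' toward for well-populated cells), with
#' `EB05 = exp(ln RRR - 1.645*sqrt(1/a+1/b+1/c+1/d))`. For the full
#' DuMouchel empirical-Bayes fit across many tables, see [mgps_full()].
#'
#' @inheritParams ror
#' @return Named list: `ebgm`, `ebgm05`.
#' @export
ebgm_simple <- function(tab, correction = FALSE) {
  x <- table_cells(tab, correction)
  est <- rrr(tab, correction)
  se <- sqrt(sum(1 / x))
  list(ebgm = est, ebgm05 = unname(exp(log(est) - 1.645 * se)))
}

#' Signal criteria thresholds
#'
#' The standard pharmacovigilance thresholds: ROR requires case count
#' `N >= 3` and lower 95% CI bound `> 1`; PRR requires `PRR >= 2`,
#' `chi2 >= 4` and `N >= 3`; BCPNN requires `IC025 > 0`; MGPS requires
#' `EB05 > 2`.
#'
#' @param ror_n,ror_low,prr_min,chi2_min,prr_n,ic025_min,ebgm05_min
#'   Thresholds; defaults as above.
#' @param require_ror If `TRUE`, "significant" additionally requires the
#'   ROR criterion among the met criteria.
#' @return Object of class `signal_criteria`.
#' @export
signal_criteria <- function(ror_n = 3L, ror_low = 1, prr_min = 2,
                            chi2_min = 4, prr_n = 3L, ic025_min = 0,
                            ebgm05_min = 2, require_ror = FALSE) {
  structure(list(ror_n = ror_n, ror_low = ror_low, prr_min = prr_min,
                 chi2_min = chi2_min, prr_n = prr_n, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min, require_ror = require_ror),
            class = "signal_criteria")
}

#' Classify a signal from its four estimators
#'
#' A term is `positive` when the ROR criterion is met, and `significant`
#' when two or more of the four algorithm criteria are met (any two by
#' default; set `require_ror` in [signal_criteria()] to demand ROR among
#' them).
#'
#' @param stats List/one-row data.frame with `N` (case count a), `ror_low`,
#'   `prr`, `chi2`, `ic025`, `ebgm05`.
#' @param criteria A [signal_criteria()].
#' @return List: `flags` (named logical over ror/prr/bcpnn/mgps),
#'   `n_met`, `classification` in `none/positive/significant`.
#' @export
classify_signal <- function(stats, criteria = signal_criteria()) {
  flags <- c(
    ror = stats$N >= criteria$ror_n && stats$ror_low > criteria$ror_low,
    prr = stats$prr >= criteria$prr_min && stats$chi2 >= criteria$chi2_min &&
      stats$N >= criteria$prr_n,
    bcpnn = stats$ic025 > criteria$ic025_min,
    mgps = stats$ebgm05 > criteria$ebgm05_min
  )
  n_met <- sum(flags)
  significant <- n_met >= 2L && (!criteria$require_ror || flags[["ror"]])
  classification <- if (significant) "significant"
    else if (flags[["ror"]]) "positive" else "none"
  list(flags = flags, n_met = n_met, classification = classification)
}

#' Compute all four estimators and classification for a set of tables
#'
#' Vectorized driver over the rows of a contingency table set (from
#' [build_all()]); mirrors the standard signal-table layout: term, N,
#' ROR (CI), PRR (chi2), IC (IC025), EBGM (EB05), flags, classification.
#'
#' @param tables `data.table` with columns `term, level, a, b, c, d`.
#' @param criteria A [signal_criteria()].
#' @param correction,ic025_mode,fixed_width Passed to the estimators.
#' @param ebgm_mode `"simple"` (closed form, default) or `"dumouchel"`
#'   (full empirical-Bayes fit via [mgps_full()] across all rows).
#' @return `data.table` with estimator columns, per-algorithm flag columns
#'   (`flag_ror`, `flag_prr`, `flag_bcpnn`, `flag_mgps`), `n_criteria`, and
#'   `classification`.
#' @export
signal_table <- function(tables, criteria = signal_criteria(),
                         correction = FALSE,
                         ic025_mode = "noren", fixed_width = 1.66,
                         ebgm_mode = c("simple", "dumouchel")) {
  ebgm_mode <- match.arg(ebgm_mode)
  tables <- data.table::as.data.table(tables)
  if (!nrow(tables)) {
    return(data.table::data.table(
      term = character(), level = character(), N = integer(),
      ror = numeric(), ror_low = numeric(), ror_high = numeric(),
      prr = numeric(), chi2 = numeric(), ic = numeric(), ic025 = numeric(),
      ebgm = numeric(), ebgm05 = numeric(),
      flag_ror = logical(), flag_prr = logical(), flag_bcpnn = logical(),
      flag_mgps = logical(), n_criteria = integer(),
      classification = character()))
  }
  rows <- lapply(seq_len(nrow(tables)), function(i) {
    tab <- tables[i]
    r <- ror(tab, correction)
    p <- prr(tab, correction)
    ic <- information_component(tab, correction, ic025_mode, fixed_width)
    e <- ebgm_simple(tab, correction)
    data.table::data.table(
      term = tab$term, level = tab$level, N = as.integer(tab$a),
      ror = r$ror, ror_low = r$low, ror_high = r$high,
      prr = p$prr, chi2 = p$chi2, ic = ic$ic, ic025 = ic$ic025,
      ebgm = e$ebgm, ebgm05 = e$ebgm05)
  })
  out <- data.table::rbindlist(rows)
  if (ebgm_mode == "dumouchel") {
    fit <- mgps_full(tables)
    out$ebgm <- fit$results$ebgm
    out$ebgm05 <- fit$results$eb05
  }
  cls <- lapply(seq_len(nrow(out)), function(i) {
    classify_signal(out[i], criteria)
  })
  out$flag_ror <- vapply(cls, function(z) z$flags[["ror"]], logical(1))
  out$flag_prr <- vapply(cls, function(z) z$flags[["prr"]], logical(1))
  out$flag_bcpnn <- vapply(cls, function(z) z$flags[["bcpnn"]], logical(1))
  out$flag_mgps <- vapply(cls, function(z) z$flags[["mgps"]], logical(1))
  out$n_criteria <- vapply(cls, function(z) z$n_met, integer(1))
  out$classification <- vapply(cls, function(z) z$classification,
                               character(1))
  out[]
}

#' Export a signal table, rounded for reporting
#'
#' Writes the standard column layout with estimates rounded to 2 decimals
#' (full precision is retained in the in-memory table).
#'
#' @param sig `data.table` from [signal_table()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(sig, path) {
  out <- data.table::copy(sig)
  num <- c("ror", "ror_low", "ror_high", "prr", "chi2", "ic", "ic025",
           "ebgm", "ebgm05")
  for (cn in intersect(num, names(out))) out[[cn]] <- round(out[[cn]], 2)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
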