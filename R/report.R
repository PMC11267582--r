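# Descriptive reporting: demographic composition of the cleaned case set,
# sex-stratified signal tables, algorithm-overlap counts, and the
# end-to-end pipeline orchestrator.

#' Convert FAERS age entries to years
#'
#' Applies the `AGE_COD` unit: `YR` years, `DEC` decades, `MON` months,
#' `WK` weeks, `DY` days; a missing unit with a plausible numeric age is
#' taken as years; anything unparseable becomes `NA`.
#'
#' @param age,age_cod Character vectors from DEMO.
#' @return Numeric vector of ages in years.
#' @export
age_years <- function(age, age_cod) {
  num <- suppressWarnings(as.numeric(age))
  factor <- rep(NA_real_, length(num))
  cod <- toupper(trimws(age_cod))
  factor[cod == "YR"] <- 1
  factor[cod == "DEC"] <- 10
  factor[cod == "MON"] <- 1 / 12
  factor[cod == "WK"] <- 1 / 52.18
  factor[cod == "DY"] <- 1 / 365.25
  factor[cod == "" & !is.na(num)] <- 1
  num * factor
}

#' @noRd
count_table <- function(categories, total, order_by_count = FALSE) {
  tab <- table(categories)
  dt <- data.table::data.table(category = names(tab),
                               count = as.integer(tab))
  if (order_by_count) data.table::setorderv(dt, "count", order = -1L)
  dt$percent <- pct1(dt$count, total)
  dt
}

#' Demographic and administrative summary of a case set
#'
#' Case counts and percentages (1 decimal, denominators include unknowns)
#' per category: sex, age band (18-64 / 65-85 / >=86), weight band
#' (<50 / 50-100 / >100 kg), reporter occupation, reporter country,
#' serious outcomes, indications, and reporting year. `Unknown` is a
#' first-class category throughout.
#'
#' @param cs A `case_set`.
#' @return Object of class `demographics_summary`: named list of
#'   `data.table`s (`category`, `count`, `percent`) plus `total`.
#' @export
summarize_demographics <- function(cs) {
  demo <- cs$demo
  total <- nrow(demo)
  if (!total) {
    return(structure(list(tables = list(), total = 0L),
                     class = "demographics_summary"))
  }
  sex <- c(F = "Female", M = "Male")[toupper(trimws(demo$SEX))]
  sex[is.na(sex)] <- "Unknown"

  yrs <- age_years(demo$AGE, demo$AGE_COD)
  age_band <- rep("Unknown", total)
  age_band[!is.na(yrs) & yrs < 18] <- "<18"
  age_band[!is.na(yrs) & yrs >= 18 & yrs <= 64] <- "18-64"
  age_band[!is.na(yrs) & yrs >= 65 & yrs <= 85] <- "65-85"
  age_band[!is.na(yrs) & yrs > 85] <- ">=86"

  wt <- suppressWarnings(as.numeric(demo$WT))
  wt_band <- rep("Unknown", total)
  wt_band[!is.na(wt) & wt < 50] <- "<50"
  wt_band[!is.na(wt) & wt >= 50 & wt <= 100] <- "50-100"
  wt_band[!is.na(wt) & wt > 100] <- ">100"

  occ <- c(CN = "Consumer", HP = "Health professional", MD = "Physician",
           PH = "Pharmacist", OT = "Other")[toupper(trimws(demo$OCCP_COD))]
  occ[is.na(occ)] <- "Unknown"

  country <- trimws(demo$REPORTER_COUNTRY)
  country[!nzchar(country)] <- "Unknown"

  year <- substr(trimws(demo$FDA_DT), 1L, 4L)
  year[!grepl("^[0-9]{4}$", year)] <- "Unknown"

  tables <- list(
    sex = count_table(sex, total),
    age = count_table(age_band, total),
    weight = count_table(wt_band, total),
    reporter = count_table(occ, total, order_by_count = TRUE),
    country = count_table(country, total, order_by_count = TRUE),
    year = count_table(year, total)
  )

  # outcomes: a report may carry several; Unknown = no outcome row
  if (!is.null(cs$outc) && nrow(cs$outc)) {
    oc_map <- c(DE = "Death", LT = "Life-threatening", HO = "Hospitalization",
                DS = "Disability", CA = "Congenital anomaly",
                OT = "Other serious", RI = "Required intervention")
    oc <- cs$outc[cs$outc$PRIMARYID %in% demo$PRIMARYID]
    lab <- oc_map[toupper(trimws(oc$OUTC_COD))]
    lab[is.na(lab)] <- "Other serious"
    per <- unique(data.table::data.table(PRIMARYID = oc$PRIMARYID,
                                         category = lab))
    out_t <- per[, list(count = .N), by = "category"]
    unknown_n <- total - length(unique(per$PRIMARYID))
    out_t <- rbind(out_t, data.table::data.table(category = "Unknown",
                                                 count = unknown_n))
    data.table::setorderv(out_t, "count", order = -1L)
    out_t$percent <- pct1(out_t$count, total)
    tables$outcome <- out_t
  } else {
    tables$outcome <- data.table::data.table(category = "Unknown",
                                             count = total,
                                             percent = pct1(total, total))
  }

  if (!is.null(cs$indi) && nrow(cs$indi)) {
    ind <- cs$indi[cs$indi$PRIMARYID %in% demo$PRIMARYID]
    per <- unique(data.table::data.table(PRIMARYID = ind$PRIMARYID,
                                         category = trimws(ind$INDI_PT)))
    ind_t <- per[, list(count = .N), by = "category"]
    data.table::setorderv(ind_t, "count", order = -1L)
    ind_t$percent <- pct1(ind_t$count, total)
    tables$indication <- ind_t
  }

  structure(list(tables = tables, total = total),
            class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("Demographics summary: %d reports\n", x$total))
  for (nm in names(x$tables)) {
    tab <- utils::head(x$tables[[nm]], 8L)
    cat(sprintf("  %s:\n", nm))
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-28s %6d  (%.1f%%)\n", tab$category[i],
                  tab$count[i], tab$percent[i]))
    }
  }
  invisible(x)
}

#' Sex-stratified signal tables with a between-stratum test
#'
#' Computes the full four-algorithm signal table separately for female and
#' male reports (unknown-sex reports are dropped from both strata) and
#' tests the difference of log reporting odds ratios between strata with a
#' z-test on pooled standard errors. Terms with no target case in a
#' stratum are reported one-sided with `NA` for that stratum.
#'
#' @param target,background `case_set`s.
#' @param terms Character vector of PTs (default: every PT with at least
#'   `min_count` target cases overall).
#' @param criteria A [signal_criteria()].
#' @param min_count Minimum overall case count for default term selection.
#' @return `data.table`: one row per term with per-stratum `N`, `ror`,
#'   `ror_low`, `ror_high`, `classification` (suffix `_f`/`_m`), plus `z`
#'   and `p_value`.
#' @export
stratify_by_sex <- function(target, background, terms = NULL,
                            criteria = signal_criteria(), min_count = 3L) {
  sex_ids <- function(cs, code) {
    cs$demo$PRIMARYID[toupper(trimws(cs$demo$SEX)) == code]
  }
  strata <- list(
    f = list(target = subset_case_set(target, sex_ids(target, "F")),
             background = subset_case_set(background,
                                          sex_ids(background, "F"))),
    m = list(target = subset_case_set(target, sex_ids(target, "M")),
             background = subset_case_set(background,
                                          sex_ids(background, "M")))
  )
  if (is.null(terms)) {
    all_tab <- build_all(target, background, level = "PT")
    terms <- all_tab$term[all_tab$a >= min_count]
  }
  per_stratum <- lapply(strata, function(s) {
    tabs <- build_all(s$target, s$background, level = "PT", min_count = 1L)
    tabs[tabs$term %in% terms & tabs$a > 0 & tabs$b > 0 & tabs$c > 0 &
           tabs$d > 0]
  })
  sigs <- lapply(per_stratum, function(tabs) {
    if (nrow(tabs)) signal_table(tabs, criteria) else signal_table(tabs)
  })
  out <- data.table::data.table(term = terms)
  for (st in c("f", "m")) {
    s <- sigs[[st]]
    idx <- match(terms, s$term)
    out[[paste0("N_", st)]] <- s$N[idx]
    out[[paste0("ror_", st)]] <- s$ror[idx]
    out[[paste0("ror_low_", st)]] <- s$ror_low[idx]
    out[[paste0("ror_high_", st)]] <- s$ror_high[idx]
    out[[paste0("classification_", st)]] <- s$classification[idx]
  }
  # z-test on the difference of log RORs; SE from the CI width
  se <- function(low, high) (log(high) - log(low)) / (2 * 1.96)
  se_f <- se(out$ror_low_f, out$ror_high_f)
  se_m <- se(out$ror_low_m, out$ror_high_m)
  out$z <- (log(out$ror_f) - log(out$ror_m)) / sqrt(se_f^2 + se_m^2)
  out$p_value <- 2 * stats::pnorm(-abs(out$z))
  out
}

#' Algorithm-overlap counts for a signal table
#'
#' How many terms satisfy exactly 0..4 of the four criteria, how many
#' satisfy each count or more, and the count per criteria subset --
#' a tabular substitute for a Venn diagram.
#'
#' @param sig `data.table` from [signal_table()].
#' @return List: `by_n_criteria` (exact counts), `at_least` (cumulative),
#'   `by_subset` (`data.table` of flag combinations).
#' @export
criteria_overlap <- function(sig) {
  n_tab <- vapply(0:4, function(k) sum(sig$n_criteria == k), integer(1))
  names(n_tab) <- as.character(0:4)
  at_least <- rev(cumsum(rev(n_tab)))
  combo <- apply(cbind(ror = sig$flag_ror, prr = sig$flag_prr,
                       bcpnn = sig$flag_bcpnn, mgps = sig$flag_mgps), 1L,
                 function(f) paste(names(f)[f], collapse = "+"))
  combo[combo == ""] <- "(none)"
  by_subset <- data.table::data.table(criteria = combo)[, list(count = .N),
                                                        by = "criteria"]
  data.table::setorderv(by_subset, "count", order = -1L)
  list(by_n_criteria = n_tab, at_least = at_least, by_subset = by_subset)
}

#' Run the full pipeline: clean, signal-detect, time-to-onset, report
#'
#' Orchestrates ingest -> contingency -> four-algorithm signals (PT and
#' SOC) -> algorithm overlap -> TTO analysis (summary, bins, growth rates,
#' Weibull fit, KS goodness of fit, per-SOC Kruskal-Wallis) ->
#' demographics -> sex-stratified signals, writing delimited outputs and a
#' JSON run log to `out_dir`. Any stage failure aborts with the stage name.
#'
#' @param input A directory of FAERS-dialect quarterly files, a
#'   `faers_dataset`, or a named list of area tables.
#' @param out_dir Output directory.
#' @param synonyms,pt_exclusions,indication_exclusion Cleaning
#'   configuration.
#' @param map PT->SOC map (`data.table` with `pt`, `soc`); defaults to the
#'   demonstration vocabulary's map.
#' @param criteria A [signal_criteria()].
#' @param ic025_mode,ebgm_mode Estimator variants (see [signal_table()]).
#' @param levels Which aggregation levels to run (`"PT"`, `"SOC"`).
#' @return Invisibly, a list with the cleaned sets, signal tables, TTO
#'   results, demographics, stratified signals, overlap counts and run log.
#' @export
run_pipeline <- function(input, out_dir,
                         synonyms = default_synonyms(),
                         pt_exclusions = default_pt_exclusions(),
                         indication_exclusion = default_indication_exclusion(),
                         map = NULL,
                         criteria = signal_criteria(),
                         ic025_mode = "noren",
                         ebgm_mode = "simple",
                         levels = c("PT", "SOC")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(map)) {
    map <- default_pt_vocabulary()[, c("pt", "soc"), with = FALSE]
  }

  tables <- stage("load", {
    if (is.character(input)) read_faers_dir(input)
    else if (inherits(input, "faers_dataset")) input$tables
    else input
  })

  cleaned <- stage("clean", clean_cases(tables, synonyms, pt_exclusions,
                                        indication_exclusion))
  write_cleaning_report(cleaned$report,
                        file.path(out_dir, "cleaning_report.json"))
  data.table::fwrite(cleaned$target$demo,
                     file.path(out_dir, "cleaned_target_demo.tsv"),
                     sep = "\t")

  sigs <- list()
  overlaps <- list()
  for (lv in levels) {
    tabs <- stage(paste0("contingency_", lv),
                  build_all(cleaned$target, cleaned$background, level = lv,
                            map = map))
    sig <- stage(paste0("signals_", lv),
                 signal_table(tabs[tabs$a > 0 & tabs$c > 0],
                              criteria = criteria,
                              ic025_mode = ic025_mode,
                              ebgm_mode = ebgm_mode))
    write_contingency(tabs, file.path(out_dir,
                                      sprintf("contingency_%s.tsv",
                                              tolower(lv))))
    write_signal_table(sig, file.path(out_dir,
                                      sprintf("signals_%s.tsv",
                                              tolower(lv))))
    sigs[[lv]] <- sig
    overlaps[[lv]] <- criteria_overlap(sig)
  }
  jsonlite::write_json(
    lapply(overlaps, function(o) list(by_n_criteria = as.list(o$by_n_criteria),
                                      at_least = as.list(o$at_least))),
    file.path(out_dir, "criteria_overlap.json"), auto_unbox = TRUE,
    pretty = TRUE)

  tto_res <- stage("tto", compute_tto(cleaned$target, synonyms))
  data.table::fwrite(tto_res$tto, file.path(out_dir, "tto.tsv"), sep = "\t")
  data.table::fwrite(tto_res$exclusions,
                     file.path(out_dir, "tto_exclusions.tsv"), sep = "\t")
  tto_summary <- NULL
  weib <- NULL
  ks <- NULL
  bins <- NULL
  if (nrow(tto_res$tto) >= 10L) {
    tto_summary <- summarize_tto(tto_res$tto$tto_days)
    bins <- stage("tto_bins", bin_counts(tto_res$tto$tto_days))
    weib <- stage("weibull", fit_weibull(tto_res$tto$tto_days))
    ks <- stage("ks", weibull_ks_test(tto_res$tto$tto_days, weib))
    jsonlite::write_json(list(
      summary = tto_summary,
      bins = list(month = bins$month, quarter = bins$quarter,
                  over_year = bins$over_year,
                  quarter_growth_rate = growth_rate(bins$quarter)),
      weibull = list(shape = weib$shape, shape_ci = weib$shape_ci,
                     scale = weib$scale, scale_ci = weib$scale_ci,
                     onset_type = weib$onset_type, n = weib$n),
      ks = ks), file.path(out_dir, "tto_analysis.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  demog <- stage("demographics", summarize_demographics(cleaned$target))
  for (nm in names(demog$tables)) {
    data.table::fwrite(demog$tables[[nm]],
                       file.path(out_dir,
                                 sprintf("demographics_%s.tsv", nm)),
                       sep = "\t")
  }

  strat <- NULL
  if ("PT" %in% names(sigs) && nrow(sigs$PT)) {
    sig_terms <- sigs$PT$term[sigs$PT$classification != "none"]
    if (length(sig_terms)) {
      strat <- stage("stratify",
                     stratify_by_sex(cleaned$target, cleaned$background,
                                     terms = sig_terms,
                                     criteria = criteria))
      data.table::fwrite(strat, file.path(out_dir, "signals_by_sex.tsv"),
                         sep = "\t")
    }
  }

  log <- list(
    stages = as.list(cleaned$report$stages),
    n_target = n_cases(cleaned$target),
    n_background = n_cases(cleaned$background),
    n_tto = nrow(tto_res$tto),
    n_tto_excluded = nrow(tto_res$exclusions),
    levels = levels,
    ic025_mode = ic025_mode,
    ebgm_mode = ebgm_mode,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cleaned = cleaned, signals = sigs, overlap = overlaps,
                 tto = tto_res, tto_summary = tto_summary, bins = bins,
                 weibull = weib, ks = ks, demographics = demog,
                 stratified = strat, out_dir = out_dir, log = log))
}
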