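# Synthetic FAERS emitter: quarterly "$"-delimited table sets with a
# ground-truth ledger, so every downstream cleaning and signal-detection
# stage can be tested against known answers.

FAERS_AREAS <- c("demo", "drug", "reac", "ther", "indi", "outc", "rpsr")

#' Sample time-to-onset day counts from a Weibull law
#'
#' Draws `n` time-to-onset values (days from therapy start to event) from a
#' Weibull distribution with the given shape and scale and rounds them to
#' whole days, matching the day-resolution of spontaneous-report dates.
#'
#' @param n Number of draws (>= 0).
#' @param shape Weibull shape beta (> 0); values < 1 give a decreasing
#'   hazard ("early-failure" onset profile).
#' @param scale Weibull scale eta in days (> 0); about 63.2% of events
#'   occur within `scale` days regardless of shape.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of `n` non-negative day counts.
#' @examples
#' x <- sample_tto(1000, shape = 0.89, scale = 269.56, seed = 1)
#' mean(x <= 269.56)  # ~ 1 - exp(-1) = 0.632
#' @export
sample_tto <- function(n, shape, scale, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("n must be a single non-negative count", call. = FALSE)
  }
  if (!is.numeric(shape) || shape <= 0) {
    stop("shape must be > 0", call. = FALSE)
  }
  if (!is.numeric(scale) || scale <= 0) {
    stop("scale must be > 0", call. = FALSE)
  }
  if (n == 0) return(integer())
  if (!is.null(seed)) set.seed(as.integer(seed))
  as.integer(round(stats::rweibull(n, shape = shape, scale = scale)))
}

#' @noRd
sample_cat <- function(n, dist) {
  if (n == 0L) return(character())
  sample(names(dist), n, replace = TRUE, prob = dist)
}

#' @noRd
degrade_dates <- function(dt_int, missing_p, partial_p) {
  # dt_int: integer YYYYMMDD; returns character with "" (missing) and
  # YYYYMM (partial) degradations.
  n <- length(dt_int)
  out <- as.character(dt_int)
  u <- stats::runif(n)
  partial <- u >= missing_p & u < missing_p + partial_p
  out[partial] <- substr(out[partial], 1L, 6L)
  out[u < missing_p] <- ""
  out
}

#' @noRd
quarter_label <- function(d) {
  paste0(format(d, "%Y"), "Q", (as.POSIXlt(d)$mon %/% 3L) + 1L)
}

#' Generate a synthetic FAERS-like quarterly dataset
#'
#' Emits a full set of FAERS-dialect tables (DEMO, DRUG, REAC, THER, INDI,
#' OUTC, RPSR) for multi-quarter reporting, together with a ground-truth
#' ledger: which cases carry the target drug as primary suspect, the true
#' per-PT relative risks, the true duplicate-version structure, and the true
#' time-to-onset of each report. Target-drug reports sample each preferred
#' term with probability `base_prob * rr` (capped at 0.95); every report has
#' at least one drug and one PT; duplicate cases are emitted as a second
#' version with strictly larger `PRIMARYID` and later `FDA_DT`; event dates
#' equal therapy start plus a rounded Weibull(shape, scale) draw.
#'
#' @param config A [faers_config()].
#' @param out_dir Optional directory; when given, quarterly "$"-delimited
#'   files and the ledger are written there (see [write_dataset()]).
#' @return An object of class `faers_dataset`: list with `tables` (one
#'   `data.table` per area, plus internal `quarter` column), `ledger`
#'   (`cases`, `signals`, `pt_counts`), `quarters`, `config`, and `dir`
#'   (`NULL` unless written).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  validate_faers_config(config)
  set.seed(config$seed)
  n <- config$n_reports
  dg <- config$demographic_distributions
  miss <- config$missingness

  if (n == 0L) {
    ds <- empty_dataset(config)
    if (!is.null(out_dir)) ds <- write_dataset(ds, out_dir)
    return(ds)
  }

  caseid <- 100000000L + seq_len(n)
  is_target <- stats::runif(n) < config$target_fraction

  ## reporting date within a quarter drawn from the yearly volume profile
  year <- sample_cat(n, dg$year)
  qtr <- sample(1:4, n, replace = TRUE)
  q_start <- as.Date(paste0(year, "-", c("01", "04", "07", "10")[qtr], "-01"))
  fda_date <- q_start + sample.int(90L, n, replace = TRUE) - 1L

  ## demographics with configured missingness
  sex <- sample_cat(n, dg$sex)
  sex <- c(Female = "F", Male = "M")[sex]
  sex[stats::runif(n) < miss$sex] <- ""

  age_band <- sample_cat(n, dg$age)
  age <- integer(n)
  age[age_band == "18-64"] <- sample(18:64, sum(age_band == "18-64"), TRUE)
  age[age_band == "65-85"] <- sample(65:85, sum(age_band == "65-85"), TRUE)
  age[age_band == ">=86"] <- sample(86:99, sum(age_band == ">=86"), TRUE)
  age_chr <- as.character(age)
  age_cod <- rep("YR", n)
  age_miss <- stats::runif(n) < miss$age
  age_chr[age_miss] <- ""
  age_cod[age_miss] <- ""

  wt_band <- sample_cat(n, dg$weight)
  wt <- numeric(n)
  wt[wt_band == "<50"] <- round(stats::runif(sum(wt_band == "<50"), 35, 49.9), 1)
  wt[wt_band == "50-100"] <- round(stats::runif(sum(wt_band == "50-100"), 50, 100), 1)
  wt[wt_band == ">100"] <- round(stats::runif(sum(wt_band == ">100"), 100.1, 140), 1)
  wt_chr <- as.character(wt)
  wt_cod <- rep("KG", n)
  wt_miss <- stats::runif(n) < miss$weight
  wt_chr[wt_miss] <- ""
  wt_cod[wt_miss] <- ""

  reporter <- sample_cat(n, dg$reporter)
  occp <- c(Consumer = "CN", `Health professional` = "HP", Physician = "MD",
            Pharmacist = "PH", Other = "OT", Unknown = "")[reporter]

  country <- sample_cat(n, dg$country)
  other_countries <- c("FR", "IT", "CA", "JP", "BR", "NL", "IN")
  country[country == "Other"] <-
    sample(other_countries, sum(country == "Other"), TRUE)

  outcome <- sample_cat(n, dg$outcome)
  outc_cod <- c(`Other serious` = "OT", Hospitalization = "HO", Death = "DE",
                `Life-threatening` = "LT", Disability = "DS",
                `Congenital anomaly` = "CA", Unknown = "")[outcome]

  indication <- sample_cat(n, dg$indication)
  other_indis <- c("Acne", "Eczema", "Arthritis", "Asthma")
  indication[indication == "Other"] <-
    sample(other_indis, sum(indication == "Other"), TRUE)

  ## drugs: one PS drug per report; extras get SS/C/I roles
  n_drugs <- 1L + pmin(stats::rgeom(n, config$drugs_per_report_p),
                       config$max_drugs - 1L)
  bg <- config$background_drugs
  ps_name <- character(n)
  ps_name[is_target] <- sample(config$synonym_variants, sum(is_target), TRUE)
  ps_name[!is_target] <- sample(bg$name, sum(!is_target), TRUE,
                                prob = bg$weight)

  ## PT incidence matrix: Bernoulli per vocabulary term, with injected
  ## relative risks applied to target-PS reports
  vocab <- config$pt_vocabulary
  rr <- rep(1, nrow(vocab))
  if (nrow(config$injected_signals)) {
    idx <- match(config$injected_signals$pt, vocab$pt)
    rr[idx] <- config$injected_signals$rr
  }
  p_bg <- vocab$base_prob
  p_tg <- pmin(p_bg * rr, 0.95)
  pt_mat <- matrix(FALSE, n, nrow(vocab))
  for (j in seq_len(nrow(vocab))) {
    p <- ifelse(is_target, p_tg[j], p_bg[j])
    pt_mat[, j] <- stats::runif(n) < p
  }
  none <- rowSums(pt_mat) == 0L
  if (any(none)) {
    for (i in which(none)) {
      p <- if (is_target[i]) p_tg else p_bg
      pt_mat[i, sample.int(nrow(vocab), 1L, prob = p)] <- TRUE
    }
  }
  has_excl_pt <- stats::runif(n) < config$excluded_pt_rate
  has_excl_indi <- stats::runif(n) < config$excluded_pt_rate

  ## dates: event = fda - reporting delay; start = event - true TTO
  tto_true <- as.integer(round(stats::rweibull(n, config$tto_shape,
                                               config$tto_scale)))
  neg_err <- stats::runif(n) < config$negative_tto_rate
  delay <- sample(10:120, n, replace = TRUE)
  event_date <- fda_date - delay
  start_date <- event_date - tto_true
  # input-error reports: therapy start recorded after the event
  start_date[neg_err] <- event_date[neg_err] +
    sample(1:200, sum(neg_err), replace = TRUE)
  event_chr <- degrade_dates(date_to_int(event_date), miss$event_dt,
                             config$partial_date_rate)
  start_chr <- degrade_dates(date_to_int(start_date), miss$start_dt,
                             config$partial_date_rate)
  end_chr <- degrade_dates(date_to_int(event_date + 30L), 0.5,
                           config$partial_date_rate)

  ## duplicate versions: same case, larger PRIMARYID, later FDA_DT
  dup <- stats::runif(n) < config$duplicate_rate
  fda2_date <- fda_date + sample(1:90, n, replace = TRUE)

  case_idx <- c(seq_len(n), which(dup))
  version <- c(rep(1L, n), rep(2L, sum(dup)))
  v_fda <- c(fda_date, fda2_date[dup])
  primaryid <- sprintf("%d%02d", caseid[case_idx], version)
  v_quarter <- quarter_label(v_fda)
  o <- order(case_idx, version)
  case_idx <- case_idx[o]; version <- version[o]
  v_fda <- v_fda[o]; primaryid <- primaryid[o]; v_quarter <- v_quarter[o]

  demo <- data.table::data.table(
    quarter = v_quarter,
    PRIMARYID = primaryid,
    CASEID = as.character(caseid[case_idx]),
    FDA_DT = as.character(date_to_int(v_fda)),
    EVENT_DT = event_chr[case_idx],
    SEX = sex[case_idx],
    AGE = age_chr[case_idx],
    AGE_COD = age_cod[case_idx],
    WT = wt_chr[case_idx],
    WT_COD = wt_cod[case_idx],
    OCCP_COD = occp[case_idx],
    REPORTER_COUNTRY = country[case_idx]
  )

  ## long drug table
  extra <- n_drugs - 1L
  drug_case <- c(seq_len(n), rep(seq_len(n), extra))
  drug_seq <- c(rep(1L, n), sequence(extra) + 1L)
  dname <- character(length(drug_case))
  dname[seq_len(n)] <- ps_name
  n_extra <- length(drug_case) - n
  if (n_extra) {
    sec <- sample(bg$name, n_extra, TRUE, prob = bg$weight)
    # occasionally the target appears in a non-PS role on background reports
    swap <- stats::runif(n_extra) < config$target_nonps_rate &
      !is_target[drug_case[-seq_len(n)]]
    sec[swap] <- config$target_drug_name
    dname[-seq_len(n)] <- sec
  }
  role <- c(rep("PS", n),
            if (n_extra) sample(names(config$role_code_probs), n_extra, TRUE,
                                prob = config$role_code_probs) else character())
  do <- order(drug_case, drug_seq)
  drug_case <- drug_case[do]; drug_seq <- drug_seq[do]
  dname <- dname[do]; role <- role[do]

  drug_rows <- data.table::data.table(case = drug_case, DRUG_SEQ = drug_seq,
                                      DRUGNAME = dname, ROLE_COD = role)
  drug <- expand_versions(drug_rows, case_idx, version, primaryid, caseid,
                          v_quarter)

  ## reaction table (vocabulary PTs + injected exclusion-list PT)
  reac_case <- rep(seq_len(n), times = rowSums(pt_mat))
  reac_pt <- vocab$pt[unlist(apply(pt_mat, 1L, which, simplify = FALSE),
                             use.names = FALSE)]
  if (any(has_excl_pt)) {
    reac_case <- c(reac_case, which(has_excl_pt))
    reac_pt <- c(reac_pt, rep(config$excluded_pt_name, sum(has_excl_pt)))
  }
  ro <- order(reac_case)
  reac_rows <- data.table::data.table(case = reac_case[ro], PT = reac_pt[ro])
  reac <- expand_versions(reac_rows, case_idx, version, primaryid, caseid,
                          v_quarter)

  ther_rows <- data.table::data.table(case = seq_len(n), DSG_DRUG_SEQ = 1L,
                                      START_DT = start_chr, END_DT = end_chr)
  ther <- expand_versions(ther_rows, case_idx, version, primaryid, caseid,
                          v_quarter)

  indi_case <- seq_len(n)
  indi_pt <- indication
  if (any(has_excl_indi)) {
    indi_case <- c(indi_case, which(has_excl_indi))
    indi_pt <- c(indi_pt, rep(default_indication_exclusion(),
                              sum(has_excl_indi)))
  }
  io <- order(indi_case)
  indi_rows <- data.table::data.table(case = indi_case[io],
                                      INDI_DRUG_SEQ = 1L,
                                      INDI_PT = indi_pt[io])
  indi <- expand_versions(indi_rows, case_idx, version, primaryid, caseid,
                          v_quarter)

  has_outc <- outc_cod != ""
  outc_rows <- data.table::data.table(case = which(has_outc),
                                      OUTC_COD = outc_cod[has_outc])
  outc <- expand_versions(outc_rows, case_idx, version, primaryid, caseid,
                          v_quarter)

  rpsr_rows <- data.table::data.table(case = seq_len(n),
                                      RPSR_COD = ifelse(country == "US",
                                                        "CSM", "FGN"))
  rpsr <- expand_versions(rpsr_rows, case_idx, version, primaryid, caseid,
                          v_quarter)

  ## ground-truth ledger
  event_full <- date_status(event_chr) == "full"
  start_full <- date_status(start_chr) == "full"
  ledger_cases <- data.table::data.table(
    caseid = as.character(caseid),
    n_versions = 1L + as.integer(dup),
    final_primaryid = sprintf("%d%02d", caseid, 1L + as.integer(dup)),
    is_target = is_target,
    sex = sex,
    tto_true = tto_true,
    tto_negative = neg_err,
    tto_usable = is_target & event_full & start_full & !neg_err,
    n_pts = rowSums(pt_mat),
    has_excluded_pt = has_excl_pt
  )
  target_final <- is_target
  pt_counts <- data.table::data.table(
    pt = vocab$pt,
    soc = vocab$soc,
    a_true = colSums(pt_mat[target_final, , drop = FALSE]),
    bg_true = colSums(pt_mat[!target_final, , drop = FALSE])
  )
  signals <- data.table::data.table(pt = vocab$pt, soc = vocab$soc,
                                    base_prob = p_bg, rr = rr,
                                    p_target = p_tg)

  ds <- structure(list(
    tables = list(demo = demo, drug = drug, reac = reac, ther = ther,
                  indi = indi, outc = outc, rpsr = rpsr),
    ledger = list(cases = ledger_cases, signals = signals,
                  pt_counts = pt_counts),
    quarters = sort(unique(v_quarter)),
    config = config,
    dir = NULL
  ), class = "faers_dataset")
  if (!is.null(out_dir)) ds <- write_dataset(ds, out_dir)
  ds
}

#' @noRd
expand_versions <- function(rows, case_idx, version, primaryid, caseid,
                            v_quarter) {
  # replicate per-case child rows for every emitted version of the case
  vmap <- data.table::data.table(vrow = seq_along(case_idx),
                                 case = case_idx)
  merged <- merge(vmap, rows, by = "case", allow.cartesian = TRUE,
                  sort = FALSE)
  data.table::setorder(merged, vrow)
  out <- data.table::data.table(
    quarter = v_quarter[merged$vrow],
    PRIMARYID = primaryid[merged$vrow],
    CASEID = as.character(caseid[merged$case])
  )
  for (cn in setdiff(names(rows), "case")) out[[cn]] <- merged[[cn]]
  out
}

#' @noRd
empty_dataset <- function(config) {
  empty <- function(cols) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character()), length(cols) + 1L),
                      c("quarter", cols)))
    dt
  }
  structure(list(
    tables = list(
      demo = empty(c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "SEX",
                     "AGE", "AGE_COD", "WT", "WT_COD", "OCCP_COD",
                     "REPORTER_COUNTRY")),
      drug = empty(c("PRIMARYID", "CASEID", "DRUG_SEQ", "DRUGNAME",
                     "ROLE_COD")),
      reac = empty(c("PRIMARYID", "CASEID", "PT")),
      ther = empty(c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT",
                     "END_DT")),
      indi = empty(c("PRIMARYID", "CASEID", "INDI_DRUG_SEQ", "INDI_PT")),
      outc = empty(c("PRIMARYID", "CASEID", "OUTC_COD")),
      rpsr = empty(c("PRIMARYID", "CASEID", "RPSR_COD"))
    ),
    ledger = list(
      cases = data.table::data.table(caseid = character(),
                                     n_versions = integer(),
                                     final_primaryid = character(),
                                     is_target = logical(),
                                     sex = character(),
                                     tto_true = integer(),
                                     tto_negative = logical(),
                                     tto_usable = logical(),
                                     n_pts = integer(),
                                     has_excluded_pt = logical()),
      signals = data.table::data.table(pt = character(), soc = character(),
                                       base_prob = numeric(), rr = numeric(),
                                       p_target = numeric()),
      pt_counts = data.table::data.table(pt = character(), soc = character(),
                                         a_true = integer(),
                                         bg_true = integer())
    ),
    quarters = character(),
    config = config,
    dir = NULL
  ), class = "faers_dataset")
}

#' Write a synthetic dataset as FAERS-dialect quarterly files
#'
#' One "$"-delimited ASCII file per area per quarter
#' (`<area>_<quarter>.txt`, e.g. `demo_2020q1.txt`), first row = FAERS
#' column headers, plus the ground-truth ledger as tab-delimited sidecar
#' files (`ledger_cases.tsv`, `ledger_signals.tsv`, `ledger_pt_counts.tsv`).
#'
#' @param ds A `faers_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `ds` with `dir` set, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  quarters <- ds$quarters
  if (!length(quarters)) quarters <- "0000q0"  # still emit headers
  for (area in FAERS_AREAS) {
    tab <- ds$tables[[area]]
    for (q in quarters) {
      sub <- tab[tab$quarter == q,
                 setdiff(names(tab), "quarter"), with = FALSE]
      path <- file.path(out_dir,
                        sprintf("%s_%s.txt", area, tolower(q)))
      data.table::fwrite(sub, path, sep = "$", quote = FALSE)
    }
  }
  for (nm in names(ds$ledger)) {
    data.table::fwrite(ds$ledger[[nm]],
                       file.path(out_dir, sprintf("ledger_%s.tsv", nm)),
                       sep = "\t")
  }
  ds$dir <- out_dir
  invisible(ds)
}

#' @export
print.faers_dataset <- function(x, ...) {
  cat("Synthetic FAERS dataset\n")
  cat(sprintf("  cases: %d (%d demo rows incl. duplicate versions)\n",
              nrow(x$ledger$cases), nrow(x$tables$demo)))
  cat(sprintf("  target-PS cases: %d\n", sum(x$ledger$cases$is_target)))
  cat(sprintf("  quarters: %s\n", paste(x$quarters, collapse = " ")))
  if (!is.null(x$dir)) cat(sprintf("  written to: %s\n", x$dir))
  invisible(x)
}
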