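# Shared fixtures: tiny hand-built case sets and small generator configs.

# A case_set built directly from vectors; all tables keyed by PRIMARYID.
make_case_set <- function(demo, drug = NULL, reac = NULL, ther = NULL,
                          indi = NULL, outc = NULL) {
  as_dt <- function(x) if (is.null(x)) NULL else data.table::as.data.table(
    lapply(x, as.character))
  structure(list(demo = as_dt(demo), drug = as_dt(drug), reac = as_dt(reac),
                 ther = as_dt(ther), indi = as_dt(indi), outc = as_dt(outc),
                 rpsr = NULL),
            class = "case_set")
}

# Minimal DEMO row set with defaults for unused columns.
make_demo <- function(primaryid, caseid = primaryid,
                      fda_dt = "20200101", event_dt = "",
                      sex = "", age = "", age_cod = "", wt = "",
                      wt_cod = "", occp = "", country = "US") {
  data.table::data.table(
    PRIMARYID = as.character(primaryid), CASEID = as.character(caseid),
    FDA_DT = fda_dt, EVENT_DT = event_dt, SEX = sex, AGE = age,
    AGE_COD = age_cod, WT = wt, WT_COD = wt_cod, OCCP_COD = occp,
    REPORTER_COUNTRY = country)
}

small_config <- function(...) {
  faers_config(n_reports = 500, seed = 11, ...)
}

# Independent closed-form evaluation of the four estimators, written out
# directly so the package implementation is checked against plain
# arithmetic.
oracle_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  list(
    ror = ror,
    ror_low = exp(log(ror) - 1.96 * se),
    ror_high = exp(log(ror) + 1.96 * se),
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
    rrr = a * n / ((a + b) * (a + c)),
    ic = log2(a * n / ((a + b) * (a + c))),
    ebgm05 = exp(log(a * n / ((a + b) * (a + c))) - 1.645 * se)
  )
}

tab_row <- function(a, b, c, d) {
  data.table::data.table(term = "X", level = "PT", a = a, b = b, c = c,
                         d = d, n = a + b + c + d)
}
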