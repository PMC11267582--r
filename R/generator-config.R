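# Generator configuration: every distribution, rate and association strength
# for the synthetic FAERS emitter lives in one validated object.

#' Configuration for the synthetic FAERS generator
#'
#' Builds a validated configuration for [generate_dataset()]. Defaults
#' emulate the reporting profile of a recently approved psoriasis biologic
#' in a spontaneous-reporting system: consumer-dominated reporting, mostly
#' US reports, heavy missingness in age/weight, report volume growing by
#' year, multi-drug reports with exactly one primary-suspect (PS) drug, and
#' time-to-onset following a Weibull law with shape < 1 (early-failure
#' type).
#'
#' @param n_reports Number of distinct cases to emit (duplicate versions are
#'   extra rows on top of this).
#' @param target_drug_name Canonical target drug name.
#' @param synonym_variants Name variants used for the target drug's
#'   `DRUGNAME`; a random variant is used per report so synonym matching is
#'   exercised.
#' @param target_fraction Fraction of cases whose PS drug is the target.
#' @param background_drugs `data.frame(name, weight)` for background PS and
#'   concomitant drugs.
#' @param pt_vocabulary `data.frame(pt, soc, base_prob)`: baseline
#'   per-report occurrence probability of each preferred term.
#' @param injected_signals `data.frame(pt, rr)`: relative-risk multipliers
#'   (>= 0) applied to `base_prob` when the target drug is the PS drug.
#' @param role_code_probs Named probabilities over `SS`, `C`, `I` for
#'   non-primary drugs (exactly one drug per report carries role `PS`).
#' @param duplicate_rate Fraction of cases emitted as two versions (same
#'   `CASEID`, strictly increasing `FDA_DT` and `PRIMARYID`).
#' @param missingness Named list of per-field missing fractions:
#'   `sex`, `age`, `weight`, `event_dt`, `start_dt`.
#' @param partial_date_rate Fraction of recorded dates degraded to partial
#'   (`YYYYMM`) form.
#' @param excluded_pt_rate Rate at which one exclusion-list PT
#'   (`excluded_pt_name`) and the uninformative indication term are injected.
#' @param excluded_pt_name The injected exclusion-list PT.
#' @param negative_tto_rate Fraction of reports with the event dated before
#'   therapy start (input errors that TTO analysis must exclude).
#' @param target_nonps_rate Probability that a background report carries the
#'   target drug in a non-PS role.
#' @param drugs_per_report_p Success probability of the truncated geometric
#'   law for the number of drugs per report.
#' @param max_drugs Cap on drugs per report.
#' @param tto_shape,tto_scale True Weibull shape (beta) and scale (eta,
#'   days) of time to onset.
#' @param demographic_distributions Named list of categorical distributions
#'   (see [default_demographics()]).
#' @param seed Integer RNG seed.
#'
#' @return An object of class `faers_config`.
#' @export
faers_config <- function(n_reports = 5000L,
                         target_drug_name = "TILDRAKIZUMAB",
                         synonym_variants = default_synonyms(),
                         target_fraction = 0.05,
                         background_drugs = default_background_drugs(),
                         pt_vocabulary = default_pt_vocabulary(),
                         injected_signals = NULL,
                         role_code_probs = c(SS = 0.40, C = 0.45, I = 0.15),
                         duplicate_rate = 0.10,
                         missingness = list(sex = 0.16, age = 0.58,
                                            weight = 0.789,
                                            event_dt = 0.45,
                                            start_dt = 0.30),
                         partial_date_rate = 0.05,
                         excluded_pt_rate = 0.02,
                         excluded_pt_name = "Product dose omission issue",
                         negative_tto_rate = 0.01,
                         target_nonps_rate = 0.02,
                         drugs_per_report_p = 0.6,
                         max_drugs = 5L,
                         tto_shape = 0.89,
                         tto_scale = 269.56,
                         demographic_distributions = default_demographics(),
                         seed = 1L) {
  if (is.null(injected_signals)) {
    injected_signals <- data.table::data.table(pt = character(),
                                               rr = numeric())
  }
  cfg <- list(
    n_reports = as.integer(n_reports),
    target_drug_name = target_drug_name,
    synonym_variants = synonym_variants,
    target_fraction = target_fraction,
    background_drugs = data.table::as.data.table(background_drugs),
    pt_vocabulary = data.table::as.data.table(pt_vocabulary),
    injected_signals = data.table::as.data.table(injected_signals),
    role_code_probs = role_code_probs,
    duplicate_rate = duplicate_rate,
    missingness = missingness,
    partial_date_rate = partial_date_rate,
    excluded_pt_rate = excluded_pt_rate,
    excluded_pt_name = excluded_pt_name,
    negative_tto_rate = negative_tto_rate,
    target_nonps_rate = target_nonps_rate,
    drugs_per_report_p = drugs_per_report_p,
    max_drugs = as.integer(max_drugs),
    tto_shape = tto_shape,
    tto_scale = tto_scale,
    demographic_distributions = demographic_distributions,
    seed = as.integer(seed)
  )
  class(cfg) <- "faers_config"
  validate_faers_config(cfg)
  cfg
}

#' @noRd
config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration field '%s': %s", field, msg),
       call. = FALSE)
}

#' Validate a generator configuration
#'
#' Checks all probability, distribution and positivity invariants; errors
#' name the offending field.
#'
#' @param cfg A `faers_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_faers_config <- function(cfg) {
  frac01 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 0 && x <= 1
  if (!is.integer(cfg$n_reports) || is.na(cfg$n_reports) ||
      cfg$n_reports < 0L) {
    config_error("n_reports", "must be a non-negative integer")
  }
  if (!length(cfg$synonym_variants)) {
    config_error("synonym_variants", "must be non-empty")
  }
  for (f in c("target_fraction", "duplicate_rate", "partial_date_rate",
              "excluded_pt_rate", "negative_tto_rate", "target_nonps_rate",
              "drugs_per_report_p")) {
    if (!frac01(cfg[[f]])) config_error(f, "must be a probability in [0,1]")
  }
  for (f in names(cfg$missingness)) {
    if (!frac01(cfg$missingness[[f]])) {
      config_error(paste0("missingness$", f),
                   "must be a probability in [0,1]")
    }
  }
  v <- cfg$pt_vocabulary
  if (!all(c("pt", "soc", "base_prob") %in% names(v))) {
    config_error("pt_vocabulary", "needs columns pt, soc, base_prob")
  }
  if (anyDuplicated(v$pt)) config_error("pt_vocabulary", "duplicate PTs")
  if (!all(v$base_prob > 0 & v$base_prob < 1)) {
    config_error("pt_vocabulary", "base probabilities must lie in (0,1)")
  }
  s <- cfg$injected_signals
  if (nrow(s)) {
    if (!all(c("pt", "rr") %in% names(s))) {
      config_error("injected_signals", "needs columns pt, rr")
    }
    if (!all(s$rr >= 0)) config_error("injected_signals", "rr must be >= 0")
    if (!all(s$pt %in% v$pt)) {
      config_error("injected_signals", "signal PTs must be in pt_vocabulary")
    }
  }
  rp <- cfg$role_code_probs
  if (!all(names(rp) %in% c("PS", "SS", "C", "I")) ||
      abs(sum(rp) - 1) > 1e-9 || any(rp < 0)) {
    config_error("role_code_probs",
                 "must be a distribution over FAERS role codes summing to 1")
  }
  for (nm in names(cfg$demographic_distributions)) {
    d <- cfg$demographic_distributions[[nm]]
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      config_error(paste0("demographic_distributions$", nm),
                   "must be a probability vector summing to 1")
    }
  }
  if (!is.numeric(cfg$tto_shape) || cfg$tto_shape <= 0) {
    config_error("tto_shape", "must be > 0")
  }
  if (!is.numeric(cfg$tto_scale) || cfg$tto_scale <= 0) {
    config_error("tto_scale", "must be > 0")
  }
  bg <- cfg$background_drugs
  if (!all(c("name", "weight") %in% names(bg)) || !nrow(bg) ||
      any(bg$weight <= 0)) {
    config_error("background_drugs",
                 "needs rows of (name, weight) with positive weights")
  }
  invisible(cfg)
}

#' @export
print.faers_config <- function(x, ...) {
  cat("FAERS synthetic-generator configuration\n")
  cat(sprintf("  cases: %d (target PS fraction %.3f, duplicate rate %.2f)\n",
              x$n_reports, x$target_fraction, x$duplicate_rate))
  cat(sprintf("  target drug: %s (%d name variants)\n",
              x$target_drug_name, length(x$synonym_variants)))
  cat(sprintf("  PT vocabulary: %d terms in %d SOCs; %d injected signal(s)\n",
              nrow(x$pt_vocabulary), length(unique(x$pt_vocabulary$soc)),
              nrow(x$injected_signals)))
  cat(sprintf("  time to onset: Weibull(shape = %.3g, scale = %.4g days)\n",
              x$tto_shape, x$tto_scale))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
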