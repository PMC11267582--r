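# Shipped defaults: the target-drug synonym list, the PT/indication exclusion
# lists, a demonstration PT->SOC vocabulary, and demographic target
# distributions used by the synthetic generator.

#' Default tildrakizumab synonym list
#'
#' Brand and generic name variants under which the target drug appears in
#' FAERS `DRUGNAME` fields, including blinded-trial labels and the common
#' "IIUMYA"/"ILUMYA" spellings. Matching is case-insensitive and
#' whitespace-normalized (see [match_drug()]).
#'
#' @return Character vector of 12 name variants.
#' @export
default_synonyms <- function() {
  c(
    "TILDRAKIZUMAB",
    "IIUMYA",
    "ILUMYA",
    "SCH900222",
    "SCH-900222",
    "MK-3222",
    "BLINDED TILDRAKIZUMAB 100 MG ML INJECTION",
    "BLINDED TILDRAKIZUMAB INJECTION",
    "BLINDED TILDRAKIZUMAB",
    "TILDRAKIZUMAB ASMN",
    "ILUMYA TILDRAKIZUMAB",
    "ILUMYA TILDRAKIZUMAB ASMN"
  )
}

#' Default preferred-term exclusion list
#'
#' Non-drug-related administration/logistics terms removed from reaction
#' lists during cleaning (medication-error style PTs that do not describe an
#' adverse drug reaction).
#'
#' @return Character vector of PT names.
#' @export
default_pt_exclusions <- function() {
  c(
    "Product administration interrupted",
    "Product administration error",
    "Product distribution issue",
    "Product storage error",
    "Product dose omission issue",
    "Circumstance or information capable of leading to medication error",
    "Treatment noncompliance",
    "Needle issue",
    "Inappropriate schedule of product administration"
  )
}

#' Default indication exclusion term
#'
#' The uninformative indication entry removed from indication lists.
#'
#' @return Character scalar.
#' @export
default_indication_exclusion <- function() {
  "Product used for unknown indication"
}

#' Demonstration PT to SOC vocabulary
#'
#' A small MedDRA-like vocabulary: preferred terms, their primary system
#' organ class, and a baseline per-report occurrence probability used by the
#' synthetic generator. This is a demonstration mapping, not a licensed
#' MedDRA dictionary.
#'
#' @return `data.table` with columns `pt`, `soc`, `base_prob`.
#' @export
default_pt_vocabulary <- function() {
  inf <- "Infections and infestations"
  skin <- "Skin and subcutaneous tissue disorders"
  gen <- "General disorders and administration site conditions"
  gi <- "Gastrointestinal disorders"
  nerv <- "Nervous system disorders"
  card <- "Cardiac disorders"
  surg <- "Surgical and medical procedures"
  inj <- "Injury, poisoning and procedural complications"
  msk <- "Musculoskeletal and connective tissue disorders"
  resp <- "Respiratory, thoracic and mediastinal disorders"
  psy <- "Psychiatric disorders"
  inv <- "Investigations"
  data.table::data.table(
    pt = c(
      "Nasopharyngitis", "Upper respiratory tract infection",
      "Urinary tract infection", "Pneumonia", "Bronchitis", "Cellulitis",
      "Sinusitis", "Herpes zoster", "Vulvovaginal candidiasis",
      "Tuberculosis", "Herpes simplex", "Coronavirus infection",
      "Diverticulitis",
      "Psoriasis", "Pruritus", "Rash", "Urticaria", "Erythema", "Alopecia",
      "Drug ineffective", "Condition aggravated", "Fatigue", "Pyrexia",
      "Injection site pain", "Injection site urticaria",
      "Therapeutic response decreased", "Disease recurrence",
      "Therapy non-responder",
      "Nausea", "Diarrhoea", "Vomiting", "Abdominal pain", "Constipation",
      "Headache", "Dizziness", "Migraine", "Paraesthesia",
      "Atrial fibrillation", "Myocardial infarction", "Palpitations",
      "Aortic valve incompetence",
      "Therapy cessation", "Therapy interrupted",
      "Exposure during pregnancy", "Fall", "Contusion", "Meniscus injury",
      "Arthralgia", "Back pain", "Myalgia",
      "Cough", "Dyspnoea", "Oropharyngeal pain",
      "Insomnia", "Anxiety", "Depression",
      "Weight increased", "Blood pressure increased"
    ),
    soc = c(
      rep(inf, 13L), rep(skin, 6L), rep(gen, 9L), rep(gi, 5L),
      rep(nerv, 4L), rep(card, 4L), rep(surg, 2L), rep(inj, 4L),
      rep(msk, 3L), rep(resp, 3L), rep(psy, 3L), rep(inv, 2L)
    ),
    base_prob = c(
      0.030, 0.020, 0.018, 0.015, 0.010, 0.008, 0.008, 0.006, 0.002,
      0.001, 0.002, 0.004, 0.002,
      0.025, 0.030, 0.035, 0.012, 0.010, 0.008,
      0.120, 0.040, 0.050, 0.025, 0.020, 0.004, 0.010, 0.008, 0.006,
      0.045, 0.040, 0.025, 0.020, 0.012,
      0.055, 0.030, 0.010, 0.008,
      0.006, 0.006, 0.008, 0.001,
      0.010, 0.008,
      0.005, 0.020, 0.010, 0.001,
      0.040, 0.025, 0.015,
      0.025, 0.030, 0.010,
      0.015, 0.012, 0.012,
      0.015, 0.012
    )
  )
}

#' Default background drug list
#'
#' Co-reported / comparator drugs and sampling weights for the synthetic
#' generator's background reports.
#'
#' @return `data.table` with columns `name`, `weight`.
#' @export
default_background_drugs <- function() {
  data.table::data.table(
    name = c(
      "ADALIMUMAB", "USTEKINUMAB", "SECUKINUMAB", "ETANERCEPT",
      "METHOTREXATE", "PREDNISONE", "IBUPROFEN", "METFORMIN",
      "LISINOPRIL", "ATORVASTATIN", "OMEPRAZOLE", "SERTRALINE",
      "LEVOTHYROXINE", "AMLODIPINE", "GABAPENTIN"
    ),
    weight = c(10, 8, 8, 7, 6, 5, 5, 4, 4, 4, 3, 3, 3, 2, 2)
  )
}

#' Default demographic target distributions
#'
#' Categorical distributions (conditional on the value being recorded) that
#' the synthetic generator draws from: sex, age band, weight band, reporter
#' occupation, reporter country, one serious-outcome category per report,
#' indication, and reporting year. They reflect the composition typical of a
#' recently approved dermatology biologic in a spontaneous-reporting system:
#' consumer-dominated reporting, mostly US reports, heavy missingness in age
#' and weight, and report volume growing year on year.
#'
#' @return Named list of named probability vectors, each summing to 1.
#' @export
default_demographics <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(Female = 470, Male = 519)),
    age = norm(c(`18-64` = 295, `65-85` = 189, `>=86` = 10)),
    weight = norm(c(`<50` = 7, `50-100` = 165, `>100` = 76)),
    reporter = norm(c(
      Consumer = 614, `Health professional` = 299, Physician = 193,
      Pharmacist = 36, Other = 9, Unknown = 26
    )),
    country = norm(c(
      US = 801, DE = 98, ES = 60, GB = 48, AU = 42, Other = 128
    )),
    outcome = norm(c(
      `Other serious` = 335, Hospitalization = 201, Death = 40,
      `Life-threatening` = 18, Disability = 8, `Congenital anomaly` = 2,
      Unknown = 687
    )),
    indication = norm(c(
      Psoriasis = 642, Hypertension = 71, `Diabetes mellitus` = 20,
      `Psoriatic arthropathy` = 19, Depression = 9, Other = 416
    )),
    year = norm(c(
      `2018` = 13, `2019` = 96, `2020` = 168, `2021` = 219, `2022` = 289,
      `2023` = 392
    ))
  )
}

#' Read a PT to SOC map from a two-column delimited file
#'
#' @param path File with columns `pt` and `soc` (tab- or comma-delimited,
#'   header required).
#' @return `data.table` with columns `pt`, `soc`; errors if a PT maps to
#'   more than one SOC.
#' @export
read_pt_soc_map <- function(path) {
  m <- data.table::fread(path, header = TRUE)
  if (!all(c("pt", "soc") %in% names(m))) {
    stop("PT->SOC map must have columns 'pt' and 'soc': ", path,
         call. = FALSE)
  }
  m <- unique(m[, c("pt", "soc"), with = FALSE])
  dup <- m$pt[duplicated(m$pt)]
  if (length(dup)) {
    stop("PT maps to multiple SOCs: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Write a PT to SOC map to a tab-delimited file
#'
#' @param map `data.table`/data.frame with columns `pt`, `soc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pt_soc_map <- function(map, path) {
  data.table::fwrite(map[, c("pt", "soc")], path, sep = "\t")
  invisible(path)
}
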