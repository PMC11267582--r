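# Reading FAERS-dialect quarterly tables and applying the cleaning rules:
# cross-quarter case deduplication, target-drug synonym matching,
# primary-suspect filtering, and PT/indication exclusions.

MANDATORY_COLS <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "SEX", "AGE",
           "AGE_COD", "WT", "WT_COD", "OCCP_COD", "REPORTER_COUNTRY"),
  drug = c("PRIMARYID", "CASEID", "DRUGNAME", "ROLE_COD"),
  reac = c("PRIMARYID", "CASEID", "PT"),
  ther = c("PRIMARYID", "CASEID", "START_DT"),
  indi = c("PRIMARYID", "CASEID", "INDI_PT"),
  outc = c("PRIMARYID", "CASEID", "OUTC_COD"),
  rpsr = c("PRIMARYID", "CASEID", "RPSR_COD")
)

#' Read one quarter of FAERS-dialect tables
#'
#' Reads "$"-delimited ASCII files with FAERS column headers. All columns are
#' kept as character: unparseable or partial dates are preserved verbatim,
#' never silently coerced.
#'
#' @param paths Named list/vector of file paths; names among
#'   `demo, drug, reac, ther, indi, outc, rpsr` (`demo` required).
#' @return Named list of `data.table`s.
#' @export
read_quarter <- function(paths) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || !all(names(paths) %in% names(MANDATORY_COLS))) {
    stop("paths must be named with FAERS areas: ",
         paste(names(MANDATORY_COLS), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (area in names(paths)) {
    p <- paths[[area]]
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    tab <- data.table::fread(p, sep = "$", quote = "",
                             colClasses = "character", header = TRUE)
    missing_cols <- setdiff(MANDATORY_COLS[[area]], names(tab))
    if (length(missing_cols)) {
      stop(sprintf("file %s is missing mandatory column(s): %s",
                   p, paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    out[[area]] <- tab
  }
  out
}

#' Read all quarters from a directory
#'
#' Discovers files named `<area>_<quarter>.txt` (as written by
#' [write_dataset()]) and row-binds each area across quarters, so that
#' deduplication can operate on the whole loaded range.
#'
#' @param dir Directory holding quarterly files.
#' @return Named list of `data.table`s, one per area present.
#' @export
read_faers_dir <- function(dir) {
  files <- list.files(dir, pattern = "^(demo|drug|reac|ther|indi|outc|rpsr)_.*\\.txt$",
                      full.names = TRUE)
  if (!length(files)) stop("no FAERS-dialect files found in ", dir,
                           call. = FALSE)
  area <- sub("_.*$", "", basename(files))
  out <- list()
  for (a in unique(area)) {
    tabs <- lapply(files[area == a], function(p) {
      read_quarter(stats::setNames(list(p), a))[[1L]]
    })
    out[[a]] <- data.table::rbindlist(tabs, use.names = TRUE)
  }
  out
}

#' Deduplicate case versions
#'
#' FAERS resubmits cases: the same `CASEID` appears under several
#' `PRIMARYID`s/`FDA_DT`s across quarters. Keeps exactly one row per
#' `CASEID`: the latest `FDA_DT`, ties broken by the largest `PRIMARYID`
#' (`mode = "latest"`, default), or simply the largest `PRIMARYID`
#' (`mode = "max_primaryid"`). Idempotent and invariant to input row order.
#'
#' @param demo DEMO `data.table` with `CASEID`, `FDA_DT`, `PRIMARYID`.
#' @param mode Dedup rule, `"latest"` or `"max_primaryid"`.
#' @return List with `demo` (surviving rows) and `dropped` (PRIMARYIDs of
#'   removed versions).
#' @export
deduplicate <- function(demo, mode = c("latest", "max_primaryid")) {
  mode <- match.arg(mode)
  demo <- data.table::as.data.table(demo)
  if (!nrow(demo)) return(list(demo = demo, dropped = character()))
  pid_num <- suppressWarnings(as.numeric(demo$PRIMARYID))
  if (mode == "latest") {
    fda <- suppressWarnings(as.numeric(demo$FDA_DT))
    fda[is.na(fda)] <- -Inf
    o <- order(demo$CASEID, fda, pid_num)
  } else {
    o <- order(demo$CASEID, pid_num)
  }
  demo_sorted <- demo[o]
  keep <- !duplicated(demo_sorted$CASEID, fromLast = TRUE)
  list(demo = demo_sorted[keep],
       dropped = demo_sorted$PRIMARYID[!keep])
}

#' Match drug names against a synonym list
#'
#' Case-insensitive, whitespace-trimmed (and inner-whitespace-collapsed)
#' exact matching against the synonym list; no substring matching unless
#' `substring = TRUE`.
#'
#' @param drugname Character vector of `DRUGNAME` values.
#' @param synonyms Non-empty character vector of name variants.
#' @param substring If `TRUE`, additionally match names that contain a
#'   synonym as a word.
#' @return Logical vector.
#' @export
match_drug <- function(drugname, synonyms = default_synonyms(),
                       substring = FALSE) {
  if (!length(synonyms)) stop("synonym list must be non-empty", call. = FALSE)
  x <- norm_name(drugname)
  syn <- norm_name(synonyms)
  hit <- x %in% syn
  if (substring) {
    for (s in syn) hit <- hit | grepl(s, x, fixed = TRUE)
  }
  hit
}

#' @noRd
target_case_ids <- function(drug, synonyms, role = NULL) {
  hit <- match_drug(drug$DRUGNAME, synonyms)
  if (!is.null(role)) hit <- hit & drug$ROLE_COD %in% role
  unique(drug$PRIMARYID[hit])
}

#' Filter to primary-suspect target cases
#'
#' Retains the cases that document the target drug (per the synonym list)
#' with role code `PS`.
#'
#' @param demo Deduplicated DEMO table.
#' @param drug DRUG table.
#' @param synonyms Synonym list for the target drug.
#' @return DEMO rows of retained cases.
#' @export
filter_primary_suspect <- function(demo, drug, synonyms = default_synonyms()) {
  ids <- target_case_ids(data.table::as.data.table(drug), synonyms,
                         role = "PS")
  demo <- data.table::as.data.table(demo)
  demo[demo$PRIMARYID %in% ids]
}

#' Remove excluded preferred terms and indications
#'
#' Deletes exclusion-list PTs from reaction lists and the uninformative
#' indication term from indication lists (case-insensitive). Cases left
#' without any reaction are dropped and logged.
#'
#' @param reac REAC table.
#' @param indi INDI table (or `NULL`).
#' @param pt_exclusions Character vector of PTs to remove.
#' @param indication_exclusion Indication term to remove.
#' @return List with `reac`, `indi`, `dropped_cases` (PRIMARYIDs whose only
#'   reactions were excluded), and `n_pt_removed`.
#' @export
exclude_pts <- function(reac, indi = NULL,
                        pt_exclusions = default_pt_exclusions(),
                        indication_exclusion = default_indication_exclusion()) {
  reac <- data.table::as.data.table(reac)
  before_ids <- unique(reac$PRIMARYID)
  excl <- toupper(trimws(reac$PT)) %in% toupper(pt_exclusions)
  reac2 <- reac[!excl]
  dropped <- setdiff(before_ids, unique(reac2$PRIMARYID))
  if (!is.null(indi)) {
    indi <- data.table::as.data.table(indi)
    indi <- indi[!(toupper(trimws(indi$INDI_PT)) %in%
                     toupper(indication_exclusion))]
  }
  list(reac = reac2, indi = indi, dropped_cases = dropped,
       n_pt_removed = sum(excl))
}

#' @noRd
subset_case_set <- function(tables, ids) {
  pick <- function(tab) {
    if (is.null(tab)) return(NULL)
    tab[tab$PRIMARYID %in% ids]
  }
  structure(list(
    demo = pick(tables$demo),
    drug = pick(tables$drug),
    reac = pick(tables$reac),
    ther = pick(tables$ther),
    indi = pick(tables$indi),
    outc = pick(tables$outc),
    rpsr = pick(tables$rpsr)
  ), class = "case_set")
}

#' Number of cases in a case set
#' @param cs A `case_set`.
#' @return Integer count of unique reports.
#' @export
n_cases <- function(cs) nrow(cs$demo)

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("case_set: %d reports, %d reaction rows, %d drug rows\n",
              nrow(x$demo), if (is.null(x$reac)) 0L else nrow(x$reac),
              if (is.null(x$drug)) 0L else nrow(x$drug)))
  invisible(x)
}

#' Clean a loaded FAERS table set
#'
#' Runs the fixed cleaning pipeline: cross-quarter deduplication (one row
#' per `CASEID`), target-drug synonym matching, primary-suspect filtering,
#' and PT/indication exclusion, producing disjoint target and background
#' case sets plus a stage-count cleaning report. The background holds all
#' deduplicated non-target-PS reports (target mentions in non-PS roles stay
#' in the background unless `drop_target_mentions = TRUE`).
#'
#' @param tables Named list of area tables (as from [read_faers_dir()] or a
#'   `faers_dataset$tables`).
#' @param synonyms Target-drug synonym list.
#' @param pt_exclusions,indication_exclusion Exclusion lists.
#' @param dedup_mode Passed to [deduplicate()].
#' @param drop_target_mentions If `TRUE`, reports mentioning the target in
#'   any role are removed from the background.
#' @return List with `target` (`case_set`), `background` (`case_set`) and
#'   `report` (`cleaning_report`: stage counts + dropped identifiers).
#' @export
clean_cases <- function(tables,
                        synonyms = default_synonyms(),
                        pt_exclusions = default_pt_exclusions(),
                        indication_exclusion = default_indication_exclusion(),
                        dedup_mode = "latest",
                        drop_target_mentions = FALSE) {
  stopifnot(!is.null(tables$demo), !is.null(tables$drug),
            !is.null(tables$reac))
  raw_rows <- nrow(tables$demo)
  dd <- deduplicate(tables$demo, mode = dedup_mode)
  demo <- dd$demo
  kept_ids <- demo$PRIMARYID

  drug <- data.table::as.data.table(tables$drug)
  drug <- drug[drug$PRIMARYID %in% kept_ids]
  reac <- data.table::as.data.table(tables$reac)
  reac <- reac[reac$PRIMARYID %in% kept_ids]
  indi <- if (!is.null(tables$indi)) {
    t <- data.table::as.data.table(tables$indi); t[t$PRIMARYID %in% kept_ids]
  }

  match_ids <- target_case_ids(drug, synonyms)           # any role
  ps_ids <- target_case_ids(drug, synonyms, role = "PS") # PS only

  ex <- exclude_pts(reac, indi, pt_exclusions, indication_exclusion)
  reac <- ex$reac
  indi <- ex$indi
  alive <- setdiff(kept_ids, ex$dropped_cases)

  target_ids <- intersect(ps_ids, alive)
  bg_ids <- setdiff(alive, target_ids)
  if (drop_target_mentions) bg_ids <- setdiff(bg_ids, match_ids)

  tables2 <- list(demo = demo, drug = drug, reac = reac, ther =
                    if (!is.null(tables$ther)) {
                      t <- data.table::as.data.table(tables$ther)
                      t[t$PRIMARYID %in% kept_ids]
                    },
                  indi = indi,
                  outc = if (!is.null(tables$outc)) {
                    t <- data.table::as.data.table(tables$outc)
                    t[t$PRIMARYID %in% kept_ids]
                  },
                  rpsr = if (!is.null(tables$rpsr)) {
                    t <- data.table::as.data.table(tables$rpsr)
                    t[t$PRIMARYID %in% kept_ids]
                  })

  report <- structure(list(
    stages = c(raw_rows = raw_rows,
               after_dedup = nrow(demo),
               after_drug_match = length(intersect(match_ids, kept_ids)),
               after_ps_filter = length(intersect(ps_ids, kept_ids)),
               after_pt_exclusion = length(target_ids)),
    dropped = list(dedup = dd$dropped,
                   empty_reaction = ex$dropped_cases),
    n_pt_rows_removed = ex$n_pt_removed
  ), class = "cleaning_report")

  list(target = subset_case_set(tables2, target_ids),
       background = subset_case_set(tables2, bg_ids),
       report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report (target-drug pipeline)\n")
  st <- x$stages
  lab <- c(raw_rows = "raw DEMO rows",
           after_dedup = "unique cases after dedup",
           after_drug_match = "cases mentioning target (any role)",
           after_ps_filter = "cases with target as primary suspect",
           after_pt_exclusion = "target cases after PT exclusion")
  for (nm in names(st)) cat(sprintf("  %-42s %d\n", lab[[nm]], st[[nm]]))
  cat(sprintf("  excluded PT rows removed: %d\n", x$n_pt_rows_removed))
  invisible(x)
}

#' Serialize a cleaning report to JSON
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(list(stages = as.list(report$stages),
                            n_pt_rows_removed = report$n_pt_rows_removed,
                            dropped = report$dropped),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
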