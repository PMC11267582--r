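# 2x2 contingency construction for (target drug, term) pairs at PT or SOC
# level. Counting unit is the unique report: a report with the same PT twice
# contributes once; at SOC level a report counts toward a SOC if at least
# one of its PTs maps there.

#' Build one 2x2 contingency table for a term
#'
#' Cells: `a` = target reports with the term, `b` = target reports without,
#' `c` = background reports with, `d` = background reports without.
#'
#' @param target,background `case_set`s, disjoint by `PRIMARYID`.
#' @param term PT name (level `"PT"`) or SOC name (level `"SOC"`).
#' @param level `"PT"` or `"SOC"`.
#' @param map PT->SOC map (`data.table` with `pt`, `soc`); required at SOC
#'   level.
#' @return One-row `data.table` with `term, level, a, b, c, d, n`.
#' @export
build_table <- function(target, background, term, level = c("PT", "SOC"),
                        map = NULL) {
  level <- match.arg(level)
  ids_t <- report_ids_with_term(target, term, level, map)
  ids_b <- report_ids_with_term(background, term, level, map)
  nt <- n_cases(target)
  nb <- n_cases(background)
  a <- length(ids_t)
  c_ <- length(ids_b)
  data.table::data.table(term = term, level = level,
                         a = a, b = nt - a, c = c_, d = nb - c_,
                         n = nt + nb)
}

#' @noRd
report_ids_with_term <- function(cs, term, level, map) {
  reac <- cs$reac
  if (level == "PT") {
    return(unique(reac$PRIMARYID[toupper(trimws(reac$PT)) ==
                                   toupper(trimws(term))]))
  }
  if (is.null(map)) stop("a PT->SOC map is required at SOC level",
                         call. = FALSE)
  if (!(term %in% map$soc)) {
    stop("SOC term not present in the PT->SOC map: ", term, call. = FALSE)
  }
  pts <- map$pt[map$soc == term]
  unique(reac$PRIMARYID[toupper(trimws(reac$PT)) %in% toupper(trimws(pts))])
}

#' Build 2x2 tables for every term observed in the target case set
#'
#' One table per distinct PT (or mapped SOC) occurring in the target set.
#' Tables with `a` below `min_count` are kept but flagged
#' (`below_min = TRUE`); the reporting convention in disproportionality
#' analysis is a minimum case count of 3.
#'
#' @inheritParams build_table
#' @param min_count Flagging threshold on `a` (default 3).
#' @return `data.table` with columns `term, level, a, b, c, d, n,
#'   below_min`, one row per term, ordered by decreasing `a`.
#' @export
build_all <- function(target, background, level = c("PT", "SOC"),
                      map = NULL, min_count = 3L) {
  level <- match.arg(level)
  nt <- n_cases(target)
  nb <- n_cases(background)
  reac_t <- normalize_terms(target$reac, level, map)
  reac_b <- normalize_terms(background$reac, level, map)
  if (!nrow(reac_t)) {
    return(data.table::data.table(term = character(), level = character(),
                                  a = integer(), b = integer(),
                                  c = integer(), d = integer(),
                                  n = integer(), below_min = logical()))
  }
  # rows of reac_t/reac_b are already unique (report, term) pairs
  a_tab <- reac_t[, list(a = .N), by = "term"]
  c_tab <- reac_b[, list(c = .N), by = "term"]
  out <- merge(a_tab, c_tab, by = "term", all.x = TRUE)
  out$c[is.na(out$c)] <- 0L
  out$level <- level
  out$b <- nt - out$a
  out$d <- nb - out$c
  out$n <- nt + nb
  out$below_min <- out$a < min_count
  data.table::setcolorder(out, c("term", "level", "a", "b", "c", "d", "n",
                                 "below_min"))
  data.table::setorderv(out, "a", order = -1L)
  out[]
}

#' @noRd
normalize_terms <- function(reac, level, map) {
  PRIMARYID <- NULL  # data.table NSE
  dt <- data.table::data.table(PRIMARYID = reac$PRIMARYID,
                               term = trimws(reac$PT))
  if (level == "SOC") {
    if (is.null(map)) stop("a PT->SOC map is required at SOC level",
                           call. = FALSE)
    idx <- match(toupper(dt$term), toupper(trimws(map$pt)))
    dt$term <- map$soc[idx]
    dt <- dt[!is.na(dt$term)]
  }
  unique(dt)
}

#' Export contingency tables to a delimited file
#' @param tables `data.table` from [build_all()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_contingency <- function(tables, path) {
  data.table::fwrite(tables, path, sep = "\t")
  invisible(path)
}
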