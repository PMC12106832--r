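#' Session-level cohort tables
#'
#' The analysis unit is the MRI session, one row per session, held in a plain
#' `data.frame` with reserved columns `session_id`, `participant_id`,
#' `cohort`, `group`, `scan_age_wpc`, `birth_age_wpc`, `sex`, `scanner_id`,
#' `field_strength_tesla`, followed by one column per morphometric feature.
#' Ages are continuous weeks post-conception (wPC). Sessions from the same
#' participant are treated as independent rows (cross-sectional design);
#' participant counts are reported but never used as denominators. Missing sex
#' is an explicit `"NA"` level, never dropped.
#'
#' `validate_cohort` enforces the row invariants: unique `session_id`; fetal
#' sessions carry no birth age; postnatal/preterm sessions have
#' `birth_age_wpc <= scan_age_wpc`, with preterm birth `< 37` wPC and
#' postnatal birth `>= 37` wPC.
#'
#' @param table a cohort `data.frame`.
#' @param path a CSV/TSV file path (UTF-8, header row, "." decimal separator,
#'   empty string = missing).
#' @param dialect `"csv"` or `"tsv"`.
#' @name cohort_table
NULL

cohort_columns <- c("session_id", "participant_id", "cohort", "group",
                    "scan_age_wpc", "birth_age_wpc", "sex", "scanner_id",
                    "field_strength_tesla")
group_levels <- c("fetal", "postnatal", "preterm")
cohort_levels <- c("marsfet", "dhcp_fetal", "dhcp_postnatal", "dhcp_preterm")
sex_levels <- c("M", "F", "NA")
term_cutoff_wpc <- 37

#' @rdname cohort_table
#' @export
validate_cohort <- function(table) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(cohort_columns, names(table))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  errs <- character(0)
  dup <- unique(table$session_id[duplicated(table$session_id)])
  if (length(dup))
    errs <- c(errs, paste0("duplicate session_id: ",
                           paste(head(dup, 5L), collapse = ", ")))
  bad_age <- which(!is.finite(table$scan_age_wpc) | table$scan_age_wpc <= 0)
  if (length(bad_age))
    errs <- c(errs, paste0("row ", bad_age,
                           ": scan_age_wpc must be a positive number"))
  bad_grp <- which(!table$group %in% group_levels)
  if (length(bad_grp))
    errs <- c(errs, paste0("row ", bad_grp, ": unknown group '",
                           table$group[bad_grp], "'"))
  ok_grp <- table$group %in% group_levels
  i <- which(ok_grp & table$group == "fetal" & !is.na(table$birth_age_wpc))
  if (length(i))
    errs <- c(errs, paste0("row ", i, ": fetal session must not carry a birth age"))
  post <- which(ok_grp & table$group %in% c("postnatal", "preterm"))
  miss <- post[is.na(table$birth_age_wpc[post])]
  if (length(miss))
    errs <- c(errs, paste0("row ", miss, ": ", table$group[miss],
                           " session requires birth_age_wpc"))
  late <- post[!is.na(table$birth_age_wpc[post]) &
               table$birth_age_wpc[post] > table$scan_age_wpc[post]]
  if (length(late))
    errs <- c(errs, paste0("row ", late, ": birth_age_wpc exceeds scan_age_wpc"))
  i <- which(ok_grp & table$group == "preterm" & !is.na(table$birth_age_wpc) &
             table$birth_age_wpc >= term_cutoff_wpc)
  if (length(i))
    errs <- c(errs, paste0("row ", i, ": preterm birth age must be < ",
                           term_cutoff_wpc, " wPC"))
  i <- which(ok_grp & table$group == "postnatal" & !is.na(table$birth_age_wpc) &
             table$birth_age_wpc < term_cutoff_wpc)
  if (length(i))
    errs <- c(errs, paste0("row ", i, ": postnatal birth age must be >= ",
                           term_cutoff_wpc, " wPC"))
  bad_sex <- which(!table$sex %in% sex_levels)
  if (length(bad_sex))
    errs <- c(errs, paste0("row ", bad_sex, ": sex must be one of M, F, NA"))
  if (length(errs))
    stop("invalid cohort table:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(table)
}

#' @rdname cohort_table
#' @export
read_cohort_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  na.strings = "", fileEncoding = "UTF-8",
                  check.names = FALSE)
  for (col in c("session_id", "participant_id", "cohort", "group",
                "scanner_id"))
    if (col %in% names(tab)) tab[[col]] <- as.character(tab[[col]])
  if ("sex" %in% names(tab)) {
    tab$sex <- as.character(tab$sex)
    tab$sex[is.na(tab$sex)] <- "NA"   # explicit missing-sex level
  }
  if (!"birth_age_wpc" %in% names(tab)) tab$birth_age_wpc <- NA_real_
  tab$birth_age_wpc <- as.numeric(tab$birth_age_wpc)
  if ("scan_age_wpc" %in% names(tab)) {
    suppressWarnings(num <- as.numeric(tab$scan_age_wpc))
    bad <- which(is.na(num) & !is.na(tab$scan_age_wpc))
    if (length(bad))
      stop("row ", paste(bad, collapse = ", "),
           ": unparsable scan_age_wpc", call. = FALSE)
    tab$scan_age_wpc <- num
  }
  validate_cohort(tab)
  tab
}

#' @rdname cohort_table
#' @export
write_cohort_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  out <- table
  out$sex[out$sex == "NA"] <- NA_character_
  utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Pool, filter and summarize cohort tables
#'
#' `pool_cohorts` concatenates session tables (disjoint `session_id` sets
#' required); `filter_group` keeps rows whose `group` is in `keep`;
#' `summarize_cohort` returns session/participant counts, the sex split and
#' scan-age statistics (sample-sd convention).
#'
#' @param tables a list of cohort `data.frame`s.
#' @param keep character subset of `c("fetal", "postnatal", "preterm")`.
#' @param table a cohort `data.frame`.
#' @return `pool_cohorts` and `filter_group` return a cohort `data.frame`;
#'   `summarize_cohort` an object of class `cohort_summary`.
#' @examples
#' tab <- simulate_cohort(seed = 1)
#' summarize_cohort(filter_group(tab, c("fetal", "postnatal")))
#' @export
pool_cohorts <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop("need at least one table")
  ids <- unlist(lapply(tables, `[[`, "session_id"))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("session_id collision across tables: ",
         paste(head(dup, 5L), collapse = ", "))
  all_cols <- unique(unlist(lapply(tables, names)))
  tables <- lapply(tables, function(t) {
    for (col in setdiff(all_cols, names(t))) t[[col]] <- NA
    t[all_cols]
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' @rdname pool_cohorts
#' @export
filter_group <- function(table, keep) {
  stopifnot(is.data.frame(table))
  keep <- match.arg(keep, group_levels, several.ok = TRUE)
  out <- table[table$group %in% keep, , drop = FALSE]
  if (!nrow(out)) warning("filter_group: no sessions left", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname pool_cohorts
#' @export
summarize_cohort <- function(table) {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) stop("empty cohort table")
  ages <- table$scan_age_wpc
  n <- nrow(table)
  structure(list(
    n_sessions = n,
    n_participants = length(unique(table$participant_id)),
    sex_counts = c(M = sum(table$sex == "M"), F = sum(table$sex == "F"),
                   `NA` = sum(table$sex == "NA")),
    age_min = min(ages), age_max = max(ages), age_mean = mean(ages),
    age_sd = if (n > 1L) sd(ages) else 0,
    age_sd_defined = n > 1L
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat("  sessions:     ", x$n_sessions, " (", x$n_participants,
      " participants)\n", sep = "")
  cat("  sex (M:F:NA): ", paste(x$sex_counts, collapse = ":"), "\n", sep = "")
  cat(sprintf("  scan age:      %.1f-%.1f wPC (mean = %.1f; sd = %.1f%s)\n",
              x$age_min, x$age_max, x$age_mean, x$age_sd,
              if (x$age_sd_defined) "" else "; undefined for n = 1"))
  invisible(x)
}
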