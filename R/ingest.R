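## Cohort container: a metadata table (one row per trace = per eye per
## recording session) plus a named list of µV sample vectors keyed by
## trace_id, and an ordered filter log.
new_perg_cohort <- function(meta, signals,
                            filter_log = data.frame(rule = character(),
                                                    removed = integer())) {
  stopifnot(is.data.frame(meta), all(meta$trace_id %in% names(signals)))
  signals <- signals[meta$trace_id]
  structure(list(meta = meta, signals = signals, filter_log = filter_log),
            class = "perg_cohort")
}

#' @export
print.perg_cohort <- function(x, ...) {
  cat("PERG cohort: ", nrow(x$meta), " traces, ",
      length(unique(x$meta$subject_id)), " subjects\n", sep = "")
  if ("group" %in% names(x$meta)) {
    tab <- table(x$meta$group)
    cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (nrow(x$filter_log)) {
    cat("  filters applied:\n")
    for (i in seq_len(nrow(x$filter_log)))
      cat("    ", x$filter_log$rule[i], ": removed ",
          x$filter_log$removed[i], "\n", sep = "")
  }
  invisible(x)
}

#' Write a cohort as a PERG archive (per-recording signal CSVs + metadata)
#'
#' Emits the same CSV dialect [read_perg_ioba()] reads: one signal file
#' per recording session holding a time column and one µV column per eye,
#' plus a `metadata.csv` table with one row per session.
#'
#' @param cohort a `perg_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the metadata file path.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "perg_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- cohort$meta
  rows <- list()
  for (rid in unique(meta$record_id)) {
    sub <- meta[meta$record_id == rid, ]
    fs <- sub$fs_hz[1]
    n <- length(cohort$signals[[sub$trace_id[1]]])
    sig <- data.frame(time_ms = (seq_len(n) - 1) / fs * 1000)
    for (i in seq_len(nrow(sub)))
      sig[[paste0(tolower(sub$eye[i]), "_uv")]] <-
        cohort$signals[[sub$trace_id[i]]]
    utils::write.csv(sig, file.path(dir, paste0(rid, ".csv")),
                     row.names = FALSE)
    rows[[rid]] <- data.frame(
      record_id = rid, subject_id = sub$subject_id[1],
      visit_date = sub$visit_date[1], diagnosis = sub$diagnosis[1],
      diagnosis_secondary = sub$diagnosis_secondary[1],
      comments = sub$comments[1],
      va_le_logmar = if (any(sub$eye == "LE"))
        sub$va_logmar[sub$eye == "LE"][1] else NA_real_,
      va_re_logmar = if (any(sub$eye == "RE"))
        sub$va_logmar[sub$eye == "RE"][1] else NA_real_,
      fs_hz = fs)
  }
  path <- file.path(dir, "metadata.csv")
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a PERG archive: per-recording signal CSVs plus a metadata table
#'
#' Each signal file must carry a time column and one or two per-eye µV
#' columns (`le_uv`, `re_uv`); the metadata table must carry subject id,
#' diagnosis, comments, visit date and visual-acuity columns. One trace is
#' produced per eye per signal file. Visit ordinals are assigned by
#' ascending visit date within subject. Signal files that fail to parse
#' are reported in the returned `problems` attribute, never silently
#' dropped.
#'
#' @param signal_paths character vector of signal CSV paths; file names
#'   (minus extension) are the record ids.
#' @param metadata_path path to the metadata CSV.
#' @param columns optional named list overriding metadata column names
#'   (defaults: `subject_id`, `diagnosis`, `diagnosis_secondary`,
#'   `comments`, `visit_date`, `va_le_logmar`, `va_re_logmar`, `fs_hz`).
#' @return a `perg_cohort`.
#' @export
read_perg_ioba <- function(signal_paths, metadata_path, columns = list()) {
  cols <- utils::modifyList(list(
    subject_id = "subject_id", diagnosis = "diagnosis",
    diagnosis_secondary = "diagnosis_secondary", comments = "comments",
    visit_date = "visit_date", va_le_logmar = "va_le_logmar",
    va_re_logmar = "va_re_logmar", fs_hz = "fs_hz"), columns)
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("record_id", unlist(cols[c("subject_id", "diagnosis",
                                       "comments", "visit_date")]))
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  rec_ids <- sub("\\.csv$", "", basename(signal_paths))
  absent <- setdiff(md$record_id, rec_ids)
  if (length(absent))
    stop("metadata rows without a signal file: ",
         paste(absent, collapse = ", "))
  meta <- list(); signals <- list(); problems <- character()
  for (i in seq_along(signal_paths)) {
    rid <- rec_ids[i]
    row <- md[md$record_id == rid, , drop = FALSE]
    if (nrow(row) == 0L) {
      problems <- c(problems, paste0(rid, ": no metadata row"))
      next
    }
    sig <- tryCatch(utils::read.csv(signal_paths[i]), error = function(e) e)
    if (inherits(sig, "error")) {
      problems <- c(problems, paste0(rid, ": ", conditionMessage(sig)))
      next
    }
    eye_cols <- intersect(c("le_uv", "re_uv"), names(sig))
    if (!length(eye_cols)) {
      problems <- c(problems, paste0(rid, ": no per-eye µV column"))
      next
    }
    getcol <- function(name, default = NA) {
      cn <- cols[[name]]
      if (!is.null(cn) && cn %in% names(row)) row[[cn]] else default
    }
    fs <- suppressWarnings(as.numeric(getcol("fs_hz", "1700")))
    if (is.na(fs)) fs <- 1700
    for (ec in eye_cols) {
      eye <- toupper(sub("_uv$", "", ec))
      trace_id <- paste0(rid, "_", eye)
      va_raw <- getcol(if (eye == "LE") "va_le_logmar" else "va_re_logmar")
      meta[[trace_id]] <- data.frame(
        trace_id = trace_id, record_id = rid,
        subject_id = as.character(getcol("subject_id")),
        eye = eye, visit = NA_integer_,
        visit_date = as.character(getcol("visit_date")),
        diagnosis = as.character(getcol("diagnosis")),
        diagnosis_secondary = as.character(getcol("diagnosis_secondary", "")),
        comments = as.character(getcol("comments", "")),
        va_logmar = suppressWarnings(as.numeric(va_raw)),
        group = NA_character_, fs_hz = fs)
      signals[[trace_id]] <- as.numeric(sig[[ec]])
    }
  }
  meta <- do.call(rbind, c(meta, make.row.names = FALSE))
  ## visit ordinal: ascending date within subject (ties share an ordinal)
  meta$visit <- ave(as.integer(as.Date(meta$visit_date)), meta$subject_id,
                    FUN = function(d) match(d, sort(unique(d))))
  out <- new_perg_cohort(meta, signals)
  attr(out, "problems") <- problems
  out
}

.ond_diagnoses <- c("Inherited optic atrophy", "Bilateral optic atrophy",
                    "Optic neuropathy")

#' Apply the study's cohort curation rules
#'
#' Assigns clinical groups and applies the curation filters in order,
#' logging each rule's removal count:
#' \enumerate{
#'   \item group assignment: OND for diagnoses "Inherited optic atrophy",
#'     "Bilateral optic atrophy" or "Optic neuropathy"; HV for diagnosis
#'     exactly "Normal" with an empty secondary-diagnosis field; all other
#'     traces removed (rule `diagnosis_group`);
#'   \item traces whose comments contain "mercury poisoning"
#'     (case-insensitive substring) removed (rule `mercury`);
#'   \item traces lacking a visual-acuity value removed (rule
#'     `missing_va`);
#'   \item unless `multi_visit`, only each subject's first visit retained
#'     (rule `first_visit`); reliability analyses need repeated visits and
#'     set `multi_visit = TRUE`.
#' }
#' The filters are conjunctive predicates, so the retained set does not
#' depend on their order; only the per-rule counts do.
#'
#' @param cohort a `perg_cohort` from [read_perg_ioba()] or
#'   [simulate_cohort()].
#' @param multi_visit keep all visits (default `FALSE`).
#' @return the filtered `perg_cohort`, with `filter_log` extended.
#' @export
curate <- function(cohort, multi_visit = FALSE) {
  stopifnot(inherits(cohort, "perg_cohort"))
  meta <- cohort$meta
  log <- cohort$filter_log
  drop_rule <- function(meta, keep, rule) {
    log <<- rbind(log, data.frame(rule = rule, removed = sum(!keep)))
    meta[keep, , drop = FALSE]
  }
  is_ond <- meta$diagnosis %in% .ond_diagnoses
  is_hv <- meta$diagnosis == "Normal" &
    (is.na(meta$diagnosis_secondary) |
       !nzchar(trimws(meta$diagnosis_secondary)))
  meta$group <- ifelse(is_ond, "OND", ifelse(is_hv, "HV", "other"))
  meta <- drop_rule(meta, meta$group != "other", "diagnosis_group")
  meta <- drop_rule(meta, !grepl("mercury poisoning", meta$comments,
                                 ignore.case = TRUE), "mercury")
  meta <- drop_rule(meta, !is.na(meta$va_logmar), "missing_va")
  if (!multi_visit) {
    first <- ave(meta$visit, meta$subject_id, FUN = min)
    meta <- drop_rule(meta, meta$visit == first, "first_visit")
  }
  new_perg_cohort(meta, cohort$signals[meta$trace_id], log)
}

#' Average a subject's traces within visit, then across visits
#'
#' Pointwise arithmetic mean across eyes/repeats within each visit, then
#' across the subject's retained visits, yielding one subject-level trace
#' (appropriate for bilateral conditions and avoiding pseudoreplication).
#'
#' @param cohort a curated `perg_cohort` whose traces share length and
#'   sampling rate within each subject.
#' @return list with `traces` (named list subject_id -> averaged µV
#'   vector) and `group` (named character vector of group labels).
#' @export
subject_average <- function(cohort) {
  stopifnot(inherits(cohort, "perg_cohort"))
  meta <- cohort$meta
  traces <- list(); group <- character()
  for (sid in unique(meta$subject_id)) {
    sub <- meta[meta$subject_id == sid, ]
    lens <- unique(vapply(cohort$signals[sub$trace_id], length, integer(1)))
    if (length(lens) != 1L)
      stop("subject ", sid, " has traces of unequal length")
    visit_means <- lapply(split(sub$trace_id, sub$visit), function(ids)
      Reduce(`+`, cohort$signals[ids]) / length(ids))
    traces[[sid]] <- Reduce(`+`, visit_means) / length(visit_means)
    group[sid] <- if ("group" %in% names(sub)) sub$group[1] else NA_character_
  }
  list(traces = traces, group = group)
}

#' Average a subject's traces within each visit (across eyes/repeats)
#'
#' Like [subject_average()] but stopping at the visit level, as needed for
#' test-retest reliability.
#'
#' @inheritParams subject_average
#' @return data.frame-driven list: `traces` keyed `"subject|visit"`,
#'   plus a `key` data.frame (`subject_id`, `visit`, `group`).
#' @export
visit_average <- function(cohort) {
  stopifnot(inherits(cohort, "perg_cohort"))
  meta <- cohort$meta
  traces <- list(); key <- list()
  for (sid in unique(meta$subject_id)) {
    sub <- meta[meta$subject_id == sid, ]
    for (v in sort(unique(sub$visit))) {
      ids <- sub$trace_id[sub$visit == v]
      k <- paste(sid, v, sep = "|")
      traces[[k]] <- Reduce(`+`, cohort$signals[ids]) / length(ids)
      key[[k]] <- data.frame(subject_id = sid, visit = v,
                             group = sub$group[1])
    }
  }
  list(traces = traces, key = do.call(rbind, c(key, make.row.names = FALSE)))
}
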