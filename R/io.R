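record_columns <- c("rat_id", "group", "day", "weight_g", "sucrose_g", "water_g",
                    "rearing_count", "of_ref", "epm_ref")

#' Read or write per-rat behavioural record tables
#'
#' Delimited text, one row per rat x measurement day, with the exact
#' header `rat_id,group,day,weight_g,sucrose_g,water_g,rearing_count,of_ref,epm_ref`.
#' Schema violations (unknown columns, non-numeric cells, duplicate
#' rat-day keys) are reported with line numbers.  Writing then reading a
#' table is the identity.
#'
#' @param path CSV file path.
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("records file '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), record_columns))
    abort_io(sprintf("records file '%s': header must be exactly '%s' (got '%s')",
                     path, paste(record_columns, collapse = ","),
                     paste(names(df), collapse = ",")))
  for (col in c("day", "weight_g", "sucrose_g", "water_g", "rearing_count")) {
    v <- df[[col]]
    blank <- is.na(v) | v == "" | v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      abort_validation(sprintf("records file '%s', line %d: column '%s' has non-numeric value '%s'",
                               path, bad[1] + 1L, col, v[bad[1]]))
    df[[col]] <- num
  }
  for (col in c("of_ref", "epm_ref"))
    df[[col]][df[[col]] %in% c("", "NA")] <- NA_character_
  key <- paste(df$rat_id, df$day)
  dup <- which(duplicated(key))
  if (length(dup))
    abort_validation(sprintf("records file '%s', line %d: duplicate (rat, day) key '%s'",
                             path, dup[1] + 1L, key[dup[1]]))
  df
}

#' @rdname read_records
#' @param records data.frame with the record columns.
#' @export
write_records <- function(records, path) {
  stopifnot(all(record_columns %in% names(records)))
  write.csv(records[record_columns], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write score-card tables
#'
#' One row per rat; see [score_rat()] for the columns.
#'
#' @param cards data.frame of score cards (rbind of [score_rat()] rows).
#' @param path CSV file path.
#' @export
write_scorecards <- function(cards, path) {
  write.csv(cards, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scorecards
#' @export
read_scorecards <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("scorecard file '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("rat_id", "total_depression", "total_anxiety")
  if (!all(needed %in% names(df)))
    abort_io(sprintf("scorecard file '%s' lacks columns %s", path,
                     paste(setdiff(needed, names(df)), collapse = ", ")))
  if ("flags" %in% names(df)) df$flags[is.na(df$flags)] <- ""
  df
}

#' Write or read the von Frey series of a cohort
#'
#' Long CSV with header `rat_id,day,force_g,response` (response 0/1), in
#' application order within each rat-day.
#'
#' @param vf named list of [von_frey_series()], keyed `"rat|day"`.
#' @param path CSV file path.
#' @export
write_von_frey <- function(vf, path) {
  rows <- do.call(rbind, lapply(names(vf), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(rat_id = parts[1], day = as.integer(parts[2]),
               force_g = vf[[k]]$forces_applied,
               response = as.integer(vf[[k]]$responses),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_von_frey
#' @param force_set allowed filament forces.
#' @export
read_von_frey <- function(path, force_set = c(15, 10, 8, 6, 4, 2)) {
  if (!file.exists(path)) abort_io(sprintf("von Frey file '%s' does not exist", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("rat_id", "day", "force_g", "response")))
    abort_io(sprintf("von Frey file '%s': header must be 'rat_id,day,force_g,response'", path))
  out <- lapply(split(df, paste(df$rat_id, df$day, sep = "|")), function(d)
    von_frey_series(d$force_g, d$response == 1, force_set = force_set))
  out
}

#' Persist a simulated cohort as plain-text files
#'
#' Writes `records.csv`, `von_frey.csv` and one `trajectories/<ref>.csv`
#' per trial into `dir`; `read_cohort()` reconstructs the cohort from the
#' same layout.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "trajectories"), recursive = TRUE, showWarnings = FALSE)
  write_records(cohort$records, file.path(dir, "records.csv"))
  write_von_frey(cohort$von_frey, file.path(dir, "von_frey.csv"))
  for (ref in names(cohort$trajectories))
    write_trajectory(cohort$trajectories[[ref]], file.path(dir, "trajectories", paste0(ref, ".csv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @param of_geometry,epm_geometry arena geometries for the trajectories.
#' @export
read_cohort <- function(dir, of_geometry = of_arena(), epm_geometry = epm_arena()) {
  records <- read_records(file.path(dir, "records.csv"))
  vf <- read_von_frey(file.path(dir, "von_frey.csv"))
  tdir <- file.path(dir, "trajectories")
  trajs <- list()
  refs <- stats::na.omit(unique(c(records$of_ref, records$epm_ref)))
  for (ref in refs) {
    f <- file.path(tdir, paste0(ref, ".csv"))
    if (!file.exists(f)) abort_io(sprintf("missing trajectory file '%s'", f))
    geom <- if (ref %in% records$epm_ref) epm_geometry else of_geometry
    trajs[[ref]] <- read_trajectory(f, geom)
  }
  structure(list(records = records, von_frey = vf, trajectories = trajs,
                 targets = NULL, design = NULL),
            class = "cohort")
}
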