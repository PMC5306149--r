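# Survey records: ingestion, exclusion filters and tabulations.
#
# A survey record is one mussel observation: the lake it came from, the
# year, the day of the spawning season (days since 1 May), its species,
# and whether it released bitterling embryos while bagged. Depth and
# shell length are carried along when present but are not used by the
# default model (they are collinear with species).

#' Derive calendar month from day of season
#'
#' Day 1 is 1 May; days 1--31 map to May, 32--61 to June, 62--92 to July
#' and 93 onwards to August.
#'
#' @param day Integer vector of days since 1 May (>= 1).
#' @return Factor with levels May, June, July, August.
#' @export
month_from_day <- function(day) {
  m <- ifelse(day <= 31, "May",
       ifelse(day <= 61, "June",
       ifelse(day <= 92, "July", "August")))
  factor(m, levels = month_levels())
}

#' Read survey records from CSV
#'
#' Reads a survey CSV with canonical columns
#' \code{lake,year,day,species,released} (plus optional
#' \code{date,release_count,depth_mm,length_mm}), validates every row,
#' derives \code{month} from \code{day}, and returns one record per row.
#' When \code{release_count} is present, \code{released} is recomputed as
#' \code{release_count > 0}: the dissection validation showed that
#' presence, not count, is the reliable signal.
#'
#' @param path Path to a CSV file with a header row (UTF-8).
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   \code{c(lake = "site_id", day = "season_day")}.
#' @return A data frame of validated survey records with columns
#'   \code{lake, year, day, month, species, released} and any optional
#'   columns present.
#' @export
read_survey <- function(path, dialect = NULL) {
  if (!file.exists(path))
    sg_error("seasongamm_config_error", sprintf("survey file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      hit <- match(dialect[[canon]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canon
    }
  }
  required <- c("lake", "year", "day", "species", "released")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) && "release_count" %in% names(raw))
    missing_cols <- setdiff(missing_cols, "released")
  if (length(missing_cols))
    sg_error("seasongamm_config_error",
             sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  as_survey_records(raw)
}

#' Validate a data frame of survey records
#'
#' Applied by [read_survey()] and usable directly on in-memory frames.
#' Unknown species labels and out-of-range days are reported with their
#' row numbers.
#'
#' @param df Data frame with canonical survey columns.
#' @return The validated data frame with \code{month} derived and
#'   \code{species} as a factor over [species_levels()].
#' @export
as_survey_records <- function(df) {
  sp <- tolower(trimws(as.character(df$species)))
  bad_sp <- which(!sp %in% species_levels())
  if (length(bad_sp))
    sg_error("seasongamm_validation_error",
             sprintf("unknown species label(s) %s at row(s) %s",
                     paste(unique(sp[bad_sp]), collapse = ", "),
                     paste(head(bad_sp, 10), collapse = ", ")))
  day <- suppressWarnings(as.integer(df$day))
  bad_day <- which(is.na(day) | day < 1 | day > 123)
  if (length(bad_day))
    sg_error("seasongamm_validation_error",
             sprintf("day outside 1..123 (1 May-31 Aug) or malformed at row(s) %s",
                     paste(head(bad_day, 10), collapse = ", ")))
  out <- df
  out$species <- factor(sp, levels = species_levels())
  out$day <- day
  out$lake <- as.integer(out$lake)
  out$year <- as.integer(out$year)
  if ("release_count" %in% names(out)) {
    rc <- suppressWarnings(as.numeric(out$release_count))
    if (anyNA(rc))
      sg_error("seasongamm_validation_error",
               sprintf("malformed release_count at row(s) %s",
                       paste(head(which(is.na(rc)), 10), collapse = ", ")))
    out$released <- as.integer(rc > 0)
  } else {
    out$released <- as.integer(as.numeric(out$released) > 0)
  }
  out$month <- month_from_day(out$day)
  canon <- c("lake", "year", "day", "month", "species", "released")
  extra <- setdiff(names(out), canon)
  out[, c(canon, extra), drop = FALSE]
}

#' Write survey records to CSV
#'
#' Inverse of [read_survey()]: writes the canonical columns so that a
#' read/write round trip preserves every field (\code{month} is derived
#' from \code{day} on read and is not written).
#'
#' @param records Survey record data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(records, path) {
  out <- records[, setdiff(names(records), "month"), drop = FALSE]
  out$species <- as.character(out$species)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude lakes and months from a survey
#'
#' Drops records from the given lakes and months, preserving the order of
#' the remaining records. The survey analysed in the source study excluded
#' August (no embryo releases) and two lakes with incomplete coverage.
#'
#' @param records Survey record data frame.
#' @param excluded_lakes Integer lake ids to drop (default none).
#' @param excluded_months Month names to drop; unambiguous abbreviations
#'   such as \code{"Aug"} are accepted.
#' @return The filtered data frame (possibly empty), input unmodified.
#' @export
apply_exclusions <- function(records, excluded_lakes = integer(),
                             excluded_months = character()) {
  months <- character()
  if (length(excluded_months)) {
    idx <- pmatch(tolower(excluded_months), tolower(month_levels()),
                  duplicates.ok = TRUE)
    if (anyNA(idx))
      sg_error("seasongamm_validation_error",
               sprintf("unknown month(s): %s",
                       paste(excluded_months[is.na(idx)], collapse = ", ")))
    months <- month_levels()[idx]
  }
  keep <- !(records$lake %in% excluded_lakes) &
          !(as.character(records$month) %in% months)
  records[keep, , drop = FALSE]
}

#' Cross-tabulate survey records
#'
#' Counts records along one or two axes drawn from
#' \code{lake, month, year, species}, with margin totals.
#'
#' @param records Survey record data frame.
#' @param rows Axis for table rows.
#' @param cols Optional second axis for columns.
#' @return A \code{count_table}: list with \code{counts} (named vector or
#'   matrix), \code{row_totals}, \code{col_totals} (two-way only) and
#'   \code{total}.
#' @export
tabulate_records <- function(records, rows, cols = NULL) {
  axes <- c("lake", "month", "year", "species")
  rows <- match.arg(rows, axes)
  axis_factor <- function(ax) {
    v <- records[[ax]]
    switch(ax,
      month   = factor(v, levels = month_levels()),
      species = factor(v, levels = species_levels()),
      factor(v))
  }
  if (is.null(cols)) {
    counts <- table(axis_factor(rows), dnn = NULL)
    counts <- setNames(as.integer(counts), names(counts))
    out <- list(counts = counts, row_totals = counts,
                total = sum(counts), rows = rows, cols = NULL)
  } else {
    cols <- match.arg(cols, axes)
    tab <- table(axis_factor(rows), axis_factor(cols), dnn = NULL)
    counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                     dimnames = dimnames(tab))
    out <- list(counts = counts,
                row_totals = rowSums(counts),
                col_totals = colSums(counts),
                total = sum(counts), rows = rows, cols = cols)
  }
  structure(out, class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Survey count table (", x$rows,
      if (!is.null(x$cols)) paste0(" x ", x$cols), "), total ",
      x$total, "\n", sep = "")
  print(x$counts)
  invisible(x)
}
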