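# Reading and writing the two registries and the linkage pair file.
#
# Both inputs are delimited text with a header; a column mapping translates
# source column names to the canonical field names used throughout the
# package. Dates are carried as raw text into cleaning: the repair rules
# operate on dates a parser would reject.

.PERSON_REQUIRED <- c("record_id", "first_name", "birth_date", "sex",
                      "vital_status")
.PERSON_OPTIONAL <- c("birth_surname", "current_surname", "birth_city",
                      "birth_country", "death_date")
.MORT_REQUIRED <- c("fnmd_id", "surname", "first_name", "birth_date",
                    "death_date")
.MORT_OPTIONAL <- c("middle_names", "sex", "birth_city", "birth_country",
                    "death_zip")

.DEFAULT_SEX_MAP <- c(m = "m", f = "f", male = "m", female = "f",
                      h = "m", homme = "m", femme = "f",
                      "1" = "m", "2" = "f")

#' Describe how a delimited file maps onto the canonical fields
#'
#' @param columns named character vector or list: canonical field name ->
#'   source column name. Canonical fields not listed are taken to have the
#'   canonical name itself as the source column.
#' @param delimiter field separator (default `","`).
#' @param encoding file encoding (default `"UTF-8"`).
#' @param date_format informational date format pattern (dates are carried
#'   as raw text; the pattern is kept for provenance only).
#' @param sex_map named character vector mapping source sex codes
#'   (lowercased, trimmed) to `"m"`/`"f"`; unmapped codes become missing.
#' @param middle_sep regular expression separating multiple given names in
#'   the mortality file's middle-name cell (default whitespace).
#' @param na_strings cell values read as missing.
#' @return an object of class `column_mapping`.
#' @export
column_mapping <- function(columns = character(), delimiter = ",",
                           encoding = "UTF-8", date_format = "%Y-%m-%d",
                           sex_map = .DEFAULT_SEX_MAP,
                           middle_sep = "[[:space:]]+",
                           na_strings = c("", "NA")) {
  columns <- unlist(columns)
  structure(list(columns = columns, delimiter = delimiter,
                 encoding = encoding, date_format = date_format,
                 sex_map = sex_map, middle_sep = middle_sep,
                 na_strings = na_strings),
            class = "column_mapping")
}

#' Read a column mapping from a YAML file
#'
#' The YAML file may contain any of the [column_mapping()] fields
#' (`columns`, `delimiter`, `encoding`, `date_format`, `sex_map`,
#' `middle_sep`, `na_strings`).
#'
#' @param path path to a YAML file.
#' @return a `column_mapping`.
#' @export
read_column_mapping <- function(path) {
  spec <- yaml::read_yaml(path)
  args <- spec[intersect(names(spec),
                         names(formals(column_mapping)))]
  if (!is.null(args$sex_map)) args$sex_map <- unlist(args$sex_map)
  do.call(column_mapping, args)
}

.source_col <- function(mapping, field) {
  cols <- mapping$columns
  if (field %in% names(cols)) cols[[field]] else field
}

.read_delim_raw <- function(path, mapping) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, sep = mapping$delimiter, colClasses = "character",
           na.strings = mapping$na_strings, fileEncoding = mapping$encoding,
           check.names = FALSE, stringsAsFactors = FALSE)
}

.extract_fields <- function(raw, mapping, required, optional, what) {
  out <- list()
  for (field in c(required, optional)) {
    col <- .source_col(mapping, field)
    if (col %in% names(raw)) {
      out[[field]] <- .blank_to_na(raw[[col]])
    } else if (field %in% required) {
      stop("required column ", sQuote(col), " (field ", field,
           ") not found in ", what, " file", call. = FALSE)
    } else {
      out[[field]] <- rep(NA_character_, nrow(raw))
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.map_sex <- function(x, sex_map) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(sex_map[key])
  out[is.na(match(key, names(sex_map)))] <- NA_character_
  as.character(out)
}

#' Read a local patient registry
#'
#' @param path delimited file with a header row.
#' @param mapping a [column_mapping()]; canonical fields: `record_id`,
#'   `birth_surname`, `current_surname`, `first_name`, `birth_date`, `sex`,
#'   `birth_city`, `birth_country`, `vital_status`, `death_date`.
#' @return data.frame of class `person_records`, one row per data row in
#'   file order; missing cells are `NA`, sex is mapped to `"m"`/`"f"`/`NA`.
#' @export
read_person_table <- function(path, mapping = column_mapping()) {
  raw <- .read_delim_raw(path, mapping)
  df <- .extract_fields(raw, mapping, .PERSON_REQUIRED, .PERSON_OPTIONAL,
                        "local registry")
  dup <- df$record_id[duplicated(df$record_id)]
  if (length(dup))
    stop("duplicate record_id in local registry: ", sQuote(dup[1]),
         call. = FALSE)
  df$sex <- .map_sex(df$sex, mapping$sex_map)
  vs <- tolower(trimws(df$vital_status))
  df$vital_status <- ifelse(is.na(vs), NA_character_,
                            ifelse(vs %in% c("deceased", "dead", "d"),
                                   "deceased",
                                   ifelse(vs %in% c("alive", "living", "a"),
                                          "alive", NA_character_)))
  class(df) <- c("person_records", "data.frame")
  df
}

#' Read a national mortality file
#'
#' @param path delimited file with a header row.
#' @param mapping a [column_mapping()]; canonical fields: `fnmd_id`,
#'   `surname`, `first_name`, `middle_names`, `birth_date`, `sex`,
#'   `birth_city`, `birth_country`, `death_date`, `death_zip`. The
#'   middle-name cell is split on `mapping$middle_sep` (order preserved).
#' @return data.frame of class `mortality_records`; `middle_names` is a
#'   list column of character vectors (empty when the cell is empty).
#' @export
read_mortality_table <- function(path, mapping = column_mapping()) {
  raw <- .read_delim_raw(path, mapping)
  df <- .extract_fields(raw, mapping, .MORT_REQUIRED, .MORT_OPTIONAL,
                        "mortality")
  dup <- df$fnmd_id[duplicated(df$fnmd_id)]
  if (length(dup))
    stop("duplicate fnmd_id in mortality file: ", sQuote(dup[1]),
         call. = FALSE)
  dd <- as.Date(df$death_date, format = "%Y-%m-%d")
  if (anyNA(dd)) {
    bad <- which(is.na(dd))[1]
    stop("unparseable death_date in mortality file row ", bad, ": ",
         sQuote(df$death_date[bad]), call. = FALSE)
  }
  df$death_date <- format(dd, "%Y-%m-%d")
  df$sex <- .map_sex(df$sex, mapping$sex_map)
  df$middle_names <- lapply(df$middle_names, function(cell) {
    if (is.na(cell)) return(character(0))
    parts <- strsplit(cell, mapping$middle_sep)[[1]]
    parts[nzchar(parts)]
  })
  class(df) <- c("mortality_records", "data.frame")
  df
}

.PAIR_COLUMNS <- c("local_id", "fnmd_id", "d_first", "d_surname", "d_date",
                   "d_sex", "d_total", "d_city", "selected", "ambiguous",
                   "death_date")

#' Write the retained pairs of a linkage run to CSV
#'
#' One row per retained pair with the five field distances, the total, the
#' selection flags and the death date, in a stable column order, sorted by
#' (local id, mortality id). Re-running with the same input produces a
#' byte-identical file.
#'
#' @param pairs data.frame of match results (e.g. `linkage$pairs` from
#'   [link_records()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  for (col in .PAIR_COLUMNS)
    if (!col %in% names(pairs)) pairs[[col]] <- rep(NA, nrow(pairs))
  pairs <- pairs[.PAIR_COLUMNS]
  pairs <- pairs[order(pairs$local_id, pairs$fnmd_id), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(pairs, con, row.names = FALSE, quote = FALSE, na = "",
            eol = "\n")
  invisible(path)
}

#' Read a pair file written by [write_pairs()]
#'
#' @param path CSV path.
#' @return data.frame with the pair-file columns; distances integer,
#'   `selected`/`ambiguous` logical.
#' @export
read_pairs <- function(path) {
  df <- read.csv(path, colClasses = "character", na.strings = "",
                 stringsAsFactors = FALSE)
  for (col in c("d_first", "d_surname", "d_date", "d_sex", "d_total",
                "d_city"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("selected", "ambiguous"))
    df[[col]] <- as.logical(df[[col]])
  df
}
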