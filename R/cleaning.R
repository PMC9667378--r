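# Text normalisation, birth-date repair and derived name/city variants.
#
# All comparison fields end up as lowercase ASCII letters a-z: the national
# mortality file carries no accents, so the local registry must be brought
# down to the same alphabet before any distance is computed.

# accented characters (both cases) and their ASCII replacements; multi-char
# ligatures are handled separately because chartr() is 1:1
.ACCENT_FROM <- paste0(
  "àáâãäåāăą",
  "ÀÁÂÃÄÅĀĂĄ",
  "çćčÇĆČ",
  "èéêëēėę",
  "ÈÉÊËĒĖĘ",
  "ìíîïīį",
  "ÌÍÎÏĪĮ",
  "ñńÑŃ",
  "òóôõöøō",
  "ÒÓÔÕÖØŌ",
  "ùúûüūÙÚÛÜŪ",
  "ýÿÝŸ",
  "žźżŽŹŻ",
  "šśŠŚ")
.ACCENT_TO <- paste0(
  "aaaaaaaaa", "aaaaaaaaa",
  "cccccc",
  "eeeeeee", "eeeeeee",
  "iiiiii", "iiiiii",
  "nnnn",
  "ooooooo", "ooooooo",
  "uuuuuuuuuu",
  "yyyy",
  "zzzzzz",
  "ssss")

#' Lowercase text and strip accents
#'
#' Transliterates accented Latin letters (and the ae/oe/ss ligatures) to
#' plain ASCII and lowercases the result. Non-letter characters are kept;
#' use [normalize_text()] for the full comparison normalisation.
#'
#' @param x character vector.
#' @return character vector of the same length; `NA` is preserved.
#' @export
#' @examples
#' strip_accents("Hélène-Françoise")
strip_accents <- function(x) {
  x <- enc2utf8(as.character(x))
  x <- gsub("æ|Æ", "ae", x)
  x <- gsub("œ|Œ", "oe", x)
  x <- gsub("ß", "ss", x)
  tolower(chartr(.ACCENT_FROM, .ACCENT_TO, x))
}

#' Normalise a text field for comparison
#'
#' Strips accents, lowercases, and removes every character that is not a
#' letter a-z (digits, punctuation, spaces). This is the cleaning applied to
#' every name and city field on both sides before distances are computed.
#'
#' @param x character vector.
#' @return character vector containing only characters a-z; empty strings
#'   stay empty and `NA` stays `NA`.
#' @export
#' @examples
#' normalize_text("Pierre-Olivier")   # "pierreolivier"
#' normalize_text("Élise 2")     # "elise"
normalize_text <- function(x) {
  gsub("[^a-z]", "", strip_accents(x))
}

.days_in_month <- function(y, m) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- rep(NA_integer_, length(m))
  ok <- !is.na(m) & m >= 1L & m <= 12L
  out[ok] <- dm[m[ok]]
  leap <- ok & m == 2L & ((y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L)
  out[leap] <- 29L
  out
}

.valid_ymd <- function(y, m, d) {
  dm <- .days_in_month(y, m)
  !is.na(m) & !is.na(d) & !is.na(dm) & d >= 1L & d <= dm
}

#' Repair a raw birth date into a valid 8-digit YYYYMMDD string
#'
#' Mortality-file birth dates may have day and month recorded as "00"
#' (unknown), or day and month in the wrong order (e.g. 1960-31-03). The
#' repair rule is: a 00-00 day/month becomes January 1; an otherwise valid
#' date is kept; an invalid date is retried with day and month swapped; if
#' still invalid, January 1 is used.
#'
#' @param raw character vector of `YYYY-MM-DD`-shaped strings (any
#'   non-digit separators; day/month may be absent or "00").
#' @return character vector of 8-digit `YYYYMMDD` strings, each a valid
#'   calendar date. `NA` input gives `NA`.
#' @export
#' @examples
#' repair_birth_date(c("1956-00-00", "1960-31-03", "1959-32-33"))
#' # "19560101" "19600331" "19590101"
repair_birth_date <- function(raw) {
  raw <- as.character(raw)
  out <- rep(NA_character_, length(raw))
  live <- !is.na(raw)
  if (!any(live)) return(out)
  m <- regmatches(raw, regexec(
    "([0-9]{4})[^0-9]*([0-9]{1,2})?[^0-9]*([0-9]{1,2})?", raw))
  nogroup <- live & vapply(m, length, 0L) == 0L
  if (any(nogroup))
    stop("cannot extract a 4-digit year from birth date ",
         paste(sQuote(raw[nogroup][1]), collapse = ", "), call. = FALSE)
  pick <- function(i) vapply(m, function(g) if (length(g) >= i) g[i] else "",
                             character(1))
  y <- suppressWarnings(as.integer(pick(2L)))
  mo <- suppressWarnings(as.integer(pick(3L)))
  dy <- suppressWarnings(as.integer(pick(4L)))
  if (any(live & is.na(y)))
    stop("cannot extract a 4-digit year from birth date ",
         sQuote(raw[live & is.na(y)][1]), call. = FALSE)
  mo[is.na(mo)] <- 0L
  dy[is.na(dy)] <- 0L

  fm <- rep(1L, length(raw))  # final month/day default to January 1
  fd <- rep(1L, length(raw))
  keep <- .valid_ymd(y, mo, dy) & !(mo == 0L & dy == 0L)
  fm[keep] <- mo[keep]
  fd[keep] <- dy[keep]
  swap <- !keep & !(mo == 0L & dy == 0L) & .valid_ymd(y, dy, mo)
  fm[swap] <- dy[swap]
  fd[swap] <- mo[swap]
  out[live] <- sprintf("%04d%02d%02d", y[live], fm[live], fd[live])
  out
}

#' Remove a district suffix from a city name and normalise it
#'
#' Large French cities are recorded with an arrondissement mention (e.g.
#' "Paris, 13ème arrondissement"); only the city proper is compared, so a
#' trailing ordinal (digits, optional er/e/ème) with an optional
#' "arrondissement" word and preceding punctuation is removed before
#' [normalize_text()].
#'
#' @param raw character vector of city names.
#' @return normalised (a-z only) city names.
#' @export
#' @examples
#' clean_city("Paris, 13ème arrondissement")  # "paris"
#' clean_city("Lyon 3e")                           # "lyon"
clean_city <- function(raw) {
  pat <- paste0("[[:space:],;:/-]*[0-9]{1,2}[[:space:]]*",
                "(er|e|eme|ème|éme)?[[:space:]]*",
                "(arrondissement|arrdt|arr\\.?)?[[:space:]]*$")
  normalize_text(sub(pat, "", as.character(raw), ignore.case = TRUE))
}

.default_abbrev_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "city_abbreviations.tsv",
                          package = "mortlink")
      tab <- read.csv(path, sep = "\t", header = TRUE,
                      colClasses = "character")
      cache <<- setNames(tab$expansion, tab$abbrev)
    }
    cache
  }
})

#' Expand abbreviation tokens in a city name
#'
#' Local registries abbreviate common city-name particles ("St-Martin-sr-
#' Ocre"); the mortality file writes them in full. Each token of the name is
#' looked up in a substitution table (packaged default: st/ste ->
#' saint/sainte, sr/s -> sur, ss -> sous, etc.) and the expanded name is then
#' normalised.
#'
#' @param raw character vector of city names.
#' @param table named character vector mapping lowercase abbreviation tokens
#'   to their expansion; default is the packaged table
#'   (`extdata/city_abbreviations.tsv`).
#' @return normalised (a-z only) expanded city names.
#' @export
#' @examples
#' expand_city_abbrev("St-Martin-sr-Ocre")  # "saintmartinsurocre"
expand_city_abbrev <- function(raw, table = NULL) {
  if (is.null(table)) table <- .default_abbrev_table()
  raw <- as.character(raw)
  out <- rep(NA_character_, length(raw))
  live <- which(!is.na(raw))
  if (!length(live)) return(out)
  toks <- strsplit(raw[live], "[[:space:]'./,-]+")
  out[live] <- vapply(toks, function(tk) {
    key <- strip_accents(tk)
    hit <- !is.na(match(key, names(table)))
    tk[hit] <- table[key[hit]]
    paste0(tk, collapse = "")
  }, character(1))
  normalize_text(out)
}

#' Build the three first-name comparison variants
#'
#' From a (possibly compound) first name and an optional first middle name,
#' builds the variants used for the first-name distance: the first
#' hyphen/space-delimited element (`firstname_0`), the whole cleaned first
#' name (`firstname_1`), and the first name concatenated with the first
#' middle name (`firstname_12`; equals `firstname_1` when no middle name).
#'
#' @param first_name character vector of raw first names.
#' @param first_middle_name character vector of raw first middle names, or
#'   `NA` where absent.
#' @return data.frame with columns `firstname_0`, `firstname_1`,
#'   `firstname_12` (all normalised a-z text).
#' @export
#' @examples
#' build_firstname_variants("Pierre-Olivier", "Christian")
#' # pierre / pierreolivier / pierreolivierchristian
build_firstname_variants <- function(first_name, first_middle_name = NA) {
  first_name <- as.character(first_name)
  n <- length(first_name)
  first_middle_name <- rep_len(as.character(first_middle_name), n)
  f1 <- normalize_text(first_name)
  bad <- is.na(f1) | f1 == ""
  if (any(bad))
    stop("first name empty after cleaning: ",
         sQuote(first_name[bad][1]), call. = FALSE)
  f0 <- normalize_text(sub("[[:space:]-].*$", "", first_name))
  f0[is.na(f0) | f0 == ""] <- f1[is.na(f0) | f0 == ""]
  mid <- normalize_text(first_middle_name)
  mid[is.na(mid)] <- ""
  data.frame(firstname_0 = f0, firstname_1 = f1,
             firstname_12 = paste0(f1, mid), stringsAsFactors = FALSE)
}

.blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

.first_middle <- function(middle_names) {
  if (is.list(middle_names)) {
    vapply(middle_names, function(v) {
      v <- .blank_to_na(v)
      v <- v[!is.na(v)]
      if (length(v)) v[1] else NA_character_
    }, character(1))
  } else {
    middle_names <- as.character(middle_names)
    if (!length(middle_names)) return(character(0))
    vapply(strsplit(ifelse(is.na(middle_names), "", middle_names),
                    "[[:space:]]+"),
           function(v) if (length(v) && nzchar(v[1])) v[1]
           else NA_character_, character(1))
  }
}

#' Clean a registry table into comparison-ready records
#'
#' Applies the whole cleaning pipeline to a local-registry or mortality-file
#' table: name normalisation, first-name variant construction, birth-date
#' repair, city cleaning (and, on the local side, abbreviation expansion),
#' country grouping, and the two blocking keys (repaired birth date, and the
#' first 4 letters of the first name + first 4 letters of the preferred
#' surname — birth surname when present, current surname otherwise; names
#' shorter than 4 letters contribute their full length).
#'
#' @param records a `person_records` or `mortality_records` data.frame (see
#'   [read_person_table()] / [read_mortality_table()]).
#' @param side `"local"` or `"fnmd"`; inferred from the class of `records`
#'   when possible.
#' @param home_country normalised token identifying the home country
#'   (default `"france"`); used for the `country_group` stratum field.
#' @param abbrev optional abbreviation table for [expand_city_abbrev()].
#' @return data.frame of class `clean_records` with one row per input row:
#'   `source_id`, `side`, `firstname_0/1/12`, `surname_birth`,
#'   `surname_current`, `birth_date8`, `sex`, `city`, `city_expanded`,
#'   `country_group`, `key_date`, `key_name`, `death_date`.
#' @export
clean_records <- function(records, side = NULL, home_country = "france",
                          abbrev = NULL) {
  if (is.null(side)) {
    side <- if (inherits(records, "mortality_records")) "fnmd"
            else if (inherits(records, "person_records")) "local"
            else stop("side must be given for a plain data.frame")
  }
  side <- match.arg(side, c("local", "fnmd"))
  df <- as.data.frame(records, stringsAsFactors = FALSE)

  if (side == "local") {
    id <- df$record_id
    sur_birth <- normalize_text(.blank_to_na(df$birth_surname))
    sur_cur <- normalize_text(.blank_to_na(df$current_surname))
    mid <- rep(NA_character_, nrow(df))
    death <- if ("death_date" %in% names(df)) .blank_to_na(df$death_date)
             else rep(NA_character_, nrow(df))
  } else {
    id <- df$fnmd_id
    sur_birth <- normalize_text(.blank_to_na(df$surname))
    sur_cur <- rep(NA_character_, nrow(df))
    mid <- if ("middle_names" %in% names(df)) .first_middle(df$middle_names)
           else rep(NA_character_, nrow(df))
    death <- .blank_to_na(df$death_date)
  }
  sur_birth[which(sur_birth == "")] <- NA_character_
  sur_cur[which(sur_cur == "")] <- NA_character_

  fv <- build_firstname_variants(df$first_name, mid)
  if (side == "local") fv$firstname_12 <- fv$firstname_1

  date8 <- repair_birth_date(df$birth_date)
  city_raw <- .blank_to_na(df$birth_city)
  # district mentions are dropped on both sides; the expanded variant (local
  # side only) additionally rewrites abbreviation tokens
  pat_city <- clean_city(city_raw)
  pat_city[which(pat_city == "")] <- NA_character_
  if (side == "local") {
    pat <- paste0("[[:space:],;:/-]*[0-9]{1,2}[[:space:]]*",
                  "(er|e|eme|ème|éme)?[[:space:]]*",
                  "(arrondissement|arrdt|arr\\.?)?[[:space:]]*$")
    no_district <- sub(pat, "", as.character(city_raw), ignore.case = TRUE)
    city_exp <- expand_city_abbrev(no_district, table = abbrev)
    city_exp[which(city_exp == "")] <- NA_character_
  } else {
    city_exp <- rep(NA_character_, nrow(df))
  }

  country <- normalize_text(.blank_to_na(df$birth_country))
  country_group <- ifelse(is.na(country) | country == "", "missing",
                          ifelse(country == normalize_text(home_country),
                                 "france", "other"))

  pref_sur <- ifelse(!is.na(sur_birth), sur_birth, sur_cur)
  key_name <- ifelse(is.na(pref_sur), NA_character_,
                     paste0(substr(fv$firstname_1, 1L, 4L),
                            substr(pref_sur, 1L, 4L)))

  sex <- .blank_to_na(if ("sex" %in% names(df)) df$sex else NA)
  out <- data.frame(
    source_id = as.character(id), side = rep(side, nrow(df)),
    firstname_0 = fv$firstname_0, firstname_1 = fv$firstname_1,
    firstname_12 = fv$firstname_12,
    surname_birth = sur_birth, surname_current = sur_cur,
    birth_date8 = date8, sex = sex,
    city = pat_city, city_expanded = city_exp,
    country_group = country_group,
    key_date = date8, key_name = key_name,
    death_date = death, stringsAsFactors = FALSE)
  class(out) <- c("clean_records", "data.frame")
  out
}
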