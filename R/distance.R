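# Per-field edit distances between cleaned records.

#' Restricted Damerau-Levenshtein (optimal string alignment) distance
#'
#' Minimum number of single-character insertions, deletions, substitutions
#' and transpositions of two adjacent characters needed to turn `a` into
#' `b`, with the restriction that no substring is edited twice (the OSA
#' variant). Vectorised with the usual recycling rules; computed in C++.
#'
#' @param a,b character vectors of cleaned strings.
#' @return integer vector of distances; `NA` where either input is `NA`.
#' @export
#' @examples
#' dld("jeanpoqu", "jeanpoku")  # 1
#' dld("ab", "ba")              # 1 (one adjacent transposition)
dld <- function(a, b) {
  .dld_cpp(as.character(a), as.character(b))
}

#' Per-field distance profile for candidate pairs
#'
#' For each (local, mortality) candidate pair computes the five field
#' distances used by the deterministic matching rule:
#' \describe{
#'   \item{d_first}{minimum DLD between the local cleaned first name and the
#'     three mortality-side first-name variants (first element, whole first
#'     name, first name + first middle name).}
#'   \item{d_surname}{minimum DLD between the mortality surname and the
#'     local birth surname / current surname (missing surnames skipped;
#'     both missing is a data error).}
#'   \item{d_date}{DLD between the two repaired 8-digit birth-date strings.}
#'   \item{d_sex}{0 if the sexes agree or either is missing, 1 if both are
#'     present and differ.}
#'   \item{d_city}{minimum DLD between the mortality birth city and the
#'     local city / expanded-abbreviation city; `NA` when either side has no
#'     city. Used only for best-pair selection, never for validation.}
#' }
#' `d_total` is the sum of the first four distances.
#'
#' @param local_clean,fnmd_clean `clean_records` tables
#'   (see [clean_records()]).
#' @param pairs data.frame with columns `local_id`, `fnmd_id` identifying
#'   the pairs to score (e.g. from [block_pairs()]).
#' @return `pairs` with columns `d_first`, `d_surname`, `d_date`, `d_sex`,
#'   `d_total`, `d_city` appended.
#' @export
field_distances <- function(local_clean, fnmd_clean, pairs) {
  li <- match(pairs$local_id, local_clean$source_id)
  fi <- match(pairs$fnmd_id, fnmd_clean$source_id)
  if (anyNA(li) || anyNA(fi))
    stop("pairs reference ids absent from the cleaned tables")
  l <- local_clean[li, , drop = FALSE]
  f <- fnmd_clean[fi, , drop = FALSE]

  if (nrow(pairs) == 0L) {
    pairs$d_first <- pairs$d_surname <- pairs$d_date <- pairs$d_sex <-
      pairs$d_total <- pairs$d_city <- integer(0)
    return(pairs)
  }

  d_first <- pmin(dld(l$firstname_1, f$firstname_0),
                  dld(l$firstname_1, f$firstname_1),
                  dld(l$firstname_1, f$firstname_12))

  both_missing <- is.na(l$surname_birth) & is.na(l$surname_current)
  if (any(both_missing))
    stop("local record with no surname at all: ",
         sQuote(l$source_id[both_missing][1]), call. = FALSE)
  d_surname <- pmin(dld(l$surname_birth, f$surname_birth),
                    dld(l$surname_current, f$surname_birth), na.rm = TRUE)

  d_date <- dld(l$birth_date8, f$birth_date8)
  d_sex <- ifelse(is.na(l$sex) | is.na(f$sex), 0L,
                  ifelse(l$sex == f$sex, 0L, 1L))
  d_city <- suppressWarnings(
    pmin(dld(l$city, f$city), dld(l$city_expanded, f$city), na.rm = TRUE))
  d_city[is.na(l$city) & is.na(l$city_expanded)] <- NA_integer_
  d_city[is.na(f$city)] <- NA_integer_

  pairs$d_first <- as.integer(d_first)
  pairs$d_surname <- as.integer(d_surname)
  pairs$d_date <- as.integer(d_date)
  pairs$d_sex <- as.integer(d_sex)
  pairs$d_total <- pairs$d_first + pairs$d_surname + pairs$d_date +
    pairs$d_sex
  pairs$d_city <- as.integer(d_city)
  pairs
}
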