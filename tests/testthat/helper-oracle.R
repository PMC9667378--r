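# Independent oracles and fixture builders used across the suite.

# Brute-force restricted Damerau-Levenshtein distance: memoised recursion
# written directly from the recurrence, in R. Independent of the package's
# C++ kernel.
dld_oracle <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ".", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- min(rec(i - 1L, j) + 1L,
                rec(i, j - 1L) + 1L,
                rec(i - 1L, j - 1L) + (sa[i] != sb[j]))
    if (i > 1L && j > 1L && sa[i] == sb[j - 1L] && sa[i - 1L] == sb[j])
      best <- min(best, rec(i - 2L, j - 2L) + 1L)
    memo[[key]] <- best
    best
  }
  rec(length(sa), length(sb))
}

random_strings <- function(k, max_len, alphabet = letters) {
  vapply(sample.int(max_len + 1L, k, replace = TRUE) - 1L, function(len)
    paste0(sample(alphabet, len, replace = TRUE), collapse = ""),
    character(1))
}

# Reference linkage: scores every (local, fnmd) pair that shares a blocking
# key, using an inline restatement of the validation and selection rules.
# Only the dld() string kernel is shared with the implementation under test
# (it is itself checked against dld_oracle()).
brute_reference <- function(local, fnmd, thresholds = dld_thresholds()) {
  lc <- clean_records(local, "local")
  fc <- clean_records(fnmd, "fnmd")
  idx <- expand.grid(li = seq_len(nrow(lc)), fi = seq_len(nrow(fc)))
  same_date <- lc$key_date[idx$li] == fc$key_date[idx$fi]
  same_name <- !is.na(lc$key_name[idx$li]) & !is.na(fc$key_name[idx$fi]) &
    lc$key_name[idx$li] == fc$key_name[idx$fi]
  idx <- idx[which(same_date | same_name), , drop = FALSE]
  l <- lc[idx$li, ]
  f <- fc[idx$fi, ]
  d_first <- pmin(dld(l$firstname_1, f$firstname_0),
                  dld(l$firstname_1, f$firstname_1),
                  dld(l$firstname_1, f$firstname_12))
  d_sur <- pmin(dld(l$surname_birth, f$surname_birth),
                dld(l$surname_current, f$surname_birth), na.rm = TRUE)
  d_date <- dld(l$birth_date8, f$birth_date8)
  d_sex <- ifelse(is.na(l$sex) | is.na(f$sex) | l$sex == f$sex, 0L, 1L)
  d_tot <- d_first + d_sur + d_date + d_sex
  d_city <- suppressWarnings(
    pmin(dld(l$city, f$city), dld(l$city_expanded, f$city), na.rm = TRUE))
  ok <- d_first <= thresholds$max_first & d_sur <= thresholds$max_surname &
    d_date <= thresholds$max_date & d_sex <= thresholds$max_sex &
    d_tot <= thresholds$max_total
  res <- data.frame(local_id = l$source_id, fnmd_id = f$source_id,
                    d_total = d_tot, d_city = d_city,
                    death_date = f$death_date,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  # independent selection: stable sort then first-per-local
  cr <- ifelse(is.na(res$d_city), .Machine$integer.max, res$d_city)
  o <- order(res$local_id, res$d_total, cr,
             ifelse(is.na(res$death_date), "", res$death_date), res$fnmd_id)
  res <- res[o, , drop = FALSE]
  res$selected <- !duplicated(res$local_id)
  rownames(res) <- NULL
  res
}

# small typed builders for hand fixtures
person_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(birth_surname = NA_character_,
                   current_surname = NA_character_,
                   birth_city = NA_character_,
                   birth_country = NA_character_,
                   vital_status = "alive", death_date = NA_character_,
                   sex = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  class(df) <- c("person_records", "data.frame")
  df
}

mortality_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(middle_names = NA_character_, sex = NA_character_,
                   birth_city = NA_character_, birth_country = NA_character_,
                   death_date = "2010-06-15", death_zip = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  class(df) <- c("mortality_records", "data.frame")
  df
}
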