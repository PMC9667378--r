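# Synthetic linked registries with ground truth and an explicit
# error-injection model.
#
# The generator emulates the corruptions seen between a hospital registry
# and the national mortality file: clerical typos (single edits), married
# surnames with the birth surname sometimes unrecorded, compound and
# concatenated given names, invalid day/month order, day and month recorded
# as "00", district mentions on big-city births, accents on the local side
# only (the mortality file carries none), and decoy records that share a
# blocking key with a real patient without being them.

.pool_file <- function(name) {
  path <- system.file("extdata", name, package = "mortlink")
  readLines(path, encoding = "UTF-8")
}

.name_pools <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- list(m = .pool_file("first_names_m.txt"),
                     f = .pool_file("first_names_f.txt"),
                     surnames = .pool_file("surnames.txt"),
                     cities = .pool_file("cities.txt"))
    cache
  }
})

.FOREIGN_COUNTRIES <- c("Portugal", "Italie", "Espagne", "Algérie",
                        "Maroc", "Tunisie", "Belgique", "Allemagne",
                        "Pologne", "Turquie", "Vietnam", "Senegal")

#' Error-injection model for the synthetic cohort generator
#'
#' All rates are probabilities in `[0, 1]`, applied independently per
#' record (per field where relevant). Defaults are synthetic design
#' choices, calibrated so the direct reference strategy loses roughly ten
#' sensitivity points against the distance-based strategy; see the package
#' vignette for the derivation.
#'
#' @param typo_first,typo_surname probability of a single random edit
#'   (insertion/deletion/substitution/adjacent transposition) in the
#'   mortality-file first name / surname.
#' @param typo_date probability of a single digit substitution in the
#'   mortality-file birth date.
#' @param daymonth_swap probability that the mortality file records the
#'   birth date with day and month inverted; applied only when the true day
#'   exceeds 12, i.e. when the inversion produces an invalid date (the
#'   documented mortality-file quirk).
#' @param missing_daymonth probability that the mortality-file birth date
#'   has day and month recorded as "00".
#' @param married_name probability that a woman's current surname differs
#'   from her birth surname.
#' @param birth_surname_omitted probability, given a married name, that the
#'   local registry lacks the birth surname.
#' @param compound_first probability of a compound (hyphenated) first name.
#' @param middle_name probability that the mortality file carries at least
#'   one middle name.
#' @param local_truncate probability, given a compound first name, that the
#'   local registry stores only its first element.
#' @param local_concat probability, given a middle name, that the local
#'   registry stores first and middle name concatenated.
#' @param sex_error probability of a sex flip in the mortality file.
#' @param accent_keep probability that the local registry preserves accents
#'   (the mortality file never has any).
#' @param district_suffix probability of a district mention on a
#'   Paris/Lyon/Marseille birth city, each side independently.
#' @param born_outside fraction of patients born outside the home country.
#' @param decoy_rate fraction of locals that get a mortality-file decoy
#'   sharing one blocking key (same birth date, or same name pair with a
#'   different birth date) but belonging to a different person.
#' @param background_rate unrelated mortality records, as a fraction of n.
#' @param near_twin_rate fraction of living locals with a mortality record
#'   one single edit away (a pre-index death of an almost-namesake).
#' @param homonym_twin_rate fraction of living locals with an exact
#'   homonym (same name, birth date and sex) dead before the index date.
#' @param post_index_death fraction of living-at-index locals who truly
#'   died after the index date and appear in the mortality file.
#' @return object of class `error_model`.
#' @export
error_model <- function(typo_first = 0.03, typo_surname = 0.03,
                        typo_date = 0.01, daymonth_swap = 0.08,
                        missing_daymonth = 0.02, married_name = 0.35,
                        birth_surname_omitted = 0.12, compound_first = 0.15,
                        middle_name = 0.6, local_truncate = 0.25,
                        local_concat = 0.03, sex_error = 0.003,
                        accent_keep = 0.9, district_suffix = 0.3,
                        born_outside = 0.08, decoy_rate = 0.10,
                        background_rate = 0.20, near_twin_rate = 0.008,
                        homonym_twin_rate = 0.001,
                        post_index_death = 0.05) {
  model <- as.list(environment())
  bad <- vapply(model, function(v)
    !is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1,
    logical(1))
  if (any(bad))
    stop("error-model rates must be single numbers in [0, 1]: ",
         paste(names(model)[bad], collapse = ", "), call. = FALSE)
  structure(model, class = "error_model")
}

#' Apply one single-character edit to a string
#'
#' Produces a string at restricted Damerau-Levenshtein distance exactly 1
#' from the input: a random insertion, deletion, substitution or adjacent
#' transposition. The edit alphabet is digits if the input is all digits,
#' letters otherwise.
#'
#' @param value non-empty string (insertion also accepts empty input).
#' @param kind one of `"insertion"`, `"deletion"`, `"substitution"`,
#'   `"transposition"`; default picks one feasible kind at random.
#' @return the edited string.
#' @export
corrupt_field <- function(value, kind = NULL) {
  value <- as.character(value)
  stopifnot(length(value) == 1L, !is.na(value))
  chars <- strsplit(value, "")[[1]]
  n <- length(chars)
  alphabet <- if (n > 0 && all(chars %in% as.character(0:9)))
    as.character(0:9) else letters
  feasible <- "insertion"
  if (n >= 1L) feasible <- c(feasible, "deletion", "substitution")
  if (n >= 2L && any(chars[-1] != chars[-n]))
    feasible <- c(feasible, "transposition")
  if (is.null(kind)) {
    kind <- sample(feasible, 1L)
  } else {
    kind <- match.arg(kind, c("insertion", "deletion", "substitution",
                              "transposition"))
    if (!kind %in% feasible)
      stop("edit kind ", sQuote(kind), " impossible for input ",
           sQuote(value), call. = FALSE)
  }
  switch(kind,
    insertion = {
      pos <- sample.int(n + 1L, 1L)
      paste0(paste0(chars[seq_len(pos - 1L)], collapse = ""),
             sample(alphabet, 1L),
             paste0(chars[seq_len(n)[seq_len(n) >= pos]], collapse = ""))
    },
    deletion = paste0(chars[-sample.int(n, 1L)], collapse = ""),
    substitution = {
      pos <- sample.int(n, 1L)
      chars[pos] <- sample(setdiff(alphabet, chars[pos]), 1L)
      paste0(chars, collapse = "")
    },
    transposition = {
      ok <- which(chars[-n] != chars[-1])
      pos <- if (length(ok) == 1L) ok else sample(ok, 1L)
      tmp <- chars[pos]
      chars[pos] <- chars[pos + 1L]
      chars[pos + 1L] <- tmp
      paste0(chars, collapse = "")
    })
}

.rand_birth_date <- function(k) {
  y <- sample(1920:1999, k, replace = TRUE)
  m <- sample(1:12, k, replace = TRUE)
  d <- mapply(function(yy, mm) sample.int(.days_in_month(yy, mm), 1L), y, m)
  sprintf("%04d-%02d-%02d", y, m, d)
}

.rand_date_between <- function(k, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  format(from + sample.int(as.integer(to - from) + 1L, k,
                           replace = TRUE) - 1L, "%Y-%m-%d")
}

.maybe <- function(p) runif(1) < p

# one random identity; returns a list of true attributes
.rand_identity <- function(pools, model, sex = NULL, bof = NULL) {
  if (is.null(sex)) sex <- sample(c("m", "f"), 1L)
  first <- sample(pools[[sex]], 1L)
  if (.maybe(model$compound_first)) {
    second <- sample(setdiff(pools[[sex]], first), 1L)
    first <- paste(first, second, sep = "-")
  }
  middle <- if (.maybe(model$middle_name))
    sample(pools[[sex]], 1L) else NA_character_
  sur_birth <- sample(pools$surnames, 1L)
  sur_cur <- sur_birth
  if (sex == "f" && .maybe(model$married_name))
    sur_cur <- sample(setdiff(pools$surnames, sur_birth), 1L)
  if (is.null(bof)) bof <- .maybe(model$born_outside)
  list(sex = sex, first = first, middle = middle,
       sur_birth = sur_birth, sur_cur = sur_cur,
       birth_date = .rand_birth_date(1L),
       city = sample(pools$cities, 1L),
       country = if (bof) sample(.FOREIGN_COUNTRIES, 1L) else "France",
       bof = bof)
}

.BIG_CITIES <- c("Paris", "Lyon", "Marseille")

.city_with_district <- function(city, p) {
  if (city %in% .BIG_CITIES && .maybe(p))
    paste0(city, ", ", sample(1:20, 1L), "ème arrondissement")
  else city
}

# the local registry's view of an identity
.local_view <- function(id, model) {
  first <- id$first
  if (grepl("-", first) && .maybe(model$local_truncate)) {
    first <- sub("-.*$", "", first)
  } else if (!is.na(id$middle) && .maybe(model$local_concat)) {
    first <- paste(first, id$middle, sep = "-")
  }
  sur_birth <- id$sur_birth
  if (id$sur_cur != id$sur_birth && .maybe(model$birth_surname_omitted))
    sur_birth <- NA_character_
  city <- .city_with_district(id$city, model$district_suffix)
  if (!.maybe(model$accent_keep)) {
    first <- strip_accents(first)
    sur_birth <- if (is.na(sur_birth)) sur_birth else strip_accents(sur_birth)
    city <- strip_accents(city)
  }
  list(first = first, sur_birth = sur_birth, sur_cur = id$sur_cur,
       city = city)
}

# the mortality file's view of an identity (accent-free, with injected
# clerical errors); death_date supplied by the caller
.fnmd_view <- function(id, model, corrupt = TRUE) {
  first <- strip_accents(id$first)
  sur <- strip_accents(id$sur_birth)
  middle <- if (is.na(id$middle)) "" else strip_accents(id$middle)
  sex <- id$sex
  date <- id$birth_date
  if (corrupt) {
    if (.maybe(model$typo_first)) first <- corrupt_field(first)
    if (.maybe(model$typo_surname)) sur <- corrupt_field(sur)
    day <- as.integer(substr(date, 9, 10))
    if (.maybe(model$missing_daymonth)) {
      date <- paste0(substr(date, 1, 4), "-00-00")
    } else if (day > 12L && .maybe(model$daymonth_swap)) {
      date <- paste0(substr(date, 1, 4), "-", substr(date, 9, 10), "-",
                     substr(date, 6, 7))
    } else if (.maybe(model$typo_date)) {
      pos <- sample(c(1:4, 6:7, 9:10), 1L)
      ch <- substr(date, pos, pos)
      substr(date, pos, pos) <- sample(setdiff(as.character(0:9), ch), 1L)
    }
    if (.maybe(model$sex_error)) sex <- if (sex == "m") "f" else "m"
  }
  city <- strip_accents(.city_with_district(id$city, model$district_suffix))
  list(surname = sur, first = first, middle = middle, date = date,
       sex = sex, city = city, country = strip_accents(id$country))
}

.exact_counts <- function(total, fraction) {
  a <- round(total * fraction)
  c(a, total - a)
}

# All 8-digit strings at restricted DLD <= 1 from a repaired date (both
# sides of a pair are always 8 digits, so only substitutions and adjacent
# transpositions can give distance 1).
.date_neighbors <- function(date8) {
  ch <- strsplit(date8, "")[[1]]
  out <- character(0)
  for (pos in 1:8)
    for (dg in setdiff(as.character(0:9), ch[pos])) {
      v <- ch
      v[pos] <- dg
      out <- c(out, paste0(v, collapse = ""))
    }
  for (pos in 1:7)
    if (ch[pos] != ch[pos + 1]) {
      v <- ch
      v[c(pos, pos + 1)] <- v[c(pos + 1, pos)]
      out <- c(out, paste0(v, collapse = ""))
    }
  c(date8, unique(out))
}

# Identity separation registry. A synthetic gold standard is only a valid
# instrument if "non-match" is observable: two distinct generated persons
# must never sit within the validation budget of each other (d_date <= 1,
# d_surname <= 1, first-name variant distance <= 2, total <= 2), otherwise
# no algorithm could reach specificity 1 even on error-free data. Identities
# are rejection-sampled against this registry; intentional near-matches
# (decoys, twins) are injected explicitly and never registered.
.identity_sketch <- function(id) {
  fv <- build_firstname_variants(id$first,
                                 if (is.na(id$middle)) NA else id$middle)
  list(f0 = fv$firstname_0, f1 = fv$firstname_1, f12 = fv$firstname_12,
       sb = normalize_text(id$sur_birth), sc = normalize_text(id$sur_cur),
       date8 = repair_birth_date(id$birth_date))
}

.identity_collides <- function(sk, registry) {
  for (d8 in .date_neighbors(sk$date8)) {
    bucket <- registry[[d8]]
    if (is.null(bucket)) next
    d_date <- if (d8 == sk$date8) 0L else 1L
    for (other in bucket) {
      d_first <- min(dld(sk$f1, c(other$f0, other$f1, other$f12)),
                     dld(other$f1, c(sk$f0, sk$f1, sk$f12)))
      if (d_first > 2L) next
      d_sur <- min(dld(c(sk$sb, sk$sc), other$sb),
                   dld(c(other$sb, other$sc), sk$sb))
      if (d_sur > 1L) next
      if (d_first + d_sur + d_date <= 2L) return(TRUE)
    }
  }
  FALSE
}

.register_identity <- function(sk, registry) {
  registry[[sk$date8]] <- c(registry[[sk$date8]], list(sk))
}

# draw identities until one is separated from everything already registered
.rand_separated_identity <- function(pools, model, registry,
                                     sex = NULL, bof = NULL,
                                     max_tries = 100L) {
  for (k in seq_len(max_tries)) {
    id <- .rand_identity(pools, model, sex = sex, bof = bof)
    sk <- .identity_sketch(id)
    if (!.identity_collides(sk, registry)) {
      .register_identity(sk, registry)
      return(id)
    }
  }
  stop("could not draw a separated identity; name pools too small for n",
       call. = FALSE)
}

#' Generate a linked synthetic cohort with ground truth
#'
#' Builds a local patient registry of `n` persons (a deceased sensitivity
#' set and a living-at-index specificity set, each split exactly by sex and
#' birth country) plus a mortality file containing the corrupted
#' counterparts of the deceased patients, post-index deaths of some living
#' patients, near-twin and homonym decoys targeting living patients, key-
#' sharing decoys and unrelated background records. Reproducible for a
#' given seed.
#'
#' @param n number of local records (`>= 1`).
#' @param model an [error_model()].
#' @param seed integer seed.
#' @param deceased_fraction fraction of locals in the deceased set.
#' @param index_date specificity index date.
#' @return object of class `linkage_cohort`: list with `person`
#'   (`person_records`), `mortality` (`mortality_records`), `gold`
#'   (record_id, truth, stratum, true_fnmd_id, encounter dates), `model`,
#'   `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(50, seed = 42)
#' table(coh$gold$truth, coh$gold$stratum)
simulate_cohort <- function(n, model = error_model(), seed = 1L,
                            deceased_fraction = 0.5,
                            index_date = "2016-01-01") {
  if (!inherits(model, "error_model"))
    stop("model must be built with error_model()", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (deceased_fraction < 0 || deceased_fraction > 1)
    stop("deceased_fraction must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  pools <- .name_pools()
  index_date <- as.Date(index_date)

  dl <- .exact_counts(n, deceased_fraction)
  n_dec <- dl[1]
  n_liv <- dl[2]
  plan <- function(k, truth) {
    if (k == 0L) return(NULL)
    ms <- .exact_counts(k, 0.5)
    out <- NULL
    for (sex in c("m", "f")) {
      ks <- if (sex == "m") ms[1] else ms[2]
      ob <- .exact_counts(ks, model$born_outside)
      out <- rbind(out,
                   data.frame(truth = truth, sex = sex,
                              bof = rep(c(TRUE, FALSE), c(ob[1], ob[2])),
                              stringsAsFactors = FALSE))
    }
    out
  }
  design <- rbind(plan(n_dec, "deceased"), plan(n_liv, "living"))
  stopifnot(nrow(design) == n)

  # preallocated column accumulators (a record per row is far too slow)
  pcol <- function(k) rep(NA_character_, k)
  person <- list(record_id = pcol(n), birth_surname = pcol(n),
                 current_surname = pcol(n), first_name = pcol(n),
                 birth_date = pcol(n), sex = pcol(n), birth_city = pcol(n),
                 birth_country = pcol(n), vital_status = pcol(n),
                 death_date = pcol(n))
  gold <- list(record_id = pcol(n), truth = pcol(n), stratum = pcol(n),
               true_fnmd_id = pcol(n), death_date = pcol(n),
               encounter_pre = pcol(n), encounter_post = pcol(n))
  mcap <- 3L * n + 16L
  m_id <- pcol(mcap); m_sur <- pcol(mcap); m_first <- pcol(mcap)
  m_mid <- pcol(mcap); m_date <- pcol(mcap); m_sex <- pcol(mcap)
  m_city <- pcol(mcap); m_country <- pcol(mcap); m_death <- pcol(mcap)
  m_zip <- pcol(mcap)
  fid <- 0L
  push_mort <- function(view, death_date) {
    fid <<- fid + 1L
    id <- sprintf("F%06d", fid)
    m_id[fid] <<- id
    m_sur[fid] <<- view$surname
    m_first[fid] <<- view$first
    m_mid[fid] <<- view$middle
    m_date[fid] <<- view$date
    m_sex[fid] <<- view$sex
    m_city[fid] <<- view$city
    m_country[fid] <<- view$country
    m_death[fid] <<- death_date
    m_zip[fid] <<- sprintf("%05d", sample(1000:95999, 1L))
    id
  }

  registry <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    row <- design[i, ]
    id <- .rand_separated_identity(pools, model, registry,
                                   sex = row$sex, bof = row$bof)
    lv <- .local_view(id, model)
    rid <- sprintf("L%06d", i)
    deceased <- row$truth == "deceased"
    death_date <- NA_character_
    true_fnmd <- NA_character_
    enc_pre <- enc_post <- NA_character_
    if (deceased) {
      death_date <- .rand_date_between(1L, "2001-01-01", "2020-12-31")
      true_fnmd <- push_mort(.fnmd_view(id, model), death_date)
    } else {
      enc_pre <- .rand_date_between(1L, "2001-01-01", "2015-12-31")
      enc_post <- .rand_date_between(1L, "2016-01-02", "2020-12-31")
      if (.maybe(model$post_index_death)) {
        post_dd <- .rand_date_between(1L, "2016-02-01", "2020-12-31")
        true_fnmd <- push_mort(.fnmd_view(id, model, corrupt = FALSE),
                               post_dd)
      }
      if (.maybe(model$near_twin_rate)) {
        tw <- .fnmd_view(id, model, corrupt = FALSE)
        which_field <- sample(c("surname", "first", "date"), 1L)
        if (which_field == "date") {
          # keep the edited date valid: bump the day-units digit
          d <- as.integer(substr(tw$date, 9, 10))
          d2 <- if (d > 1L) d - 1L else d + 1L
          substr(tw$date, 9, 10) <- sprintf("%02d", d2)
        } else {
          tw[[which_field]] <- corrupt_field(tolower(tw[[which_field]]))
        }
        push_mort(tw, .rand_date_between(1L, "2001-01-01", "2015-12-31"))
      }
      if (.maybe(model$homonym_twin_rate)) {
        push_mort(.fnmd_view(id, model, corrupt = FALSE),
                  .rand_date_between(1L, "2001-01-01", "2015-12-31"))
      }
    }
    if (.maybe(model$decoy_rate)) {
      share_date <- .maybe(0.5)
      for (k in 1:100) {
        dec <- .rand_identity(pools, model)
        if (share_date) dec$birth_date <- id$birth_date  # share date key
        else {                                           # share name key
          dec$first <- id$first
          dec$sur_birth <- id$sur_birth
          dec$sur_cur <- id$sur_birth
        }
        sk <- .identity_sketch(dec)
        if (!.identity_collides(sk, registry)) {
          .register_identity(sk, registry)
          push_mort(.fnmd_view(dec, model, corrupt = FALSE),
                    .rand_date_between(1L, "2001-01-01", "2020-12-31"))
          break
        }
      }
    }
    person$record_id[i] <- rid
    person$birth_surname[i] <- lv$sur_birth
    person$current_surname[i] <- lv$sur_cur
    person$first_name[i] <- lv$first
    person$birth_date[i] <- id$birth_date
    person$sex[i] <- id$sex
    person$birth_city[i] <- lv$city
    person$birth_country[i] <- id$country
    person$vital_status[i] <- if (deceased) "deceased" else "alive"
    person$death_date[i] <- death_date
    gold$record_id[i] <- rid
    gold$truth[i] <- row$truth
    gold$stratum[i] <- paste0(row$sex, "_", if (row$bof) "bof" else "bif")
    gold$true_fnmd_id[i] <- true_fnmd
    gold$death_date[i] <- death_date
    gold$encounter_pre[i] <- enc_pre
    gold$encounter_post[i] <- enc_post
  }

  n_bg <- round(n * model$background_rate)
  for (j in seq_len(n_bg)) {
    other <- .rand_separated_identity(pools, model, registry)
    push_mort(.fnmd_view(other, model),
              .rand_date_between(1L, "2001-01-01", "2020-12-31"))
  }

  person <- as.data.frame(person, stringsAsFactors = FALSE)
  gold <- as.data.frame(gold, stringsAsFactors = FALSE)
  keep <- seq_len(fid)
  mortality <- data.frame(fnmd_id = m_id[keep], surname = m_sur[keep],
                          first_name = m_first[keep],
                          middle_names = m_mid[keep],
                          birth_date = m_date[keep], sex = m_sex[keep],
                          birth_city = m_city[keep],
                          birth_country = m_country[keep],
                          death_date = m_death[keep],
                          death_zip = m_zip[keep],
                          stringsAsFactors = FALSE)
  mortality <- mortality[sample.int(nrow(mortality)), , drop = FALSE]
  rownames(person) <- rownames(gold) <- rownames(mortality) <- NULL
  class(person) <- c("person_records", "data.frame")
  class(mortality) <- c("mortality_records", "data.frame")
  structure(list(person = person, mortality = mortality, gold = gold,
                 model = model, seed = as.integer(seed)),
            class = "linkage_cohort")
}

#' @export
print.linkage_cohort <- function(x, ...) {
  cat("Synthetic linkage cohort (seed ", x$seed, ")\n", sep = "")
  cat("  local records:    ", nrow(x$person), "\n", sep = "")
  cat("  mortality records:", nrow(x$mortality), "\n")
  print(table(truth = x$gold$truth, stratum = x$gold$stratum))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the local registry, the mortality file and the gold standard as
#' CSV, plus the error model as YAML, into `dir`.
#'
#' @param cohort a `linkage_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mort <- cohort$mortality
  mort$middle_names <- vapply(mort$middle_names, function(v)
    paste0(v, collapse = " "), character(1))
  write.csv(cohort$person, file.path(dir, "local.csv"),
            row.names = FALSE, na = "")
  write.csv(mort, file.path(dir, "mortality.csv"),
            row.names = FALSE, na = "")
  write.csv(cohort$gold, file.path(dir, "gold.csv"),
            row.names = FALSE, na = "")
  yaml::write_yaml(unclass(cohort$model),
                   file.path(dir, "error_model.yaml"))
  invisible(dir)
}
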