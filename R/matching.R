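# Pair validation against the learned distance thresholds, the direct
# exact-matching reference strategy, and best-pair selection.

#' Distance thresholds for the deterministic matching rule
#'
#' The defaults are the values learned on a stratified training sample:
#' maximal DLD of 2 for the first name, 1 for the surname, 1 for the birth
#' date, 1 for sex, and 2 for the total of those four distances.
#'
#' @param max_first,max_surname,max_date,max_sex,max_total non-negative
#'   integer bounds. `max_total` may not exceed the sum of the four
#'   per-field bounds.
#' @return an object of class `dld_thresholds`.
#' @export
dld_thresholds <- function(max_first = 2L, max_surname = 1L, max_date = 1L,
                           max_sex = 1L, max_total = 2L) {
  t <- lapply(list(max_first = max_first, max_surname = max_surname,
                   max_date = max_date, max_sex = max_sex,
                   max_total = max_total), function(v) {
    v <- as.integer(v)
    if (length(v) != 1L || is.na(v) || v < 0L)
      stop("thresholds must be single non-negative integers", call. = FALSE)
    v
  })
  if (t$max_total > t$max_first + t$max_surname + t$max_date + t$max_sex)
    stop("max_total exceeds the sum of the per-field bounds", call. = FALSE)
  structure(t, class = "dld_thresholds")
}

#' @export
print.dld_thresholds <- function(x, ...) {
  cat("maximal DLDs: first", x$max_first, "| surname", x$max_surname,
      "| birth date", x$max_date, "| sex", x$max_sex,
      "| total", x$max_total, "\n")
  invisible(x)
}

#' Validate candidate pairs against the thresholds
#'
#' A pair matches iff every per-field distance is within its bound and the
#' total of the four field distances is within the total bound. The city
#' distance plays no role in validation.
#'
#' @param profile data.frame with columns `d_first`, `d_surname`, `d_date`,
#'   `d_sex`, `d_total` (e.g. from [field_distances()]).
#' @param thresholds a [dld_thresholds()] object.
#' @return logical vector, one element per row of `profile`.
#' @export
validate_pair <- function(profile, thresholds = dld_thresholds()) {
  profile$d_first <= thresholds$max_first &
    profile$d_surname <= thresholds$max_surname &
    profile$d_date <= thresholds$max_date &
    profile$d_sex <= thresholds$max_sex &
    profile$d_total <= thresholds$max_total
}

# minimal cleaning used by the direct reference strategy: lowercase and
# accent removal only — no non-letter removal, no date repair, no variants
.direct_key <- function(surname_birth, surname_current, first_name,
                        birth_date, sex) {
  sur <- ifelse(!is.na(.blank_to_na(surname_birth)),
                surname_birth, surname_current)
  paste(strip_accents(sur), strip_accents(first_name),
        trimws(as.character(birth_date)),
        tolower(trimws(as.character(sex))), sep = "\r")
}

#' Direct exact match between two records (reference strategy)
#'
#' The reference strategy applies minimal cleaning (accent removal and
#' lowercasing only) and links two records iff surname (birth surname if
#' present, current surname otherwise), first name, birth date and sex are
#' all exactly equal.
#'
#' @param local one-or-more-row data.frame with `birth_surname`,
#'   `current_surname`, `first_name`, `birth_date`, `sex`.
#' @param fnmd data.frame with `surname`, `first_name`, `birth_date`,
#'   `sex`; recycled row-wise against `local`.
#' @return logical vector.
#' @export
direct_match <- function(local, fnmd) {
  kl <- .direct_key(local$birth_surname, local$current_surname,
                    local$first_name, local$birth_date, local$sex)
  kf <- .direct_key(fnmd$surname, NA_character_, fnmd$first_name,
                    fnmd$birth_date, fnmd$sex)
  kl == kf
}

#' Select the most pertinent pair(s) for each local record
#'
#' Among the validated pairs of one local record: the pair with the
#' smallest total distance wins; ties are broken by the smallest city
#' distance (a missing city distance sorts last); remaining ties are all
#' kept and flagged `ambiguous`, with `selected = TRUE` on the first by
#' (death date, mortality id) order so output is deterministic.
#'
#' @param validated data.frame of validated pairs with columns `local_id`,
#'   `fnmd_id`, `d_total`, `d_city`, `death_date`.
#' @return the same data.frame with logical columns `selected` and
#'   `ambiguous` appended; at most one `selected` pair per local record
#'   unless flagged ambiguous.
#' @export
select_best <- function(validated) {
  n <- nrow(validated)
  validated$selected <- rep(FALSE, n)
  validated$ambiguous <- rep(FALSE, n)
  if (n == 0L) return(validated)
  city_rank <- ifelse(is.na(validated$d_city), .Machine$integer.max,
                      validated$d_city)
  dd <- ifelse(is.na(validated$death_date), "", validated$death_date)
  groups <- split(seq_len(n), validated$local_id)
  for (idx in groups) {
    tot <- validated$d_total[idx]
    top <- idx[tot == min(tot)]
    if (length(top) > 1L) {
      cr <- city_rank[top]
      top <- top[cr == min(cr)]
    }
    if (length(top) > 1L) {
      validated$ambiguous[top] <- TRUE
      o <- order(dd[top], validated$fnmd_id[top])
      validated$selected[top[o[1L]]] <- TRUE
    } else {
      validated$selected[top] <- TRUE
    }
  }
  validated
}

# one strategy run on full (already read) tables; chunking/parallelism live
# in link_records()
.run_dld <- function(local, fnmd, thresholds, home_country = "france",
                     chunks = NULL, workers = 1L) {
  lc <- clean_records(local, side = "local", home_country = home_country)
  fc <- clean_records(fnmd, side = "fnmd", home_country = home_country)
  pieces <- if (is.null(chunks)) list(fc) else chunks(fc)
  if (!length(pieces)) pieces <- list(fc)
  score_piece <- function(piece) {
    cand <- block_pairs(lc, piece)
    cand <- field_distances(lc, piece, cand)
    cand
  }
  scored <- if (workers > 1L && length(pieces) > 1L) {
    parallel::mclapply(pieces, score_piece, mc.cores = workers)
  } else {
    lapply(pieces, score_piece)
  }
  cand <- do.call(rbind, scored)
  cand <- cand[!duplicated(cand[c("local_id", "fnmd_id")]), , drop = FALSE]
  n_cand_date <- sum(cand$by_date)
  n_cand_name <- sum(cand$by_name)
  ok <- validate_pair(cand, thresholds)
  val <- cand[ok, , drop = FALSE]
  val$death_date <- fc$death_date[match(val$fnmd_id, fc$source_id)]
  val <- select_best(val)
  val <- val[order(val$local_id, val$fnmd_id), , drop = FALSE]
  rownames(val) <- NULL
  list(pairs = val,
       counts = c(n_local = nrow(lc), n_fnmd = nrow(fc),
                  n_candidates = nrow(cand),
                  n_candidates_date = n_cand_date,
                  n_candidates_name = n_cand_name,
                  n_validated = nrow(val),
                  n_selected = sum(val$selected)))
}

.run_direct <- function(local, fnmd) {
  kl <- .direct_key(local$birth_surname, local$current_surname,
                    local$first_name, local$birth_date, local$sex)
  kf <- .direct_key(fnmd$surname, NA_character_, fnmd$first_name,
                    fnmd$birth_date, fnmd$sex)
  l <- data.frame(key = kl, local_id = as.character(local$record_id),
                  stringsAsFactors = FALSE)
  f <- data.frame(key = kf, fnmd_id = as.character(fnmd$fnmd_id),
                  death_date = as.character(fnmd$death_date),
                  stringsAsFactors = FALSE)
  m <- merge(l, f, by = "key")[c("local_id", "fnmd_id", "death_date")]
  if (nrow(m)) {
    m$d_first <- m$d_surname <- m$d_date <- m$d_sex <- m$d_total <- 0L
    m$d_city <- NA_integer_
  } else {
    m$d_first <- m$d_surname <- m$d_date <- m$d_sex <- m$d_total <-
      integer(0)
    m$d_city <- integer(0)
  }
  m <- select_best(m)
  m <- m[order(m$local_id, m$fnmd_id),
         c("local_id", "fnmd_id", "d_first", "d_surname", "d_date", "d_sex",
           "d_total", "d_city", "death_date", "selected", "ambiguous")]
  rownames(m) <- NULL
  list(pairs = m,
       counts = c(n_local = nrow(local), n_fnmd = nrow(fnmd),
                  n_candidates = nrow(m), n_candidates_date = NA,
                  n_candidates_name = NA, n_validated = nrow(m),
                  n_selected = sum(m$selected)))
}

#' Run a full matching strategy over two registries
#'
#' Low-level, single-pass runner: `"dld"` performs cleaning, two-pass
#' blocking, distance computation, threshold validation and best-pair
#' selection; `"direct"` performs the exact-key reference join. Prefer
#' [link_records()], which adds chunking, parallel workers and the result
#' class.
#'
#' @param local `person_records` data.frame.
#' @param fnmd `mortality_records` data.frame.
#' @param strategy `"dld"` or `"direct"`.
#' @param thresholds a [dld_thresholds()] (dld strategy only).
#' @param home_country home-country token for `country_group`.
#' @return list with `pairs` (retained pairs with distances and selection
#'   flags) and `counts` (summary counts).
#' @export
run_strategy <- function(local, fnmd, strategy = c("dld", "direct"),
                         thresholds = dld_thresholds(),
                         home_country = "france") {
  strategy <- match.arg(strategy)
  if (strategy == "dld") .run_dld(local, fnmd, thresholds, home_country)
  else .run_direct(local, fnmd)
}
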