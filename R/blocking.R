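# Candidate-pair generation.
#
# Two successive simple blocking passes: records are compared only if they
# share the exact birth date, or the exact concatenation of the first 4
# letters of the first name and the first 4 letters of the preferred
# surname. The candidate set is the union of the two passes, deduplicated.
# A pair mismatching on one key can still be compared through the other;
# only pairs mismatching on both are never compared.

.join_on_key <- function(local_clean, fnmd_clean, key) {
  lk <- local_clean[[key]]
  fk <- fnmd_clean[[key]]
  l <- data.frame(key = lk, local_id = local_clean$source_id,
                  stringsAsFactors = FALSE)
  f <- data.frame(key = fk, fnmd_id = fnmd_clean$source_id,
                  stringsAsFactors = FALSE)
  l <- l[!is.na(l$key) & nzchar(l$key), , drop = FALSE]
  f <- f[!is.na(f$key) & nzchar(f$key), , drop = FALSE]
  m <- merge(l, f, by = "key")
  m[c("local_id", "fnmd_id")]
}

#' Generate candidate pairs by two-pass blocking
#'
#' Emits a candidate pair for every (local, mortality) combination whose
#' cleaned records agree exactly on the repaired birth date (`date_block`)
#' or on the 4+4 first-name/surname prefix key (`name_block`). Pairs
#' qualifying under both keys appear once, with both passes recorded.
#'
#' @param local_clean,fnmd_clean `clean_records` tables.
#' @return data.frame with columns `local_id`, `fnmd_id`, `by_date`,
#'   `by_name` (logicals, at least one `TRUE` per row), deduplicated and
#'   sorted by (local_id, fnmd_id).
#' @export
block_pairs <- function(local_clean, fnmd_clean) {
  d <- .join_on_key(local_clean, fnmd_clean, "key_date")
  n <- .join_on_key(local_clean, fnmd_clean, "key_name")
  d$by_date <- rep(TRUE, nrow(d))
  n$by_name <- rep(TRUE, nrow(n))
  both <- merge(d, n, by = c("local_id", "fnmd_id"), all = TRUE)
  both$by_date <- !is.na(both$by_date)
  both$by_name <- !is.na(both$by_name)
  both <- both[order(both$local_id, both$fnmd_id), , drop = FALSE]
  rownames(both) <- NULL
  both
}
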