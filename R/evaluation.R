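# Stratified sensitivity/specificity evaluation and paired strategy
# comparison.
#
# Design: sensitivity is measured on gold-standard deaths inside the death
# window; specificity on patients proven alive at an index date (hospital
# encounters on both sides of it), counting only links to deaths registered
# BEFORE the index date as false positives — a link to a later death is a
# patient who genuinely died after the index date, not an error.

#' Evaluation design parameters
#'
#' @param index_date date at which specificity-set patients are known
#'   alive (default `"2016-01-01"`).
#' @param window_start,window_end death window for the sensitivity set
#'   (defaults 2001-01-01 and 2020-12-31).
#' @param pct_born_outside percentage (0-100) of the reference population
#'   born outside the home country; used to weight the four strata (sex x
#'   birth country), with the sexes weighted half each.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return object of class `evaluation_config`.
#' @export
evaluation_config <- function(index_date = "2016-01-01",
                              window_start = "2001-01-01",
                              window_end = "2020-12-31",
                              pct_born_outside = 8,
                              conf_level = 0.95) {
  if (!is.numeric(pct_born_outside) || pct_born_outside < 0 ||
      pct_born_outside > 100)
    stop("pct_born_outside must be a percentage in [0, 100]", call. = FALSE)
  structure(list(index_date = as.Date(index_date),
                 window_start = as.Date(window_start),
                 window_end = as.Date(window_end),
                 pct_born_outside = pct_born_outside,
                 conf_level = conf_level),
            class = "evaluation_config")
}

#' Stratum weights from a born-outside percentage
#'
#' The four strata are sex x birth country. Sexes weigh half each; within
#' each sex the born-outside stratum weighs `pct/100` and the born-in
#' stratum the complement, so the weights sum to 1.
#'
#' @param pct_born_outside percentage (0-100).
#' @return named numeric vector over `m_bif`, `f_bif`, `m_bof`, `f_bof`.
#' @export
#' @examples
#' stratum_weights(4.5)  # 0.4775 0.4775 0.0225 0.0225
stratum_weights <- function(pct_born_outside) {
  w <- pct_born_outside / 100
  c(m_bif = (1 - w) / 2, f_bif = (1 - w) / 2,
    m_bof = w / 2, f_bof = w / 2)
}

#' Percentage of a census population born outside the home country
#'
#' @param born_outside,total census counts, `0 < born_outside <= total`.
#' @return `100 * born_outside / total`.
#' @export
#' @examples
#' census_weight(40394, 897639)  # 4.5 (Nantes, 2012 census)
census_weight <- function(born_outside, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(born_outside < 0 | born_outside > total))
    stop("born_outside must be in (0, total]", call. = FALSE)
  100 * born_outside / total
}

#' Detection status of gold-standard deceased records
#'
#' A deceased gold-standard record counts as detected (true positive) iff
#' the linkage selected at least one pair for it whose death date lies in
#' the death window.
#'
#' @param gold data.frame with `record_id` for the deceased records.
#' @param pairs pair data.frame (with `selected` and `death_date`).
#' @param config an [evaluation_config()].
#' @return logical vector along `gold$record_id`.
#' @export
classify_for_sensitivity <- function(gold, pairs,
                                     config = evaluation_config()) {
  sel <- pairs[pairs$selected, , drop = FALSE]
  dd <- as.Date(sel$death_date)
  inwin <- !is.na(dd) & dd >= config$window_start & dd <= config$window_end
  gold$record_id %in% sel$local_id[inwin]
}

#' Non-linkage status of gold-standard living records
#'
#' A living-at-index gold-standard record counts as a true negative iff it
#' is not linked (selected pair) to any death dated before the index date.
#' Links to post-index deaths do not count against specificity: the patient
#' was alive at the index date and died later.
#'
#' @param gold data.frame with `record_id` for the living records.
#' @param pairs pair data.frame.
#' @param config an [evaluation_config()].
#' @return logical vector: `TRUE` = true negative.
#' @export
classify_for_specificity <- function(gold, pairs,
                                     config = evaluation_config()) {
  sel <- pairs[pairs$selected, , drop = FALSE]
  dd <- as.Date(sel$death_date)
  pre <- !is.na(dd) & dd < config$index_date
  !(gold$record_id %in% sel$local_id[pre])
}

#' Weighted overall proportion with a confidence interval
#'
#' Stratified-sampling-proportion estimator: point estimate
#' `sum(w_s * p_s)`; variance `sum(w_s^2 * p_s (1 - p_s) / n_s)`; Wald
#' interval clipped to `[0, 1]`.
#'
#' @param p per-stratum proportions.
#' @param n per-stratum sample sizes (all >= 1).
#' @param weights per-stratum weights summing to 1 (tolerance 1e-9).
#' @param conf_level confidence level.
#' @return list with `estimate`, `se`, `lower`, `upper`.
#' @export
#' @examples
#' weighted_performance(c(0.9, 0.8, 0.95, 0.85), c(100, 100, 100, 100),
#'                      c(0.4775, 0.4775, 0.0225, 0.0225))
weighted_performance <- function(p, n, weights, conf_level = 0.95) {
  if (length(p) != length(n) || length(p) != length(weights))
    stop("p, n and weights must have the same length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("stratum weights must sum to 1", call. = FALSE)
  if (any(n < 1)) stop("every stratum needs n >= 1", call. = FALSE)
  est <- sum(weights * p)
  v <- sum(weights^2 * p * (1 - p) / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(estimate = est, se = sqrt(v),
       lower = max(0, est - z * sqrt(v)),
       upper = min(1, est + z * sqrt(v)))
}

#' McNemar test on paired classification outcomes
#'
#' Compares two strategies classified on the same gold-standard records.
#' With discordant counts `b` (first right, second wrong) and `c` (the
#' reverse), the continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)`
#' is referred to chi-square with 1 df; when `b + c < 25` the p-value is
#' instead the exact binomial two-sided probability. With no discordant
#' pairs the test is degenerate and `p = 1`.
#'
#' @param x,y logical vectors of per-record correctness for the two
#'   strategies.
#' @return list with `b`, `c`, `statistic`, `p_value`, `method`,
#'   `degenerate`.
#' @export
mcnemar_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  b <- sum(x & !y)
  cc <- sum(!x & y)
  nd <- b + cc
  if (nd == 0L)
    return(list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  stat <- (abs(b - cc) - 1)^2 / nd
  if (nd < 25L) {
    p <- min(1, 2 * pbinom(min(b, cc), nd, 0.5))
    method <- "exact binomial"
  } else {
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-square"
  }
  list(b = b, c = cc, statistic = stat, p_value = p, method = method,
       degenerate = FALSE)
}

.eval_measure <- function(gold, pairs, config, truth_value, classify) {
  g <- gold[gold$truth == truth_value, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  ok <- classify(g, pairs, config)
  strata <- sort(unique(g$stratum))
  per <- data.frame(stratum = strata,
                    n = vapply(strata, function(s) sum(g$stratum == s), 0L),
                    p = vapply(strata, function(s)
                      mean(ok[g$stratum == s]), 0),
                    stringsAsFactors = FALSE)
  z <- qnorm(1 - (1 - config$conf_level) / 2)
  per$se <- sqrt(per$p * (1 - per$p) / per$n)
  per$lower <- pmax(0, per$p - z * per$se)
  per$upper <- pmin(1, per$p + z * per$se)
  w <- stratum_weights(config$pct_born_outside)
  missing_strata <- setdiff(names(w), per$stratum)
  if (length(missing_strata) == 0L) {
    ww <- w[per$stratum]
    overall <- weighted_performance(per$p, per$n, ww, config$conf_level)
  } else {
    # fall back to the unweighted pooled proportion when the gold standard
    # does not carry the full sex x birth-country design
    pp <- mean(ok)
    nn <- length(ok)
    se <- sqrt(pp * (1 - pp) / nn)
    overall <- list(estimate = pp, se = se,
                    lower = max(0, pp - z * se), upper = min(1, pp + z * se))
  }
  list(per_stratum = per, overall = overall, outcomes = ok,
       record_id = g$record_id)
}

#' Evaluate a linkage against a gold standard
#'
#' Computes per-stratum and weighted overall sensitivity (on the deceased
#' gold records) and specificity (on the living-at-index records), with
#' confidence intervals.
#'
#' @param object a `linkage` object or a pair data.frame.
#' @param gold gold-standard data.frame with columns `record_id`, `truth`
#'   (`"deceased"` / `"living"`), `stratum` (`m_bif`, `f_bif`, `m_bof`,
#'   `f_bof`).
#' @param config an [evaluation_config()].
#' @return object of class `linkage_evaluation`: per-stratum tables,
#'   overall estimates and the raw per-record outcome vectors.
#' @export
evaluate_linkage <- function(object, gold, config = evaluation_config()) {
  pairs <- if (inherits(object, "linkage")) object$pairs else object
  sens <- .eval_measure(gold, pairs, config, "deceased",
                        classify_for_sensitivity)
  spec <- .eval_measure(gold, pairs, config, "living",
                        classify_for_specificity)
  structure(list(sensitivity = sens, specificity = spec, config = config),
            class = "linkage_evaluation")
}

.fmt_pct <- function(est, lower, upper) {
  sprintf("%.1f%% (%.1f-%.1f)", 100 * est, 100 * lower, 100 * upper)
}

#' @export
print.linkage_evaluation <- function(x, ...) {
  cat("Linkage evaluation (weights: born outside",
      paste0(x$config$pct_born_outside, "%,"), "sexes 1/2 each)\n")
  for (m in c("sensitivity", "specificity")) {
    part <- x[[m]]
    if (is.null(part)) next
    o <- part$overall
    cat(sprintf("  %-11s %s\n", m, .fmt_pct(o$estimate, o$lower, o$upper)))
    for (i in seq_len(nrow(part$per_stratum))) {
      r <- part$per_stratum[i, ]
      cat(sprintf("    %-7s n=%-5d %s\n", r$stratum, r$n,
                  .fmt_pct(r$p, r$lower, r$upper)))
    }
  }
  invisible(x)
}

#' Compare two strategies on the same gold standard
#'
#' Runs [mcnemar_paired()] on the per-record sensitivity outcomes and on
#' the per-record specificity outcomes of two evaluations of the same gold
#' standard.
#'
#' @param eval1,eval2 `linkage_evaluation` objects for the same `gold`.
#' @return list with elements `sensitivity` and `specificity`, each a
#'   [mcnemar_paired()] result (or `NULL` when the measure is absent).
#' @export
compare_strategies <- function(eval1, eval2) {
  cmp <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NULL)
    if (!identical(a$record_id, b$record_id))
      stop("evaluations do not cover the same records", call. = FALSE)
    mcnemar_paired(a$outcomes, b$outcomes)
  }
  list(sensitivity = cmp(eval1$sensitivity, eval2$sensitivity),
       specificity = cmp(eval1$specificity, eval2$specificity))
}
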