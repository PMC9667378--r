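profile_row <- function(f, s, d, x, city = NA_integer_) {
  data.frame(d_first = f, d_surname = s, d_date = d, d_sex = x,
             d_total = f + s + d + x, d_city = city)
}

test_that("validation applies every per-field bound and the total bound", {
  t <- dld_thresholds()
  expect_true(validate_pair(profile_row(0, 0, 0, 0), t))
  expect_true(validate_pair(profile_row(0, 1, 0, 1), t))   # total exactly 2
  expect_false(validate_pair(profile_row(3, 0, 0, 0), t))  # first bound
  expect_false(validate_pair(profile_row(2, 1, 0, 0), t))  # total only
  expect_false(validate_pair(profile_row(0, 2, 0, 0), t))  # surname bound
  # vectorised
  p <- rbind(profile_row(1, 0, 1, 0), profile_row(2, 1, 1, 1))
  expect_identical(validate_pair(p, t), c(TRUE, FALSE))
})

test_that("threshold construction enforces the total-bound invariant", {
  expect_error(dld_thresholds(max_total = 7), "max_total")
  expect_error(dld_thresholds(max_first = -1), "non-negative")
  t5 <- dld_thresholds(max_total = 5)
  expect_identical(t5$max_total, 5L)
})

test_that("direct matching requires exact equality after minimal cleaning", {
  l <- person_df(record_id = "l", birth_surname = "Lefèvre",
                 current_surname = "Martin", first_name = "Élise",
                 birth_date = "1950-03-21", sex = "f")
  f_same <- mortality_df(fnmd_id = "f", surname = "Lefevre",
                         first_name = "Elise", birth_date = "1950-03-21",
                         sex = "f")
  expect_true(direct_match(l, f_same))       # accents/case ignored
  f_typo <- f_same
  f_typo$surname <- "Lefevro"
  expect_false(direct_match(l, f_typo))
  f_date <- f_same
  f_date$birth_date <- "1950-21-03"          # no date repair in direct mode
  expect_false(direct_match(l, f_date))
  # current surname used only when birth surname is absent
  l2 <- l
  l2$birth_surname <- NA
  f_cur <- f_same
  f_cur$surname <- "Martin"
  expect_true(direct_match(l2, f_cur))
  expect_false(direct_match(l, f_cur))
})

test_that("best-pair selection: minimal total, then city, then flagged tie", {
  one <- data.frame(local_id = "a", fnmd_id = "f1", d_total = 2L,
                    d_city = NA_integer_, death_date = "2010-01-01")
  s <- select_best(one)
  expect_true(s$selected && !s$ambiguous)

  totals <- data.frame(local_id = "a", fnmd_id = c("f1", "f2"),
                       d_total = c(0L, 2L), d_city = NA_integer_,
                       death_date = "2010-01-01")
  s <- select_best(totals)
  expect_identical(s$fnmd_id[s$selected], "f1")
  expect_false(any(s$ambiguous))

  city <- data.frame(local_id = "a", fnmd_id = c("f1", "f2"),
                     d_total = 1L, d_city = c(3L, 0L),
                     death_date = "2010-01-01")
  s <- select_best(city)
  expect_identical(s$fnmd_id[s$selected], "f2")

  # missing city distance sorts after any defined one
  cityna <- data.frame(local_id = "a", fnmd_id = c("f1", "f2"),
                       d_total = 1L, d_city = c(NA, 4L),
                       death_date = "2010-01-01")
  s <- select_best(cityna)
  expect_identical(s$fnmd_id[s$selected], "f2")

  tie <- data.frame(local_id = "a", fnmd_id = c("f2", "f1"),
                    d_total = 1L, d_city = 0L,
                    death_date = c("2011-05-05", "2009-01-01"))
  s <- select_best(tie)
  expect_true(all(s$ambiguous))
  expect_identical(s$fnmd_id[s$selected], "f1")  # earliest death date first
  expect_identical(sum(s$selected), 1L)
})

test_that("selection keeps at most one selected pair per local record", {
  coh <- simulate_cohort(200, seed = 23)
  fit <- link_records(coh$person, coh$mortality)
  per_local <- tapply(fit$pairs$selected, fit$pairs$local_id, sum)
  expect_true(all(per_local <= 1))
})

test_that("strategy runs classify deceased records as the spec of each", {
  # exact subset, no noise: both strategies find every deceased local
  model0 <- error_model(typo_first = 0, typo_surname = 0, typo_date = 0,
                        daymonth_swap = 0, missing_daymonth = 0,
                        married_name = 0, birth_surname_omitted = 0,
                        compound_first = 0.2, middle_name = 0.5,
                        local_truncate = 0, local_concat = 0,
                        sex_error = 0, accent_keep = 1,
                        district_suffix = 0, born_outside = 0.1,
                        decoy_rate = 0, background_rate = 0,
                        near_twin_rate = 0, homonym_twin_rate = 0,
                        post_index_death = 0)
  coh <- simulate_cohort(120, model = model0, seed = 29)
  dead <- coh$gold$record_id[coh$gold$truth == "deceased"]
  for (strat in c("dld", "direct")) {
    fit <- link_records(coh$person, coh$mortality, strategy = strat)
    expect_true(all(dead %in% matched_ids(fit)), label = strat)
  }

  # empty mortality file: nobody linked
  empty <- coh$mortality[0, , drop = FALSE]
  expect_length(matched_ids(link_records(coh$person, empty)), 0L)

  # one-substitution surname noise: distance strategy holds, direct fails
  noisy <- coh$mortality
  set.seed(31)
  noisy$surname <- vapply(noisy$surname, corrupt_field, character(1),
                          kind = "substitution")
  expect_true(all(dead %in%
                    matched_ids(link_records(coh$person, noisy))))
  expect_length(matched_ids(link_records(coh$person, noisy,
                                         strategy = "direct")), 0L)
})

test_that("raising thresholds never removes a validated pair", {
  coh <- simulate_cohort(150, seed = 37)
  lc <- clean_records(coh$person, "local")
  fc <- clean_records(coh$mortality, "fnmd")
  cand <- field_distances(lc, fc, block_pairs(lc, fc))
  prev <- 0L
  for (mt in 0:5) {
    t <- dld_thresholds(max_total = mt)
    now <- sum(validate_pair(cand, t))
    expect_gte(now, prev)
    prev <- now
  }
  # wider per-field bounds also only add pairs
  ok_def <- validate_pair(cand, dld_thresholds())
  ok_wide <- validate_pair(cand, dld_thresholds(3, 2, 2, 1, 5))
  expect_true(all(ok_wide[ok_def]))
})

test_that("every direct match is also a distance match at defaults", {
  coh <- simulate_cohort(250, seed = 41)
  direct <- link_records(coh$person, coh$mortality, strategy = "direct")
  fit <- link_records(coh$person, coh$mortality)
  expect_true(all(matched_ids(direct) %in% matched_ids(fit)))
})
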