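test_that("generation is reproducible and honours the stratum design", {
  a <- simulate_cohort(100, seed = 101)
  b <- simulate_cohort(100, seed = 101)
  expect_identical(a$person, b$person)
  expect_identical(a$mortality, b$mortality)
  expect_identical(a$gold, b$gold)
  c2 <- simulate_cohort(100, seed = 102)
  expect_false(identical(a$person, c2$person))

  # exact design: deceased fraction, sexes, born-outside counts
  tab <- table(a$gold$truth, a$gold$stratum)
  expect_identical(sum(a$gold$truth == "deceased"), 50L)
  m <- error_model()
  per_sex <- 25L
  expect_identical(unname(tab["deceased", "m_bof"]),
                   as.integer(round(per_sex * m$born_outside)))
  expect_identical(unname(tab["living", "f_bif"]),
                   per_sex - as.integer(round(per_sex * m$born_outside)))
})

test_that("every deceased local has exactly one true mortality counterpart", {
  coh <- simulate_cohort(150, seed = 103)
  dead <- coh$gold[coh$gold$truth == "deceased", ]
  expect_false(anyNA(dead$true_fnmd_id))
  expect_false(any(duplicated(dead$true_fnmd_id)))
  expect_true(all(dead$true_fnmd_id %in% coh$mortality$fnmd_id))
  liv <- coh$gold[coh$gold$truth == "living", ]
  expect_false(anyNA(liv$encounter_pre))
  expect_true(all(as.Date(liv$encounter_pre) < as.Date("2016-01-01")))
  expect_true(all(as.Date(liv$encounter_post) > as.Date("2016-01-01")))
})

test_that("single-field corruption lands at distance exactly one", {
  set.seed(107)
  words <- c("dupont", "a", "19500321", "marie", "aa")
  for (w in words) {
    for (k in c("insertion", "deletion", "substitution")) {
      out <- corrupt_field(w, k)
      expect_identical(dld(w, out), 1L, label = paste(w, k))
    }
  }
  expect_identical(corrupt_field("a", "deletion"), "")
  expect_identical(dld("ab", corrupt_field("ab", "transposition")), 1L)
  expect_error(corrupt_field("", "deletion"), "impossible")
  expect_error(corrupt_field("aa", "transposition"), "impossible")
  # random kind, many draws, digits stay digits
  for (i in 1:50) {
    out <- corrupt_field("19611224")
    expect_identical(dld("19611224", out), 1L)
    expect_true(grepl("^[0-9]*$", out))
  }
})

test_that("stacked corruption stays within k edits of the original", {
  # each corruption step moves exactly one restricted-DLD unit; a chain of
  # k insert/delete/substitute steps therefore stays within k (chains
  # containing transpositions can exceed k under the restricted distance,
  # whose optimal alignment may not reuse a transposed block)
  set.seed(109)
  for (i in 1:40) {
    w <- paste0(sample(letters, sample(4:10, 1), replace = TRUE),
                collapse = "")
    k <- sample(1:3, 1)
    out <- w
    for (j in seq_len(k)) {
      kind <- sample(c("insertion", "deletion", "substitution"), 1)
      nxt <- if (nzchar(out)) corrupt_field(out, kind)
             else corrupt_field(out, "insertion")
      expect_identical(dld(out, nxt), 1L)
      out <- nxt
    }
    expect_lte(dld(w, out), k)
  }
})

test_that("error-model switches steer the generated corruption", {
  base <- error_model(typo_first = 0, typo_surname = 0, typo_date = 0,
                      daymonth_swap = 0, married_name = 0,
                      birth_surname_omitted = 0, sex_error = 0,
                      decoy_rate = 0, background_rate = 0,
                      near_twin_rate = 0, homonym_twin_rate = 0,
                      post_index_death = 0, missing_daymonth = 1)
  coh <- simulate_cohort(60, model = base, seed = 113)
  expect_true(all(grepl("-00-00$", coh$mortality$birth_date)))

  none <- error_model(typo_first = 0, typo_surname = 0, typo_date = 0,
                      daymonth_swap = 0, married_name = 0,
                      birth_surname_omitted = 0, sex_error = 0,
                      decoy_rate = 0, background_rate = 0,
                      near_twin_rate = 0, homonym_twin_rate = 0,
                      post_index_death = 0, missing_daymonth = 0,
                      compound_first = 0, middle_name = 0,
                      local_truncate = 0, local_concat = 0,
                      district_suffix = 0, accent_keep = 1)
  coh0 <- simulate_cohort(60, model = none, seed = 113)
  # mortality file is exactly the accent-stripped deceased records
  dead <- coh0$person[coh0$person$vital_status == "deceased", ]
  mort <- coh0$mortality[match(
    coh0$gold$true_fnmd_id[coh0$gold$truth == "deceased"],
    coh0$mortality$fnmd_id), ]
  expect_identical(nrow(mort), nrow(dead))
  expect_identical(mort$surname, strip_accents(dead$birth_surname))
  expect_identical(mort$birth_date, dead$birth_date)
  expect_identical(mort$sex, dead$sex)

  expect_error(error_model(typo_first = 1.5), "\\[0, 1\\]")
  expect_error(simulate_cohort(0), ">= 1")
  expect_error(simulate_cohort(10, deceased_fraction = 2), "deceased_fraction")
})

test_that("written cohorts read back through the io layer", {
  coh <- simulate_cohort(80, seed = 127)
  dir <- tempfile()
  write_cohort(coh, dir)
  p <- read_person_table(file.path(dir, "local.csv"))
  m <- read_mortality_table(file.path(dir, "mortality.csv"))
  expect_identical(p$record_id, coh$person$record_id)
  expect_identical(m$fnmd_id, coh$mortality$fnmd_id)
  expect_identical(p$birth_surname, coh$person$birth_surname)
  expect_true(file.exists(file.path(dir, "error_model.yaml")))
  # linkage agrees whether run in memory or from the written files
  fit_mem <- link_records(coh$person, coh$mortality)
  fit_file <- link_records(p, m)
  expect_identical(fit_mem$pairs$fnmd_id, fit_file$pairs$fnmd_id)
})
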