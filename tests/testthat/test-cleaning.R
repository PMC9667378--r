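test_that("text normalisation keeps only lowercase unaccented letters", {
  expect_identical(normalize_text("Pierre-Olivier"), "pierreolivier")
  expect_identical(normalize_text("Élise 2"), "elise")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("Jean-François N°3"), "jeanfrancoisn")
  expect_identical(normalize_text("Hélène Œdipe ßaß"),
                   "heleneoedipessass")
  expect_identical(normalize_text(NA), NA_character_)
  # idempotence on a batch of already-cleaned strings
  set.seed(11)
  raw <- c("Müller", "de l'Isle", "SAINT-ÉTIENNE", random_strings(50, 10))
  once <- normalize_text(raw)
  expect_identical(normalize_text(once), once)
  expect_true(all(grepl("^[a-z]*$", once)))
})

test_that("birth-date repair follows the 00-00 / swap / fallback rules", {
  expect_identical(repair_birth_date("1956-00-00"), "19560101")
  expect_identical(repair_birth_date("1960-31-03"), "19600331")
  expect_identical(repair_birth_date("1959-32-33"), "19590101")
  # valid dates pass through unchanged
  expect_identical(repair_birth_date("1950-03-21"), "19500321")
  expect_identical(repair_birth_date("2000-02-29"), "20000229")  # leap day
  expect_identical(repair_birth_date("1999-02-29"), "19990101")  # not leap
  # partial zero day falls back to January 1 via the same cascade
  expect_identical(repair_birth_date("1970-05-00"), "19700101")
  expect_identical(repair_birth_date("1970-00-15"), "19700101")
  expect_identical(repair_birth_date(NA), NA_character_)
  expect_error(repair_birth_date("not a date"), "4-digit year")
})

test_that("repaired dates are always valid calendar dates", {
  set.seed(21)
  y <- sample(1900:2020, 300, replace = TRUE)
  m <- sample(0:39, 300, replace = TRUE)
  d <- sample(0:39, 300, replace = TRUE)
  raw <- sprintf("%04d-%02d-%02d", y, m, d)
  rep8 <- repair_birth_date(raw)
  expect_true(all(grepl("^[0-9]{8}$", rep8)))
  parsed <- as.Date(rep8, format = "%Y%m%d")
  expect_false(anyNA(parsed))
  # when the original date was already valid it must be kept
  valid <- !is.na(as.Date(raw, format = "%Y-%m-%d"))
  expect_identical(rep8[valid], gsub("-", "", raw[valid]))
})

test_that("district mentions are suppressed from city names", {
  expect_identical(clean_city("Paris, 13ème arrondissement"), "paris")
  expect_identical(clean_city("Lyon 3e"), "lyon")
  expect_identical(clean_city("Marseille 2eme arrondissement"), "marseille")
  expect_identical(clean_city("Nantes"), "nantes")
  expect_identical(clean_city("Saint-Étienne"), "saintetienne")
})

test_that("abbreviation tokens expand before normalisation", {
  expect_identical(expand_city_abbrev("St-Martin-sr-Ocre"),
                   "saintmartinsurocre")
  expect_identical(expand_city_abbrev("Ste-Anne"), "sainteanne")
  expect_identical(expand_city_abbrev("bordeaux"), "bordeaux")
  expect_identical(expand_city_abbrev("Neuilly s/ Seine"),
                   "neuillysurseine")
  custom <- c(vn = "villeneuve")
  expect_identical(expand_city_abbrev("Vn-les-Avignon", table = custom),
                   "villeneuvelesavignon")
})

test_that("first-name variants follow the compound/middle-name rules", {
  v <- build_firstname_variants(
    c("Jean", "Marie", "Pierre-Olivier", "Elon-Louis"),
    c(NA, "Claire", "Christian", NA))
  expect_identical(v$firstname_0, c("jean", "marie", "pierre", "elon"))
  expect_identical(v$firstname_1,
                   c("jean", "marie", "pierreolivier", "elonlouis"))
  expect_identical(v$firstname_12,
                   c("jean", "marieclaire", "pierreolivierchristian",
                     "elonlouis"))
  expect_error(build_firstname_variants("  2  ", NA), "empty after")
})

test_that("variant containment holds on random name material", {
  set.seed(31)
  pools <- c("Jean", "Marie-Claire", "Élise", "Pierre-Olivier", "Anne Lise",
             "Loïc", "François-Xavier")
  first <- sample(pools, 60, replace = TRUE)
  mid <- sample(c(pools, NA, NA), 60, replace = TRUE)
  v <- build_firstname_variants(first, mid)
  expect_true(all(startsWith(v$firstname_1, v$firstname_0)))
  expect_true(all(startsWith(v$firstname_12, v$firstname_1)))
})

test_that("clean_records builds blocking keys and preferred surname", {
  p <- person_df(record_id = c("a", "b"),
                 first_name = c("Jean", "Ana"),
                 birth_surname = c(NA, "Li"),
                 current_surname = c("Dupont", NA),
                 birth_date = c("1950-03-21", "1980-26-11"),
                 sex = c("m", "f"))
  cl <- clean_records(p, "local")
  expect_identical(cl$key_name, c("jeandupo", "anali"))
  expect_identical(cl$key_date, c("19500321", "19801126"))
  # birth surname preferred over current when both present
  p2 <- person_df(record_id = "c", first_name = "Luc",
                  birth_surname = "Morel", current_surname = "Blanc",
                  birth_date = "1970-01-02", sex = "m")
  expect_identical(clean_records(p2, "local")$key_name, "lucmore")
})

test_that("clean_records handles both sides' specific fields", {
  m <- mortality_df(fnmd_id = "f1", surname = "Durand",
                    first_name = "Elon-Louis", birth_date = "1940-11-26",
                    sex = "m", birth_city = "Paris, 13ème arrondissement",
                    birth_country = "France")
  cm <- clean_records(m, "fnmd")
  expect_identical(cm$firstname_12, "elonlouis")
  expect_identical(cm$city, "paris")
  expect_true(is.na(cm$city_expanded))       # expansion is local-side only
  expect_identical(cm$country_group, "france")

  p <- person_df(record_id = "p1", first_name = "Jean",
                 birth_surname = "Roux", birth_date = "1950-01-01",
                 sex = "m", birth_city = "St-Martin-sr-Ocre",
                 birth_country = "Algérie")
  cp <- clean_records(p, "local")
  expect_identical(cp$city_expanded, "saintmartinsurocre")
  expect_identical(cp$firstname_12, cp$firstname_1)
  expect_identical(cp$country_group, "other")
})

test_that("cleaning a cleaned record changes nothing", {
  coh <- simulate_cohort(60, seed = 5)
  cl <- clean_records(coh$person, "local")
  for (col in c("firstname_0", "firstname_1", "firstname_12",
                "surname_birth", "surname_current", "city"))
    expect_identical(normalize_text(cl[[col]]), cl[[col]], label = col)
  expect_identical(repair_birth_date(cl$birth_date8), cl$birth_date8)
})
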